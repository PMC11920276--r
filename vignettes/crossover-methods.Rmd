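---
title: "Models and methods behind crossim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind crossim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

crossim studies individual variation in meiotic recombination from
SNP-array data in pedigreed populations. This vignette documents the models
the package implements, the assumptions they make, the tunable parameters
that matter, and the numerical and design choices taken where the problem
was genuinely open. It states no empirical result that the package's tests
and acceptance script do not themselves compute.

## The crossover process model

Crossovers are modelled on the genetic (Morgan) scale, because interference
acts along the synaptonemal complex, whose length tracks genetic rather
than physical distance. The generating model (and the fitted likelihood) is
the Houseworth–Stahl interference-escape process:

- **Class I (interfering) events.** Chiasmata form on the four-strand
  bivalent as a *stationary gamma renewal process* with shape ν and rate
  2ν(1 − p) per Morgan. Each chiasma is passed to a given gamete
  independently with probability 1/2 ("thinning"; chromatid interference is
  assumed absent). The thinned inter-arrival density is the geometric
  mixture Σ_k (1/2)^k Gamma(kν, 2ν(1 − p)).
- **Class II (escaping) events.** A homogeneous Poisson process with
  gamete-scale rate p per Morgan is superposed.

The rates are normalized so the expected gamete crossover count equals the
chromosome length in Morgans for *every* (ν, p): interference redistributes
crossovers, it does not change the map length. ν = 1 collapses to a Poisson
process; ν ≈ 6–10 is the mammalian range.

**Stationarity.** The fitted likelihood assumes the renewal process is in
equilibrium at the chromosome start. The simulator realizes this by
starting the chiasma process 30 mean inter-arrivals plus 2 Morgans before
the origin and discarding events left of it, rather than drawing the first
interval from the closed-form length-biased distribution. The two are
equivalent in distribution up to an error that decays geometrically in the
burn-in length and is far below Monte-Carlo noise here; the burn-in is
simpler and correct for non-integer ν, where the equilibrium distribution
has no convenient sampler.

## The single-gamete likelihood

For one gamete chromosome of length L Morgans with ordered crossovers
x₁ < … < x_m, the likelihood sums over all 2^m assignments of crossovers to
Class I/II. A Class I subset {a₁ < … < a_j} contributes

ρ·S*(a₁) · Π f*(a_{i+1} − a_i) · S*(L − a_j),

with ρ = 1 − p, f* the thinned inter-arrival density above and S* its
survival function; ρ·S*(·) is the stationary forward-recurrence density and
the last factor right-censors the unfinished interval. An empty Class I
subset contributes the stationary void probability
S_eq(L) = 1 − ρ∫₀ᴸ S*(u)du, evaluated in closed form through incomplete
gamma integrals. A Class II subset of size b contributes p^b e^{−pL}.

Numerical choices:

- The geometric series is truncated where the (1/2)^k weight falls below
  1e-12 (k = 40), with an additional data-driven cut: terms whose gamma
  component has mass below 1e-13 left of the largest evaluated distance are
  dropped and their weight folded into an exact geometric tail for survival
  functions. This keeps full double precision while making the evaluation
  cost scale with the data rather than the worst case.
- The 2^m partition sum is computed exactly; m rarely exceeds 5 on
  chromosome-scale data, and configurations with m > 20 are rejected with
  an error rather than approximated.
- At ν = 1, p = 0 every configuration has log-likelihood exactly −L; this
  Poisson reduction is asserted in the test suite to 1e-8 and anchors the
  start/gap/censoring bookkeeping.

**Fitting.** `fit_stahl()` pools all of an individual's gamete chromosomes
with equal weight (chromosomes without crossovers included — they carry
rate and interference information). A coarse grid (ν log-spaced in
[0.5, 50], p in {0, 0.02, …, 0.2}) seeds a Nelder–Mead polish on
(log ν, t) with p = 0.5·t²/(1+t²), a transform that makes the p = 0
boundary an interior point so boundary solutions are found smoothly.
Standard errors come from a central finite-difference Hessian and are
reported but never used for gating. `fit_gamma()` is the p = 0 submodel;
its maximized log-likelihood can never exceed the Stahl fit's, which the
tests assert.

## Crossover calling

Real pipelines phase parents population-wise; crossim replaces that step
with phase-known parental haplotypes (from the simulator, or external
phasing for real data — a documented requirement). At each marker where the
focal parent is heterozygous, the transmitted haplotype is inferred when
the offspring genotype plus the other parent's genotype make it
unambiguous; double-heterozygous trios and missing genotypes are skipped,
Mendelian inconsistencies are skipped and counted.

Crossovers are called at phase changes between *accepted runs* of
consecutive same-origin informative markers. A run shorter than
`min_support` markers (default 3) is treated as genotyping error: its
markers are discarded and the runs re-evaluated, so an isolated flip
A A B A A yields no call. Short runs at chromosome ends are dropped rather
than called against the boundary. The default of 3 absorbs isolated array
errors at ~50K-density without suppressing true double crossovers, but it
is an explicitly different filter from likelihood-based callers used on
real data; no equivalence is claimed, and genuinely short double
crossovers and crossovers inside the terminal two marker intervals are
invisible by construction. The interval point estimate is the flanking
midpoint, unbiased under a uniform position prior on the interval.

## Phenotypes

- **r̄_intra = Σ_k 2 p_k (1 − p_k) L_k².** Two ambiguities had to be
  resolved. (1) Whether L_k is physical or genetic length: physical bp is
  used, since the statistic describes shuffling of loci along the physical
  genome; this is a package decision flagged for sensitivity analysis, and
  `genome_fractions()` makes the choice explicit and swappable. (2) Whether
  p_k is a marker-count proportion or a physical-length proportion of the
  transmitted segments: the default is the marker proportion (the phrase
  "proportion of alleles" reads most naturally as counting loci);
  `p_weight = "length"` switches to bp-weighted segments with switch points
  at flanking-marker midpoints. Both are exposed because the definition's
  source does not disambiguate. The statistic is invariant to which
  parental haplotype is labelled A.
- **Distance to telomere.** Arm assignment compares the crossover midpoint
  to the centromere; acrocentric chromosomes (centromere modelled exactly
  at a terminus) have one arm whose telomere is the opposite end. Only the
  crossover closest to each arm's telomere counts (≤ 2 per metacentric,
  ≤ 1 per acrocentric chromosome), and a gamete with zero crossovers gets a
  missing value, not zero — averaging in zeros would conflate "no
  crossover" with "crossover at the telomere".
- **Descriptives.** Sex differences use Welch's unequal-variance t-test;
  phenotype pairs use Pearson correlations overall and within sex. These
  wrap the standard R implementations; degenerate groups (zero variance)
  are flagged rather than tested.

## The synthetic world

The simulator's defaults describe one fixed, documented world, not tuning
knobs:

- **Genome**: 18 autosomes, 1–12 metacentric (centromere at 40% of the
  length), 13–18 acrocentric, physical lengths declining 260→60 Mb
  (pig-like scale; real assembly lengths are deliberately not encoded, and
  lengths are user-configurable). Sex-specific maps total 2440 cM (female)
  and 1820 cM (male) — chosen so expected gamete counts match typical
  female/male autosomal totals near 24 and 18 — with a minimum chromosome
  length of 50 cM reflecting the obligate crossover, and mild telomeric
  enrichment (the distal quarters carry 30% of the cM each).
- **Founders** are in linkage equilibrium with allele frequencies
  ~ U(0.05, 0.5); gametes create linkage within families. GWAS power
  statements on this world therefore do not transfer to populations with
  ancestral LD, and no fine-scale hotspot structure (PRDM9-style) is
  simulated.
- **Genotyping error** flips each allele independently (default 0 in the
  stated world; 0.2% in the caller's robustness regression); missingness is
  independent per genotype.
- **Phenotypes** can also be simulated directly (non-mechanistically):
  breeding values follow the pedigree recursion with Mendelian-sampling
  variance V_A/2, ignoring inbreeding — a documented limitation, acceptable
  for the shallow pedigrees used here; records add a permanent-environment
  effect, an optional additive QTL, and i.i.d. residuals.
- Every stochastic entry point takes a seed, uses one local RNG stream, and
  restores the caller's RNG state; identical seed + config gives
  bit-identical output.

A green test on this world establishes that the estimators recover the
parameters of the process they assume, at the stated sample sizes. It does
not establish robustness to phasing error, ancestral LD, map error, or
selection — none of which the generator emulates.

## REML animal model

`reml_animal_model()` fits y = Xb + Za + (Z·pe) + e with a ~ N(0, A·V_A)
structured by the pedigree numerator relationship matrix (Henderson's
sparse inverse, no inbreeding adjustment) and, for repeated gamete records,
a permanent-environment effect at the individual level. Estimation is
average-information REML on the mixed-model equations with three
safeguards: (1) three EM warm-up iterations, because AI steps computed far
from the optimum can leave the parameter space; (2) step-halving line
search on the AI direction with EM fallback, so the restricted likelihood
never decreases; (3) an active-set treatment of the boundary — variances
are floored at 1e-10·V_P, a component pinned at the floor is excluded from
AI updates and released only if its gradient points back into the interior.
Convergence is |Δ log L_R| < 1e-8. The implementation is verified against a
direct dense-V restricted likelihood oracle in the tests, including a
dataset whose optimum sits exactly on the V_A = 0 boundary. Heritability
SEs use the delta method on the inverse AI matrix.

## GWAS

The association model is y = a + bx + g + e on one record per individual
(FID means), with g structured by a VanRaden genomic relationship matrix
using aggregate scaling (cross-products divided by Σ 2p_j(1−p_j); missing
dosages imputed to the marker mean). For each chromosome the GRM is built
from all *other* chromosomes (LOCO), its eigendecomposition reduces the
REML to a one-dimensional search over the variance ratio, and each SNP on
the chromosome is tested by a generalized-least-squares Wald test with the
variance components held fixed — the standard mixed-model GWAS
approximation. Effects are reported for the minor allele. Genomic control
divides the χ² statistics by λ = median(χ²)/0.4549 only when λ > 1;
deflation is left uncorrected, following standard practice since inflating
significance after observing λ < 1 is anticonservative. Multiple testing
uses the Bonferroni threshold α/n_tests only.

Since the permanent-environment effect is not identifiable from one record
per individual, the GWAS model deliberately omits it.

## Known limitations

- The caller requires externally phased parents; phasing error is not
  modelled.
- Interval-censoring of crossover positions is ignored: positions enter
  the interference likelihood as flanking midpoints.
- No chromatid interference, no obligate-crossover constraint, no
  centromere effects in the renewal model — consistent with the fitted
  likelihood's assumptions, so simulator and estimator share blind spots.
- Bivariate/multivariate REML (genetic correlations) is out of scope; the
  univariate machinery is the deliverable.
- Several test designs are scaled-down versions of their stated designs
  (replicate counts reduced from 10–20 to 3–6) to keep the suite inside a
  CI budget; the acceptance script runs the full replicate counts where a
  target specifies them.
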