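# Houseworth-Stahl likelihood machinery.
#
# All internal computation is on the Morgan scale. The interfering (Class I)
# gamete process is the 1/2-thinning of a stationary gamma renewal process
# (chiasma shape nu, chiasma rate lambda = 2*nu*rho per Morgan, so the gamete
# Class I intensity is rho). The escaping (Class II) process is homogeneous
# Poisson with intensity p = 1 - rho. The infinite thinning series
# sum_k (1/2)^k Gamma(k*nu, lambda) is truncated at STAHL_KMAX, where the
# geometric weight (1/2)^k has fallen below 1e-12; a (1/2)^K tail term keeps
# survival functions from losing mass.

STAHL_KMAX <- 40L

# number of series terms with non-negligible gamma mass below xmax; terms
# beyond contribute < 1e-13 each and, for survival functions, collapse into
# an exact geometric tail
stahl_kmax <- function(xmax, nu, lambda) {
  k <- 1L
  while (k < STAHL_KMAX &&
         pgamma(xmax, shape = (k + 1L) * nu, rate = lambda) > 1e-13)
    k <- k + 1L
  min(k + 1L, STAHL_KMAX)
}

# inter-arrival density of the thinned process: sum_k (1/2)^k g(x; k nu, lambda)
stahl_fstar <- function(x, nu, lambda, kmax = STAHL_KMAX) {
  out <- numeric(length(x))
  for (k in seq_len(kmax))
    out <- out + 0.5^k * dgamma(x, shape = k * nu, rate = lambda)
  out
}

# survival function of the thinned inter-arrival distribution; terms beyond
# kmax have upper tail ~ 1 at every evaluated x, giving the 0.5^kmax tail
stahl_sstar <- function(x, nu, lambda, kmax = STAHL_KMAX) {
  out <- rep(0.5^kmax, length(x))
  for (k in seq_len(kmax))
    out <- out + 0.5^k * pgamma(x, shape = k * nu, rate = lambda,
                                lower.tail = FALSE)
  out
}

# P(no gamete Class I event in [0, L]) under the stationary thinned process:
# 1 - rho * int_0^L S*(u) du, via the closed form of int_0^x F*(u) du
stahl_seq <- function(L, nu, lambda, rho, kmax = STAHL_KMAX) {
  I <- numeric(length(L))
  for (k in seq_len(kmax)) {
    a <- k * nu
    I <- I + 0.5^k * (L * pgamma(L, shape = a, rate = lambda) -
                        (a / lambda) * pgamma(L, shape = a + 1, rate = lambda))
  }
  pmax(1 - rho * (L - I), 0)
}

#' Inter-crossover distance density of the thinned gamma model
#'
#' Density of the distance between consecutive gamete crossovers under the
#' gamma interference model without escape, i.e. the 1/2-thinning of a gamma
#' renewal chiasma process with shape `nu` and rate `2 * nu` per Morgan. The
#' density integrates to 1 and has mean 1 Morgan for every `nu`; at `nu = 1`
#' it reduces to the rate-1 exponential (no interference).
#'
#' @param x distances in Morgans (>= 0).
#' @param nu gamma shape parameter (> 0).
#' @return density values.
#' @export
thinned_gamma_density <- function(x, nu) {
  if (!is.finite(nu) || nu <= 0) stop("nu must be > 0")
  stopifnot(all(x >= 0))
  stahl_fstar(x, nu, 2 * nu)
}

# Precompute the partition structure of a dataset: for every gamete-chromosome
# with m observed crossovers, all 2^m assignments of crossovers to Class I/II,
# flattened so one likelihood evaluation is a handful of vectorized
# density/survival calls. Positions and lengths in Morgans.
stahl_prep <- function(positions, lengths) {
  n <- length(positions)
  stopifnot(length(lengths) %in% c(1L, n))
  if (length(lengths) == 1L) lengths <- rep(lengths, n)
  sub_chrom <- integer(0); sub_nA <- integer(0); sub_nB <- integer(0)
  sub_start <- numeric(0); sub_cens <- numeric(0)
  gap_vals_l <- list(); gap_sub_l <- list()
  nsub_tot <- 0L
  for (i in seq_len(n)) {
    x <- as.numeric(positions[[i]])
    L <- lengths[i]
    if (is.unsorted(x, strictly = FALSE)) stop("positions must be sorted")
    if (length(x) && (x[1L] <= 0 || x[length(x)] >= L))
      stop("positions must lie strictly inside (0, length)")
    m <- length(x)
    if (m > 20L) stop("more than 20 crossovers on one chromosome; refusing ",
                      "to enumerate 2^m partitions")
    for (s in 0:(2^m - 1L)) {
      inA <- if (m) as.logical(bitwAnd(s, 2^(seq_len(m) - 1L))) else logical(0)
      a <- x[inA]
      nsub_tot <- nsub_tot + 1L
      sub_chrom[nsub_tot] <- i
      sub_nA[nsub_tot] <- length(a)
      sub_nB[nsub_tot] <- m - length(a)
      sub_start[nsub_tot] <- if (length(a)) a[1L] else NA_real_
      sub_cens[nsub_tot] <- if (length(a)) L - a[length(a)] else NA_real_
      if (length(a) > 1L) {
        g <- diff(a)
        gap_vals_l[[length(gap_vals_l) + 1L]] <- g
        gap_sub_l[[length(gap_sub_l) + 1L]] <- rep(nsub_tot, length(g))
      }
    }
  }
  gap_vals <- if (length(gap_vals_l)) unlist(gap_vals_l) else numeric(0)
  gap_sub <- if (length(gap_sub_l)) unlist(gap_sub_l) else integer(0)
  list(n = n, L = lengths, sub_chrom = sub_chrom, sub_nA = sub_nA,
       sub_nB = sub_nB, sub_start = sub_start, sub_cens = sub_cens,
       gap_vals = gap_vals, gap_sub = gap_sub, nsub = nsub_tot,
       m = vapply(positions, length, 1L))
}

# total log-likelihood of a prepared dataset at (nu, p)
stahl_loglik_prep <- function(prep, nu, p) {
  if (!is.finite(nu) || nu <= 0) return(-Inf)
  if (!is.finite(p) || p < 0 || p >= 1) return(-Inf)
  rho <- 1 - p
  lambda <- 2 * nu * rho
  xmax <- max(prep$L, prep$gap_vals, prep$sub_start, prep$sub_cens,
              na.rm = TRUE)
  kmax <- stahl_kmax(xmax, nu, lambda)
  logS_start <- rep(0, prep$nsub)
  logS_cens <- rep(0, prep$nsub)
  nonempty <- prep$sub_nA > 0L
  logS_start[nonempty] <- log(pmax(stahl_sstar(prep$sub_start[nonempty],
                                               nu, lambda, kmax), 1e-300))
  logS_cens[nonempty] <- log(pmax(stahl_sstar(prep$sub_cens[nonempty],
                                              nu, lambda, kmax), 1e-300))
  gap_term <- rep(0, prep$nsub)
  if (length(prep$gap_vals)) {
    lf <- log(pmax(stahl_fstar(prep$gap_vals, nu, lambda, kmax), 1e-300))
    gs <- rowsum(lf, prep$gap_sub)
    gap_term[as.integer(rownames(gs))] <- gs[, 1L]
  }
  # probability of an empty Class I chromosome, cached over unique lengths
  uL <- unique(prep$L)
  seq_u <- log(pmax(stahl_seq(uL, nu, lambda, rho, kmax), 1e-300))
  log_seq <- seq_u[match(prep$L, uL)]
  nBlogp <- ifelse(prep$sub_nB == 0L, 0, prep$sub_nB * log(p))
  term <- ifelse(nonempty,
                 log(rho) + logS_start + logS_cens + gap_term,
                 log_seq[prep$sub_chrom]) +
    nBlogp - p * prep$L[prep$sub_chrom]
  # sum the 2^m partition likelihoods within each gamete-chromosome; term
  # magnitudes are moderate (bounded by a few units of L and m log p), so a
  # direct exp-sum-log is safe here
  s <- rowsum(exp(term), prep$sub_chrom)
  sum(log(s[, 1L]))
}

#' Stahl log-likelihood of one gamete chromosome
#'
#' Log-likelihood of an observed crossover configuration on one chromosome of
#' one gamete under the Houseworth-Stahl interference-escape model. The
#' likelihood sums over all `2^m` assignments of the `m` observed crossovers
#' to the interfering (Class I) and escaping (Class II) pathways; the Class I
#' subset is scored under the stationary thinned gamma renewal process
#' (stationary start and right-censoring terms included) and the Class II
#' subset under a homogeneous Poisson process of rate `p` per Morgan. At
#' `nu = 1, p = 0` the model is a rate-1 Poisson process and the
#' log-likelihood equals `-L` (Morgans) for every configuration.
#'
#' @param positions_cM sorted crossover positions in cM, strictly inside
#'   `(0, length_cM)`.
#' @param length_cM chromosome genetic length in cM.
#' @param nu gamma shape (> 0).
#' @param p escape fraction in \[0, 1).
#' @return scalar log-likelihood.
#' @export
chromosome_loglik <- function(positions_cM, length_cM, nu, p = 0) {
  if (!is.finite(nu) || nu <= 0) stop("nu must be > 0")
  if (!is.finite(p) || p < 0 || p >= 1) stop("p must be in [0, 1)")
  prep <- stahl_prep(list(positions_cM / 100), length_cM / 100)
  stahl_loglik_prep(prep, nu, p)
}
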