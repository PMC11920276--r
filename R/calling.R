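#' Genotype quality control
#'
#' Drops markers failing minor-allele-frequency, call-rate or 1-df
#' Hardy-Weinberg chi-squared filters. The HWE statistic compares observed
#' genotype counts at each marker to expectation under the estimated allele
#' frequency; only grossly deviating markers (default chi2 > 600) are
#' removed, as array-scale HWE deviation usually indicates genotyping
#' artefacts rather than biology.
#'
#' @param geno n x M dosage matrix (0/1/2/NA), columns named by marker.
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param callrate_min minimum genotype call rate (default 0.95).
#' @param hwe_chi2_max maximum 1-df HWE chi-squared (default 600).
#' @return list: `geno` (filtered matrix), `keep` (logical per marker),
#'   `report` (`data.table` per marker: `marker`, `maf`, `callrate`,
#'   `hwe_chi2`, `dropped`, `reason`), `n_dropped` (named counts per
#'   criterion).
#' @export
qc_genotypes <- function(geno, maf_min = 0.01, callrate_min = 0.95,
                         hwe_chi2_max = 600) {
  if (is.null(dim(geno)) || nrow(geno) == 0L || ncol(geno) == 0L)
    stop("empty genotype table")
  n <- colSums(!is.na(geno))
  callrate <- n / nrow(geno)
  p <- colMeans(geno, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0
  n0 <- colSums(geno == 0, na.rm = TRUE)
  n1 <- colSums(geno == 1, na.rm = TRUE)
  n2 <- colSums(geno == 2, na.rm = TRUE)
  e0 <- n * (1 - p)^2; e1 <- n * 2 * p * (1 - p); e2 <- n * p^2
  chi2 <- numeric(ncol(geno))
  poly <- maf > 0 & n > 0
  chi2[poly] <- (n0[poly] - e0[poly])^2 / e0[poly] +
    (n1[poly] - e1[poly])^2 / e1[poly] +
    (n2[poly] - e2[poly])^2 / e2[poly]
  fail_maf <- maf < maf_min
  fail_cr <- callrate < callrate_min
  fail_hwe <- chi2 > hwe_chi2_max
  dropped <- fail_maf | fail_cr | fail_hwe
  reason <- rep("", ncol(geno))
  reason[fail_hwe] <- "hwe"
  reason[fail_cr] <- "callrate"
  reason[fail_maf] <- "maf"   # maf reported with highest precedence
  mk <- colnames(geno)
  if (is.null(mk)) mk <- sprintf("m%d", seq_len(ncol(geno)))
  list(geno = geno[, !dropped, drop = FALSE], keep = !dropped,
       report = data.table(marker = mk, maf = maf, callrate = callrate,
                           hwe_chi2 = chi2, dropped = dropped,
                           reason = reason),
       n_dropped = c(maf = sum(fail_maf), callrate = sum(fail_cr),
                     hwe = sum(fail_hwe), total = sum(dropped)))
}

#' Infer the inheritance vector of one gamete on one chromosome
#'
#' At each marker where the focal parent is heterozygous, determines which of
#' the parent's two phased haplotypes was transmitted, using the offspring
#' genotype and the other parent's genotype. Markers where the transmitted
#' allele is ambiguous (offspring and both parents heterozygous), where any
#' genotype is missing, or where the trio is Mendelian-inconsistent are
#' skipped (inconsistencies are counted).
#'
#' @param focal_haps 2 x m matrix of the focal parent's phased alleles on
#'   this chromosome (row 1 = haplotype A).
#' @param other_geno other parent's dosages (length m).
#' @param off_geno offspring dosages (length m).
#' @param panel_chr panel rows for the chromosome (`marker`, `bp`).
#' @return `data.table` of informative markers: `marker`, `bp`,
#'   `origin` ("hapA"/"hapB"); attributes `n_ambiguous`, `n_mendel_err`.
#' @export
infer_inheritance <- function(focal_haps, other_geno, off_geno, panel_chr) {
  m <- nrow(panel_chr)
  stopifnot(ncol(focal_haps) == m, length(other_geno) == m,
            length(off_geno) == m)
  hA <- focal_haps[1L, ]; hB <- focal_haps[2L, ]
  het <- hA != hB
  # transmitted focal allele, NA when unknown
  tf <- rep(NA_integer_, m)
  ok <- het & !is.na(off_geno)
  tf[ok & off_geno == 0L] <- 0L
  tf[ok & off_geno == 2L] <- 1L
  ok1 <- ok & off_geno == 1L & !is.na(other_geno)
  tf[ok1 & other_geno == 0L] <- 1L   # other parent contributed 0
  tf[ok1 & other_geno == 2L] <- 0L
  # Mendelian check: offspring allele from other parent must be producible
  to <- off_geno - tf                 # allele attributed to the other parent
  mend <- !is.na(tf) & !is.na(other_geno) &
    ((to == 0L & other_geno == 2L) | (to == 1L & other_geno == 0L))
  n_mendel <- sum(mend)
  tf[mend] <- NA_integer_
  amb <- ok1 & other_geno == 1L
  keep <- !is.na(tf)
  out <- data.table(marker = panel_chr$marker[keep], bp = panel_chr$bp[keep],
                    origin = ifelse(tf[keep] == hA[keep], "hapA", "hapB"))
  setattr(out, "n_ambiguous", sum(amb, na.rm = TRUE))
  setattr(out, "n_mendel_err", n_mendel)
  out
}

#' Call crossover intervals from an inheritance vector
#'
#' Crossovers are called at phase changes between runs of consecutive
#' informative markers with the same parental origin. A run is accepted only
#' if it spans at least `min_support` markers; shorter interior runs are
#' treated as genotyping error and their markers are discarded before
#' re-evaluating phase changes, and short runs at chromosome ends are dropped
#' (no crossover is called against a chromosome boundary). Interval
#' endpoints are the last marker of the left accepted run and the first
#' marker of the right accepted run; the point estimate is the interval
#' midpoint.
#'
#' @param iv inheritance vector for one gamete chromosome
#'   (see [infer_inheritance()]): columns `bp`, `origin`, sorted by `bp`.
#' @param min_support minimum run length in informative markers (default 3).
#' @return `data.table` of intervals: `left_bp`, `right_bp`, `midpoint_bp`.
#' @export
call_crossovers <- function(iv, min_support = 3L) {
  stopifnot(min_support >= 1L)
  bp <- iv$bp; org <- iv$origin
  if (is.unsorted(bp)) stop("inheritance vector must be sorted by bp")
  repeat {
    if (length(org) == 0L)
      return(data.table(left_bp = numeric(0), right_bp = numeric(0),
                        midpoint_bp = numeric(0)))
    r <- rle(org)
    if (all(r$lengths >= min_support) || length(r$lengths) == 1L) break
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    short <- which(r$lengths < min_support)
    # drop markers of short runs (ends included), then re-examine
    drop <- unlist(lapply(short, function(j) starts[j]:ends[j]))
    bp <- bp[-drop]; org <- org[-drop]
  }
  r <- rle(org)
  if (length(r$lengths) <= 1L ||
      (length(r$lengths) == 1L && r$lengths[1L] < min_support))
    return(data.table(left_bp = numeric(0), right_bp = numeric(0),
                      midpoint_bp = numeric(0)))
  ends <- cumsum(r$lengths)
  left <- bp[ends[-length(ends)]]
  right <- bp[ends[-length(ends)] + 1L]
  data.table(left_bp = left, right_bp = right,
             midpoint_bp = (left + right) / 2)
}

#' Call crossovers for every gamete in a simulated or assembled dataset
#'
#' Convenience driver: for each parent-offspring pair and chromosome, infers
#' the inheritance vector from the focal parent's phased haplotypes and the
#' observed genotypes, calls crossover intervals, and returns both.
#'
#' @param sim a `gamete_sim` (or a list with `genome`, `pedigree`, `haps`,
#'   `geno` laid out the same way).
#' @param min_support run-support threshold for [call_crossovers()].
#' @return list with `intervals` (`data.table`: `fid`, `offspring`, `chrom`,
#'   `left_bp`, `right_bp`, `midpoint_bp`) and `origins` (`data.table`:
#'   `fid`, `offspring`, `chrom`, `marker`, `bp`, `origin`).
#' @export
call_crossovers_all <- function(sim, min_support = 3L) {
  gen <- sim$genome; ped <- as.data.table(sim$pedigree)
  panel <- gen$panel
  mk_rows <- split(seq_len(nrow(panel)), panel$chrom)
  off <- ped[!is.na(sire) & !is.na(dam)]
  iv_l <- list(); xo_l <- list()
  for (i in seq_len(nrow(off))) {
    oid <- off$id[i]
    for (role in c("sire", "dam")) {
      fidp <- off[[role]][i]
      for (k in names(mk_rows)) {
        rows <- mk_rows[[k]]
        iv <- infer_inheritance(sim$haps[[fidp]][, rows, drop = FALSE],
                                sim$geno[off[[if (role == "sire") "dam"
                                              else "sire"]][i], rows],
                                sim$geno[oid, rows],
                                panel[rows])
        if (nrow(iv))
          iv_l[[length(iv_l) + 1L]] <-
            data.table(fid = fidp, offspring = oid, chrom = as.integer(k), iv)
        xo <- call_crossovers(iv, min_support)
        if (nrow(xo))
          xo_l[[length(xo_l) + 1L]] <-
            data.table(fid = fidp, offspring = oid, chrom = as.integer(k), xo)
      }
    }
  }
  empty_xo <- data.table(fid = character(), offspring = character(),
                         chrom = integer(), left_bp = numeric(),
                         right_bp = numeric(), midpoint_bp = numeric())
  empty_iv <- data.table(fid = character(), offspring = character(),
                         chrom = integer(), marker = character(),
                         bp = numeric(), origin = character())
  list(intervals = if (length(xo_l)) rbindlist(xo_l) else empty_xo,
       origins = if (length(iv_l)) rbindlist(iv_l) else empty_iv)
}
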