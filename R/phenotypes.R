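#' Per-gamete autosomal crossover count
#'
#' @param intervals crossover-interval table with columns `fid`, `offspring`
#'   (and anything else); one row per called crossover.
#' @return `data.table` with `fid`, `offspring`, `count`.
#' @export
crossover_count <- function(intervals) {
  iv <- as.data.table(intervals)
  iv[, .(count = .N), by = .(fid, offspring)]
}

#' Intra-chromosomal allelic shuffling of one gamete
#'
#' The probability that a random pair of loci on the same chromosome is
#' uncoupled by recombination in this gamete:
#' \deqn{\bar r_{intra} = \sum_k 2 p_k (1 - p_k) L_k^2}
#' where `p_k` is the proportion of alleles on chromosome `k` deriving from
#' one of the focal parent's two haplotypes (the statistic is symmetric in
#' the labelling) and `L_k` is the chromosome's physical length as a
#' fraction of the genome. By default `p_k` is the proportion of phased
#' informative markers assigned to haplotype A; `p_weight = "length"`
#' instead weights by the physical length of the origin segments (switch
#' points at midpoints between adjacent discordant markers, ends extended
#' to the chromosome boundaries).
#'
#' @param origins origin table for one gamete: columns `chrom`, `bp`,
#'   `origin` ("hapA"/"hapB").
#' @param chrom_defs a [chromosome_table()]; every chromosome must have at
#'   least one phased marker.
#' @param p_weight `"markers"` or `"length"`.
#' @return scalar in \[0, 0.5\].
#' @export
r_intra <- function(origins, chrom_defs, p_weight = c("markers", "length")) {
  p_weight <- match.arg(p_weight)
  og <- as.data.table(origins)
  L <- genome_fractions(chrom_defs)
  tot <- 0
  for (k in chrom_defs$chrom) {
    sub <- og[chrom == k][order(bp)]
    if (nrow(sub) == 0L)
      stop("no phased markers on chromosome ", k)
    if (p_weight == "markers") {
      p <- mean(sub$origin == "hapA")
    } else {
      isA <- sub$origin == "hapA"
      bnd <- c(0, (sub$bp[-1L] + sub$bp[-nrow(sub)]) / 2,
               chrom_defs$bp_length[match(k, chrom_defs$chrom)])
      p <- sum((bnd[-1L] - bnd[-length(bnd)])[isA]) /
        chrom_defs$bp_length[match(k, chrom_defs$chrom)]
    }
    tot <- tot + 2 * p * (1 - p) * L[[as.character(k)]]^2
  }
  tot
}

#' Mean crossover distance to the telomere of one gamete
#'
#' For each chromosome arm carrying at least one crossover, the distance (in
#' Mb) from the arm's telomere to the closest crossover on that arm: on the
#' p arm of a metacentric chromosome this is the crossover position, on the
#' q arm the chromosome length minus the position; acrocentric chromosomes
#' have a single arm with its telomere opposite the (terminal) centromere.
#' At most one crossover is counted per arm. The gamete value is the mean
#' over all contributing arms; a gamete with zero crossovers has no defined
#' value (`NA`, not zero).
#'
#' @param intervals interval table for one gamete: columns `chrom`,
#'   `midpoint_bp`.
#' @param chrom_defs a [chromosome_table()].
#' @return scalar Mb, or `NA_real_` for a crossover-free gamete.
#' @export
distance_to_telomere <- function(intervals, chrom_defs) {
  iv <- as.data.table(intervals)
  if (nrow(iv) == 0L) return(NA_real_)
  dists <- c()
  for (k in unique(iv$chrom)) {
    row <- match(k, chrom_defs$chrom)
    len <- chrom_defs$bp_length[row]
    cen <- chrom_defs$centromere_bp[row]
    pos <- iv[chrom == k, midpoint_bp]
    if (chrom_defs$arm_class[row] == "acrocentric") {
      d <- if (cen == 0) len - pos else pos
      dists <- c(dists, min(d))
    } else {
      p_arm <- pos[pos < cen]; q_arm <- pos[pos >= cen]
      if (length(p_arm)) dists <- c(dists, min(p_arm))
      if (length(q_arm)) dists <- c(dists, min(len - q_arm))
    }
  }
  mean(dists) / 1e6
}

#' Per-gamete crossover phenotypes
#'
#' Computes all per-gamete phenotypes (crossover count, intra-chromosomal
#' allelic shuffling, distance to telomere) for every gamete present in the
#' interval and origin tables.
#'
#' @param intervals crossover intervals: `fid`, `offspring`, `chrom`,
#'   `midpoint_bp`.
#' @param origins marker origin calls: `fid`, `offspring`, `chrom`, `bp`,
#'   `origin`. Gametes are enumerated from this table so crossover-free
#'   gametes are included.
#' @param gen a `genome`.
#' @param p_weight passed to [r_intra()].
#' @return `data.table`: `fid`, `offspring`, `count`, `r_intra`,
#'   `dist_telomere_mb`.
#' @export
gamete_phenotypes <- function(intervals, origins, gen,
                              p_weight = "markers") {
  iv <- as.data.table(intervals); og <- as.data.table(origins)
  gam <- unique(og[, .(fid, offspring)])
  res <- lapply(seq_len(nrow(gam)), function(i) {
    f <- gam$fid[i]; o <- gam$offspring[i]
    sub_iv <- iv[fid == f & offspring == o]
    sub_og <- og[fid == f & offspring == o]
    data.table(fid = f, offspring = o, count = nrow(sub_iv),
               r_intra = r_intra(sub_og, gen$chrom, p_weight),
               dist_telomere_mb = distance_to_telomere(sub_iv, gen$chrom))
  })
  rbindlist(res)
}

#' Aggregate gamete phenotypes to focal-individual means
#'
#' @param gp per-gamete phenotype table from [gamete_phenotypes()].
#' @param sexes optional named vector mapping fid to "M"/"F".
#' @return `data.table`: `fid`, `sex`, `n_gametes`, `count`, `r_intra`,
#'   `dist_telomere_mb` (means; telomere distance averaged over gametes
#'   where it is defined).
#' @export
aggregate_fid <- function(gp, sexes = NULL) {
  gp <- as.data.table(gp)
  out <- gp[, .(n_gametes = .N, count = mean(count),
                r_intra = mean(r_intra),
                dist_telomere_mb = mean(dist_telomere_mb, na.rm = TRUE)),
            by = fid]
  out[, sex := if (is.null(sexes)) NA_character_
      else unname(sexes[as.character(fid)])]
  setcolorder(out, c("fid", "sex", "n_gametes"))
  out[]
}

#' Descriptive statistics of crossover phenotypes by sex
#'
#' Means and SDs per sex, Welch unequal-variance t-tests for the sex
#' difference in each phenotype, and Pearson correlations (with two-sided
#' P-values) between every phenotype pair, overall and within each sex.
#'
#' @param pheno table with a `sex` column ("M"/"F") and numeric phenotype
#'   columns.
#' @param vars phenotype column names; defaults to all numeric columns
#'   except `n_gametes`.
#' @return list: `means` (`data.table`), `t_tests` (`data.table`:
#'   `phenotype`, `t`, `df`, `p`), `correlations` (`data.table`: `group`,
#'   `var1`, `var2`, `r`, `p`).
#' @export
summarize_descriptives <- function(pheno, vars = NULL) {
  ph <- as.data.table(pheno)
  if (is.null(vars))
    vars <- setdiff(names(ph)[vapply(ph, is.numeric, TRUE)], "n_gametes")
  stopifnot("sex" %in% names(ph), length(vars) >= 1L)
  means <- ph[, c(list(n = .N),
                  unlist(lapply(.SD, function(v)
                    list(mean = mean(v, na.rm = TRUE),
                         sd = sd(v, na.rm = TRUE))),
                    recursive = FALSE)),
              by = sex, .SDcols = vars]
  tt <- rbindlist(lapply(vars, function(v) {
    x <- ph[sex == "M"][[v]]; y <- ph[sex == "F"][[v]]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2L || length(y) < 2L || (sd(x) == 0 && sd(y) == 0))
      return(data.table(phenotype = v, t = NA_real_, df = NA_real_,
                        p = NA_real_, note = "degenerate"))
    if (identical(sort(x), sort(y)))
      return(data.table(phenotype = v, t = 0, df = length(x) + length(y) - 2,
                        p = 1, note = "identical groups"))
    w <- t.test(x, y)
    data.table(phenotype = v, t = unname(w$statistic),
               df = unname(w$parameter), p = w$p.value, note = "")
  }))
  groups <- list(all = ph, M = ph[sex == "M"], F = ph[sex == "F"])
  cors <- rbindlist(lapply(names(groups), function(gname) {
    d <- groups[[gname]]
    prs <- if (length(vars) > 1L) utils::combn(vars, 2L, simplify = FALSE)
           else list(c(vars, vars))
    rbindlist(lapply(prs, function(pr) {
      x <- d[[pr[1L]]]; y <- d[[pr[2L]]]
      ok <- complete.cases(x, y)
      if (sum(ok) < 3L || sd(x[ok]) == 0 || sd(y[ok]) == 0)
        return(data.table(group = gname, var1 = pr[1L], var2 = pr[2L],
                          r = NA_real_, p = NA_real_))
      ct <- cor.test(x[ok], y[ok])
      data.table(group = gname, var1 = pr[1L], var2 = pr[2L],
                 r = unname(ct$estimate), p = ct$p.value)
    }))
  }))
  list(means = means, t_tests = tt, correlations = cors)
}
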