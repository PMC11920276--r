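#' Genomic relationship matrix
#'
#' VanRaden-style GRM with aggregate scaling: genotype dosages are centered
#' by twice the observed allele frequency and the cross-product is divided
#' by `sum(2 p_j (1 - p_j))` over the markers used. Missing dosages are
#' imputed to the marker mean. With `exclude_chrom`, markers on that
#' chromosome are left out (the LOCO construction).
#'
#' @param geno n x M dosage matrix (0/1/2/NA), columns named by marker.
#' @param panel marker panel (`marker`, `chrom`, `bp`); required when
#'   `exclude_chrom` is used.
#' @param exclude_chrom chromosome index to drop, or `NULL`.
#' @return n x n symmetric matrix; attribute `n_markers` records how many
#'   markers entered.
#' @export
grm <- function(geno, panel = NULL, exclude_chrom = NULL) {
  use <- rep(TRUE, ncol(geno))
  if (!is.null(exclude_chrom)) {
    if (is.null(panel)) stop("panel required to exclude a chromosome")
    keep_mk <- panel$marker[!panel$chrom %in% exclude_chrom]
    use <- colnames(geno) %in% keep_mk
  }
  Gm <- geno[, use, drop = FALSE]
  p <- colMeans(Gm, na.rm = TRUE) / 2
  poly <- p > 0 & p < 1 & !is.nan(p)
  Gm <- Gm[, poly, drop = FALSE]; p <- p[poly]
  if (ncol(Gm) < 2L) stop("fewer than 2 usable markers for the GRM")
  Wm <- sweep(Gm, 2L, 2 * p)
  Wm[is.na(Wm)] <- 0
  G <- tcrossprod(Wm) / sum(2 * p * (1 - p))
  attr(G, "n_markers") <- ncol(Gm)
  G
}

#' Genomic control correction
#'
#' The inflation factor lambda is the median observed 1-df association
#' chi-squared divided by its null median (0.4549). Statistics are deflated
#' by lambda only when lambda exceeds 1; deflation below 1 is not inflated
#' back, following standard genomic-control practice.
#'
#' @param chi2 vector of 1-df Wald chi-squared statistics.
#' @return list: `lambda`, `chi2_adj`, `p_adj`.
#' @export
genomic_control <- function(chi2) {
  if (length(chi2) == 0L) stop("empty chi-squared vector")
  lambda <- median(chi2, na.rm = TRUE) / qchisq(0.5, df = 1)
  chi2_adj <- if (lambda > 1) chi2 / lambda else chi2
  list(lambda = lambda, chi2_adj = chi2_adj,
       p_adj = pchisq(chi2_adj, df = 1, lower.tail = FALSE))
}

#' Bonferroni genome-wide significance threshold
#'
#' @param alpha family-wise error rate in (0, 1).
#' @param n_tests number of tests (>= 1).
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  if (!is.finite(n_tests) || n_tests < 1) stop("n_tests must be >= 1")
  alpha / n_tests
}

# 1-D REML for y = Xb + g + e with g ~ N(0, sigma_g^2 K), on the
# eigenbasis of K; returns variance components and the rotated pieces
emma_reml <- function(y, X, eig) {
  n <- length(y)
  d <- pmax(eig$values, 1e-10)
  U <- eig$vectors
  yt <- as.numeric(crossprod(U, y))
  Xt <- crossprod(U, X)
  p <- ncol(X)
  rll <- function(ldelta) {
    delta <- exp(ldelta)
    w <- 1 / (d + delta)
    XtWX <- crossprod(Xt, Xt * w)
    beta <- solve(XtWX, crossprod(Xt, yt * w))
    r <- yt - as.numeric(Xt %*% beta)
    s2 <- sum(w * r^2) / (n - p)
    -0.5 * ((n - p) * log(s2) + sum(log(d + delta)) +
              as.numeric(determinant(XtWX)$modulus) + (n - p))
  }
  op <- optimize(rll, interval = c(-10, 10), maximum = TRUE, tol = 1e-6)
  delta <- exp(op$maximum)
  w <- 1 / (d + delta)
  XtWX <- crossprod(Xt, Xt * w)
  beta <- solve(XtWX, crossprod(Xt, yt * w))
  r <- yt - as.numeric(Xt %*% beta)
  s2g <- sum(w * r^2) / (n - p)
  list(sigma_g2 = s2g, sigma_e2 = delta * s2g, delta = delta,
       U = U, d = d, yt = yt, Xt = Xt, loglik = op$objective)
}

#' Mixed-linear-model association scan with LOCO relatedness correction
#'
#' For each chromosome, variance components of the model
#' `y = a + b x + g + e` are estimated once by REML with `g` structured by
#' the genomic relationship matrix built from all *other* chromosomes
#' (leave one chromosome out, so the tested SNP's own chromosome does not
#' absorb its signal). Every SNP on the chromosome is then tested by a
#' generalized-least-squares Wald test of its additive dosage effect `b`,
#' reported for the minor allele. Genomic control is applied to the pooled
#' chi-squared statistics.
#'
#' @param pheno data.frame with `id`, `value`, plus covariate columns.
#' @param geno n x M dosage matrix with rownames = ids.
#' @param panel marker panel (`marker`, `chrom`, `bp`).
#' @param covariates character vector of fixed-covariate columns of `pheno`
#'   (e.g. crossover count for count-corrected scans), or `NULL`.
#' @return `data.table` sorted by chromosome and position: `marker`,
#'   `chrom`, `bp`, `maf`, `beta`, `se`, `chi2`, `p_raw`, `p_gc`, `note`
#'   (monomorphic SNPs are kept with `note = "monomorphic"` and NA
#'   statistics). Attribute `lambda` holds the genomic-control factor.
#' @export
mlm_loco_gwas <- function(pheno, geno, panel, covariates = NULL) {
  ph <- as.data.table(pheno)
  stopifnot(all(c("id", "value") %in% names(ph)))
  ids <- intersect(ph$id, rownames(geno))
  if (length(ids) < 3L) stop("fewer than 3 phenotyped, genotyped ids")
  ph <- ph[match(ids, id)]
  Gt <- geno[ids, , drop = FALSE]
  y <- ph$value
  X <- if (is.null(covariates)) matrix(1, length(y), 1L) else
    model.matrix(stats::reformulate(covariates), data = ph)
  pn <- as.data.table(panel)
  res <- list()
  for (k in sort(unique(pn$chrom))) {
    mks <- pn[chrom == k, marker]
    mks <- mks[mks %in% colnames(Gt)]
    if (!length(mks)) next
    K <- grm(Gt, pn, exclude_chrom = k)
    fit <- emma_reml(y, X, eigen(K, symmetric = TRUE))
    w <- 1 / (fit$sigma_g2 * (fit$d + fit$delta))   # precision weights
    Xt <- fit$Xt; yt <- fit$yt
    XtWX <- crossprod(Xt, Xt * w)
    Xs <- Gt[, mks, drop = FALSE]
    frq <- colMeans(Xs, na.rm = TRUE) / 2
    mono <- !is.finite(frq) | frq <= 0 | frq >= 1
    # orient to the minor allele and impute missing to the mean
    Xs <- sweep(Xs, 2L, 0)
    flip <- which(frq > 0.5)
    Xs[, flip] <- 2 - Xs[, flip]
    frq_minor <- pmin(frq, 1 - frq)
    for (j in seq_len(ncol(Xs)))
      Xs[is.na(Xs[, j]), j] <- 2 * frq_minor[j]
    Xst <- crossprod(fit$U, Xs)
    coefs <- solve(XtWX, crossprod(Xt, Xst * w))
    EX <- Xst - Xt %*% coefs                 # residualized SNPs
    den <- colSums(EX * (w * EX))
    num <- colSums(EX * (w * yt))
    beta <- num / den
    sev <- sqrt(1 / den)
    chi2 <- (beta / sev)^2
    out <- data.table(marker = mks, chrom = k,
                      bp = pn[chrom == k][match(mks, marker), bp],
                      maf = frq_minor, beta = beta, se = sev, chi2 = chi2,
                      note = "")
    out[mono, `:=`(beta = NA_real_, se = NA_real_, chi2 = NA_real_,
                   note = "monomorphic")]
    res[[length(res) + 1L]] <- out
  }
  out <- rbindlist(res)
  out[, p_raw := pchisq(chi2, df = 1, lower.tail = FALSE)]
  gc <- genomic_control(out[note == "", chi2])
  out[, p_gc := p_raw]
  out[note == "", p_gc := gc$p_adj]
  setorder(out, chrom, bp)
  setcolorder(out, c("marker", "chrom", "bp", "maf", "beta", "se", "chi2",
                     "p_raw", "p_gc", "note"))
  setattr(out, "lambda", gc$lambda)
  out[]
}
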