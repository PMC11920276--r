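test_that("a_matrix_inverse matches dense oracles", {
  # founders only -> identity
  fo <- data.frame(id = letters[1:4], sire = NA, dam = NA)
  expect_equal(as.matrix(a_matrix_inverse(fo)), diag(4),
               ignore_attr = TRUE)

  # sire-dam-offspring trio: closed-form pattern and numeric inverse of
  # the directly built A
  trio <- data.frame(id = c("s", "d", "o"), sire = c(NA, NA, "s"),
                     dam = c(NA, NA, "d"))
  Ai <- as.matrix(a_matrix_inverse(trio))
  expect_equal(Ai, matrix(c(1.5, 0.5, -1, 0.5, 1.5, -1, -1, -1, 2), 3),
               ignore_attr = TRUE)
  A <- a_matrix(trio)
  expect_equal(A, matrix(c(1, 0, .5, 0, 1, .5, .5, .5, 1), 3),
               ignore_attr = TRUE)
  expect_equal(Ai, solve(A), ignore_attr = TRUE)

  # random pedigrees up to 200 individuals: Henderson inverse times the
  # tabular A equals identity
  for (s in 1:3) {
    ped <- simulate_pedigree(3 + s, 8 + 4 * s, 3, generations = 2,
                             seed = 40 + s)
    A <- a_matrix(ped)
    Ai <- as.matrix(a_matrix_inverse(ped))
    expect_lt(max(abs(A %*% Ai - diag(nrow(ped)))), 1e-8)
  }

  cyc <- data.frame(id = c("a", "b"), sire = c("b", "a"),
                    dam = c(NA, NA))
  expect_error(a_matrix_inverse(cyc), "cyclic")
})

test_that("REML matches a direct dense-V oracle on a small dataset", {
  ped <- simulate_pedigree(3, 10, 4, seed = 5)
  sim <- simulate_phenotypes_direct(ped, 2, 1, 5, 10, 5, seed = 6)
  fit <- reml_animal_model(sim$records, ped, repeated = TRUE)
  expect_true(fit$converged)

  # independent restricted likelihood maximized on the dense V scale
  rec <- sim$records
  A <- a_matrix(ped)
  n <- nrow(rec)
  Z <- matrix(0, n, nrow(ped)); Z[cbind(1:n, match(rec$id, ped$id))] <- 1
  fids <- unique(rec$id)
  Zp <- matrix(0, n, length(fids)); Zp[cbind(1:n, match(rec$id, fids))] <- 1
  X <- matrix(1, n, 1); y <- rec$value
  nll <- function(lth) {
    th <- exp(lth)
    V <- th[1] * Z %*% A %*% t(Z) + th[2] * tcrossprod(Zp) + th[3] * diag(n)
    Vi <- solve(V); XVX <- crossprod(X, Vi %*% X)
    P <- Vi - Vi %*% X %*% solve(XVX, crossprod(X, Vi))
    0.5 * (determinant(V)$modulus + log(det(XVX)) +
             as.numeric(t(y) %*% P %*% y))
  }
  op <- optim(log(c(1, 1, 5)), nll, method = "Nelder-Mead",
              control = list(maxit = 3000, reltol = 1e-12))
  oracle <- exp(op$par)
  # this dataset sits on the V_A = 0 boundary; both must agree there
  expect_equal(fit$V_A, oracle[1], tolerance = 0.02 * fit$V_P)
  expect_equal(fit$V_PE, oracle[2], tolerance = 0.02)
  expect_equal(fit$V_E, oracle[3], tolerance = 0.02)
})

test_that("REML likelihood never decreases across EM fallback steps", {
  ped <- simulate_pedigree(4, 16, 4, seed = 7)
  sim <- simulate_phenotypes_direct(ped, 3, 1, 6, 0, 4, seed = 8)
  fit <- reml_animal_model(sim$records, ped, repeated = TRUE)
  tr <- fit$trace
  em <- which(tr$step == "EM")
  em <- em[em > 1]
  if (length(em))
    expect_true(all(tr$loglik[em] >= tr$loglik[em - 1] - 1e-8))
  expect_true(all(diff(tr$loglik) > -1e-6))   # overall ascent
})

test_that("REML recovers a null and a moderate heritability", {
  # V_A = 0: estimates collapse to the boundary (5 seeded replicates of a
  # 400-FID design, scaled down from the 10-replicate design for runtime)
  h2_null <- vapply(1:5, function(r) {
    ped <- simulate_pedigree(10, 40, 10, seed = 500 + r)
    sim <- simulate_phenotypes_direct(ped, 0, 0, 10, 0, 1, seed = 510 + r)
    reml_animal_model(sim$records, ped)$h2
  }, 0)
  expect_lt(median(h2_null), 0.02)

  # h2 = 0.3 with a 800-FID sire-dam design, single records
  h2_03 <- vapply(1:3, function(r) {
    ped <- simulate_pedigree(20, 80, 10, seed = 520 + r)
    sim <- simulate_phenotypes_direct(ped, 3, 0, 7, 0, 1, seed = 530 + r)
    reml_animal_model(sim$records, ped)$h2
  }, 0)
  expect_lt(abs(median(h2_03) - 0.3), 0.08)
})

test_that("REML separates additive and permanent-environment variance", {
  # V_A = 1, V_PE = 1, V_E = 8, 10 records per FID (3 seeded replicates,
  # 400 FIDs; scaled down from the spec-scale design for runtime)
  h2 <- pe2 <- numeric(3)
  for (r in 1:3) {
    ped <- simulate_pedigree(20, 80, 5, seed = 540 + r)
    sim <- simulate_phenotypes_direct(ped, 1, 1, 8, 0, 10, seed = 550 + r)
    fit <- reml_animal_model(sim$records, ped, repeated = TRUE)
    h2[r] <- fit$h2; pe2[r] <- fit$pe2
  }
  expect_lt(abs(median(h2) - 0.10), 0.04)
  expect_lt(abs(median(pe2) - 0.10), 0.04)
})

test_that("grm construction and LOCO bookkeeping", {
  set.seed(63)
  n <- 300; m <- 800
  p <- runif(m, 0.1, 0.5)
  G <- sapply(p, function(pp) rbinom(n, 2, pp))
  pn <- snp_panel(chrom = rep(1:4, each = m / 4),
                  bp = rep(seq(1e6, 5e7, length.out = m / 4), 4))
  colnames(G) <- pn$marker
  rownames(G) <- sprintf("i%d", 1:n)

  K <- grm(G)
  expect_equal(K, t(K))
  # unrelated founders: mean diagonal ~ 1
  expect_lt(abs(mean(diag(K)) - 1), 0.05)

  # duplicated individuals: off-diagonal equals the diagonal
  G2 <- rbind(G, G[7, , drop = FALSE])
  rownames(G2) <- c(rownames(G), "dup")
  K2 <- grm(G2)
  expect_equal(K2[7, n + 1], K2[7, 7])

  # LOCO removes exactly the excluded chromosome's markers
  K3 <- grm(G, pn, exclude_chrom = 2)
  expect_identical(attr(K3, "n_markers"),
                   as.integer(m - sum(pn$chrom == 2)))
  expect_error(grm(G[, 1, drop = FALSE]), "fewer than 2")
})

test_that("null GWAS is calibrated: uniform P, lambda ~ 1, 5% type I", {
  set.seed(64)
  n <- 300; m <- 10000L
  p <- runif(m, 0.1, 0.5)
  G <- sapply(p, function(pp) rbinom(n, 2, pp))
  pn <- snp_panel(chrom = rep(1:10, each = m / 10),
                  bp = rep(seq(1e6, 1e8, length.out = m / 10), 10))
  colnames(G) <- pn$marker
  rownames(G) <- sprintf("i%d", 1:n)
  ph <- data.frame(id = rownames(G), value = rnorm(n))
  res <- mlm_loco_gwas(ph, G, pn)
  expect_identical(nrow(res), m)
  expect_gt(stats::ks.test(res$p_raw, "punif")$p.value, 0.01)
  expect_gt(mean(res$p_raw < 0.05), 0.035)
  expect_lt(mean(res$p_raw < 0.05), 0.065)
  expect_gt(attr(res, "lambda"), 0.9)
  expect_lt(attr(res, "lambda"), 1.1)
})

test_that("planted QTL: top hit, sign, and scale equivariance", {
  set.seed(65)
  n <- 400; m <- 1800
  p <- runif(m, 0.1, 0.5)
  G <- sapply(p, function(pp) rbinom(n, 2, pp))
  pn <- snp_panel(chrom = rep(1:6, each = m / 6),
                  bp = rep(seq(1e6, 1e8, length.out = m / 6), 6))
  colnames(G) <- pn$marker
  rownames(G) <- sprintf("i%d", 1:n)
  causal <- 1234L
  y <- 5 + 0.9 * G[, causal] + rnorm(n, 0, 1.2)
  ph <- data.frame(id = rownames(G), value = y)
  res <- mlm_loco_gwas(ph, G, pn)
  top <- res[which.min(res$p_raw)]
  expect_identical(top$marker, pn$marker[causal])
  # effect reported for the minor allele: sign matches the orientation
  want_sign <- if (mean(G[, causal]) / 2 > 0.5) -1 else 1
  expect_identical(sign(top$beta), want_sign)

  ph2 <- data.frame(id = rownames(G), value = 2 * y)
  res2 <- mlm_loco_gwas(ph2, G, pn)
  i <- match(pn$marker[causal], res2$marker)
  j <- match(pn$marker[causal], res$marker)
  expect_equal(res2$beta[i], 2 * res$beta[j], tolerance = 1e-6)
  expect_equal(res2$se[i], 2 * res$se[j], tolerance = 1e-6)
  expect_equal(res2$p_raw[i], res$p_raw[j], tolerance = 1e-6)

  # monomorphic SNPs are skipped with a reason
  G3 <- G; G3[, 5] <- 0L
  res3 <- mlm_loco_gwas(ph, G3, pn)
  expect_identical(res3[marker == pn$marker[5], note], "monomorphic")
})

test_that("LOCO relieves proximal contamination at the causal SNP", {
  # full-GRM Wald test implemented independently here as the comparator
  full_grm_chi2 <- function(y, X, G, x) {
    K <- grm(G)
    eig <- eigen(K, symmetric = TRUE)
    d <- pmax(eig$values, 1e-10); U <- eig$vectors
    yt <- crossprod(U, y); Xt <- crossprod(U, X)
    rll <- function(ld) {
      w <- 1 / (d + exp(ld))
      b <- solve(crossprod(Xt, Xt * w), crossprod(Xt, yt * w))
      r <- yt - Xt %*% b
      s2 <- sum(w * r^2) / (length(y) - ncol(X))
      -0.5 * ((length(y) - ncol(X)) * log(s2) + sum(log(d + exp(ld))) +
                determinant(crossprod(Xt, Xt * w))$modulus)
    }
    op <- optimize(rll, c(-8, 8), maximum = TRUE)
    w <- 1 / (d + exp(op$maximum))
    xt <- crossprod(U, x)
    cf <- solve(crossprod(Xt, Xt * w), crossprod(Xt, xt * w))
    ex <- xt - Xt %*% cf
    r <- yt - Xt %*% solve(crossprod(Xt, Xt * w), crossprod(Xt, yt * w))
    s2 <- sum(w * r^2) / (length(y) - ncol(X))
    b <- sum(ex * (w * yt)) / sum(ex * (w * ex))
    (b / sqrt(s2 / sum(ex * (w * ex))))^2
  }
  set.seed(66)
  n <- 250; m <- 900
  pn <- snp_panel(chrom = rep(1:6, each = m / 6),
                  bp = rep(seq(1e6, 1e8, length.out = m / 6), 6))
  wins <- 0L
  for (r in 1:10) {
    p <- runif(m, 0.1, 0.5)
    G <- sapply(p, function(pp) rbinom(n, 2, pp))
    colnames(G) <- pn$marker
    rownames(G) <- sprintf("i%d", 1:n)
    causal <- 77L
    y <- 0.8 * G[, causal] + rnorm(n)
    ph <- data.frame(id = rownames(G), value = y)
    res <- mlm_loco_gwas(ph, G, pn)
    chi_loco <- res$chi2[match(pn$marker[causal], res$marker)]
    chi_full <- full_grm_chi2(y, matrix(1, n, 1), G, G[, causal])
    if (chi_loco >= chi_full) wins <- wins + 1L
  }
  expect_gte(wins, 8L)
})

test_that("genomic control calibration and scaling", {
  x <- qchisq(c(0.2, 0.4, 0.5, 0.6, 0.8), df = 1)
  gc1 <- genomic_control(x)
  expect_equal(gc1$lambda, 1)
  expect_equal(gc1$chi2_adj, x)   # lambda = 1 leaves P unchanged
  gc2 <- genomic_control(2 * x)
  expect_equal(gc2$lambda, 2)
  # deflation (lambda < 1) never inflates significance
  gc3 <- genomic_control(0.5 * x)
  expect_equal(gc3$chi2_adj, 0.5 * x)
  expect_error(genomic_control(numeric(0)), "empty")
})

test_that("bonferroni_threshold arithmetic", {
  expect_equal(signif(bonferroni_threshold(0.05, 524587), 3), 9.53e-8)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 5), 0.01)
  expect_error(bonferroni_threshold(1.2, 10), "alpha")
  expect_error(bonferroni_threshold(0.05, 0), "n_tests")
})
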