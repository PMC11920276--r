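test_that("qc_genotypes applies MAF, call-rate and HWE filters", {
  set.seed(51)
  n <- 200
  # 10 markers: marker 1 has MAF 0.005, marker 2 call rate 0.90, rest clean
  geno <- sapply(1:10, function(j) rbinom(n, 2, 0.3))
  geno[, 1] <- c(rep(1L, 2), rep(0L, n - 2))            # maf = 0.005
  geno[21:40, 2] <- NA                                  # call rate 0.90
  colnames(geno) <- sprintf("m%d", 1:10)
  qc <- qc_genotypes(geno)
  expect_identical(sum(qc$keep), 8L)
  expect_identical(unname(qc$n_dropped["total"]), 2L)
  expect_identical(qc$report[marker == "m1", reason], "maf")
  expect_identical(qc$report[marker == "m2", reason], "callrate")

  # monomorphic marker is removed at the MAF boundary
  mono <- matrix(0L, n, 1, dimnames = list(NULL, "mono"))
  expect_identical(sum(qc_genotypes(cbind(geno[, 3:4], mono))$keep), 2L)

  # counts exactly at Hardy-Weinberg expectation: chi2 = 0, retained
  hw <- matrix(c(rep(0L, n / 4), rep(1L, n / 2), rep(2L, n / 4)), ncol = 1,
               dimnames = list(NULL, "hw"))
  qhw <- qc_genotypes(cbind(geno[, 3:4], hw))
  expect_equal(qhw$report[marker == "hw", hwe_chi2], 0)
  expect_true(qhw$keep[3])

  expect_error(qc_genotypes(matrix(numeric(0), 0, 0)), "empty")
})

test_that("infer_inheritance transmission and ambiguity rules", {
  pan <- data.table::data.table(marker = sprintf("m%d", 1:4),
                                bp = c(10, 20, 30, 40) * 1e6)
  focal <- rbind(c(0L, 1L, 0L, 1L),   # hapA
                 c(1L, 0L, 1L, 0L))   # hapB
  # m1: offspring hom 0 -> transmitted 0 = hapA
  # m2: offspring hom 2 -> transmitted 1 = hapA
  # m3: offspring het, other parent hom 0 -> transmitted 1 = hapB
  # m4: offspring het, other parent het -> ambiguous, skipped
  iv <- infer_inheritance(focal, other_geno = c(0L, 1L, 0L, 1L),
                          off_geno = c(0L, 2L, 1L, 1L), pan)
  expect_identical(iv$origin, c("hapA", "hapA", "hapB"))
  expect_identical(attr(iv, "n_ambiguous"), 1L)

  # focal homozygous markers never appear
  iv2 <- infer_inheritance(rbind(c(1L, 1L), c(1L, 0L)),
                           c(0L, 0L), c(1L, 1L), pan[1:2])
  expect_identical(nrow(iv2), 1L)

  # Mendelian inconsistency: offspring 0 but other parent hom 2
  iv3 <- infer_inheritance(rbind(c(0L, 0L), c(1L, 1L)),
                           c(2L, 0L), c(0L, 1L), pan[1:2])
  expect_identical(attr(iv3, "n_mendel_err"), 1L)
  expect_false("m1" %in% iv3$marker)

  # missing genotypes are skipped
  iv4 <- infer_inheritance(focal, c(0L, NA, 0L, 0L),
                           c(NA, 1L, 1L, 0L), pan)
  expect_false(any(c("m1", "m2") %in% iv4$marker))
})

test_that("infer_inheritance matches simulator truth on error-free trios", {
  sim <- small_sim(seed = 303, n_markers = 150, offspring = 2)
  ped <- sim$pedigree
  panel <- sim$genome$panel
  off <- ped[!is.na(ped$sire), ][1:4, ]
  for (i in seq_len(nrow(off))) {
    oid <- off$id[i]
    rows <- which(panel$chrom == 1)
    iv <- infer_inheritance(sim$haps[[off$sire[i]]][, rows],
                            sim$geno[off$dam[i], rows],
                            sim$geno[oid, rows], panel[rows])
    truth <- sim$origins[[oid]][1, rows]          # 1 = hapA, 2 = hapB
    got <- iv$origin
    want <- c("hapA", "hapB")[truth[match(iv$marker,
                                          panel$marker[rows])]]
    expect_identical(got, want)   # 100% of informative markers
    expect_gt(nrow(iv), 0)
  }
})

test_that("call_crossovers run logic and error absorption", {
  mkiv <- function(orgs) data.table::data.table(
    marker = sprintf("m%d", seq_along(orgs)),
    bp = seq_along(orgs) * 1e6, origin = orgs)

  expect_identical(nrow(call_crossovers(mkiv(rep("hapA", 10)))), 0L)

  # clean single switch: interval flanked by the switch-adjacent markers
  iv <- mkiv(c(rep("hapA", 5), rep("hapB", 5)))
  xo <- call_crossovers(iv, min_support = 3)
  expect_identical(nrow(xo), 1L)
  expect_equal(xo$left_bp, 5e6)
  expect_equal(xo$right_bp, 6e6)
  expect_equal(xo$midpoint_bp, 5.5e6)

  # isolated single-marker flip is absorbed (A A B A A)
  expect_identical(
    nrow(call_crossovers(mkiv(c("hapA", "hapA", "hapB", "hapA", "hapA")),
                         min_support = 3)), 0L)
  # ... but kept at min_support = 1
  expect_identical(
    nrow(call_crossovers(mkiv(c("hapA", "hapA", "hapB", "hapA", "hapA")),
                         min_support = 1)), 2L)

  # short run at a chromosome end is dropped, not called
  expect_identical(
    nrow(call_crossovers(mkiv(c(rep("hapA", 6), "hapB", "hapB")),
                         min_support = 3)), 0L)

  # interval endpoints after absorbing an error inside the transition
  iv2 <- mkiv(c(rep("hapA", 5), "hapB", "hapA", rep("hapB", 6)))
  # runs: A5 B1 A1 B6 -> short interior runs dropped -> A5 B6
  xo2 <- call_crossovers(iv2, min_support = 3)
  expect_identical(nrow(xo2), 1L)
  expect_equal(xo2$left_bp, 5e6)
  expect_equal(xo2$right_bp, 8e6)

  # determinism
  expect_identical(call_crossovers(iv2, 3), call_crossovers(iv2, 3))
  expect_error(call_crossovers(mkiv("hapA"), min_support = 0))
})

test_that("error-free calling with min_support 1 conserves counts exactly", {
  sim <- small_sim(seed = 304, n_markers = 300, offspring = 4)
  calls <- call_crossovers_all(sim, min_support = 1)
  panel <- sim$genome$panel
  og <- calls$origins
  # informative span per gamete-chromosome: truth outside the first/last
  # informative marker is unobservable in principle
  span <- og[, .(lo = min(bp), hi = max(bp)), by = .(fid, offspring, chrom)]
  truth <- merge(sim$truth_xo, span, by = c("fid", "offspring", "chrom"))
  truth_vis <- truth[bp > lo & bp < hi]
  tcount <- truth_vis[, .N, by = .(fid, offspring, chrom)]
  ccount <- calls$intervals[, .N, by = .(fid, offspring, chrom)]
  cmp <- merge(tcount, ccount, by = c("fid", "offspring", "chrom"),
               all = TRUE)
  cmp[is.na(cmp)] <- 0L
  expect_identical(cmp$N.x, cmp$N.y)

  # every visible true crossover lies inside its called interval
  setkey(calls$intervals, fid, offspring, chrom)
  for (i in seq_len(nrow(truth_vis))) {
    ivs <- calls$intervals[J(truth_vis$fid[i], truth_vis$offspring[i],
                             truth_vis$chrom[i])]
    expect_true(any(ivs$left_bp <= truth_vis$bp[i] &
                      ivs$right_bp >= truth_vis$bp[i]))
  }
})

test_that("calling is robust to array-scale genotyping error", {
  # 0.2% per-allele error, min_support 3, dense informative panel:
  # mean absolute per-gamete count error stays below 0.1 (fixed seed)
  sim <- small_sim(seed = 305, n_markers = 600, offspring = 6,
                   error_rate = 0.002)
  calls <- call_crossovers_all(sim, min_support = 3)
  tcount <- sim$truth_xo[, .N, by = .(fid, offspring)]
  ccount <- calls$intervals[, .N, by = .(fid, offspring)]
  cmp <- merge(tcount, ccount, by = c("fid", "offspring"), all = TRUE)
  cmp[is.na(cmp)] <- 0L
  expect_lt(mean(abs(cmp$N.x - cmp$N.y)), 0.1)
})
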