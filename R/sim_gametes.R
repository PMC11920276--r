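#' Simulate genotypes and gametes through a pedigree
#'
#' Drops haplotypes through a pedigree by simulating every meiosis under the
#' Stahl interference-escape crossover process ([simulate_stahl_positions()])
#' on the transmitting parent's sex-specific genetic map. Founder haplotypes
#' are drawn in linkage equilibrium at per-marker allele frequencies
#' `~ Uniform(0.05, 0.5)` (or supplied). Crossovers are simulated in cM and
#' placed on the physical scale by inverse map interpolation; a crossover
#' falling exactly on a marker is placed in the interval to its right. The
#' transmitted gamete switches between the parent's two phased haplotypes at
#' each crossover. Observed genotypes are the sum of the two transmitted
#' gametes with independent per-allele flip errors and per-genotype
#' missingness; the error-free truth (haplotypes, origins, crossover
#' positions) is retained for oracle checks.
#'
#' @param ped pedigree `data.table` (see [simulate_pedigree()]).
#' @param gen a `genome` with a marker panel.
#' @param nu interference shape (> 0).
#' @param p_escape escape fraction in \[0, 1).
#' @param error_rate per-allele genotyping error rate in \[0, 1).
#' @param missing_rate per-genotype missing rate in \[0, 1).
#' @param founder_freq optional numeric vector of founder allele frequencies
#'   (one per marker).
#' @param seed integer seed; one seeded generator drives the whole call.
#' @return list of class `gamete_sim`: `genome`, `pedigree`, `freq`,
#'   `haps` (per-id 2 x M phased haplotype matrix; row 1 = paternal gamete),
#'   `geno` (observed n x M dosage matrix with NAs), `truth_xo`
#'   (`data.table`: `fid`, `offspring`, `chrom`, `bp`, `cM`), and `origins`
#'   (per-offspring 2 x M matrix of transmitted parental haplotype indices).
#' @export
simulate_gametes <- function(ped, gen, nu = 8, p_escape = 0,
                             error_rate = 0, missing_rate = 0,
                             founder_freq = NULL, seed = NULL) {
  panel <- gen$panel
  if (is.null(panel) || nrow(panel) == 0L) stop("marker panel is empty")
  stopifnot(error_rate >= 0, error_rate < 1, missing_rate >= 0,
            missing_rate < 1)
  ped <- as.data.table(ped)
  with_seed(seed, {
    M <- nrow(panel)
    chroms <- unique(panel$chrom)
    mk_idx <- split(seq_len(M), panel$chrom)   # marker rows per chromosome
    if (is.null(founder_freq)) founder_freq <- runif(M, 0.05, 0.5)
    stopifnot(length(founder_freq) == M)
    lens <- list(M = map_lengths_cM(gen$map, "M"),
                 F = map_lengths_cM(gen$map, "F"))
    ord <- pedigree_order(ped)
    haps <- vector("list", nrow(ped)); names(haps) <- ped$id
    origins <- vector("list", nrow(ped)); names(origins) <- ped$id
    xo_l <- list()

    meiosis <- function(parent_id, parent_sex) {
      ph <- haps[[parent_id]]
      gam <- integer(M); org <- integer(M)
      xo_rows <- list()
      for (k in chroms) {
        idx <- mk_idx[[as.character(k)]]
        Lk <- lens[[parent_sex]][[as.character(k)]]
        xo_cM <- simulate_stahl_positions(Lk, nu, p_escape)[[1L]]
        xo_bp <- if (length(xo_cM)) cM_to_bp(gen$map, k, parent_sex, xo_cM)
                 else numeric(0)
        h0 <- sample(2L, 1L)
        sw <- findInterval(panel$bp[idx], xo_bp, left.open = TRUE)
        org_k <- ifelse(sw %% 2L == 0L, h0, 3L - h0)
        org[idx] <- org_k
        gam[idx] <- ph[cbind(org_k, idx)]
        if (length(xo_bp))
          xo_rows[[length(xo_rows) + 1L]] <-
            data.table(chrom = k, bp = xo_bp, cM = xo_cM)
      }
      list(gam = gam, org = org,
           xo = if (length(xo_rows)) rbindlist(xo_rows) else NULL)
    }

    for (i in ord) {
      id_i <- ped$id[i]
      if (is.na(ped$sire[i]) && is.na(ped$dam[i])) {
        haps[[id_i]] <- rbind(rbinom(M, 1L, founder_freq),
                              rbinom(M, 1L, founder_freq))
      } else {
        pat <- meiosis(ped$sire[i], "M")
        mat <- meiosis(ped$dam[i], "F")
        haps[[id_i]] <- rbind(pat$gam, mat$gam)
        origins[[id_i]] <- rbind(pat$org, mat$org)
        if (!is.null(pat$xo))
          xo_l[[length(xo_l) + 1L]] <-
            data.table(fid = ped$sire[i], offspring = id_i, pat$xo)
        if (!is.null(mat$xo))
          xo_l[[length(xo_l) + 1L]] <-
            data.table(fid = ped$dam[i], offspring = id_i, mat$xo)
      }
    }

    geno <- t(vapply(haps, function(h) {
      a1 <- h[1L, ]; a2 <- h[2L, ]
      if (error_rate > 0) {
        f1 <- runif(M) < error_rate; f2 <- runif(M) < error_rate
        a1 <- ifelse(f1, 1L - a1, a1); a2 <- ifelse(f2, 1L - a2, a2)
      }
      as.integer(a1 + a2)
    }, integer(M)))
    if (missing_rate > 0)
      geno[matrix(runif(length(geno)) < missing_rate, nrow(geno))] <- NA
    rownames(geno) <- ped$id; colnames(geno) <- panel$marker

    truth_xo <- if (length(xo_l)) {
      tx <- rbindlist(xo_l); setkey(tx, fid, offspring, chrom, bp); tx[]
    } else data.table(fid = character(), offspring = character(),
                      chrom = integer(), bp = numeric(), cM = numeric())
    structure(list(genome = gen, pedigree = ped, freq = founder_freq,
                   haps = haps, geno = geno, truth_xo = truth_xo,
                   origins = origins),
              class = "gamete_sim")
  })
}

#' @export
print.gamete_sim <- function(x, ...) {
  cat(sprintf("<gamete_sim> %d individuals x %d markers, %d true crossovers\n",
              nrow(x$geno), ncol(x$geno), nrow(x$truth_xo)))
  invisible(x)
}

#' Simulate phenotypes with a pedigree-structured genetic architecture
#'
#' Direct (non-mechanistic) phenotype simulation: breeding values follow the
#' pedigree recursion `a_i = (a_sire + a_dam)/2 + m_i` with
#' Mendelian-sampling variance `V_A / 2` (three quarters with one unknown
#' parent, `V_A` for founders; inbreeding ignored). Records are
#' `y_ij = mean + a_i + pe_i + qtl_i + e_ij` with `pe_i ~ N(0, V_PE)` and
#' `e_ij ~ N(0, V_E)`; an optional additive QTL adds `effect * dosage_i`.
#'
#' @param ped pedigree table with `id`, `sire`, `dam`.
#' @param V_A,V_PE,V_E variance components (>= 0).
#' @param mean phenotype mean.
#' @param n_records_per_fid repeated records per focal individual.
#' @param record_ids ids receiving records; defaults to all non-founders,
#'   or all individuals if the pedigree is founders-only.
#' @param qtl optional list `list(dosage = <named 0/1/2 vector>, effect = b)`.
#' @param seed integer seed.
#' @return list: `records` (`data.table` `id`, `gamete`, `value`), `bv`
#'   (named breeding values), `pe` (named permanent-environment effects).
#' @export
simulate_phenotypes_direct <- function(ped, V_A, V_PE, V_E, mean = 0,
                                       n_records_per_fid = 1,
                                       record_ids = NULL, qtl = NULL,
                                       seed = NULL) {
  stopifnot(V_A >= 0, V_PE >= 0, V_E >= 0, n_records_per_fid >= 1)
  ped <- as.data.table(ped)
  with_seed(seed, {
    ord <- pedigree_order(ped)
    idx <- setNames(seq_len(nrow(ped)), ped$id)
    a <- numeric(nrow(ped))
    for (i in ord) {
      s <- ped$sire[i]; d <- ped$dam[i]
      pa <- 0; vm <- V_A
      if (!is.na(s)) { pa <- pa + a[idx[[s]]] / 2; vm <- vm - V_A / 4 }
      if (!is.na(d)) { pa <- pa + a[idx[[d]]] / 2; vm <- vm - V_A / 4 }
      a[i] <- pa + rnorm(1L, 0, sqrt(vm))
    }
    names(a) <- ped$id
    if (is.null(record_ids)) {
      nf <- ped[!is.na(sire) | !is.na(dam), id]
      record_ids <- if (length(nf)) nf else ped$id
    }
    stopifnot(all(record_ids %in% ped$id))
    pe <- setNames(rnorm(length(record_ids), 0, sqrt(V_PE)), record_ids)
    q <- setNames(numeric(length(record_ids)), record_ids)
    if (!is.null(qtl)) {
      stopifnot(all(record_ids %in% names(qtl$dosage)))
      q <- qtl$effect * qtl$dosage[record_ids]
    }
    rec <- rbindlist(lapply(record_ids, function(f)
      data.table(id = f, gamete = seq_len(n_records_per_fid),
                 value = mean + a[[f]] + pe[[f]] + q[[f]] +
                   rnorm(n_records_per_fid, 0, sqrt(V_E)))))
    list(records = rec, bv = a, pe = pe)
  })
}
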