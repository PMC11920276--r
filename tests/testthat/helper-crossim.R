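# Shared fixture builders. Everything is generated in code at test time;
# sizes are deliberately small (seconds, not minutes) and seeds fixed.

# toy genome: n_chrom equal-length chromosomes, uniform (linear) maps for
# both sexes, optionally a marker panel with equally spaced markers
toy_genome <- function(n_chrom = 2, len_mb = 100, cM = 100,
                       n_markers = 0, arm_class = NULL, centromere_frac = 0.4) {
  bp_len <- rep(len_mb * 1e6, n_chrom)
  if (is.null(arm_class)) arm_class <- rep("metacentric", n_chrom)
  cen <- ifelse(arm_class == "metacentric", round(centromere_frac * bp_len), 0)
  cd <- chromosome_table(bp_len, cen, arm_class)
  anchors <- data.table::rbindlist(lapply(c("F", "M"), function(s)
    data.table::rbindlist(lapply(seq_len(n_chrom), function(k)
      data.table::data.table(chrom = k, sex = s,
                             bp = c(0, bp_len[k] / 2, bp_len[k]),
                             cM = c(0, cM / 2, cM))))))
  gm <- genetic_map(anchors)
  pn <- NULL
  if (n_markers > 0) {
    pn <- data.table::rbindlist(lapply(seq_len(n_chrom), function(k)
      data.table::data.table(chrom = k,
                             bp = round(seq(1, bp_len[k],
                                            length.out = n_markers)))))
    pn <- snp_panel(pn$chrom, pn$bp)
  }
  genome(cd, gm, pn)
}

# origins table for one gamete from explicit per-chromosome origin vectors
toy_origins <- function(origin_list) {
  data.table::rbindlist(lapply(seq_along(origin_list), function(k)
    data.table::data.table(chrom = k,
                           bp = seq_along(origin_list[[k]]) * 1e6,
                           origin = origin_list[[k]])))
}

# independent pair-enumeration oracle for intra-chromosomal shuffling:
# draw every ordered marker pair (with replacement) within each chromosome,
# count the uncoupled fraction, weight by squared genome fraction
r_intra_oracle <- function(origins, chrom_defs) {
  L <- chrom_defs$bp_length / sum(chrom_defs$bp_length)
  tot <- 0
  for (k in chrom_defs$chrom) {
    o <- origins[origins$chrom == k, ][["origin"]]
    m <- length(o)
    unc <- 0
    for (i in seq_len(m)) for (j in seq_len(m))
      if (o[i] != o[j]) unc <- unc + 1
    tot <- tot + (unc / m^2) * L[match(k, chrom_defs$chrom)]^2
  }
  tot
}

# small error-free gamete simulation reused by calling/phenotype tests
small_sim <- function(seed = 101, n_markers = 300, n_chrom = 2,
                      nu = 8, error_rate = 0, missing_rate = 0,
                      n_sires = 2, n_dams = 4, offspring = 4,
                      freq = 0.5) {
  gen <- toy_genome(n_chrom = n_chrom, n_markers = n_markers)
  ped <- simulate_pedigree(n_sires, n_dams, offspring, seed = seed)
  sim <- simulate_gametes(ped, gen, nu = nu, p_escape = 0,
                          error_rate = error_rate,
                          missing_rate = missing_rate,
                          founder_freq = rep(freq, n_markers * n_chrom),
                          seed = seed + 1)
  sim
}
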