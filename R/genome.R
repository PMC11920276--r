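#' Chromosome definitions
#'
#' Builds the table of physical chromosome properties used throughout the
#' package: base-pair length, centromere position and arm class. Metacentric
#' chromosomes have an internal centromere and two arms; acrocentric
#' chromosomes are modelled with the centromere coincident with one terminus,
#' so they carry a single arm.
#'
#' @param bp_length integer vector of chromosome lengths in bp.
#' @param centromere_bp centromere positions in bp. For metacentric
#'   chromosomes these must be strictly inside the chromosome; for acrocentric
#'   chromosomes they must equal 0 or `bp_length`.
#' @param arm_class character vector, `"metacentric"` or `"acrocentric"`.
#' @return A `data.table` with columns `chrom`, `bp_length`, `centromere_bp`,
#'   `arm_class`, one row per autosome, `chrom` = 1..n.
#' @export
chromosome_table <- function(bp_length, centromere_bp, arm_class) {
  n <- length(bp_length)
  stopifnot(length(centromere_bp) == n, length(arm_class) == n)
  if (n == 0L) stop("no chromosomes")
  arm_class <- match.arg(arm_class, c("metacentric", "acrocentric"),
                         several.ok = TRUE)
  cd <- data.table(
    chrom = seq_len(n),
    bp_length = as.numeric(bp_length),
    centromere_bp = as.numeric(centromere_bp),
    arm_class = arm_class
  )
  bad <- cd[arm_class == "metacentric" &
              !(centromere_bp > 0 & centromere_bp < bp_length), chrom]
  if (length(bad))
    stop("metacentric centromere not interior on chromosome(s) ",
         paste(bad, collapse = ", "))
  bad <- cd[arm_class == "acrocentric" &
              !(centromere_bp == 0 | centromere_bp == bp_length), chrom]
  if (length(bad))
    stop("acrocentric centromere must be terminal on chromosome(s) ",
         paste(bad, collapse = ", "))
  cd[]
}

#' Sex-specific genetic map
#'
#' A genetic map is a set of (bp, cM) interpolation anchors per chromosome and
#' sex. Anchors must be strictly increasing in bp, non-decreasing in cM, and
#' start at cM = 0.
#'
#' @param anchors data.frame with columns `chrom`, `sex` ("M"/"F"), `bp`, `cM`.
#' @return A `data.table` of class `genetic_map`, keyed by chromosome and sex.
#' @export
genetic_map <- function(anchors) {
  gm <- as.data.table(anchors)[, .(chrom, sex, bp = as.numeric(bp),
                                   cM = as.numeric(cM))]
  stopifnot(all(gm$sex %in% c("M", "F")))
  setkey(gm, chrom, sex, bp)
  gm[, {
    if (.N < 2L) stop("map needs >= 2 anchors for chromosome ", chrom[1L],
                      " sex ", sex[1L])
    if (any(diff(bp) <= 0)) stop("anchors not strictly increasing in bp")
    if (any(diff(cM) < 0)) stop("anchors decreasing in cM")
    if (cM[1L] != 0) stop("first anchor must be at cM = 0")
    NULL
  }, by = .(chrom, sex)]
  setattr(gm, "class", c("genetic_map", class(gm)))
  gm[]
}

#' Total genetic length per chromosome
#'
#' @param map a [genetic_map()].
#' @param sex "M" or "F".
#' @return named numeric vector of total cM per chromosome.
#' @export
map_lengths_cM <- function(map, sex) {
  s <- sex
  tot <- map[sex == s, .(cM = max(cM)), by = chrom]
  setNames(tot$cM, tot$chrom)
}

#' SNP marker panel
#'
#' @param chrom chromosome index per marker.
#' @param bp physical position per marker (1-based, inclusive).
#' @param id marker identifiers; defaults to `chr<k>_<bp>`.
#' @return `data.table` with columns `marker`, `chrom`, `bp`, sorted by
#'   chromosome then position.
#' @export
snp_panel <- function(chrom, bp, id = NULL) {
  if (is.null(id)) id <- sprintf("chr%d_%d", chrom, as.integer(bp))
  pn <- data.table(marker = id, chrom = as.integer(chrom), bp = as.numeric(bp))
  setkey(pn, chrom, bp)
  dup <- pn[, any(duplicated(bp)), by = chrom][V1 == TRUE, chrom]
  if (length(dup))
    stop("duplicate marker positions on chromosome(s) ",
         paste(dup, collapse = ", "))
  pn[]
}

#' Assemble a genome object
#'
#' Bundles chromosome definitions, genetic map and SNP panel and checks
#' cross-references (marker positions within chromosomes, map coverage).
#'
#' @param chrom_defs a [chromosome_table()].
#' @param map a [genetic_map()].
#' @param panel a [snp_panel()] or `NULL`.
#' @return list of class `genome` with elements `chrom`, `map`, `panel`.
#' @export
genome <- function(chrom_defs, map, panel = NULL) {
  g <- structure(list(chrom = chrom_defs, map = map, panel = panel),
                 class = "genome")
  rep <- validate_genome(g)
  if (nrow(rep)) stop("invalid genome:\n  ",
                      paste(rep$message, collapse = "\n  "))
  g
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %d autosomes, %.0f Mb total", nrow(x$chrom),
              sum(x$chrom$bp_length) / 1e6))
  for (s in c("F", "M"))
    if (any(x$map$sex == s))
      cat(sprintf("; %s map %.0f cM", s, sum(map_lengths_cM(x$map, s))))
  if (!is.null(x$panel)) cat(sprintf("; %d markers", nrow(x$panel)))
  cat("\n")
  invisible(x)
}

#' Validate a genome configuration
#'
#' Checks every structural invariant of the chromosome table, genetic map and
#' marker panel and reports violations rather than erroring, so inconsistent
#' inputs can be inspected.
#'
#' @param g a `genome` object, or a list with elements `chrom`, `map`,
#'   `panel`.
#' @return `data.table` with columns `component`, `where`, `message`; zero
#'   rows when everything passes.
#' @export
validate_genome <- function(g) {
  out <- list()
  add <- function(component, where, message)
    out[[length(out) + 1L]] <<- data.table(component = component,
                                           where = where, message = message)
  cd <- g$chrom
  if (is.null(cd) || nrow(cd) == 0L) {
    add("chrom", "", "no chromosomes")
  } else {
    if (!identical(sort(cd$chrom), seq_len(nrow(cd))))
      add("chrom", "", "chromosome indices not contiguous from 1")
    for (i in seq_len(nrow(cd))) {
      if (cd$bp_length[i] <= 0)
        add("chrom", paste0("chr", cd$chrom[i]), "non-positive bp_length")
      if (cd$arm_class[i] == "metacentric" &&
          !(cd$centromere_bp[i] > 0 && cd$centromere_bp[i] < cd$bp_length[i]))
        add("chrom", paste0("chr", cd$chrom[i]),
            sprintf("metacentric centromere not interior on chr%d",
                    cd$chrom[i]))
      if (cd$arm_class[i] == "acrocentric" &&
          !(cd$centromere_bp[i] %in% c(0, cd$bp_length[i])))
        add("chrom", paste0("chr", cd$chrom[i]),
            sprintf("acrocentric centromere not terminal on chr%d",
                    cd$chrom[i]))
    }
  }
  if (!is.null(g$map) && nrow(g$map)) {
    g$map[, {
      if (any(diff(bp) <= 0) || any(diff(cM) < 0) || cM[1L] != 0)
        add("map", sprintf("chr%d/%s", chrom[1L], sex[1L]),
            sprintf("non-monotone or unanchored map on chr%d sex %s",
                    chrom[1L], sex[1L]))
      k <- chrom[1L]
      if (!is.null(cd) && k %in% cd$chrom &&
          max(bp) > cd$bp_length[match(k, cd$chrom)])
        add("map", sprintf("chr%d/%s", chrom[1L], sex[1L]),
            sprintf("map anchor beyond chr%d end", k))
      NULL
    }, by = .(chrom, sex)]
  }
  if (!is.null(g$panel) && nrow(g$panel)) {
    pn <- g$panel
    if (!is.null(cd)) {
      m <- merge(pn, cd[, .(chrom, bp_length)], by = "chrom", all.x = TRUE)
      bad <- m[is.na(bp_length) | bp > bp_length | bp < 1]
      for (i in seq_len(nrow(bad)))
        add("panel", bad$marker[i],
            sprintf("marker %s outside chromosome %d", bad$marker[i],
                    bad$chrom[i]))
    }
    dup <- pn[, .(d = any(duplicated(bp))), by = chrom][d == TRUE, chrom]
    for (k in dup) add("panel", paste0("chr", k),
                       sprintf("duplicate positions on chr%d", k))
  }
  if (length(out)) rbindlist(out) else
    data.table(component = character(), where = character(),
               message = character())
}

#' Chromosome lengths as genome fractions
#'
#' Physical chromosome length divided by total genome length. These are the
#' weights \eqn{L_k} used by the intra-chromosomal allelic shuffling
#' statistic, where each chromosome's contribution is scaled by the squared
#' fraction of the genome it represents.
#'
#' @param chrom_defs a [chromosome_table()].
#' @return numeric vector of fractions summing to 1, named by chromosome.
#' @export
genome_fractions <- function(chrom_defs) {
  if (is.null(chrom_defs) || nrow(chrom_defs) == 0L) stop("no chromosomes")
  stopifnot(all(chrom_defs$bp_length > 0))
  setNames(chrom_defs$bp_length / sum(chrom_defs$bp_length),
           chrom_defs$chrom)
}

#' Interpolate physical position to genetic position
#'
#' Piecewise-linear interpolation between the flanking map anchors, on the
#' requested sex-specific map. Monotone non-decreasing in `bp`; exact at
#' anchors.
#'
#' @param map a [genetic_map()].
#' @param chrom chromosome index (scalar).
#' @param sex "M" or "F" (scalar).
#' @param bp numeric vector of positions.
#' @return numeric vector of cM positions.
#' @export
bp_to_cM <- function(map, chrom, sex, bp) {
  k <- chrom; s <- sex
  a <- map[J(k, s), on = c("chrom", "sex")]
  if (nrow(a) < 2L || anyNA(a$bp))
    stop("no map (>= 2 anchors) for chromosome ", k, " sex ", s)
  if (any(bp < 0 | bp > max(a$bp))) stop("position out of range")
  stats::approx(a$bp, a$cM, xout = bp, method = "linear", ties = "ordered",
                rule = 1, yleft = 0)$y
}

#' Interpolate genetic position to physical position
#'
#' Inverse of [bp_to_cM()]. Where the map has zero recombination (flat cM
#' segments) the inverse is set-valued; the leftmost bp is returned.
#'
#' @inheritParams bp_to_cM
#' @param cM numeric vector of genetic positions.
#' @return numeric vector of bp positions.
#' @export
cM_to_bp <- function(map, chrom, sex, cM) {
  k <- chrom; s <- sex
  a <- map[J(k, s), on = c("chrom", "sex")]
  if (nrow(a) < 2L || anyNA(a$bp))
    stop("no map (>= 2 anchors) for chromosome ", k, " sex ", s)
  if (any(cM < 0 | cM > max(a$cM))) stop("position out of range")
  stats::approx(a$cM, a$bp, xout = cM, method = "linear", ties = min,
                rule = 2)$y
}

#' Default synthetic genome
#'
#' An 18-autosome genome with pig-like physical scale: chromosomes 1-12
#' metacentric, 13-18 acrocentric, lengths declining from ~260 Mb to ~60 Mb.
#' Sex-specific maps are piecewise linear with mild telomeric enrichment of
#' recombination; the female map totals ~2440 cM and the male ~1820 cM, so
#' expected gamete crossover counts match typical female/male autosomal
#' totals of roughly 24 and 18.
#'
#' @param n_markers_per_chrom markers to place on each chromosome (equally
#'   spaced with a small jitter-free offset); `0` for no panel.
#' @return a `genome` object.
#' @export
default_genome <- function(n_markers_per_chrom = 60) {
  n <- 18L
  mb <- round(seq(260, 60, length.out = n))
  bp_len <- mb * 1e6
  arm <- rep(c("metacentric", "acrocentric"), c(12L, 6L))
  cen <- ifelse(arm == "metacentric", round(0.4 * bp_len), 0)
  cd <- chromosome_table(bp_len, cen, arm)

  tot_mb <- sum(mb)
  len_cM <- function(total) 50 + (total - 50 * n) * mb / tot_mb
  fr_bp <- c(0, .25, .5, .75, 1)     # anchor bp fractions
  fr_cM <- c(0, .30, .50, .70, 1)    # distal halves recombine more
  anchors <- rbindlist(lapply(c(F = "F", M = "M"), function(s) {
    tot <- if (s == "F") 2440 else 1820
    L <- len_cM(tot)
    rbindlist(lapply(seq_len(n), function(k)
      data.table(chrom = k, sex = s, bp = fr_bp * bp_len[k],
                 cM = fr_cM * L[k])))
  }))
  gm <- genetic_map(anchors)

  pn <- NULL
  if (n_markers_per_chrom > 0) {
    m <- as.integer(n_markers_per_chrom)
    pn <- rbindlist(lapply(seq_len(n), function(k)
      data.table(chrom = k,
                 bp = round(seq(1, bp_len[k], length.out = m)))))
    pn <- snp_panel(pn$chrom, pn$bp)
  }
  genome(cd, gm, pn)
}
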