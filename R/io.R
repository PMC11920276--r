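# Plain-TSV dialects: tab-separated, '#'-prefixed header comments, NA for
# missing. Every writer stamps tool version, seed and parameters so any
# output can be regenerated; readers skip comment lines and validate.

crossim_version <- function() {
  as.character(utils::packageVersion("crossim"))
}

#' Write a table in the package TSV dialect
#'
#' @param x data.frame/data.table.
#' @param path output path.
#' @param what short content tag recorded in the header.
#' @param seed,params optional provenance recorded in the header.
#' @return `path`, invisibly.
#' @export
write_tsv_c <- function(x, path, what = "table", seed = NULL,
                        params = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# crossim %s; what=%s%s%s", crossim_version(), what,
                     if (!is.null(seed)) paste0("; seed=", seed) else "",
                     if (!is.null(params))
                       paste0("; params=", paste(names(params), params,
                                                 sep = "=",
                                                 collapse = ",")) else ""),
             con)
  writeLines(sprintf("# written=%s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
             con)
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read a table in the package TSV dialect
#'
#' @param path input path.
#' @return `data.table`.
#' @export
read_tsv_c <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  as.data.table(read.delim(path, comment.char = "#", sep = "\t",
                           na.strings = "NA", stringsAsFactors = FALSE))
}

#' Write / read a genotype dosage matrix
#'
#' Rows are individuals (first column `id`), remaining columns are markers
#' with 0/1/2/NA dosages.
#'
#' @param geno matrix with rownames = ids.
#' @param path file path.
#' @inheritParams write_tsv_c
#' @return `write_genotypes()` returns `path`; `read_genotypes()` an
#'   integer matrix with rownames. Malformed dosage tokens are an error
#'   naming the offending data line.
#' @export
write_genotypes <- function(geno, path, seed = NULL, params = NULL) {
  dt <- data.table(id = rownames(geno))
  dt <- cbind(dt, as.data.table(geno))
  write_tsv_c(dt, path, "genotypes", seed, params)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  lines <- readLines(path)
  data_ln <- which(!startsWith(lines, "#"))
  if (!length(data_ln)) stop("no data in ", path)
  hdr <- strsplit(lines[data_ln[1L]], "\t", fixed = TRUE)[[1L]]
  body <- data_ln[-1L]
  rows <- strsplit(lines[body], "\t", fixed = TRUE)
  m <- length(hdr) - 1L
  out <- matrix(NA_integer_, length(rows), m,
                dimnames = list(vapply(rows, `[[`, "", 1L), hdr[-1L]))
  for (i in seq_along(rows)) {
    v <- rows[[i]][-1L]
    bad <- !v %in% c("0", "1", "2", "NA")
    if (any(bad))
      stop(sprintf("invalid genotype token '%s' at line %d of %s",
                   v[which(bad)[1L]], body[i], path))
    out[i, ] <- suppressWarnings(as.integer(v))
  }
  out
}

#' Write / read crossover intervals as BED-like TSV
#'
#' Columns `chrom`, `left_bp`, `right_bp`, `fid`, `offspring`,
#' `midpoint_bp`; the interval is the open span between the two flanking
#' informative markers.
#'
#' @param intervals interval table.
#' @param path file path.
#' @inheritParams write_tsv_c
#' @export
write_intervals <- function(intervals, path, seed = NULL, params = NULL) {
  iv <- as.data.table(intervals)
  write_tsv_c(iv[, .(chrom, left_bp, right_bp, fid, offspring, midpoint_bp)],
              path, "crossover_intervals", seed, params)
}

#' @rdname write_intervals
#' @export
read_intervals <- function(path) {
  iv <- read_tsv_c(path)
  need <- c("chrom", "left_bp", "right_bp", "fid", "offspring",
            "midpoint_bp")
  if (!all(need %in% names(iv)))
    stop("interval file missing columns: ",
         paste(setdiff(need, names(iv)), collapse = ", "))
  iv[]
}

#' Write / read phased haplotypes
#'
#' Two rows per individual (columns `id`, `hap` in 1:2, then one column per
#' marker with 0/1 alleles).
#'
#' @param haps named list of 2 x M haplotype matrices.
#' @param markers marker names (column header).
#' @param path file path.
#' @inheritParams write_tsv_c
#' @export
write_haplotypes <- function(haps, markers, path, seed = NULL) {
  rows <- lapply(names(haps), function(ind) {
    dt <- data.table(id = ind, hap = 1:2)
    dt[, (markers) := as.data.table(haps[[ind]])]
    dt
  })
  write_tsv_c(rbindlist(rows), path, "haplotypes", seed)
}

#' @rdname write_haplotypes
#' @export
read_haplotypes <- function(path) {
  dt <- read_tsv_c(path)
  ids <- unique(dt$id)
  mk <- setdiff(names(dt), c("id", "hap"))
  out <- lapply(ids, function(i) {
    h <- as.matrix(dt[id == i][order(hap), ..mk])
    dimnames(h) <- NULL
    h
  })
  names(out) <- ids
  out
}

#' Write / read a genome configuration as JSON
#'
#' Serializes chromosome definitions, map anchors and the marker panel into
#' one JSON document.
#'
#' @param g a `genome`.
#' @param path file path.
#' @export
write_genome <- function(g, path) {
  jsonlite::write_json(
    list(version = crossim_version(),
         chrom = g$chrom, map = as.data.table(g$map),
         panel = if (!is.null(g$panel)) g$panel else NULL),
    path, dataframe = "columns", digits = NA, null = "null", auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_genome
#' @export
read_genome <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cd <- as.data.table(j$chrom)
  gm <- genetic_map(as.data.table(j$map))
  pn <- if (!is.null(j$panel) && length(j$panel))
    snp_panel(j$panel$chrom, j$panel$bp, j$panel$marker) else NULL
  genome(cd, gm, pn)
}
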