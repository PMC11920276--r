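#' Default pipeline configuration
#'
#' Returns the full configuration list for [run_pipeline()] with every
#' parameter at its documented default; pass overrides as named arguments.
#' Stage toggles live under `stages`; simulation parameters mirror the
#' synthetic-data generator defaults.
#'
#' @param ... named overrides of top-level config entries.
#' @return named list.
#' @export
default_pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    out_dir = NULL,
    stages = list(simulate = TRUE, call = TRUE, phenotype = TRUE,
                  interference = TRUE, h2 = TRUE, gwas = TRUE),
    n_markers_per_chrom = 60L,
    n_sires = 5L, n_dams = 20L, offspring_per_pair = 4L,
    nu = 8, p_escape = 0.05,
    error_rate = 0, missing_rate = 0,
    min_support = 3L,
    p_weight = "markers",
    h2_repeated = TRUE,
    gwas_covariates = NULL)
  ov <- list(...)
  cfg[names(ov)] <- ov
  cfg
}

#' Run the full synthetic pipeline
#'
#' Executes the enabled stages in order: simulate gametes, call crossovers,
#' compute phenotypes, fit per-FID interference, estimate heritability of
#' the crossover count, and run the LOCO association scan on FID means.
#' Each stage writes its outputs as headered TSV under `out_dir`, and a
#' JSON manifest records package version, seed, parameters and per-stage
#' status. A disabled stage is marked "skipped"; a stage whose inputs are
#' missing raises an error naming the stage.
#'
#' @param config list from [default_pipeline_config()] (or a path to a JSON
#'   file with the same structure).
#' @return invisibly, a list with the in-memory stage results and
#'   `manifest`.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  cfg <- default_pipeline_config()
  cfg[names(config)] <- config
  if (is.null(cfg$out_dir)) stop("config$out_dir is required")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(cfg$seed, 6L)
  status <- list()
  res <- list()
  pth <- function(f) file.path(cfg$out_dir, f)
  msg <- function(stage, ...) message(sprintf("[%s] %s", stage,
                                              sprintf(...)))

  gen <- default_genome(cfg$n_markers_per_chrom)
  write_genome(gen, pth("genome.json"))

  if (isTRUE(cfg$stages$simulate)) {
    msg("simulate", "pedigree %dx%d, %d offspring/pair", cfg$n_sires,
        cfg$n_dams, cfg$offspring_per_pair)
    ped <- simulate_pedigree(cfg$n_sires, cfg$n_dams,
                             cfg$offspring_per_pair, seed = seeds[1L])
    sim <- simulate_gametes(ped, gen, nu = cfg$nu,
                            p_escape = cfg$p_escape,
                            error_rate = cfg$error_rate,
                            missing_rate = cfg$missing_rate,
                            seed = seeds[2L])
    write_tsv_c(ped, pth("pedigree.tsv"), "pedigree", cfg$seed)
    write_genotypes(sim$geno, pth("genotypes.tsv"), cfg$seed)
    write_haplotypes(sim$haps, gen$panel$marker, pth("haplotypes.tsv"),
                     cfg$seed)
    write_tsv_c(sim$truth_xo, pth("truth_crossovers.tsv"),
                "truth_crossovers", cfg$seed)
    res$sim <- sim
    status$simulate <- "complete"
  } else status$simulate <- "skipped"

  if (isTRUE(cfg$stages$call)) {
    if (is.null(res$sim))
      stop("stage 'call' requires outputs of stage 'simulate'")
    msg("call", "min_support=%d", cfg$min_support)
    calls <- call_crossovers_all(res$sim, min_support = cfg$min_support)
    write_intervals(calls$intervals, pth("crossovers.tsv"), cfg$seed,
                    params = c(min_support = cfg$min_support))
    write_tsv_c(calls$origins, pth("inheritance_vectors.tsv"),
                "inheritance_vectors", cfg$seed)
    res$calls <- calls
    status$call <- "complete"
  } else status$call <- "skipped"

  sexes <- NULL
  if (!is.null(res$sim)) {
    ped <- res$sim$pedigree
    sexes <- setNames(ped$sex, ped$id)
  }

  if (isTRUE(cfg$stages$phenotype)) {
    if (is.null(res$calls))
      stop("stage 'phenotype' requires outputs of stage 'call'")
    msg("phenotype", "computing per-gamete phenotypes")
    gp <- gamete_phenotypes(res$calls$intervals, res$calls$origins,
                            gen, p_weight = cfg$p_weight)
    fp <- aggregate_fid(gp, sexes)
    write_tsv_c(gp, pth("gamete_phenotypes.tsv"), "gamete_phenotypes",
                cfg$seed)
    write_tsv_c(fp, pth("fid_phenotypes.tsv"), "fid_phenotypes", cfg$seed)
    res$gp <- gp; res$fp <- fp
    status$phenotype <- "complete"
  } else status$phenotype <- "skipped"

  if (isTRUE(cfg$stages$interference)) {
    if (is.null(res$calls))
      stop("stage 'interference' requires outputs of stage 'call'")
    msg("interference", "per-FID Stahl fits")
    fits <- fit_stahl_per_fid(res$calls$intervals, gen, sexes)
    write_tsv_c(fits, pth("interference.tsv"), "stahl_fits", cfg$seed)
    res$interference <- fits
    status$interference <- "complete"
  } else status$interference <- "skipped"

  if (isTRUE(cfg$stages$h2)) {
    if (is.null(res$gp))
      stop("stage 'h2' requires outputs of stage 'phenotype'")
    msg("h2", "animal model on gamete crossover count")
    rec <- res$gp[, .(id = fid, value = count)]
    vc <- reml_animal_model(rec, res$sim$pedigree,
                            repeated = isTRUE(cfg$h2_repeated))
    jsonlite::write_json(
      list(V_A = vc$V_A, V_PE = vc$V_PE, V_E = vc$V_E, V_P = vc$V_P,
           h2 = vc$h2, pe2 = vc$pe2, converged = vc$converged,
           seed = cfg$seed),
      pth("variance_components.json"), auto_unbox = TRUE, digits = NA)
    res$h2 <- vc
    status$h2 <- "complete"
  } else status$h2 <- "skipped"

  if (isTRUE(cfg$stages$gwas)) {
    if (is.null(res$fp))
      stop("stage 'gwas' requires outputs of stage 'phenotype'")
    msg("gwas", "LOCO scan on FID mean crossover count")
    ph <- res$fp[, .(id = fid, value = count)]
    gw <- mlm_loco_gwas(ph, res$sim$geno, gen$panel,
                        covariates = cfg$gwas_covariates)
    write_tsv_c(gw, pth("gwas.tsv"), "gwas",
                cfg$seed, params = c(lambda = attr(gw, "lambda")))
    res$gwas <- gw
    status$gwas <- "complete"
  } else status$gwas <- "skipped"

  manifest <- list(package = "crossim", version = crossim_version(),
                   seed = cfg$seed,
                   parameters = cfg[setdiff(names(cfg),
                                            c("stages", "out_dir"))],
                   stages = status,
                   written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  res$manifest <- manifest
  invisible(res)
}
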