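#' Fit the Houseworth-Stahl interference-escape model
#'
#' Maximum-likelihood estimation of the interference shape `nu` and escape
#' fraction `p` by pooling the per-chromosome Stahl likelihood
#' ([chromosome_loglik()]) over all supplied gamete chromosomes with equal
#' weight. A coarse grid search (log-spaced `nu` in \[0.5, 50\], `p` in
#' 0, 0.02, ..., 0.2) seeds a derivative-free Nelder-Mead polish on the
#' transformed parameters `(log nu, t)` with `p = 0.5 t^2 / (1 + t^2)`, so
#' the boundary `p = 0` is an interior point of the search space.
#'
#' @param positions list of numeric vectors: sorted crossover positions in cM
#'   for each gamete chromosome. Chromosomes with zero crossovers must be
#'   present as empty vectors; they carry information about the crossover
#'   rate and interference strength.
#' @param lengths_cM numeric vector (or scalar) of chromosome genetic lengths
#'   in cM, parallel to `positions`.
#' @param fid optional label stored in the result.
#' @param polish logical; run the Nelder-Mead polish after the grid.
#' @param nu_grid,p_grid grid values for the coarse search.
#' @return An object of class `stahl_fit`: list with `nu_hat`, `p_hat`,
#'   `loglik`, `n_gametes` (gamete chromosomes used), `n_xo`, `converged`,
#'   `se` (approximate, from a finite-difference Hessian; `NA` on the
#'   boundary), and `trace`.
#' @export
fit_stahl <- function(positions, lengths_cM, fid = NA, polish = TRUE,
                      nu_grid = exp(seq(log(0.5), log(50), length.out = 15)),
                      p_grid = seq(0, 0.2, by = 0.02)) {
  prep <- stahl_prep(lapply(positions, `/`, 100), lengths_cM / 100)
  if (sum(prep$m) == 0L)
    return(structure(list(fid = fid, nu_hat = NA_real_, p_hat = NA_real_,
                          loglik = NA_real_, n_gametes = prep$n,
                          n_xo = 0L, converged = FALSE, se = c(NA, NA),
                          trace = "no crossovers: likelihood uninformative"),
                     class = "stahl_fit"))
  grid <- as.matrix(expand.grid(nu = nu_grid, p = p_grid))
  gl <- apply(grid, 1L, function(th)
    stahl_loglik_prep(prep, th[1L], th[2L]))
  best <- which.max(gl)
  nu0 <- grid[best, 1L]; p0 <- grid[best, 2L]
  fit <- list(par = c(log(nu0), sqrt(p0 / (0.5 - p0))), value = -gl[best],
              convergence = 0L, counts = c(0L, NA))
  if (polish) {
    obj <- function(th) {
      nu <- exp(th[1L]); p <- 0.5 * th[2L]^2 / (1 + th[2L]^2)
      -stahl_loglik_prep(prep, nu, p)
    }
    fit <- optim(fit$par, obj, method = "Nelder-Mead",
                 control = list(reltol = 1e-10, maxit = 500))
  }
  nu_hat <- exp(fit$par[1L])
  p_hat <- 0.5 * fit$par[2L]^2 / (1 + fit$par[2L]^2)
  se <- stahl_se(prep, nu_hat, p_hat)
  structure(list(fid = fid, nu_hat = nu_hat, p_hat = p_hat,
                 loglik = -fit$value, n_gametes = prep$n,
                 n_xo = sum(prep$m), converged = fit$convergence == 0L,
                 se = se,
                 trace = sprintf(
                   "grid best nu=%.3g p=%.3g loglik=%.4f; polish evals=%s",
                   nu0, p0, gl[best], fit$counts[1L])),
            class = "stahl_fit")
}

#' Fit the gamma interference model (no escape)
#'
#' The `p = 0` submodel of [fit_stahl()]: all crossovers are Class I. Grid
#' search on `nu` followed by a golden-section polish. Its maximized
#' log-likelihood can never exceed the Stahl fit's (nested models).
#'
#' @inheritParams fit_stahl
#' @return A `stahl_fit` with `p_hat = 0`.
#' @export
fit_gamma <- function(positions, lengths_cM, fid = NA, polish = TRUE,
                      nu_grid = exp(seq(log(0.5), log(50),
                                        length.out = 15))) {
  prep <- stahl_prep(lapply(positions, `/`, 100), lengths_cM / 100)
  if (sum(prep$m) == 0L)
    return(structure(list(fid = fid, nu_hat = NA_real_, p_hat = 0,
                          loglik = NA_real_, n_gametes = prep$n,
                          n_xo = 0L, converged = FALSE, se = c(NA, NA),
                          trace = "no crossovers: likelihood uninformative"),
                     class = "stahl_fit"))
  gl <- vapply(nu_grid, function(nu) stahl_loglik_prep(prep, nu, 0), 0)
  best <- which.max(gl)
  nu_hat <- nu_grid[best]; ll <- gl[best]; conv <- TRUE
  if (polish) {
    lo <- nu_grid[max(1L, best - 1L)]
    hi <- nu_grid[min(length(nu_grid), best + 1L)]
    op <- optimize(function(lnu) -stahl_loglik_prep(prep, exp(lnu), 0),
                   interval = log(c(lo, hi)), tol = 1e-7)
    nu_hat <- exp(op$minimum); ll <- -op$objective
  }
  se <- stahl_se(prep, nu_hat, 0)
  structure(list(fid = fid, nu_hat = nu_hat, p_hat = 0, loglik = ll,
                 n_gametes = prep$n, n_xo = sum(prep$m), converged = conv,
                 se = c(se[1L], NA),
                 trace = sprintf("gamma submodel; grid best nu=%.3g",
                                 nu_grid[best])),
            class = "stahl_fit")
}

# approximate SEs from a central finite-difference Hessian on (nu, p);
# p-boundary fits get NA for the p component
stahl_se <- function(prep, nu, p) {
  h <- c(nu * 1e-3, 1e-3)
  f <- function(nu, p) stahl_loglik_prep(prep, nu, p)
  out <- c(NA_real_, NA_real_)
  H11 <- (f(nu + h[1], p) - 2 * f(nu, p) + f(nu - h[1], p)) / h[1]^2
  if (is.finite(H11) && H11 < 0) out[1L] <- sqrt(-1 / H11)
  if (p > 2 * h[2L] && p < 0.5 - 2 * h[2L]) {
    H22 <- (f(nu, p + h[2]) - 2 * f(nu, p) + f(nu, p - h[2])) / h[2]^2
    H12 <- (f(nu + h[1], p + h[2]) - f(nu + h[1], p - h[2]) -
              f(nu - h[1], p + h[2]) + f(nu - h[1], p - h[2])) /
      (4 * h[1] * h[2])
    H <- matrix(c(H11, H12, H12, H22), 2L)
    V <- try(solve(-H), silent = TRUE)
    if (!inherits(V, "try-error") && all(base::diag(V) > 0))
      out <- sqrt(base::diag(V))
  }
  out
}

#' @export
print.stahl_fit <- function(x, ...) {
  cat(sprintf(
    "<stahl_fit%s> nu = %.3f, p = %.4f, loglik = %.3f, %d gamete-chromosomes (%d crossovers)%s\n",
    if (!is.na(x$fid)) paste0(" fid=", x$fid) else "",
    x$nu_hat, x$p_hat, x$loglik, x$n_gametes, x$n_xo,
    if (!x$converged) " [not converged]" else ""))
  invisible(x)
}

#' Build interference input from called crossover intervals
#'
#' Converts crossover interval midpoints to sex-specific cM positions and
#' assembles, for one focal individual, the per-gamete-chromosome position
#' lists (including empty chromosomes) that [fit_stahl()] expects.
#'
#' @param intervals data.frame of crossover intervals with columns
#'   `offspring`, `chrom`, `midpoint_bp` (one focal parent's gametes).
#' @param gen a `genome`.
#' @param sex sex of the focal parent ("M"/"F"): selects the map.
#' @param gametes character/integer vector of all gamete (offspring)
#'   identifiers for this parent, so zero-crossover chromosomes are included;
#'   defaults to the offspring present in `intervals`.
#' @return list with `positions` (list of cM vectors) and `lengths_cM`.
#' @export
stahl_data_from_intervals <- function(intervals, gen, sex,
                                      gametes = unique(intervals$offspring)) {
  iv <- as.data.table(intervals)
  lens <- map_lengths_cM(gen$map, sex)
  chroms <- as.integer(names(lens))
  positions <- vector("list", length(gametes) * length(chroms))
  lengths <- numeric(length(positions))
  i <- 0L
  for (g in gametes) {
    for (k in chroms) {
      i <- i + 1L
      mids <- sort(iv[offspring == g & chrom == k, midpoint_bp])
      cm <- if (length(mids)) bp_to_cM(gen$map, k, sex, mids) else numeric(0)
      # clamp away from the boundary: interval midpoints can in principle
      # interpolate to 0 or L cM at chromosome ends
      L <- lens[as.character(k)]
      cm <- pmin(pmax(cm, 1e-6 * L), (1 - 1e-6) * L)
      positions[[i]] <- cm
      lengths[i] <- L
    }
  }
  list(positions = positions, lengths_cM = lengths)
}

#' Per-FID Stahl fits
#'
#' Fits the interference-escape model separately for each focal individual
#' from a table of called crossover intervals, pooling all of that
#' individual's gametes and chromosomes.
#'
#' @param intervals data.frame with columns `fid`, `offspring`, `chrom`,
#'   `midpoint_bp`.
#' @param gen a `genome`.
#' @param sexes named vector mapping fid to "M"/"F".
#' @param model `"stahl"` (free `p`) or `"gamma"` (`p = 0`).
#' @return `data.table` with one row per FID: `fid`, `sex`, `nu_hat`,
#'   `p_hat`, `loglik`, `n_gametes`, `converged`.
#' @export
fit_stahl_per_fid <- function(intervals, gen, sexes, model = "stahl") {
  model <- match.arg(model, c("stahl", "gamma"))
  iv <- as.data.table(intervals)
  rbindlist(lapply(unique(iv$fid), function(f) {
    sub <- iv[fid == f]
    dat <- stahl_data_from_intervals(sub, gen, sexes[[as.character(f)]])
    fit <- if (model == "stahl")
      fit_stahl(dat$positions, dat$lengths_cM, fid = f)
    else fit_gamma(dat$positions, dat$lengths_cM, fid = f)
    data.table(fid = f, sex = sexes[[as.character(f)]],
               nu_hat = fit$nu_hat, p_hat = fit$p_hat, loglik = fit$loglik,
               n_gametes = length(unique(sub$offspring)),
               converged = fit$converged)
  }))
}
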