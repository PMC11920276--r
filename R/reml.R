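#' Pedigree animal model by AI-REML
#'
#' Univariate mixed ("animal") model with an additive genetic effect
#' structured by the pedigree numerator relationship matrix and, for
#' repeated records, a permanent-environment effect on the focal individual:
#' `y = Xb + Z a + (Z pe) + e`, `a ~ N(0, A V_A)`, `pe ~ N(0, I V_PE)`,
#' `e ~ N(0, I V_E)`. Variance components are estimated by restricted
#' maximum likelihood using average-information (AI) updates with
#' expectation-maximization (EM) fallback steps whenever an AI step leaves
#' the parameter space or decreases the restricted likelihood. Variances
#' are floored at `1e-10 * var(y)`; convergence is declared when successive
#' restricted log-likelihoods differ by less than `1e-8`.
#'
#' @param records data.frame with columns `id`, `value`, plus any covariate
#'   columns named in `covariates`. Multiple rows per id are repeated
#'   records.
#' @param ped pedigree with columns `id`, `sire`, `dam`; must contain every
#'   record id.
#' @param repeated logical; fit the permanent-environment effect.
#' @param covariates character vector of fixed-covariate column names.
#' @param max_iter,tol iteration cap and log-likelihood tolerance.
#' @return object of class `variance_components`: `V_A`, `V_PE`, `V_E`,
#'   `V_P`, `h2`, `pe2`, `se` (approximate SEs incl. delta-method `h2`),
#'   `loglik`, `converged`, `iterations`, `trace` (per-iteration
#'   `data.table`).
#' @export
reml_animal_model <- function(records, ped, repeated = FALSE,
                              covariates = NULL, max_iter = 100L,
                              tol = 1e-8) {
  rec <- as.data.table(records)
  ped <- as.data.table(ped)
  stopifnot(all(c("id", "value") %in% names(rec)))
  if (!all(rec$id %in% ped$id))
    stop("record id(s) missing from pedigree: ",
         paste(head(setdiff(rec$id, ped$id)), collapse = ", "))
  y <- rec$value
  n <- length(y)
  q <- nrow(ped)
  X <- if (is.null(covariates)) matrix(1, n, 1L) else
    model.matrix(stats::reformulate(covariates), data = rec)
  p <- qr(X)$rank
  Za <- sparseMatrix(i = seq_len(n), j = match(rec$id, ped$id), x = 1,
                     dims = c(n, q))
  fids <- unique(rec$id)
  q_pe <- if (repeated) length(fids) else 0L
  W <- if (repeated)
    cbind(Matrix::Matrix(X, sparse = TRUE), Za,
          sparseMatrix(i = seq_len(n), j = match(rec$id, fids), x = 1,
                       dims = c(n, q_pe)))
  else cbind(Matrix::Matrix(X, sparse = TRUE), Za)
  nt <- ncol(W)
  ia <- ncol(X) + seq_len(q)                 # coefficient rows for a
  ipe <- if (repeated) ncol(X) + q + seq_len(q_pe) else integer(0)
  Ainv <- a_matrix_inverse(ped)
  ldet_A <- -2 * Matrix::determinant(Matrix::Cholesky(
    Ainv, perm = TRUE, LDL = FALSE), sqrt = TRUE)$modulus  # -log|A^-1|
  WtW <- crossprod(W)
  Wty <- as.numeric(crossprod(W, y))
  yty <- sum(y^2)
  vp0 <- var(y)
  floor_v <- 1e-10 * vp0

  theta <- if (repeated) c(va = 0.3, vpe = 0.1, ve = 0.6) * vp0
           else c(va = 0.3, ve = 0.7) * vp0
  k_a <- 1L; k_pe <- if (repeated) 2L else NA_integer_
  k_e <- if (repeated) 3L else 2L

  eval_mme <- function(th) {
    va <- th[k_a]; ve <- th[k_e]
    vpe <- if (repeated) th[k_pe] else NA_real_
    Gi <- Ainv / va
    C <- WtW / ve
    C[ia, ia] <- C[ia, ia] + Gi
    if (repeated) C[ipe, ipe] <- C[ipe, ipe] + Diagonal(q_pe) / vpe
    ch <- Matrix::Cholesky(Matrix::forceSymmetric(C), perm = TRUE,
                           LDL = FALSE)
    sol <- as.numeric(solve(ch, Wty / ve))
    yPy <- (yty - sum(sol * Wty)) / ve
    ldet_C <- 2 * Matrix::determinant(ch, sqrt = TRUE)$modulus
    # log|V| + log|X'V^-1 X| = n log ve + log|G| + log|C| with C scaled
    # by 1/ve (Harville identity)
    ll <- -0.5 * (n * log(ve) + ldet_A + q * log(va) +
                    (if (repeated) q_pe * log(vpe) else 0) +
                    ldet_C + yPy)
    list(ll = as.numeric(ll), sol = sol, ch = ch, C = C)
  }

  em_ai_info <- function(th, mm) {
    va <- th[k_a]; ve <- th[k_e]
    vpe <- if (repeated) th[k_pe] else NA_real_
    Cinv <- as.matrix(solve(mm$ch, base::diag(nt)))
    ua <- mm$sol[ia]
    Taa <- sum(Ainv * Cinv[ia, ia])
    uAu <- as.numeric(ua %*% (Ainv %*% ua))
    ehat <- as.numeric(y - W %*% mm$sol)
    Py <- ehat / ve
    em <- theta
    em[k_a] <- (uAu + Taa) / q
    if (repeated) {
      upe <- mm$sol[ipe]
      Tpe <- sum(base::diag(Cinv)[ipe])
      em[k_pe] <- (sum(upe^2) + Tpe) / q_pe
    }
    em[k_e] <- (yty - sum(mm$sol * Wty)) / (n - p)
    # gradient
    TWW <- sum(WtW * Cinv)
    trP <- n / ve - TWW / ve^2
    trPVa <- (q - Taa / va) / va
    tvec <- list()
    tvec[[k_a]] <- as.numeric(Za %*% ua) / va
    if (repeated) {
      upe <- mm$sol[ipe]
      trPVpe <- (q_pe - sum(base::diag(Cinv)[ipe]) / vpe) / vpe
      tvec[[k_pe]] <- as.numeric(W[, ipe] %*% upe) / vpe
    }
    tvec[[k_e]] <- Py
    g <- numeric(length(theta))
    g[k_a] <- -0.5 * (trPVa - sum(tvec[[k_a]] * Py))
    if (repeated) g[k_pe] <- -0.5 * (trPVpe - sum(tvec[[k_pe]] * Py))
    g[k_e] <- -0.5 * (trP - sum(Py * Py))
    # average information: AI_ij = t_i' P t_j / 2
    Pt <- lapply(tvec, function(t) {
      st <- as.numeric(solve(mm$ch, as.numeric(crossprod(W, t)) / ve))
      (t - as.numeric(W %*% st)) / ve
    })
    K <- length(theta)
    AI <- matrix(0, K, K)
    for (i in seq_len(K)) for (j in i:K) {
      AI[i, j] <- 0.5 * sum(tvec[[i]] * Pt[[j]])
      AI[j, i] <- AI[i, j]
    }
    list(em = em, g = g, AI = AI)
  }

  mm <- eval_mme(theta)
  trace <- list()
  converged <- FALSE
  AI_last <- NULL
  pin_tol <- 1e-6 * vp0       # components below this are treated as zero
  pinned <- rep(FALSE, length(theta))
  n_warmup <- 3L              # EM warm-up before trusting AI steps
  for (it in seq_len(max_iter)) {
    info <- em_ai_info(theta, mm)
    AI_last <- info$AI
    # release a pinned component if its gradient points into the interior
    pinned[pinned & info$g > 0] <- FALSE
    free <- which(!pinned)
    step_type <- "EM"; mm_new <- NULL; th_new <- NULL
    if (it > n_warmup && length(free)) {
      dir <- tryCatch(as.numeric(solve(info$AI[free, free, drop = FALSE],
                                       info$g[free])),
                      error = function(e) NULL)
      if (!is.null(dir) && all(is.finite(dir))) {
        fac <- 1
        for (half in 1:6) {       # step-halving line search
          cand <- theta
          cand[free] <- theta[free] + fac * dir
          cand <- pmax(cand, floor_v)
          mm_c <- eval_mme(cand)
          if (is.finite(mm_c$ll) && mm_c$ll >= mm$ll - 1e-12) {
            th_new <- cand; mm_new <- mm_c
            step_type <- if (fac == 1) "AI" else "AI-halved"
            break
          }
          fac <- fac / 2
        }
      }
    }
    if (is.null(mm_new)) {      # EM fallback: guaranteed uphill
      th_new <- theta
      th_new[free] <- pmax(info$em[free], floor_v)
      mm_new <- eval_mme(th_new)
    }
    newly_pinned <- th_new < pin_tol & th_new > floor_v
    pinned[th_new < pin_tol] <- TRUE
    th_new[pinned] <- floor_v
    if (any(newly_pinned)) mm_new <- eval_mme(th_new)
    trace[[it]] <- data.table(iter = it, step = step_type,
                              loglik = mm_new$ll,
                              V_A = th_new[k_a],
                              V_PE = if (repeated) th_new[k_pe] else 0,
                              V_E = th_new[k_e])
    dl <- abs(mm_new$ll - mm$ll)
    theta <- th_new; mm <- mm_new
    if (dl < tol && it > n_warmup) { converged <- TRUE; break }
  }
  va <- theta[k_a]; ve <- theta[k_e]
  vpe <- if (repeated) theta[k_pe] else 0
  vtot <- va + vpe + ve
  se <- c(V_A = NA_real_, V_PE = NA_real_, V_E = NA_real_, h2 = NA_real_,
          pe2 = NA_real_)
  Vcov <- tryCatch(solve(AI_last), error = function(e) NULL)
  if (!is.null(Vcov) && all(is.finite(Vcov)) &&
      all(base::diag(Vcov) >= 0)) {
    sd3 <- sqrt(base::diag(Vcov))
    se["V_A"] <- sd3[k_a]; se["V_E"] <- sd3[k_e]
    if (repeated) se["V_PE"] <- sd3[k_pe]
    gh <- numeric(length(theta))
    gh[k_a] <- (vtot - va) / vtot^2
    gh[k_e] <- -va / vtot^2
    if (repeated) gh[k_pe] <- -va / vtot^2
    se["h2"] <- sqrt(max(0, as.numeric(gh %*% Vcov %*% gh)))
    if (repeated) {
      gp <- numeric(length(theta))
      gp[k_pe] <- (vtot - vpe) / vtot^2
      gp[k_a] <- -vpe / vtot^2; gp[k_e] <- -vpe / vtot^2
      se["pe2"] <- sqrt(max(0, as.numeric(gp %*% Vcov %*% gp)))
    }
  }
  structure(list(V_A = unname(va), V_PE = unname(vpe), V_E = unname(ve),
                 V_P = unname(vtot), h2 = unname(va / vtot),
                 pe2 = unname(vpe / vtot), se = se, loglik = mm$ll,
                 converged = converged, iterations = length(trace),
                 trace = rbindlist(trace)),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(
    "<variance_components> V_A=%.4g V_PE=%.4g V_E=%.4g V_P=%.4g\n  h2=%.4f (SE %.4f)  pe2=%.4f  logL=%.4f  %s in %d iter\n",
    x$V_A, x$V_PE, x$V_E, x$V_P, x$h2, x$se[["h2"]], x$pe2, x$loglik,
    if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}
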