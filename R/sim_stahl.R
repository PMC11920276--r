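#' Simulate gamete crossover positions under the Stahl escape model
#'
#' Crossovers arise from two superposed processes on the genetic (Morgan)
#' scale. Interfering (Class I) chiasmata form on the four-strand bivalent as
#' a stationary gamma renewal process with shape `nu` and rate
#' `2 * nu * (1 - p_escape)` events per Morgan; each chiasma is transmitted to
#' the gamete independently with probability 1/2 (thinning; no chromatid
#' interference). Non-interfering (Class II) crossovers are superposed as a
#' homogeneous Poisson process with gamete-scale rate `p_escape` per Morgan.
#' The expected total gamete crossover count therefore equals the chromosome
#' length in Morgans for every `(nu, p_escape)`.
#'
#' Stationarity of the renewal process is achieved by starting the process a
#' long burn-in distance (30 mean inter-arrivals + 2 Morgans) before the
#' chromosome and discarding events left of the origin.
#'
#' @param length_cM chromosome genetic length in cM (>= 0).
#' @param nu gamma shape (interference strength); `nu = 1` is the
#'   no-interference Poisson case.
#' @param p_escape fraction of crossovers escaping interference, in \[0, 1).
#' @param n number of independent gametes to draw.
#' @param seed optional integer seed (local to this call).
#' @return A list of `n` numeric vectors of sorted crossover positions in cM.
#' @export
simulate_stahl_positions <- function(length_cM, nu, p_escape = 0, n = 1,
                                     seed = NULL) {
  if (!is.finite(nu) || nu <= 0) stop("nu must be > 0")
  if (!is.finite(p_escape) || p_escape < 0 || p_escape >= 1)
    stop("p_escape must be in [0, 1)")
  if (length_cM < 0) stop("length_cM must be >= 0")
  with_seed(seed, {
    L <- length_cM / 100                       # Morgans
    if (L == 0) return(replicate(n, numeric(0), simplify = FALSE))
    lambda <- 2 * nu * (1 - p_escape)          # chiasma renewal rate
    mu <- nu / lambda                          # mean inter-arrival
    burn <- 30 * mu + 2
    lapply(seq_len(n), function(i) {
      # chiasma positions on the bivalent, started in the distant past
      k0 <- ceiling((burn + L) / mu) + 10L
      x <- cumsum(rgamma(k0, shape = nu, rate = lambda)) - burn
      while (x[length(x)] < L)
        x <- c(x, x[length(x)] + cumsum(rgamma(10L, shape = nu,
                                               rate = lambda)))
      chi <- x[x > 0 & x < L]
      xo1 <- chi[runif(length(chi)) < 0.5]     # pass to gamete w.p. 1/2
      m2 <- rpois(1L, p_escape * L)            # Class II, gamete scale
      xo2 <- runif(m2, 0, L)
      sort(c(xo1, xo2)) * 100
    })
  })
}
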