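#' Model parameters for the multistate telemetry HMM
#'
#' Bundle the full parameter vector of the movement model: monthly survival
#' `phi`, monthly battery-retention `delta`, the column-stochastic pool
#' transition matrix `psi` (destination in rows, origin in columns), the
#' pool-level detection effects `beta`, and their hierarchical mean `theta`
#' and standard deviation `sigma`. The detection intercept is the fixed
#' constant -5 on the logit scale, which pins the detection curve to the
#' origin when no receivers are deployed.
#'
#' @param phi Monthly survival probability, in `[0, 1]`.
#' @param delta Monthly battery-retention probability, in `[0, 1]`.
#' @param psi Square column-stochastic matrix of pool transition
#'   probabilities; `psi[i, j]` is the probability of moving to pool `i`
#'   from pool `j` conditional on being alive with an operable battery.
#' @param beta Numeric vector of pool-level detection effects, one per pool.
#' @param theta Hierarchical mean of the pool effects.
#' @param sigma Hierarchical standard deviation of the pool effects
#'   (non-negative).
#' @param intercept Fixed logit-scale detection intercept; default -5.
#' @return An object of class `model_params`.
#' @examples
#' p <- model_params(0.96, 0.97, default_psi(6), beta = seq(0.3, 3, length.out = 6))
#' colSums(build_transition(p))
#' @export
model_params <- function(phi, delta, psi, beta, theta = mean(beta),
                         sigma = if (length(beta) > 1)
                           max(stats::sd(beta), 1e-6) else 1,
                         intercept = -5) {
  p <- structure(
    list(phi = phi, delta = delta, psi = psi, beta = as.numeric(beta),
         theta = theta, sigma = sigma, intercept = intercept),
    class = "model_params")
  validate_params(p)
  p
}

#' @rdname model_params
#' @param x A `model_params` object.
#' @export
validate_params <- function(x) {
  stopifnot(inherits(x, "model_params"))
  with(x, {
    if (!is.numeric(phi) || phi < 0 || phi > 1) stop("phi must be in [0, 1]")
    if (!is.numeric(delta) || delta < 0 || delta > 1) stop("delta must be in [0, 1]")
    if (!is.matrix(psi) || nrow(psi) != ncol(psi)) stop("psi must be square")
    if (any(psi < 0)) stop("psi entries must be non-negative")
    if (any(abs(colSums(psi) - 1) > 1e-10))
      stop("each psi column must sum to 1 (tolerance 1e-10)")
    if (length(beta) != nrow(psi)) stop("beta must have one entry per pool")
    if (sigma < 0) stop("sigma must be non-negative")
  })
  invisible(x)
}

#' @rdname model_params
#' @export
n_pools <- function(x) nrow(x$psi)

#' Default diagonally dominant pool-transition matrix
#'
#' A realistic river-pool transition kernel: strong monthly fidelity to the
#' current pool, moderate one-pool downstream drift, weaker upstream
#' movement, and rapidly decaying probabilities for multi-pool jumps. Pool 1
#' is the most downstream pool and the system is closed, so edge pools
#' accumulate the probability that would otherwise leave the river reach.
#'
#' @param n Number of pools.
#' @return An `n` by `n` column-stochastic matrix (destination rows, origin
#'   columns).
#' @export
default_psi <- function(n = 6) {
  w_down <- c(0.100, 0.025, 0.008)  # 1, 2, 3 pools downstream
  w_up <- c(0.045, 0.012, 0.004)    # upstream
  m <- matrix(0.002, n, n)
  diag(m) <- 1
  for (j in seq_len(n)) {
    for (k in seq_along(w_down)) if (j - k >= 1) m[j - k, j] <- w_down[k]
    for (k in seq_along(w_up)) if (j + k <= n) m[j + k, j] <- w_up[k]
  }
  sweep(m, 2, colSums(m), "/")
}
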