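#' Posterior movement and detection summaries
#'
#' Reduces a fitted model to the quantities of scientific interest: the
#' monthly movement matrix (posterior mean of the product
#' `phi * delta * psi[i, j]`, averaged draw-by-draw rather than as a product
#' of posterior means), its stay/upstream/downstream reduction, per-pool
#' detection-probability curves over effort (posterior median and 95%
#' credible band on a grid from zero to the pool's maximum observed effort),
#' and the detection-probability time series at the observed monthly effort.
#'
#' @param fit A `poolstate_fit` from [fit_mcmc].
#' @param effort Effort matrix or long data frame used in the fit.
#' @param grid_n Number of grid points for the detection curves.
#' @param max_draws Posterior draws used for the derived quantities
#'   (subsampled evenly when the fit holds more).
#' @return List with elements `movement_matrix`, `movement_summary` (six-pool
#'   fits only), `detection_curves`, `detection_series`, and
#'   `mean_phi_delta`.
#' @export
derive_outputs <- function(fit, effort, grid_n = 50, max_draws = 2000) {
  stopifnot(inherits(fit, "poolstate_fit"))
  effort <- effort_matrix(effort)
  P <- fit$n_pools
  d <- posterior_draws(fit, max_draws)
  phi <- d[, "phi"]; delta <- d[, "delta"]
  psi_cols <- grep("^psi\\[", colnames(d))
  mv <- matrix(colMeans(d[, psi_cols, drop = FALSE] * (phi * delta)), P, P)
  dimnames(mv) <- list(to = paste0("pool_", seq_len(P)),
                       from = paste0("pool_", seq_len(P)))
  curves <- do.call(rbind, lapply(seq_len(P), function(j) {
    xs <- seq(0, max(effort[j, ]), length.out = grid_n)
    b <- d[, paste0("beta[", j, "]")]
    rho <- stats::plogis(fit$intercept + outer(b, xs))
    qs <- apply(rho, 2, stats::quantile, c(0.5, 0.025, 0.975))
    data.frame(pool = j, x = xs, median = qs[1, ], lo = qs[2, ], hi = qs[3, ])
  }))
  series <- do.call(rbind, lapply(seq_len(P), function(j) {
    b <- d[, paste0("beta[", j, "]")]
    rho <- stats::plogis(fit$intercept + outer(b, effort[j, ]))
    qs <- apply(rho, 2, stats::quantile, c(0.5, 0.025, 0.975))
    data.frame(pool = j, month = seq_len(ncol(effort)), x = effort[j, ],
               median = qs[1, ], lo = qs[2, ], hi = qs[3, ])
  }))
  list(movement_matrix = mv,
       movement_summary = if (P == 6) summarize_movement_matrix(mv),
       detection_curves = curves, detection_series = series,
       mean_phi_delta = mean(phi * delta))
}

#' Dense-grid posterior for the collapsed single-pool model
#'
#' Exact (numerical-integration) posterior for the model with one pool, in
#' which the transition matrix collapses to the four status states and the
#' free parameters are `phi`, `delta` and the single detection effect
#' `beta` with a fixed `Normal(theta0, sigma0)` prior. Serves as an
#' independent cross-check of the MCMC sampler: both target the identical
#' posterior, so means and SDs must agree within Monte-Carlo error.
#'
#' @param histories,effort As in [fit_mcmc] (single-pool symbols
#'   `"pool_1"`, `"none"`, `"expired"`).
#' @param n_grid Grid points per dimension.
#' @param phi_range,delta_range,beta_range Grid supports; the `phi`/`delta`
#'   priors are uniform on (0,1) so restricting the grid to a range that
#'   contains the posterior mass is purely a numerical choice.
#' @param theta0,sigma0 Fixed prior mean/SD for `beta`.
#' @param intercept Fixed logit intercept.
#' @return List with marginal `mean` and `sd` for `phi`, `delta`, `beta`.
#' @export
grid_posterior_1pool <- function(histories, effort, n_grid = 50,
                                 phi_range = c(0.6, 1), delta_range = c(0.6, 1),
                                 beta_range = c(-1, 6),
                                 theta0 = 0, sigma0 = 1, intercept = -5) {
  effort <- effort_matrix(effort)[1, , drop = FALSE]
  hs <- as_history_set(histories, ncol(effort), n_pools = 1)
  stopifnot(hs$n_pools == 1)
  mid <- function(r) seq(r[1], r[2], length.out = n_grid + 1)[-1] -
    diff(r) / (2 * n_grid)
  phis <- mid(phi_range); deltas <- mid(delta_range); betas <- mid(beta_range)
  psi1 <- matrix(1, 1, 1)
  lp <- array(NA_real_, c(n_grid, n_grid, n_grid))
  for (i in seq_len(n_grid)) for (j in seq_len(n_grid)) {
    # likelihood factorizes over beta only through emissions, but the
    # forward pass is cheap enough to evaluate on the full 3-d grid
    for (k in seq_len(n_grid)) {
      lp[i, j, k] <- cpp_total_loglik(hs$obs, hs$rel_month, hs$rel_pool,
                                      hs$last_month, phis[i], deltas[j], psi1,
                                      betas[k], effort, intercept) +
        stats::dnorm(betas[k], theta0, sigma0, log = TRUE)
    }
  }
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  m_phi <- apply(w, 1, sum); m_delta <- apply(w, 2, sum)
  m_beta <- apply(w, 3, sum)
  mom <- function(g, w) {
    mu <- sum(g * w)
    list(mean = mu, sd = sqrt(sum((g - mu)^2 * w)))
  }
  list(phi = mom(phis, m_phi), delta = mom(deltas, m_delta),
       beta = mom(betas, m_beta))
}
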