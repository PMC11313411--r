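#' Effort-dependent detection probability
#'
#' Monthly probability that a fish alive with an operable transmitter in
#' pool `j` is detected at least once, as a logistic function of the mean
#' number of receivers deployed per day (`x`, "receiver-days"):
#' `rho = plogis(intercept + beta * x)`. The intercept is fixed at -5 so the
#' curve approaches zero detection as receiver deployment approaches zero.
#'
#' @param beta Pool-level detection effect (scalar or vector, recycled
#'   against `x`).
#' @param x Mean receiver-days (non-negative).
#' @param intercept Fixed logit-scale intercept; default -5.
#' @return Detection probability in (0, 1).
#' @examples
#' detection_prob(5, 1)    # 0.5: logit argument is exactly zero
#' detection_prob(2, 0)    # 1 / (1 + exp(5)), the no-receiver floor
#' @export
detection_prob <- function(beta, x, intercept = -5) {
  stopifnot(all(x >= 0))
  stats::plogis(intercept + beta * x)
}

#' Full state-transition matrix of the multistate model
#'
#' Builds the column-stochastic transition matrix over the `P + 3` latent
#' states: alive/operable in each of the `P` pools (the pool sub-matrix
#' `phi * delta * psi` nested in the top-left block), dead/operable (D/O),
#' alive/expired (A/E) and the absorbing dead/expired (D/E) state. Columns
#' index the state at time `t`, rows the state at `t + 1`.
#'
#' @param params A [model_params] object.
#' @return A `(P+3) x (P+3)` matrix whose columns sum to one.
#' @export
build_transition <- function(params) {
  validate_params(params)
  P <- n_pools(params)
  T_ <- cpp_build_transition(params$phi, params$delta, params$psi)
  states <- state_names(P)
  dimnames(T_) <- list(to = states, from = states)
  T_
}

state_names <- function(P) c(paste0("AO_pool_", seq_len(P)), "DO", "AE", "DE")

obs_symbols <- function(P) c(paste0("pool_", seq_len(P)), "none", "expired")

#' Observation distribution for one latent state
#'
#' Distribution over the observable symbols (detected in pool 1..P, not
#' detected, battery expired) conditional on the latent state in month `t`.
#' An alive/operable fish in pool `j` is detected with probability
#' `rho[j, t]` and otherwise not detected; a dead fish with an operable
#' battery is never detected; fish past their projected battery-expiration
#' date emit the asserted "expired" symbol with probability one.
#'
#' @param state Latent state: either an integer in `1..(P+3)` or one of the
#'   names `"AO_pool_j"`, `"DO"`, `"AE"`, `"DE"`.
#' @param x Per-pool effort (receiver-days) for the month, length `P`.
#' @param beta Pool-level detection effects, length `P`.
#' @param intercept Fixed logit intercept; default -5.
#' @return Named probability vector over the `P + 2` observation symbols.
#' @export
emission_dist <- function(state, x, beta, intercept = -5) {
  P <- length(beta)
  stopifnot(length(x) == P)
  if (is.character(state)) state <- match(state, state_names(P))
  stopifnot(!is.na(state), state >= 1, state <= P + 3)
  e <- stats::setNames(numeric(P + 2), obs_symbols(P))
  if (state <= P) {
    rho <- detection_prob(beta[state], x[state], intercept)
    e[state] <- rho
    e["none"] <- 1 - rho
  } else if (state == P + 1) {
    e["none"] <- 1
  } else {
    e["expired"] <- 1
  }
  e
}

# Emission matrix: (P+2) symbols x (P+3) states for month t.
emission_matrix <- function(params, x) {
  P <- n_pools(params)
  E <- matrix(0, P + 2, P + 3, dimnames = list(obs_symbols(P), state_names(P)))
  rho <- detection_prob(params$beta, x, params$intercept)
  for (j in seq_len(P)) {
    E[j, j] <- rho[j]
    E[P + 1, j] <- 1 - rho[j]
  }
  E[P + 1, P + 1] <- 1  # D/O never detected
  E[P + 2, P + 2] <- 1  # A/E asserts expired
  E[P + 2, P + 3] <- 1  # D/E asserts expired
  E
}

code_obs <- function(obs, P) {
  symbols <- obs_symbols(P)
  code <- match(obs, symbols)
  if (anyNA(code)) stop("unknown observation symbol: ",
                        paste(unique(obs[is.na(code)]), collapse = ", "))
  code
}

#' Forward-algorithm marginal log-likelihood of one monthly history
#'
#' Computes the marginal log probability of a fish's monthly observation
#' sequence given its asserted release state, summing over all latent state
#' paths with the scaled forward recursion. The release-month observation is
#' asserted (probability one); every later month multiplies in one
#' transition step and the emission probability of the recorded symbol.
#' Months at and beyond the projected battery-expiration date carry the
#' asserted "expired" symbol; months after the first expired month
#' contribute exactly zero additional log-likelihood.
#'
#' @param history A single fish's history: data frame with columns `month`
#'   (consecutive integers) and `obs` (symbols `"pool_j"`, `"none"`,
#'   `"expired"`); the first row is the release month and must be a pool
#'   symbol.
#' @param params A [model_params] object.
#' @param effort `P x n_months` matrix of receiver-days (columns are
#'   months on the same indexing as `history$month`).
#' @return Log-likelihood (scalar). `-Inf`, with a warning naming the month,
#'   if the recorded sequence is impossible under the model.
#' @export
forward_loglik <- function(history, params, effort) {
  validate_params(params)
  P <- n_pools(params)
  stopifnot(is.matrix(effort), nrow(effort) == P)
  months <- history$month
  stopifnot(length(months) >= 1, all(diff(months) == 1),
            max(months) <= ncol(effort))
  code <- code_obs(as.character(history$obs), P)
  if (code[1] > P) stop("history must start with the asserted release pool")
  T_ <- cpp_build_transition(params$phi, params$delta, params$psi)
  alpha <- numeric(P + 3)
  alpha[code[1]] <- 1
  ll <- 0
  for (s in seq_along(months)[-1]) {
    alpha <- as.vector(T_ %*% alpha)
    E <- emission_matrix(params, effort[, months[s]])
    alpha <- alpha * E[code[s], ]
    sc <- sum(alpha)
    if (sc <= 0) {
      warning("impossible observation '", history$obs[s], "' in month ",
              months[s], " under the model; log-likelihood is -Inf")
      return(-Inf)
    }
    alpha <- alpha / sc
    ll <- ll + log(sc)
  }
  ll
}

#' Joint log prior density of the model parameters
#'
#' Priors: `phi, delta ~ Uniform(0, 1)`; each `psi` column
#' `~ Dirichlet(alpha, ..., alpha)` (flat over the simplex at the default
#' `alpha = 1`); `beta_j ~ Normal(theta, sigma)` (hierarchical);
#' `theta ~ Normal(0, 1)`; `sigma ~ Uniform(0, 5)`. Densities are on the
#' natural parameter scale (no transform Jacobians).
#'
#' @param params A [model_params] object (bounds violations return `-Inf`).
#' @param dirichlet_alpha Symmetric Dirichlet concentration for the `psi`
#'   columns; default 1.
#' @param sigma_max Upper bound of the uniform prior on `sigma`; default 5.
#' @param hier If `FALSE`, `theta` and `sigma` are treated as fixed
#'   constants (no hyperprior terms); used by the collapsed single-pool
#'   cross-check.
#' @return Log prior density (scalar, possibly `-Inf`).
#' @export
log_prior <- function(params, dirichlet_alpha = 1, sigma_max = 5, hier = TRUE) {
  p <- params
  P <- n_pools(p)
  if (p$phi < 0 || p$phi > 1 || p$delta < 0 || p$delta > 1) return(-Inf)
  if (p$sigma <= 0 || (hier && p$sigma > sigma_max)) return(-Inf)
  if (any(p$psi < 0)) return(-Inf)
  a <- dirichlet_alpha
  lp <- P * (lgamma(P * a) - P * lgamma(a)) +
    (a - 1) * sum(log(pmax(p$psi, .Machine$double.xmin)))
  lp <- lp + sum(stats::dnorm(p$beta, p$theta, p$sigma, log = TRUE))
  if (hier) lp <- lp + stats::dnorm(p$theta, 0, 1, log = TRUE) - log(sigma_max)
  lp
}
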