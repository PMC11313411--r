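# Shared fixtures and independent oracles for the test suite.

# Random column-stochastic transition matrix.
random_psi <- function(P = 6) {
  m <- matrix(stats::rgamma(P * P, 1), P, P)
  sweep(m, 2, colSums(m), "/")
}

random_params <- function(P = 6) {
  model_params(stats::runif(1, 0.6, 1), stats::runif(1, 0.6, 1),
               random_psi(P), beta = stats::rnorm(P, 1, 1))
}

# Brute-force marginal likelihood: explicit sum over every latent state
# path, kept deliberately independent of the forward implementation.
brute_force_loglik <- function(history, params, effort) {
  P <- nrow(params$psi)
  K <- P + 3
  Tm <- build_transition(params)
  sym <- c(paste0("pool_", seq_len(P)), "none", "expired")
  code <- match(as.character(history$obs), sym)
  months <- history$month
  n <- length(months)
  if (n == 1) return(0)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), n - 1)))
  prob <- rep(1, nrow(paths))
  prev <- rep(code[1], nrow(paths))
  for (s in 2:n) {
    st <- paths[, s - 1]
    E <- poolstate:::emission_matrix(params, effort[, months[s]])
    prob <- prob * Tm[cbind(st, prev)] * E[cbind(rep(code[s], length(st)), st)]
    prev <- st
  }
  log(sum(prob))
}

# Small six-pool scenario used by several preprocessing tests.
small_scenario <- function(seed = 3, n_months = 18, n_per_pool = 5) {
  scenario_config(
    n_months = n_months, seed = seed,
    tagging_plan = data.frame(release_month = 1, release_pool = 1:6,
                              n = n_per_pool, species = "silver",
                              tag_life_months = 12))
}

# Minimal receiver table: one receiver per pool at km positions 10, 30, ...
toy_receivers <- function(P = 3) {
  data.frame(receiver_id = paste0("R", seq_len(P)), pool = seq_len(P),
             river_km = 20 * seq_len(P) - 10,
             deploy_date = as.Date("2015-01-01"),
             retrieve_date = as.Date("2016-01-01"), at_lock = FALSE)
}

# Tweak fields of a model_params object without re-validating (used to
# probe out-of-support values).
modifyList2 <- function(p, ...) {
  l <- unclass(p)
  dots <- list(...)
  for (nm in names(dots)) l[[nm]] <- dots[[nm]]
  structure(l, class = "model_params")
}
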