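# Adaptive Metropolis-within-Gibbs sampler for the multistate HMM.
# Latent states are marginalized by the forward algorithm (compiled), so the
# chain runs on the top-level parameters only: (phi, delta) jointly on the
# logit scale; each psi column through an anchored-softmax transform with
# its exact Jacobian (preserving the Dirichlet prior), mixing random-walk
# moves with independence proposals from the Dirichlet prior; each beta_j
# by a scalar random walk; and conjugate/grid Gibbs draws for theta and
# sigma. Random-walk increments are t-distributed (df 3) for tail mobility.
# Proposal scales adapt during warmup only (Robbins-Monro toward standard
# acceptance targets) and are frozen afterwards.

#' MCMC configuration
#'
#' @param chains Number of chains; each chain `c` is seeded with `seed + c`.
#' @param warmup Adaptation iterations discarded as burn-in.
#' @param iter Post-warmup iterations per chain (before thinning).
#' @param thin Keep every `thin`-th post-warmup draw.
#' @param seed Base integer seed.
#' @param hier Hierarchical detection effects? If `FALSE`, `theta` and
#'   `sigma` are fixed at `theta0`/`sigma0` instead of sampled.
#' @param theta0,sigma0 Fixed hyper-parameter values used when
#'   `hier = FALSE`.
#' @param dirichlet_alpha Symmetric Dirichlet concentration for `psi`
#'   columns.
#' @param sigma_max Upper bound of the uniform prior on `sigma`.
#' @return A list of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 3, warmup = 2000, iter = 6000, thin = 1,
                        seed = 1, hier = TRUE, theta0 = 0, sigma0 = 1,
                        dirichlet_alpha = 1, sigma_max = 5) {
  stopifnot(chains >= 1, warmup >= 0, iter >= 1, thin >= 1)
  structure(as.list(environment()), class = "mcmc_config")
}

#' Full-scale MCMC preset
#'
#' The production-scale sampling budget (3 chains, 10,000 warm-up
#' iterations, 100,000 sampling iterations thinned by 3); the package
#' default in [mcmc_config] is a desk-scale budget suitable for simulation
#' studies.
#'
#' @param ... Overrides passed to [mcmc_config].
#' @export
mcmc_config_full <- function(...) {
  mcmc_config(chains = 3, warmup = 10000, iter = 100000, thin = 3, ...)
}

softmax_col <- function(z) {
  e <- exp(c(z, 0) - max(c(z, 0)))
  e / sum(e)
}

# Internal: compact history set for the compiled likelihood.
as_history_set <- function(histories, n_months, n_pools = NULL) {
  stopifnot(all(c("fish_id", "month", "obs") %in% names(histories)))
  ids <- unique(histories$fish_id)
  n <- length(ids)
  pool_obs <- grep("^pool_", unique(as.character(histories$obs)), value = TRUE)
  P_seen <- max(as.integer(sub("pool_", "", pool_obs)))
  P <- if (is.null(n_pools)) P_seen else n_pools
  if (P_seen > P) stop("histories mention pool ", P_seen,
                       " but only ", P, " pools are modelled")
  obs <- matrix(0L, n, n_months)
  rel_month <- rel_pool <- last_month <- integer(n)
  sp <- split(histories[c("month", "obs")], factor(histories$fish_id, ids))
  for (f in seq_len(n)) {
    h <- sp[[f]]
    o <- h$obs[order(h$month)]
    m <- sort(h$month)
    if (any(diff(m) != 1)) stop("history months must be consecutive: ", ids[f])
    code <- code_obs(as.character(o), P)
    if (code[1] > P) stop("history must start at the release pool: ", ids[f])
    exp_idx <- which(code == P + 2)
    if (length(exp_idx) && (any(diff(exp_idx) != 1) ||
                            max(exp_idx) != length(code)))
      stop("expired symbols must form the history suffix: ", ids[f])
    last <- if (length(exp_idx)) m[min(exp_idx)] else max(m)
    keep <- m <= last
    obs[f, m[keep]] <- code[keep]
    rel_month[f] <- m[1]
    rel_pool[f] <- code[1]
    last_month[f] <- last
  }
  list(ids = ids, obs = obs, rel_month = rel_month, rel_pool = rel_pool,
       last_month = last_month, n_pools = P)
}

#' Convert a long effort table to a pool-by-month matrix
#'
#' @param effort Either a `P x n_months` matrix or a data frame with
#'   columns `pool`, `month`, `x`.
#' @param n_pools,n_months Dimensions (inferred from the data frame when
#'   missing).
#' @export
effort_matrix <- function(effort, n_pools = NULL, n_months = NULL) {
  if (is.matrix(effort)) return(effort)
  stopifnot(all(c("pool", "month", "x") %in% names(effort)))
  P <- if (is.null(n_pools)) max(effort$pool) else n_pools
  TT <- if (is.null(n_months)) max(effort$month) else n_months
  m <- matrix(0, P, TT)
  m[cbind(effort$pool, effort$month)] <- effort$x
  m
}

param_names <- function(P, hier) {
  c("phi", "delta",
    paste0("psi[", outer(seq_len(P), seq_len(P), function(i, j)
      paste0(i, ",", j)), "]"),
    paste0("beta[", seq_len(P), "]"),
    if (hier) c("theta", "sigma"))
}

#' Fit the multistate movement model by MCMC
#'
#' Samples the posterior of the movement model (survival `phi`, battery
#' retention `delta`, pool transitions `psi`, detection effects `beta` with
#' hierarchical mean `theta` and SD `sigma`) given monthly observation
#' histories and the receiver-effort covariate. The latent state sequences
#' are marginalized with the forward algorithm, so the sampler targets
#' exactly the same posterior as one that samples latent states.
#'
#' @param histories Data frame with columns `fish_id`, `month`, `obs`
#'   (symbols `"pool_j"`, `"none"`, `"expired"`), one row per fish-month
#'   from the release month onward.
#' @param effort `P x n_months` effort matrix or long data frame
#'   (see [effort_matrix]).
#' @param config An [mcmc_config].
#' @param intercept Fixed logit-scale detection intercept; default -5.
#' @return A `poolstate_fit` object: per-chain draw matrices, parameter
#'   names, acceptance rates and the configuration. Use
#'   [summary.poolstate_fit] for medians, credible intervals and R-hat.
#' @export
fit_mcmc <- function(histories, effort, config = mcmc_config(),
                     intercept = -5) {
  stopifnot(inherits(config, "mcmc_config"))
  if (nrow(histories) == 0) stop("no usable histories")
  effort <- effort_matrix(effort)
  hs <- as_history_set(histories, ncol(effort), n_pools = nrow(effort))
  P <- hs$n_pools
  chains <- lapply(seq_len(config$chains), function(ch)
    run_chain(hs, effort, config, intercept, seed = config$seed + ch))
  draws <- lapply(chains, `[[`, "draws")
  fit <- structure(list(
    draws = draws,
    param_names = colnames(draws[[1]]),
    accept = lapply(chains, `[[`, "accept"),
    config = config, n_pools = P, intercept = intercept,
    n_fish = length(hs$ids)), class = "poolstate_fit")
  s <- summary(fit)
  bad <- s$param[!is.na(s$rhat) & s$rhat >= 1.1]
  if (length(bad))
    warning("Gelman-Rubin statistic >= 1.1 for: ", paste(bad, collapse = ", "))
  fit
}

run_chain <- function(hs, effort, cfg, intercept, seed) {
  set.seed(seed)
  P <- hs$n_pools
  hier <- cfg$hier
  loglik <- function(phi, delta, psi, beta)
    cpp_total_loglik(hs$obs, hs$rel_month, hs$rel_pool, hs$last_month,
                     phi, delta, psi, beta, effort, intercept)

  # state on sampling scales
  lphi <- stats::qlogis(stats::runif(1, 0.85, 0.98))
  ldelta <- stats::qlogis(stats::runif(1, 0.85, 0.98))
  z <- matrix(stats::rnorm((P - 1) * P, 0, 0.1), max(P - 1, 0), P)
  beta <- stats::runif(P, 0.3, 2)
  theta <- if (hier) mean(beta) else cfg$theta0
  sigma <- if (hier) 1 else cfg$sigma0
  psi <- apply(z, 2, softmax_col)
  if (P == 1) psi <- matrix(1, 1, 1)
  phi <- stats::plogis(lphi); delta <- stats::plogis(ldelta)

  # log target on the sampling scale (likelihood piece + priors + Jacobians)
  lp_pd <- function(lphi, ldelta)  # U(0,1) priors + logit Jacobians
    log(stats::plogis(lphi)) + log(1 - stats::plogis(lphi)) +
    log(stats::plogis(ldelta)) + log(1 - stats::plogis(ldelta))
  a <- cfg$dirichlet_alpha
  lp_zcol <- function(pcol)  # Dirichlet prior + softmax Jacobian
    (a - 1) * sum(log(pcol)) + sum(log(pcol))
  lp_beta <- function(beta, theta, sigma)
    sum(stats::dnorm(beta, theta, sigma, log = TRUE))

  ll <- loglik(phi, delta, psi, beta)
  if (!is.finite(ll)) stop("initial parameter draw has zero likelihood")

  ls_pd <- log(0.1); ls_z <- rep(log(0.3), P); ls_beta <- rep(log(0.2), P)
  n_keep <- floor(cfg$iter / cfg$thin)
  nms <- param_names(P, hier)
  out <- matrix(NA_real_, n_keep, length(nms), dimnames = list(NULL, nms))
  acc <- c(pd = 0, psi = 0, beta = 0)
  n_tot <- cfg$warmup + cfg$iter
  kept <- 0

  for (it in seq_len(n_tot)) {
    adapt <- it <= cfg$warmup
    gam <- if (adapt) min(0.25, 2 / sqrt(it)) else 0

    # (phi, delta) block
    prop <- c(lphi, ldelta) + exp(ls_pd) * stats::rnorm(2)
    phi_p <- stats::plogis(prop[1]); delta_p <- stats::plogis(prop[2])
    ll_p <- loglik(phi_p, delta_p, psi, beta)
    lr <- (ll_p + lp_pd(prop[1], prop[2])) - (ll + lp_pd(lphi, ldelta))
    ap <- min(1, exp(lr))
    if (stats::runif(1) < ap) {
      lphi <- prop[1]; ldelta <- prop[2]; phi <- phi_p; delta <- delta_p
      ll <- ll_p
      if (!adapt) acc["pd"] <- acc["pd"] + 1
    }
    ls_pd <- ls_pd + gam * (ap - 0.30)

    # psi columns (skipped for a single pool). Random-walk moves in the
    # softmax space mix the well-identified columns; occasional
    # independence proposals from the Dirichlet prior (for which the
    # Hastings ratio reduces to the likelihood ratio) traverse the flat,
    # heavy-tailed columns of rarely detected pools.
    if (P > 1) {
      for (j in seq_len(P)) {
        indep <- stats::runif(1) < 0.25
        if (indep) {
          pcol <- stats::rgamma(P, a)
          pcol <- pcol / sum(pcol)
          zj <- log(pcol[-P] / pcol[P])
        } else {
          zj <- z[, j] + exp(ls_z[j]) * stats::rt(P - 1, df = 3)
        }
        psi_p <- psi
        psi_p[, j] <- softmax_col(zj)
        ll_p <- loglik(phi, delta, psi_p, beta)
        lr <- if (indep) ll_p - ll else
          (ll_p + lp_zcol(psi_p[, j])) - (ll + lp_zcol(psi[, j]))
        ap <- min(1, exp(lr))
        if (stats::runif(1) < ap) {
          z[, j] <- zj; psi <- psi_p; ll <- ll_p
          if (!adapt) acc["psi"] <- acc["psi"] + 1 / P
        }
        if (!indep) ls_z[j] <- ls_z[j] + gam * (ap - 0.25)
      }
    }

    # beta: per-pool scalar updates with individual adaptive scales (the
    # effects differ greatly in how well the data identify them)
    for (j in seq_len(P)) {
      beta_p <- beta
      beta_p[j] <- beta[j] + exp(ls_beta[j]) * stats::rt(1, df = 3)
      ll_p <- loglik(phi, delta, psi, beta_p)
      lr <- (ll_p + stats::dnorm(beta_p[j], theta, sigma, log = TRUE)) -
        (ll + stats::dnorm(beta[j], theta, sigma, log = TRUE))
      ap <- min(1, exp(lr))
      if (stats::runif(1) < ap) {
        beta <- beta_p; ll <- ll_p
        if (!adapt) acc["beta"] <- acc["beta"] + 1 / P
      }
      ls_beta[j] <- ls_beta[j] + gam * (ap - 0.44)
    }

    if (hier) {
      # theta | beta, sigma: conjugate normal with N(0,1) prior
      prec <- P / sigma^2 + 1
      theta <- stats::rnorm(1, (sum(beta) / sigma^2) / prec, sqrt(1 / prec))
      # sigma | beta, theta: griddy Gibbs on (0, sigma_max]
      sg <- seq(cfg$sigma_max / 400, cfg$sigma_max, length.out = 400)
      lw <- -P * log(sg) - sum((beta - theta)^2) / (2 * sg^2)
      w <- exp(lw - max(lw))
      sigma <- sample(sg, 1, prob = w)
    }

    if (!adapt && (it - cfg$warmup) %% cfg$thin == 0) {
      kept <- kept + 1
      out[kept, ] <- c(phi, delta, as.vector(psi), beta,
                       if (hier) c(theta, sigma))
    }
  }
  list(draws = out[seq_len(kept), , drop = FALSE], accept = acc / cfg$iter)
}

#' Gelman-Rubin potential scale reduction statistic
#'
#' Classic (non-split) R-hat on retained draws: with `m` chains of length
#' `n`, `W` the mean within-chain variance and `B/n` the variance of the
#' chain means, `R-hat = sqrt(((n-1)/n * W + B/n) / W)`. Defined as 1 when
#' the total variance is zero (all draws identical) and `Inf` when chains
#' are constant but unequal.
#'
#' @param x Matrix of draws (iterations in rows, chains in columns) or a
#'   list of equal-length numeric vectors.
#' @return Scalar R-hat.
#' @export
gelman_rubin <- function(x) {
  if (is.list(x)) x <- do.call(cbind, x)
  stopifnot(is.matrix(x), ncol(x) >= 2, nrow(x) >= 2)
  n <- nrow(x)
  W <- mean(apply(x, 2, stats::var))
  B_n <- stats::var(colMeans(x))  # = B/n
  vhat <- (n - 1) / n * W + B_n
  if (vhat == 0) return(1)
  if (W == 0) return(Inf)
  sqrt(vhat / W)
}

#' @describeIn fit_mcmc Posterior summary: median, mean, 2.5/97.5
#'   percentiles and Gelman-Rubin R-hat for every parameter.
#' @param object,... A `poolstate_fit`; further arguments ignored.
#' @export
summary.poolstate_fit <- function(object, ...) {
  all_draws <- do.call(rbind, object$draws)
  qs <- apply(all_draws, 2, stats::quantile, c(0.5, 0.025, 0.975))
  rhat <- if (length(object$draws) >= 2 && nrow(object$draws[[1]]) >= 2)
    vapply(seq_along(object$param_names), function(k)
      gelman_rubin(sapply(object$draws, function(d) d[, k])), numeric(1))
  else rep(NA_real_, length(object$param_names))
  data.frame(param = object$param_names, median = qs[1, ],
             mean = colMeans(all_draws), q2.5 = qs[2, ], q97.5 = qs[3, ],
             rhat = rhat, row.names = NULL)
}

#' @export
print.poolstate_fit <- function(x, ...) {
  cat("poolstate multistate HMM fit:", length(x$draws), "chains x",
      nrow(x$draws[[1]]), "retained draws,", x$n_fish, "fish,",
      x$n_pools, "pools\n")
  top <- c("phi", "delta", if (x$config$hier) c("theta", "sigma"))
  print(summary(x)[match(top, x$param_names), ], digits = 3, row.names = FALSE)
  invisible(x)
}

#' Extract posterior draws as a single matrix
#'
#' @param fit A `poolstate_fit`.
#' @param max_draws Optional cap; draws are subsampled evenly past it.
#' @export
posterior_draws <- function(fit, max_draws = NULL) {
  d <- do.call(rbind, fit$draws)
  if (!is.null(max_draws) && nrow(d) > max_draws)
    d <- d[round(seq(1, nrow(d), length.out = max_draws)), , drop = FALSE]
  d
}
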