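# Synthetic-telemetry generator: effort arithmetic, trajectory legality,
# convergence of empirical rates to the generating parameters, artifacts.

test_that("generated effort reflects the receiver plan exactly", {
  # one receiver deployed all of a 30-day month -> effort 1.0
  cfg <- scenario_config(
    n_pools = 2, n_months = 3, pool_lengths_km = c(50, 50), seed = 1,
    receiver_plan = data.frame(receiver_id = "R1", pool = 1, river_km = 10,
                               deploy_month = 1, retrieve_month = 3,
                               at_lock = FALSE),
    tagging_plan = data.frame(release_month = 1, release_pool = 1, n = 1,
                              species = "s", tag_life_months = 2),
    true_params = model_params(0.9, 0.9, default_psi(2), beta = c(1, 1)))
  x <- generate_effort(cfg)
  expect_equal(unname(x[1, ]), c(1, 1, 1))
  expect_equal(unname(x[2, ]), c(0, 0, 0))  # empty pool-month -> 0
  # 21 receivers all month: the observed maximum of large river arrays
  plan21 <- data.frame(receiver_id = sprintf("R%02d", 1:21), pool = 1,
                       river_km = seq(2, 42, by = 2), deploy_month = 1,
                       retrieve_month = 3, at_lock = FALSE)
  cfg21 <- scenario_config(
    n_pools = 2, n_months = 3, pool_lengths_km = c(50, 50), seed = 1,
    receiver_plan = plan21,
    tagging_plan = cfg$tagging_plan, true_params = cfg$true_params)
  expect_equal(unname(generate_effort(cfg21)[1, 1]), 21)
})

test_that("generator output is reproducible from the seed", {
  cfg <- small_scenario(seed = 12)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$detections, s2$detections)
  expect_identical(s1$trajectories, s2$trajectories)
  expect_identical(s1$tags, s2$tags)
  s3 <- simulate_cohort(scenario_config(
    n_months = cfg$n_months, seed = 13, tagging_plan = cfg$tagging_plan))
  expect_false(identical(s1$detections, s3$detections))
})

test_that("degenerate no-movement perfect-detection scenario", {
  # phi = delta = 1, psi = identity, beta huge: every fish detected in its
  # release pool every month
  P <- 6
  tp <- model_params(1, 1, diag(P), beta = rep(50, P))
  cfg <- scenario_config(n_months = 8, seed = 4, true_params = tp,
                         tagging_plan = data.frame(
                           release_month = 1, release_pool = 1:6, n = 3,
                           species = "s", tag_life_months = 99))
  sd <- simulate_histories(cfg)
  h <- sd$histories
  rel <- h[h$month == 1, ]
  for (f in unique(h$fish_id)) {
    hf <- h[h$fish_id == f, ]
    expect_true(all(hf$obs == hf$obs[1]))  # always detected at home
  }
  expect_equal(nrow(h), 18 * 8)
})

test_that("no trajectory revives or un-expires", {
  cfg <- small_scenario(seed = 8)
  tr <- simulate_histories(cfg)$trajectories
  rank <- c(AO = 1, DO = 2, AE = 2, DE = 3)  # legal moves never decrease
  for (f in unique(tr$fish_id)) {
    st <- tr$status[tr$fish_id == f]
    expect_true(all(diff(rank[st]) >= 0))
    # dead never becomes alive, expired never becomes operable
    expect_false(any(st == "AO" & c("x", head(st, -1)) %in% c("DO", "DE")))
    expect_false(any(st %in% c("AO", "DO") &
                       c("x", head(st, -1)) %in% c("AE", "DE")))
  }
})

test_that("empirical rates converge to the generating parameters", {
  # 2,000 fish, single release, 4 months: check psi columns, phi, delta
  P <- 6
  psi <- default_psi(P)
  tp <- model_params(0.9, 0.93, psi, beta = rep(2, P))
  cfg <- scenario_config(
    n_months = 4, seed = 21, true_params = tp,
    tagging_plan = data.frame(release_month = 1,
                              release_pool = rep(1:6, length.out = 12),
                              n = rep(2000 %/% 12, 12), species = "s",
                              tag_life_months = 99))
  tr <- simulate_histories(cfg)$trajectories
  # monthly transition frequencies among alive/operable fish
  for (j in seq_len(P)) {
    from <- tr$status == "AO" & !is.na(tr$pool) & tr$pool == j &
      tr$month < 4
    nxt <- tr[tr$month > 1 & tr$status == "AO", ]
    key_from <- paste(tr$fish_id, tr$month)[from]
    key_to <- paste(nxt$fish_id, nxt$month - 1)
    to_pool <- nxt$pool[match(key_from, key_to)]
    to_pool <- to_pool[!is.na(to_pool)]
    n <- length(to_pool)
    if (n < 200) next
    for (i in seq_len(P)) {
      phat <- mean(to_pool == i)
      se <- sqrt(psi[i, j] * (1 - psi[i, j]) / n)
      expect_lt(abs(phat - psi[i, j] * 1), 3 * se + 0.25 / n)
    }
  }
  # survival fraction per month among at-risk fish (the survival and
  # battery processes are independent)
  alive <- tr$status %in% c("AO", "AE")
  key <- paste(tr$fish_id, tr$month)
  idx_next <- match(paste(tr$fish_id, tr$month + 1), key)
  at_risk <- tr$month < 4 & alive & !is.na(idx_next)
  surv <- mean(alive[idx_next[at_risk]])
  n_s <- sum(at_risk)
  expect_lt(abs(surv - 0.9), 3 * sqrt(0.9 * 0.1 / n_s))
  # battery-retention fraction
  oper <- tr$status %in% c("AO", "DO")
  at_risk_b <- tr$month < 4 & oper & !is.na(idx_next)
  ret <- mean(oper[idx_next[at_risk_b]])
  expect_lt(abs(ret - 0.93), 3 * sqrt(0.93 * 0.07 / sum(at_risk_b)))
})

test_that("detected fraction of alive/operable fish-months matches rho", {
  P <- 6
  tp <- model_params(1, 1, default_psi(P), beta = seq(0.3, 3,
                                                      length.out = P))
  cfg <- scenario_config(
    n_months = 6, seed = 33, true_params = tp,
    tagging_plan = data.frame(release_month = 1, release_pool = 1:6,
                              n = 250, species = "s",
                              tag_life_months = 99))
  sd <- simulate_histories(cfg)
  tr <- sd$trajectories
  rho <- stats::plogis(-5 + tp$beta * sd$effort)
  for (j in seq_len(P)) {
    sel <- tr$status == "AO" & tr$month > 1 & !is.na(tr$pool) & tr$pool == j
    n <- sum(sel)
    if (n < 100) next
    # effort is constant over months in the default plan, so pool rho too
    phat <- mean(tr$detected[sel])
    expect_lt(abs(phat - rho[j, 2]), 3 * sqrt(rho[j, 2] * (1 - rho[j, 2]) / n))
  }
})

test_that("zero effort produces no detection events after release", {
  # no receivers -> detections cannot be attributed -> none are emitted
  cfg <- scenario_config(
    n_pools = 2, n_months = 6, pool_lengths_km = c(50, 50), seed = 2,
    receiver_plan = data.frame(receiver_id = "R1", pool = 1, river_km = 10,
                               deploy_month = 1, retrieve_month = 1,
                               at_lock = FALSE),
    tagging_plan = data.frame(release_month = 2, release_pool = 1:2, n = 10,
                              species = "s", tag_life_months = 4),
    true_params = model_params(1, 1, diag(2), beta = c(3, 3)))
  sim <- simulate_cohort(cfg)
  expect_equal(nrow(sim$detections), 0)
})

test_that("planted artifacts carry truth labels and realistic structure", {
  cfg <- small_scenario(seed = 3)
  sim <- plant_artifacts(simulate_cohort(cfg), n_first30 = 5,
                         n_stationary = 6)
  expect_equal(nrow(sim$artifacts), 11)
  expect_setequal(unique(sim$artifacts$kind), c("first30", "stationary"))
  # labels only in the side table, not in the event stream
  expect_false(any(grepl("first30|stationary",
                         names(sim$detections))))
  # first30 fish: all detections within 30 days of release
  for (k in which(sim$artifacts$kind == "first30")) {
    id <- sim$artifacts$fish_id[k]
    tg <- sim$tags[sim$tags$fish_id == id, ]
    d <- sim$detections[sim$detections$tag_code == tg$tag_code, ]
    expect_gt(nrow(d), 0)
    expect_lte(as.numeric(max(as.Date(d$timestamp)) -
                            as.Date(tg$release_date)), 30)
  }
})
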