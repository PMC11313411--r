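# Synthetic telemetry generator. Emulates the three raw data streams
# (receiver deployments, tag deployments, detections) from the generative
# structure the movement model assumes: Markovian monthly pool transitions,
# constant monthly survival and battery retention, and effort-dependent
# logistic detection. Months are calendar months so the streams round-trip
# through the calendar-based preprocessing unchanged.

#' Scenario configuration for the synthetic-telemetry generator
#'
#' The defaults define the package's reference study: six pools spanning a
#' 2015-2017 calendar (36 months), a cohort of 200 fish released across all
#' pools in two waves, true survival 0.96 and battery retention 0.97 per
#' month, a diagonally dominant transition matrix with downstream bias
#' ([default_psi]), and pool detection effects spanning 0.3-3 so that
#' monthly detection probabilities range from under 0.1 (most downstream
#' pool) to above 0.9, mirroring the strong downstream-to-upstream gradient
#' in array performance seen in large multi-agency river arrays.
#'
#' @param n_pools Number of pools (pool 1 most downstream).
#' @param n_months Study length in calendar months.
#' @param start First calendar month, `"YYYY-MM"`.
#' @param pool_lengths_km Per-pool river length, used to lay out receiver
#'   positions.
#' @param receiver_plan Data frame `receiver_id`, `pool`, `river_km`,
#'   `deploy_month`, `retrieve_month`, `at_lock`; `NULL` for the default
#'   full-span array (8/4/4/3/3/3 receivers per pool plus one flagged lock
#'   receiver at each internal pool boundary).
#' @param tagging_plan Data frame `release_month`, `release_pool`, `n`,
#'   `species`, `tag_life_months`; `NULL` for the default 200-fish cohort
#'   (two release waves, months 1 and 13).
#' @param true_params A [model_params] giving the generating values;
#'   `NULL` for the defaults above.
#' @param seed Integer RNG seed; the full output is reproducible from it.
#' @param daily_detection_rate Expected raw detections per detectable
#'   fish-day, used only to expand detected fish-months into event streams.
#' @param battery_mode `"stochastic"` (default): realized battery life is
#'   geometric with monthly retention `delta` and the projected expiration
#'   date written to the tag table equals the realized expiration, which is
#'   the self-consistent reading of a model that asserts expiration at the
#'   projected date. `"fixed"`: batteries last exactly
#'   `tag_life_months`.
#' @return A validated list of class `scenario_config`.
#' @export
scenario_config <- function(n_pools = 6, n_months = 36, start = "2015-01",
                            pool_lengths_km = c(129, 124, 117, 26, 39, 23),
                            receiver_plan = NULL, tagging_plan = NULL,
                            true_params = NULL, seed = 1,
                            daily_detection_rate = 2,
                            battery_mode = c("stochastic", "fixed")) {
  battery_mode <- match.arg(battery_mode)
  if (is.null(true_params))
    true_params <- model_params(0.96, 0.97, default_psi(n_pools),
                                beta = seq(0.3, 3, length.out = n_pools))
  stopifnot(length(pool_lengths_km) == n_pools, n_pools == n_pools(true_params))
  bounds_km <- c(0, cumsum(pool_lengths_km))
  if (is.null(receiver_plan)) {
    counts <- rep_len(c(8, 4, 4, 3, 3, 3), n_pools)
    rows <- lapply(seq_len(n_pools), function(j) {
      pos <- bounds_km[j] + pool_lengths_km[j] *
        seq_len(counts[j]) / (counts[j] + 1)
      data.frame(pool = j, river_km = pos, deploy_month = 1,
                 retrieve_month = n_months, at_lock = FALSE)
    })
    locks <- if (n_pools > 1)
      data.frame(pool = 2:n_pools, river_km = bounds_km[2:n_pools],
                 deploy_month = 1, retrieve_month = n_months, at_lock = TRUE)
    receiver_plan <- do.call(rbind, c(rows, list(locks)))
    receiver_plan <- cbind(receiver_id = sprintf("RX%03d",
                                                 seq_len(nrow(receiver_plan))),
                           receiver_plan)
  }
  if (is.null(tagging_plan)) {
    n1 <- c(10, 13, 15, 18, 22, 22)
    tagging_plan <- data.frame(
      release_month = rep(c(1, 13), each = n_pools),
      release_pool = rep(seq_len(n_pools), 2),
      n = rep_len(n1, 2 * n_pools),
      species = "silver", tag_life_months = 30)
  }
  cfg <- structure(list(
    n_pools = n_pools, n_months = n_months, start = start,
    pool_lengths_km = pool_lengths_km, receiver_plan = receiver_plan,
    tagging_plan = tagging_plan, true_params = true_params, seed = seed,
    daily_detection_rate = daily_detection_rate,
    battery_mode = battery_mode), class = "scenario_config")
  validate_scenario(cfg)
}

validate_scenario <- function(cfg) {
  rp <- cfg$receiver_plan; tp <- cfg$tagging_plan
  stopifnot(all(rp$pool >= 1 & rp$pool <= cfg$n_pools),
            all(rp$deploy_month >= 1),
            all(rp$retrieve_month <= cfg$n_months),
            all(rp$deploy_month <= rp$retrieve_month),
            all(tp$release_pool >= 1 & tp$release_pool <= cfg$n_pools),
            all(tp$release_month >= 1 & tp$release_month <= cfg$n_months),
            all(tp$tag_life_months >= 1), all(tp$n >= 0))
  if (anyDuplicated(rp$receiver_id))
    stop("receiver ids must be unique in the plan (one deployment interval each)")
  invisible(cfg)
}

# Deployment table (calendar dates, half-open) from the month-indexed plan.
receiver_deployments <- function(cfg) {
  rp <- cfg$receiver_plan
  data.frame(receiver_id = rp$receiver_id, pool = rp$pool,
             river_km = rp$river_km,
             deploy_date = month_start(rp$deploy_month, cfg$start),
             retrieve_date = month_start(rp$retrieve_month, cfg$start) +
               days_in(rp$retrieve_month, cfg),
             at_lock = rp$at_lock)
}

days_in <- function(i, cfg) {
  b <- seq(as.Date(paste0(cfg$start, "-01")), by = "month",
           length.out = cfg$n_months + 1)
  as.numeric(b[i + 1] - b[i])
}

#' Mean receiver-days implied by a scenario's receiver plan
#'
#' @param config A [scenario_config].
#' @return `P x n_months` effort matrix (exact day-count arithmetic via
#'   [compute_effort]).
#' @export
generate_effort <- function(config) {
  end <- format(month_start(config$n_months, config$start), "%Y-%m")
  x <- compute_effort(receiver_deployments(config), config$start, end)
  if (nrow(x) < config$n_pools)
    x <- rbind(x, matrix(0, config$n_pools - nrow(x), ncol(x)))
  x
}

# Latent cohort + monthly detection layer. Geometric lifetimes: a fish
# alive at its release month survives each subsequent month w.p. phi; the
# battery operates through L months with P(L = k) = delta^(k-1) (1-delta).
simulate_core <- function(cfg) {
  p <- cfg$true_params
  P <- cfg$n_pools
  effort <- generate_effort(cfg)
  rho <- stats::plogis(p$intercept + p$beta * effort)  # P x T, recycled rows
  tp <- cfg$tagging_plan
  n_fish <- sum(tp$n)
  ids <- sprintf("F%04d", seq_len(n_fish))
  row_of <- rep(seq_len(nrow(tp)), tp$n)
  traj <- vector("list", n_fish)
  hist <- vector("list", n_fish)
  exp_ms <- numeric(n_fish)
  geom1 <- function(q)  # 1 + Geometric(1-q); Inf when q = 1
    if (q >= 1) Inf else 1L + stats::rgeom(1, 1 - q)
  for (f in seq_len(n_fish)) {
    m0 <- tp$release_month[row_of[f]]
    p0 <- tp$release_pool[row_of[f]]
    life <- if (cfg$battery_mode == "fixed")
      tp$tag_life_months[row_of[f]] else geom1(p$delta)
    exp_m <- m0 + life
    exp_ms[f] <- exp_m
    death_m <- m0 + geom1(p$phi)  # first month the fish is dead
    months <- m0:cfg$n_months
    pool <- rep(NA_integer_, length(months))
    pool[1] <- p0
    for (s in seq_along(months)[-1]) {
      m <- months[s]
      if (m < death_m && m < exp_m)
        pool[s] <- sample.int(P, 1, prob = p$psi[, pool[s - 1]])
      else break
    }
    status <- ifelse(months < death_m,
                     ifelse(months < exp_m, "AO", "AE"),
                     ifelse(months < exp_m, "DO", "DE"))
    detected <- rep(FALSE, length(months))
    ao <- which(status == "AO")[-1]
    if (length(ao))
      detected[ao] <- stats::runif(length(ao)) <
        rho[cbind(pool[ao], months[ao])]
    obs <- ifelse(months >= exp_m, "expired",
                  ifelse(detected, paste0("pool_", pool), "none"))
    obs[1] <- paste0("pool_", p0)
    traj[[f]] <- data.frame(fish_id = ids[f], month = months, status = status,
                            pool = ifelse(status == "AO", pool, NA_integer_),
                            detected = detected)
    hist[[f]] <- data.frame(fish_id = ids[f], month = months, obs = obs)
  }
  # projected expiration = realized battery-expiration month (possibly past
  # the study calendar, in which case the date simply falls beyond it)
  rel_m <- tp$release_month[row_of]
  first_day <- as.Date(paste0(cfg$start, "-01"))
  expire_date <- as.Date(vapply(seq_len(n_fish), function(f) {
    em <- min(exp_ms[f], rel_m[f] + 600)  # cap Inf lifetimes well past study
    as.character(seq(first_day, by = "month", length.out = em + 1)[em])
  }, character(1)))
  tags <- data.frame(
    fish_id = ids,
    species = tp$species[row_of],
    tag_code = sprintf("TC%05d", seq_len(n_fish)),
    release_date = month_start(rel_m, cfg$start),
    release_pool = tp$release_pool[row_of],
    expire_date = expire_date)
  list(trajectories = do.call(rbind, traj),
       histories = do.call(rbind, hist),
       tags = tags, effort = effort, rho = rho)
}

#' Simulate monthly histories directly (no raw-event expansion)
#'
#' Fast path for simulation studies: draws the latent cohort and the
#' monthly detection layer and returns model-ready histories without
#' expanding detected months into raw detection events.
#'
#' @param config A [scenario_config].
#' @return List: `histories`, `trajectories`, `tags`, `effort`,
#'   `true_params`.
#' @export
simulate_histories <- function(config) {
  set.seed(config$seed)
  core <- simulate_core(config)
  core$true_params <- config$true_params
  core$config <- config
  core[c("histories", "trajectories", "tags", "effort", "true_params",
         "config")]
}

#' Simulate the three raw telemetry streams
#'
#' Draws latent trajectories month-by-month from the full state-transition
#' matrix, detects alive/operable fish-months with the effort-dependent
#' probability, and expands each detected fish-month into one or more raw
#' detection events (shifted-geometric count with mean
#' `daily_detection_rate` times the days in the month, uniform timestamps,
#' random non-lock receivers of the occupied pool). Dead-fish and
#' expired-battery months produce no detections. Fish are released on the
#' first day of the release month and the release month itself emits no
#' events (its residency is asserted from the tag record downstream).
#'
#' @param config A [scenario_config].
#' @return List of class `poolstate_sim`: `receivers`, `tags`,
#'   `detections`, plus ground truth (`trajectories`, `histories`,
#'   `effort`, `true_params`, `config`, and after [plant_artifacts] an
#'   `artifacts` truth table).
#' @export
simulate_cohort <- function(config) {
  set.seed(config$seed)
  core <- simulate_core(config)
  rec <- receiver_deployments(config)
  ev <- simulate_events(core$trajectories, core$tags, rec, config)
  structure(list(receivers = rec, tags = core$tags, detections = ev,
                 trajectories = core$trajectories,
                 histories = core$histories, effort = core$effort,
                 true_params = config$true_params, config = config,
                 artifacts = data.frame(fish_id = character(),
                                        kind = character(),
                                        variant = character())),
            class = "poolstate_sim")
}

simulate_events <- function(traj, tags, receivers, cfg) {
  det_rows <- traj[traj$detected, ]
  if (nrow(det_rows) == 0)
    return(data.frame(tag_code = character(), receiver_id = character(),
                      timestamp = as.POSIXct(character(), tz = "UTC")))
  tag_code <- tags$tag_code[match(det_rows$fish_id, tags$fish_id)]
  out <- vector("list", nrow(det_rows))
  for (r in seq_len(nrow(det_rows))) {
    m <- det_rows$month[r]; pool <- det_rows$pool[r]
    rx <- receivers$receiver_id[receivers$pool == pool & !receivers$at_lock &
                                month_index(receivers$deploy_date, cfg$start) <= m &
                                month_index(receivers$retrieve_date - 1, cfg$start) >= m]
    if (length(rx) == 0) next
    nd <- days_in(m, cfg)
    mu <- max(cfg$daily_detection_rate * nd, 1)
    n_ev <- 1L + stats::rgeom(1, 1 / mu)
    t0 <- as.POSIXct(month_start(m, cfg$start), tz = "UTC")
    out[[r]] <- data.frame(
      tag_code = tag_code[r],
      receiver_id = sample(rx, n_ev, replace = TRUE),
      timestamp = t0 + stats::runif(n_ev, 0, nd * 86400 - 1))
  }
  ev <- do.call(rbind, out)
  ev[order(ev$timestamp), ]
}

#' Plant suspect-tag artifacts into a simulated dataset
#'
#' Injects ground-truth labelled artifact fish for exercising the
#' suspect-tag filter: fish whose only detections fall within 30 days of
#' tagging (died or shed the tag immediately), and stationary tags in
#' three flavours — continuous detections on a single receiver,
#' simultaneous continuous detections on a planted pair of receivers under
#' 1,000 m apart, and two detection clusters on one receiver separated by
#' a long gap. All stationary artifacts are detected only in their release
#' pool. Labels live in the returned `artifacts` table only; the event
#' stream carries no marker, so the filter must rediscover them.
#'
#' @param sim A `poolstate_sim` from [simulate_cohort].
#' @param n_first30,n_stationary Numbers of artifact fish to inject.
#' @return The augmented `poolstate_sim`.
#' @export
plant_artifacts <- function(sim, n_first30 = 8, n_stationary = 9) {
  cfg <- sim$config
  set.seed(cfg$seed + 101L)
  P <- cfg$n_pools
  n_new <- n_first30 + n_stationary
  if (n_new == 0) return(sim)
  ids <- sprintf("ART%03d", seq_len(n_new))
  kinds <- c(rep("first30", n_first30), rep("stationary", n_stationary))
  variant <- c(rep("early_only", n_first30),
               rep_len(c("single_rx", "proximate_pair", "gapped"),
                       n_stationary))
  rel_month <- sample.int(max(cfg$n_months - 12, 1), n_new, replace = TRUE)
  rel_pool <- sample.int(P, n_new, replace = TRUE)
  # planted pair of proximate receivers per pool, 300 m apart
  bounds_km <- c(0, cumsum(cfg$pool_lengths_km))
  pair <- do.call(rbind, lapply(seq_len(P), function(j)
    data.frame(receiver_id = paste0("ARTRX", j, c("a", "b")), pool = j,
               river_km = bounds_km[j] + cfg$pool_lengths_km[j] / 2 +
                 c(0, 0.3),
               deploy_date = month_start(1, cfg$start),
               retrieve_date = month_start(cfg$n_months, cfg$start) +
                 days_in(cfg$n_months, cfg),
               at_lock = FALSE)))
  new_tags <- data.frame(
    fish_id = ids, species = "silver",
    tag_code = sprintf("TCA%04d", seq_len(n_new)),
    release_date = month_start(rel_month, cfg$start),
    release_pool = rel_pool,
    expire_date = as.Date(vapply(rel_month, function(m)
      as.character(seq(month_start(m, cfg$start), by = "month",
                       length.out = 41)[41]), character(1))))
  ev <- vector("list", n_new)
  for (k in seq_len(n_new)) {
    t0 <- as.POSIXct(new_tags$release_date[k], tz = "UTC")
    pool_rx <- sim$receivers[sim$receivers$pool == rel_pool[k] &
                             !sim$receivers$at_lock, ]
    if (kinds[k] == "first30") {
      days <- sort(stats::runif(15, 2, 25))
      rx <- sample(pool_rx$receiver_id, 15, replace = TRUE)
    } else if (variant[k] == "single_rx") {
      days <- seq(5, 240, by = 2.5) + stats::runif(95, 0, 0.5)
      rx <- rep(pool_rx$receiver_id[1], length(days))
    } else if (variant[k] == "proximate_pair") {
      days <- rep(seq(4, 200, by = 3), each = 2) + stats::runif(132, 0, 0.2)
      rx <- rep(paste0("ARTRX", rel_pool[k], c("a", "b")), 66)
    } else {  # gapped: two clusters >7 days apart on one receiver
      days <- c(seq(3, 40, by = 2), seq(70, 130, by = 2)) +
        stats::runif(50, 0, 0.5)
      rx <- rep(pool_rx$receiver_id[1], length(days))
    }
    ev[[k]] <- data.frame(tag_code = new_tags$tag_code[k], receiver_id = rx,
                          timestamp = t0 + days * 86400)
  }
  sim$receivers <- rbind(sim$receivers, pair)
  sim$tags <- rbind(sim$tags, new_tags)
  sim$detections <- rbind(sim$detections, do.call(rbind, ev))
  sim$detections <- sim$detections[order(sim$detections$timestamp), ]
  sim$artifacts <- rbind(sim$artifacts,
                         data.frame(fish_id = ids, kind = kinds,
                                    variant = variant))
  sim
}

#' Write a simulated scenario as delimited text
#'
#' Writes `receivers.csv`, `tags.csv`, `detections.csv` (ISO-8601
#' timestamps) and the ground-truth side tables `trajectories.csv`,
#' `histories.csv`, `artifacts.csv`, `effort.csv`.
#'
#' @param sim A `poolstate_sim`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the written file paths.
#' @export
write_scenario <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    path
  }
  det <- sim$detections
  det$timestamp <- format(det$timestamp, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  eff <- data.frame(pool = rep(seq_len(nrow(sim$effort)), ncol(sim$effort)),
                    month = rep(seq_len(ncol(sim$effort)),
                                each = nrow(sim$effort)),
                    x = as.vector(sim$effort))
  paths <- c(w(sim$receivers, "receivers.csv"), w(sim$tags, "tags.csv"),
             w(det, "detections.csv"),
             w(sim$trajectories, "trajectories.csv"),
             w(sim$histories, "histories.csv"),
             w(sim$artifacts, "artifacts.csv"), w(eff, "effort.csv"))
  invisible(paths)
}
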