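# Preprocessing: raw telemetry streams -> model-ready inputs.
# Conventions: pool 1 is the most downstream pool; months are calendar
# months indexed 1..n from a "YYYY-MM" start; deployment intervals are
# half-open [deploy, retrieve) so handover days are never double counted.

#' Calendar-month helpers
#'
#' `month_index` maps dates to 1-based month indices relative to a
#' `"YYYY-MM"` start; `month_start` is its inverse (first day of the
#' month).
#'
#' @param dates Dates (or anything `as.Date` accepts).
#' @param start Calendar origin as `"YYYY-MM"`.
#' @export
month_index <- function(dates, start) {
  d <- as.Date(paste0(format(as.Date(paste0(start, "-01")), "%Y-%m"), "-01"))
  x <- as.POSIXlt(as.Date(dates))
  o <- as.POSIXlt(d)
  12L * (x$year - o$year) + (x$mon - o$mon) + 1L
}

#' @rdname month_index
#' @param i 1-based month index.
#' @export
month_start <- function(i, start) {
  seq(as.Date(paste0(start, "-01")), by = "month", length.out = max(i))[i]
}

n_study_months <- function(start, end) {
  month_index(as.Date(paste0(end, "-01")), start)
}

#' Mean receiver-days per pool and month
#'
#' Effort covariate of the detection model: for every pool and calendar
#' month, the total number of receiver-deployment days falling in the
#' month divided by the number of days in the month. Deployment intervals
#' are half-open (`[deploy, retrieve)`); deployments extending outside the
#' calendar range are clipped with a warning; overlapping intervals for
#' one receiver id are rejected.
#'
#' @param deployments Data frame with `receiver_id`, `pool`,
#'   `deploy_date`, `retrieve_date` (and optionally `at_lock`,
#'   `river_km`).
#' @param start,end Calendar range as `"YYYY-MM"` (inclusive).
#' @return A `P x n_months` matrix of mean receivers per day.
#' @export
compute_effort <- function(deployments, start, end) {
  dep <- deployments
  dep$deploy_date <- as.Date(dep$deploy_date)
  dep$retrieve_date <- as.Date(dep$retrieve_date)
  if (any(dep$deploy_date > dep$retrieve_date))
    stop("deploy date after retrieve date")
  for (id in unique(dep$receiver_id)) {
    iv <- dep[dep$receiver_id == id, ]
    iv <- iv[order(iv$deploy_date), ]
    if (nrow(iv) > 1 &&
        any(iv$deploy_date[-1] < iv$retrieve_date[-nrow(iv)]))
      stop("overlapping deployment intervals for receiver ", id)
  }
  TT <- n_study_months(start, end)
  P <- max(dep$pool)
  bounds <- seq(as.Date(paste0(start, "-01")), by = "month",
                length.out = TT + 1)
  days_in_month <- as.numeric(diff(bounds))
  x <- matrix(0, P, TT)
  clipped <- FALSE
  for (r in seq_len(nrow(dep))) {
    s <- dep$deploy_date[r]; e <- dep$retrieve_date[r]
    if (s < bounds[1] || e > bounds[TT + 1]) clipped <- TRUE
    s <- max(s, bounds[1]); e <- min(e, bounds[TT + 1])
    if (e <= s) next
    for (t in seq_len(TT)) {
      d <- as.numeric(min(e, bounds[t + 1]) - max(s, bounds[t]))
      if (d > 0) x[dep$pool[r], t] <- x[dep$pool[r], t] + d / days_in_month[t]
    }
  }
  if (clipped) warning("deployments extending outside the calendar range were clipped")
  dimnames(x) <- list(pool = seq_len(P), month = seq_len(TT))
  x
}

# Join detections to tags and receivers; drop detections outside a
# receiver's deployment interval(s) (logged via warning).
join_detections <- function(detections, tags, receivers) {
  det <- detections
  det$timestamp <- as.POSIXct(det$timestamp, tz = "UTC")
  if (!all(det$tag_code %in% tags$tag_code))
    stop("detections with tag codes absent from the tag table")
  if (!all(det$receiver_id %in% receivers$receiver_id))
    stop("detections on receivers absent from the receiver table")
  rec1 <- receivers[!duplicated(receivers$receiver_id), ]
  k <- match(det$receiver_id, rec1$receiver_id)
  det$pool <- rec1$pool[k]
  det$river_km <- rec1$river_km[k]
  det$at_lock <- if ("at_lock" %in% names(rec1)) rec1$at_lock[k] else FALSE
  if (all(c("deploy_date", "retrieve_date") %in% names(receivers))) {
    ok <- rep(FALSE, nrow(det))
    for (r in seq_len(nrow(receivers))) {
      sel <- det$receiver_id == receivers$receiver_id[r]
      ok[sel] <- ok[sel] |
        (as.Date(det$timestamp[sel]) >= as.Date(receivers$deploy_date[r]) &
         as.Date(det$timestamp[sel]) < as.Date(receivers$retrieve_date[r]))
    }
    if (any(!ok)) {
      warning(sum(!ok), " detections outside receiver deployment intervals dropped")
      det <- det[ok, ]
    }
  }
  j <- match(det$tag_code, tags$tag_code)
  det$fish_id <- tags$fish_id[j]
  det$release_date <- as.Date(tags$release_date)[j]
  det$expire_date <- as.Date(tags$expire_date)[j]
  det$release_pool <- tags$release_pool[j]
  det
}

# Group one fish's detections into "continuous events": runs where the gap
# between successive detections is <= gap_days.
continuous_events <- function(times, gap_days) {
  o <- order(times)
  gaps <- diff(as.numeric(times[o])) / 86400
  cumsum(c(1, gaps > gap_days))[order(o)]
}

#' Screen tags for suspected dead fish and dropped transmitters
#'
#' Applies the two-part suspect-tag rule set to each tagged fish. A fish is
#' removed with reason `"first30"` when its only detections fall within the
#' first 30 days following tagging, and with reason `"stationary"` when its
#' tag kept being detected but at least two of three stationarity
#' conditions hold: (1) the whole record is a single continuous detection
#' event on one receiver or on simultaneously heard receivers in proximity;
#' (2) the maximum distance between all receivers with detections is under
#' 1,000 m; (3) the only pool of detection is the release pool. Lock
#' receivers are excluded before evaluation; fish with no detections are
#' retained (never detected is not suspect).
#'
#' @param detections,tags,receivers The three telemetry streams.
#' @param first_days Window for the post-tagging rule (days; default 30).
#' @param gap_days Maximum gap within a "continuous" detection event
#'   (days; default 7).
#' @param proximity_m Distance defining both receiver proximity and the
#'   stationary-footprint condition (metres; default 1000).
#' @param persist_days The stationary rule set targets tags that *kept on*
#'   being detected; it is only evaluated for fish whose record spans more
#'   than this many days from first to last detection (default 30).
#'   Shorter records either fall under the post-tagging rule or are too
#'   brief to call stationary, and are retained.
#' @return Data frame `fish_id`, `reason` (`kept`, `first30`,
#'   `stationary`), and the three condition flags `single_event`,
#'   `small_footprint`, `release_pool_only`.
#' @export
filter_suspect_tags <- function(detections, tags, receivers,
                                first_days = 30, gap_days = 7,
                                proximity_m = 1000, persist_days = 30) {
  det <- join_detections(detections, tags, receivers)
  det <- det[!det$at_lock, ]
  out <- data.frame(fish_id = tags$fish_id, reason = "kept",
                    single_event = NA, small_footprint = NA,
                    release_pool_only = NA)
  for (k in seq_len(nrow(tags))) {
    d <- det[det$fish_id == tags$fish_id[k], ]
    if (nrow(d) == 0) next
    if (max(as.Date(d$timestamp)) <=
        as.Date(tags$release_date[k]) + first_days) {
      out$reason[k] <- "first30"
      next
    }
    span <- as.numeric(max(as.Date(d$timestamp)) - min(as.Date(d$timestamp)))
    if (span <= persist_days) next  # too brief to have "kept being detected"
    km <- d$river_km
    spread_m <- (max(km) - min(km)) * 1000
    ev <- continuous_events(d$timestamp, gap_days)
    c1 <- length(unique(ev)) == 1 &&
      (length(unique(d$receiver_id)) == 1 || spread_m < proximity_m)
    c2 <- spread_m < proximity_m
    c3 <- all(d$pool == tags$release_pool[k])
    out$single_event[k] <- c1
    out$small_footprint[k] <- c2
    out$release_pool_only[k] <- c3
    if (c1 + c2 + c3 >= 2) out$reason[k] <- "stationary"
  }
  out
}

#' Monthly pool residency for one fish-month
#'
#' The pool where the fish resided for the majority of the month: the pool
#' with the most distinct detection-days; ties are broken by the larger
#' detection count; a double tie falls back to the previous month's
#' residency and then to the lower pool index. Lock receivers must be
#' excluded before counting (done here when the receiver table is given).
#'
#' @param detections One fish's detections for one month (`timestamp`,
#'   `receiver_id`, and `pool` unless `receivers` is supplied).
#' @param receivers Optional receiver table used to attach pools and drop
#'   lock receivers.
#' @param prev_pool Previous month's residency (for the double tie-break).
#' @return Integer pool index, or `NA` when no usable detections remain.
#' @export
monthly_residency <- function(detections, receivers = NULL,
                              prev_pool = NA_integer_) {
  d <- detections
  if (!is.null(receivers)) {
    rec1 <- receivers[!duplicated(receivers$receiver_id), ]
    k <- match(d$receiver_id, rec1$receiver_id)
    d$pool <- rec1$pool[k]
    if ("at_lock" %in% names(rec1)) d <- d[!rec1$at_lock[k], ]
  }
  if (nrow(d) == 0) return(NA_integer_)
  days <- tapply(as.Date(d$timestamp), d$pool, function(x) length(unique(x)))
  events <- tapply(d$pool, d$pool, length)
  pool_ids <- as.integer(names(days))
  best <- pool_ids[days == max(days)]
  if (length(best) > 1) {
    ev <- events[as.character(best)]
    best <- best[ev == max(ev)]
  }
  if (length(best) > 1) {
    if (!is.na(prev_pool) && prev_pool %in% best) return(as.integer(prev_pool))
    best <- min(best)
  }
  as.integer(best)
}

# All-fish residency table: fish_id, month, pool.
residency_table <- function(detections, tags, receivers, start, end) {
  det <- join_detections(detections, tags, receivers)
  det <- det[!det$at_lock, ]
  det$month <- month_index(det$timestamp, start)
  TT <- n_study_months(start, end)
  det <- det[det$month >= 1 & det$month <= TT, ]
  res <- list()
  for (id in unique(det$fish_id)) {
    d <- det[det$fish_id == id, ]
    months <- sort(unique(d$month))
    pools <- integer(length(months))
    prev <- NA_integer_
    for (s in seq_along(months)) {
      if (s > 1 && months[s] - months[s - 1] != 1) prev <- NA_integer_
      pools[s] <- monthly_residency(d[d$month == months[s], ], prev_pool = prev)
      prev <- pools[s]
    }
    res[[id]] <- data.frame(fish_id = id, month = months, pool = pools)
  }
  if (length(res) == 0)
    return(data.frame(fish_id = character(), month = integer(),
                      pool = integer()))
  do.call(rbind, c(res, list(make.row.names = FALSE)))
}

#' Build monthly observation histories
#'
#' Assembles the per-fish observation sequence used by the model: the
#' release month carries the asserted release pool; later months carry the
#' monthly residency pool when one exists and `"none"` otherwise; every
#' month from the projected battery-expiration month onward carries the
#' asserted `"expired"` symbol (residencies in or after that month — i.e.
#' detections beyond the projected expiration — are discarded).
#' Residency records dated before a fish's release are rejected with a
#' warning.
#'
#' @param tags Tag deployments (`fish_id`, `release_date`, `release_pool`,
#'   `expire_date`).
#' @param residency Residency table (`fish_id`, `month`, `pool`), e.g.
#'   from the detections via [monthly_residency].
#' @param start,end Calendar range `"YYYY-MM"`.
#' @return Data frame `fish_id`, `month`, `obs` covering every month from
#'   release through the end of the calendar for every fish.
#' @export
build_histories <- function(tags, residency, start, end) {
  TT <- n_study_months(start, end)
  out <- vector("list", nrow(tags))
  for (k in seq_len(nrow(tags))) {
    mr <- month_index(tags$release_date[k], start)
    me <- month_index(tags$expire_date[k], start)
    if (mr > TT) next
    months <- mr:TT
    obs <- rep("none", length(months))
    r <- residency[residency$fish_id == tags$fish_id[k] &
                   !is.na(residency$pool), ]
    if (any(r$month < mr)) {
      warning("residency before release dropped for ", tags$fish_id[k])
      r <- r[r$month >= mr, ]
    }
    sel <- r$month > mr & r$month < me & r$month <= TT
    obs[r$month[sel] - mr + 1] <- paste0("pool_", r$pool[sel])
    obs[1] <- paste0("pool_", tags$release_pool[k])
    if (me <= TT) obs[months >= me] <- "expired"
    out[[k]] <- data.frame(fish_id = tags$fish_id[k], month = months,
                           obs = obs)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' One-shot preprocessing of the three telemetry streams
#'
#' Runs the full reduction: suspect-tag screening, monthly residency,
#' history assembly, and the effort covariate.
#'
#' @param receivers,tags,detections The three streams (data frames or CSV
#'   paths).
#' @param start,end Calendar range `"YYYY-MM"`.
#' @param filter Apply [filter_suspect_tags] (default `TRUE`).
#' @param ... Passed to [filter_suspect_tags].
#' @return List: `histories`, `effort` (matrix), `filter_report`,
#'   `tags_retained`.
#' @export
preprocess <- function(receivers, tags, detections, start, end,
                       filter = TRUE, ...) {
  if (is.character(receivers)) receivers <- utils::read.csv(receivers)
  if (is.character(tags)) tags <- utils::read.csv(tags)
  if (is.character(detections)) detections <- utils::read.csv(detections)
  report <- if (filter) {
    filter_suspect_tags(detections, tags, receivers, ...)
  } else {
    data.frame(fish_id = tags$fish_id, reason = "kept")
  }
  keep <- report$fish_id[report$reason == "kept"]
  tags2 <- tags[tags$fish_id %in% keep, ]
  det2 <- detections[detections$tag_code %in% tags2$tag_code, ]
  res <- residency_table(det2, tags2, receivers, start, end)
  hist <- build_histories(tags2, res, start, end)
  list(histories = hist,
       effort = compute_effort(receivers, start, end),
       filter_report = report,
       tags_retained = tags2)
}
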