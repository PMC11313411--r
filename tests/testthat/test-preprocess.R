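# Preprocessing: effort arithmetic, suspect-tag screening, monthly
# residency, history assembly.

test_that("effort is exact day-count arithmetic on half-open intervals", {
  # April has 30 days: one full-month receiver plus one 15-day receiver
  dep <- data.frame(receiver_id = c("A", "B"), pool = 1,
                    river_km = c(5, 12),
                    deploy_date = as.Date(c("2015-04-01", "2015-04-01")),
                    retrieve_date = as.Date(c("2015-05-01", "2015-04-16")))
  x <- compute_effort(dep, "2015-04", "2015-05")
  expect_equal(unname(x[1, 1]), (30 + 15) / 30)
  expect_equal(unname(x[1, 2]), 0)  # empty pool-month
  # single receiver over a full month -> 1.0
  x1 <- compute_effort(dep[1, ], "2015-04", "2015-04")
  expect_equal(unname(x1[1, 1]), 1)
})

test_that("effort is invariant under splitting deployment intervals", {
  dep <- data.frame(receiver_id = "A", pool = 1, river_km = 5,
                    deploy_date = as.Date("2015-02-10"),
                    retrieve_date = as.Date("2015-07-20"))
  parts <- data.frame(receiver_id = c("A", "A", "A"), pool = 1, river_km = 5,
                      deploy_date = as.Date(c("2015-02-10", "2015-03-05",
                                              "2015-05-21")),
                      retrieve_date = as.Date(c("2015-03-05", "2015-05-21",
                                                "2015-07-20")))
  expect_equal(compute_effort(dep, "2015-01", "2015-08"),
               compute_effort(parts, "2015-01", "2015-08"))
})

test_that("effort rejects overlapping intervals and clips with a warning", {
  bad <- data.frame(receiver_id = c("A", "A"), pool = 1, river_km = 5,
                    deploy_date = as.Date(c("2015-01-01", "2015-02-01")),
                    retrieve_date = as.Date(c("2015-03-01", "2015-04-01")))
  expect_error(compute_effort(bad, "2015-01", "2015-06"), "overlapping")
  outside <- data.frame(receiver_id = "A", pool = 1, river_km = 5,
                        deploy_date = as.Date("2014-11-01"),
                        retrieve_date = as.Date("2015-02-01"))
  expect_warning(x <- compute_effort(outside, "2015-01", "2015-03"),
                 "clipped")
  expect_equal(unname(x[1, ]), c(1, 0, 0))
})

make_tags <- function(release_pool = 1) {
  data.frame(fish_id = "f1", species = "s", tag_code = "T1",
             release_date = as.Date("2015-01-01"),
             release_pool = release_pool,
             expire_date = as.Date("2016-01-01"))
}

det_at <- function(days, receiver, base = as.Date("2015-01-01")) {
  data.frame(tag_code = "T1", receiver_id = receiver,
             timestamp = as.POSIXct(base, tz = "UTC") + days * 86400)
}

test_that("fish detected only in the first 30 days are removed", {
  rec <- toy_receivers()
  det <- det_at(seq(3, 28, by = 5), "R1")
  rep <- filter_suspect_tags(det, make_tags(), rec)
  expect_equal(rep$reason, "first30")
  # detections continuing past day 30 are not first30
  det2 <- rbind(det, det_at(c(40, 80, 120), "R2"))
  rep2 <- filter_suspect_tags(det2, make_tags(), rec)
  expect_false(rep2$reason == "first30")
})

test_that("stationary tags need two of the three conditions", {
  rec <- rbind(toy_receivers(),
               data.frame(receiver_id = "R1b", pool = 1, river_km = 10.4,
                          deploy_date = as.Date("2015-01-01"),
                          retrieve_date = as.Date("2016-01-01"),
                          at_lock = FALSE))
  # continuous on receivers 400 m apart, release pool only: all conditions
  det <- det_at(seq(2, 200, by = 3), rep(c("R1", "R1b"), length.out = 67))
  rep <- filter_suspect_tags(det, make_tags(), rec)
  expect_equal(rep$reason, "stationary")
  expect_true(rep$single_event && rep$small_footprint &&
                rep$release_pool_only)
  # a long gap breaks the single-event condition but 2 of 3 still hold
  det_gap <- det_at(c(seq(2, 40, by = 2), seq(90, 150, by = 2)), "R1")
  rep_gap <- filter_suspect_tags(det_gap, make_tags(), rec)
  expect_equal(rep_gap$reason, "stationary")
  expect_false(rep_gap$single_event)
  # mobile two-pool fish spanning months: kept
  det_mob <- det_at(seq(2, 180, by = 10), rep(c("R1", "R3"), 9))
  rep_mob <- filter_suspect_tags(det_mob, make_tags(), rec)
  expect_equal(rep_mob$reason, "kept")
  # wide footprint within the release pool, episodic: only one condition
  rec_wide <- rbind(rec, data.frame(receiver_id = "R1c", pool = 1,
                                    river_km = 18,
                                    deploy_date = as.Date("2015-01-01"),
                                    retrieve_date = as.Date("2016-01-01"),
                                    at_lock = FALSE))
  det_wide <- det_at(c(5, 50, 100, 160), c("R1", "R1c", "R1", "R1c"))
  rep_wide <- filter_suspect_tags(det_wide, make_tags(), rec_wide)
  expect_equal(rep_wide$reason, "kept")
})

test_that("never-detected fish and brief records are retained", {
  rec <- toy_receivers()
  none <- data.frame(tag_code = character(), receiver_id = character(),
                     timestamp = as.POSIXct(character(), tz = "UTC"))
  expect_equal(filter_suspect_tags(none, make_tags(), rec)$reason, "kept")
  # a single ping past day 30 neither continues being detected nor
  # triggers the post-tagging rule
  one <- det_at(38, "R1")
  expect_equal(filter_suspect_tags(one, make_tags(), rec)$reason, "kept")
})

test_that("monthly residency follows majority-days with tie-breaks", {
  d <- function(days, pool) data.frame(
    timestamp = as.POSIXct("2015-03-01", tz = "UTC") + days * 86400 +
      seq_along(days),
    receiver_id = "x", pool = pool)
  # 10 detection-days in pool 3 beat 5 in pool 2
  det <- rbind(d(1:10, 3), d(11:15, 2))
  expect_equal(monthly_residency(det), 3L)
  # equal days: more detection events win
  det2 <- rbind(d(1:5, 3), d(1:5, 2), d(rep(5, 40), 2))
  expect_equal(monthly_residency(det2), 2L)
  # equal days and events: previous pool, then lower index
  det3 <- rbind(d(1:5, 4), d(6:10, 2))
  expect_equal(monthly_residency(det3, prev_pool = 4L), 4L)
  expect_equal(monthly_residency(det3, prev_pool = 6L), 2L)
  expect_equal(monthly_residency(det3), 2L)
  # residency is invariant to record order
  set.seed(5)
  det_shuf <- det[sample(nrow(det)), ]
  expect_equal(monthly_residency(det_shuf), monthly_residency(det))
})

test_that("lock-receiver detections are excluded from residency", {
  rec <- rbind(toy_receivers(),
               data.frame(receiver_id = "L1", pool = 2, river_km = 20,
                          deploy_date = as.Date("2015-01-01"),
                          retrieve_date = as.Date("2016-01-01"),
                          at_lock = TRUE))
  det <- data.frame(timestamp = as.POSIXct("2015-03-02", tz = "UTC") +
                      (1:5) * 86400, receiver_id = "L1")
  expect_true(is.na(monthly_residency(det, receivers = rec)))
  det2 <- rbind(det, data.frame(timestamp = as.POSIXct("2015-03-20",
                                                       tz = "UTC"),
                                receiver_id = "R1"))
  expect_equal(monthly_residency(det2, receivers = rec), 1L)
})

test_that("histories assemble release, residency, gaps and expiration", {
  tags <- data.frame(fish_id = "f1", species = "s", tag_code = "T1",
                     release_date = as.Date("2015-01-15"),
                     release_pool = 2,
                     expire_date = as.Date("2015-05-10"))
  res <- data.frame(fish_id = "f1", month = 1:3, pool = 2)
  h <- build_histories(tags, res, "2015-01", "2015-07")
  expect_equal(h$obs, c("pool_2", "pool_2", "pool_2", "none", "expired",
                        "expired", "expired"))
  expect_equal(h$month, 1:7)
  # detections in or after the expiration month are discarded
  res2 <- data.frame(fish_id = "f1", month = c(2, 5, 6), pool = c(3, 3, 3))
  h2 <- build_histories(tags, res2, "2015-01", "2015-07")
  expect_equal(h2$obs, c("pool_2", "pool_3", "none", "none", "expired",
                         "expired", "expired"))
  # never re-detected: all none until expiration
  h3 <- build_histories(tags, res2[0, ], "2015-01", "2015-07")
  expect_equal(h3$obs[2:4], rep("none", 3))
  # residency before release is rejected
  tags_late <- tags
  tags_late$release_date <- as.Date("2015-03-01")
  expect_warning(h4 <- build_histories(tags_late,
                                       data.frame(fish_id = "f1", month = 1,
                                                  pool = 3),
                                       "2015-01", "2015-07"),
                 "before release")
  expect_equal(h4$month, 3:7)
})

test_that("round trip: simulated streams reproduce the true histories", {
  # with per-month event expansion, preprocessing must recover exactly the
  # monthly observation layer the generator drew
  cfg <- small_scenario(seed = 14)
  sim <- simulate_cohort(cfg)
  end <- format(month_start(cfg$n_months, cfg$start), "%Y-%m")
  pre <- preprocess(sim$receivers, sim$tags, sim$detections, cfg$start, end,
                    filter = FALSE)
  truth <- sim$histories[order(sim$histories$fish_id, sim$histories$month), ]
  got <- pre$histories[order(pre$histories$fish_id, pre$histories$month), ]
  expect_equal(got$obs, truth$obs)
  expect_equal(unname(pre$effort), unname(sim$effort))
})
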