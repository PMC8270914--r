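test_that("empty cohort still places receivers; invalid spacing errors", {
  cfg <- sim_config(seed = 3, group_sizes = c(adult_male = 0, adult_female = 0,
                                              juvenile_male = 0, juvenile_female = 0))
  sys <- generate_system(cfg)
  expect_equal(nrow(sys$tagging), 0)
  expect_equal(nrow(sys$truth), 0)
  expect_gt(nrow(sys$receivers), 0)
  expect_equal(nrow(simulate_detections(sys, cfg)), 0)

  expect_error(generate_system(sim_config(receiver_spacing = 100)),
               "no receiver fits")
})

test_that("generation and simulation are deterministic for a fixed seed", {
  cfg <- sim_config(seed = 11, study_end = as.Date("2015-10-31"))
  s1 <- generate_system(cfg); s2 <- generate_system(cfg)
  expect_identical(s1$receivers, s2$receivers)
  expect_identical(s1$truth, s2$truth)
  expect_identical(simulate_detections(s1, cfg), simulate_detections(s2, cfg))
})

test_that("true seasonal ranges nest correctly by group", {
  sys <- generate_system(sim_config(seed = 5))
  tr <- sys$truth
  am <- tr$group == "adult_male"
  expect_true(all(tr$a_mating[am] <= tr$a_nonmating[am] + 1e-12))
  expect_true(all(tr$b_mating[am] >= tr$b_nonmating[am] - 1e-12))
  expect_true(all((tr$b_mating - tr$a_mating)[am] >=
                    (tr$b_nonmating - tr$a_nonmating)[am] - 1e-12))
  expect_equal(tr$a_mating[!am], tr$a_nonmating[!am])
  expect_equal(tr$b_mating[!am], tr$b_nonmating[!am])
  # ranges inside the reef and tagging receiver inside the range
  L <- sys$geometry$reefs$length_km[match(tr$home_reef, sys$geometry$reefs$reef_id)]
  expect_true(all(tr$a_mating >= 0 & tr$b_mating <= L + 1e-12))
  pos <- sys$receivers$position_km[match(tr$tag_receiver_id, sys$receivers$receiver_id)]
  expect_true(all(pos >= tr$a_nonmating - 1e-9 & pos <= tr$b_nonmating + 1e-9))
})

test_that("every true detection lies within detection radius of the seasonal range", {
  cfg <- sim_config(seed = 7, false_ping_per_day = 0,
                    group_sizes = c(adult_male = 4, adult_female = 4,
                                    juvenile_male = 4, juvenile_female = 4),
                    study_end = as.Date("2015-12-31"))
  sys <- generate_system(cfg)
  det <- simulate_detections(sys, cfg)
  ri <- match(det$receiver_id, sys$receivers$receiver_id)
  ti <- match(det$transmitter_id, sys$truth$transmitter_id)
  month <- as.integer(format(det$timestamp, "%m", tz = cfg$tz))
  mating <- month %in% 7:9
  a <- ifelse(mating, sys$truth$a_mating[ti], sys$truth$a_nonmating[ti])
  b <- ifelse(mating, sys$truth$b_mating[ti], sys$truth$b_nonmating[ti])
  pos <- sys$receivers$position_km[ri]
  expect_identical(sys$receivers$reef_id[ri], sys$truth$home_reef[ti])
  expect_true(all(pos >= a - cfg$detection_radius - 1e-9 &
                    pos <= b + cfg$detection_radius + 1e-9))
  expect_false(is.unsorted(as.numeric(det$timestamp)))
})

test_that("detected receiver span converges to the true range", {
  # one shark, uniform daily positions over [10, 20] km, receivers every
  # 2 km, ~300 days: detected span within one spacing of truth
  cfg <- sim_config(seed = 21,
                    reef_lengths = 40, receiver_spacing = 2,
                    detection_radius = 1, daily_pings_mean = 5,
                    group_sizes = c(adult_male = 0, adult_female = 1,
                                    juvenile_male = 0, juvenile_female = 0),
                    p_silent = 0, false_ping_per_day = 0,
                    study_start = as.Date("2015-01-01"),
                    study_end = as.Date("2015-11-10"),
                    tag_window_days = 1)
  sys <- generate_system(cfg)
  sys$truth$a_nonmating <- sys$truth$a_mating <- 10
  sys$truth$b_nonmating <- sys$truth$b_mating <- 20
  det <- simulate_detections(sys, cfg)
  pos <- sys$receivers$position_km[match(unique(det$receiver_id),
                                         sys$receivers$receiver_id)]
  expect_lte(abs(min(pos) - 10), cfg$receiver_spacing)
  expect_lte(abs(max(pos) - 20), cfg$receiver_spacing)
})

test_that("silent sharks transmit only inside the post-capture window", {
  cfg <- paper_cohort_config(seed = 2)
  sys <- generate_system(cfg)
  det <- simulate_detections(sys, cfg)
  silent_ids <- sys$truth$transmitter_id[sys$truth$silent]
  d <- det[det$transmitter_id %in% silent_ids, ]
  expect_gt(nrow(d), 0)  # they do ping right after tagging
  tag <- sys$tagging$tag_date[match(d$transmitter_id, sys$tagging$transmitter_id)]
  day <- as.Date(format(d$timestamp, "%Y-%m-%d", tz = cfg$tz))
  expect_true(all(day <= tag + 13))
})

test_that("MPA fixture files cover the screening edge cases", {
  dir <- withr::local_tempdir()
  fx <- generate_mpa_fixtures(dir)
  expect_true(file.exists(fx$mpa_path) && file.exists(fx$reef_path))
  js <- jsonlite::read_json(fx$mpa_path)
  cats <- vapply(js$features, function(f) f$properties$IUCN_CAT, "")
  yrs <- vapply(js$features, function(f) as.numeric(f$properties$STATUS_YR), 0)
  expect_true("VI" %in% cats)            # non no-take category present
  expect_true(any(yrs == 0))             # missing designation year present
  lons <- unlist(lapply(js$features, function(f)
    vapply(f$geometry$coordinates[[1]], function(p) as.numeric(p[[1]]), 0)))
  expect_true(any(lons > 179) && any(lons < -169))  # antimeridian straddler
})
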