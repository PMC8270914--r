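test_that("reef geometry validates its cumulative area function", {
  reefs <- data.frame(reef_id = "A", length_km = 10, start_lat = 0,
                      start_lon = 0, end_lat = 0, end_lon = 0.1)
  expect_error(reef_geometry(reefs, data.frame(reef_id = "A", s = c(0, 10),
                                               area_km2 = c(1, 5))), "A\\(0\\)")
  expect_error(reef_geometry(reefs, data.frame(reef_id = "A", s = c(0, 5, 10),
                                               area_km2 = c(0, 6, 5))),
               "non-decreasing")
  g <- reef_geometry(reefs, data.frame(reef_id = "A", s = c(0, 5, 10),
                                       area_km2 = c(0, 2, 8)))
  expect_equal(cum_area(g, "A", c(0, 2.5, 5, 7.5)), c(0, 1, 2, 5))
  expect_error(cum_area(g, "B", 1), "unknown reef")
})

test_that("daily occurrences collapse pings within local days", {
  # 100 pings in one local day at one receiver -> one occurrence
  d <- make_det(sprintf("2016-05-02 %02d:%02d:00", rep(0:23, each = 5)[1:100],
                        rep(seq(0, 55, 13), 20)[1:100]), "R1", "T1")
  expect_equal(nrow(daily_occurrences(d)), 1)

  # 23:59 and 00:01 local across midnight -> two occurrences
  d2 <- make_det(c("2016-05-02 23:59:00", "2016-05-03 00:01:00"), "R1", "T1")
  expect_equal(nrow(daily_occurrences(d2)), 2)

  # detected at two receivers the same day -> occurrences at both
  d3 <- make_det(c("2016-05-02 10:00:00", "2016-05-02 11:00:00"),
                 c("R1", "R2"), "T1")
  occ <- daily_occurrences(d3)
  expect_equal(sort(occ$receiver_id), c("R1", "R2"))
  expect_equal(length(unique(occ$day)), 1)
})

test_that("core receiver selection takes the shortest 95% prefix", {
  expect_equal(sort(select_core_receivers(c(R1 = 50, R2 = 45, R3 = 5))),
               c("R1", "R2"))
  expect_equal(select_core_receivers(c(R1 = 10)), "R1")
  expect_equal(sort(select_core_receivers(c(R1 = 1, R2 = 1))), c("R1", "R2"))
  # ties broken by ascending receiver id
  expect_equal(select_core_receivers(c(R2 = 5, R1 = 5), threshold = 0.5), "R1")
  expect_error(select_core_receivers(numeric(0)), "empty")
})

test_that("hull areas map receiver spans through A(s)", {
  g <- make_geometry(length_km = 10, density = 2)
  rec <- make_receivers(c(1, 4, 7))
  expect_equal(hull_area(c("R1", "R2"), rec, g), 6)        # A(4) - A(1)
  expect_equal(hull_area("R2", rec, g), 0)                 # single receiver
  expect_error(hull_area("R9", rec, g), "unknown receiver")

  # two reefs: per-reef hulls summed, inter-reef water contributes nothing
  g2 <- reef_geometry(
    reefs = data.frame(reef_id = c("A", "B"), length_km = 10,
                       start_lat = 0, start_lon = c(0, 1),
                       end_lat = 0, end_lon = c(0.1, 1.1)),
    area = data.frame(reef_id = rep(c("A", "B"), each = 2), s = c(0, 10, 0, 10),
                      area_km2 = c(0, 20, 0, 10)))
  rec2 <- rbind(make_receivers(c(1, 4), reef = "A", ids = c("A1", "A2")),
                make_receivers(c(2, 4), reef = "B", ids = c("B1", "B2")))
  expect_equal(hull_area(c("A1", "A2", "B1", "B2"), rec2, g2), 6 + 2)
})

test_that("compute_ud composes ranking and hull mapping", {
  g <- make_geometry(length_km = 10, density = 2)
  rec <- make_receivers(c(1, 4, 7))
  # counts R1: 50 days, R2: 45 days, R3: 5 days
  occ <- data.frame(
    transmitter_id = "T1",
    day = as.Date("2016-01-01") + c(0:49, 0:44, 50:54),
    receiver_id = rep(c("R1", "R2", "R3"), c(50, 45, 5)),
    stringsAsFactors = FALSE)
  u <- compute_ud("T1", occ, rec, g)
  expect_equal(u$ud95_km2, 6)    # core = {R1, R2}, A(4) - A(1)
  expect_equal(u$ud100_km2, 12)  # all three, A(7) - A(1)
  expect_equal(sort(u$core_receivers), c("R1", "R2"))

  # single receiver -> UD95 = UD100 = 0
  u1 <- compute_ud("T1", occ[occ$receiver_id == "R1", ], rec, g)
  expect_equal(u1$ud95_km2, 0)
  expect_equal(u1$ud100_km2, 0)

  # absent in season is NULL, not zero
  expect_null(compute_ud("T1", occ[0, ], rec, g))
  occ_nm <- occ; occ_nm$day <- as.Date("2016-01-15")  # January only
  expect_null(compute_ud("T1", occ_nm, rec, g, season = "mating"))
  expect_false(is.null(compute_ud("T1", occ_nm, rec, g, season = "non_mating")))

  # threshold 1 makes UD95 equal UD100
  u100 <- compute_ud("T1", occ, rec, g, threshold = 1)
  expect_equal(u100$ud95_km2, u100$ud100_km2)
})

test_that("UD invariants hold on simulated data", {
  cfg <- sim_config(seed = 13,
                    group_sizes = c(adult_male = 5, adult_female = 5,
                                    juvenile_male = 5, juvenile_female = 5),
                    study_end = as.Date("2016-06-30"))
  sys <- generate_system(cfg)
  det <- simulate_detections(sys, cfg)
  dw <- apply_post_capture_window(filter_false_detections(det)$detections,
                                  sys$tagging)
  co <- build_cohort(dw, sys$tagging, sys$receivers)
  occ <- daily_occurrences(dw, co)
  ud <- ud_table(occ, sys$tagging, sys$receivers, sys$geometry)
  total_area <- sum(cfg$reef_lengths * cfg$area_density)
  expect_true(all(ud$ud95_km2 >= 0))
  expect_true(all(ud$ud95_km2 <= ud$ud100_km2 + 1e-9))
  expect_true(all(ud$ud100_km2 <= total_area))

  # monotonicity: adding occurrences never decreases UD100
  id <- ud$shark[which.max(ud$n_receivers)]
  u_full <- compute_ud(id, occ, sys$receivers, sys$geometry)
  sub <- occ[occ$transmitter_id != id | seq_len(nrow(occ)) %% 2 == 0, ]
  u_half <- compute_ud(id, sub, sys$receivers, sys$geometry)
  if (!is.null(u_half)) expect_lte(u_half$ud100_km2, u_full$ud100_km2 + 1e-9)
})

test_that("seasonal exclusive use follows the interval difference", {
  g <- make_geometry(length_km = 10, density = 2)
  rec <- make_receivers(c(1, 5, 7))
  # non-mating hull [1,5]; mating hull [1,7]
  occ <- rbind(
    data.frame(transmitter_id = "T1", day = as.Date("2016-02-01") + 0:9,
               receiver_id = rep(c("R1", "R2"), 5), stringsAsFactors = FALSE),
    data.frame(transmitter_id = "T1", day = as.Date("2016-08-01") + 0:9,
               receiver_id = rep(c("R1", "R3"), 5), stringsAsFactors = FALSE))
  su <- seasonal_use("T1", occ, rec, g)
  expect_equal(su$exclusive_area_km2, 4)              # A(7) - A(5)
  expect_equal(su$fraction_exclusive_mating, 1 / 3)   # 4 / 12

  # no mating detections -> 0
  su0 <- seasonal_use("T1", occ[1:10, ], rec, g)
  expect_equal(su0$fraction_exclusive_mating, 0)

  # identical seasonal hulls -> 0 (no new reef portions explored)
  occ_same <- occ; occ_same$receiver_id <- rep(c("R1", "R2"), 10)
  expect_equal(seasonal_use("T1", occ_same, rec, g)$fraction_exclusive_mating, 0)
})

test_that("inter-reef straight-line distances behave like great circles", {
  g <- reef_geometry(
    reefs = data.frame(reef_id = c("A", "B"), length_km = 10,
                       start_lat = c(0, 0), start_lon = c(0, 1),
                       end_lat = c(0, 0), end_lon = c(0, 1)),
    area = data.frame(reef_id = rep(c("A", "B"), each = 2), s = c(0, 10, 0, 10),
                      area_km2 = c(0, 10, 0, 10)))
  expect_equal(inter_reef_distance(g, "A", "A"), 0)
  d <- inter_reef_distance(g, "A", "B")
  expect_equal(d, 111.2, tolerance = 0.001)  # one degree on the equator
  expect_equal(inter_reef_distance(g, "B", "A"), d)
})
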