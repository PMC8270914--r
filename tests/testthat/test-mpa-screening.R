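test_that("longitude normalization", {
  expect_equal(normalize_lon(c(-170, 370, 25, -150)), c(190, 10, 25, 210))
})

test_that("geodesic areas match an independent ellipsoid integration", {
  cases <- list(c(160, -0.05, 0.1, 0.1),   # equator
                c(10, 44.5, 1, 1),         # mid-latitude
                c(140, -20, 0.2, 0.2))     # study latitudes
  for (cs in cases) {
    ring <- rbind(c(cs[1], cs[2]), c(cs[1] + cs[3], cs[2]),
                  c(cs[1] + cs[3], cs[2] + cs[4]), c(cs[1], cs[2] + cs[4]),
                  c(cs[1], cs[2]))
    a <- geodesic_ring_area_km2(ring)
    oracle <- oracle_square_area_km2(cs[1], cs[2], cs[3], cs[4])
    expect_equal(a, oracle, tolerance = 0.01)   # the 1% contract
    expect_equal(a, oracle, tolerance = 1e-9)   # in fact much tighter
  }
  # additivity over disjoint pieces
  a1 <- geodesic_ring_area_km2(rbind(c(0, 0), c(0.1, 0), c(0.1, 0.1),
                                     c(0, 0.1), c(0, 0)))
  a2 <- geodesic_ring_area_km2(rbind(c(0.1, 0), c(0.2, 0), c(0.2, 0.1),
                                     c(0.1, 0.1), c(0.1, 0)))
  a12 <- geodesic_ring_area_km2(rbind(c(0, 0), c(0.2, 0), c(0.2, 0.1),
                                      c(0, 0.1), c(0, 0)))
  expect_equal(a1 + a2, a12, tolerance = 1e-9)
})

test_that("ring repair: duplicates, spikes and bowties", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0))
  a_sq <- geodesic_ring_area_km2(sq)

  dup <- rbind(c(0, 0), c(1, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0))
  r1 <- repair_ring(dup)
  expect_length(r1, 1)
  expect_equal(geodesic_ring_area_km2(r1[[1]]), a_sq, tolerance = 1e-9)

  spike <- rbind(c(0, 0), c(1, 0), c(2, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0))
  r2 <- repair_ring(spike)
  expect_length(r2, 1)
  expect_equal(geodesic_ring_area_km2(r2[[1]]), a_sq, tolerance = 1e-9)

  # bowtie -> two triangles; summed area equals the manual decomposition
  bow <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1), c(0, 0))
  r3 <- repair_ring(bow)
  expect_length(r3, 2)
  got <- sum(vapply(r3, geodesic_ring_area_km2, numeric(1)))
  tri_l <- geodesic_ring_area_km2(rbind(c(0, 0), c(0.5, 0.5), c(0, 1), c(0, 0)))
  tri_r <- geodesic_ring_area_km2(rbind(c(1, 0), c(1, 1), c(0.5, 0.5), c(1, 0)))
  expect_equal(got, tri_l + tri_r, tolerance = 1e-6)
})

test_that("convex clipping computes intersections", {
  sub <- rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2), c(0, 0))
  clip <- rbind(c(1, 1), c(3, 1), c(3, 3), c(1, 3), c(1, 1))
  out <- reefrange:::clip_ring_convex(sub, clip)
  expect_equal(geodesic_ring_area_km2(out),
               geodesic_ring_area_km2(rbind(c(1, 1), c(2, 1), c(2, 2),
                                            c(1, 2), c(1, 1))),
               tolerance = 1e-9)
  # disjoint -> empty
  far <- clip + 10
  expect_null(reefrange:::clip_ring_convex(sub, far))
  # non-convex clip refused
  lshape <- rbind(c(0, 0), c(2, 0), c(2, 1), c(1, 1), c(1, 2), c(0, 2), c(0, 0))
  expect_error(reefrange:::clip_ring_convex(sub, lshape), "convex")
})

test_that("GeoJSON reading normalizes attributes and drops bad geometry", {
  p <- withr::local_tempfile(fileext = ".geojson")
  writeLines('{
    "type": "FeatureCollection",
    "features": [
      {"type": "Feature", "properties": {"WDPAID": 7, "NAME": "NoCat", "STATUS_YR": 1999},
       "geometry": {"type": "Polygon", "coordinates": [[[0,0],[0.1,0],[0.1,0.1],[0,0.1],[0,0]]]}},
      {"type": "Feature", "properties": {"WDPAID": 8, "NAME": "NoGeom", "IUCN_CAT": "II"},
       "geometry": null}
    ]}', p)
  expect_warning(m <- read_mpa_polygons(p), "dropped")
  expect_equal(nrow(m), 1)
  expect_equal(m$iucn_category, "Not Reported")
  expect_equal(m$status_year, 1999L)

  writeLines('{"type": "FeatureCollection", "features": []}', p)
  expect_equal(nrow(read_mpa_polygons(p)), 0)
})

test_that("screening filter on the engineered fixtures is exact and idempotent", {
  dir <- withr::local_tempdir()
  fx <- generate_mpa_fixtures(dir)
  mpas <- read_mpa_polygons(fx$mpa_path)
  reefs <- read_reef_polygons(fx$reef_path)
  kept <- filter_mpas(mpas, reefs)
  expect_setequal(kept$mpa_id, as.character(fx$kept_ids))

  # dropped for the right reasons
  expect_false("2" %in% kept$mpa_id)   # IUCN VI
  expect_false("3" %in% kept$mpa_id)   # centroid at 20 E, west of the box
  expect_false("4" %in% kept$mpa_id)   # no designation year
  expect_false("6" %in% kept$mpa_id)   # no reef overlap
  expect_true("5" %in% kept$mpa_id)    # centroid at 175 W via normalization

  # idempotent and order-independent
  again <- filter_mpas(kept, reefs)
  expect_equal(again$mpa_id, kept$mpa_id)
  expect_equal(again$reef_area_km2, kept$reef_area_km2)
  shuf <- mpas[rev(seq_len(nrow(mpas))), ]
  expect_setequal(filter_mpas(shuf, reefs)$mpa_id, kept$mpa_id)

  # classification
  cls <- classify_by_reef_area(kept, 95)
  expect_setequal(cls$above$mpa_id, as.character(fx$above_95_ids))
  cls0 <- classify_by_reef_area(kept, 0)
  expect_equal(nrow(cls0$above), sum(kept$reef_area_km2 > 0))
  expect_error(classify_by_reef_area(mpas), "computed")

  # reef areas: fixture squares against the analytic oracle
  eq <- kept[kept$mpa_id == "1", ]
  expect_equal(eq$reef_area_km2, oracle_square_area_km2(160, -0.05, 0.1, 0.1),
               tolerance = 0.01)
  am <- kept[kept$mpa_id == "5", ]
  expect_equal(am$reef_area_km2, oracle_square_area_km2(-170.1, -10.1, 0.2, 0.2),
               tolerance = 0.01)
})
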