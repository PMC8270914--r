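#' Reef geometry with cumulative slope-area accounting
#'
#' A set of quasi-linear reefs, each with a curvilinear axis of given length
#' and a non-decreasing piecewise-linear cumulative area function A(s)
#' giving the km2 of outer reef slope between the reef origin and
#' curvilinear position s.  Anchor coordinates at the reef ends support
#' inter-reef straight-line distances.
#'
#' @param reefs data frame with columns `reef_id`, `length_km` and anchor
#'   coordinates `start_lat`, `start_lon`, `end_lat`, `end_lon`.
#' @param area data frame of knots (`reef_id`, `s`, `area_km2`) with
#'   A(0) = 0 and A non-decreasing up to s = length.
#' @return object of class `reef_geometry`.
#' @export
reef_geometry <- function(reefs, area) {
  stopifnot(all(c("reef_id", "length_km") %in% names(reefs)),
            all(c("reef_id", "s", "area_km2") %in% names(area)))
  knots <- split(area, area$reef_id)
  for (id in reefs$reef_id) {
    k <- knots[[id]]
    if (is.null(k)) stop_rr("no area knots for reef ", id)
    k <- k[order(k$s), ]
    if (k$s[1] != 0 || k$area_km2[1] != 0) stop_rr("A(0) must be 0 for reef ", id)
    if (any(diff(k$area_km2) < 0)) stop_rr("A(s) must be non-decreasing for reef ", id)
    knots[[id]] <- k
  }
  structure(list(reefs = reefs, knots = knots), class = "reef_geometry")
}

#' Evaluate the cumulative slope-area function A(s)
#'
#' @param geometry a [reef_geometry()].
#' @param reef_id reef identifier.
#' @param s curvilinear position(s), km; clamped to the knot range.
#' @return km2 of outer reef slope from the reef origin to s.
#' @export
cum_area <- function(geometry, reef_id, s) {
  k <- geometry$knots[[reef_id]]
  if (is.null(k)) stop_rr("unknown reef: ", reef_id)
  stats::approx(k$s, k$area_km2, xout = s, rule = 2)$y
}

#' Collapse detections into daily occurrences
#'
#' Splits the monitoring period into local calendar-day bins; a shark has an
#' occurrence at a receiver on a day iff it was detected there at least once
#' that day.  A shark-day can contribute occurrences to several receivers.
#'
#' @param detections filtered, windowed detection table.
#' @param cohort optional [build_cohort()] report; occurrences are
#'   restricted to retained sharks.
#' @param tz study-local timezone defining day boundaries.
#' @return data frame with columns `transmitter_id`, `day` (Date),
#'   `receiver_id`, one row per occurrence.
#' @export
daily_occurrences <- function(detections, cohort = NULL, tz = REEFRANGE_TZ) {
  d <- detections
  if (!is.null(cohort)) d <- d[d$transmitter_id %in% cohort$retained, , drop = FALSE]
  if (!nrow(d)) {
    return(data.frame(transmitter_id = character(), day = as.Date(character()),
                      receiver_id = character(), stringsAsFactors = FALSE))
  }
  day <- as.Date(format(d$timestamp, "%Y-%m-%d", tz = tz))
  occ <- unique(data.frame(transmitter_id = d$transmitter_id, day = day,
                           receiver_id = d$receiver_id, stringsAsFactors = FALSE))
  occ <- occ[rr_order(occ$transmitter_id, as.numeric(occ$day), occ$receiver_id), ]
  row.names(occ) <- NULL
  occ
}

#' Select the receivers holding 95% of daily occurrences
#'
#' Receivers are ranked by descending daily-occurrence count (ties broken by
#' ascending receiver id) and the shortest prefix whose cumulative count
#' reaches `threshold` of the total is returned.
#'
#' @param counts named vector of per-receiver daily-occurrence counts.
#' @param threshold cumulative share, default 0.95.
#' @return character vector of core receiver ids.
#' @export
select_core_receivers <- function(counts, threshold = 0.95) {
  if (!length(counts)) stop_rr("empty occurrence counts")
  ids <- names(counts)
  o <- rr_order(-as.numeric(counts), ids)
  cs <- cumsum(as.numeric(counts)[o])
  k <- which(cs >= threshold * sum(counts))[1]
  ids[o][seq_len(k)]
}

#' Reef-slope area of the one-dimensional hull of a receiver subset
#'
#' Per reef, the hull is the interval between the minimum and maximum
#' curvilinear positions of the subset's receivers on that reef; its area is
#' A(s_max) - A(s_min).  Hulls on different reefs are summed; the water
#' between reefs contributes zero area.  A subset confined to a single
#' receiver has a degenerate hull and zero area.
#'
#' @param receiver_ids receiver subset.
#' @param receivers receiver table (`receiver_id`, `reef_id`, `position_km`).
#' @param geometry a [reef_geometry()].
#' @return area in km2.
#' @export
hull_area <- function(receiver_ids, receivers, geometry) {
  i <- match(receiver_ids, receivers$receiver_id)
  if (anyNA(i)) stop_rr("unknown receiver(s): ",
                        paste(receiver_ids[is.na(i)], collapse = ", "))
  sub <- receivers[i, , drop = FALSE]
  total <- 0
  for (id in unique(sub$reef_id)) {
    s <- sub$position_km[sub$reef_id == id]
    total <- total + (cum_area(geometry, id, max(s)) - cum_area(geometry, id, min(s)))
  }
  total
}

hull_intervals <- function(receiver_ids, receivers) {
  i <- match(receiver_ids, receivers$receiver_id)
  sub <- receivers[i, , drop = FALSE]
  ids <- sort(unique(sub$reef_id), method = "radix")
  data.frame(reef_id = ids,
             s_min = vapply(ids, function(r) min(sub$position_km[sub$reef_id == r]), 0),
             s_max = vapply(ids, function(r) max(sub$position_km[sub$reef_id == r]), 0),
             stringsAsFactors = FALSE)
}

season_filter <- function(occ, season, mating_months = MATING_MONTHS) {
  season <- match.arg(season, c("all", "mating", "non_mating"))
  if (season == "all") return(occ)
  m <- as.integer(format(occ$day, "%m"))
  if (season == "mating") occ[m %in% mating_months, , drop = FALSE]
  else occ[!(m %in% mating_months), , drop = FALSE]
}

#' Utilization distribution of one shark
#'
#' UD100 is the reef-slope area of the hull of all receivers the shark
#' visited (in the chosen season); UD95 the area of the hull of the
#' receivers accounting for at least 95% of its daily occurrences
#' ([select_core_receivers()]).  A shark detected on a single receiver gets
#' UD95 = UD100 = 0.  A shark with no occurrence in the season yields
#' `NULL` — "absent in season", deliberately distinct from UD = 0.
#'
#' @param shark_id transmitter id.
#' @param occ a [daily_occurrences()] table.
#' @param receivers receiver table.
#' @param geometry a [reef_geometry()].
#' @param season "all", "mating" (July-September) or "non_mating".
#' @param threshold core-receiver cumulative share, default 0.95.
#' @param mating_months months of the mating season, default `7:9`.
#' @return list of class `shark_ud` (or `NULL` when absent in season) with
#'   fields `shark`, `season`, `core_receivers`, `all_receivers`, `hulls`,
#'   `ud95_km2`, `ud100_km2`, `n_days`.
#' @export
compute_ud <- function(shark_id, occ, receivers, geometry,
                       season = "all", threshold = 0.95,
                       mating_months = MATING_MONTHS) {
  so <- season_filter(occ[occ$transmitter_id == shark_id, , drop = FALSE],
                      season, mating_months)
  if (!nrow(so)) return(NULL)
  counts <- table(so$receiver_id)
  counts <- stats::setNames(as.numeric(counts), names(counts))
  core <- select_core_receivers(counts, threshold)
  all_rec <- names(counts)
  structure(list(
    shark = shark_id, season = season,
    core_receivers = core, all_receivers = all_rec,
    hulls = hull_intervals(all_rec, receivers),
    ud95_km2 = hull_area(core, receivers, geometry),
    ud100_km2 = hull_area(all_rec, receivers, geometry),
    n_days = length(unique(so$day))
  ), class = "shark_ud")
}

#' Per-shark UD table for a cohort
#'
#' @param occ a [daily_occurrences()] table.
#' @param tagging tagging table (for sex/maturity labels).
#' @param receivers receiver table.
#' @param geometry a [reef_geometry()].
#' @inheritParams compute_ud
#' @return data frame with one row per shark present in the season:
#'   `shark`, `sex`, `maturity`, `group`, `season`, `ud95_km2`, `ud100_km2`,
#'   `n_receivers`, `n_days`.
#' @export
ud_table <- function(occ, tagging, receivers, geometry, season = "all",
                     threshold = 0.95, mating_months = MATING_MONTHS) {
  ids <- sort(unique(occ$transmitter_id), method = "radix")
  rows <- lapply(ids, function(id) {
    u <- compute_ud(id, occ, receivers, geometry, season, threshold, mating_months)
    if (is.null(u)) return(NULL)
    i <- match(id, tagging$transmitter_id)
    data.frame(shark = id, sex = tagging$sex[i], maturity = tagging$maturity[i],
               group = paste(tagging$maturity[i], tagging$sex[i], sep = "_"),
               season = season, ud95_km2 = u$ud95_km2, ud100_km2 = u$ud100_km2,
               n_receivers = length(u$all_receivers), n_days = u$n_days,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(shark = character(), sex = character(),
                      maturity = character(), group = character(),
                      season = character(), ud95_km2 = numeric(),
                      ud100_km2 = numeric(), n_receivers = integer(),
                      n_days = integer(), stringsAsFactors = FALSE)
  row.names(out) <- NULL
  out
}

interval_difference <- function(m, n) {
  # [m1,m2] minus [n1,n2] -> list of intervals (possibly empty)
  if (is.null(n)) return(list(m))
  pieces <- list()
  if (n[1] > m[1]) pieces <- c(pieces, list(c(m[1], min(m[2], n[1]))))
  if (n[2] < m[2]) pieces <- c(pieces, list(c(max(m[1], n[2]), m[2])))
  Filter(function(p) p[2] > p[1], pieces)
}

#' Mating-season exclusive use of the home range
#'
#' Computes, per shark, the share of its year-round UD100 that lies in reef
#' portions visited exclusively during the mating season (July-September):
#' the per-reef interval difference of the mating hull minus the non-mating
#' hull, mapped through the cumulative area function, divided by the
#' year-round UD100.  The fraction is 0 for sharks without mating-season
#' detections and for sharks with a degenerate (zero-area) UD100.
#'
#' @inheritParams compute_ud
#' @return list of class `seasonal_use`: `shark`,
#'   `fraction_exclusive_mating`, `exclusive_area_km2`, `ud_all`,
#'   `ud_mating`, `ud_non_mating` (seasonal entries may be `NULL`).
#' @export
seasonal_use <- function(shark_id, occ, receivers, geometry,
                         threshold = 0.95, mating_months = MATING_MONTHS) {
  u_all <- compute_ud(shark_id, occ, receivers, geometry, "all",
                      threshold, mating_months)
  u_mat <- compute_ud(shark_id, occ, receivers, geometry, "mating",
                      threshold, mating_months)
  u_non <- compute_ud(shark_id, occ, receivers, geometry, "non_mating",
                      threshold, mating_months)
  excl <- 0
  if (!is.null(u_mat) && !is.null(u_all) && u_all$ud100_km2 > 0) {
    for (i in seq_len(nrow(u_mat$hulls))) {
      reef <- u_mat$hulls$reef_id[i]
      m <- c(u_mat$hulls$s_min[i], u_mat$hulls$s_max[i])
      n <- NULL
      if (!is.null(u_non)) {
        j <- match(reef, u_non$hulls$reef_id)
        if (!is.na(j)) n <- c(u_non$hulls$s_min[j], u_non$hulls$s_max[j])
      }
      for (p in interval_difference(m, n))
        excl <- excl + (cum_area(geometry, reef, p[2]) - cum_area(geometry, reef, p[1]))
    }
  }
  frac <- if (!is.null(u_all) && u_all$ud100_km2 > 0) excl / u_all$ud100_km2 else 0
  structure(list(shark = shark_id, fraction_exclusive_mating = frac,
                 exclusive_area_km2 = excl, ud_all = u_all,
                 ud_mating = u_mat, ud_non_mating = u_non),
            class = "seasonal_use")
}

#' Shortest straight-line distance between two reefs
#'
#' Great-circle distance between the nearest pair of reef end anchors.
#' Reported in movement summaries when a shark crosses between reefs; the
#' crossing is never added to UD area (inter-reef water is not reef-slope
#' habitat).
#'
#' @param geometry a [reef_geometry()].
#' @param reef_a,reef_b reef identifiers.
#' @return distance in km (0 for the same reef); symmetric.
#' @export
inter_reef_distance <- function(geometry, reef_a, reef_b) {
  if (reef_a == reef_b) return(0)
  r <- geometry$reefs
  ia <- match(reef_a, r$reef_id); ib <- match(reef_b, r$reef_id)
  if (is.na(ia) || is.na(ib)) stop_rr("unknown reef id")
  anchors <- function(i) rbind(c(r$start_lat[i], r$start_lon[i]),
                               c(r$end_lat[i], r$end_lon[i]))
  aa <- anchors(ia); bb <- anchors(ib)
  dmin <- Inf
  for (i in 1:2) for (j in 1:2)
    dmin <- min(dmin, haversine_km(aa[i, 1], aa[i, 2], bb[j, 1], bb[j, 2]))
  dmin
}

haversine_km <- function(lat1, lon1, lat2, lon2) {
  r <- 6371.0088
  p1 <- lat1 * pi / 180; p2 <- lat2 * pi / 180
  dl <- (lon2 - lon1) * pi / 180
  h <- sin((p2 - p1) / 2)^2 + cos(p1) * cos(p2) * sin(dl / 2)^2
  2 * r * asin(pmin(1, sqrt(h)))
}
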