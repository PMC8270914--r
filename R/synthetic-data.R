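#' Simulation configuration for a synthetic reef / receiver / shark system
#'
#' Describes the "world" the generator emulates: a small set of quasi-linear
#' barrier reefs carrying a regular array of acoustic receivers, and a cohort
#' of tagged sharks in four sex-by-maturity groups whose true ranges are
#' intervals of the curvilinear reef axis.  Defaults emulate the New
#' Caledonian study system: ~70 receivers across 4 regions, 147 tagged grey
#' reef sharks, group mean ranges ordered adult male >> juvenile male >
#' adult female > juvenile female, adult-male range expansion during the
#' July-September mating season, 30-90 s random transmission delays, a
#' two-week post-capture window, silent individuals and lost receivers.
#'
#' @param seed integer seed; a fixed seed makes every downstream artefact
#'   byte-identical across runs.
#' @param reef_lengths numeric, curvilinear length (km) of each reef.
#' @param area_density km2 of outer reef slope per km of reef axis; recycled
#'   across reefs.  The cumulative slope-area function is A(s) =
#'   area_density * s.
#' @param receiver_spacing regular receiver spacing (km) along each reef axis.
#' @param group_sizes named counts for the four groups (names
#'   `adult_male`, `adult_female`, `juvenile_male`, `juvenile_female`).
#' @param group_range_spans named mean non-mating range span (km) per group.
#'   Individual spans are Gamma-distributed around the group mean (CV 0.5).
#' @param male_mating_expansion km added to the adult-male span during the
#'   mating season (July-September); other groups do not expand.
#' @param detection_radius km within which a receiver can log a transmitter.
#' @param daily_pings_mean mean number of logged pings per shark-day when in
#'   range (Poisson).  A V16 tag at 30-90 s delays emits ~1200/day; the
#'   default subsamples to keep artefacts small (see the vignette).
#' @param p_silent probability a shark stops transmitting after the 14-day
#'   post-capture window (tag failure / emigration).
#' @param n_silent exact silent count overriding `p_silent`: a single count
#'   or a per-group named vector.  Used to engineer fixed cohorts.
#' @param n_lost_receivers number of receivers flagged lost (never logging).
#' @param n_lost_receiver_sharks engineer this many *silent* sharks to be
#'   tagged at receivers that are then flagged lost and are no other shark's
#'   tagging receiver (so only these sharks are excluded by the
#'   lost-receiver rule).
#' @param false_ping_per_day per shark-day probability of injecting one
#'   isolated false detection at a receiver far from the true range
#'   (exercises the false-detection filter).
#' @param study_start,study_end study period (Date).
#' @param tag_window_days sharks are tagged within this many days of
#'   `study_start`.
#' @param tz study-local timezone used for daily binning.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       reef_lengths = c(46, 38, 30, 26),
                       area_density = 1.0,
                       receiver_spacing = 2,
                       group_sizes = c(adult_male = 66L, adult_female = 24L,
                                       juvenile_male = 24L, juvenile_female = 33L),
                       group_range_spans = c(adult_male = 10, adult_female = 4.4,
                                             juvenile_male = 6.2, juvenile_female = 2.7),
                       male_mating_expansion = 11,
                       detection_radius = 0.4,
                       daily_pings_mean = 2,
                       p_silent = 0.2,
                       n_silent = NULL,
                       n_lost_receivers = 0L,
                       n_lost_receiver_sharks = 0L,
                       false_ping_per_day = 0.002,
                       study_start = as.Date("2015-07-01"),
                       study_end = as.Date("2018-12-31"),
                       tag_window_days = 60,
                       tz = REEFRANGE_TZ) {
  grp <- c("adult_male", "adult_female", "juvenile_male", "juvenile_female")
  group_sizes <- as.integer(group_sizes[grp])
  names(group_sizes) <- grp
  group_range_spans <- group_range_spans[grp]
  if (anyNA(group_sizes) || anyNA(group_range_spans))
    stop_rr("group_sizes and group_range_spans must name all four groups")
  if (any(reef_lengths <= 0) || receiver_spacing <= 0 ||
      detection_radius < 0 || any(group_range_spans < 0) ||
      male_mating_expansion < 0)
    stop_rr("lengths, spans and radii must be non-negative")
  if (sum(group_sizes) < 0L) stop_rr("group_sizes must sum to >= 0")
  if (as.numeric(study_end - study_start) <= 14)
    stop_rr("study_end must exceed study_start by more than 14 days")
  if (p_silent < 0 || p_silent > 1) stop_rr("p_silent must be in [0, 1]")
  structure(list(
    seed = as.integer(seed), reef_lengths = reef_lengths,
    area_density = rep_len(area_density, length(reef_lengths)),
    receiver_spacing = receiver_spacing,
    group_sizes = group_sizes, group_range_spans = group_range_spans,
    male_mating_expansion = male_mating_expansion,
    detection_radius = detection_radius,
    daily_pings_mean = daily_pings_mean,
    p_silent = p_silent, n_silent = n_silent,
    n_lost_receivers = as.integer(n_lost_receivers),
    n_lost_receiver_sharks = as.integer(n_lost_receiver_sharks),
    false_ping_per_day = false_ping_per_day,
    study_start = as.Date(study_start), study_end = as.Date(study_end),
    tag_window_days = tag_window_days, tz = tz
  ), class = "sim_config")
}

#' Configuration of the engineered study-cohort fixture
#'
#' A fixed synthetic cohort with the structure of the study population:
#' 147 tagged sharks of which 29 are silent after the two-week post-capture
#' window, 3 of these being tagged at receivers that were subsequently lost,
#' so that the cohort filter retains exactly 118 individuals
#' (53 adult males, 19 adult females, 19 juvenile males, 27 juvenile
#' females).  The simulated period is shortened to one year and the logged
#' ping rate subsampled purely for artefact size; both seasons are covered.
#'
#' @param seed integer seed.
#' @return a `sim_config`.
#' @export
paper_cohort_config <- function(seed = 1L) {
  sim_config(
    seed = seed,
    group_sizes = c(adult_male = 66L, adult_female = 24L,
                    juvenile_male = 24L, juvenile_female = 33L),
    n_silent = c(adult_male = 13L, adult_female = 5L,
                 juvenile_male = 5L, juvenile_female = 6L),
    n_lost_receiver_sharks = 3L,
    daily_pings_mean = 2,
    study_start = as.Date("2015-07-01"),
    study_end = as.Date("2016-06-30")
  )
}

group_levels <- function() c("adult_male", "adult_female",
                             "juvenile_male", "juvenile_female")

#' Generate a synthetic reef system, receiver array and shark cohort
#'
#' Places receivers at regular spacing along each reef axis, draws a true
#' range interval per shark (with the adult-male mating-season superset),
#' assigns every shark a tagging receiver inside its true range, designates
#' silent sharks and lost receivers, and returns ground truth for recovery
#' tests.  Deterministic for a fixed `config$seed`.
#'
#' @param config a [sim_config()].
#' @return a list of class `reef_system` with elements `geometry`
#'   (a [reef_geometry()]), `receivers`, `tagging` (data frames) and `truth`
#'   (per-shark ground truth).
#' @export
generate_system <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nr <- length(config$reef_lengths)
  reef_id <- sprintf("reef%02d", seq_len(nr))

  # geographic placement: reefs laid out west-to-east around 21 S, axes
  # running east; only anchors and receiver lat/lon depend on this
  lat0 <- -21 - 0.4 * (seq_len(nr) - 1)
  lon0 <- 163 + 1.4 * (seq_len(nr) - 1)
  km_per_deg_lon <- 111.32 * cos(lat0 * pi / 180)
  reefs <- data.frame(
    reef_id = reef_id, length_km = config$reef_lengths,
    start_lat = lat0, start_lon = lon0,
    end_lat = lat0, end_lon = lon0 + config$reef_lengths / km_per_deg_lon,
    stringsAsFactors = FALSE
  )
  area <- do.call(rbind, lapply(seq_len(nr), function(i) data.frame(
    reef_id = reef_id[i], s = c(0, config$reef_lengths[i]),
    area_km2 = c(0, config$reef_lengths[i] * config$area_density[i]),
    stringsAsFactors = FALSE
  )))
  geometry <- reef_geometry(reefs, area)

  if (config$receiver_spacing > min(config$reef_lengths))
    stop_rr("no receiver fits: receiver_spacing exceeds a reef length")
  rec <- do.call(rbind, lapply(seq_len(nr), function(i) {
    s <- seq(config$receiver_spacing / 2, config$reef_lengths[i],
             by = config$receiver_spacing)
    data.frame(reef_id = reef_id[i], position_km = s, stringsAsFactors = FALSE)
  }))
  rec$receiver_id <- sprintf("R%03d", seq_len(nrow(rec)))
  i <- match(rec$reef_id, reefs$reef_id)
  rec$lat <- reefs$start_lat[i]
  rec$lon <- reefs$start_lon[i] + rec$position_km / km_per_deg_lon[i]
  rec$status <- "active"
  rec$deploy_start <- config$study_start
  rec$deploy_end <- config$study_end
  rec <- rec[, c("receiver_id", "reef_id", "position_km", "lat", "lon",
                 "status", "deploy_start", "deploy_end")]

  n_sharks <- sum(config$group_sizes)
  if (n_sharks == 0L) {
    truth <- data.frame(transmitter_id = character(), group = character(),
                        home_reef = character(), a_nonmating = numeric(),
                        b_nonmating = numeric(), a_mating = numeric(),
                        b_mating = numeric(), tag_receiver_id = character(),
                        silent = logical(), lost_tag_receiver = logical(),
                        stringsAsFactors = FALSE)
    tagging <- data.frame(transmitter_id = character(), sex = character(),
                          maturity = character(), length_cm = numeric(),
                          tag_date = as.Date(character()),
                          tag_receiver_id = character(), stringsAsFactors = FALSE)
    return(structure(list(geometry = geometry, receivers = rec,
                          tagging = tagging, truth = truth,
                          config = config), class = "reef_system"))
  }

  group <- rep(group_levels(), config$group_sizes)
  tid <- sprintf("T%03d", seq_len(n_sharks))
  home_idx <- ((seq_len(n_sharks) - 1L) %% nr) + 1L
  home_reef <- reef_id[home_idx]
  L <- config$reef_lengths[home_idx]

  # individual spans: Gamma around the group mean (shape 4 => CV 0.5),
  # floored at the array detectability width so a resident tagged shark is
  # detectable by construction, capped at 60% of its reef
  mu <- config$group_range_spans[group]
  span <- stats::rgamma(n_sharks, shape = 4, rate = 4 / pmax(mu, 1e-6))
  floor_span <- max(0.02, config$receiver_spacing - 2 * config$detection_radius + 0.01)
  span <- pmin(pmax(span, floor_span), 0.6 * L)
  a <- stats::runif(n_sharks, 0, L - span)
  b <- a + span

  # adult-male mating expansion, clipped to the reef with overflow to the
  # other side; mating interval is a superset of the non-mating interval
  e <- ifelse(group == "adult_male", config$male_mating_expansion, 0)
  b_m <- pmin(L, b + e)
  a_m <- pmax(0, a - (e - (b_m - b)))

  # tagging receiver inside the true (non-mating) range; if the drawn
  # interval contains no receiver, extend it minimally to the nearest one
  tag_receiver_id <- character(n_sharks)
  for (j in seq_len(n_sharks)) {
    rj <- rec[rec$reef_id == home_reef[j], ]
    inside <- rj$receiver_id[rj$position_km >= a[j] & rj$position_km <= b[j]]
    if (length(inside)) {
      tag_receiver_id[j] <- if (length(inside) == 1L) inside else sample(inside, 1L)
    } else {
      k <- which.min(abs(rj$position_km - (a[j] + b[j]) / 2))
      tag_receiver_id[j] <- rj$receiver_id[k]
      a[j] <- min(a[j], rj$position_km[k]); b[j] <- max(b[j], rj$position_km[k])
      a_m[j] <- min(a_m[j], a[j]); b_m[j] <- max(b_m[j], b[j])
    }
  }

  silent <- rep(FALSE, n_sharks)
  if (!is.null(config$n_silent)) {
    ns <- config$n_silent
    if (length(ns) == 1L && is.null(names(ns))) {
      silent[sample(n_sharks, ns)] <- TRUE
    } else {
      for (g in names(ns)) {
        idx <- which(group == g)
        silent[sample(idx, min(ns[[g]], length(idx)))] <- TRUE
      }
    }
  } else if (config$p_silent > 0) {
    silent <- stats::runif(n_sharks) < config$p_silent
  }

  # lost receivers: engineered mode picks silent sharks and makes their
  # tagging receiver exclusively theirs (reassigning any co-tagged shark to
  # another receiver inside its own range), so losing it excludes exactly
  # the designated sharks
  lost_receivers <- character(0)
  lost_tag <- rep(FALSE, n_sharks)
  if (config$n_lost_receiver_sharks > 0L) {
    need <- config$n_lost_receiver_sharks
    for (j in which(silent)) {
      if (need == 0L) break
      R <- tag_receiver_id[j]
      if (R %in% lost_receivers) next
      others <- setdiff(which(tag_receiver_id == R), j)
      ok <- TRUE
      moves <- integer(0); targets <- character(0)
      for (o in others) {
        ro <- rec[rec$reef_id == home_reef[o] &
                    rec$position_km >= a[o] & rec$position_km <= b[o] &
                    rec$receiver_id != R &
                    !(rec$receiver_id %in% lost_receivers), , drop = FALSE]
        if (!nrow(ro)) { ok <- FALSE; break }
        k2 <- which.min(abs(ro$position_km - (a[o] + b[o]) / 2))
        moves <- c(moves, o); targets <- c(targets, ro$receiver_id[k2])
      }
      if (!ok) next
      tag_receiver_id[moves] <- targets
      lost_tag[j] <- TRUE
      lost_receivers <- c(lost_receivers, R)
      need <- need - 1L
    }
    if (need > 0L)
      stop_rr("cannot engineer ", config$n_lost_receiver_sharks,
              " exclusively-owned lost tagging receivers")
  }
  if (config$n_lost_receivers > length(lost_receivers)) {
    extra_n <- config$n_lost_receivers - length(lost_receivers)
    pool <- setdiff(rec$receiver_id, c(lost_receivers, tag_receiver_id[!silent]))
    lost_receivers <- c(lost_receivers, sample(pool, min(extra_n, length(pool))))
  }
  rec$status[rec$receiver_id %in% lost_receivers] <- "lost"

  sex <- ifelse(grepl("male$", group) & !grepl("female$", group), "male", "female")
  maturity <- ifelse(grepl("^adult", group), "adult", "juvenile")
  length_cm <- round(stats::rnorm(n_sharks,
                                  mean = ifelse(maturity == "adult", 155, 100),
                                  sd = 8), 1)
  tag_date <- config$study_start +
    sample.int(config$tag_window_days, n_sharks, replace = TRUE) - 1L

  tagging <- data.frame(transmitter_id = tid, sex = sex, maturity = maturity,
                        length_cm = length_cm, tag_date = tag_date,
                        tag_receiver_id = tag_receiver_id, stringsAsFactors = FALSE)
  truth <- data.frame(transmitter_id = tid, group = group, home_reef = home_reef,
                      a_nonmating = a, b_nonmating = b,
                      a_mating = a_m, b_mating = b_m,
                      tag_receiver_id = tag_receiver_id,
                      silent = silent, lost_tag_receiver = lost_tag,
                      stringsAsFactors = FALSE)
  structure(list(geometry = geometry, receivers = rec, tagging = tagging,
                 truth = truth, config = config), class = "reef_system")
}

#' Simulate acoustic detections for a generated system
#'
#' Each shark-day draws an independent uniform position from the shark's
#' seasonal true range (mating interval in July-September local time for
#' adult males).  Every active receiver within `detection_radius` of that
#' position logs a Poisson-distributed burst of pings whose inter-ping
#' delays are uniform on 30-90 s, matching the transmitter duty cycle.
#' Silent sharks transmit only during the 14-day post-capture window; lost
#' receivers log nothing.  Isolated false detections are injected at
#' far-away receivers at a small per-day rate.  Output is sorted by time.
#'
#' @param system a [generate_system()] result.
#' @param config the same [sim_config()]; the simulation seeds its own RNG
#'   stream from `config$seed` so it is reproducible in isolation.
#' @return data frame with columns `timestamp` (POSIXct UTC), `receiver_id`,
#'   `transmitter_id`.
#' @export
simulate_detections <- function(system, config = system$config) {
  stopifnot(inherits(system, "reef_system"))
  set.seed(config$seed + 1L)
  rec <- system$receivers
  truth <- system$truth
  tagging <- system$tagging
  out <- vector("list", nrow(truth))
  if (nrow(truth)) {
    all_days <- seq(config$study_start, config$study_end, by = "day")
    day_epoch_all <- as.numeric(as.POSIXct(paste(all_days, "00:00:00"),
                                           tz = config$tz))
    day_month_all <- as.integer(format(all_days, "%m"))
  }
  for (j in seq_len(nrow(truth))) {
    tr <- truth[j, ]
    tag_date <- tagging$tag_date[j]
    last_day <- if (tr$silent) min(tag_date + 13L, config$study_end) else config$study_end
    keep <- all_days >= tag_date & all_days <= last_day
    if (!any(keep)) next
    days_i <- which(keep)
    n_days <- length(days_i)
    mating <- day_month_all[days_i] %in% MATING_MONTHS
    a_use <- ifelse(mating, tr$a_mating, tr$a_nonmating)
    b_use <- ifelse(mating, tr$b_mating, tr$b_nonmating)
    pos <- stats::runif(n_days, a_use, b_use)

    rj <- rec[rec$reef_id == tr$home_reef & rec$status != "lost", ]
    inr <- abs(outer(pos, rj$position_km, "-")) <= config$detection_radius
    K <- stats::rpois(n_days, config$daily_pings_mean)
    use <- which(rowSums(inr) > 0 & K > 0)
    parts <- list()
    if (length(use)) {
      Ku <- K[use]
      total <- sum(Ku)
      gaps <- stats::runif(total, 30, 90)
      grp <- rep(seq_along(use), Ku)
      cumgap <- stats::ave(gaps, grp, FUN = cumsum)
      start <- stats::runif(length(use), 0, pmax(0, 86400 - 90 * Ku))
      t_sec <- start[grp] + cumgap
      epoch_ping <- day_epoch_all[days_i[use]][grp] + t_sec
      rec_sets <- apply(inr[use, , drop = FALSE], 1L,
                        function(z) rj$receiver_id[z], simplify = FALSE)
      per_ping <- rec_sets[grp]
      reps <- lengths(per_ping)
      parts[[1L]] <- data.frame(
        epoch = rep(epoch_ping, reps),
        receiver_id = unlist(per_ping, use.names = FALSE),
        transmitter_id = tr$transmitter_id, stringsAsFactors = FALSE)
    }
    # isolated false detections at far receivers (non-silent sharks)
    if (!tr$silent && config$false_ping_per_day > 0) {
      far <- rec$receiver_id[rec$status != "lost" &
        (rec$reef_id != tr$home_reef |
           rec$position_km < tr$a_nonmating - 2 |
           rec$position_km > tr$b_mating + 2)]
      hit <- which(stats::runif(n_days) < config$false_ping_per_day)
      if (length(hit) && length(far)) {
        parts[[2L]] <- data.frame(
          epoch = day_epoch_all[days_i[hit]] + stats::runif(length(hit), 0, 86400),
          receiver_id = sample(far, length(hit), replace = TRUE),
          transmitter_id = tr$transmitter_id, stringsAsFactors = FALSE)
      }
    }
    if (length(parts)) out[[j]] <- do.call(rbind, parts)
  }
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out) || !nrow(out)) {
    return(data.frame(timestamp = as.POSIXct(character(), tz = "UTC"),
                      receiver_id = character(), transmitter_id = character(),
                      stringsAsFactors = FALSE))
  }
  out$epoch <- round(out$epoch)
  o <- rr_order(out$epoch, out$receiver_id, out$transmitter_id)
  out <- out[o, , drop = FALSE]
  data.frame(timestamp = as.POSIXct(out$epoch, origin = "1970-01-01", tz = "UTC"),
             receiver_id = out$receiver_id,
             transmitter_id = out$transmitter_id,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write the synthetic system to CSV files
#'
#' Writes `detections.csv` (datetime ISO-8601 UTC, receiver_id,
#' transmitter_id), `receivers.csv` and `tagging.csv` in the dialects the
#' readers expect.
#'
#' @param system a [generate_system()] result.
#' @param detections a [simulate_detections()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_system_csv <- function(system, detections, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pd <- file.path(dir, "detections.csv")
  pr <- file.path(dir, "receivers.csv")
  pt <- file.path(dir, "tagging.csv")
  det <- data.frame(datetime = format(detections$timestamp,
                                      "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
                    receiver_id = detections$receiver_id,
                    transmitter_id = detections$transmitter_id)
  utils::write.csv(det, pd, row.names = FALSE, quote = FALSE)
  rec <- system$receivers
  rec$deploy_start <- format(rec$deploy_start)
  rec$deploy_end <- format(rec$deploy_end)
  utils::write.csv(rec, pr, row.names = FALSE, quote = FALSE)
  tg <- system$tagging
  tg$tag_date <- format(tg$tag_date)
  utils::write.csv(tg, pt, row.names = FALSE, quote = FALSE)
  invisible(c(detections = pd, receivers = pr, tagging = pt))
}

square_ring <- function(lon0, lat0, dlon, dlat) {
  cbind(lon = c(lon0, lon0 + dlon, lon0 + dlon, lon0, lon0),
        lat = c(lat0, lat0, lat0 + dlat, lat0 + dlat, lat0))
}

#' Write WDPA-style MPA and reef polygon fixtures
#'
#' Deterministically writes two GeoJSON files: a reef-polygon layer with
#' analytically known geodesic areas (latitude/longitude-aligned squares)
#' and a ten-record MPA layer engineered to exercise every screening rule:
#' IUCN categories I/Ia/II kept and VI dropped, a record outside the
#' longitude box, a record with no designation year, a polygon straddling
#' the antimeridian, a self-intersecting (bowtie) polygon needing repair,
#' records without reef overlap, and exactly three records whose reef area
#' exceeds 95 km2.
#'
#' @param dir output directory.
#' @return invisibly, a list with the file paths and the engineered truth
#'   (`kept_ids`, `above_95_ids`, analytic reef corner boxes).
#' @export
generate_mpa_fixtures <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  reefs <- list(
    list(name = "reef_eq",  ring = square_ring(160, -0.05, 0.1, 0.1)),
    list(name = "reef_am",  ring = square_ring(-170.1, -10.1, 0.2, 0.2)),
    list(name = "reef_mid", ring = square_ring(140, -20, 0.2, 0.2)),
    list(name = "reef_big", ring = square_ring(150, -15, 1, 1))
  )
  reef_feats <- lapply(reefs, function(r) {
    geojson_polygon_feature(list(list(r$ring)), list(NAME = r$name))
  })
  reef_path <- file.path(dir, "reefs.geojson")
  write_geojson_features(reef_feats, reef_path)

  # self-intersecting ring fully inside reef_mid; its even-odd area (two
  # triangles) stays well below the 95 km2 classification threshold
  bowtie <- cbind(lon = c(140.02, 140.10, 140.10, 140.02, 140.02),
                  lat = c(-19.98, -19.90, -19.98, -19.90, -19.98))
  mpas <- list(
    list(id = 1, name = "Equator Atoll Reserve", cat = "II",  yr = 2010,
         ring = square_ring(159.9, -0.1, 0.3, 0.2)),
    list(id = 2, name = "Mid Multi-Use Park",    cat = "VI",  yr = 2005,
         ring = square_ring(139.9, -20.1, 0.4, 0.4)),
    list(id = 3, name = "West Box Outlier",      cat = "Ia",  yr = 1990,
         ring = square_ring(19.9, -5, 0.2, 0.2)),
    list(id = 4, name = "Undated Reserve",       cat = "II",  yr = 0,
         ring = square_ring(139.9, -20.1, 0.4, 0.4)),
    list(id = 5, name = "Antimeridian Sanctuary", cat = "I",  yr = 2015,
         ring = cbind(lon = c(179.8, -169.8, -169.8, 179.8, 179.8),
                      lat = c(-10.2, -10.2, -9.8, -9.8, -10.2))),
    list(id = 6, name = "Reefless Reserve",      cat = "II",  yr = 2012,
         ring = square_ring(130, 5, 0.2, 0.2)),
    list(id = 7, name = "Bowtie Reserve",        cat = "II",  yr = 2000,
         ring = bowtie),
    list(id = 8, name = "Big South Reserve",     cat = "II",  yr = 2018,
         ring = square_ring(150, -15, 0.5, 1)),
    list(id = 9, name = "Small Big Inlier",      cat = "II",  yr = 2016,
         ring = square_ring(150.6, -14.5, 0.03, 0.03)),
    list(id = 10, name = "Tiny Mid Strict",      cat = "Ia",  yr = 2008,
         ring = square_ring(140, -19.85, 0.05, 0.05))
  )
  mpa_feats <- lapply(mpas, function(m) {
    geojson_polygon_feature(list(list(m$ring)),
                            list(WDPAID = m$id, NAME = m$name,
                                 IUCN_CAT = m$cat, STATUS_YR = m$yr))
  })
  mpa_path <- file.path(dir, "mpas.geojson")
  write_geojson_features(mpa_feats, mpa_path)
  invisible(list(mpa_path = mpa_path, reef_path = reef_path,
                 kept_ids = c(1, 5, 7, 8, 9, 10),
                 above_95_ids = c(1, 5, 8)))
}
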