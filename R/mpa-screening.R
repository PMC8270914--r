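#' Read WDPA-style MPA polygons from GeoJSON
#'
#' Reads an RFC 7946 FeatureCollection of Polygon/MultiPolygon features
#' carrying WDPA-style attributes (`WDPAID`/`WDPA_PID`, `NAME`, `IUCN_CAT`,
#' `STATUS_YR`).  Attributes are normalized (missing IUCN category becomes
#' "Not Reported"; a missing or zero status year becomes NA) and geometries
#' are validated and repaired ([repair_ring()]); features without geometry
#' are dropped with a warning.
#'
#' @param path GeoJSON file.
#' @return data frame with columns `mpa_id`, `name`, `iucn_category`,
#'   `status_year`, `centroid_lon`, `centroid_lat`, `reef_area_km2` (NA
#'   until computed) and a list column `geometry` (each element a list of
#'   polygons; each polygon a list of rings, outer first).
#' @export
read_mpa_polygons <- function(path) {
  js <- jsonlite::read_json(path)
  feats <- js$features %||% list()
  rows <- list(); geoms <- list(); dropped <- 0L
  for (f in feats) {
    g <- f$geometry
    if (is.null(g) || is.null(g$type)) { dropped <- dropped + 1L; next }
    coords <- switch(g$type,
                     Polygon = list(g$coordinates),
                     MultiPolygon = g$coordinates,
                     { dropped <- dropped + 1L; next })
    polys <- list()
    for (poly in coords) {
      rings <- lapply(poly, function(r) do.call(rbind, lapply(r, as.numeric)))
      outer_loops <- repair_ring(rings[[1]])
      if (!length(outer_loops)) next
      holes <- if (length(rings) > 1 && length(outer_loops) == 1L)
        lapply(rings[-1], function(h) repair_ring(h)[[1]]) else list()
      polys <- c(polys, list(c(outer_loops[1], holes)),
                 lapply(outer_loops[-1], list))
    }
    if (!length(polys)) { dropped <- dropped + 1L; next }
    p <- f$properties %||% list()
    iucn <- p$IUCN_CAT %||% p$iucn_category %||% ""
    if (is.null(iucn) || !nzchar(iucn)) iucn <- "Not Reported"
    yr <- p$STATUS_YR %||% p$status_year
    yr <- if (is.null(yr) || !length(yr) || is.na(suppressWarnings(as.numeric(yr))) ||
              as.numeric(yr) == 0) NA_integer_ else as.integer(yr)
    # centroid of the largest outer ring
    areas <- vapply(polys, function(pp) abs(shoelace_signed(pp[[1]])), numeric(1))
    ctr <- ring_centroid(polys[[which.max(areas)]][[1]])
    rows[[length(rows) + 1L]] <- data.frame(
      mpa_id = as.character(p$WDPAID %||% p$WDPA_PID %||% (length(rows) + 1L)),
      name = as.character(p$NAME %||% p$name %||% ""),
      iucn_category = iucn, status_year = yr,
      centroid_lon = ctr[1], centroid_lat = ctr[2],
      reef_area_km2 = NA_real_, stringsAsFactors = FALSE)
    geoms[[length(geoms) + 1L]] <- polys
  }
  if (dropped) warning(dropped, " feature(s) without usable geometry dropped")
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mpa_id = character(), name = character(),
               iucn_category = character(), status_year = integer(),
               centroid_lon = numeric(), centroid_lat = numeric(),
               reef_area_km2 = numeric(), stringsAsFactors = FALSE)
  out$geometry <- I(geoms)
  row.names(out) <- NULL
  out
}

#' Read reef habitat polygons from GeoJSON
#'
#' Reef polygons stand in for the plain-reef habitat layer used to measure
#' how much reef an MPA protects.  Each polygon must be convex (the
#' clipping algorithm requires it; the shipped fixtures are
#' latitude/longitude-aligned rectangles).
#'
#' @param path GeoJSON file.
#' @return list of closed (lon, lat) ring matrices.
#' @export
read_reef_polygons <- function(path) {
  js <- jsonlite::read_json(path)
  rings <- list()
  for (f in js$features %||% list()) {
    g <- f$geometry
    if (is.null(g)) next
    coords <- switch(g$type, Polygon = list(g$coordinates),
                     MultiPolygon = g$coordinates, list())
    for (poly in coords)
      rings[[length(rings) + 1L]] <-
        close_ring(do.call(rbind, lapply(poly[[1]], as.numeric)))
  }
  rings
}

spans_antimeridian <- function(ring) diff(range(ring[, 1])) > 180

#' Reef area covered by one MPA geometry
#'
#' Geodesic (WGS84 ellipsoid) area of the intersection between the MPA
#' polygons and the reef polygons, in km2.  Geometries straddling the
#' antimeridian are handled by normalizing longitudes to [0, 360) before
#' clipping.
#'
#' @param geometry one element of the `geometry` list column of
#'   [read_mpa_polygons()] (a list of polygons).
#' @param reef_rings a [read_reef_polygons()] result.
#' @return km2 (>= 0).
#' @export
reef_area_covered <- function(geometry, reef_rings) {
  total <- 0
  for (poly in geometry) {
    for (reef in reef_rings) {
      shift <- spans_antimeridian(poly[[1]]) || spans_antimeridian(reef)
      adj <- function(r) { if (shift) r[, 1] <- normalize_lon(r[, 1]); r }
      part <- clip_ring_convex(adj(poly[[1]]), adj(reef))
      if (is.null(part)) next
      a <- geodesic_ring_area_km2(part)
      if (length(poly) > 1) {
        for (h in poly[-1]) {
          hp <- clip_ring_convex(adj(h), adj(reef))
          if (!is.null(hp)) a <- a - geodesic_ring_area_km2(hp)
        }
      }
      total <- total + max(a, 0)
    }
  }
  total
}

#' Screen MPA records by the selection criteria
#'
#' Keeps records that (i) have IUCN category I, Ia, Ib or II (no extractive
#' activities), (ii) have a designation year, (iii) have their centroid
#' inside the latitude/longitude study box — by default 26S-26N and
#' 25E westward to 150W, the species' geographical range, with the
#' longitude test on the [0, 360) normalized scale so the box may straddle
#' the antimeridian — and (iv) intersect reef habitat.  `reef_area_km2` is
#' filled in for every record before filtering, so the operation is
#' idempotent and order-independent.
#'
#' @param records a [read_mpa_polygons()] table.
#' @param reef_rings a [read_reef_polygons()] result.
#' @param box `c(lat_min, lat_max, lon_start, lon_end)`, the longitude
#'   interval running eastward from `lon_start` to `lon_end`.
#' @return the retained records with `reef_area_km2` computed.
#' @export
filter_mpas <- function(records, reef_rings, box = c(-26, 26, 25, -150)) {
  if (!nrow(records)) return(records)
  need <- is.na(records$reef_area_km2)
  records$reef_area_km2[need] <- vapply(
    records$geometry[need], reef_area_covered, numeric(1),
    reef_rings = reef_rings)
  lon <- normalize_lon(records$centroid_lon)
  l1 <- normalize_lon(box[3]); l2 <- normalize_lon(box[4])
  in_lon <- if (l1 <= l2) lon >= l1 & lon <= l2 else lon >= l1 | lon <= l2
  keep <- records$iucn_category %in% c("I", "Ia", "Ib", "II") &
    !is.na(records$status_year) &
    records$centroid_lat >= box[1] & records$centroid_lat <= box[2] &
    in_lon & records$reef_area_km2 > 0
  out <- records[keep, , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Classify MPAs against a minimum reef-area threshold
#'
#' Partitions records at reef area strictly greater than `threshold_km2`
#' (default 95 km2, the size at which the coverage model protects the full
#' home range of 80% of adult males) and summarizes counts by designation
#' year.
#'
#' @param records MPA records with `reef_area_km2` computed.
#' @param threshold_km2 threshold, km2.
#' @return list with `above` (the records exceeding the threshold),
#'   `n_above`, `n_total` and `year_summary` (designation year, counts and
#'   how many exceed the threshold).
#' @export
classify_by_reef_area <- function(records, threshold_km2 = 95) {
  if (anyNA(records$reef_area_km2))
    stop_rr("reef_area_km2 must be computed first (see filter_mpas)")
  above <- records$reef_area_km2 > threshold_km2
  ys <- data.frame(status_year = sort(unique(records$status_year)))
  ys$n <- vapply(ys$status_year, function(y)
    sum(records$status_year == y, na.rm = TRUE), integer(1))
  ys$n_above <- vapply(ys$status_year, function(y)
    sum(above & records$status_year == y, na.rm = TRUE), integer(1))
  list(above = records[above, , drop = FALSE],
       n_above = sum(above), n_total = nrow(records),
       year_summary = ys)
}

#' Write MPA records back to GeoJSON
#'
#' @param records MPA records (e.g. the screened subset).
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_mpa_geojson <- function(records, path) {
  feats <- lapply(seq_len(nrow(records)), function(i) {
    geojson_polygon_feature(records$geometry[[i]], list(
      WDPAID = records$mpa_id[i], NAME = records$name[i],
      IUCN_CAT = records$iucn_category[i],
      STATUS_YR = if (is.na(records$status_year[i])) 0L else records$status_year[i],
      REEF_AREA_KM2 = round(records$reef_area_km2[i], 6)))
  })
  write_geojson_features(feats, path)
}
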