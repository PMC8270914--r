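# Minimal planar/ellipsoidal geometry toolkit for WDPA-style polygon
# screening.  No geospatial stack is assumed: areas use a closed-form
# meridian-band integral on the WGS84 ellipsoid, intersections use
# Sutherland-Hodgman clipping against convex reef polygons, and invalid
# rings get a light-weight repair (dedup, spike removal, bowtie splitting).

WGS84_A <- 6378137          # semi-major axis, m
WGS84_F <- 1 / 298.257223563

#' Normalize longitudes to the [0, 360) interval
#'
#' Used for centroid/box tests and clipping of geometries that straddle the
#' antimeridian.
#' @param lon numeric degrees.
#' @return degrees in [0, 360).
#' @export
normalize_lon <- function(lon) ((lon %% 360) + 360) %% 360

# Cumulative meridian area factor: F(phi) such that the ellipsoid area of a
# band [phi1, phi2] spanning dlambda radians of longitude is
# dlambda * (F(phi2) - F(phi1)).  Closed form of integral b^2 cos(phi) /
# (1 - e^2 sin^2 phi)^2 dphi.
meridian_area_factor <- function(phi_rad) {
  f <- WGS84_F; e2 <- f * (2 - f); e <- sqrt(e2)
  b <- WGS84_A * (1 - f)
  s <- sin(phi_rad)
  (b^2 / 2) * (s / (1 - e2 * s^2) + (1 / (2 * e)) * log((1 + e * s) / (1 - e * s)))
}

close_ring <- function(ring) {
  if (!all(ring[1, ] == ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
  ring
}

open_ring <- function(ring) {
  if (nrow(ring) > 1 && all(ring[1, ] == ring[nrow(ring), ]))
    ring <- ring[-nrow(ring), , drop = FALSE]
  ring
}

densify_ring <- function(ring, max_step = 0.05) {
  ring <- close_ring(ring)
  out <- list()
  for (i in seq_len(nrow(ring) - 1)) {
    p <- ring[i, ]; q <- ring[i + 1, ]
    dlon <- q[1] - p[1]
    if (abs(dlon) > 180) dlon <- dlon - sign(dlon) * 360  # antimeridian hop
    n <- max(1L, ceiling(max(abs(dlon), abs(q[2] - p[2])) / max_step))
    t <- seq(0, 1, length.out = n + 1L)[-(n + 1L)]
    out[[i]] <- cbind(p[1] + t * dlon, p[2] + t * (q[2] - p[2]))
  }
  close_ring(do.call(rbind, out))
}

#' Geodesic area of a polygon ring on the WGS84 ellipsoid
#'
#' Edges are treated as straight lines in longitude/latitude space
#' (densified internally); longitude steps are wrapped so rings straddling
#' the antimeridian are handled.  Returns the unsigned area.
#'
#' @param ring two-column matrix (lon, lat) in degrees, closed or open.
#' @return area in km2.
#' @export
geodesic_ring_area_km2 <- function(ring) {
  ring <- densify_ring(ring)
  lam <- ring[, 1] * pi / 180
  phi <- ring[, 2] * pi / 180
  dl <- diff(lam)
  dl <- ifelse(dl > pi, dl - 2 * pi, ifelse(dl < -pi, dl + 2 * pi, dl))
  Fp <- meridian_area_factor(phi)
  s <- sum(dl * (Fp[-length(Fp)] + Fp[-1]) / 2)
  abs(s) / 1e6
}

# polygon = list of rings, first outer, rest holes
geodesic_polygon_area_km2 <- function(polygon) {
  a <- geodesic_ring_area_km2(polygon[[1]])
  if (length(polygon) > 1)
    a <- a - sum(vapply(polygon[-1], geodesic_ring_area_km2, numeric(1)))
  max(a, 0)
}

# planar signed area (degree^2) for orientation / convexity / centroids
shoelace_signed <- function(ring) {
  ring <- close_ring(ring)
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  sum(x[-n] * y[-1] - x[-1] * y[-n]) / 2
}

# planar centroid with antimeridian-aware longitude shifting; returns
# c(lon, lat) with lon in (-180, 180]
ring_centroid <- function(ring) {
  ring <- close_ring(ring)
  lon <- ring[, 1]
  if (diff(range(lon)) > 180) lon <- normalize_lon(lon)
  x <- lon; y <- ring[, 2]; n <- length(x)
  cr <- x[-n] * y[-1] - x[-1] * y[-n]
  a <- sum(cr) / 2
  if (abs(a) < 1e-14) {
    cx <- mean(x[-n]); cy <- mean(y[-n])
  } else {
    cx <- sum((x[-n] + x[-1]) * cr) / (6 * a)
    cy <- sum((y[-n] + y[-1]) * cr) / (6 * a)
  }
  if (cx > 180) cx <- cx - 360
  c(cx, cy)
}

ring_is_convex <- function(ring) {
  ring <- open_ring(close_ring(ring))
  n <- nrow(ring)
  if (n < 3) return(FALSE)
  v <- rbind(ring, ring[1:2, , drop = FALSE])
  cr <- numeric(n)
  for (i in seq_len(n)) {
    a <- v[i + 1, ] - v[i, ]; b <- v[i + 2, ] - v[i + 1, ]
    cr[i] <- a[1] * b[2] - a[2] * b[1]
  }
  all(cr >= -1e-12) || all(cr <= 1e-12)
}

# Sutherland-Hodgman: clip an arbitrary simple subject ring against a
# *convex* clip ring.  Both as open/closed (lon, lat) matrices in a common
# longitude frame.  Returns a closed ring matrix or NULL if empty.
clip_ring_convex <- function(subject, clip) {
  if (!ring_is_convex(clip))
    stop_rr("clip polygon must be convex (reef fixtures are rectangles)")
  clip <- open_ring(close_ring(clip))
  if (shoelace_signed(clip) < 0) clip <- clip[rev(seq_len(nrow(clip))), , drop = FALSE]
  out <- open_ring(close_ring(subject))
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (is.null(out) || nrow(out) < 3) return(NULL)
    a <- clip[i, ]; b <- clip[if (i == nc) 1L else i + 1L, ]
    inside <- function(p) (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1]) >= -1e-12
    inter <- function(p, q) {
      # intersection of segment pq with infinite line ab
      d1 <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
      d2 <- (b[1] - a[1]) * (q[2] - a[2]) - (b[2] - a[2]) * (q[1] - a[1])
      t <- d1 / (d1 - d2)
      p + t * (q - p)
    }
    res <- list()
    n <- nrow(out)
    for (k in seq_len(n)) {
      p <- out[k, ]; q <- out[if (k == n) 1L else k + 1L, ]
      pi_ <- inside(p); qi <- inside(q)
      if (pi_ && qi) res[[length(res) + 1L]] <- q
      else if (pi_ && !qi) res[[length(res) + 1L]] <- inter(p, q)
      else if (!pi_ && qi) { res[[length(res) + 1L]] <- inter(p, q); res[[length(res) + 1L]] <- q }
    }
    out <- if (length(res)) do.call(rbind, res) else NULL
  }
  if (is.null(out) || nrow(out) < 3) return(NULL)
  close_ring(out)
}

seg_intersection <- function(p1, p2, p3, p4) {
  # proper interior crossing of segments p1p2 and p3p4, or NULL
  d <- (p2[1] - p1[1]) * (p4[2] - p3[2]) - (p2[2] - p1[2]) * (p4[1] - p3[1])
  if (abs(d) < 1e-15) return(NULL)
  t <- ((p3[1] - p1[1]) * (p4[2] - p3[2]) - (p3[2] - p1[2]) * (p4[1] - p3[1])) / d
  u <- ((p3[1] - p1[1]) * (p2[2] - p1[2]) - (p3[2] - p1[2]) * (p2[1] - p1[1])) / d
  eps <- 1e-9
  if (t <= eps || t >= 1 - eps || u <= eps || u >= 1 - eps) return(NULL)
  p1 + t * (p2 - p1)
}

#' Repair an invalid polygon ring
#'
#' Light-weight stand-in for a GEOS zero-width buffer: drops duplicate
#' consecutive vertices and zero-area spikes, and splits self-intersecting
#' (bowtie) rings at their crossing points into simple loops.  The summed
#' area of the returned loops equals the even-odd area of the input.
#'
#' @param ring (lon, lat) matrix.
#' @param depth internal recursion guard.
#' @return list of simple closed rings.
#' @export
repair_ring <- function(ring, depth = 0L) {
  ring <- open_ring(close_ring(ring))
  # drop consecutive duplicates
  keep <- c(TRUE, rowSums(abs(diff(ring))) > 1e-12)
  ring <- ring[keep, , drop = FALSE]
  # drop spikes (v[i-1] == v[i+1])
  repeat {
    n <- nrow(ring)
    if (n < 3) return(list())
    nxt <- c(2:n, 1L); prv <- c(n, 1:(n - 1))
    spike <- rowSums(abs(ring[prv, , drop = FALSE] - ring[nxt, , drop = FALSE])) < 1e-12
    if (!any(spike)) break
    ring <- ring[-which(spike)[1], , drop = FALSE]
  }
  n <- nrow(ring)
  if (depth < 10L) {
    for (i in seq_len(n - 2)) {
      jmax <- if (i == 1) n - 1 else n
      for (j in (i + 2):jmax) {
        p <- seg_intersection(ring[i, ], ring[i %% n + 1, ],
                              ring[j, ], ring[j %% n + 1, ])
        if (!is.null(p)) {
          loop1 <- rbind(p, ring[(i + 1):j, , drop = FALSE])
          idx2 <- if (j == n) seq_len(i) else c((j + 1):n, seq_len(i))
          loop2 <- rbind(p, ring[idx2, , drop = FALSE])
          return(c(repair_ring(loop1, depth + 1L),
                   repair_ring(loop2, depth + 1L)))
        }
      }
    }
  }
  list(close_ring(ring))
}

# ---- GeoJSON helpers (RFC 7946 subset: Polygon / MultiPolygon features) ----

geojson_polygon_feature <- function(polygons, properties) {
  coords <- lapply(polygons, function(poly) lapply(poly, function(r) unname(close_ring(r))))
  geom <- if (length(polygons) == 1L) {
    list(type = "Polygon", coordinates = coords[[1]])
  } else {
    list(type = "MultiPolygon", coordinates = coords)
  }
  list(type = "Feature", properties = properties, geometry = geom)
}

write_geojson_features <- function(features, path) {
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
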