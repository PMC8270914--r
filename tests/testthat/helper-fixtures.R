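# Shared in-code fixtures and independent oracles.

# one linear reef with A(s) = density * s
make_geometry <- function(length_km = 10, density = 2, reef = "reefA") {
  reef_geometry(
    reefs = data.frame(reef_id = reef, length_km = length_km,
                       start_lat = -21, start_lon = 165,
                       end_lat = -21, end_lon = 165 + length_km / 104,
                       stringsAsFactors = FALSE),
    area = data.frame(reef_id = reef, s = c(0, length_km),
                      area_km2 = c(0, density * length_km),
                      stringsAsFactors = FALSE))
}

make_receivers <- function(positions, reef = "reefA",
                           ids = sprintf("R%d", seq_along(positions))) {
  data.frame(receiver_id = ids, reef_id = reef, position_km = positions,
             lat = -21, lon = 165 + positions / 104, status = "active",
             stringsAsFactors = FALSE)
}

# detections at given local times (study timezone UTC+11)
make_det <- function(times_local, receiver, transmitter) {
  data.frame(
    timestamp = as.POSIXct(times_local, tz = "Etc/GMT-11"),
    receiver_id = receiver, transmitter_id = transmitter,
    stringsAsFactors = FALSE)
}

# independent brute-force coverage oracle: explicit double loop over
# (interval, shark), same interval convention as the documented model
brute_force_pi <- function(ud, S, dS = 1) {
  n <- ceiling(S / dS)
  acc <- 0
  for (i in seq_len(n)) {
    lo <- (i - 1) * dS
    hi <- min(i * dS, S)
    ci <- (lo + hi) / 2
    s <- 0
    for (j in seq_along(ud)) {
      if (ci - ud[j] / 2 >= 0 && ci + ud[j] / 2 <= S) s <- s + 1
    }
    acc <- acc + s / length(ud)
  }
  acc / n
}

# independent ellipsoid-band area oracle: numeric integration of
# b^2 cos(phi) / (1 - e^2 sin^2 phi)^2 over latitude
oracle_square_area_km2 <- function(lon_w, lat_s, dlon, dlat) {
  a <- 6378137; f <- 1 / 298.257223563
  e2 <- f * (2 - f); b <- a * (1 - f)
  band <- stats::integrate(function(phi) b^2 * cos(phi) / (1 - e2 * sin(phi)^2)^2,
                           lat_s * pi / 180, (lat_s + dlat) * pi / 180,
                           rel.tol = 1e-12)$value
  band * dlon * pi / 180 / 1e6
}

# independent pooled-t oracle for exhaustive split enumeration
oracle_pooled_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp <- sqrt(((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2))
  (mean(x) - mean(y)) / (sp * sqrt(1 / nx + 1 / ny))
}

# all permutations of 1..n (for exhaustive permutation-ANOVA oracles)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

random_ud_sample <- function(n) {
  # mixture emulating a UD distribution: excess zeros + right-skewed areas
  z <- runif(n) < 0.3
  v <- ifelse(z, 0, rgamma(n, shape = 1.2, scale = 12))
  round(v, 3)
}
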