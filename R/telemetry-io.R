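#' Read a detection table
#'
#' Reads a CSV of raw detection events (`datetime` ISO-8601 UTC,
#' `receiver_id`, `transmitter_id`), drops malformed rows with a warning
#' giving their count, and returns records sorted by timestamp.
#'
#' @param path CSV file path.
#' @return data frame with columns `timestamp` (POSIXct UTC),
#'   `receiver_id`, `transmitter_id`, sorted ascending by time.
#' @export
read_detections <- function(path) {
  d <- utils::read.csv(path, colClasses = "character")
  need <- c("datetime", "receiver_id", "transmitter_id")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop_rr("detections file misses column(s): ",
                            paste(miss, collapse = ", "))
  ts <- as.POSIXct(d$datetime, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  alt <- is.na(ts) & !is.na(d$datetime)
  ts[alt] <- as.POSIXct(d$datetime[alt], format = "%Y-%m-%d %H:%M:%S", tz = "UTC")
  bad <- is.na(ts) | d$receiver_id == "" | d$transmitter_id == ""
  if (any(bad)) warning(sum(bad), " malformed detection row(s) dropped")
  out <- data.frame(timestamp = ts[!bad], receiver_id = d$receiver_id[!bad],
                    transmitter_id = d$transmitter_id[!bad],
                    stringsAsFactors = FALSE)
  out <- out[rr_order(as.numeric(out$timestamp), out$receiver_id,
                      out$transmitter_id), , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Read a receiver deployment table
#'
#' @param path CSV with columns receiver_id, reef_id, position_km, lat, lon,
#'   status, deploy_start, deploy_end.
#' @return data frame; `status` is one of "active"/"lost".
#' @export
read_receivers <- function(path) {
  r <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("receiver_id", "reef_id", "position_km", "status")
  miss <- setdiff(need, names(r))
  if (length(miss)) stop_rr("receivers file misses column(s): ",
                            paste(miss, collapse = ", "))
  if (anyDuplicated(r$receiver_id)) stop_rr("duplicate receiver_id")
  for (col in c("deploy_start", "deploy_end"))
    if (col %in% names(r)) r[[col]] <- as.Date(r[[col]])
  r
}

#' Read a shark tagging metadata table
#'
#' @param path CSV with columns transmitter_id, sex, maturity, length_cm,
#'   tag_date, tag_receiver_id.
#' @param receivers optional receiver table to validate `tag_receiver_id`
#'   against.
#' @return data frame with `tag_date` as Date.
#' @export
read_tagging <- function(path, receivers = NULL) {
  t <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("transmitter_id", "sex", "maturity", "tag_date", "tag_receiver_id")
  miss <- setdiff(need, names(t))
  if (length(miss)) stop_rr("tagging file misses column(s): ",
                            paste(miss, collapse = ", "))
  if (!all(t$sex %in% c("male", "female")))
    stop_rr("sex must be 'male' or 'female'")
  if (!all(t$maturity %in% c("adult", "juvenile")))
    stop_rr("maturity must be 'adult' or 'juvenile'")
  t$tag_date <- as.Date(t$tag_date)
  if (!is.null(receivers)) {
    unknown <- setdiff(t$tag_receiver_id, receivers$receiver_id)
    if (length(unknown)) stop_rr("tagging receivers not in receiver table: ",
                                 paste(unknown, collapse = ", "))
  }
  t
}

#' Remove potential false detections
#'
#' A detection is considered false, and removed, iff no other detection of
#' the same transmitter at the same receiver occurs within `window_s`
#' seconds of it.  Single isolated pings are the classic signature of code
#' collisions on 69 kHz arrays; the default window of 3600 s is about 60
#' times the 60 s mean transmission delay.  The rule is idempotent.
#'
#' @param detections detection table sorted by timestamp.
#' @param window_s support window in seconds (> 0).
#' @return list with `detections` (the retained, still-sorted table) and
#'   `n_removed`.
#' @export
filter_false_detections <- function(detections, window_s = 3600) {
  if (window_s <= 0) stop_rr("window_s must be > 0")
  if (!nrow(detections))
    return(list(detections = detections, n_removed = 0L))
  o <- rr_order(detections$transmitter_id, detections$receiver_id,
                as.numeric(detections$timestamp))
  d <- detections[o, , drop = FALSE]
  key <- paste(d$transmitter_id, d$receiver_id, sep = "\r")
  tt <- as.numeric(d$timestamp)
  n <- nrow(d)
  same_prev <- c(FALSE, key[-1] == key[-n])
  gap_prev <- c(Inf, tt[-1] - tt[-n]); gap_prev[!same_prev] <- Inf
  gap_next <- c(gap_prev[-1], Inf)
  same_next <- c(same_prev[-1], FALSE); gap_next[!same_next] <- Inf
  keep <- gap_prev <= window_s | gap_next <= window_s
  out <- d[keep, , drop = FALSE]
  out <- out[rr_order(as.numeric(out$timestamp), out$receiver_id,
                      out$transmitter_id), , drop = FALSE]
  row.names(out) <- NULL
  list(detections = out, n_removed = as.integer(n - nrow(out)))
}

#' Drop detections inside the post-capture window
#'
#' Removes detections of each shark whose timestamp falls in the closed-open
#' interval [capture instant, capture instant + `days` x 86400 s), where the
#' capture instant is local midnight of the tagging date.  Animals often
#' behave atypically immediately after capture and tagging, so this window
#' is excluded before any home-range computation.
#'
#' @param detections detection table.
#' @param tagging tagging table covering every transmitter present.
#' @param days window length in days (default 14).
#' @param tz study-local timezone fixing the capture instant.
#' @return the filtered detection table.
#' @export
apply_post_capture_window <- function(detections, tagging, days = 14,
                                      tz = REEFRANGE_TZ) {
  unknown <- setdiff(unique(detections$transmitter_id), tagging$transmitter_id)
  if (length(unknown))
    stop_rr("detections reference unknown transmitter(s): ",
            paste(unknown, collapse = ", "))
  if (!nrow(detections) || days == 0) return(detections)
  tag_instant <- as.numeric(as.POSIXct(paste(tagging$tag_date, "00:00:00"),
                                       tz = tz))
  cutoff <- tag_instant[match(detections$transmitter_id,
                              tagging$transmitter_id)] + days * 86400
  out <- detections[as.numeric(detections$timestamp) >= cutoff, , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Apply the cohort exclusion rules
#'
#' Excludes (1) sharks tagged at a receiver flagged lost — their home range
#' cannot be anchored — and then (2) sharks with zero remaining detections
#' after filtering and the post-capture window.  The lost-receiver rule has
#' precedence, so a shark matching both is counted once, under
#' lost-receiver, and the exclusion sets are disjoint.
#'
#' @param detections filtered, windowed detection table.
#' @param tagging tagging table (defines `n_tagged`).
#' @param receivers receiver table with a `status` column.
#' @return an object of class `cohort_report`: counts, retained ids and
#'   per-group retained counts.
#' @export
build_cohort <- function(detections, tagging, receivers) {
  lost <- receivers$receiver_id[receivers$status == "lost"]
  excl_lost <- tagging$transmitter_id[tagging$tag_receiver_id %in% lost]
  remaining <- setdiff(tagging$transmitter_id, excl_lost)
  with_det <- unique(detections$transmitter_id)
  excl_silent <- setdiff(remaining, with_det)
  retained <- setdiff(remaining, excl_silent)
  grp <- interaction(tagging$maturity, tagging$sex, sep = "_")
  per_group <- table(group = grp[tagging$transmitter_id %in% retained])
  structure(list(
    n_tagged = nrow(tagging),
    n_excluded_lost_receiver = length(excl_lost),
    n_excluded_silent = length(excl_silent),
    n_retained = length(retained),
    retained = sort(retained, method = "radix"),
    excluded_lost_receiver = sort(excl_lost, method = "radix"),
    excluded_silent = sort(excl_silent, method = "radix"),
    per_group_retained = per_group
  ), class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("Cohort report\n")
  cat("  tagged:                ", x$n_tagged, "\n")
  cat("  excluded lost receiver:", x$n_excluded_lost_receiver, "\n")
  cat("  excluded silent:       ", x$n_excluded_silent, "\n")
  cat("  retained:              ", x$n_retained, "\n")
  print(x$per_group_retained)
  invisible(x)
}
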