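#' Log-transform utilization distribution values
#'
#' The transform applied to UD areas before all group statistics:
#' y = log10(1 + x).  Defined for x >= 0 only.
#'
#' @param values non-negative numeric vector (km2).
#' @return transformed values.
#' @export
transform_ud <- function(values) {
  if (anyNA(values) || any(values < 0)) stop_rr("UD values must be >= 0")
  log10(1 + values)
}

#' Two-way permutation ANOVA
#'
#' Univariate ANOVA with sequential (type-I) sums of squares for factor A,
#' factor B and their interaction, whose p-values come from unrestricted
#' permutation of the responses rather than F-theory.  Permutation stops
#' early, per term, by an Anscombe-style sequential rule: once at least
#' `min_iter` permutations are in, a term's p-value is frozen when the
#' estimated standard error of p falls below `Ca * p`; otherwise it runs to
#' `max_iter`.  p-values carry the +1 correction, so they are never 0.
#'
#' Responses should already be on the analysis scale (see
#' [transform_ud()]).
#'
#' @param values numeric responses.
#' @param factor_a,factor_b factors with at least two levels each.
#' @param max_iter permutation budget per term (default 5000).
#' @param seed optional integer seed.
#' @param Ca relative standard-error threshold of the stopping rule.
#' @param min_iter minimum permutations before a term may stop.
#' @param name_a,name_b term labels in the output.
#' @return data frame of class `permanova` with one row per term
#'   (A, B, interaction, residuals) and columns `term`, `df`, `sum_sq`,
#'   `mean_sq`, `iterations`, `p_perm` (NA for the residual row).
#' @export
permanova_two_way <- function(values, factor_a, factor_b, max_iter = 5000,
                              seed = NULL, Ca = 0.1, min_iter = 100,
                              name_a = deparse(substitute(factor_a)),
                              name_b = deparse(substitute(factor_b))) {
  y <- as.numeric(values)
  a <- factor(factor_a); b <- factor(factor_b)
  n <- length(y)
  if (length(a) != n || length(b) != n) stop_rr("length mismatch")
  if (nlevels(a) < 2 || nlevels(b) < 2) stop_rr("each factor needs >= 2 levels")
  if (n < 4) stop_rr("need n >= 4")
  if (!is.null(seed)) set.seed(seed)
  Qs <- lapply(list(~1, ~a, ~a + b, ~a * b), function(f)
    qr.Q(qr(stats::model.matrix(f, data = data.frame(a = a, b = b)))))
  rss <- function(Y, Q) colSums(Y^2) - colSums(crossprod(Q, Y)^2)
  ss_terms <- function(Y) {
    r <- lapply(Qs, rss, Y = Y)
    rbind(r[[1]] - r[[2]], r[[2]] - r[[3]], r[[3]] - r[[4]])
  }
  Ym <- matrix(y, n, 1)
  ss_obs <- drop(ss_terms(Ym))
  rss_full <- rss(Ym, Qs[[4]])
  df <- c((nlevels(a) - 1), (nlevels(b) - 1),
          (nlevels(a) - 1) * (nlevels(b) - 1))
  df_res <- n - 1L - sum(df)
  if (df_res < 1) stop_rr("no residual degrees of freedom")

  exceed <- numeric(3); m <- 0L
  done <- logical(3); iters <- integer(3); p_fin <- numeric(3)
  block <- 250L
  while (m < max_iter && !all(done)) {
    B <- min(block, max_iter - m)
    P <- vapply(seq_len(B), function(i) sample.int(n), integer(n))
    SS <- ss_terms(matrix(y[P], n, B))
    m <- m + B
    for (k in 1:3) {
      if (done[k]) next
      exceed[k] <- exceed[k] + sum(SS[k, ] >= ss_obs[k] - 1e-12)
      p <- (1 + exceed[k]) / (1 + m)
      se <- sqrt(p * (1 - p) / m)
      if (m >= min_iter && se <= Ca * p) {
        done[k] <- TRUE; iters[k] <- m; p_fin[k] <- p
      }
    }
  }
  for (k in which(!done)) {
    iters[k] <- m; p_fin[k] <- (1 + exceed[k]) / (1 + m)
  }
  out <- data.frame(
    term = c(name_a, name_b, "interaction", "residuals"),
    df = c(df, df_res),
    sum_sq = c(ss_obs, rss_full),
    mean_sq = c(ss_obs / df, rss_full / df_res),
    iterations = c(iters, NA),
    p_perm = c(p_fin, NA),
    stringsAsFactors = FALSE
  )
  class(out) <- c("permanova", "data.frame")
  out
}

pooled_t <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  num <- mean(x) - mean(y)
  s2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
  den <- sqrt(s2 * (1 / n1 + 1 / n2))
  if (den == 0) return(if (num == 0) 0 else sign(num) * Inf)
  num / den
}

#' Pairwise permutation Student tests
#'
#' For every pair of groups, the classic pooled-variance Student t is
#' computed on the observed split, and its permutation p-value as
#' (1 + #\{|t*| >= |t_obs|\}) / (1 + n_perm) under random reallocation of
#' observations between the two groups.  With `exact = TRUE` all distinct
#' splits are enumerated instead and the p-value is the exact tail
#' fraction.  Pairs involving a group of fewer than two observations are
#' reported as NA.
#'
#' @param values numeric responses (already on the analysis scale).
#' @param groups group labels.
#' @param n_perm permutations per pair (default 999).
#' @param seed optional integer seed.
#' @param exact enumerate all splits (feasible for small pairs only).
#' @return symmetric matrix of p-values with unit diagonal.
#' @export
pairwise_permutation_t <- function(values, groups, n_perm = 999, seed = NULL,
                                   exact = FALSE) {
  g <- factor(groups)
  if (nlevels(g) < 2) stop_rr("need >= 2 groups")
  if (!is.null(seed)) set.seed(seed)
  lv <- levels(g)
  P <- matrix(NA_real_, nlevels(g), nlevels(g), dimnames = list(lv, lv))
  diag(P) <- 1
  for (i in seq_len(nlevels(g) - 1)) for (j in (i + 1):nlevels(g)) {
    x <- values[g == lv[i]]; y <- values[g == lv[j]]
    if (length(x) < 2 || length(y) < 2) next
    t_obs <- abs(pooled_t(x, y))
    z <- c(x, y); n1 <- length(x); nz <- length(z)
    if (exact) {
      splits <- utils::combn(nz, n1)
      tt <- apply(splits, 2, function(ix) abs(pooled_t(z[ix], z[-ix])))
      p <- mean(tt >= t_obs - 1e-12)
    } else {
      cnt <- 0L
      for (r in seq_len(n_perm)) {
        ix <- sample.int(nz, n1)
        if (abs(pooled_t(z[ix], z[-ix])) >= t_obs - 1e-12) cnt <- cnt + 1L
      }
      p <- (1 + cnt) / (1 + n_perm)
    }
    P[i, j] <- P[j, i] <- p
  }
  P
}

#' Percentile bootstrap confidence interval for a mean
#'
#' @param values numeric vector (n >= 1).
#' @param n_boot bootstrap resamples (default 200).
#' @param level confidence level (default 0.95).
#' @param seed optional integer seed.
#' @return named vector `mean`, `lower`, `upper`.
#' @export
bootstrap_mean_ci <- function(values, n_boot = 200, level = 0.95, seed = NULL) {
  if (!length(values)) stop_rr("empty input")
  if (!is.null(seed)) set.seed(seed)
  n <- length(values)
  means <- colMeans(matrix(values[sample.int(n, n * n_boot, replace = TRUE)],
                           n, n_boot))
  alpha <- (1 - level) / 2
  q <- stats::quantile(means, c(alpha, 1 - alpha), names = FALSE)
  c(mean = mean(values), lower = q[1], upper = q[2])
}

#' Cumulative home-range curve with a bootstrap confidence band
#'
#' Empirical cumulative fraction of sharks whose UD is at most x, evaluated
#' at the observed values, with a pointwise 95% band from bootstrapping over
#' individuals (default 200 runs).  The band always contains the point
#' estimate.
#'
#' @inheritParams bootstrap_mean_ci
#' @return object of class `cumulative_curve`: `values` (sorted unique),
#'   `fraction`, `lower`, `upper`, `n`, `n_boot`.
#' @export
cumulative_curve <- function(values, n_boot = 200, level = 0.95, seed = NULL) {
  if (!length(values)) stop_rr("empty input")
  if (!is.null(seed)) set.seed(seed)
  grid <- sort(unique(values))
  est <- vapply(grid, function(g) mean(values <= g), numeric(1))
  n <- length(values)
  bs <- matrix(values[sample.int(n, n * n_boot, replace = TRUE)], n, n_boot)
  M <- vapply(seq_along(grid),
              function(i) colMeans(bs <= grid[i]), numeric(n_boot))
  alpha <- (1 - level) / 2
  lower <- apply(M, 2, stats::quantile, probs = alpha, names = FALSE)
  upper <- apply(M, 2, stats::quantile, probs = 1 - alpha, names = FALSE)
  structure(list(values = grid, fraction = est,
                 lower = pmin(lower, est), upper = pmax(upper, est),
                 n = n, n_boot = n_boot), class = "cumulative_curve")
}

#' Fraction of sharks with UD below a threshold, with bootstrap CI
#'
#' Strict inequality, matching "home range lower than x km2" summaries.
#'
#' @param values UD values.
#' @param threshold_km2 threshold (strict).
#' @inheritParams bootstrap_mean_ci
#' @return list with `fraction`, `lower`, `upper`, `threshold_km2`.
#' @export
proportion_below <- function(values, threshold_km2, n_boot = 200,
                             level = 0.95, seed = NULL) {
  if (!length(values)) stop_rr("empty input")
  ind <- as.numeric(values < threshold_km2)
  ci <- bootstrap_mean_ci(ind, n_boot = n_boot, level = level, seed = seed)
  list(fraction = unname(ci["mean"]), lower = unname(ci["lower"]),
       upper = unname(ci["upper"]), threshold_km2 = threshold_km2)
}
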