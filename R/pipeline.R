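#' Pipeline configuration
#'
#' Bundles the fixed constants of the analysis: the 0.95 core-receiver
#' threshold, the 10 km2 reporting threshold, the 95 km2 MPA classification
#' threshold, the 0.8 coverage target, permutation/bootstrap budgets
#' (5000 / 999 / 200) and a master seed from which every stage derives its
#' own seed (stage seeds are `seed + 100 + stage index`, so stages are
#' reproducible in isolation).
#'
#' @param out_dir output directory.
#' @param seed master seed.
#' @param sim a [sim_config()] for the synthetic stage (default the
#'   engineered study cohort, [paper_cohort_config()]).
#' @param core_threshold cumulative occurrence share defining UD95.
#' @param report_threshold_km2 UD threshold for "small home range" summaries.
#' @param mpa_threshold_km2 reef-area threshold for MPA classification.
#' @param coverage_target target fraction for [min_size_for_target()].
#' @param max_iter,n_perm,n_boot permutation ANOVA budget, pairwise-test
#'   permutations, bootstrap runs.
#' @param coverage_grid MPA sizes (km2) for the coverage curves.
#' @param reference_sizes named reef-slope areas at which Pi is reported.
#' @param false_window_s false-detection support window, seconds.
#' @param post_capture_days post-capture exclusion window, days.
#' @param tz study-local timezone.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, sim = paper_cohort_config(seed),
                            core_threshold = 0.95,
                            report_threshold_km2 = 10,
                            mpa_threshold_km2 = 95,
                            coverage_target = 0.8,
                            max_iter = 5000, n_perm = 999, n_boot = 200,
                            coverage_grid = c(1:100, seq(110, 500, 10)),
                            reference_sizes = c(abore_slope = 10,
                                                entrecasteaux_slope = 80,
                                                chesterfield_slope = 1130),
                            false_window_s = 3600, post_capture_days = 14,
                            tz = REEFRANGE_TZ) {
  stopifnot(core_threshold > 0, core_threshold <= 1,
            coverage_target > 0, coverage_target < 1,
            mpa_threshold_km2 > 0)
  structure(list(out_dir = out_dir, seed = as.integer(seed), sim = sim,
                 core_threshold = core_threshold,
                 report_threshold_km2 = report_threshold_km2,
                 mpa_threshold_km2 = mpa_threshold_km2,
                 coverage_target = coverage_target,
                 max_iter = max_iter, n_perm = n_perm, n_boot = n_boot,
                 coverage_grid = coverage_grid,
                 reference_sizes = reference_sizes,
                 false_window_s = false_window_s,
                 post_capture_days = post_capture_days, tz = tz),
            class = "pipeline_config")
}

stage_seed <- function(cfg, k) (cfg$seed + 100L + k) %% .Machine$integer.max

#' Run the full analysis pipeline
#'
#' simulate -> read -> filter false detections -> post-capture window ->
#' cohort exclusions -> daily occurrences -> seasonal UD tables ->
#' permutation/bootstrap statistics -> MPA coverage model -> WDPA-style
#' screening.  All tabular and JSON outputs are written under
#' `config$out_dir` and are byte-identical across runs with the same master
#' seed.  Each stage logs its record counts; any stage error aborts with
#' the stage name.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return invisibly, the report list (also written as `report.json`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(...)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_rr("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  }

  # -- simulate ---------------------------------------------------------
  sim <- config$sim
  system <- stage("simulate", generate_system(sim))
  det_raw <- stage("simulate", simulate_detections(system, sim))
  paths <- stage("simulate", write_system_csv(system, det_raw, out))
  fixtures <- stage("simulate", generate_mpa_fixtures(file.path(out, "fixtures")))
  say("simulate: ", nrow(det_raw), " detections, ",
      nrow(system$receivers), " receivers, ", nrow(system$tagging), " sharks")

  # -- read & filter ----------------------------------------------------
  det <- stage("read", read_detections(paths["detections"]))
  receivers <- stage("read", read_receivers(paths["receivers"]))
  tagging <- stage("read", read_tagging(paths["tagging"], receivers))
  ff <- stage("filter", filter_false_detections(det, config$false_window_s))
  say("filter: removed ", ff$n_removed, " presumed-false detection(s)")
  det_w <- stage("window", apply_post_capture_window(
    ff$detections, tagging, config$post_capture_days, config$tz))
  cohort <- stage("cohort", build_cohort(det_w, tagging, receivers))
  say("cohort: ", cohort$n_retained, " of ", cohort$n_tagged, " retained (",
      cohort$n_excluded_lost_receiver, " lost-receiver, ",
      cohort$n_excluded_silent, " silent)")

  # -- home range -------------------------------------------------------
  occ <- stage("homerange", daily_occurrences(det_w, cohort, config$tz))
  geometry <- system$geometry
  uds <- lapply(c(all = "all", mating = "mating", non_mating = "non_mating"),
                function(s) ud_table(occ, tagging, receivers, geometry, s,
                                     config$core_threshold))
  for (s in names(uds))
    utils::write.csv(uds[[s]], file.path(out, paste0("ud_", s, ".csv")),
                     row.names = FALSE)
  su <- lapply(cohort$retained, function(id)
    seasonal_use(id, occ, receivers, geometry, config$core_threshold))
  su_df <- data.frame(
    shark = vapply(su, `[[`, "", "shark"),
    fraction_exclusive_mating = vapply(su, `[[`, 0, "fraction_exclusive_mating"),
    stringsAsFactors = FALSE)
  su_df$group <- uds$all$group[match(su_df$shark, uds$all$shark)]
  utils::write.csv(su_df, file.path(out, "seasonal_use.csv"), row.names = FALSE)
  say("homerange: ", nrow(occ), " daily occurrences, ",
      nrow(uds$all), " year-round UD rows")

  # -- statistics -------------------------------------------------------
  k <- 0L
  stats_out <- list()
  for (s in names(uds)) for (metric in c("ud95_km2", "ud100_km2")) {
    tab <- uds[[s]]
    if (nrow(tab) < 8) next
    k <- k + 1L
    y <- transform_ud(tab[[metric]])
    pm <- stage("stats", permanova_two_way(
      y, tab$sex, tab$maturity, max_iter = config$max_iter,
      seed = stage_seed(config, k), name_a = "sex", name_b = "maturity"))
    k <- k + 1L
    pw <- stage("stats", pairwise_permutation_t(
      y, tab$group, n_perm = config$n_perm, seed = stage_seed(config, k)))
    stats_out[[paste(metric, s, sep = ".")]] <-
      list(permanova = pm, pairwise_p = pw)
  }
  k <- k + 1L
  excl_pm <- stage("stats", permanova_two_way(
    su_df$fraction_exclusive_mating,
    uds$all$sex[match(su_df$shark, uds$all$shark)],
    uds$all$maturity[match(su_df$shark, uds$all$shark)],
    max_iter = config$max_iter, seed = stage_seed(config, k),
    name_a = "sex", name_b = "maturity"))

  group_means <- list(); props <- list(); curves <- list()
  for (metric in c("ud95_km2", "ud100_km2")) {
    v_all <- uds$all[[metric]]
    v_am <- uds$all[[metric]][uds$all$group == "adult_male"]
    k <- k + 1L
    group_means[[metric]] <- lapply(
      split(uds$all[[metric]], uds$all$group),
      bootstrap_mean_ci, n_boot = config$n_boot, seed = stage_seed(config, k))
    group_means[[metric]]$overall <-
      bootstrap_mean_ci(v_all, n_boot = config$n_boot,
                        seed = stage_seed(config, k) + 1L)
    k <- k + 1L
    props[[metric]] <- list(
      all = proportion_below(v_all, config$report_threshold_km2,
                             config$n_boot, seed = stage_seed(config, k)),
      adult_male = proportion_below(v_am, config$report_threshold_km2,
                                    config$n_boot, seed = stage_seed(config, k) + 1L))
    k <- k + 1L
    curves[[metric]] <- cumulative_curve(v_all, config$n_boot,
                                         seed = stage_seed(config, k))
  }
  jsonlite::write_json(
    lapply(stats_out, function(x) list(
      permanova = x$permanova, pairwise_p = as.data.frame(x$pairwise_p))),
    file.path(out, "stats.json"), dataframe = "rows", digits = 10, pretty = TRUE)
  say("stats: ", length(stats_out), " metric-season combinations tested")

  # -- MPA coverage model ----------------------------------------------
  cov <- list()
  for (subset in c("all", "adult_male")) for (metric in c("ud95_km2", "ud100_km2")) {
    tab <- uds$all
    v <- if (subset == "all") tab[[metric]] else tab[[metric]][tab$group == "adult_male"]
    cc <- stage("coverage", coverage_curve(v, config$coverage_grid))
    cc$subset <- subset; cc$metric <- sub("_km2", "", metric)
    cov[[paste(subset, metric, sep = ".")]] <- cc
  }
  cov_df <- do.call(rbind, cov)
  row.names(cov_df) <- NULL
  utils::write.csv(cov_df, file.path(out, "coverage.csv"), row.names = FALSE)
  pi_ref <- lapply(cov, function(cc) {
    v <- if (cc$subset[1] == "all") uds$all[[paste0(cc$metric[1], "_km2")]]
         else uds$all[[paste0(cc$metric[1], "_km2")]][uds$all$group == "adult_male"]
    vapply(config$reference_sizes, function(S)
      coverage_probability(v, S)$Pi, numeric(1))
  })
  v_am100 <- uds$all$ud100_km2[uds$all$group == "adult_male"]
  s_star <- if (length(v_am100))
    stage("coverage", min_size_for_target(v_am100, config$coverage_target))
  else NA_real_
  say("coverage: S* for ", config$coverage_target, " of adult-male UD100 = ",
      s_star, " km2")

  # -- MPA screening ----------------------------------------------------
  mpas <- stage("screen", read_mpa_polygons(fixtures$mpa_path))
  reefs <- stage("screen", read_reef_polygons(fixtures$reef_path))
  kept <- stage("screen", filter_mpas(mpas, reefs))
  cls <- stage("screen", classify_by_reef_area(kept, config$mpa_threshold_km2))
  write_mpa_geojson(kept, file.path(out, "screened_mpas.geojson"))
  say("screen: ", nrow(kept), " of ", nrow(mpas), " MPAs retained, ",
      cls$n_above, " above ", config$mpa_threshold_km2, " km2 of reef")

  report <- list(
    schema_version = "1",
    seed = config$seed,
    cohort = list(n_tagged = cohort$n_tagged,
                  n_excluded_lost_receiver = cohort$n_excluded_lost_receiver,
                  n_excluded_silent = cohort$n_excluded_silent,
                  n_retained = cohort$n_retained,
                  per_group_retained = as.list(cohort$per_group_retained)),
    n_detections_raw = nrow(det_raw),
    n_false_removed = ff$n_removed,
    group_means = group_means,
    proportion_below_threshold = props,
    exclusive_mating_permanova = excl_pm,
    pi_at_reference_sizes = pi_ref,
    min_size_for_target = list(target = config$coverage_target,
                               metric = "ud100", subset = "adult_male",
                               S_star_km2 = s_star),
    screening = list(n_input = nrow(mpas), n_retained = nrow(kept),
                     n_above_threshold = cls$n_above,
                     above_ids = cls$above$mpa_id))
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(report)
}
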