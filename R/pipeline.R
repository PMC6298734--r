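#' Assemble a pipeline run configuration
#'
#' Collects every tunable of the full analysis in one list. Inputs are
#' either the three CSV paths (`haul_table`, `specimen_table`,
#' `diet_table`) or a synthetic `scenario` (a list with elements `survey`,
#' a [survey_scenario()], and `diet`, a [diet_scenario()]); exactly one of
#' the two must be supplied.
#'
#' @param haul_table,specimen_table,diet_table input CSV paths.
#' @param scenario synthetic scenario list (`survey`, `diet`).
#' @param species_pair the two predator names (default `c("PH", "ATF")`).
#' @param size_range closed fork-length window, cm.
#' @param cell_size grid cell edge, metres.
#' @param standardization `"max"`, `"mean"` or `"median"`.
#' @param habitat_threshold whole-cell exclusion threshold on stdA.
#' @param min_stomachs minimum non-empty stomachs per predator per
#'   year-cell for a dietary overlap estimate.
#' @param dredge logical: run all-subsets AIC selection (slower) or fit
#'   the full model directly.
#' @param policy model choice policy when `dredge = TRUE`
#'   (`"min_aic"` or `"force_full"`).
#' @param k_depth,k_lonlat smooth basis dimensions (see [model_spec()]).
#' @param boundaries area boundary schemes (see [assign_area()]).
#' @param grouping which boundary scheme groups the ANCOVA and per-area
#'   correlations (name within `boundaries`).
#' @param alpha significance level (default 0.1).
#' @param year_as how year enters the ANCOVA (see [overlap_ancova()]).
#' @param seed integer seed for all stochastic stages.
#' @param out_dir optional directory; when given, every intermediate table
#'   and a run log are written there as CSV/text.
#' @return a list of class `run_config`.
#' @export
run_config <- function(haul_table = NULL, specimen_table = NULL,
                       diet_table = NULL, scenario = NULL,
                       species_pair = c("PH", "ATF"),
                       size_range = c(30, 69), cell_size = 1e5,
                       standardization = "max", habitat_threshold = 0.25,
                       min_stomachs = 3L, dredge = FALSE,
                       policy = "min_aic", k_depth = 10, k_lonlat = 30,
                       boundaries = default_boundaries(),
                       grouping = "inpfc", alpha = 0.1,
                       year_as = "factor", seed = 1L, out_dir = NULL) {
  paths_given <- !is.null(haul_table)
  if (paths_given == !is.null(scenario))
    stop("supply either input table paths or a synthetic scenario (not both)")
  if (paths_given) {
    for (p in c(haul_table, specimen_table, diet_table))
      if (!file.exists(p)) stop("input path does not exist: ", p)
  }
  if (!grouping %in% names(boundaries))
    stop("grouping '", grouping, "' not among boundary schemes: ",
         paste(names(boundaries), collapse = ", "))
  structure(list(
    haul_table = haul_table, specimen_table = specimen_table,
    diet_table = diet_table, scenario = scenario,
    species_pair = species_pair, size_range = size_range,
    cell_size = cell_size, standardization = standardization,
    habitat_threshold = habitat_threshold,
    min_stomachs = as.integer(min_stomachs), dredge = dredge,
    policy = policy, k_depth = k_depth, k_lonlat = k_lonlat,
    boundaries = boundaries, grouping = grouping, alpha = alpha,
    year_as = year_as, seed = as.integer(seed), out_dir = out_dir),
    class = "run_config")
}

stage_msg <- function(log, stage, text) {
  message("[", stage, "] ", text)
  c(log, paste0("[", stage, "] ", text))
}

#' Run the full niche-overlap analysis
#'
#' Executes every stage in order: ingest (or simulate), covariate filter,
#' size-adjusted CPUE, delta-GAM fitting per species, gridded prediction,
#' standardization and habitat exclusion, spatial overlap, dietary
#' overlap, and the partitioning statistics. All stages are pure functions
#' of (inputs, config, seed): rerunning an identical config yields an
#' identical bundle. When `config$out_dir` is set, every intermediate
#' table plus a run log (package version, seed, config echo) is written
#' there; on a stage failure the error names the stage and partial outputs
#' already written are retained.
#'
#' @param config a [run_config()].
#' @return a list of class `run_bundle`: `hauls`, `filter_report`,
#'   `fits` (per species: presence and log-CPUE `gam_fit`s, and model
#'   tables when dredging), `grid`, `env`, `abundance` (stdA field),
#'   `habitat` (exclusion result), `spatial` (S field), `spatial_cells`
#'   (per-cell mean S), `diet` (D field), `pairs` (year-cells with both S
#'   and D), `ancova_S`, `ancova_D`, `tukey_S`, `correlation` (basin and
#'   per-area), `annual`, `log`.
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log <- character()
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  sp <- config$species_pair

  # ---- ingest or simulate -------------------------------------------------
  if (!is.null(config$scenario)) {
    log <- stage_msg(log, "simulate", paste0(
      "generating synthetic survey (seed ", config$seed, ")"))
    bundle_in <- run_stage("simulate", {
      sc <- config$scenario$survey
      sc$seed <- config$seed
      sim <- simulate_hauls(sc)
      lens <- simulate_lengths(sim, size_range = config$size_range)
      ds <- config$scenario$diet
      ds$seed <- config$seed
      diet_tab <- simulate_stomachs(sim, lens$specimens, ds)
      list(hauls = sim$hauls, specimens = lens$specimens,
           diet = diet_tab, sim = sim)
    })
  } else {
    log <- stage_msg(log, "ingest", paste("reading", config$haul_table))
    bundle_in <- run_stage("ingest", list(
      hauls = read_haul_table(config$haul_table),
      specimens = read_specimen_table(config$specimen_table),
      diet = read_diet_table(config$diet_table), sim = NULL))
  }

  # ---- covariate filter + adjusted CPUE ----------------------------------
  flt <- run_stage("filter", filter_complete_covariates(bundle_in$hauls))
  log <- stage_msg(log, "filter", paste0(
    flt$report$n_input, " tows in; ",
    flt$report$n_excluded_missing_covariates,
    " excluded (missing depth/temp); ", flt$report$n_retained, " retained"))
  hauls <- flt$hauls
  for (s in sp) {
    ac <- run_stage("adjusted_cpue",
                    adjusted_cpue(hauls, bundle_in$specimens, s,
                                  size_range = config$size_range))
    hauls[[paste0("adj_cpue_", s)]] <- ac$adj_cpue
    hauls[[paste0("presence_", s)]] <- ac$presence
  }

  # ---- delta-GAM fits -----------------------------------------------------
  fits <- list()
  for (s in sp) {
    dat <- hauls
    dat$presence <- dat[[paste0("presence_", s)]]
    dat$adj_cpue <- dat[[paste0("adj_cpue_", s)]]
    pos <- dat[dat$adj_cpue > 0, ]
    fits[[s]] <- run_stage(paste0("fit_", s), {
      spec_p <- model_spec("presence", k_depth = config$k_depth,
                           k_lonlat = config$k_lonlat)
      spec_c <- model_spec("log_cpue", k_depth = config$k_depth,
                           k_lonlat = config$k_lonlat)
      if (config$dredge) {
        tab_p <- dredge_aic(dat, spec_p)
        tab_c <- dredge_aic(pos, spec_c)
        list(presence = select_best(tab_p, config$policy)$fit,
             log_cpue = select_best(tab_c, config$policy)$fit,
             table_presence = tab_p, table_log_cpue = tab_c)
      } else {
        list(presence = fit_presence(dat, spec_p),
             log_cpue = fit_log_cpue(pos, spec_c))
      }
    })
    log <- stage_msg(log, paste0("fit_", s), sprintf(
      "presence dev %.1f%%, log-CPUE dev %.1f%% (n+ = %d)",
      fits[[s]]$presence$dev_expl, fits[[s]]$log_cpue$dev_expl, nrow(pos)))
  }

  # ---- grid, prediction, standardization, spatial overlap -----------------
  extent <- c(range(hauls$lon), range(hauls$lat))
  grid <- run_stage("grid", build_grid(extent, config$cell_size))
  env <- run_stage("grid", cell_year_env(hauls, grid))
  log <- stage_msg(log, "grid", paste0(
    grid$nx, "x", grid$ny, " cells; ", nrow(env), " year-cell combinations"))
  pred <- do.call(rbind, lapply(sp, function(s) {
    data.frame(species = s, year = env$year, cell_id = env$cell_id,
               po = predict_occurrence(fits[[s]]$presence, env),
               pa = predict_abundance(fits[[s]]$log_cpue, env))
  }))
  field <- run_stage("standardize",
                     combine_and_standardize(pred, config$standardization))
  hab <- run_stage("exclude",
                   exclude_low_habitat(field, sp, config$habitat_threshold))
  log <- stage_msg(log, "exclude", paste0(
    hab$n_excluded, " low-habitat cell(s) excluded; ",
    length(hab$retained), " retained"))
  field_r <- field[field$cell_id %in% hab$retained, ]
  s_field <- run_stage("spatial_overlap", spatial_overlap(field_r, sp))
  s_cells <- cell_means(s_field, "S")

  # ---- dietary overlap ----------------------------------------------------
  groups <- run_stage("diet", group_stomachs(
    bundle_in$diet, bundle_in$hauls, grid, sp,
    size_range = config$size_range,
    min_per_predator = config$min_stomachs))
  groups$qualifying <- groups$qualifying[
    groups$qualifying$cell_id %in% hab$retained, , drop = FALSE]
  d_field <- run_stage("diet", dietary_overlap(groups, sp))
  log <- stage_msg(log, "diet", paste0(
    nrow(d_field), " year-cell dietary overlap estimate(s)"))

  # ---- partitioning statistics -------------------------------------------
  pairs <- merge(s_field[, c("year", "cell_id", "S")],
                 d_field[, c("year", "cell_id", "D")],
                 by = c("year", "cell_id"))
  sch <- config$boundaries[[config$grouping]]
  cell_lon <- stats::setNames(grid$cells$lon, grid$cells$cell_id)
  s_area <- assign_area(cell_lon[s_field$cell_id],
                        config$boundaries)[[config$grouping]]
  p_area <- assign_area(cell_lon[pairs$cell_id],
                        config$boundaries)[[config$grouping]]
  stats_out <- run_stage("stats", {
    anc_S <- overlap_ancova(s_field$S, s_area, s_field$year,
                            alpha = config$alpha, year_as = config$year_as)
    anc_D <- if (nrow(d_field) >= 10 &&
                 length(unique(assign_area(cell_lon[d_field$cell_id],
                                           config$boundaries)[[config$grouping]])) >= 2)
      overlap_ancova(d_field$D,
                     assign_area(cell_lon[d_field$cell_id],
                                 config$boundaries)[[config$grouping]],
                     d_field$year, alpha = config$alpha,
                     year_as = config$year_as) else NULL
    tuk <- tukey_hsd(s_field$S, s_area)
    corr <- rbind(pearson_partitioning(pairs, "basin"),
                  if (nrow(pairs) >= 3)
                    pearson_partitioning(pairs, "area", area = p_area))
    list(ancova_S = anc_S, ancova_D = anc_D, tukey_S = tuk,
         correlation = corr)
  })
  annual <- annual_summary(s_field, d_field)
  if (nrow(pairs) >= 3) {
    basin <- stats_out$correlation[stats_out$correlation$group == "basin", ]
    log <- stage_msg(log, "stats", sprintf(
      "basin-wide S-D correlation r = %.3f (n = %d, p = %.3g)",
      basin$r, basin$n, basin$p))
  }

  bundle <- structure(list(
    hauls = hauls, filter_report = flt$report, fits = fits, grid = grid,
    env = env, abundance = field, habitat = hab, spatial = s_field,
    spatial_cells = s_cells, diet = d_field, pairs = pairs,
    ancova_S = stats_out$ancova_S, ancova_D = stats_out$ancova_D,
    tukey_S = stats_out$tukey_S, correlation = stats_out$correlation,
    annual = annual, truth = bundle_in$sim$truth, config = config,
    log = log), class = "run_bundle")
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

#' @export
print.run_bundle <- function(x, ...) {
  cat("<run_bundle>\n")
  cat("  ", x$filter_report$n_retained, "tows;",
      nrow(x$spatial), "spatial and", nrow(x$diet),
      "dietary year-cell estimates\n")
  cat(sprintf("   mean S = %.3f (SD %.3f); mean D = %s\n",
              mean(x$spatial$S), stats::sd(x$spatial$S),
              if (nrow(x$diet)) sprintf("%.3f (SD %.3f)", mean(x$diet$D),
                                        stats::sd(x$diet$D)) else "-"))
  basin <- x$correlation[x$correlation$group == "basin", ]
  if (nrow(basin) && !is.na(basin$r))
    cat(sprintf("   basin-wide S-D correlation r = %.3f (df = %d, p = %.3g)\n",
                basin$r, basin$df, basin$p))
  invisible(x)
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name)
    utils::write.csv(df, file.path(out_dir, paste0(name, ".csv")),
                     row.names = FALSE, na = "")
  w(bundle$env, "cell_year_env")
  w(as.data.frame(bundle$abundance), "abundance_field")
  w(as.data.frame(bundle$spatial), "spatial_overlap")
  w(bundle$spatial_cells, "spatial_overlap_cell_means")
  if (nrow(bundle$diet)) w(bundle$diet, "dietary_overlap")
  if (nrow(bundle$pairs)) w(bundle$pairs, "overlap_pairs")
  w(bundle$correlation, "partitioning_correlation")
  w(bundle$annual, "annual_summary")
  cfg <- bundle$config
  cfg$boundaries <- NULL
  cfg$scenario <- if (is.null(cfg$scenario)) NULL else "<scenario object>"
  writeLines(c(
    paste0("nichepart ", as.character(utils::packageVersion("nichepart"))),
    paste0("run time: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
    paste0("seed: ", cfg$seed), "",
    "config:", utils::capture.output(utils::str(unclass(cfg))), "",
    "log:", bundle$log),
    file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar fields map directly onto [run_config()] arguments. The
#' `scenario` field may be the string `"demo"` or `"partitioning"`
#' (resolved via [default_survey_scenario()] / [default_diet_scenario()],
#' with optional `hauls_per_year`), or be omitted in favour of the three
#' input paths.
#'
#' @param path YAML file.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  scenario <- NULL
  if (!is.null(y$scenario)) {
    hp <- if (is.null(y$hauls_per_year)) 2000L else as.integer(y$hauls_per_year)
    seed <- if (is.null(y$seed)) 1L else as.integer(y$seed)
    scenario <- switch(
      as.character(y$scenario),
      demo = list(survey = default_survey_scenario(hauls_per_year = hp,
                                                   seed = seed),
                  diet = default_diet_scenario(seed = seed)),
      partitioning = list(
        survey = default_survey_scenario(hauls_per_year = hp, seed = seed),
        diet = default_diet_scenario(partitioning = TRUE, seed = seed)),
      stop("unknown scenario: ", y$scenario))
  }
  args <- y[intersect(names(y), names(formals(run_config)))]
  args$scenario <- scenario
  do.call(run_config, args)
}
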