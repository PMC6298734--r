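#' Simulate a trawl-survey haul table with known truth
#'
#' Draws haul locations uniformly within the scenario extent for each survey
#' year, evaluates the environmental fields, and for each species draws
#' presence as a Bernoulli of the logistic linear predictor and, where
#' present, CPUE as the exponential of a Gaussian draw around the log-scale
#' mean. A fraction of hauls have depth and/or temperature blanked to
#' emulate incomplete field records.
#'
#' @param scenario a [survey_scenario()].
#' @return a list of class `survey_sim` with elements
#'   \describe{
#'     \item{hauls}{data.frame with `haul_id`, `year`, `lon`, `lat`,
#'       `depth`, `temp` and one `cpue_<species>` column per species
#'       (number/ha; 0 where absent).}
#'     \item{truth}{list with, per species, closures
#'       `presence_prob(lon, lat, depth, temp, year)` and
#'       `mean_log_cpue(...)` (the exact surfaces used), plus
#'       `haul_truth`, the per-haul true presence probabilities and
#'       log-CPUE means evaluated before any covariate blanking.}
#'   }
#' @details Identical scenario and seed give byte-identical tables. Blanked
#'   covariates affect only the emitted haul table; catches were generated
#'   from the complete environment.
#' @export
simulate_hauls <- function(scenario) {
  stopifnot(inherits(scenario, "survey_scenario"))
  set.seed(scenario$seed)
  ext <- scenario$extent
  n_y <- scenario$hauls_per_year
  years <- rep(scenario$years, each = n_y)
  n <- length(years)
  lon <- stats::runif(n, ext[1], ext[2])
  lat <- stats::runif(n, ext[3], ext[4])
  depth <- scenario$depth_field(lon, lat, years)
  temp <- scenario$temp_field(lon, lat, years)
  bad <- !is.finite(depth) | !is.finite(temp)
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("non-finite environmental field at lon=%.4f lat=%.4f year=%d",
                 lon[i], lat[i], years[i]))
  }
  hauls <- data.frame(haul_id = sprintf("H%06d", seq_len(n)),
                      year = years, lon = lon, lat = lat,
                      depth = depth, temp = temp)
  truth <- list(species = list())
  haul_truth <- data.frame(haul_id = hauls$haul_id)
  for (sp in names(scenario$species_params)) {
    p <- scenario$species_params[[sp]]
    eta_fun <- local({
      p_loc <- p
      function(lon, lat, depth, temp, year) {
        p_loc$year_effects[as.character(year)] +
          p_loc$spatial_surface(lon, lat) +
          p_loc$depth_response(depth) + p_loc$temp_response(temp)
      }
    })
    po_fun <- local({
      p_loc <- p; eta_loc <- eta_fun
      function(lon, lat, depth, temp, year)
        stats::plogis(p_loc$presence_offset +
                        eta_loc(lon, lat, depth, temp, year))
    })
    mlc_fun <- local({
      p_loc <- p; eta_loc <- eta_fun
      function(lon, lat, depth, temp, year)
        p_loc$cpue_offset + eta_loc(lon, lat, depth, temp, year)
    })
    po <- unname(po_fun(lon, lat, depth, temp, years))
    mlc <- unname(mlc_fun(lon, lat, depth, temp, years))
    if (any(!is.finite(po))) {
      i <- which(!is.finite(po))[1]
      stop(sprintf("non-finite surface for %s at lon=%.4f lat=%.4f", sp,
                   lon[i], lat[i]))
    }
    present <- stats::rbinom(n, 1L, po)
    cpue <- ifelse(present == 1L,
                   exp(stats::rnorm(n, mlc, p$cpue_sd)), 0)
    hauls[[paste0("cpue_", sp)]] <- cpue
    truth$species[[sp]] <- list(presence_prob = po_fun,
                                mean_log_cpue = mlc_fun)
    haul_truth[[paste0("po_", sp)]] <- po
    haul_truth[[paste0("mlc_", sp)]] <- mlc
  }
  # blank covariates on a fraction of hauls (depth, temp, or both)
  if (scenario$missing_covariate_rate > 0) {
    hit <- stats::runif(n) < scenario$missing_covariate_rate
    which_blank <- sample(1:3, n, replace = TRUE)  # 1 depth, 2 temp, 3 both
    hauls$depth[hit & which_blank != 2] <- NA_real_
    hauls$temp[hit & which_blank != 1] <- NA_real_
  }
  truth$haul_truth <- haul_truth
  structure(list(hauls = hauls, truth = truth, scenario = scenario),
            class = "survey_sim")
}

#' @export
print.survey_sim <- function(x, ...) {
  cat("<survey_sim>", nrow(x$hauls), "hauls,",
      length(x$truth$species), "species,",
      length(unique(x$hauls$year)), "years\n")
  invisible(x)
}

#' Simulate fork-length subsamples for a simulated survey
#'
#' For each haul where a species is present, draws up to `subsample_max`
#' fork lengths from that species' lognormal length distribution, rounded
#' to whole cm (the measurement resolution). The realized proportion of
#' lengths in a reference size range is recorded in the returned truth.
#'
#' @param sim a `survey_sim` from [simulate_hauls()].
#' @param size_range reference fork-length interval (cm, closed) whose true
#'   in-range probability is recorded; default `c(30, 69)`.
#' @return list with `specimens` (data.frame `haul_id`, `species`,
#'   `fork_length`) and `truth` (per species: the lognormal parameters and
#'   `in_range_prob`, the probability a rounded length falls inside
#'   `size_range`).
#' @export
simulate_lengths <- function(sim, size_range = c(30, 69)) {
  stopifnot(inherits(sim, "survey_sim"))
  scenario <- sim$scenario
  set.seed(scenario$seed + 1L)
  out <- vector("list", length(scenario$species_params))
  truth <- list()
  names(out) <- names(scenario$species_params)
  for (sp in names(scenario$species_params)) {
    p <- scenario$species_params[[sp]]
    present <- sim$hauls[[paste0("cpue_", sp)]] > 0
    idx <- which(present)
    n_fish <- pmin(scenario$subsample_max,
                   1L + stats::rpois(length(idx), p$lengths_per_haul - 1))
    lens <- round(stats::rlnorm(sum(n_fish), p$length_meanlog, p$length_sdlog))
    lens <- pmax(lens, 1)
    out[[sp]] <- data.frame(
      haul_id = rep(sim$hauls$haul_id[idx], n_fish),
      species = rep(sp, length(lens)), fork_length = lens)
    truth[[sp]] <- list(
      length_meanlog = p$length_meanlog, length_sdlog = p$length_sdlog,
      in_range_prob = stats::plnorm(size_range[2] + 0.5, p$length_meanlog,
                                    p$length_sdlog) -
        stats::plnorm(size_range[1] - 0.5, p$length_meanlog, p$length_sdlog))
  }
  specimens <- do.call(rbind, out)
  if (is.null(specimens))
    specimens <- data.frame(haul_id = character(), species = character(),
                            fork_length = numeric())
  rownames(specimens) <- NULL
  list(specimens = specimens, truth = truth)
}

#' Evaluate the generative truth at prediction points
#'
#' Evaluates a simulation's true presence-probability and mean-log-CPUE
#' surfaces at a set of prediction covariates (e.g. the output of
#' [cell_year_env()]) and returns them in the same shape the fitted models
#' produce, so truth and estimate flow through the identical
#' standardization and overlap code.
#'
#' @param sim a `survey_sim`.
#' @param env data.frame with `year`, `cell_id`, `lon`, `lat`, `depth`,
#'   `temp`.
#' @return data.frame `species`, `year`, `cell_id`, `po` (true occurrence
#'   probability), `pa` (true positive-catch abundance, `exp` of the mean
#'   log CPUE).
#' @export
truth_predictions <- function(sim, env) {
  stopifnot(inherits(sim, "survey_sim"))
  do.call(rbind, lapply(names(sim$truth$species), function(sp) {
    tr <- sim$truth$species[[sp]]
    data.frame(species = sp, year = env$year, cell_id = env$cell_id,
               po = unname(tr$presence_prob(env$lon, env$lat, env$depth,
                                            env$temp, env$year)),
               pa = exp(unname(tr$mean_log_cpue(env$lon, env$lat, env$depth,
                                                env$temp, env$year))))
  }))
}

# draw one Dirichlet vector with parameter alpha (zeros stay exactly zero)
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) {
    # numerically degenerate draw: fall back to the mean composition
    return(alpha / sum(alpha))
  }
  g / sum(g)
}

#' Simulate stomach contents for a simulated survey
#'
#' Follows the at-sea protocol: per haul, species and protocol size class
#' (<31, 31-50, 51-70, >70 cm), up to `stomachs_per_haul_cap` fish from the
#' length subsample are sampled for diets. Each stomach is empty with
#' probability `empty_prob` (fullness code 1); otherwise its prey-weight
#' composition is a Dirichlet draw centred on the group-mean composition
#' for its (species, region, size class), scaled by a lognormal total prey
#' weight, so the expected pooled composition equals the scenario mean.
#'
#' @param sim a `survey_sim`.
#' @param specimens the `specimens` table from [simulate_lengths()].
#' @param diet a [diet_scenario()].
#' @return data.frame with one row per prey item (`haul_id`, `stomach_id`,
#'   `species`, `fork_length`, `fullness`, `taxon`, `weight_g`); empty
#'   stomachs appear as a single row with blank `taxon`, `weight_g = 0` and
#'   `fullness = 1`.
#' @export
simulate_stomachs <- function(sim, specimens, diet) {
  stopifnot(inherits(sim, "survey_sim"), inherits(diet, "diet_scenario"))
  set.seed(diet$seed + sim$scenario$seed)
  hauls <- sim$hauls
  empty_tab <- data.frame(haul_id = character(), stomach_id = character(),
                          species = character(), fork_length = numeric(),
                          fullness = integer(), taxon = character(),
                          weight_g = numeric())
  if (!nrow(specimens)) return(empty_tab)
  # only a fraction of hauls is worked up for diets
  sampled_hauls <- hauls$haul_id[
    stats::runif(nrow(hauls)) < diet$haul_sampling_prob]
  sp_rows <- merge(specimens[specimens$haul_id %in% sampled_hauls, ],
                   hauls[, c("haul_id", "lon", "year")], by = "haul_id")
  if (!nrow(sp_rows)) return(empty_tab)
  sp_rows$size_class <- as.character(protocol_size_class(sp_rows$fork_length))
  sp_rows$region <- diet_region_of(diet, sp_rows$lon)
  # cap stomachs per haul x species x protocol size class
  key <- paste(sp_rows$haul_id, sp_rows$species, sp_rows$size_class)
  ord <- sample(nrow(sp_rows))  # random choice of which fish are sampled
  sp_rows <- sp_rows[ord, ]
  keep <- stats::ave(seq_along(ord), key[ord],
                     FUN = seq_along) <= diet$stomachs_per_haul_cap
  sam <- sp_rows[keep, ]
  n_st <- nrow(sam)
  if (n_st == 0) return(empty_tab)
  sam$stomach_id <- sprintf("S%06d", seq_len(n_st))
  empty <- stats::runif(n_st) < diet$empty_prob
  # group-mean composition per stomach, then one Dirichlet draw per row
  comp_key <- paste(sam$species, sam$region, sam$size_class, sep = "\r")
  uk <- unique(comp_key)
  comp_mat <- t(vapply(strsplit(uk, "\r", fixed = TRUE), function(k)
    comp_lookup(diet, k[1], k[2], k[3]), numeric(length(diet$taxa))))
  P <- comp_mat[match(comp_key, uk), , drop = FALSE]
  G <- matrix(stats::rgamma(n_st * ncol(P),
                            shape = diet$concentration * P, rate = 1),
              n_st, ncol(P))
  rs <- rowSums(G)
  degen <- rs == 0 & !empty
  if (any(degen)) { G[degen, ] <- P[degen, ]; rs[degen] <- 1 }
  W <- G / ifelse(rs > 0, rs, 1)
  total <- stats::rlnorm(n_st, log(diet$weight_scale), 0.5)
  W <- W * total
  fullness <- sample(2:7, n_st, replace = TRUE)
  # long format: one row per positive prey weight; empties get one stub row
  full_idx <- which(!empty)
  pos <- which(W[full_idx, , drop = FALSE] > 0, arr.ind = TRUE)
  items <- data.frame(
    haul_id = sam$haul_id[full_idx][pos[, 1]],
    stomach_id = sam$stomach_id[full_idx][pos[, 1]],
    species = sam$species[full_idx][pos[, 1]],
    fork_length = sam$fork_length[full_idx][pos[, 1]],
    fullness = fullness[full_idx][pos[, 1]],
    taxon = diet$taxa[pos[, 2]],
    weight_g = W[full_idx, , drop = FALSE][pos])
  n_e <- sum(empty)
  stubs <- data.frame(
    haul_id = sam$haul_id[empty], stomach_id = sam$stomach_id[empty],
    species = sam$species[empty], fork_length = sam$fork_length[empty],
    fullness = rep(1L, n_e), taxon = rep("", n_e), weight_g = rep(0, n_e))
  out <- rbind(items, stubs)
  out <- out[order(out$stomach_id, out$taxon), ]
  rownames(out) <- NULL
  out
}
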