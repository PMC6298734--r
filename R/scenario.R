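#' Survey scenario: the generative truth behind a synthetic trawl survey
#'
#' A `survey_scenario` fully specifies a synthetic bottom-trawl survey: the
#' years surveyed, the lon/lat extent, per-species response surfaces on the
#' logit (presence) and natural-log (positive CPUE) scales, environmental
#' fields, and sampling rates. The same object is the ground truth against
#' which model recovery is judged: its surfaces are plain R closures and can
#' be evaluated at arbitrary coordinates.
#'
#' Each species' linear predictor is
#' `eta = year_effect[year] + spatial_surface(lon, lat) + depth_response(z) + temp_response(T)`;
#' presence probability is `plogis(presence_offset + eta)` and the mean of
#' log CPUE (given presence) is `cpue_offset + eta`, with log-scale residual
#' SD `cpue_sd`.
#'
#' @param years integer vector of survey years.
#' @param extent numeric length 4: `c(lon_min, lon_max, lat_min, lat_max)`
#'   in decimal degrees.
#' @param hauls_per_year positive integer, tows simulated per year.
#' @param species_params named list (one entry per species) of lists with
#'   elements `year_effects` (named numeric, one per year), `spatial_surface`
#'   (function of lon, lat), `depth_response` (function of depth, m),
#'   `temp_response` (function of temperature, deg C), `presence_offset`,
#'   `cpue_offset`, `cpue_sd` (> 0), `length_meanlog`, `length_sdlog`
#'   (lognormal fork-length distribution, cm), `lengths_per_haul` (mean
#'   number of fish measured per positive haul).
#' @param depth_field,temp_field functions of `(lon, lat, year)` giving
#'   bottom depth (m) and bottom temperature (deg C).
#' @param missing_covariate_rate fraction in `[0, 1)` of hauls with depth
#'   and/or temperature blanked, emulating incomplete field records.
#' @param subsample_max cap on fork lengths measured per species per haul.
#' @param seed integer seed governing all draws from this scenario.
#' @return an object of class `survey_scenario`.
#' @seealso [simulate_hauls()], [default_survey_scenario()]
#' @export
survey_scenario <- function(years, extent, hauls_per_year, species_params,
                            depth_field, temp_field,
                            missing_covariate_rate = 0,
                            subsample_max = 200L, seed = 1L) {
  stopifnot(length(extent) == 4, extent[1] < extent[2], extent[3] < extent[4],
            hauls_per_year >= 1, subsample_max <= 200L)
  if (!(missing_covariate_rate >= 0 && missing_covariate_rate < 1))
    stop("missing_covariate_rate must be in [0, 1)")
  for (sp in names(species_params)) {
    p <- species_params[[sp]]
    if (!is.null(p$cpue_sd) && p$cpue_sd <= 0)
      stop("cpue_sd must be > 0 for species ", sp)
    missing_years <- setdiff(as.character(years), names(p$year_effects))
    if (length(missing_years))
      stop("year_effects for species ", sp, " lacks years: ",
           paste(missing_years, collapse = ", "))
  }
  structure(
    list(years = as.integer(years), extent = as.numeric(extent),
         hauls_per_year = as.integer(hauls_per_year),
         species_params = species_params,
         depth_field = depth_field, temp_field = temp_field,
         missing_covariate_rate = missing_covariate_rate,
         subsample_max = as.integer(subsample_max), seed = as.integer(seed)),
    class = "survey_scenario")
}

#' @export
print.survey_scenario <- function(x, ...) {
  cat("<survey_scenario>\n")
  cat("  years:", paste(x$years, collapse = " "), "\n")
  cat(sprintf("  extent: lon [%.1f, %.1f], lat [%.1f, %.1f]\n",
              x$extent[1], x$extent[2], x$extent[3], x$extent[4]))
  cat("  hauls/year:", x$hauls_per_year,
      " species:", paste(names(x$species_params), collapse = ", "), "\n")
  cat("  missing covariate rate:", x$missing_covariate_rate,
      " seed:", x$seed, "\n")
  invisible(x)
}

#' Diet scenario: generative stomach-content compositions
#'
#' Specifies how synthetic stomach contents are drawn. Group-level
#' prey-weight compositions are indexed by predator species, longitudinal
#' region and protocol size class; individual non-empty stomachs draw their
#' composition from a Dirichlet distribution centred on the group mean with
#' the given concentration, so the expected pooled composition equals the
#' group mean while individual stomachs vary realistically.
#'
#' Composition keys are matched most-specific first:
#' `"species|region|sizeclass"`, then `"species|region"`, then `"species"`.
#' Size classes follow the at-sea sampling protocol: `"<31"`, `"31-50"`,
#' `"51-70"`, `">70"` (cm fork length).
#'
#' @param taxa character vector of prey-taxon names.
#' @param composition named list of probability vectors over `taxa`
#'   (each nonnegative, summing to 1 within 1e-9), keyed as described above.
#' @param empty_prob probability a sampled stomach is empty (fullness code 1).
#' @param stomachs_per_haul_cap stomachs sampled per haul, species and
#'   protocol size class (the field protocol caps this at 5).
#' @param weight_scale median total prey weight (g) of a non-empty stomach.
#' @param concentration Dirichlet concentration; larger values give
#'   stomachs closer to the group-mean composition.
#' @param haul_sampling_prob probability that a haul is worked up for
#'   diets at all; stomach sampling at sea covers only a fraction of tows,
#'   so diet data are much sparser than catch data.
#' @param region_breaks optional list `list(breaks =, labels =)` of ordered
#'   longitude breakpoints defining regions; `NULL` puts everything in one
#'   region `"all"`.
#' @param seed integer seed for the stomach-sampling stage.
#' @return an object of class `diet_scenario`.
#' @export
diet_scenario <- function(taxa, composition, empty_prob = 0.3,
                          stomachs_per_haul_cap = 5L, weight_scale = 10,
                          concentration = 20, haul_sampling_prob = 1,
                          region_breaks = NULL, seed = 1L) {
  stopifnot(empty_prob >= 0, empty_prob <= 1, weight_scale > 0,
            concentration > 0, stomachs_per_haul_cap >= 1,
            haul_sampling_prob > 0, haul_sampling_prob <= 1)
  for (key in names(composition)) {
    w <- composition[[key]]
    if (length(w) != length(taxa))
      stop("composition '", key, "' length != number of taxa")
    if (any(w < 0) || abs(sum(w) - 1) > 1e-9)
      stop("composition '", key, "' must be nonnegative and sum to 1 (got ",
           format(sum(w), digits = 12), ")")
  }
  structure(
    list(taxa = taxa, composition = composition, empty_prob = empty_prob,
         stomachs_per_haul_cap = as.integer(stomachs_per_haul_cap),
         weight_scale = weight_scale, concentration = concentration,
         haul_sampling_prob = haul_sampling_prob,
         region_breaks = region_breaks, seed = as.integer(seed)),
    class = "diet_scenario")
}

# protocol size class of a fork length (cm)
protocol_size_class <- function(fl) {
  cut(fl, breaks = c(-Inf, 30.5, 50.5, 70.5, Inf),
      labels = c("<31", "31-50", "51-70", ">70"), right = TRUE)
}

# most-specific-first composition lookup
comp_lookup <- function(ds, species, region, size_class) {
  for (key in c(paste(species, region, size_class, sep = "|"),
                paste(species, region, sep = "|"), species)) {
    if (!is.null(ds$composition[[key]])) return(ds$composition[[key]])
  }
  stop("no composition for species '", species, "', region '", region,
       "', size class '", size_class, "'")
}

diet_region_of <- function(ds, lon) {
  if (is.null(ds$region_breaks)) return(rep("all", length(lon)))
  rb <- ds$region_breaks
  idx <- findInterval(lon, rb$breaks)
  out <- rep(NA_character_, length(lon))
  ok <- idx >= 1 & idx <= length(rb$labels)
  out[ok] <- rb$labels[idx[ok]]
  out[!ok] <- "all"
  out
}

#' Default survey scenario for the Gulf-of-Alaska-like demonstration
#'
#' Two demersal flatfish predators, "PH" (shallow, cool, western affinity;
#' present in roughly 60% of tows) and "ATF" (near-ubiquitous, warmer and
#' deeper affinity), sampled over eight triennial survey years across a
#' 26-degree longitudinal shelf. Depth increases offshore (to the south)
#' and temperature increases eastward and decreases with depth, so the two
#' covariates are negatively correlated as in shelf surveys.
#'
#' @param hauls_per_year tows per year (default 2000).
#' @param years survey years (default eight, triennial from 1990).
#' @param missing_covariate_rate see [survey_scenario()].
#' @param seed integer seed.
#' @param temp_effect logical; set `FALSE` to generate data with no
#'   temperature effect for either species (used to study model selection
#'   when a covariate is truly absent).
#' @return a `survey_scenario`.
#' @export
default_survey_scenario <- function(hauls_per_year = 2000L,
                                    years = seq(1990L, 2011L, by = 3L),
                                    missing_covariate_rate = 0,
                                    seed = 1L, temp_effect = TRUE) {
  extent <- c(-160, -134, 54, 60)
  depth_field <- function(lon, lat, year) {
    40 + 420 * stats::plogis(2.2 * (57.2 - lat) + 0.05 * (lon + 147)) +
      25 * sin((lon + 160) * pi / 9)
  }
  temp_field <- function(lon, lat, year) {
    z <- depth_field(lon, lat, year)
    4.8 + 0.11 * (lon + 147) - 0.004 * (z - 150) +
      0.5 * sin(2 * pi * (year - 1990) / 7)
  }
  yrs <- as.character(years)
  ye <- function(amp) stats::setNames(amp * sin(seq_along(years) / 2), yrs)
  tr_ph <- if (temp_effect) function(T) -0.045 * (T - 5.5)^2 else function(T) 0 * T
  tr_atf <- if (temp_effect) function(T) 0.16 * (T - 5) else function(T) 0 * T
  species_params <- list(
    PH = list(
      year_effects = ye(0.35),
      spatial_surface = function(lon, lat) -0.09 * (lon + 147) +
        0.5 * cos((lat - 54) * pi / 6),
      depth_response = function(z) 1.9 * exp(-((z - 85) / 95)^2) - 0.6,
      temp_response = tr_ph,
      presence_offset = 0.55, cpue_offset = 1.1, cpue_sd = 0.9,
      length_meanlog = log(45), length_sdlog = 0.38, lengths_per_haul = 15),
    ATF = list(
      year_effects = ye(0.2),
      spatial_surface = function(lon, lat) 0.02 * (lon + 147) +
        0.25 * cos((lat - 56) * pi / 8),
      depth_response = function(z) 1.6 * exp(-((z - 240) / 190)^2) - 0.3,
      temp_response = tr_atf,
      presence_offset = 1.7, cpue_offset = 1.6, cpue_sd = 1.0,
      length_meanlog = log(42), length_sdlog = 0.30, lengths_per_haul = 15)
  )
  survey_scenario(years = years, extent = extent,
                  hauls_per_year = hauls_per_year,
                  species_params = species_params,
                  depth_field = depth_field, temp_field = temp_field,
                  missing_covariate_rate = missing_covariate_rate,
                  subsample_max = 200L, seed = seed)
}

#' Default diet scenario
#'
#' Eight prey taxa spanning fishes and benthic invertebrates. "PH" takes a
#' mixed fish/invertebrate diet; "ATF" is strongly piscivorous. With
#' `partitioning = FALSE` compositions do not vary in space, so spatial and
#' dietary overlap are generated independently. With `partitioning = TRUE`
#' the two predators' diets diverge in the western region (where their
#' spatial overlap under [default_survey_scenario()] is highest) and
#' converge in the east, building a negative spatial-dietary dependence
#' into the truth.
#'
#' Diet sampling covers only 20% of hauls by default, emulating the
#' sparseness of food-habits collections relative to catch records.
#'
#' @param partitioning logical, see Details.
#' @param empty_prob fraction of sampled stomachs that are empty.
#' @param concentration Dirichlet concentration of per-stomach compositions.
#' @param haul_sampling_prob fraction of hauls worked up for diets.
#' @param seed integer seed.
#' @return a `diet_scenario`.
#' @export
default_diet_scenario <- function(partitioning = FALSE, empty_prob = 0.3,
                                  concentration = 20,
                                  haul_sampling_prob = 0.2, seed = 1L) {
  taxa <- c("walleye_pollock", "pacific_herring", "capelin", "flatfish_unid",
            "tanner_crab", "pandalid_shrimp", "octopus", "polychaete")
  ph  <- c(0.22, 0.08, 0.05, 0.10, 0.28, 0.17, 0.05, 0.05)
  atf <- c(0.55, 0.12, 0.18, 0.08, 0.02, 0.04, 0.01, 0.00)
  comp <- list(PH = ph / sum(ph), ATF = atf / sum(atf))
  region_breaks <- NULL
  if (partitioning) {
    # west: near-disjoint diets; east: shared diet -> D high where S low
    ph_w  <- c(0.02, 0.01, 0.01, 0.04, 0.48, 0.34, 0.06, 0.04)
    atf_w <- c(0.62, 0.05, 0.25, 0.06, 0.00, 0.01, 0.01, 0.00)
    shared_e <- c(0.35, 0.30, 0.15, 0.10, 0.04, 0.04, 0.01, 0.01)
    comp <- list(
      `PH|west` = ph_w / sum(ph_w), `ATF|west` = atf_w / sum(atf_w),
      `PH|east` = shared_e / sum(shared_e),
      `ATF|east` = shared_e / sum(shared_e),
      PH = ph / sum(ph), ATF = atf / sum(atf))
    region_breaks <- list(breaks = c(-160, -147, -134),
                          labels = c("west", "east"))
  }
  diet_scenario(taxa = taxa, composition = comp, empty_prob = empty_prob,
                stomachs_per_haul_cap = 5L, weight_scale = 10,
                concentration = concentration,
                haul_sampling_prob = haul_sampling_prob,
                region_breaks = region_breaks, seed = seed)
}
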