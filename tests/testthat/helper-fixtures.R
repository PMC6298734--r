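# shared fixture builders; everything is generated in code at test time

# small two-species survey scenario (fast to simulate and fit)
tiny_survey <- function(hauls_per_year = 150, seed = 1, ...) {
  default_survey_scenario(hauls_per_year = hauls_per_year, seed = seed, ...)
}

# scenario with a spatially flat, covariate-free presence probability
flat_scenario <- function(p = 0.6, n = 10000, seed = 1,
                          missing_covariate_rate = 0) {
  sp <- list(
    X = list(year_effects = c(`2000` = 0),
             spatial_surface = function(lon, lat) 0 * lon,
             depth_response = function(z) 0 * z,
             temp_response = function(T) 0 * T,
             presence_offset = stats::qlogis(p), cpue_offset = 0.5,
             cpue_sd = 0.7, length_meanlog = log(45), length_sdlog = 0.3,
             lengths_per_haul = 10))
  survey_scenario(years = 2000, extent = c(-150, -140, 54, 58),
                  hauls_per_year = n, species_params = sp,
                  depth_field = function(lon, lat, year) 100 + 0 * lon,
                  temp_field = function(lon, lat, year) 5 + 0 * lon,
                  missing_covariate_rate = missing_covariate_rate,
                  seed = seed)
}

# a small, hand-sized prey-item table
tiny_diet_table <- function() {
  data.frame(
    haul_id = c("H1", "H1", "H1", "H2", "H2", "H3"),
    stomach_id = c("S1", "S1", "S2", "S3", "S3", "S4"),
    species = c("PH", "PH", "PH", "ATF", "ATF", "ATF"),
    fork_length = c(45, 45, 60, 40, 40, 35),
    fullness = c(4L, 4L, 1L, 5L, 5L, 3L),
    taxon = c("crab", "pollock", "", "pollock", "herring", "pollock"),
    weight_g = c(10, 30, 0, 5, 15, 8))
}

# random composition vector over the given taxa
rand_comp <- function(q, taxa = paste0("t", seq_len(q))) {
  w <- stats::rgamma(length(taxa), 1)
  stats::setNames(w / sum(w), taxa)
}

expand_counts_fixture <- function() {
  counts <- utils::read.csv(system.file("extdata", "goa_tow_counts.csv",
                                        package = "nichepart"))
  expand_tow_counts(counts, n_missing_covariates = 716)
}
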