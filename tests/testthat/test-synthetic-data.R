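test_that("identical scenario and seed give byte-identical outputs", {
  sc <- tiny_survey(hauls_per_year = 80, seed = 9)
  sim1 <- simulate_hauls(sc)
  sim2 <- simulate_hauls(sc)
  expect_identical(sim1$hauls, sim2$hauls)
  l1 <- simulate_lengths(sim1)
  l2 <- simulate_lengths(sim2)
  expect_identical(l1$specimens, l2$specimens)
  ds <- default_diet_scenario(seed = 4)
  expect_identical(simulate_stomachs(sim1, l1$specimens, ds),
                   simulate_stomachs(sim2, l2$specimens, ds))
})

test_that("hauls respect presence/CPUE coupling and the extent", {
  sim <- simulate_hauls(tiny_survey(hauls_per_year = 200, seed = 2))
  h <- sim$hauls
  for (cc in grep("^cpue_", names(h), value = TRUE)) {
    expect_true(all(h[[cc]] >= 0))
  }
  expect_true(all(h$lon >= -160 & h$lon <= -134))
  expect_true(all(h$lat >= 54 & h$lat <= 60))
})

test_that("empirical presence frequency matches a constant-probability truth", {
  p <- 0.6
  n <- 10000
  sim <- simulate_hauls(flat_scenario(p = p, n = n, seed = 3))
  freq <- mean(sim$hauls$cpue_X > 0)
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(freq - p), 3 * se)
  # the recorded truth is exactly the constant
  tr <- sim$truth$species$X$presence_prob(-145, 56, 100, 5, 2000)
  expect_equal(unname(tr), p, tolerance = 1e-12)
})

test_that("covariate blanking follows the configured rate", {
  sim0 <- simulate_hauls(flat_scenario(n = 2000, seed = 5,
                                       missing_covariate_rate = 0))
  expect_false(anyNA(sim0$hauls$depth) || anyNA(sim0$hauls$temp))
  sim <- simulate_hauls(flat_scenario(n = 5000, seed = 5,
                                      missing_covariate_rate = 0.2))
  miss <- is.na(sim$hauls$depth) | is.na(sim$hauls$temp)
  expect_lt(abs(mean(miss) - 0.2), 3 * sqrt(0.2 * 0.8 / 5000))
})

test_that("non-finite environmental fields fail with the offending coordinate", {
  sc <- flat_scenario(n = 10, seed = 1)
  sc$depth_field <- function(lon, lat, year) ifelse(lon < -145, NaN, 100)
  expect_error(simulate_hauls(sc), "non-finite environmental field at lon")
})

test_that("length subsamples track the lognormal truth", {
  # species absent everywhere -> empty specimen table
  sc <- flat_scenario(p = 1e-9, n = 200, seed = 6)
  sim <- simulate_hauls(sc)
  lens <- simulate_lengths(sim)
  expect_equal(nrow(lens$specimens), 0)

  # empirical in-range proportion within 3 binomial SEs of the truth
  sc2 <- flat_scenario(p = 1, n = 1000, seed = 7)
  sc2$species_params$X$lengths_per_haul <- 10
  sim2 <- simulate_hauls(sc2)
  lens2 <- simulate_lengths(sim2)
  p_true <- lens2$truth$X$in_range_prob
  inr <- lens2$specimens$fork_length >= 30 & lens2$specimens$fork_length <= 69
  n <- length(inr)
  expect_gt(n, 5000)
  expect_lt(abs(mean(inr) - p_true), 3 * sqrt(p_true * (1 - p_true) / n))

  # distribution wholly inside the window -> in-range probability ~ 1
  sc3 <- flat_scenario(p = 1, n = 50, seed = 8)
  sc3$species_params$X$length_meanlog <- log(45)
  sc3$species_params$X$length_sdlog <- 0.05
  l3 <- simulate_lengths(simulate_hauls(sc3))
  expect_gt(l3$truth$X$in_range_prob, 0.999)
  expect_true(all(l3$specimens$fork_length >= 30 &
                    l3$specimens$fork_length <= 69))
})

test_that("stomach protocol caps and empty-stomach flagging hold", {
  sc <- tiny_survey(hauls_per_year = 60, seed = 11)
  sim <- simulate_hauls(sc)
  lens <- simulate_lengths(sim)
  ds <- default_diet_scenario(seed = 2)
  st <- simulate_stomachs(sim, lens$specimens, ds)
  # cap: <= 5 stomachs per haul x species x protocol size class
  stom <- unique(st[, c("haul_id", "stomach_id", "species", "fork_length")])
  bin <- cut(stom$fork_length, c(-Inf, 30.5, 50.5, 70.5, Inf))
  counts <- table(paste(stom$haul_id, stom$species, bin))
  expect_true(all(counts <= 5))
  # empty stomachs carry fullness code 1 and zero weight
  empties <- st[st$fullness == 1, ]
  expect_true(all(empties$weight_g == 0 & empties$taxon == ""))
  expect_true(all(st$weight_g[st$fullness > 1] > 0))
})

test_that("all-empty and single-taxon diet scenarios behave as identities", {
  sc <- flat_scenario(p = 1, n = 40, seed = 12)
  sim <- simulate_hauls(sc)
  lens <- simulate_lengths(sim)
  ds_empty <- diet_scenario(taxa = c("a", "b"),
                            composition = list(X = c(0.5, 0.5)),
                            empty_prob = 1, seed = 1)
  st <- simulate_stomachs(sim, lens$specimens, ds_empty)
  expect_true(all(st$fullness == 1L))
  ds_one <- diet_scenario(taxa = c("a", "b"),
                          composition = list(X = c(1, 0)),
                          empty_prob = 0, seed = 1)
  st1 <- simulate_stomachs(sim, lens$specimens, ds_one)
  expect_true(all(st1$taxon == "a"))
})

test_that("pooled stomach composition converges to the scenario mean", {
  sc <- flat_scenario(p = 1, n = 600, seed = 13)
  sc$species_params$X$lengths_per_haul <- 8
  sim <- simulate_hauls(sc)
  lens <- simulate_lengths(sim)
  target <- c(0.5, 0.3, 0.2)
  ds <- diet_scenario(taxa = c("a", "b", "c"),
                      composition = list(X = target),
                      empty_prob = 0, concentration = 20, seed = 3)
  st <- simulate_stomachs(sim, lens$specimens, ds)
  expect_gt(length(unique(st$stomach_id)), 2000)
  w <- tapply(st$weight_g, st$taxon, sum)
  pooled <- as.numeric(w[c("a", "b", "c")] / sum(w))
  expect_true(all(abs(pooled - target) < 0.03))
})

test_that("invalid compositions are rejected at scenario construction", {
  expect_error(diet_scenario(taxa = c("a", "b"),
                             composition = list(X = c(0.6, 0.5))),
               "sum to 1")
  expect_error(diet_scenario(taxa = c("a", "b"),
                             composition = list(X = c(-0.1, 1.1))),
               "nonnegative")
})

test_that("truth surfaces are evaluable at arbitrary coordinates", {
  sim <- simulate_hauls(tiny_survey(hauls_per_year = 30, seed = 14))
  tr <- sim$truth$species$PH
  po <- tr$presence_prob(c(-150, -140), c(55, 58), c(100, 200), c(4, 6),
                         c(1990, 1993))
  expect_length(po, 2)
  expect_true(all(po > 0 & po < 1))
  env <- data.frame(year = 1990, cell_id = "c", lon = -150, lat = 55,
                    depth = 120, temp = 5)
  tp <- truth_predictions(sim, env)
  expect_equal(nrow(tp), 2)
  expect_true(all(tp$pa > 0))
})
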