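grid_fix <- function() build_grid(c(-160, -140, 54, 60), cell_size = 1e5)

hauls_fix <- function(n = 6) {
  data.frame(haul_id = paste0("H", 1:n), year = 1990,
             lon = -150, lat = 55, depth = 100, temp = 5)
}

# build a diet table with n_ph/n_atf non-empty stomachs in one haul
diet_fix <- function(n_ph, n_atf, taxon = "pollock") {
  mk <- function(sp, n, off)
    if (n == 0) NULL else
      data.frame(haul_id = "H1", stomach_id = paste0(sp, off + 1:n),
                 species = sp, fork_length = 45, fullness = 4L,
                 taxon = taxon, weight_g = 10)
  rbind(mk("PH", n_ph, 0), mk("ATF", n_atf, 100))
}

test_that("year-cell groups qualify only with enough non-empty stomachs of both predators", {
  g <- grid_fix()
  h <- hauls_fix()
  gs <- group_stomachs(diet_fix(3, 2), h, g, c("PH", "ATF"))
  expect_equal(nrow(gs$qualifying), 0)
  gs2 <- group_stomachs(diet_fix(3, 3), h, g, c("PH", "ATF"))
  expect_equal(nrow(gs2$qualifying), 1)
  # empty stomachs and out-of-range fish do not count
  d <- diet_fix(3, 3)
  d$fullness[d$stomach_id == "PH1"] <- 1L
  d$weight_g[d$stomach_id == "PH1"] <- 0
  gs3 <- group_stomachs(d, h, g, c("PH", "ATF"))
  expect_equal(nrow(gs3$qualifying), 0)
  d2 <- diet_fix(4, 3)
  d2$fork_length[d2$stomach_id == "PH1"] <- 75
  gs4 <- group_stomachs(d2, h, g, c("PH", "ATF"))
  expect_equal(nrow(gs4$qualifying), 1)
  expect_equal(gs4$counts$n_stomachs[gs4$counts$species == "PH"], 3L)
})

test_that("qualifying sets match a brute-force count oracle on random fixtures", {
  g <- grid_fix()
  set.seed(9)
  for (rep in 1:5) {
    n_h <- 40
    h <- data.frame(haul_id = paste0("H", 1:n_h),
                    year = sample(c(1990, 1993), n_h, TRUE),
                    lon = runif(n_h, -158, -142), lat = runif(n_h, 54.5, 59),
                    depth = 100, temp = 5)
    n_s <- 150
    d <- data.frame(haul_id = sample(h$haul_id, n_s, TRUE),
                    stomach_id = paste0("S", 1:n_s),
                    species = sample(c("PH", "ATF"), n_s, TRUE),
                    fork_length = sample(25:80, n_s, TRUE),
                    fullness = sample(c(1L, 3L, 5L), n_s, TRUE,
                                      prob = c(0.3, 0.4, 0.3)),
                    taxon = sample(c("a", "b"), n_s, TRUE),
                    weight_g = rlnorm(n_s))
    d$weight_g[d$fullness == 1] <- 0
    d$taxon[d$fullness == 1] <- ""
    gs <- group_stomachs(d, h, g, c("PH", "ATF"))
    # oracle: explicit scan
    dd <- merge(d, h[, c("haul_id", "year", "lon", "lat")], by = "haul_id")
    dd$cell <- locate_cell(dd$lon, dd$lat, g)
    dd <- dd[dd$fullness > 1 & dd$weight_g > 0 &
               dd$fork_length >= 30 & dd$fork_length <= 69, ]
    keys <- unique(paste(dd$year, dd$cell))
    oracle <- keys[vapply(keys, function(k) {
      sub <- dd[paste(dd$year, dd$cell) == k, ]
      length(unique(sub$stomach_id[sub$species == "PH"])) >= 3 &&
        length(unique(sub$stomach_id[sub$species == "ATF"])) >= 3
    }, logical(1))]
    expect_setequal(paste(gs$qualifying$year, gs$qualifying$cell_id), oracle)
  }
})

test_that("prey proportions pool weights and sum to one", {
  items <- data.frame(stomach_id = "S1", taxon = c("crab", "pollock"),
                      weight_g = c(10, 30))
  expect_equal(prey_proportions(items),
               c(crab = 0.25, pollock = 0.75))
  one <- data.frame(stomach_id = "S1", taxon = "crab", weight_g = 5)
  expect_equal(prey_proportions(one), c(crab = 1))
  expect_error(prey_proportions(one[0, ]), "zero total")
  set.seed(10)
  for (rep in 1:10) {
    n <- 50
    items <- data.frame(stomach_id = sample(paste0("S", 1:8), n, TRUE),
                        taxon = sample(letters[1:5], n, TRUE),
                        weight_g = rlnorm(n))
    w <- prey_proportions(items)
    oracle <- vapply(names(w), function(t)
      sum(items$weight_g[items$taxon == t]) / sum(items$weight_g), numeric(1))
    expect_equal(w, oracle, tolerance = 1e-12)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    # equal-stomach-weight variant also sums to 1
    w2 <- prey_proportions(items, "mean_of_stomachs")
    expect_equal(sum(w2), 1, tolerance = 1e-12)
  }
})

test_that("Schoener's D obeys its identities", {
  w <- rand_comp(4)
  expect_equal(schoener(w, w), 1)
  expect_equal(schoener(c(a = 1), c(b = 1)), 0)
  # hand evaluation of the formula
  expect_equal(schoener(c(x = 0.5, y = 0.5, z = 0),
                        c(x = 0.25, y = 0.25, z = 0.5)), 0.5)
  set.seed(11)
  for (rep in 1:20) {
    a <- rand_comp(sample(2:6, 1))
    b <- rand_comp(sample(2:6, 1), taxa = sample(letters[1:8], sample(2:6, 1)))
    d <- schoener(a, b)
    expect_gte(d, 0)
    expect_lte(d, 1)
    expect_equal(d, schoener(b, a))
    # D + half the L1 distance on the taxon union equals 1
    taxa <- union(names(a), names(b))
    av <- setNames(numeric(length(taxa)), taxa); av[names(a)] <- a
    bv <- setNames(numeric(length(taxa)), taxa); bv[names(b)] <- b
    expect_equal(d + 0.5 * sum(abs(av - bv)), 1, tolerance = 1e-12)
    # zero-padding with unobserved taxa leaves D unchanged
    a_pad <- c(a, zz = 0)
    expect_equal(schoener(a_pad, b), d)
  }
  expect_error(schoener(c(a = 0.7), c(a = 1)), "sum to 1")
})

test_that("diversity and evenness match their closed forms", {
  q <- 5
  u <- rep(1 / q, q)
  expect_equal(shannon(u), log(q), tolerance = 1e-12)
  expect_equal(pielou(u), 1, tolerance = 1e-12)
  expect_equal(shannon(c(1)), 0)
  expect_true(is.na(pielou(c(1))))
  expect_equal(shannon(c(0.5, 0.5)), log(2), tolerance = 1e-12)
  set.seed(12)
  for (rep in 1:10) {
    w <- rand_comp(sample(2:8, 1))
    h_oracle <- -sum(w[w > 0] * log(w[w > 0]))
    expect_equal(shannon(w), h_oracle, tolerance = 1e-12)
    expect_equal(pielou(w), h_oracle / log(sum(w > 0)), tolerance = 1e-12)
  }
})

test_that("gridded dietary overlap approaches 1 for identical generating diets", {
  # same composition for both predators; D rises toward 1 with group size
  g <- grid_fix()
  comp <- c(0.4, 0.3, 0.2, 0.1)
  d_of_n <- vapply(c(3, 10, 100), function(n) {
    set.seed(n)
    mk <- function(sp) {
      do.call(rbind, lapply(1:n, function(i) {
        w <- as.numeric(stats::rgamma(4, 25 * comp))
        data.frame(haul_id = "H1", stomach_id = paste0(sp, i), species = sp,
                   fork_length = 45, fullness = 4L,
                   taxon = paste0("t", 1:4), weight_g = w)
      }))
    }
    gs <- group_stomachs(rbind(mk("PH"), mk("ATF")), hauls_fix(1), g,
                         c("PH", "ATF"))
    dietary_overlap(gs, c("PH", "ATF"))$D
  }, numeric(1))
  expect_true(all(diff(d_of_n) > 0))
  expect_gt(d_of_n[3], 0.95)
})

test_that("rarefaction curves are monotone with the exact endpoint", {
  set.seed(13)
  n_st <- 25
  d <- data.frame(haul_id = "H1", stomach_id = rep(paste0("S", 1:n_st), 2),
                  species = "PH", fork_length = 45, fullness = 4L,
                  taxon = c(sample(letters[1:6], n_st, TRUE),
                            sample(letters[1:6], n_st, TRUE)),
                  weight_g = rlnorm(2 * n_st))
  rc <- rarefaction(d, "PH", n_resamples = 200, seed = 7)
  expect_true(all(diff(rc$mean_taxa) >= 0))
  expect_equal(rc$mean_taxa[n_st], length(unique(d$taxon)))
  expect_true(all(rc$lo <= rc$hi))
  expect_true(all(rc$mean_taxa >= 1 & rc$mean_taxa <= length(unique(d$taxon))))
  # single shared taxon -> flat curve at 1
  d1 <- d
  d1$taxon <- "a"
  rc1 <- rarefaction(d1, "PH", n_resamples = 20, seed = 1)
  expect_true(all(rc1$mean_taxa == 1))
  # matches vegan's analytic sample-based accumulation within MC error
  inc <- table(d$stomach_id, d$taxon) > 0
  exact <- vegan::specaccum(inc * 1, method = "exact")
  expect_lt(max(abs(rc$mean_taxa - exact$richness)), 0.2)
})

test_that("rare-taxon folding preserves mass and respects the threshold", {
  comp <- data.frame(
    species = "PH", area = "west", size_class = "30-39",
    taxon = c("t_big", "t_small1", "t_small2"),
    W = c(0.985, 0.005, 0.01), n_stomachs = 10L)
  taxonomy <- data.frame(taxon = c("t_big", "t_small1", "t_small2"),
                         broad_group = c("G1", "G2", "G2"))
  # threshold 0: identity
  out0 <- aggregate_rare_taxa(comp, taxonomy, threshold = 0)
  expect_setequal(out0$taxon, comp$taxon)
  out <- aggregate_rare_taxa(comp, taxonomy, threshold = 0.02)
  expect_setequal(out$taxon, c("t_big", "G2"))
  expect_equal(sum(out$W), 1, tolerance = 1e-12)
  expect_equal(out$W[out$taxon == "G2"], 0.015, tolerance = 1e-12)
  # all taxa rare and in one broad group -> single entry with W = 1
  comp2 <- data.frame(species = "PH", area = "west", size_class = "30-39",
                      taxon = paste0("t", 1:4), W = rep(0.25, 4),
                      n_stomachs = 5L)
  tax2 <- data.frame(taxon = paste0("t", 1:4), broad_group = "G")
  out2 <- aggregate_rare_taxa(comp2, tax2, threshold = 0.5)
  expect_equal(out2$taxon, "G")
  expect_equal(out2$W, 1)
  # unknown taxon folds into "other" with a warning
  tax3 <- taxonomy[-2, ]
  expect_warning(out3 <- aggregate_rare_taxa(comp, tax3, threshold = 0.02),
                 "other")
  expect_true("other" %in% out3$taxon)
})

test_that("size-class composition tables cover the analysis bins", {
  sim <- simulate_hauls(tiny_survey(hauls_per_year = 80, seed = 15))
  lens <- simulate_lengths(sim)
  st <- simulate_stomachs(sim, lens$specimens,
                          default_diet_scenario(seed = 5))
  comp <- size_class_compositions(st, sim$hauls)
  expect_true(all(comp$size_class %in% c("30-39", "40-49", "50-59", "60-69")))
  sums <- aggregate(W ~ species + area + size_class, comp, sum)
  expect_true(all(abs(sums$W - 1) < 1e-9))
})
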