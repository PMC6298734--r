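test_that("ANCOVA is null when groups are exact copies", {
  set.seed(14)
  base <- rnorm(10)
  d <- expand.grid(rep = 1:10, area = c("w", "e"), year = c(1990, 1993, 1996))
  d$v <- base[d$rep]  # identical across areas and years
  res <- overlap_ancova(d$v, d$area, d$year)
  expect_lt(res$interaction$F, 1e-10)
  expect_true(all(res$main_effects$F < 1e-10))
  expect_true(all(res$main_effects$p > 0.999))
})

test_that("sequential-SS F statistics reproduce a nested-RSS oracle", {
  set.seed(15)
  for (year_as in c("factor", "numeric")) {
    for (rep in 1:5) {
      n <- 60
      area <- factor(sample(c("a", "b", "c"), n, TRUE))
      year <- sample(c(1990, 1993, 1996, 1999), n, TRUE)
      v <- rnorm(n) + as.numeric(area) * 0.3 + 0.05 * (year - 1990)
      res <- overlap_ancova(v, area, year, year_as = year_as)
      yr <- if (year_as == "factor") factor(year) else year
      rss <- function(f) sum(resid(lm(f))^2)
      dfree <- function(f) lm(f)$df.residual
      # main-effects stage, area entered first
      r0 <- rss(v ~ 1); r1 <- rss(v ~ area); r2 <- rss(v ~ area + yr)
      df_area <- dfree(v ~ 1) - dfree(v ~ area)
      df_yr <- dfree(v ~ area) - dfree(v ~ area + yr)
      ms_res <- r2 / dfree(v ~ area + yr)
      expect_equal(res$main_effects$F[1], ((r0 - r1) / df_area) / ms_res,
                   tolerance = 1e-8)
      expect_equal(res$main_effects$F[2], ((r1 - r2) / df_yr) / ms_res,
                   tolerance = 1e-8)
      # interaction stage
      r3 <- rss(v ~ area * yr)
      df_int <- dfree(v ~ area + yr) - dfree(v ~ area * yr)
      expect_equal(res$interaction$F,
                   ((r2 - r3) / df_int) / (r3 / dfree(v ~ area * yr)),
                   tolerance = 1e-8)
    }
  }
})

test_that("a pure area shift with a common trend is detected as such", {
  set.seed(16)
  n <- 200
  area <- factor(sample(c("w", "e"), n, TRUE))
  year <- sample(seq(1990, 2011, 3), n, TRUE)
  v <- 0.01 * (year - 1990) + ifelse(area == "w", 0.5, 0) + rnorm(n, sd = 0.2)
  res <- overlap_ancova(v, area, year, year_as = "numeric")
  expect_gt(res$interaction$p, 0.1)
  expect_lt(res$main_effects$p[res$main_effects$term == "area"], 1e-6)
})

test_that("Tukey HSD agrees with the studentized-range oracle", {
  # identical group means -> adjusted p near 1
  set.seed(17)
  v <- rep(rnorm(10), 3)
  g <- rep(c("a", "b", "c"), each = 10)
  tk <- tukey_hsd(v, g)
  expect_true(all(tk$p_adj > 0.999))
  expect_true(all(abs(tk$diff) < 1e-12))
  # two groups: adjusted p equals the pooled-variance t-test p (q = t*sqrt(2))
  v2 <- rnorm(24)
  g2 <- rep(c("a", "b"), each = 12)
  tk2 <- tukey_hsd(v2, g2)
  tt <- t.test(v2 ~ g2, var.equal = TRUE)
  expect_equal(tk2$p_adj, tt$p.value, tolerance = 1e-10)
  # three unbalanced groups against an explicit ptukey computation
  v3 <- rnorm(40, mean = rep(c(0, 0.5, 1), length.out = 40))
  g3 <- factor(rep(c("a", "b", "c"), length.out = 40))
  tk3 <- tukey_hsd(v3, g3)
  fit <- aov(v3 ~ g3)
  mse <- sum(resid(fit)^2) / fit$df.residual
  means <- tapply(v3, g3, mean)
  ns <- table(g3)
  for (i in seq_len(nrow(tk3))) {
    pair <- strsplit(tk3$contrast[i], "-")[[1]]
    se <- sqrt(mse / 2 * (1 / ns[pair[1]] + 1 / ns[pair[2]]))
    q <- abs(means[pair[1]] - means[pair[2]]) / se
    p_oracle <- ptukey(q, nmeans = 3, df = fit$df.residual,
                       lower.tail = FALSE)
    expect_equal(tk3$p_adj[i], unname(p_oracle), tolerance = 1e-8)
  }
  expect_error(tukey_hsd(c(1, 2, 3), c("a", "a", "b")), "at least two")
})

test_that("the Pearson partitioning test matches the textbook formulas", {
  # collinear pairs
  p <- data.frame(S = 1:10 / 10, D = 2 * (1:10) / 10)
  res <- pearson_partitioning(p)
  expect_equal(res$r, 1, tolerance = 1e-12)
  # degenerate: constant D flagged, not crashed
  p2 <- data.frame(S = runif(10), D = rep(0.3, 10))
  res2 <- pearson_partitioning(p2)
  expect_true(is.na(res2$r))
  expect_match(res2$note, "zero variance")
  set.seed(18)
  for (rep in 1:20) {
    n <- sample(5:60, 1)
    p <- data.frame(S = runif(n), D = runif(n))
    res <- pearson_partitioning(p)
    sx <- p$S - mean(p$S); sy <- p$D - mean(p$D)
    r_oracle <- sum(sx * sy) / sqrt(sum(sx^2) * sum(sy^2))
    t_oracle <- r_oracle * sqrt((n - 2) / (1 - r_oracle^2))
    expect_equal(res$r, r_oracle, tolerance = 1e-12)
    expect_equal(res$t, t_oracle, tolerance = 1e-12)
    expect_equal(res$df, n - 2)
    expect_equal(res$p, 2 * pt(abs(t_oracle), n - 2, lower.tail = FALSE),
                 tolerance = 1e-12)
    # t-r identity
    expect_lt(abs(res$t - res$r * sqrt(res$df / (1 - res$r^2))), 1e-9)
  }
})

test_that("per-area grouping returns one result per area", {
  set.seed(19)
  p <- data.frame(S = runif(30), D = runif(30))
  area <- rep(c("w", "c", "e"), each = 10)
  res <- pearson_partitioning(p, "area", area = area)
  expect_setequal(res$group, c("w", "c", "e"))
  expect_true(all(res$n == 10))
})

test_that("a generated negative S-D dependence is recovered; independence is not", {
  set.seed(20)
  n <- 200
  S <- runif(n)
  D <- pmax(pmin(0.8 - 0.6 * S + rnorm(n, sd = 0.15), 1), 0)
  res <- pearson_partitioning(data.frame(S = S, D = D))
  expect_lt(res$r, 0)
  expect_lt(res$p, 0.1)
  res0 <- pearson_partitioning(data.frame(S = runif(n), D = runif(n)))
  expect_gt(abs(res0$r), 0)  # defined
  expect_lt(abs(res0$r), 0.25)
})

test_that("annual summaries equal a group-by oracle", {
  s <- data.frame(year = c(1990, 1990, 1993), S = c(0.2, 0.4, 0.3))
  d <- data.frame(year = c(1990), D = c(0.5))
  a <- annual_summary(s, d)
  expect_equal(a$mean[a$index == "S" & a$year == 1990], 0.3)
  expect_equal(a$sd[a$index == "S" & a$year == 1990], sd(c(0.2, 0.4)))
  # single value: NA sd and a degenerate interval
  row_d <- a[a$index == "D", ]
  expect_true(is.na(row_d$sd))
  expect_equal(row_d$lo, row_d$hi)
  # constant field: zero sd
  s2 <- data.frame(year = rep(1990, 5), S = rep(0.7, 5))
  a2 <- annual_summary(s2)
  expect_equal(a2$sd, 0)
  expect_equal(a2$mean, 0.7)
  set.seed(21)
  s3 <- data.frame(year = sample(c(1990, 1993, 1996), 50, TRUE),
                   S = runif(50))
  a3 <- annual_summary(s3)
  for (y in unique(s3$year)) {
    v <- s3$S[s3$year == y]
    expect_equal(a3$mean[a3$year == y & a3$index == "S"], mean(v))
    expect_equal(a3$n[a3$year == y & a3$index == "S"], length(v))
  }
})
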