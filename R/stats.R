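#' ANCOVA of an overlap index on area and survey year
#'
#' Two-stage analysis with sequential (type-I) sums of squares. Stage 1
#' tests the area x year interaction; stage 2 drops the interaction and
#' reports the main effects, with area entered before year. Year enters as
#' a factor by default (each survey year its own level, matching the
#' fitted degrees of freedom of the original analysis); `year_as =
#' "numeric"` treats it as a continuous covariate instead.
#'
#' @param values numeric overlap values (one per year-cell).
#' @param area factor or character of area labels.
#' @param year survey years.
#' @param alpha significance level for the flags (default 0.1).
#' @param year_as `"factor"` (default) or `"numeric"`.
#' @return object of class `ancova_result`: list with `interaction` and
#'   `main_effects` data.frames of `term`, `df`, `df_resid`, `F`, `p`,
#'   `significant`, plus the two `lm` fits.
#' @export
overlap_ancova <- function(values, area, year, alpha = 0.1,
                           year_as = c("factor", "numeric")) {
  year_as <- match.arg(year_as)
  area <- factor(area)
  if (nlevels(area) < 2) stop("need at least two areas")
  if (length(unique(year)) < 2) stop("need at least two years")
  yr <- if (year_as == "factor") factor(year) else as.numeric(year)
  dat <- data.frame(v = values, area = area, yr = yr)
  fit1 <- stats::lm(v ~ area * yr, data = dat)
  if (any(is.na(stats::coef(fit1)[grep("^area[^:]*$|^yr", names(stats::coef(fit1)))])))
    stop("rank-deficient design: some area/year combinations unestimable")
  an1 <- stats::anova(fit1)
  fit2 <- stats::lm(v ~ area + yr, data = dat)
  an2 <- stats::anova(fit2)
  row_of <- function(an, term) {
    i <- which(rownames(an) == term)
    data.frame(term = term, df = an$Df[i],
               df_resid = an$Df[nrow(an)],
               F = an$`F value`[i], p = an$`Pr(>F)`[i],
               significant = an$`Pr(>F)`[i] < alpha)
  }
  structure(list(
    interaction = row_of(an1, "area:yr"),
    main_effects = rbind(row_of(an2, "area"), row_of(an2, "yr")),
    alpha = alpha, year_as = year_as,
    fit_interaction = fit1, fit_main = fit2),
    class = "ancova_result")
}

#' @export
print.ancova_result <- function(x, ...) {
  cat("<ancova_result> sequential SS, alpha =", x$alpha,
      ", year as", x$year_as, "\n")
  cat("interaction stage:\n")
  print(x$interaction, row.names = FALSE)
  cat("main-effects stage:\n")
  print(x$main_effects, row.names = FALSE)
  invisible(x)
}

#' Tukey HSD pairwise area contrasts
#'
#' Post hoc comparisons of area means using the studentized-range
#' distribution, applied when the ANCOVA flags a significant area effect.
#'
#' @param values numeric overlap values.
#' @param area area labels (>= 2 groups, each with n >= 2).
#' @return data.frame `contrast`, `diff`, `lwr`, `upr`, `p_adj`.
#' @export
tukey_hsd <- function(values, area) {
  area <- factor(area)
  if (nlevels(area) < 2) stop("need at least two groups")
  if (any(table(area) < 2))
    stop("every group needs at least two observations")
  tk <- stats::TukeyHSD(stats::aov(values ~ area))$area
  data.frame(contrast = rownames(tk), diff = tk[, "diff"],
             lwr = tk[, "lwr"], upr = tk[, "upr"],
             p_adj = tk[, "p adj"], row.names = NULL)
}

#' Pearson correlation between spatial and dietary overlap
#'
#' The resource-partitioning test: a significantly negative correlation
#' between the spatial overlap index S and the dietary overlap index D
#' across year-cells indicates partitioning. Year-cells lacking either
#' index are excluded before calling this. Degrees of freedom are
#' `n - 2`; p-values are two-sided.
#'
#' @param pairs data.frame with columns `S` and `D` (one row per
#'   year-cell), optionally an area column for `grouping = "area"`.
#' @param grouping `"basin"` (all pairs pooled) or `"area"`.
#' @param area area labels (required for `grouping = "area"`).
#' @return data.frame `group`, `n`, `r`, `df`, `t`, `p`, `note`; a group
#'   with fewer than 3 pairs or zero variance in either index yields `NA`
#'   statistics with an explanatory note.
#' @export
pearson_partitioning <- function(pairs, grouping = c("basin", "area"),
                                 area = NULL) {
  grouping <- match.arg(grouping)
  one <- function(g, label) {
    n <- nrow(g)
    if (n < 3)
      return(data.frame(group = label, n = n, r = NA_real_, df = NA_real_,
                        t = NA_real_, p = NA_real_, note = "fewer than 3 pairs"))
    if (stats::sd(g$S) == 0 || stats::sd(g$D) == 0)
      return(data.frame(group = label, n = n, r = NA_real_, df = NA_real_,
                        t = NA_real_, p = NA_real_,
                        note = "zero variance; correlation undefined"))
    ct <- stats::cor.test(g$S, g$D, method = "pearson")
    data.frame(group = label, n = n, r = unname(ct$estimate),
               df = unname(ct$parameter), t = unname(ct$statistic),
               p = ct$p.value, note = "")
  }
  if (grouping == "basin") return(one(pairs, "basin"))
  if (is.null(area)) stop("grouping = 'area' requires area labels")
  out <- do.call(rbind, lapply(split(seq_len(nrow(pairs)), area), function(i)
    one(pairs[i, , drop = FALSE], unique(as.character(area[i])))))
  rownames(out) <- NULL
  out
}

#' Annual summaries of the overlap indices
#'
#' Per-year mean, SD and normal-approximation 95% confidence interval for
#' each index on its available year-cell set. A year with a single value
#' has `sd = NA` and a degenerate interval at the mean.
#'
#' @param s_field data.frame with `year` and `S`.
#' @param d_field data.frame with `year` and `D` (may be `NULL`).
#' @return data.frame `index`, `year`, `n`, `mean`, `sd`, `lo`, `hi`.
#' @export
annual_summary <- function(s_field, d_field = NULL) {
  one <- function(df, col) {
    do.call(rbind, lapply(split(df[[col]], df$year), function(v) {
      n <- length(v)
      m <- mean(v)
      s <- if (n > 1) stats::sd(v) else NA_real_
      half <- if (n > 1) 1.96 * s / sqrt(n) else 0
      data.frame(index = col, n = n, mean = m, sd = s,
                 lo = m - half, hi = m + half)
    }))
  }
  a <- one(s_field, "S")
  a$year <- as.integer(rownames(a))
  if (!is.null(d_field) && nrow(d_field)) {
    b <- one(d_field, "D")
    b$year <- as.integer(rownames(b))
    a <- rbind(a, b)
  }
  rownames(a) <- NULL
  a[, c("index", "year", "n", "mean", "sd", "lo", "hi")]
}
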