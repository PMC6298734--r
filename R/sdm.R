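#' Specify one stage of the delta model
#'
#' The delta (hurdle) species distribution model has two stages: a binomial
#' GAM with a logit link for presence/absence, and a Gaussian GAM with an
#' identity link for natural-log CPUE where the species is present. Both
#' stages share the same candidate terms: survey year as a categorical
#' fixed factor, a bivariate thin-plate smooth of (lon, lat), and
#' univariate smooths of depth and bottom temperature. Smoothness is
#' chosen by generalized cross-validation. The temperature smooth basis is
#' fixed at dimension 4 to avoid over-fitting; depth and the bivariate
#' location term get generous defaults and are shrunk by the smoothing
#' penalty.
#'
#' @param response `"presence"` or `"log_cpue"`.
#' @param terms subset of `c("year", "lonlat", "depth", "temp")`; an
#'   intercept is always included.
#' @param k_depth,k_lonlat basis dimensions for the depth and location
#'   smooths (defaults 10 and 30).
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(response = c("presence", "log_cpue"),
                       terms = c("year", "lonlat", "depth", "temp"),
                       k_depth = 10, k_lonlat = 30) {
  response <- match.arg(response)
  allowed <- c("year", "lonlat", "depth", "temp")
  if (length(terms) && !all(terms %in% allowed))
    stop("terms must be a subset of: ", paste(allowed, collapse = ", "))
  structure(list(response = response, terms = unique(terms),
                 k = list(depth = k_depth, lonlat = k_lonlat, temp = 4)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", x$response, "~",
      if (length(x$terms)) paste(x$terms, collapse = " + ") else "1", "\n")
  invisible(x)
}

spec_formula <- function(spec, lhs) {
  parts <- character()
  if ("year" %in% spec$terms) parts <- c(parts, "year_f")
  if ("lonlat" %in% spec$terms)
    parts <- c(parts, sprintf("s(lon, lat, k = %d)", spec$k$lonlat))
  if ("depth" %in% spec$terms)
    parts <- c(parts, sprintf("s(depth, k = %d)", spec$k$depth))
  if ("temp" %in% spec$terms)
    parts <- c(parts, sprintf("s(temp, k = %d)", spec$k$temp))
  if (!length(parts)) parts <- "1"
  stats::as.formula(paste(lhs, "~", paste(parts, collapse = " + ")),
                    env = globalenv())
}

check_covariates <- function(data, spec) {
  need <- c("lon", "lat", "depth", "temp", "year")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("data lacks column(s): ", paste(miss, collapse = ", "))
  if (anyNA(data[need]))
    stop("data has missing covariates; run filter_complete_covariates() first")
}

new_gam_fit <- function(model, spec) {
  sm <- summary(model)
  structure(
    list(model = model, spec = spec,
         dev_expl = unname(sm$dev.expl * 100),
         df = sum(model$edf),
         logLik = as.numeric(stats::logLik(model)),
         aic = stats::AIC(model),
         gcv = unname(model$gcv.ubre),
         sigma = if (spec$response == "log_cpue") sqrt(model$sig2) else NA_real_,
         year_levels = levels(model$model$year_f)),
    class = "gam_fit")
}

#' @export
print.gam_fit <- function(x, ...) {
  cat("<gam_fit>", x$spec$response, "~",
      if (length(x$spec$terms)) paste(x$spec$terms, collapse = " + ") else "1",
      "\n")
  cat(sprintf("  dev. explained %.1f%%, edf %.1f, logLik %.1f, AIC %.1f, GCV/UBRE %.4g\n",
              x$dev_expl, x$df, x$logLik, x$aic, x$gcv))
  if (!is.na(x$sigma)) cat(sprintf("  residual SD (log scale) %.3f\n", x$sigma))
  invisible(x)
}

#' Fit the presence/absence stage
#'
#' Binomial GAM with a logit link; smoothing penalties chosen by GCV/UBRE.
#'
#' @param data data.frame with `presence` (0/1), `year`, `lon`, `lat`,
#'   `depth`, `temp`; covariates must be complete.
#' @param spec a [model_spec()] with `response = "presence"`.
#' @return a `gam_fit`.
#' @export
fit_presence <- function(data, spec = model_spec("presence")) {
  stopifnot(spec$response == "presence")
  check_covariates(data, spec)
  if (length(unique(data$presence)) < 2)
    stop("presence response has a single class (all ",
         unique(data$presence)[1], "); cannot fit the binomial stage")
  data$year_f <- factor(data$year)
  m <- mgcv::gam(spec_formula(spec, "presence"), data = data,
                 family = stats::binomial(link = "logit"),
                 method = "GCV.Cp")
  new_gam_fit(m, spec)
}

#' Fit the positive-catch stage on natural-log CPUE
#'
#' Gaussian GAM with identity link on `log(adj_cpue)`, restricted to hauls
#' where the species was present.
#'
#' @param data data.frame of positive hauls with `adj_cpue` (> 0) and the
#'   covariates.
#' @param spec a [model_spec()] with `response = "log_cpue"`.
#' @return a `gam_fit` (with `sigma`, the log-scale residual SD).
#' @export
fit_log_cpue <- function(data, spec = model_spec("log_cpue")) {
  stopifnot(spec$response == "log_cpue")
  check_covariates(data, spec)
  if (any(data$adj_cpue <= 0))
    stop("fit_log_cpue requires adj_cpue > 0 for every row (found ",
         sum(data$adj_cpue <= 0), " nonpositive)")
  data$year_f <- factor(data$year)
  data$log_cpue <- log(data$adj_cpue)
  m <- mgcv::gam(spec_formula(spec, "log_cpue"), data = data,
                 family = stats::gaussian(), method = "GCV.Cp")
  new_gam_fit(m, spec)
}

fit_stage <- function(data, spec) {
  if (spec$response == "presence") fit_presence(data, spec)
  else fit_log_cpue(data, spec)
}

#' All-subsets AIC model selection
#'
#' Fits every subset of the full specification's terms (the intercept is
#' always retained) and tabulates deviance explained, effective degrees of
#' freedom, log likelihood, AIC difference from the best model, Akaike
#' weights, and the GCV/UBRE score, sorted by AIC. A failed candidate fit
#' is recorded as a row of `NA`s rather than aborting the table.
#'
#' @param data data for the stage (see [fit_presence()] / [fit_log_cpue()]).
#' @param full_spec the full [model_spec()]; its terms define the
#'   candidate set (at most `2^4` models).
#' @return a `model_table`: data.frame with one indicator column per
#'   candidate term plus `dev_expl`, `df`, `logLik`, `AIC`, `dAIC`,
#'   `weight`, `gcv`. The fitted models ride along as
#'   `attr(, "fits")` and their specs as `attr(, "specs")`.
#' @export
dredge_aic <- function(data, full_spec) {
  terms <- full_spec$terms
  n_t <- length(terms)
  subsets <- lapply(seq_len(2^n_t) - 1L, function(m) {
    terms[bitwAnd(m, 2^(seq_len(n_t) - 1L)) > 0]
  })
  fits <- vector("list", length(subsets))
  rows <- vector("list", length(subsets))
  specs <- vector("list", length(subsets))
  for (i in seq_along(subsets)) {
    spec_i <- model_spec(full_spec$response, subsets[[i]],
                         k_depth = full_spec$k$depth,
                         k_lonlat = full_spec$k$lonlat)
    specs[[i]] <- spec_i
    ind <- as.data.frame(as.list(stats::setNames(
      terms %in% subsets[[i]], terms)))
    fit <- tryCatch(fit_stage(data, spec_i), error = function(e) e)
    row <- if (inherits(fit, "error")) {
      data.frame(dev_expl = NA_real_, df = NA_real_, logLik = NA_real_,
                 AIC = NA_real_, gcv = NA_real_,
                 note = conditionMessage(fit))
    } else {
      fits[[i]] <- fit
      data.frame(dev_expl = fit$dev_expl, df = fit$df, logLik = fit$logLik,
                 AIC = fit$aic, gcv = fit$gcv, note = "")
    }
    rows[[i]] <- if (n_t > 0) cbind(ind, row) else row
  }
  tab <- do.call(rbind, rows)
  tab$dAIC <- tab$AIC - min(tab$AIC, na.rm = TRUE)
  rel <- exp(-tab$dAIC / 2)
  tab$weight <- rel / sum(rel, na.rm = TRUE)
  ord <- order(tab$AIC)
  tab <- tab[ord, c(terms, "dev_expl", "df", "logLik", "dAIC", "weight",
                    "gcv", "AIC", "note")]
  rownames(tab) <- NULL
  structure(tab, fits = fits[ord], specs = specs[ord],
            class = c("model_table", "data.frame"))
}

#' Pick a model from an all-subsets table
#'
#' `"min_aic"` returns the specification with the lowest AIC. `"force_full"`
#' returns the model containing every candidate term regardless of its AIC
#' rank — used when consistency of covariates across species and response
#' types is preferred over strict parsimony.
#'
#' @param table a `model_table` from [dredge_aic()].
#' @param policy `"min_aic"` or `"force_full"`.
#' @return list with `spec` (the chosen [model_spec()]), `fit` (its
#'   `gam_fit`, if that candidate fitted) and `row` (its table row).
#' @export
select_best <- function(table, policy = c("min_aic", "force_full")) {
  policy <- match.arg(policy)
  stopifnot(inherits(table, "model_table"), nrow(table) > 0)
  specs <- attr(table, "specs")
  term_cols <- setdiff(names(table), c("dev_expl", "df", "logLik", "dAIC",
                                       "weight", "gcv", "AIC", "note"))
  i <- if (policy == "min_aic") {
    which.min(table$AIC)
  } else {
    full <- which(rowSums(as.matrix(table[term_cols])) == length(term_cols))
    if (!length(full)) stop("no full model in table")
    full[1]
  }
  list(spec = specs[[i]], fit = attr(table, "fits")[[i]],
       row = table[i, , drop = FALSE])
}

check_predict_input <- function(fit, newdata) {
  check_covariates(newdata, fit$spec)
  if ("year" %in% fit$spec$terms) {
    unseen <- setdiff(as.character(newdata$year), fit$year_levels)
    if (length(unseen))
      stop("year level(s) not seen in training: ",
           paste(unseen, collapse = ", "))
  }
  newdata$year_f <- factor(as.character(newdata$year),
                           levels = fit$year_levels)
  newdata
}

#' Predict occurrence probability and positive-catch abundance
#'
#' `predict_occurrence` returns the inverse-logit of the presence linear
#' predictor, in (0, 1). `predict_abundance` returns `exp()` of the
#' predicted log CPUE. No lognormal bias correction is applied: downstream
#' the abundance field is divided by a per-species statistic, so any
#' constant multiplicative correction cancels exactly.
#'
#' @param fit a `gam_fit` of the matching stage.
#' @param newdata data.frame with complete `year`, `lon`, `lat`, `depth`,
#'   `temp`; all year levels must have been seen in training.
#' @return numeric vector, one value per row of `newdata`.
#' @export
predict_occurrence <- function(fit, newdata) {
  stopifnot(inherits(fit, "gam_fit"), fit$spec$response == "presence")
  nd <- check_predict_input(fit, newdata)
  as.numeric(mgcv::predict.gam(fit$model, newdata = nd, type = "response"))
}

#' @rdname predict_occurrence
#' @export
predict_abundance <- function(fit, newdata) {
  stopifnot(inherits(fit, "gam_fit"), fit$spec$response == "log_cpue")
  nd <- check_predict_input(fit, newdata)
  exp(as.numeric(mgcv::predict.gam(fit$model, newdata = nd)))
}
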