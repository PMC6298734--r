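#' @title Reading the survey tables
#' @description
#' The pipeline reads three plain CSV tables. Missing values are encoded as
#' empty fields. Columns beyond those documented are ignored with a warning.
#'
#' * haul table: `haul_id`, `year`, `lon`, `lat`, `depth` (m, may be blank),
#'   `temp` (deg C, may be blank), and one `cpue_<species>` column per
#'   species (number/ha).
#' * specimen table: `haul_id`, `species`, `fork_length` (cm).
#' * diet table: one row per prey item: `haul_id`, `stomach_id`, `species`,
#'   `fork_length` (cm), `fullness` (1-7; 1 = empty), `taxon`,
#'   `weight_g` (g). An empty stomach is a single row with blank `taxon`
#'   and `weight_g = 0`.
#'
#' @param path path to a CSV file.
#' @return a data.frame of typed records.
#' @name read_tables
NULL

# parse a character column to numeric, failing with the offending row
parse_num <- function(x, col, allow_blank = FALSE) {
  x <- trimws(x)
  blank <- x == "" | is.na(x)
  out <- suppressWarnings(as.numeric(x))
  bad <- !blank & is.na(out)
  if (any(bad))
    stop(sprintf("malformed numeric value '%s' in column '%s', data row %d",
                 x[which(bad)[1]], col, which(bad)[1]))
  if (!allow_blank && any(blank))
    stop(sprintf("blank value not allowed in column '%s', data row %d",
                 col, which(blank)[1]))
  out
}

read_table_checked <- function(path, required, numeric_cols,
                               blank_ok = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character",
                        check.names = FALSE, na.strings = NULL)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         " in ", path)
  extra <- setdiff(names(df), required)
  if (length(extra))
    warning("ignoring unknown column(s): ", paste(extra, collapse = ", "))
  df <- df[, required, drop = FALSE]
  for (col in numeric_cols)
    df[[col]] <- parse_num(df[[col]], col, allow_blank = col %in% blank_ok)
  df
}

#' @rdname read_tables
#' @export
read_haul_table <- function(path) {
  header <- names(utils::read.csv(path, nrows = 0, check.names = FALSE))
  cpue_cols <- grep("^cpue_", header, value = TRUE)
  if (!length(cpue_cols)) stop("haul table has no cpue_<species> column")
  req <- c("haul_id", "year", "lon", "lat", "depth", "temp", cpue_cols)
  df <- read_table_checked(path, req,
                           numeric_cols = c("year", "lon", "lat", "depth",
                                            "temp", cpue_cols),
                           blank_ok = c("depth", "temp"))
  if (anyDuplicated(df$haul_id))
    stop("duplicate haul_id: ", df$haul_id[anyDuplicated(df$haul_id)])
  if (any(df[cpue_cols] < 0, na.rm = TRUE)) stop("negative CPUE in ", path)
  df$year <- as.integer(df$year)
  df
}

#' @rdname read_tables
#' @export
read_specimen_table <- function(path) {
  df <- read_table_checked(path, c("haul_id", "species", "fork_length"),
                           numeric_cols = "fork_length")
  if (nrow(df) && any(df$fork_length <= 0)) stop("non-positive fork_length")
  df
}

#' @rdname read_tables
#' @export
read_diet_table <- function(path) {
  req <- c("haul_id", "stomach_id", "species", "fork_length", "fullness",
           "taxon", "weight_g")
  df <- read_table_checked(path, req,
                           numeric_cols = c("fork_length", "fullness",
                                            "weight_g"))
  if (nrow(df)) {
    if (any(!(df$fullness %in% 1:7))) stop("fullness code outside 1..7")
    if (any(df$weight_g < 0)) stop("negative prey weight")
  }
  df$fullness <- as.integer(df$fullness)
  df
}

#' @rdname read_tables
#' @param x table to write.
#' @export
write_haul_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname read_tables
#' @export
write_specimen_table <- write_haul_table

#' @rdname read_tables
#' @export
write_diet_table <- write_haul_table

#' Exclude hauls with missing depth or bottom temperature
#'
#' All model stages require the same complete covariate set, so tows with a
#' missing depth or bottom temperature are dropped before any fitting.
#'
#' @param hauls a haul table (see [read_haul_table()]).
#' @return list with `hauls` (the retained rows) and `report`, a
#'   `filter_report` with `n_input`, `n_excluded_missing_covariates`,
#'   `n_retained` and `n_positive` (named count of retained hauls with
#'   positive CPUE, per species). The bookkeeping identity
#'   `n_input = n_excluded + n_retained` always holds.
#' @export
filter_complete_covariates <- function(hauls) {
  keep <- !is.na(hauls$depth) & !is.na(hauls$temp)
  retained <- hauls[keep, , drop = FALSE]
  cpue_cols <- grep("^cpue_", names(hauls), value = TRUE)
  n_pos <- vapply(cpue_cols, function(cc) sum(retained[[cc]] > 0), integer(1))
  names(n_pos) <- sub("^cpue_", "", cpue_cols)
  report <- structure(
    list(n_input = nrow(hauls),
         n_excluded_missing_covariates = sum(!keep),
         n_retained = nrow(retained), n_positive = n_pos),
    class = "filter_report")
  list(hauls = retained, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>", x$n_input, "tows in;",
      x$n_excluded_missing_covariates, "excluded (missing depth/temp);",
      x$n_retained, "retained\n")
  if (length(x$n_positive))
    cat("  positive tows:",
        paste(names(x$n_positive), x$n_positive, sep = "=", collapse = "  "),
        "\n")
  invisible(x)
}

#' Size-adjusted CPUE and presence for one species
#'
#' Total CPUE counts fish of all sizes, but the analysis is restricted to a
#' fork-length window, so each haul's CPUE is multiplied by the proportion
#' of its length subsample falling inside the window (closed interval,
#' lengths in whole cm). Presence for modelling is `adj_cpue > 0`, i.e. it
#' reflects the size restriction.
#'
#' @param hauls haul table.
#' @param specimens specimen table.
#' @param species species name (must match a `cpue_<species>` column).
#' @param size_range closed fork-length interval in cm, default `c(30, 69)`.
#' @param on_missing_lengths what to do when a haul has positive CPUE but
#'   no length subsample: `"zero"` (default) treats the in-range proportion
#'   as 0; `"error"` fails.
#' @return data.frame `haul_id`, `adj_cpue`, `presence` (0/1), aligned to
#'   `hauls`.
#' @export
adjusted_cpue <- function(hauls, specimens, species,
                          size_range = c(30, 69),
                          on_missing_lengths = c("zero", "error")) {
  on_missing_lengths <- match.arg(on_missing_lengths)
  cc <- paste0("cpue_", species)
  if (!cc %in% names(hauls)) stop("no column ", cc, " in haul table")
  sp <- specimens[specimens$species == species, , drop = FALSE]
  n_tot <- tapply(sp$fork_length, sp$haul_id, length)
  n_in <- tapply(sp$fork_length >= size_range[1] &
                   sp$fork_length <= size_range[2], sp$haul_id, sum)
  tot <- as.numeric(n_tot[hauls$haul_id])
  inr <- as.numeric(n_in[hauls$haul_id])
  prop <- ifelse(is.na(tot) | tot == 0, 0, inr / tot)
  orphan <- hauls[[cc]] > 0 & (is.na(tot) | tot == 0)
  if (any(orphan) && on_missing_lengths == "error")
    stop("haul(s) with positive CPUE but no length subsample: ",
         paste(utils::head(hauls$haul_id[orphan], 5), collapse = ", "))
  adj <- hauls[[cc]] * prop
  data.frame(haul_id = hauls$haul_id, adj_cpue = adj,
             presence = as.integer(adj > 0))
}

#' Assign statistical / regulatory area labels from longitude
#'
#' Areas are used purely as grouping factors, so they are defined as
#' ordered longitude breakpoints per scheme rather than polygons. Interval
#' membership is half-open `[west, east)`: a longitude exactly on a
#' breakpoint belongs to the eastern (higher-longitude) interval.
#'
#' @param lon numeric vector of longitudes (decimal degrees).
#' @param boundaries a list of schemes, each `list(breaks =, labels =)`
#'   with `length(breaks) == length(labels) + 1`, breaks ascending. See
#'   [default_boundaries()].
#' @return data.frame with one column of labels per scheme; longitudes
#'   outside all intervals get `"unassigned"`.
#' @export
assign_area <- function(lon, boundaries = default_boundaries()) {
  out <- lapply(boundaries, function(sch) {
    stopifnot(length(sch$breaks) == length(sch$labels) + 1,
              !is.unsorted(sch$breaks))
    idx <- findInterval(lon, sch$breaks)        # [b_k, b_{k+1})
    lab <- rep("unassigned", length(lon))
    ok <- idx >= 1 & idx <= length(sch$labels) & lon < max(sch$breaks)
    lab[ok] <- sch$labels[idx[ok]]
    lab
  })
  as.data.frame(out, optional = TRUE)
}

#' Expand area-by-year tow count margins into a tow-level haul table
#'
#' Survey summaries are often published only as counts of tows (total and
#' positive per species) by statistical area and year. This reconstructs a
#' minimal tow-level haul table with exactly those margins: one row per
#' tow, positive tows getting unit CPUE, located at a representative
#' longitude for their area. Optionally appends tows with missing
#' depth/temperature, so that the covariate filter's bookkeeping can be
#' checked against published retained-tow counts.
#'
#' @param counts data.frame with columns `area`, `year`, `total_tows` and
#'   one `positive_<species>` column per species (see
#'   `system.file("extdata", "goa_tow_counts.csv", package = "nichepart")`).
#' @param n_missing_covariates number of extra tows with blank depth and
#'   temperature to append.
#' @param boundaries boundary schemes; area longitudes are interval
#'   midpoints of the first scheme.
#' @return a haul table (`haul_id`, `year`, `lon`, `lat`, `depth`, `temp`,
#'   `cpue_<species>`).
#' @export
expand_tow_counts <- function(counts, n_missing_covariates = 0L,
                              boundaries = default_boundaries()) {
  sch <- boundaries[[1]]
  mid <- stats::setNames(
    (sch$breaks[-length(sch$breaks)] + sch$breaks[-1]) / 2, sch$labels)
  sp_cols <- grep("^positive_", names(counts), value = TRUE)
  species <- sub("^positive_", "", sp_cols)
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    n <- counts$total_tows[i]
    if (n == 0) return(NULL)
    h <- data.frame(year = counts$year[i],
                    lon = mid[[counts$area[i]]], lat = 57,
                    depth = 100, temp = 5)
    h <- h[rep(1, n), , drop = FALSE]
    for (k in seq_along(species)) {
      npos <- counts[[sp_cols[k]]][i]
      h[[paste0("cpue_", species[k])]] <- rep(c(1, 0), c(npos, n - npos))
    }
    h
  })
  out <- do.call(rbind, rows)
  if (n_missing_covariates > 0) {
    ext <- out[rep(1, n_missing_covariates), , drop = FALSE]
    ext$depth <- NA_real_
    ext$temp <- NA_real_
    for (s in species) ext[[paste0("cpue_", s)]] <- 0
    out <- rbind(out, ext)
  }
  out <- cbind(haul_id = sprintf("T%05d", seq_len(nrow(out))), out)
  rownames(out) <- NULL
  out
}

#' Default area boundary configuration
#'
#' Approximate longitudinal breakpoints for the five INPFC statistical
#' areas (Shumagin, Chirikof, Kodiak, Yakutat, Southeastern) and the four
#' IPHC regulatory areas (4A, 3B, 3A, 2C) of the Gulf of Alaska. Exact
#' regulatory polygons are intentionally not reproduced; the analyses use
#' areas only as grouping factors and the breakpoints are configurable.
#'
#' @return named list of boundary schemes for [assign_area()].
#' @export
default_boundaries <- function() {
  list(
    inpfc = list(breaks = c(-170, -159, -154, -147, -137, -130),
                 labels = c("Shumagin", "Chirikof", "Kodiak", "Yakutat",
                            "Southeastern")),
    iphc = list(breaks = c(-170, -164, -154, -137, -130),
                labels = c("4A", "3B", "3A", "2C"))
  )
}
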