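#' Transverse-Mercator projection used for the uniform grid
#'
#' A uniform square tiling needs one projected planar frame, so the whole
#' study extent is projected with a single spherical transverse-Mercator
#' zone (central meridian `lon0`, scale factor `k0`, sphere radius `R` in
#' metres). The closed-form spherical forward/inverse maps are used; for
#' building a 100 km aggregation grid the difference from the ellipsoidal
#' series is immaterial, and the zone is a configuration item.
#'
#' @param lon0 central meridian (decimal degrees).
#' @param lat0 latitude origin (decimal degrees).
#' @param k0 central scale factor (default 0.9996 as in UTM).
#' @param R sphere radius in metres (default 6371000).
#' @return object of class `tm_projection`.
#' @export
tm_projection <- function(lon0, lat0 = 0, k0 = 0.9996, R = 6371000) {
  structure(list(lon0 = lon0, lat0 = lat0, k0 = k0, R = R),
            class = "tm_projection")
}

#' @rdname tm_projection
#' @param lon,lat coordinates in decimal degrees.
#' @param proj a `tm_projection`.
#' @return `tm_project`: data.frame `x`, `y` in metres;
#'   `tm_unproject`: data.frame `lon`, `lat` in degrees.
#' @export
tm_project <- function(lon, lat, proj) {
  rad <- pi / 180
  dl <- (lon - proj$lon0) * rad
  phi <- lat * rad
  B <- cos(phi) * sin(dl)
  x <- proj$R * proj$k0 * atanh(B)
  y <- proj$R * proj$k0 *
    (atan2(tan(phi), cos(dl)) - proj$lat0 * rad)
  data.frame(x = x, y = y)
}

#' @rdname tm_projection
#' @param x,y projected coordinates in metres.
#' @export
tm_unproject <- function(x, y, proj) {
  rad <- pi / 180
  xs <- x / (proj$R * proj$k0)
  D <- y / (proj$R * proj$k0) + proj$lat0 * rad
  phi <- asin(sin(D) / cosh(xs))
  lam <- proj$lon0 * rad + atan2(sinh(xs), cos(D))
  data.frame(lon = lam / rad, lat = phi / rad)
}

#' Build the uniform analysis grid
#'
#' Tiles the projected bounding box of the lon/lat extent with square
#' cells (default 100 km x 100 km). Cell membership is half-open,
#' `[min, max)` in projected coordinates, so every in-extent point maps to
#' exactly one cell and assignment at cell edges is deterministic.
#'
#' @param extent numeric length 4: `c(lon_min, lon_max, lat_min, lat_max)`.
#' @param cell_size cell edge in metres (default 1e5).
#' @param proj a [tm_projection()]; default centres the zone on the extent.
#' @return object of class `overlap_grid`: list with `proj`, `cell_size`,
#'   `origin`, `nx`, `ny` and `cells`, a data.frame of cell ids, indices,
#'   projected centres and lon/lat centres.
#' @export
build_grid <- function(extent, cell_size = 1e5, proj = NULL) {
  stopifnot(length(extent) == 4, extent[1] < extent[2],
            extent[3] < extent[4], cell_size > 0)
  if (is.null(proj))
    proj <- tm_projection(lon0 = mean(extent[1:2]))
  # project a dense boundary sample to bound the extent in the plane
  lon_s <- seq(extent[1], extent[2], length.out = 101)
  lat_s <- seq(extent[3], extent[4], length.out = 101)
  border <- rbind(
    data.frame(lon = lon_s, lat = extent[3]),
    data.frame(lon = lon_s, lat = extent[4]),
    data.frame(lon = extent[1], lat = lat_s),
    data.frame(lon = extent[2], lat = lat_s))
  pr <- tm_project(border$lon, border$lat, proj)
  origin <- c(floor(min(pr$x) / cell_size) * cell_size,
              floor(min(pr$y) / cell_size) * cell_size)
  # tiny relative guard so an exactly tiling extent does not gain a row of
  # cells from floating-point round-off (the tiling is half-open [min, max))
  nx <- ceiling((max(pr$x) - origin[1]) / cell_size - 1e-9)
  ny <- ceiling((max(pr$y) - origin[2]) / cell_size - 1e-9)
  ij <- expand.grid(ix = seq_len(nx), iy = seq_len(ny))
  xc <- origin[1] + (ij$ix - 0.5) * cell_size
  yc <- origin[2] + (ij$iy - 0.5) * cell_size
  ll <- tm_unproject(xc, yc, proj)
  cells <- data.frame(cell_id = sprintf("c%02d_%02d", ij$ix, ij$iy),
                      ix = ij$ix, iy = ij$iy, x = xc, y = yc,
                      lon = ll$lon, lat = ll$lat)
  structure(list(proj = proj, cell_size = cell_size, origin = origin,
                 nx = nx, ny = ny, cells = cells),
            class = "overlap_grid")
}

#' @export
print.overlap_grid <- function(x, ...) {
  cat("<overlap_grid>", x$nx, "x", x$ny, "cells of",
      x$cell_size / 1000, "km; central meridian", x$proj$lon0, "\n")
  invisible(x)
}

#' Locate points in the grid
#'
#' @param lon,lat coordinates in decimal degrees.
#' @param grid an [build_grid()] object.
#' @return character vector of cell ids; `NA` for points outside the grid.
#' @export
locate_cell <- function(lon, lat, grid) {
  pr <- tm_project(lon, lat, grid$proj)
  ix <- floor((pr$x - grid$origin[1]) / grid$cell_size) + 1L
  iy <- floor((pr$y - grid$origin[2]) / grid$cell_size) + 1L
  out <- sprintf("c%02d_%02d", ix, iy)
  out[ix < 1 | ix > grid$nx | iy < 1 | iy > grid$ny] <- NA_character_
  out
}

#' Cell-year environmental summaries
#'
#' Arithmetic means of depth and bottom temperature over the hauls located
#' in each (year, cell) combination; combinations with no hauls are simply
#' absent (no prediction is made there). The cell-centre lon/lat are
#' attached as prediction coordinates.
#'
#' @param hauls covariate-complete haul table.
#' @param grid an [build_grid()] object.
#' @return data.frame `year`, `cell_id`, `lon`, `lat` (cell centres),
#'   `depth`, `temp` (haul means), `n_hauls`.
#' @export
cell_year_env <- function(hauls, grid) {
  if (anyNA(hauls$depth) || anyNA(hauls$temp))
    stop("hauls must be covariate-complete; run filter_complete_covariates()")
  cell <- locate_cell(hauls$lon, hauls$lat, grid)
  keep <- !is.na(cell)
  h <- hauls[keep, ]
  cell <- cell[keep]
  agg <- stats::aggregate(cbind(depth, temp) ~ cell_id + year,
                          data = data.frame(h[, c("depth", "temp", "year")],
                                            cell_id = cell),
                          FUN = mean)
  cnt <- stats::aggregate(list(n_hauls = rep(1L, nrow(h))),
                          by = list(cell_id = cell, year = h$year), FUN = sum)
  env <- merge(agg, cnt, by = c("cell_id", "year"))
  env <- merge(env, grid$cells[, c("cell_id", "lon", "lat")], by = "cell_id")
  env[order(env$year, env$cell_id),
      c("year", "cell_id", "lon", "lat", "depth", "temp", "n_hauls")]
}

#' Combine and standardize the two model stages into an abundance field
#'
#' Overall abundance is the product `A = PO * PA` of predicted occurrence
#' probability and predicted positive-catch abundance, per species, year
#' and grid cell. Each species' field is standardized by dividing by a
#' species-level statistic of `A` over all year-cells: the maximum
#' (default, giving values in [0, 1] with at least one exact 1), or the
#' mean or median (same spatial pattern on a different scale).
#'
#' @param pred data.frame with columns `species`, `year`, `cell_id`, `po`,
#'   `pa`.
#' @param method `"max"`, `"mean"` or `"median"`.
#' @return the input with `A` and `stdA` columns appended (class
#'   `abundance_field`).
#' @export
combine_and_standardize <- function(pred, method = c("max", "mean", "median")) {
  method <- match.arg(method)
  stopifnot(all(c("species", "year", "cell_id", "po", "pa") %in% names(pred)))
  if (any(pred$po < 0 | pred$po > 1)) stop("po outside [0, 1]")
  if (any(pred$pa < 0)) stop("pa must be nonnegative")
  pred$A <- pred$po * pred$pa
  stat <- switch(method, max = max, mean = mean, median = stats::median)
  denom <- tapply(pred$A, pred$species, stat)
  if (any(denom <= 0))
    stop("standardizer undefined: all-zero abundance for species ",
         paste(names(denom)[denom <= 0], collapse = ", "))
  pred$stdA <- pred$A / as.numeric(denom[pred$species])
  class(pred) <- c("abundance_field", "data.frame")
  attr(pred, "method") <- method
  pred
}

#' Exclude cells of poor habitat suitability for both species
#'
#' A grid cell is excluded only when its standardized abundance is below
#' the threshold for *both* species in *every* predicted year
#' (whole-cell exclusion): such cells are poor habitat for both predators
#' and contribute no information about overlap.
#'
#' @param field an `abundance_field` holding both species (max-standardized).
#' @param species_pair character length 2.
#' @param threshold exclusion threshold on `stdA` (default 0.25).
#' @return list with `retained` and `excluded` cell-id vectors and
#'   `n_excluded`.
#' @export
exclude_low_habitat <- function(field, species_pair, threshold = 0.25) {
  stopifnot(length(species_pair) == 2)
  f <- field[field$species %in% species_pair, ]
  cell_max <- stats::aggregate(stdA ~ cell_id + species, data = f, FUN = max)
  wide <- stats::reshape(cell_max, idvar = "cell_id", timevar = "species",
                         direction = "wide")
  m <- as.matrix(wide[, -1, drop = FALSE])
  below <- rowSums(m < threshold, na.rm = TRUE) == ncol(m) &
    rowSums(!is.na(m)) == ncol(m)
  excluded <- wide$cell_id[below]
  list(retained = setdiff(unique(f$cell_id), excluded),
       excluded = excluded, n_excluded = length(excluded))
}

#' Spatial overlap index on the grid
#'
#' Per year and cell, `S` is the product of the two species'
#' max-standardized abundances, ranging from 0 (no overlap) to 1 (complete
#' overlap). The two species must be predicted on exactly the same
#' (year, cell) set.
#'
#' @param field an `abundance_field` restricted to the retained cells.
#' @param species_pair character length 2.
#' @return data.frame `year`, `cell_id`, `stdA_<sp1>`, `stdA_<sp2>`, `S`
#'   (class `overlap_field`).
#' @export
spatial_overlap <- function(field, species_pair) {
  stopifnot(length(species_pair) == 2)
  a <- field[field$species == species_pair[1],
             c("year", "cell_id", "stdA")]
  b <- field[field$species == species_pair[2],
             c("year", "cell_id", "stdA")]
  key_a <- paste(a$year, a$cell_id)
  key_b <- paste(b$year, b$cell_id)
  if (nrow(a) != nrow(b) || !setequal(key_a, key_b))
    stop("the two species are not predicted on the same (year, cell) set")
  m <- merge(a, b, by = c("year", "cell_id"),
             suffixes = paste0("_", species_pair))
  m$S <- m[[paste0("stdA_", species_pair[1])]] *
    m[[paste0("stdA_", species_pair[2])]]
  m <- m[order(m$year, m$cell_id), ]
  rownames(m) <- NULL
  class(m) <- c("overlap_field", "data.frame")
  m
}

#' Per-cell means of an overlap field across years
#'
#' @param overlap an overlap field with `cell_id` and a value column.
#' @param value name of the value column (default `"S"`).
#' @return data.frame `cell_id`, `mean`, `n_years`.
#' @export
cell_means <- function(overlap, value = "S") {
  agg <- stats::aggregate(overlap[[value]],
                          by = list(cell_id = overlap$cell_id),
                          FUN = mean)
  names(agg)[2] <- "mean"
  agg$n_years <- as.integer(table(overlap$cell_id)[agg$cell_id])
  agg
}
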