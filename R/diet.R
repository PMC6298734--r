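#' Group stomachs by survey year and grid cell
#'
#' Attaches haul locations, locates each stomach in the grid, keeps
#' non-empty stomachs (at least one prey item of positive weight and
#' fullness code > 1) of predators inside the fork-length window, and
#' determines which (year, cell) combinations qualify for a dietary
#' overlap estimate: both predators must have at least `min_per_predator`
#' non-empty stomachs there.
#'
#' @param diet_records prey-item table (see [read_diet_table()]).
#' @param hauls haul table carrying `haul_id`, `year`, `lon`, `lat`.
#' @param grid an [build_grid()] object.
#' @param species_pair the two predator names.
#' @param size_range closed fork-length interval (cm), default `c(30, 69)`.
#' @param min_per_predator minimum non-empty stomachs per predator per
#'   (year, cell), default 3.
#' @return list with
#'   `items` (prey rows of qualifying groups, with `year`, `cell_id`),
#'   `counts` (non-empty stomach counts per year, cell and species) and
#'   `qualifying` (data.frame `year`, `cell_id`).
#' @export
group_stomachs <- function(diet_records, hauls, grid, species_pair,
                           size_range = c(30, 69), min_per_predator = 3L) {
  stopifnot(length(species_pair) == 2)
  d <- merge(diet_records, hauls[, c("haul_id", "year", "lon", "lat")],
             by = "haul_id")
  d$cell_id <- locate_cell(d$lon, d$lat, grid)
  d <- d[!is.na(d$cell_id) &
           d$fork_length >= size_range[1] & d$fork_length <= size_range[2] &
           d$species %in% species_pair, , drop = FALSE]
  # a stomach is non-empty iff fullness > 1 and it has a positive prey weight
  nonempty_ids <- unique(d$stomach_id[d$fullness > 1L & d$weight_g > 0])
  d <- d[d$stomach_id %in% nonempty_ids & d$weight_g > 0, , drop = FALSE]
  if (!nrow(d)) {
    empty <- data.frame(year = integer(), cell_id = character())
    return(list(items = cbind(d, data.frame()), counts =
                  data.frame(year = integer(), cell_id = character(),
                             species = character(), n_stomachs = integer()),
                qualifying = empty))
  }
  st <- unique(d[, c("stomach_id", "year", "cell_id", "species")])
  counts <- stats::aggregate(list(n_stomachs = st$stomach_id),
                             by = st[, c("year", "cell_id", "species")],
                             FUN = length)
  wide <- stats::reshape(counts, idvar = c("year", "cell_id"),
                         timevar = "species", direction = "wide")
  cnt_cols <- paste0("n_stomachs.", species_pair)
  for (cc in setdiff(cnt_cols, names(wide))) wide[[cc]] <- NA_integer_
  ok <- !is.na(wide[[cnt_cols[1]]]) & wide[[cnt_cols[1]]] >= min_per_predator &
    !is.na(wide[[cnt_cols[2]]]) & wide[[cnt_cols[2]]] >= min_per_predator
  qualifying <- wide[ok, c("year", "cell_id")]
  rownames(qualifying) <- NULL
  key <- paste(d$year, d$cell_id)
  items <- d[key %in% paste(qualifying$year, qualifying$cell_id), ,
             drop = FALSE]
  rownames(items) <- NULL
  list(items = items, counts = counts, qualifying = qualifying)
}

#' Prey-weight proportions of a diet group
#'
#' Pools prey weights across the group's stomachs per taxon and divides by
#' the group's total prey weight (default). The alternative
#' `"mean_of_stomachs"` averages per-stomach proportion vectors instead,
#' weighting each stomach equally regardless of its total contents.
#'
#' @param items prey rows of one group: columns `stomach_id`, `taxon`,
#'   `weight_g`.
#' @param method `"pooled"` (default) or `"mean_of_stomachs"`.
#' @return named numeric vector of proportions summing to 1.
#' @export
prey_proportions <- function(items, method = c("pooled", "mean_of_stomachs")) {
  method <- match.arg(method)
  if (!nrow(items) || sum(items$weight_g) <= 0)
    stop("diet group has zero total prey weight")
  if (method == "pooled") {
    w <- tapply(items$weight_g, items$taxon, sum)
    out <- as.numeric(w) / sum(w)
    names(out) <- names(w)
  } else {
    per_st <- lapply(split(items, items$stomach_id), function(s) {
      w <- tapply(s$weight_g, factor(s$taxon, levels = unique(items$taxon)),
                  sum, default = 0)
      w / sum(w)
    })
    m <- do.call(rbind, per_st)
    out <- colMeans(m)
  }
  out[order(names(out))]
}

#' Schoener's similarity index of two diet compositions
#'
#' `D = 1 - 0.5 * sum_t |W_a(t) - W_b(t)|` over the union of prey taxa
#' observed in either composition (taxa absent from one side enter as 0).
#' `D` ranges from 0 (complete separation) to 1 (complete overlap), and
#' equals one minus the total-variation (half-L1) distance between the
#' compositions.
#'
#' @param w_a,w_b named proportion vectors, each summing to 1 (within 1e-6).
#' @return `D` in `[0, 1]`.
#' @export
schoener <- function(w_a, w_b) {
  if (abs(sum(w_a) - 1) > 1e-6 || abs(sum(w_b) - 1) > 1e-6)
    stop("compositions must each sum to 1")
  if (any(w_a < 0) || any(w_b < 0)) stop("negative proportion")
  taxa <- union(names(w_a), names(w_b))
  a <- b <- stats::setNames(numeric(length(taxa)), taxa)
  a[names(w_a)] <- w_a
  b[names(w_b)] <- w_b
  1 - 0.5 * sum(abs(a - b))
}

#' Shannon diversity and Pielou evenness of a composition
#'
#' `H' = -sum W_t ln W_t` over positive entries (natural log);
#' `J' = H' / ln(Q)` with `Q` the number of taxa observed (positive
#' entries). `J'` is undefined for a single-taxon diet and is returned as
#' `NA` in that case.
#'
#' @param w proportion vector summing to 1.
#' @return numeric scalar.
#' @export
shannon <- function(w) {
  if (abs(sum(w) - 1) > 1e-6) stop("composition must sum to 1")
  as.numeric(vegan::diversity(w, index = "shannon"))
}

#' @rdname shannon
#' @export
pielou <- function(w) {
  q <- sum(w > 0)
  if (q < 2) return(NA_real_)
  shannon(w) / log(q)
}

#' Dietary overlap across the grid
#'
#' Computes Schoener's D between the two predators' prey-weight
#' compositions in every qualifying (year, cell) group.
#'
#' @param groups result of [group_stomachs()].
#' @param species_pair the two predator names.
#' @param method passed to [prey_proportions()].
#' @return data.frame `year`, `cell_id`, `n_<sp1>`, `n_<sp2>` (non-empty
#'   stomachs), `D`.
#' @export
dietary_overlap <- function(groups, species_pair,
                            method = c("pooled", "mean_of_stomachs")) {
  method <- match.arg(method)
  q <- groups$qualifying
  if (!nrow(q))
    return(data.frame(year = integer(), cell_id = character(),
                      D = numeric()))
  items <- groups$items
  res <- lapply(seq_len(nrow(q)), function(i) {
    g <- items[items$year == q$year[i] & items$cell_id == q$cell_id[i], ]
    w1 <- prey_proportions(g[g$species == species_pair[1], ], method)
    w2 <- prey_proportions(g[g$species == species_pair[2], ], method)
    n1 <- length(unique(g$stomach_id[g$species == species_pair[1]]))
    n2 <- length(unique(g$stomach_id[g$species == species_pair[2]]))
    data.frame(year = q$year[i], cell_id = q$cell_id[i],
               n1 = n1, n2 = n2, D = schoener(w1, w2))
  })
  out <- do.call(rbind, res)
  names(out)[3:4] <- paste0("n_", species_pair)
  out
}

#' Sample-based rarefaction of prey taxa over stomachs
#'
#' Expected number of distinct prey taxa as a function of the number of
#' non-empty stomachs sampled, by repeated subsampling without
#' replacement. Within each resample richness is accumulated cumulatively
#' along a random stomach order, so every curve (and hence the mean) is
#' non-decreasing, and the endpoint at the full sample equals the total
#' observed taxon count.
#'
#' @param diet_records prey-item table.
#' @param species predator to curve.
#' @param n_resamples number of random stomach orderings (default 100).
#' @param seed integer seed for the resampling.
#' @return data.frame `m` (stomachs), `mean_taxa`, `lo`, `hi` (2.5% and
#'   97.5% resampling quantiles).
#' @export
rarefaction <- function(diet_records, species, n_resamples = 100L,
                        seed = 1L) {
  d <- diet_records[diet_records$species == species &
                      diet_records$fullness > 1 & diet_records$weight_g > 0, ]
  if (!nrow(d)) stop("no non-empty stomachs for species ", species)
  inc <- table(d$stomach_id, d$taxon) > 0
  n <- nrow(inc)
  set.seed(seed)
  rich <- matrix(0L, n_resamples, n)
  for (r in seq_len(n_resamples)) {
    ord <- sample.int(n)
    seen <- cum_any(inc[ord, , drop = FALSE])
    rich[r, ] <- as.integer(rowSums(seen))
  }
  data.frame(m = seq_len(n),
             mean_taxa = colMeans(rich),
             lo = apply(rich, 2, stats::quantile, 0.025),
             hi = apply(rich, 2, stats::quantile, 0.975))
}

# cumulative "any seen so far" down the rows of a logical matrix
cum_any <- function(m) {
  if (nrow(m) == 1) return(m * 1)
  apply(m, 2, cummax)
}

#' Size-class diet compositions for display
#'
#' Pools prey weights per predator species, area and 10-cm size class
#' (30-39, 40-49, 50-59, 60-69 cm by default) and returns the long table
#' of proportions. [aggregate_rare_taxa()] folds taxa whose overall
#' proportion within a species falls below a threshold into their broader
#' taxonomic group, preserving total mass exactly.
#'
#' @param diet_records prey-item table.
#' @param hauls haul table (for longitudes).
#' @param boundaries boundary schemes (see [assign_area()]); the first
#'   scheme is used for the area grouping.
#' @param bins lower edges plus upper bound of the size classes,
#'   default `c(30, 40, 50, 60, 70)`.
#' @return data.frame `species`, `area`, `size_class`, `taxon`, `W`,
#'   `n_stomachs`.
#' @export
size_class_compositions <- function(diet_records, hauls,
                                    boundaries = default_boundaries(),
                                    bins = c(30, 40, 50, 60, 70)) {
  d <- merge(diet_records, hauls[, c("haul_id", "lon")], by = "haul_id")
  d <- d[d$fullness > 1 & d$weight_g > 0 &
           d$fork_length >= bins[1] & d$fork_length < bins[length(bins)], ]
  lab <- paste(bins[-length(bins)], bins[-1] - 1, sep = "-")
  d$size_class <- cut(d$fork_length, breaks = bins - 0.5, labels = lab,
                      right = FALSE)
  d$area <- assign_area(d$lon, boundaries)[[1]]
  res <- lapply(split(d, list(d$species, d$area, d$size_class), drop = TRUE),
                function(g) {
                  w <- prey_proportions(g)
                  data.frame(species = g$species[1], area = g$area[1],
                             size_class = as.character(g$size_class[1]),
                             taxon = names(w), W = as.numeric(w),
                             n_stomachs = length(unique(g$stomach_id)))
                })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' @rdname size_class_compositions
#' @param comp a composition table from [size_class_compositions()].
#' @param taxonomy data.frame `taxon`, `broad_group` mapping each taxon to
#'   its broader taxonomic group.
#' @param threshold overall-proportion cutoff below which a taxon is
#'   folded (default 0.01); 0 folds nothing.
#' @export
aggregate_rare_taxa <- function(comp, taxonomy, threshold = 0.01) {
  overall <- stats::aggregate(W ~ species + taxon, data = comp, FUN = sum)
  tot <- tapply(overall$W, overall$species, sum)
  overall$p <- overall$W / as.numeric(tot[overall$species])
  rare <- overall[overall$p < threshold, c("species", "taxon")]
  lookup <- stats::setNames(taxonomy$broad_group, taxonomy$taxon)
  is_rare <- paste(comp$species, comp$taxon) %in%
    paste(rare$species, rare$taxon)
  grp <- lookup[comp$taxon]
  if (any(is_rare & is.na(grp))) {
    warning("taxon/taxa missing from taxonomy map folded into 'other': ",
            paste(unique(comp$taxon[is_rare & is.na(grp)]), collapse = ", "))
    grp[is.na(grp)] <- "other"
  }
  comp$display_taxon <- ifelse(is_rare, unname(grp), comp$taxon)
  out <- stats::aggregate(
    W ~ species + area + size_class + display_taxon + n_stomachs,
    data = comp, FUN = sum)
  names(out)[names(out) == "display_taxon"] <- "taxon"
  out[order(out$species, out$area, out$size_class, -out$W), ]
}
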