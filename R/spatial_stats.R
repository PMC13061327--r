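# Quantitative comparison layer: 2D cross-sections of the simulated
# tumoroid and the five spatial statistics computed on labelled cell
# tables (stem percentage, Moran's I, entropy of pairwise stem-stem
# distances, centrality, and the aSS intra-coefficient with its
# permutation confidence band), plus classification against the
# experimentally observed index ranges.

#' Construct a labelled 2D cell table
#'
#' The common currency of the statistics layer: one row per cell with
#' planar coordinates in micrometres and a binary stem/differentiated
#' label, the schema of QuPath cell-detection exports.
#'
#' @param x_um,y_um coordinates in micrometres.
#' @param label `"stem"` or `"differentiated"` (factors and 0/1 integers
#'   with 1 = stem are accepted).
#' @param radius_um optional cell radii in micrometres.
#'
#' @return A data.frame of class `cell_table`.
#' @export
cell_table <- function(x_um, y_um, label, radius_um = NULL) {
  if (is.numeric(label)) label <- CELL_TYPES[as.integer(label) + 1L]
  label <- as.character(label)
  df <- data.frame(x_um = as.numeric(x_um), y_um = as.numeric(y_um),
                   label = label, stringsAsFactors = FALSE)
  if (!is.null(radius_um)) df$radius_um <- as.numeric(radius_um)
  validate_cell_table(df)
}

validate_cell_table <- function(df) {
  need <- c("x_um", "y_um", "label")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("cell table is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) < 1) stop("cell table must contain at least one cell")
  if (any(!is.finite(df$x_um)) || any(!is.finite(df$y_um)))
    stop("cell table coordinates must be finite")
  bad <- which(!df$label %in% CELL_TYPES)
  if (length(bad) > 0)
    stop("invalid label value(s) in row(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         ": labels must be 'stem' or 'differentiated'")
  class(df) <- unique(c("cell_table", class(df)))
  df
}

#' Experimentally observed index ranges
#'
#' Minimum and maximum of the four spatial indices measured on the ten
#' immunohistochemistry sections, used as classification bands for
#' simulated sections.
#'
#' @param percentage,moran,entropy,centrality numeric length-2
#'   `(min, max)` per index.
#'
#' @return Named list of ranges, class `experimental_ranges`.
#' @export
experimental_ranges <- function(percentage = c(2.8, 11.2),
                                moran = c(0.09, 0.48),
                                entropy = c(0.05, 0.21),
                                centrality = c(0.53, 1.1)) {
  r <- list(percentage = percentage, moran = moran, entropy = entropy,
            centrality = centrality)
  stopifnot(all(vapply(r, function(v)
    length(v) == 2 && v[1] <= v[2], logical(1))))
  class(r) <- "experimental_ranges"
  r
}

#' 2D cross-section of a 3D cell population
#'
#' Cuts the tumoroid with the plane `z = z_fraction * L` and returns
#' every cell whose sphere intersects the plane
#' (`|z_c - z0| <= r_ext`), with coordinates converted to micrometres.
#'
#' @param pop a `cell_population`, `simulation_result` or population
#'   table (data.frame with `x`, `y`, `z`, `type` and `r_ext`).
#' @param z_fraction position of the section plane as a fraction of the
#'   domain edge (0.5 = central section).
#' @param unit_to_um micrometres per spatial unit.
#' @param L domain edge length (spatial units).
#'
#' @return A [cell_table()] (possibly empty, with a warning).
#' @export
cross_section <- function(pop, z_fraction = 0.5,
                          unit_to_um = um_per_unit(), L = 80) {
  stopifnot(z_fraction > 0, z_fraction < 1)
  if (inherits(pop, "simulation_result")) {
    unit_to_um <- pop$config$domain$unit_to_um
    L <- pop$config$domain$L
    pop <- pop$final
  }
  if (inherits(pop, "cell_population")) {
    z <- pop$pos[, 3]
    x <- pop$pos[, 1]
    y <- pop$pos[, 2]
    r <- radius_from_volume(pop$volume)
    lab <- pop$type
  } else {
    z <- pop$z; x <- pop$x; y <- pop$y; r <- pop$r_ext
    lab <- as.integer(pop$type == "stem")
  }
  z0 <- z_fraction * L
  keep <- abs(z - z0) <= r
  if (!any(keep)) {
    warning("empty cross-section at z = ", z0)
    df <- data.frame(x_um = numeric(0), y_um = numeric(0),
                     label = character(0), radius_um = numeric(0),
                     stringsAsFactors = FALSE)
    class(df) <- c("cell_table", class(df))
    return(df)
  }
  cell_table(x[keep] * unit_to_um, y[keep] * unit_to_um,
             lab[keep], r[keep] * unit_to_um)
}

#' Stem-cell percentage of a cell table
#'
#' @param table a [cell_table()].
#' @return 100 times the number of stem cells over the total.
#' @export
stem_percentage <- function(table) {
  table <- validate_cell_table(table)
  100 * sum(table$label == "stem") / nrow(table)
}

# shared neighbor structure: pairs (i, j, d) within `radius`, plus degree
neighbor_structure <- function(table, radius) {
  nb <- neighbor_pairs_2d_cpp(table$x_um, table$y_um, radius)
  nb$deg <- tabulate(c(nb$i, nb$j), nbins = nrow(table))
  nb
}

#' Moran's I of the stem/differentiated labels
#'
#' Spatial autocorrelation of the binary label vector under a
#' row-normalised neighborhood weight matrix: cells within
#' `neighbor_radius` micrometres are neighbors and share weight
#' `1/degree`; `w_ii = 0`; isolated cells get zero weight rows.  Values
#' near 0 indicate random labelling, positive values clustering,
#' negative values dispersion.
#'
#' @param table a [cell_table()].
#' @param neighbor_radius neighbor distance cutoff in micrometres
#'   (inclusive), default 15.
#'
#' @return Moran's I, or `NA` with a warning when undefined (single
#'   label, or no neighbor pairs).
#' @export
morans_I <- function(table, neighbor_radius = 15) {
  table <- validate_cell_table(table)
  n <- nrow(table)
  x <- as.numeric(table$label == "stem")
  if (length(unique(x)) < 2) {
    warning("Moran's I undefined: only one label present")
    return(NA_real_)
  }
  nb <- neighbor_structure(table, neighbor_radius)
  if (length(nb$i) == 0) {
    warning("Moran's I undefined: no neighbor pairs within radius")
    return(NA_real_)
  }
  z <- x - mean(x)
  # each unordered pair contributes z_i z_j (1/deg_i + 1/deg_j)
  num <- sum(z[nb$i] * z[nb$j] * (1 / nb$deg[nb$i] + 1 / nb$deg[nb$j]))
  S0 <- sum(nb$deg > 0)  # row sums are 1 for non-isolated cells
  n * num / (S0 * sum(z^2))
}

#' Entropy of the pairwise stem-stem distance distribution
#'
#' Histograms all pairwise distances between stem cells into `bins`
#' equal-width bins over `[0, range_max]` and returns the Shannon
#' entropy `-sum p_i log p_i` (natural log, empty bins contribute 0).
#' Elongated or fragmented stem-cell clusters spread the distance
#' distribution and increase the entropy; compact single clusters
#' concentrate it.
#'
#' @param table a [cell_table()].
#' @param bins number of equal-width bins (default 64).
#' @param range_max upper edge of the histogram in micrometres; defaults
#'   to the diagonal of the bounding box of all cells.  The experimental
#'   band for this index is calibration-sensitive: it is only comparable
#'   between tables binned the same way.
#'
#' @return Entropy (nats), or `NA` with a warning when fewer than two
#'   stem cells are present.
#' @export
entropy_index <- function(table, bins = 64, range_max = NULL) {
  table <- validate_cell_table(table)
  s <- table[table$label == "stem", ]
  if (nrow(s) < 2) {
    warning("entropy undefined: fewer than 2 stem cells")
    return(NA_real_)
  }
  if (is.null(range_max))
    range_max <- sqrt(diff(range(table$x_um))^2 + diff(range(table$y_um))^2)
  d <- as.numeric(dist(cbind(s$x_um, s$y_um)))
  d <- pmin(d, range_max)  # numerical guard at the diagonal
  h <- tabulate(pmin(floor(d / range_max * bins) + 1L, bins), nbins = bins)
  p <- h / sum(h)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Centrality index of the stem cells
#'
#' Ratio of the mean distance of stem cells to the image centre over the
#' mean distance of differentiated cells to the same centre.  Values
#' below 1 indicate that stem cells sit closer to the centre than
#' differentiated cells.
#'
#' @param table a [cell_table()].
#' @param center `"centroid"` (centroid of all cells, default) or
#'   `"bbox"` (bounding-box centre).
#'
#' @return Centrality ratio, or `NA` with a warning for single-label
#'   tables.
#' @export
centrality_index <- function(table, center = c("centroid", "bbox")) {
  table <- validate_cell_table(table)
  center <- match.arg(center)
  stem <- table$label == "stem"
  if (all(stem) || !any(stem)) {
    warning("centrality undefined: only one label present")
    return(NA_real_)
  }
  ctr <- if (center == "centroid") {
    c(mean(table$x_um), mean(table$y_um))
  } else {
    c(mean(range(table$x_um)), mean(range(table$y_um)))
  }
  d <- sqrt((table$x_um - ctr[1])^2 + (table$y_um - ctr[2])^2)
  mean(d[stem]) / mean(d[!stem])
}

# aSS from precomputed neighbor structure and a logical stem vector
a_ss_from_structure <- function(nb, stem, n) {
  ns <- sum(stem)
  cnt_stem <- tabulate(c(nb$i[stem[nb$j]], nb$j[stem[nb$i]]), nbins = n)
  ratio <- ifelse(nb$deg == 0, 1, cnt_stem / pmax(nb$deg, 1L))
  (n - 1) / (ns * (ns - 1)) * sum(ratio[stem])
}

#' aSS intra-coefficient of spatial aggregation
#'
#' Normalised same-type neighborhood fraction around stem cells:
#' `aSS = (N_t - 1) / (N_S (N_S - 1)) * sum_i N_S(C_i, r) / N_t(C_i, r)`
#' over stem cells `C_i`, where the neighborhood counts within radius
#' `r` (inclusive) exclude the focal cell and an empty neighborhood
#' contributes 1 (the 0/0 rule).  Under random labelling its average is
#' 1; values above 1 indicate stem-cell aggregation, below 1 dispersion.
#'
#' @param table a [cell_table()].
#' @param r neighborhood radius in micrometres.
#'
#' @return aSS, or `NA` with a warning when fewer than two stem cells.
#' @export
a_ss <- function(table, r) {
  table <- validate_cell_table(table)
  stem <- table$label == "stem"
  if (sum(stem) < 2) {
    warning("aSS undefined: fewer than 2 stem cells")
    return(NA_real_)
  }
  nb <- neighbor_structure(table, r)
  a_ss_from_structure(nb, stem, nrow(table))
}

#' Permutation confidence band for aSS under random labelling
#'
#' Estimates the variance of aSS over `n_perm` uniform random label
#' permutations (stem count fixed) and builds the band
#' `[1 - q, 1 + q]` with `q = sqrt(var / alpha)`; by Chebyshev's
#' inequality the band has coverage at least `1 - alpha` under the null
#' hypothesis of random stem locations, so `|aSS - 1| > q` rejects
#' randomness.
#'
#' @param table a [cell_table()].
#' @param r neighborhood radius in micrometres.
#' @param alpha confidence level parameter (default 0.05).
#' @param n_perm number of permutations (`>= 100`).
#'
#' @return List with `a_ss` (observed), `q`, `lower`, `upper`,
#'   `perm_mean`, `perm_var`, `reject` (logical) and `degenerate`
#'   (`TRUE` when no cell has a neighbor at this radius, collapsing the
#'   band to a point).
#' @export
a_ss_band <- function(table, r, alpha = 0.05, n_perm = 1000) {
  stopifnot(n_perm >= 100, alpha > 0, alpha < 1)
  table <- validate_cell_table(table)
  n <- nrow(table)
  stem <- table$label == "stem"
  ns <- sum(stem)
  if (ns < 2) {
    warning("aSS undefined: fewer than 2 stem cells")
    return(NULL)
  }
  nb <- neighbor_structure(table, r)
  obs <- a_ss_from_structure(nb, stem, n)
  vals <- numeric(n_perm)
  for (k in seq_len(n_perm)) {
    lab <- logical(n)
    lab[sample.int(n, ns)] <- TRUE
    vals[k] <- a_ss_from_structure(nb, lab, n)
  }
  v <- var(vals)
  degenerate <- length(nb$i) == 0
  if (degenerate) {
    warning("no neighbor pairs at this radius: confidence band collapses")
    v <- 0
  }
  q <- sqrt(v / alpha)
  list(a_ss = obs, q = q, lower = 1 - q, upper = 1 + q,
       perm_mean = mean(vals), perm_var = v,
       reject = abs(obs - 1) > q, degenerate = degenerate)
}

#' aSS curve over a radius grid
#'
#' Computes aSS and its permutation band at every radius of an
#' increasing grid and reports the smallest radius at which randomness
#' is no longer rejected (the characteristic cluster radius is the last
#' rejecting radius below it).
#'
#' @param table a [cell_table()].
#' @param r_grid increasing positive radii (micrometres).
#' @param alpha,n_perm see [a_ss_band()].
#'
#' @return List with `curve` (data.frame: r, a_ss, lower, upper,
#'   reject) and `r_random` (first grid radius with `|aSS - 1| <= q`,
#'   `NA` if randomness is rejected everywhere).
#' @export
a_ss_scan <- function(table, r_grid, alpha = 0.05, n_perm = 1000) {
  stopifnot(all(r_grid > 0), !is.unsorted(r_grid))
  rows <- lapply(r_grid, function(r) {
    b <- a_ss_band(table, r, alpha, n_perm)
    data.frame(r = r, a_ss = b$a_ss, lower = b$lower, upper = b$upper,
               reject = b$reject)
  })
  curve <- do.call(rbind, rows)
  idx <- which(!curve$reject)
  list(curve = curve,
       r_random = if (length(idx) > 0) curve$r[idx[1]] else NA_real_)
}

#' Classify an index value against an experimental range
#'
#' @param value index value.
#' @param range numeric `(min, max)`.
#'
#' @return `"below"`, `"within"` (boundary-inclusive) or `"above"`;
#'   `NA` for an `NA` value.
#' @export
classify <- function(value, range) {
  stopifnot(length(range) == 2, range[1] <= range[2])
  if (is.na(value)) return(NA_character_)
  if (value < range[1]) "below"
  else if (value > range[2]) "above"
  else "within"
}

#' All four indices of a cell table, with classification
#'
#' @param table a [cell_table()].
#' @param ranges an [experimental_ranges()].
#' @param neighbor_radius Moran neighbor radius (micrometres).
#' @param bins entropy histogram bins.
#'
#' @return An object of class `stats_report`: list with `indices`
#'   (named numeric), `classification` (named character) and
#'   `acceptable` (all four within).
#' @export
stats_report <- function(table, ranges = experimental_ranges(),
                         neighbor_radius = 15, bins = 64) {
  idx <- c(percentage = stem_percentage(table),
           moran = morans_I(table, neighbor_radius),
           entropy = entropy_index(table, bins),
           centrality = centrality_index(table))
  cls <- vapply(names(ranges), function(nm) classify(idx[[nm]], ranges[[nm]]),
                character(1))
  structure(list(indices = idx, classification = cls,
                 acceptable = all(cls == "within", na.rm = FALSE)),
            class = "stats_report")
}

#' @export
print.stats_report <- function(x, ...) {
  cat("spatial indices:\n")
  for (nm in names(x$indices))
    cat(sprintf("  %-11s %8.4f  [%s]\n", nm, x$indices[[nm]],
                x$classification[[nm]]))
  cat(if (isTRUE(x$acceptable)) "all indices within experimental ranges\n"
      else "not all indices within experimental ranges\n")
  invisible(x)
}
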