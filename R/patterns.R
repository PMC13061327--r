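# Generators of labelled 2D point patterns emulating the
# immunohistochemistry cell tables (~2,500 cells per section, ~4.5 um
# cell radius, stem fraction of a few percent), with controlled label
# structure: random (the null model), clustered and dispersed.

#' Specification of a synthetic labelled point pattern
#'
#' Defaults emulate a typical section: 2,500 cells on a 450 um square
#' field with a 6% stem fraction.
#'
#' @param n cell count (`>= 10`).
#' @param stem_fraction expected stem fraction, in (0, 1).
#' @param extent side of the square field (micrometres).
#' @param structure `"random"`, `"clustered"` or `"dispersed"`.
#' @param n_clusters number of stem clusters (clustered structure).
#' @param cluster_sd cluster radius parameter in micrometres (clustered).
#' @param min_separation minimum stem-stem distance (dispersed).
#' @param hardcore_radius optional hard-core radius (micrometres): no two
#'   cells closer than twice this value; 0 disables the constraint (the
#'   experimental mean cell radius is 4.5 um).
#' @param seed optional seed applied by the generators.
#'
#' @return An object of class `pattern_spec`.
#' @export
pattern_spec <- function(n = 2500, stem_fraction = 0.06, extent = 450,
                         structure = c("random", "clustered", "dispersed"),
                         n_clusters = 3, cluster_sd = 30,
                         min_separation = 30, hardcore_radius = 0,
                         seed = NULL) {
  structure <- match.arg(structure)
  stopifnot(n >= 10, stem_fraction > 0, stem_fraction < 1, extent > 0,
            n_clusters >= 1, cluster_sd > 0, min_separation > 0,
            hardcore_radius >= 0)
  out <- list(n = n, stem_fraction = stem_fraction, extent = extent,
              structure = structure, n_clusters = n_clusters,
              cluster_sd = cluster_sd, min_separation = min_separation,
              hardcore_radius = hardcore_radius, seed = seed)
  class(out) <- "pattern_spec"
  out
}

# uniform positions, optionally with a hard core (dart throwing)
sample_positions <- function(spec) {
  n <- spec$n
  if (spec$hardcore_radius <= 0) {
    return(cbind(runif(n, 0, spec$extent), runif(n, 0, spec$extent)))
  }
  dmin <- 2 * spec$hardcore_radius
  if (n * pi * spec$hardcore_radius^2 > 0.55 * spec$extent^2)
    stop("hard-core packing infeasible at this density")
  pos <- matrix(NA_real_, n, 2)
  placed <- 0L
  tries <- 0L
  max_tries <- 200L * n
  while (placed < n && tries < max_tries) {
    cand <- runif(2, 0, spec$extent)
    ok <- placed == 0L ||
      min((pos[seq_len(placed), 1] - cand[1])^2 +
            (pos[seq_len(placed), 2] - cand[2])^2) >= dmin^2
    if (ok) {
      placed <- placed + 1L
      pos[placed, ] <- cand
    }
    tries <- tries + 1L
  }
  if (placed < n) stop("hard-core packing failed after ", max_tries, " tries")
  pos
}

#' Random labelled pattern (complete spatial randomness null model)
#'
#' Uniform positions on the field; labels i.i.d. Bernoulli with the
#' requested stem fraction.
#'
#' @param spec a [pattern_spec()] with `structure = "random"`.
#'
#' @return A [cell_table()].
#' @export
gen_random <- function(spec = pattern_spec(structure = "random")) {
  if (!is.null(spec$seed)) set.seed(spec$seed)
  pos <- sample_positions(spec)
  lab <- stats::rbinom(spec$n, 1, spec$stem_fraction)
  cell_table(pos[, 1], pos[, 2], lab)
}

#' Clustered labelled pattern
#'
#' Positions are uniform as in [gen_random()]; the stem labels (exactly
#' `round(n * stem_fraction)` of them) are assigned preferentially to
#' points near `n_clusters` random cluster centres, with Gaussian weight
#' of standard deviation `cluster_sd`.  Labelling a fixed point set
#' isolates label autocorrelation from density effects.
#'
#' @param spec a [pattern_spec()] with `structure = "clustered"`.
#'
#' @return A [cell_table()].
#' @export
gen_clustered <- function(spec = pattern_spec(structure = "clustered")) {
  if (!is.null(spec$seed)) set.seed(spec$seed)
  pos <- sample_positions(spec)
  ns <- max(2L, round(spec$n * spec$stem_fraction))
  ctr <- cbind(runif(spec$n_clusters, 0, spec$extent),
               runif(spec$n_clusters, 0, spec$extent))
  w <- rep(0, spec$n)
  for (k in seq_len(spec$n_clusters)) {
    d2 <- (pos[, 1] - ctr[k, 1])^2 + (pos[, 2] - ctr[k, 2])^2
    w <- w + exp(-d2 / (2 * spec$cluster_sd^2))
  }
  stem_idx <- sample.int(spec$n, ns, prob = w + 1e-12)
  lab <- integer(spec$n)
  lab[stem_idx] <- 1L
  cell_table(pos[, 1], pos[, 2], lab)
}

#' Dispersed labelled pattern (negative autocorrelation control)
#'
#' Positions are uniform; exactly `round(n * stem_fraction)` stem labels
#' are placed greedily so that all stem-stem distances are at least
#' `min_separation` where feasible; when the constraint cannot be met the
#' remaining labels are placed best-effort (maximising the distance to
#' the already placed stems) with a warning.
#'
#' @param spec a [pattern_spec()] with `structure = "dispersed"`.
#'
#' @return A [cell_table()].
#' @export
gen_dispersed <- function(spec = pattern_spec(structure = "dispersed")) {
  if (!is.null(spec$seed)) set.seed(spec$seed)
  pos <- sample_positions(spec)
  ns <- max(1L, round(spec$n * spec$stem_fraction))
  ord <- sample.int(spec$n)
  chosen <- integer(0)
  mind2 <- rep(Inf, spec$n)  # squared distance of each point to chosen stems
  for (i in ord) {
    if (length(chosen) >= ns) break
    if (mind2[i] >= spec$min_separation^2) {
      chosen <- c(chosen, i)
      d2 <- (pos[, 1] - pos[i, 1])^2 + (pos[, 2] - pos[i, 2])^2
      mind2 <- pmin(mind2, d2)
    }
  }
  if (length(chosen) < ns) {
    warning("dispersed labelling infeasible at min_separation = ",
            spec$min_separation, "; placing remaining labels best-effort")
    while (length(chosen) < ns) {
      free <- setdiff(seq_len(spec$n), chosen)
      i <- free[which.max(mind2[free])]
      chosen <- c(chosen, i)
      d2 <- (pos[, 1] - pos[i, 1])^2 + (pos[, 2] - pos[i, 2])^2
      mind2 <- pmin(mind2, d2)
    }
  }
  lab <- integer(spec$n)
  lab[chosen] <- 1L
  cell_table(pos[, 1], pos[, 2], lab)
}

#' Generate a pattern according to its specification
#'
#' Dispatches on `spec$structure`.
#'
#' @param spec a [pattern_spec()].
#' @return A [cell_table()].
#' @export
gen_pattern <- function(spec) {
  switch(spec$structure,
         random = gen_random(spec),
         clustered = gen_clustered(spec),
         dispersed = gen_dispersed(spec))
}

#' Write a cell table to CSV
#'
#' Columns `x_um`, `y_um`, `label` and optionally `radius_um`;
#' coordinates in micrometres.  The round-trip through
#' [read_cell_table()] is lossless.
#'
#' @param table a [cell_table()].
#' @param path output file path.
#' @export
write_cell_table <- function(table, path) {
  table <- validate_cell_table(table)
  write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Read a cell table from CSV
#'
#' Reads either the native schema (`x_um`, `y_um`, `label`) or, via
#' `col_map`, tabular cell-detection exports such as QuPath's.  Label
#' values other than `stem` / `differentiated` can be recoded with
#' `stem_values`.
#'
#' @param path CSV file path.
#' @param col_map optional named character vector mapping native column
#'   names to the file's column names, e.g.
#'   `c(x_um = "Centroid X um", y_um = "Centroid Y um", label = "Class")`.
#' @param stem_values values of the label column to be read as stem
#'   cells (everything else becomes differentiated); `NULL` requires
#'   literal `stem`/`differentiated` values.
#'
#' @return A [cell_table()].
#' @export
read_cell_table <- function(path, col_map = NULL, stem_values = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(col_map)) {
    miss <- setdiff(unname(col_map), names(df))
    if (length(miss) > 0)
      stop("mapped column(s) not found in file: ",
           paste(miss, collapse = ", "))
    for (nm in names(col_map)) df[[nm]] <- df[[col_map[[nm]]]]
  }
  need <- c("x_um", "y_um", "label")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("file is missing column(s): ", paste(miss, collapse = ", "))
  if (!is.null(stem_values))
    df$label <- ifelse(df$label %in% stem_values, "stem", "differentiated")
  keep <- intersect(c(need, "radius_um"), names(df))
  validate_cell_table(df[, keep, drop = FALSE])
}
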