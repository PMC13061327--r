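# Stem-cell signaling terms entering the CD133 burst rate: a binary
# stem-stem contact signal, and a nonlocal diffusive signal equal to the
# Gauss transform of the stem-cell positions (Gaussian kernel of variance
# delta/2, the "reachable area" delta being the squared diffusion length).

#' Diffusive-signal configuration
#'
#' @param q per-source signal strength (default 0.3).
#' @param delta reachable area (spatial units squared); the kernel is
#'   `exp(-d^2 / delta)`, i.e. a Gaussian of standard deviation
#'   `sqrt(delta / 2)`.  `delta = 1` is felt over ~4.5 um, `delta = 2`
#'   over ~6.4 um (about one cell diameter).
#' @param epsilon relative-error tolerance of the fast transform.
#' @param method `"fast"` (grid-truncated, error `<= epsilon`) or
#'   `"direct"` (exact summation).
#' @param perception which cells evaluate the signal: `"all"` (default;
#'   every cell's CD133 gene senses the field, which lets differentiated
#'   cells be pulled back toward stemness) or `"stem"` (stem cells only).
#' @param include_self whether a stem cell perceives its own emission
#'   (autocrine term), default `TRUE`.
#'
#' @return An object of class `diffusion_config`.
#' @export
diffusion_config <- function(q = 0.3, delta = 2, epsilon = 0.01,
                             method = c("fast", "direct"),
                             perception = c("all", "stem"),
                             include_self = TRUE) {
  method <- match.arg(method)
  perception <- match.arg(perception)
  stopifnot(q >= 0, delta > 0, epsilon > 0)
  structure(list(q = q, delta = delta, epsilon = epsilon, method = method,
                 perception = perception, include_self = include_self),
            class = "diffusion_config")
}

#' Binary stem-stem contact signal
#'
#' A cell receives `S = 1` iff it is a stem cell and at least one of its
#' contact neighbors is a stem cell; both emission and perception of the
#' contact signal are stem-cell characteristics.  The signal enters the
#' CD133 sigmoid as `+ gamma * S`.
#'
#' @param types cell types: character (`"stem"`/`"differentiated"`) or
#'   integer codes (1 = stem, 0 = differentiated).
#' @param contacts 2-column contact pair matrix from [find_contacts()].
#'
#' @return Integer vector of 0/1 per cell.
#' @export
contact_signal <- function(types, contacts) {
  if (is.character(types)) types <- as.integer(types == "stem")
  n <- length(types)
  S <- integer(n)
  if (NROW(contacts) > 0) {
    i <- contacts[, 1]
    j <- contacts[, 2]
    ss <- types[i] == 1L & types[j] == 1L
    S[i[ss]] <- 1L
    S[j[ss]] <- 1L
  }
  S
}

#' Direct Gauss transform
#'
#' Exact evaluation of `S(t) = sum_j q_j exp(-||t - h_j||^2 / delta)` at
#' every target.  A target coinciding with a source includes that
#' source's full contribution `q_j`.
#'
#' @param source_positions n_s x d matrix of source locations.
#' @param q source strengths: scalar or length-n_s vector.
#' @param delta reachable area (`> 0`).
#' @param target_positions n_t x d matrix of target locations.
#'
#' @return Numeric vector of length n_t.
#' @export
gauss_transform_direct <- function(source_positions, q, delta,
                                   target_positions) {
  stopifnot(delta > 0)
  src <- as.matrix(source_positions)
  tgt <- as.matrix(target_positions)
  if (nrow(src) == 0) return(numeric(nrow(tgt)))
  stopifnot(ncol(src) == ncol(tgt))
  q <- rep_len(as.numeric(q), nrow(src))
  gauss_direct_cpp(src, q, delta, tgt)
}

#' Fast Gauss transform with a relative-error guarantee
#'
#' Grid-binned truncated evaluation: for each target, all sources within
#' an adaptive cutoff (anchored at the nearest source) are summed and the
#' neglected tail is provably at most `epsilon` times the retained sum,
#' so the per-target relative error against [gauss_transform_direct()]
#' is bounded by `epsilon`.  Cost is near-linear in sources + targets for
#' spatially bounded configurations.
#'
#' @inheritParams gauss_transform_direct
#' @param epsilon relative-error tolerance (`> 0`), default 0.01.
#'
#' @return Numeric vector of length n_t.
#' @export
gauss_transform_fast <- function(source_positions, q, delta,
                                 target_positions, epsilon = 0.01) {
  stopifnot(delta > 0, epsilon > 0)
  src <- as.matrix(source_positions)
  tgt <- as.matrix(target_positions)
  if (nrow(src) == 0) return(numeric(nrow(tgt)))
  stopifnot(ncol(src) == ncol(tgt))
  if (ncol(src) == 2) {  # embed planar configurations
    src <- cbind(src, 0)
    tgt <- cbind(tgt, 0)
  }
  q <- rep_len(as.numeric(q), nrow(src))
  gauss_fast_cpp(src, q, delta, tgt, epsilon)
}

#' Diffusive signal perceived by each cell of a population
#'
#' Sources are the current stem cells (strength `q` each, located at the
#' cell centres).  Depending on `cfg$perception`, either every cell or
#' only stem cells evaluate the field; non-perceiving cells get 0.  With
#' `include_self = TRUE` a stem cell's own emission contributes `q`
#' (autocrine term), so an isolated stem cell perceives exactly `q`.
#'
#' @param pos n x 3 matrix of cell centres.
#' @param types cell types (character or 0/1 integer, 1 = stem).
#' @param cfg a [diffusion_config()].
#'
#' @return Numeric vector of per-cell perceived intensities `S_diff`.
#' @export
perceived_diffusive_signal <- function(pos, types, cfg = diffusion_config()) {
  if (is.character(types)) types <- as.integer(types == "stem")
  pos <- as.matrix(pos)
  n <- nrow(pos)
  stem <- which(types == 1L)
  out <- numeric(n)
  if (length(stem) == 0) return(out)
  tgt_idx <- if (cfg$perception == "stem") stem else seq_len(n)
  src <- pos[stem, , drop = FALSE]
  tgt <- pos[tgt_idx, , drop = FALSE]
  f <- if (cfg$method == "direct") {
    gauss_transform_direct(src, cfg$q, cfg$delta, tgt)
  } else {
    gauss_transform_fast(src, cfg$q, cfg$delta, tgt, cfg$epsilon)
  }
  if (!cfg$include_self) {
    # subtract each stem target's own kernel contribution (exp(0) = 1)
    self_pos <- match(tgt_idx, stem)
    f[!is.na(self_pos)] <- f[!is.na(self_pos)] - cfg$q
    f <- pmax(f, 0)
  }
  out[tgt_idx] <- f
  out
}
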