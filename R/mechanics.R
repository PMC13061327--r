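# Off-lattice 3D mechanics: contact detection on a uniform grid, pairwise
# overlap relaxation of visco-elastic spheres with rigid cores, and the
# "motile" self-propelled movement mode with contact-class-dependent speeds.

#' Simulation domain
#'
#' Cells live in a cube `[0, L]^3` with reflexive boundaries; one spatial
#' unit corresponds to 6.4 micrometres.
#'
#' @param L edge length in spatial units (default 80, i.e. 512 um).
#' @param unit_to_um conversion factor (micrometres per spatial unit).
#'
#' @return An object of class `sim_domain`.
#' @export
sim_domain <- function(L = 80, unit_to_um = um_per_unit()) {
  stopifnot(L > 0, unit_to_um > 0)
  structure(list(L = L, unit_to_um = unit_to_um), class = "sim_domain")
}

#' Contact-dependent velocity rules for motile cells
#'
#' A motile cell without contacts moves at `default_speed`.  On contact
#' the speed is set by the classes in contact: a stem cell with at least
#' one stem neighbor takes `v_SS`; a stem cell with only differentiated
#' neighbors, or a differentiated cell with at least one stem neighbor,
#' takes `v_SD`; a differentiated cell with only differentiated neighbors
#' takes `v_DD`.  Low values mimic cell-cell adhesion.
#'
#' @param default_speed free speed, spatial units per hour (default 0.3).
#' @param v_SS,v_SD,v_DD contact speeds (spatial units per hour).
#'
#' @return An object of class `velocity_rules`.
#' @export
velocity_rules <- function(default_speed = 0.3, v_SS = default_speed,
                           v_SD = default_speed, v_DD = default_speed) {
  stopifnot(default_speed >= 0, v_SS >= 0, v_SD >= 0, v_DD >= 0)
  structure(list(default_speed = default_speed, v_SS = v_SS,
                 v_SD = v_SD, v_DD = v_DD), class = "velocity_rules")
}

#' Find all cell-cell contacts
#'
#' Two cells are in contact when the distance of their centres is smaller
#' than the sum of their external radii.  Uses a uniform spatial grid, so
#' the cost is near-linear in the number of cells.
#'
#' @param pos n x 3 matrix of cell centres (spatial units).
#' @param r_ext external radii, length n.
#'
#' @return Integer matrix with two columns `i`, `j` (1-based, `i < j`),
#'   one row per unordered contact pair.
#' @export
find_contacts <- function(pos, r_ext) {
  pos <- as.matrix(pos)
  stopifnot(ncol(pos) == 3, length(r_ext) == nrow(pos))
  out <- find_contacts_cpp(pos, as.numeric(r_ext))
  colnames(out) <- c("i", "j")
  out
}

#' Resolve overlaps between cells
#'
#' Applies pairwise central repulsive displacements to overlapping pairs:
#' a soft push proportional to the external-radius overlap and a ten-fold
#' stiffer push on rigid-core overlap, in an overdamped Jacobi iteration.
#' Sweeps repeat until the largest core overlap falls below `tol` or
#' `max_sweeps` is reached; soft shell overlap may persist across steps
#' (visco-elastic behavior).  Deterministic given positions.
#'
#' @param pos n x 3 matrix of centres.
#' @param r_int,r_ext core and external radii.
#' @param L domain edge length; positions are reflected into `[0, L]^3`.
#' @param eta_shell per-sweep displacement fraction of the shell overlap.
#' @param eta_core additional fraction applied to core overlap
#'   (stiffness ratio core:shell = 10:1 by default).
#' @param tol core-overlap tolerance (spatial units).
#' @param max_sweeps maximum relaxation sweeps per call.
#'
#' @return List with `pos` (new positions), `sweeps`, `converged`; a
#'   warning is emitted when the core tolerance was not reached.
#' @export
relax_overlaps <- function(pos, r_int, r_ext, L = 80,
                           eta_shell = 0.05, eta_core = 10 * eta_shell,
                           tol = 1e-3, max_sweeps = 20) {
  pos <- as.matrix(pos)
  out <- relax_overlaps_cpp(pos, as.numeric(r_int), as.numeric(r_ext),
                            L, eta_shell, eta_core, tol, max_sweeps)
  if (!out$converged)
    warning("overlap relaxation did not reach core tolerance after ",
            out$sweeps, " sweeps (crowded configuration)")
  out
}

#' Speed of a motile cell from its contact classes
#'
#' @param type cell type, `"stem"` or `"differentiated"`.
#' @param neighbor_types character vector of contact neighbor types
#'   (possibly empty).
#' @param rules a [velocity_rules()].
#'
#' @return Speed in spatial units per hour.
#' @export
motile_speed <- function(type, neighbor_types, rules = velocity_rules()) {
  if (length(neighbor_types) == 0) return(rules$default_speed)
  any_stem <- any(neighbor_types == "stem")
  if (type == "stem") {
    if (any_stem) rules$v_SS else rules$v_SD
  } else {
    if (any_stem) rules$v_SD else rules$v_DD
  }
}

# vectorised speed table used by the simulator: types is 0/1 (diff/stem),
# contacts a 2-column pair matrix
contact_speeds <- function(types, contacts, rules) {
  n <- length(types)
  has_contact <- logical(n)
  has_stem_nb <- logical(n)
  if (nrow(contacts) > 0) {
    i <- contacts[, 1]
    j <- contacts[, 2]
    has_contact[i] <- TRUE
    has_contact[j] <- TRUE
    stem_i <- types[i] == 1L
    stem_j <- types[j] == 1L
    has_stem_nb[i[stem_j]] <- TRUE
    has_stem_nb[j[stem_i]] <- TRUE
  }
  sp <- rep(rules$default_speed, n)
  stem <- types == 1L
  sp[has_contact & stem & has_stem_nb] <- rules$v_SS
  sp[has_contact & stem & !has_stem_nb] <- rules$v_SD
  sp[has_contact & !stem & has_stem_nb] <- rules$v_SD
  sp[has_contact & !stem & !has_stem_nb] <- rules$v_DD
  sp
}

# reflect positions into [0, L]^3; returns list(pos, reflected flag per cell)
reflect_into_domain <- function(pos, L) {
  refl <- logical(nrow(pos))
  for (c in 1:3) {
    x <- pos[, c]
    bad <- x < 0 | x > L
    x[x < 0] <- -x[x < 0]
    x[x > L] <- 2 * L - x[x > L]
    x <- pmin(pmax(x, 0), L)
    pos[, c] <- x
    refl <- refl | bad
  }
  list(pos = pos, reflected = refl)
}

#' Advance cell positions for one time step
#'
#' In `"mobile"` mode cells move only through overlap relaxation (passive
#' forces from growth and division).  In `"motile"` mode each cell first
#' advances `speed * dt` along a persistent random heading (re-drawn when
#' the cell is in contact or was reflected at a boundary) and overlaps
#' are then relaxed.  All centres stay inside the domain.
#'
#' @param pos n x 3 centre matrix.
#' @param r_int,r_ext radii vectors.
#' @param speed per-cell speeds (motile mode).
#' @param heading n x 3 matrix of unit heading vectors (motile mode);
#'   modified headings are returned.
#' @param redraw logical vector: cells whose heading must be re-drawn
#'   before moving (contact events).
#' @param dt time step (hours).
#' @param domain a [sim_domain()].
#' @param mode `"mobile"` or `"motile"`.
#' @param ... passed to [relax_overlaps()].
#'
#' @return List with `pos`, `heading`, `redraw` (cells reflected this
#'   step, whose heading is re-drawn next step).
#' @export
update_positions <- function(pos, r_int, r_ext, speed = NULL, heading = NULL,
                             redraw = NULL, dt = 0.1, domain = sim_domain(),
                             mode = c("mobile", "motile"), ...) {
  mode <- match.arg(mode)
  pos <- as.matrix(pos)
  n <- nrow(pos)
  reflected <- logical(n)
  if (mode == "motile") {
    if (is.null(heading)) heading <- random_headings(n)
    if (!is.null(redraw) && any(redraw))
      heading[redraw, ] <- random_headings(sum(redraw))
    pos <- pos + heading * (speed * dt)
    rf <- reflect_into_domain(pos, domain$L)
    pos <- rf$pos
    reflected <- rf$reflected
  }
  rel <- suppressWarnings(
    relax_overlaps(pos, r_int, r_ext, L = domain$L, ...))
  list(pos = rel$pos, heading = heading, redraw = reflected,
       converged = rel$converged)
}

random_headings <- function(n) {
  m <- matrix(rnorm(3 * n), n, 3)
  m / sqrt(rowSums(m^2))
}
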