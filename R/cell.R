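# Single-cell life cycle: linear volume growth capped at Vmax, division
# gated jointly by volume doubling and the Cyclin E protein level, fate
# (stem vs differentiated) re-assessed at division from the CD133 protein.

CELL_TYPES <- c("differentiated", "stem")  # coded 0 / 1 internally

#' Fate and growth configuration
#'
#' @param differentiation_threshold threshold `Th` on the CD133 protein:
#'   a daughter cell is stem iff `P_CD133 >= Th` at division.
#' @param proliferation_threshold threshold on the Cyclin E protein
#'   gating division (default 0.01).
#' @param growth_rate volume growth rate `g` (volume units per hour);
#'   the default 0.05 corresponds to a ~20 h volume doubling.
#'
#' @return An object of class `fate_config`.
#' @export
fate_config <- function(differentiation_threshold = 0.004,
                        proliferation_threshold = 0.01,
                        growth_rate = 0.05) {
  stopifnot(differentiation_threshold > 0, proliferation_threshold > 0,
            growth_rate > 0)
  structure(list(differentiation_threshold = differentiation_threshold,
                 proliferation_threshold = proliferation_threshold,
                 growth_rate = growth_rate),
            class = "fate_config")
}

#' Radius of a spherical cell from its volume
#'
#' `r = (3 V / (4 pi))^(1/3)`; a unit-volume cell has radius ~0.62
#' spatial units (~4 um) and a division-ready cell (V = 2) ~0.78 units
#' (~5 um).
#'
#' @param V volume(s), dimensionless sphere-volume units; must be `> 0`.
#'
#' @return Radius in spatial units.
#' @export
radius_from_volume <- function(V) {
  if (any(V <= 0)) stop("volume must be positive")
  (3 * V / (4 * pi))^(1 / 3)
}

#' One cell agent
#'
#' Constructor for a single cell state, mainly used in unit tests and
#' small examples; the simulator stores the population in column form
#' (see [initialize_population()]).
#'
#' @param id integer cell id.
#' @param position numeric length-3 centre (spatial units).
#' @param volume volume in `[1, 2.2]`.
#' @param type `"stem"` or `"differentiated"`.
#' @param grn a [grn_state()].
#' @param mother_id id of the mother cell or `NA`.
#' @param birth_time time of birth (hours).
#' @param speed self-propulsion speed (spatial units per hour).
#' @param core_ratio ratio of the rigid-core radius to the external
#'   radius, in (0, 1).
#'
#' @return An object of class `cell_state`.
#' @export
cell_state <- function(id, position = c(0, 0, 0), volume = 1,
                       type = c("stem", "differentiated"),
                       grn = grn_state(), mother_id = NA_integer_,
                       birth_time = 0, speed = 0, core_ratio = 0.5) {
  type <- match.arg(type)
  stopifnot(volume >= 1, volume <= 2.2, length(position) == 3,
            core_ratio > 0, core_ratio < 1)
  r <- radius_from_volume(volume)
  structure(list(id = as.integer(id), mother_id = as.integer(mother_id),
                 type = type, position = as.numeric(position),
                 volume = volume, r_external = r,
                 r_internal = core_ratio * r, core_ratio = core_ratio,
                 speed = speed, grn = grn, birth_time = birth_time),
            class = "cell_state")
}

#' Grow a cell linearly in volume
#'
#' Volume increases at constant rate `g` and is capped at the maximum
#' volume 2.2; both radii are updated consistently.
#'
#' @param cell a [cell_state()].
#' @param dt time step (hours).
#' @param g growth rate (volume units per hour).
#' @param v_max maximum volume (default 2.2).
#'
#' @return The grown `cell_state`.
#' @export
grow <- function(cell, dt, g = 0.05, v_max = 2.2) {
  stopifnot(dt >= 0)
  cell$volume <- min(cell$volume + g * dt, v_max)
  cell$r_external <- radius_from_volume(cell$volume)
  cell$r_internal <- cell$core_ratio * cell$r_external
  cell
}

#' Is a cell ready to divide?
#'
#' A cell divides when its volume has at least doubled (`V >= 2`) and the
#' Cyclin E protein has reached the proliferation threshold.
#'
#' @param cell a [cell_state()].
#' @param cfg a [fate_config()].
#'
#' @return Logical.
#' @export
can_divide <- function(cell, cfg = fate_config()) {
  cell$volume >= 2 && cell$grn$P[["CyclinE"]] >= cfg$proliferation_threshold
}

#' Assign stem or differentiated fate from the CD133 protein level
#'
#' Boundary-inclusive rule: stem iff `P_CD133 >= Th`.  Under the model's
#' initial condition `P_CD133 = 2 Th`, halving at the first division
#' leaves daughters exactly at `Th`, so the first generation can remain
#' stem.
#'
#' @param P_CD133 CD133 protein amount(s).
#' @param Th differentiation threshold (`> 0`).
#'
#' @return Character vector, `"stem"` or `"differentiated"`.
#' @export
assign_fate <- function(P_CD133, Th) {
  stopifnot(Th > 0)
  ifelse(P_CD133 >= Th, "stem", "differentiated")
}

#' Divide a cell into two daughters
#'
#' Each daughter inherits half the mother's volume and half of every
#' molecular amount (mRNA and protein).  Daughters are placed at the
#' mother centre plus/minus `eps * u` for a uniformly random unit vector
#' `u`, with `eps` equal to half the daughter radius; the mechanics layer
#' then resolves residual overlap.  Fates are re-assessed from the
#' daughters' CD133 protein.
#'
#' @param cell a [cell_state()] for which [can_divide()] holds.
#' @param cfg a [fate_config()].
#' @param time division time (hours), recorded as the daughters' birth time.
#' @param ids integer length-2 vector of ids for the daughters.
#'
#' @return A list with elements `daughters` (list of two `cell_state`)
#'   and `event` (one-row data.frame: time, mother id and type, daughter
#'   ids and types, de-differentiation flag).
#' @export
divide <- function(cell, cfg = fate_config(), time = 0,
                   ids = cell$id + c(1L, 2L)) {
  u <- random_unit_vector()
  v <- cell$volume / 2
  eps <- radius_from_volume(v) / 2
  g2 <- grn_state(cell$grn$M / 2, cell$grn$P / 2)
  mk <- function(id, sgn) {
    cell_state(id = id, position = cell$position + sgn * eps * u,
               volume = v,
               type = assign_fate(g2$P[["CD133"]],
                                  cfg$differentiation_threshold),
               grn = g2, mother_id = cell$id, birth_time = time,
               speed = cell$speed, core_ratio = cell$core_ratio)
  }
  d1 <- mk(ids[1], +1)
  d2 <- mk(ids[2], -1)
  event <- data.frame(time = time, mother_id = cell$id,
                      mother_type = cell$type,
                      daughter1_id = d1$id, daughter2_id = d2$id,
                      daughter1_type = d1$type, daughter2_type = d2$type,
                      dedifferentiation = is_dedifferentiation(
                        cell$type, d1$type, d2$type),
                      stringsAsFactors = FALSE)
  list(daughters = list(d1, d2), event = event)
}

#' Is a division event a de-differentiation event?
#'
#' True iff a differentiated mother gives rise to two stem daughters,
#' i.e. the mother's CD133 protein rose above twice the threshold during
#' its lifetime.  Such jumps between cell types are a by-product of the
#' stochastic network, whose types are basins of attraction rather than
#' hard-wired states.
#'
#' @param mother_type,daughter1_type,daughter2_type cell types
#'   (`"stem"` or `"differentiated"`); vectorised.
#'
#' @return Logical.
#' @export
is_dedifferentiation <- function(mother_type, daughter1_type, daughter2_type) {
  mother_type == "differentiated" &
    daughter1_type == "stem" & daughter2_type == "stem"
}

random_unit_vector <- function() {
  repeat {
    v <- rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-12) return(v / n)
  }
}
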