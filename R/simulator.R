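# Population-level orchestration: initial cluster of stem cells, the
# per-step update (contacts -> signaling -> stochastic gene expression ->
# growth -> divisions -> movement), event logging and the scan driver.

#' Full simulation configuration
#'
#' Bundles every model parameter.  Defaults reproduce the reference
#' conditions: `dt = 0.1` h, 15 initial stem cells at the centre of an
#' 80-unit cube, stop when the population exceeds `stop_count` cells
#' (desk-scale default 10,000; the full-scale experiments use 50,000).
#'
#' @param dt time step in hours.
#' @param n_init number of initial stem cells.
#' @param stop_count stop once the population exceeds this count.
#' @param scenario signaling scenario: `"none"`, `"contact"` (stem-stem
#'   contact signal of strength `gamma`) or `"diffusive"` (nonlocal
#'   Gaussian signal, see [diffusion_config()]).
#' @param gamma contact-signal strength added to the CD133 sigmoid.
#' @param diffusion a [diffusion_config()].
#' @param params a [gene_params()].
#' @param theta interaction matrix, see [interaction_matrix()].
#' @param fate a [fate_config()]; `fate$differentiation_threshold` is the
#'   stem/differentiated threshold `Th`.
#' @param domain a [sim_domain()].
#' @param motility `"mobile"` (passive, forces only) or `"motile"`
#'   (self-propelled with contact-dependent speeds).
#' @param rules a [velocity_rules()] (motile mode).
#' @param core_ratio rigid-core to external radius ratio.
#' @param eta_shell,eta_core,relax_tol,max_sweeps overlap-relaxation
#'   controls, see [relax_overlaps()].
#' @param snapshot_stride store a full population snapshot every this
#'   many steps (0 = final state only).
#' @param max_hours simulated-time safety stop (hours).
#' @param max_wall_secs wall-clock budget; exceeded runs return a
#'   partial result flagged in `stopped`.
#'
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(dt = 0.1, n_init = 15, stop_count = 10000,
                              scenario = c("none", "contact", "diffusive"),
                              gamma = 0.3,
                              diffusion = diffusion_config(),
                              params = gene_params(),
                              theta = interaction_matrix(),
                              fate = fate_config(),
                              domain = sim_domain(),
                              motility = c("mobile", "motile"),
                              rules = velocity_rules(),
                              core_ratio = 0.5,
                              eta_shell = 0.05, eta_core = 10 * eta_shell,
                              relax_tol = 1e-3, max_sweeps = 20,
                              snapshot_stride = 0,
                              max_hours = 5000,
                              max_wall_secs = Inf) {
  scenario <- match.arg(scenario)
  motility <- match.arg(motility)
  stopifnot(dt > 0, n_init >= 1, stop_count > n_init, gamma >= 0,
            core_ratio > 0, core_ratio < 1)
  structure(list(dt = dt, n_init = n_init, stop_count = stop_count,
                 scenario = scenario, gamma = gamma, diffusion = diffusion,
                 params = params, theta = theta, fate = fate,
                 domain = domain, motility = motility, rules = rules,
                 core_ratio = core_ratio, eta_shell = eta_shell,
                 eta_core = eta_core, relax_tol = relax_tol,
                 max_sweeps = max_sweeps,
                 snapshot_stride = snapshot_stride,
                 max_hours = max_hours, max_wall_secs = max_wall_secs),
            class = "simulation_config")
}

#' Initial population: a compact cluster of stem cells
#'
#' Places `n_init` unit-volume stem cells side by side (touching spheres
#' on a cubic packing) at the centre of the domain.  Molecular state per
#' cell: CD133 protein at twice the differentiation threshold (so the
#' first daughter generation can remain stem), all other proteins 0, all
#' mRNA 0 except CD133 mRNA drawn i.i.d. from an exponential burst
#' distribution with mean 50 molecules.
#'
#' @param cfg a [simulation_config()].
#'
#' @return An object of class `cell_population`: a list of parallel
#'   arrays (`pos`, `volume`, `type`, `M`, `P`, `id`, `mother_id`,
#'   `birth_time`, `speed`, `heading`) plus bookkeeping fields.
#' @export
initialize_population <- function(cfg = simulation_config()) {
  n <- cfg$n_init
  r <- radius_from_volume(1)
  spacing <- 2 * r
  m <- ceiling(n^(1 / 3)) + 1
  g <- expand.grid(i = -m:m, j = -m:m, k = -m:m)
  off <- as.matrix(g) * spacing
  ord <- order(rowSums(off^2), g$i, g$j, g$k)
  off <- off[ord[seq_len(n)], , drop = FALSE]
  centre <- rep(cfg$domain$L / 2, 3)
  pos <- sweep(off, 2, centre, `+`)
  if (any(pos < 0) || any(pos > cfg$domain$L))
    stop("initial cluster does not fit inside the domain")
  Th <- cfg$fate$differentiation_threshold
  M <- matrix(0, n, 3, dimnames = list(NULL, gene_names()))
  P <- matrix(0, n, 3, dimnames = list(NULL, gene_names()))
  M[, 1] <- rexp(n, 1) * cfg$params$burst_mean[[1]]
  P[, 1] <- 2 * Th
  pop <- list(n = n,
              pos = unname(pos),
              volume = rep(1, n),
              type = rep(1L, n),           # 1 = stem, 0 = differentiated
              M = M, P = P,
              id = seq_len(n),
              mother_id = rep(NA_integer_, n),
              birth_time = rep(0, n),
              speed = rep(cfg$rules$default_speed, n),
              heading = random_headings(n),
              redraw = logical(n),
              next_id = n + 1L,
              core_ratio = cfg$core_ratio)
  class(pop) <- "cell_population"
  pop
}

#' External radii of all cells in a population
#'
#' @param pop a `cell_population`.
#' @return Numeric vector of external radii (spatial units).
#' @export
population_radii <- function(pop) radius_from_volume(pop$volume)

#' One simulation tick
#'
#' Sub-step order (signal computed from start-of-step state):
#' contacts, signaling terms, per-cell stochastic gene-network advance,
#' volume growth, divisions with fate assignment and event logging, then
#' movement with overlap relaxation and boundary reflection.
#'
#' @param pop a `cell_population`.
#' @param cfg a [simulation_config()].
#' @param t current time (hours), used to stamp division events.
#'
#' @return List with `pop` (updated population) and `events` (NULL or a
#'   data.frame of this step's divisions).
#' @export
sim_step <- function(pop, cfg, t = 0) {
  r_ext <- radius_from_volume(pop$volume)
  contacts <- find_contacts(pop$pos, r_ext)

  signal <- numeric(pop$n)
  if (cfg$scenario == "contact") {
    signal <- cfg$gamma * contact_signal(pop$type, contacts)
  } else if (cfg$scenario == "diffusive") {
    signal <- perceived_diffusive_signal(pop$pos, pop$type, cfg$diffusion)
  }

  adv <- pdmp_advance_cpp(pop$M, pop$P, cfg$dt,
                          cfg$params$d0, cfg$params$d1, cfg$params$s1,
                          cfg$params$k0, cfg$params$k1, cfg$params$beta,
                          cfg$params$burst_mean, cfg$theta, signal)
  pop$M <- adv$M
  pop$P <- adv$P

  pop$volume <- pmin(pop$volume + cfg$fate$growth_rate * cfg$dt, 2.2)

  if (cfg$motility == "motile") {
    pop$speed <- contact_speeds(pop$type, contacts, cfg$rules)
    if (nrow(contacts) > 0)  # contact events re-randomize the heading
      pop$redraw[unique(as.vector(contacts))] <- TRUE
  }

  div <- which(pop$volume >= 2 &
                 pop$P[, 3] >= cfg$fate$proliferation_threshold)
  events <- NULL
  if (length(div) > 0) {
    nd <- length(div)
    Th <- cfg$fate$differentiation_threshold
    u <- random_headings(nd)
    vol_d <- pop$volume[div] / 2
    eps <- radius_from_volume(vol_d) / 2
    Md <- pop$M[div, , drop = FALSE] / 2
    Pd <- pop$P[div, , drop = FALSE] / 2
    type_d <- as.integer(Pd[, 1] >= Th)
    mother_id <- pop$id[div]
    mother_type <- pop$type[div]
    id1 <- pop$next_id + seq_len(nd) - 1L
    id2 <- pop$next_id + nd + seq_len(nd) - 1L
    pop$next_id <- pop$next_id + 2L * nd

    events <- data.frame(
      time = t, mother_id = mother_id,
      mother_type = CELL_TYPES[mother_type + 1L],
      daughter1_id = id1, daughter2_id = id2,
      daughter1_type = CELL_TYPES[type_d + 1L],
      daughter2_type = CELL_TYPES[type_d + 1L],
      dedifferentiation = mother_type == 0L & type_d == 1L,
      stringsAsFactors = FALSE)

    pos1 <- pop$pos[div, , drop = FALSE] + u * eps
    pos2 <- pop$pos[div, , drop = FALSE] - u * eps
    # daughter 1 replaces the mother in place; daughter 2 is appended
    pop$pos[div, ] <- pos1
    pop$volume[div] <- vol_d
    pop$type[div] <- type_d
    pop$M[div, ] <- Md
    pop$P[div, ] <- Pd
    pop$id[div] <- id1
    pop$mother_id[div] <- mother_id
    pop$birth_time[div] <- t
    pop$redraw[div] <- TRUE

    pop$pos <- rbind(pop$pos, pos2)
    pop$volume <- c(pop$volume, vol_d)
    pop$type <- c(pop$type, type_d)
    pop$M <- rbind(pop$M, Md)
    pop$P <- rbind(pop$P, Pd)
    pop$id <- c(pop$id, id2)
    pop$mother_id <- c(pop$mother_id, mother_id)
    pop$birth_time <- c(pop$birth_time, rep(t, nd))
    pop$speed <- c(pop$speed, pop$speed[div])
    pop$heading <- rbind(pop$heading, random_headings(nd))
    pop$redraw <- c(pop$redraw, rep(TRUE, nd))
    pop$n <- pop$n + nd
  }

  r_ext <- radius_from_volume(pop$volume)
  upd <- update_positions(pop$pos, pop$core_ratio * r_ext, r_ext,
                          speed = pop$speed, heading = pop$heading,
                          redraw = pop$redraw, dt = cfg$dt,
                          domain = cfg$domain, mode = cfg$motility,
                          eta_shell = cfg$eta_shell,
                          eta_core = cfg$eta_core,
                          tol = cfg$relax_tol,
                          max_sweeps = cfg$max_sweeps)
  pop$pos <- upd$pos
  if (cfg$motility == "motile") {
    pop$heading <- upd$heading
    pop$redraw <- upd$redraw
  } else {
    pop$redraw <- logical(pop$n)
  }
  list(pop = pop, events = events)
}

#' Run a tumoroid growth simulation
#'
#' Seeds the random-number generator, builds the initial stem-cell
#' cluster and iterates [sim_step()] until the population exceeds
#' `cfg$stop_count` (or a safety budget is hit, in which case the result
#' is flagged partial).  Identical `seed` and `cfg` give bit-identical
#' results.
#'
#' @param cfg a [simulation_config()].
#' @param seed integer seed for R's global RNG.
#'
#' @return An object of class `simulation_result`: list with `final`
#'   (the end-state `cell_population`), `divisions` (the division log,
#'   one row per event with de-differentiation flags), `snapshots`
#'   (named list of population tables, present when
#'   `cfg$snapshot_stride > 0`), `hours`, `n_steps`, `stopped` (one of
#'   `"stop_count"`, `"max_hours"`, `"wall"`), `seed` and `wall_secs`.
#' @export
run_simulation <- function(cfg = simulation_config(), seed = 1) {
  set.seed(seed)
  t_start <- proc.time()[["elapsed"]]
  pop <- initialize_population(cfg)
  logs <- list()
  snaps <- list()
  step_i <- 0L
  stopped <- "stop_count"
  while (pop$n <= cfg$stop_count) {
    t <- step_i * cfg$dt
    if (t >= cfg$max_hours) {
      stopped <- "max_hours"
      break
    }
    if ((proc.time()[["elapsed"]] - t_start) > cfg$max_wall_secs) {
      stopped <- "wall"
      break
    }
    out <- sim_step(pop, cfg, t)
    pop <- out$pop
    if (!is.null(out$events)) logs[[length(logs) + 1L]] <- out$events
    step_i <- step_i + 1L
    if (cfg$snapshot_stride > 0 && step_i %% cfg$snapshot_stride == 0L)
      snaps[[sprintf("t%.1f", step_i * cfg$dt)]] <- population_table(pop)
  }
  divisions <- if (length(logs) > 0) {
    do.call(rbind, logs)
  } else {
    data.frame(time = numeric(0), mother_id = integer(0),
               mother_type = character(0), daughter1_id = integer(0),
               daughter2_id = integer(0), daughter1_type = character(0),
               daughter2_type = character(0), dedifferentiation = logical(0),
               stringsAsFactors = FALSE)
  }
  structure(list(final = pop, divisions = divisions, snapshots = snaps,
                 hours = step_i * cfg$dt, n_steps = step_i,
                 stopped = stopped, seed = seed, config = cfg,
                 wall_secs = proc.time()[["elapsed"]] - t_start),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("tumoroid simulation:", x$final$n, "cells after", x$hours,
      "simulated hours (", x$n_steps, "steps, seed", x$seed, ")\n")
  cat("  divisions:", nrow(x$divisions),
      " de-differentiation events:", sum(x$divisions$dedifferentiation), "\n")
  cat("  stem fraction:", round(100 * mean(x$final$type == 1L), 2), "%\n")
  if (x$stopped != "stop_count")
    cat("  PARTIAL RESULT: stopped by", x$stopped, "\n")
  invisible(x)
}

#' Flat table of a population's cell states
#'
#' @param pop a `cell_population`.
#' @param signal optional per-cell perceived signal to include.
#'
#' @return Data frame with id, mother id, type, position, volume, radius
#'   and the per-gene molecular amounts.
#' @export
population_table <- function(pop, signal = NULL) {
  g <- gene_names()
  df <- data.frame(id = pop$id, mother_id = pop$mother_id,
                   type = CELL_TYPES[pop$type + 1L],
                   x = pop$pos[, 1], y = pop$pos[, 2], z = pop$pos[, 3],
                   volume = pop$volume,
                   r_ext = radius_from_volume(pop$volume),
                   birth_time = pop$birth_time,
                   stringsAsFactors = FALSE)
  M <- pop$M
  P <- pop$P
  colnames(M) <- paste0("M_", g)
  colnames(P) <- paste0("P_", g)
  df <- cbind(df, M, P)
  if (!is.null(signal)) df$signal <- signal
  df
}

#' Fraction of divisions that are de-differentiation events
#'
#' 100 times the number of divisions in which a differentiated mother
#' produced two stem daughters, over all division events.
#'
#' @param result a `simulation_result` (or any data.frame shaped like
#'   its `divisions` log).
#'
#' @return Percentage; `NA` with a warning when no division occurred.
#' @export
dedifferentiation_fraction <- function(result) {
  log <- if (inherits(result, "simulation_result")) result$divisions
         else result
  if (nrow(log) == 0) {
    warning("no division events: de-differentiation fraction is undefined")
    return(NA_real_)
  }
  100 * sum(log$dedifferentiation) / nrow(log)
}

# apply a named scan parameter to a configuration
set_scan_parameter <- function(cfg, name, value) {
  switch(name,
    gamma = { cfg$gamma <- value },
    Th = ,
    differentiation_threshold = {
      cfg$fate$differentiation_threshold <- value
    },
    delta = { cfg$diffusion$delta <- value },
    q = { cfg$diffusion$q <- value },
    v_SS = { cfg$rules$v_SS <- value },
    v_SD = { cfg$rules$v_SD <- value },
    v_DD = { cfg$rules$v_DD <- value },
    default_speed = { cfg$rules$default_speed <- value },
    growth_rate = { cfg$fate$growth_rate <- value },
    stop_count = { cfg$stop_count <- value },
    stop("unknown scan parameter: ", name)
  )
  cfg
}

#' Parameter scan with index classification
#'
#' Runs replicate simulations for every row of a parameter grid, computes
#' the four spatial indices (stem percentage, Moran's I, entropy,
#' centrality) on the central cross-section of each run, averages over
#' replicates and classifies every index against the experimental ranges.
#' A grid point is acceptable when all four indices fall within their
#' ranges.
#'
#' @param grid data.frame; columns name scan parameters (`gamma`, `Th`,
#'   `delta`, `q`, `v_SS`, `v_SD`, `v_DD`, ...), one row per combination.
#' @param base_cfg the [simulation_config()] to modify.
#' @param replicates number of replicate seeds per grid point.
#' @param seeds optional seed vector (default `1:replicates`).
#' @param z_fraction position of the cross-section plane.
#' @param ranges an [experimental_ranges()].
#'
#' @return Data frame: the grid, per-index mean and sd, per-index
#'   classification and the `acceptable` flag.
#' @export
run_scan <- function(grid, base_cfg = simulation_config(), replicates = 5,
                     seeds = seq_len(replicates), z_fraction = 0.5,
                     ranges = experimental_ranges()) {
  stopifnot(is.data.frame(grid), nrow(grid) > 0)
  res <- vector("list", nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    cfg <- base_cfg
    for (nm in names(grid)) cfg <- set_scan_parameter(cfg, nm, grid[[nm]][gi])
    idx <- matrix(NA_real_, length(seeds), 4,
                  dimnames = list(NULL, names(ranges)))
    for (si in seq_along(seeds)) {
      sim <- run_simulation(cfg, seed = seeds[si])
      tab <- cross_section(sim$final, z_fraction,
                           unit_to_um = cfg$domain$unit_to_um,
                           L = cfg$domain$L)
      idx[si, ] <- c(stem_percentage(tab),
                     morans_I(tab),
                     entropy_index(tab),
                     centrality_index(tab))
    }
    mu <- colMeans(idx)
    sdv <- apply(idx, 2, sd)
    cls <- vapply(names(ranges), function(nm)
      classify(mu[[nm]], ranges[[nm]]), character(1))
    row <- cbind(grid[gi, , drop = FALSE],
                 as.data.frame(as.list(stats::setNames(
                   mu, paste0(names(ranges), "_mean")))),
                 as.data.frame(as.list(stats::setNames(
                   sdv, paste0(names(ranges), "_sd")))),
                 as.data.frame(as.list(stats::setNames(
                   cls, paste0(names(ranges), "_class"))),
                   stringsAsFactors = FALSE))
    row$acceptable <- all(cls == "within")
    res[[gi]] <- row
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
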