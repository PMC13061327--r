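# Bursty piecewise-deterministic Markov process for the three-gene network.
# Between bursts mRNA and protein decay/accumulate deterministically
# (M' = -d0 M, P' = s1 M - d1 P); bursts add an exponential jump to M at a
# protein-dependent sigmoidal rate.

#' Kinetic parameters of the three-gene network
#'
#' Per-gene kinetic parameters of the bursty gene-expression model.  The
#' defaults are the model's reference parameterisation: mRNA degradation
#' `d0 = 1` per hour for every gene, protein degradation `d1 = 0.001` per
#' hour for CD133 and `0.01` for SYP and Cyclin E, protein synthesis
#' `s1 = 0.01 * d1`, basal activities `beta = -3` (CD133) and `-5` (SYP,
#' Cyclin E), and exponential burst sizes with mean 50 molecules.  The
#' minimum and maximum burst frequencies `k0`, `k1` are free configuration
#' parameters with defaults 0 and 1 per hour.
#'
#' @param d0 mRNA degradation rates (per hour), length-3 numeric.
#' @param d1 protein degradation rates (per hour).
#' @param s1 protein synthesis rates (per hour); default `0.01 * d1`.
#' @param k0 minimum burst frequencies (per hour).
#' @param k1 maximum burst frequencies (per hour).
#' @param beta basal activities (dimensionless).
#' @param burst_mean mean exponential burst size (molecules), length 3 or 1.
#'
#' @return An object of class `gene_params`: a list of named length-3
#'   numeric vectors.
#' @export
gene_params <- function(d0 = c(1, 1, 1),
                        d1 = c(0.001, 0.01, 0.01),
                        s1 = 0.01 * d1,
                        k0 = c(0, 0, 0),
                        k1 = c(1, 1, 1),
                        beta = c(-3, -5, -5),
                        burst_mean = c(50, 50, 50)) {
  g <- gene_names()
  rec <- function(x) {
    x <- rep_len(as.numeric(x), 3L)
    names(x) <- g
    x
  }
  p <- list(d0 = rec(d0), d1 = rec(d1), s1 = rec(s1), k0 = rec(k0),
            k1 = rec(k1), beta = rec(beta), burst_mean = rec(burst_mean))
  stopifnot(all(p$d0 > p$d1), all(p$d1 >= 0), all(p$k1 >= p$k0),
            all(p$k0 >= 0), all(p$burst_mean > 0))
  class(p) <- "gene_params"
  p
}

#' Gene-gene interaction matrix
#'
#' Interaction strengths `theta[source, target]` of the network: CD133 and
#' SYP form a toggle switch (self-activation 15, mutual repression -40);
#' SYP strongly activates Cyclin E (250) while CD133 weakly inhibits it
#' (-2), so differentiated cells proliferate faster than stem cells.
#'
#' @param theta optional 3x3 numeric matrix (rows: source gene, columns:
#'   target gene) overriding the default.
#'
#' @return A 3x3 numeric matrix with dimnames `gene_names()`.
#' @export
interaction_matrix <- function(theta = NULL) {
  g <- gene_names()
  if (is.null(theta)) {
    theta <- matrix(c(
      #        CD133   SYP  CyclinE     (target ->)
      15,   -40,   -2,   # source CD133
      -40,    15,  250,   # source SYP
      0,     0,    0),  # source CyclinE
      nrow = 3, byrow = TRUE, dimnames = list(g, g))
  } else {
    theta <- as.matrix(theta)
    stopifnot(identical(dim(theta), c(3L, 3L)))
    dimnames(theta) <- list(g, g)
  }
  theta
}

#' Per-cell molecular state
#'
#' @param M mRNA amounts (molecules), length-3 non-negative numeric.
#' @param P protein amounts, length-3 non-negative numeric.
#'
#' @return An object of class `grn_state` (list with `M` and `P`).
#' @export
grn_state <- function(M = c(0, 0, 0), P = c(0, 0, 0)) {
  stopifnot(length(M) == 3, length(P) == 3, all(M >= 0), all(P >= 0))
  s <- list(M = stats::setNames(as.numeric(M), gene_names()),
            P = stats::setNames(as.numeric(P), gene_names()))
  class(s) <- "grn_state"
  s
}

#' Signaling term entering the CD133 burst-rate sigmoid
#'
#' @param kind one of `"none"`, `"contact"`, `"diffusive"`.
#' @param value non-negative scalar: `gamma * S` for contact signaling,
#'   the perceived diffusive intensity for diffusive signaling.
#'
#' @return An object of class `signal_term`.
#' @export
signal_term <- function(kind = c("none", "contact", "diffusive"), value = 0) {
  kind <- match.arg(kind)
  if (kind == "none") value <- 0
  stopifnot(is.numeric(value), length(value) == 1, value >= 0)
  structure(list(kind = kind, value = value), class = "signal_term")
}

#' Sigmoid argument of the burst rate for one target gene
#'
#' Computes `sigma = beta_target + sum_source theta[source, target] *
#' P_source`, plus the signaling term when the target is CD133.  The
#' orientation follows the interaction matrix: `theta[i, j]` is the
#' influence of gene i's protein on gene j's burst frequency.
#'
#' @param P protein vector (length 3, order `gene_names()`).
#' @param target gene name or index of the regulated gene.
#' @param theta interaction matrix, see [interaction_matrix()].
#' @param beta basal activity of the target gene (scalar), or the
#'   length-3 beta vector from which the target entry is taken.
#' @param signal optional [signal_term()]; only affects CD133.
#'
#' @return Numeric scalar sigma.
#' @export
compute_sigma <- function(P, target, theta = interaction_matrix(),
                          beta = gene_params()$beta, signal = signal_term()) {
  stopifnot(length(P) == 3)
  if (is.character(target)) {
    tgt <- match(target, gene_names())
    if (is.na(tgt)) stop("unknown gene id: ", target)
  } else {
    tgt <- as.integer(target)
    if (is.na(tgt) || tgt < 1L || tgt > 3L) stop("unknown gene id: ", target)
  }
  b <- if (length(beta) == 3) beta[[tgt]] else beta[[1]]
  s <- b + sum(theta[, tgt] * as.numeric(P))
  if (tgt == 1L && inherits(signal, "signal_term")) s <- s + signal$value
  s
}

#' Burst frequency from the sigmoid argument
#'
#' `k_on = k0 + (k1 - k0) / (1 + exp(-sigma))`; strictly increasing in
#' sigma and bounded in `[k0, k1]`.
#'
#' @param sigma sigmoid argument (any real; vectorised).
#' @param k0,k1 minimum and maximum burst frequencies (per hour).
#'
#' @return Burst rate(s), per hour.
#' @export
burst_rate <- function(sigma, k0 = 0, k1 = 1) {
  stopifnot(all(k1 >= k0), all(k0 >= 0))
  k0 + (k1 - k0) / (1 + exp(-sigma))
}

# closed-form decay of (M, P) over dt for one or more genes; M0, P0, d0,
# d1, s1 may be vectors (or matrices for M0/P0 with genes in columns)
relax_closed_form <- function(M0, P0, dt, d0, d1, s1) {
  if (dt < 0) stop("dt must be >= 0")
  eM <- exp(-outer_dt(d0, dt, M0))
  # outer_dt returns d * dt broadcast to the shape of M0
  M <- M0 * eM
  e1 <- exp(-outer_dt(d1, dt, P0))
  near <- abs(d0 - d1) < 1e-12
  conv <- if (is.matrix(M0)) {
    dd0 <- matrix(d0, nrow(M0), 3, byrow = TRUE)
    dd1 <- matrix(d1, nrow(M0), 3, byrow = TRUE)
    ifelse(matrix(near, nrow(M0), 3, byrow = TRUE),
           dt * exp(-dd0 * dt),
           (e1 - eM) / (dd0 - dd1))
  } else {
    ifelse(near, dt * exp(-d0 * dt), (e1 - eM) / (d0 - d1))
  }
  P <- P0 * e1 + s1v(s1, M0) * M0 * conv
  list(M = M, P = P)
}

outer_dt <- function(d, dt, template) {
  if (is.matrix(template)) matrix(d * dt, nrow(template), 3, byrow = TRUE)
  else d * dt
}

s1v <- function(s1, template) {
  if (is.matrix(template)) matrix(s1, nrow(template), 3, byrow = TRUE)
  else s1
}

#' Deterministic relaxation of a molecular state between bursts
#'
#' Advances `M' = -d0 M`, `P' = s1 M - d1 P` over `dt` hours using the
#' exact closed form (not an Euler step):
#' `M(dt) = M0 exp(-d0 dt)` and
#' `P(dt) = P0 exp(-d1 dt) + s1 M0 (exp(-d1 dt) - exp(-d0 dt)) / (d0 - d1)`,
#' with the analytic limit `s1 M0 dt exp(-d0 dt)` when `d0 == d1`.
#'
#' @param state a [grn_state()].
#' @param dt time step (hours, `>= 0`).
#' @param params a [gene_params()].
#'
#' @return The relaxed `grn_state`.
#' @export
relax <- function(state, dt, params = gene_params()) {
  r <- relax_closed_form(state$M, state$P, dt, params$d0, params$d1, params$s1)
  grn_state(r$M, r$P)
}

#' Apply one transcriptional burst to a gene
#'
#' Increases the gene's mRNA amount by one draw from an exponential
#' distribution with the given mean; all other state components are
#' unchanged.  Uses R's global random-number stream.
#'
#' @param state a [grn_state()].
#' @param gene gene name or index.
#' @param burst_mean mean burst size (molecules).
#'
#' @return The updated `grn_state`.
#' @export
apply_burst <- function(state, gene, burst_mean = 50) {
  stopifnot(burst_mean > 0)
  if (is.character(gene)) gene <- match(gene, gene_names())
  stopifnot(!is.na(gene), gene >= 1, gene <= 3)
  state$M[[gene]] <- state$M[[gene]] + rexp(1, 1) * burst_mean
  state
}

#' Advance the bursty PDMP of one cell over a time step
#'
#' Reference single-cell implementation of the stochastic update: per
#' gene (in the fixed order CD133, SYP, CyclinE) a candidate burst time
#' is drawn from an exponential clock at the current burst rate; if the
#' earliest clock falls inside the interval the state is relaxed to that
#' time, the burst applied, all rates recomputed from the updated state
#' and the procedure continues; otherwise the state is relaxed to the end
#' of the interval.  Several bursts may occur within one step.  Burst
#' rates are held constant between events.
#'
#' @param state a [grn_state()].
#' @param dt time step (hours).
#' @param params a [gene_params()].
#' @param theta interaction matrix.
#' @param signal a [signal_term()] entering the CD133 sigmoid.
#'
#' @return The updated `grn_state`.
#' @export
pdmp_step <- function(state, dt, params = gene_params(),
                      theta = interaction_matrix(), signal = signal_term()) {
  remaining <- dt
  M <- state$M
  P <- state$P
  sig <- c(signal$value, 0, 0)
  repeat {
    sigma <- params$beta + as.numeric(P %*% theta) + sig
    k <- burst_rate(sigma, params$k0, params$k1)
    # one exponential draw per gene in fixed order (deterministic RNG use)
    u <- c(rexp(1, 1), rexp(1, 1), rexp(1, 1))
    tau <- ifelse(k > 0, u / k, Inf)
    g <- which.min(tau)
    if (tau[g] > remaining || !is.finite(tau[g])) {
      r <- relax_closed_form(M, P, remaining, params$d0, params$d1, params$s1)
      return(grn_state(r$M, r$P))
    }
    r <- relax_closed_form(M, P, tau[g], params$d0, params$d1, params$s1)
    M <- r$M
    P <- r$P
    M[[g]] <- M[[g]] + rexp(1, 1) * params$burst_mean[[g]]
    remaining <- remaining - tau[g]
  }
}

#' Simulate a single-cell GRN trajectory
#'
#' Runs the PDMP for one isolated cell over `n_steps` steps of length
#' `dt`, recording the molecular state after every step.  Intended for
#' debugging and for inspecting the toggle-switch dynamics.
#'
#' @param n_steps number of steps.
#' @param dt step length (hours).
#' @param state initial [grn_state()].
#' @param params a [gene_params()].
#' @param theta interaction matrix.
#' @param signal constant [signal_term()].
#' @param file optional path; if given the trajectory is written as CSV
#'   (columns: time, M and P per gene).
#'
#' @return A data.frame with columns `time`, `M_<gene>`, `P_<gene>`.
#' @export
simulate_grn_trajectory <- function(n_steps, dt = 0.1,
                                    state = grn_state(),
                                    params = gene_params(),
                                    theta = interaction_matrix(),
                                    signal = signal_term(),
                                    file = NULL) {
  g <- gene_names()
  out <- matrix(NA_real_, n_steps + 1L, 7L)
  colnames(out) <- c("time", paste0("M_", g), paste0("P_", g))
  out[1L, ] <- c(0, state$M, state$P)
  for (i in seq_len(n_steps)) {
    state <- pdmp_step(state, dt, params, theta, signal)
    out[i + 1L, ] <- c(i * dt, state$M, state$P)
  }
  df <- as.data.frame(out)
  if (!is.null(file)) write.csv(df, file, row.names = FALSE)
  df
}
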