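# Plain key-value serialisation of the full simulation configuration,
# so runs are reproducible from a single text file.  Format: one
# `key = value` per line, vectors comma-separated, '#' starts a comment.

flatten_config <- function(cfg) {
  g <- gene_names()
  num <- function(x) paste(format(x, digits = 15, trim = TRUE,
                                  scientific = FALSE), collapse = ", ")
  kv <- c(
    dt = num(cfg$dt), n_init = num(cfg$n_init),
    stop_count = num(cfg$stop_count), scenario = cfg$scenario,
    gamma = num(cfg$gamma), motility = cfg$motility,
    core_ratio = num(cfg$core_ratio), eta_shell = num(cfg$eta_shell),
    eta_core = num(cfg$eta_core), relax_tol = num(cfg$relax_tol),
    max_sweeps = num(cfg$max_sweeps),
    snapshot_stride = num(cfg$snapshot_stride),
    max_hours = num(cfg$max_hours),
    domain.L = num(cfg$domain$L),
    domain.unit_to_um = num(cfg$domain$unit_to_um),
    fate.differentiation_threshold =
      num(cfg$fate$differentiation_threshold),
    fate.proliferation_threshold = num(cfg$fate$proliferation_threshold),
    fate.growth_rate = num(cfg$fate$growth_rate),
    diffusion.q = num(cfg$diffusion$q),
    diffusion.delta = num(cfg$diffusion$delta),
    diffusion.epsilon = num(cfg$diffusion$epsilon),
    diffusion.method = cfg$diffusion$method,
    diffusion.perception = cfg$diffusion$perception,
    diffusion.include_self = if (cfg$diffusion$include_self) "true"
                             else "false",
    rules.default_speed = num(cfg$rules$default_speed),
    rules.v_SS = num(cfg$rules$v_SS), rules.v_SD = num(cfg$rules$v_SD),
    rules.v_DD = num(cfg$rules$v_DD))
  for (f in c("d0", "d1", "s1", "k0", "k1", "beta", "burst_mean"))
    kv[paste0("grn.", f)] <- num(cfg$params[[f]])
  for (src in g)
    kv[paste0("theta.", src)] <- num(cfg$theta[src, ])
  kv
}

#' Write a simulation configuration to a key-value text file
#'
#' All model parameters (time stepping, fate thresholds, mechanics,
#' signaling, gene kinetics and the interaction matrix) are serialised
#' as `key = value` lines; [read_sim_config()] restores an equivalent
#' [simulation_config()].
#'
#' @param cfg a [simulation_config()].
#' @param path output file path.
#' @export
write_sim_config <- function(cfg, path) {
  kv <- flatten_config(cfg)
  lines <- c("# tumoroid simulation configuration",
             paste(names(kv), "=", kv))
  writeLines(lines, path)
  invisible(path)
}

#' Read a simulation configuration from a key-value text file
#'
#' Unknown keys raise an error; missing keys keep their defaults.
#'
#' @param path file written by [write_sim_config()] (or by hand).
#' @return A [simulation_config()].
#' @export
read_sim_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  parts <- regmatches(lines, regexec("^([A-Za-z0-9._]+)\\s*=\\s*(.*)$",
                                     lines))
  bad <- lines[vapply(parts, length, integer(1)) != 3]
  if (length(bad) > 0)
    stop("malformed configuration line(s): ",
         paste(utils::head(bad, 3), collapse = "; "))
  keys <- vapply(parts, `[`, character(1), 2)
  vals <- vapply(parts, `[`, character(1), 3)
  getv <- function(key, default) {
    if (!key %in% keys) return(default)
    vals[[match(key, keys)]]
  }
  numv <- function(key, default) {
    v <- getv(key, NULL)
    if (is.null(v)) return(default)
    out <- suppressWarnings(as.numeric(trimws(strsplit(v, ",")[[1]])))
    if (any(is.na(out))) stop("non-numeric value for key: ", key)
    out
  }
  known <- c("dt", "n_init", "stop_count", "scenario", "gamma", "motility",
             "core_ratio", "eta_shell", "eta_core", "relax_tol",
             "max_sweeps", "snapshot_stride", "max_hours", "domain.L",
             "domain.unit_to_um", "fate.differentiation_threshold",
             "fate.proliferation_threshold", "fate.growth_rate",
             "diffusion.q", "diffusion.delta", "diffusion.epsilon",
             "diffusion.method", "diffusion.perception",
             "diffusion.include_self", "rules.default_speed", "rules.v_SS",
             "rules.v_SD", "rules.v_DD",
             paste0("grn.", c("d0", "d1", "s1", "k0", "k1", "beta",
                              "burst_mean")),
             paste0("theta.", gene_names()))
  unknown <- setdiff(keys, known)
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  def <- simulation_config()
  theta <- interaction_matrix()
  for (src in gene_names())
    theta[src, ] <- numv(paste0("theta.", src), theta[src, ])
  params <- gene_params(
    d0 = numv("grn.d0", def$params$d0),
    d1 = numv("grn.d1", def$params$d1),
    s1 = numv("grn.s1", def$params$s1),
    k0 = numv("grn.k0", def$params$k0),
    k1 = numv("grn.k1", def$params$k1),
    beta = numv("grn.beta", def$params$beta),
    burst_mean = numv("grn.burst_mean", def$params$burst_mean))
  simulation_config(
    dt = numv("dt", def$dt),
    n_init = numv("n_init", def$n_init),
    stop_count = numv("stop_count", def$stop_count),
    scenario = getv("scenario", def$scenario),
    gamma = numv("gamma", def$gamma),
    diffusion = diffusion_config(
      q = numv("diffusion.q", def$diffusion$q),
      delta = numv("diffusion.delta", def$diffusion$delta),
      epsilon = numv("diffusion.epsilon", def$diffusion$epsilon),
      method = getv("diffusion.method", def$diffusion$method),
      perception = getv("diffusion.perception", def$diffusion$perception),
      include_self = tolower(getv("diffusion.include_self", "true")) %in%
        c("true", "1", "yes")),
    params = params,
    theta = theta,
    fate = fate_config(
      differentiation_threshold =
        numv("fate.differentiation_threshold",
             def$fate$differentiation_threshold),
      proliferation_threshold =
        numv("fate.proliferation_threshold",
             def$fate$proliferation_threshold),
      growth_rate = numv("fate.growth_rate", def$fate$growth_rate)),
    domain = sim_domain(L = numv("domain.L", def$domain$L),
                        unit_to_um = numv("domain.unit_to_um",
                                          def$domain$unit_to_um)),
    motility = getv("motility", def$motility),
    rules = velocity_rules(
      default_speed = numv("rules.default_speed",
                           def$rules$default_speed),
      v_SS = numv("rules.v_SS", def$rules$v_SS),
      v_SD = numv("rules.v_SD", def$rules$v_SD),
      v_DD = numv("rules.v_DD", def$rules$v_DD)),
    core_ratio = numv("core_ratio", def$core_ratio),
    eta_shell = numv("eta_shell", def$eta_shell),
    eta_core = numv("eta_core", def$eta_core),
    relax_tol = numv("relax_tol", def$relax_tol),
    max_sweeps = numv("max_sweeps", def$max_sweeps),
    snapshot_stride = numv("snapshot_stride", def$snapshot_stride),
    max_hours = numv("max_hours", def$max_hours))
}
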