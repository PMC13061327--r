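# Orchestration: initial conditions, stepping, stopping, logging, scans.

test_that("initial population follows the seeding protocol", {
  cfg <- simulation_config()
  set.seed(1)
  pop <- initialize_population(cfg)
  expect_equal(pop$n, 15)
  expect_true(all(pop$type == 1L))
  expect_true(all(pop$volume == 1))
  expect_true(all(pop$pos >= 0 & pop$pos <= 80))
  # gathered side by side around the cube centre
  expect_true(all(abs(pop$pos - 40) < 5))
  ctr_dist <- sqrt(rowSums((pop$pos - 40)^2))
  expect_lt(max(ctr_dist), 4)
  # CD133 protein at exactly twice the differentiation threshold
  expect_true(all(pop$P[, 1] ==
                    2 * cfg$fate$differentiation_threshold))
  expect_true(all(pop$P[, 2:3] == 0))
  expect_true(all(pop$M[, 2:3] == 0))
  # initial cluster must fit in the domain
  tiny <- simulation_config(domain = sim_domain(L = 1), stop_count = 100)
  expect_error(initialize_population(tiny), "does not fit")
})

test_that("initial CD133 mRNA is exponential with mean 50", {
  cfg <- simulation_config()
  set.seed(2)
  m <- replicate(700, mean(initialize_population(cfg)$M[, 1]))
  expect_equal(mean(m), 50, tolerance = 0.02)
})

test_that("a division-ready cell adds exactly one cell in one step", {
  cfg <- simulation_config(stop_count = 100)
  set.seed(3)
  pop <- initialize_population(cfg)
  pop$volume[1] <- 2.0
  pop$P[1, 3] <- 0.02  # Cyclin E above the proliferation threshold
  out <- sim_step(pop, cfg, t = 0)
  expect_equal(out$pop$n, 16)
  expect_equal(nrow(out$events), 1)
  expect_equal(out$events$mother_id, 1)
  expect_equal(out$events$mother_type, "stem")
  # volume is conserved through the division (only growth adds volume)
  expect_equal(sum(out$pop$volume),
               sum(pop$volume) + cfg$fate$growth_rate * cfg$dt * pop$n,
               tolerance = 1e-9)
  # the two daughters carry half of the mother's grown volume each
  d_rows <- c(1, out$pop$n)
  expect_equal(out$pop$volume[d_rows[1]], out$pop$volume[d_rows[2]])
})

test_that("runs stop just above the configured population size", {
  cfg <- simulation_config(stop_count = 100, scenario = "none",
                           fate = fate_config(differentiation_threshold = 0.003))
  r <- run_simulation(cfg, seed = 4)
  expect_gt(r$final$n, 100)
  expect_lt(r$final$n, 110)
  expect_equal(r$stopped, "stop_count")
  expect_equal(nrow(r$divisions), r$final$n - 15)
})

test_that("identical seeds give bit-identical runs", {
  cfg <- simulation_config(stop_count = 150, scenario = "contact",
                           fate = fate_config(differentiation_threshold = 0.004))
  a <- run_simulation(cfg, seed = 99)
  b <- run_simulation(cfg, seed = 99)
  expect_identical(a$divisions, b$divisions)
  expect_identical(a$final$pos, b$final$pos)
  expect_identical(a$final$M, b$final$M)
  c <- run_simulation(cfg, seed = 100)
  expect_false(identical(a$divisions, c$divisions))
})

test_that("motile mode with velocity rules runs and stays in the domain", {
  cfg <- simulation_config(stop_count = 60, motility = "motile",
                           rules = velocity_rules(0.3, v_SS = 0.256,
                                                  v_SD = 0, v_DD = 0),
                           fate = fate_config(differentiation_threshold = 0.003))
  r <- run_simulation(cfg, seed = 5)
  expect_gt(r$final$n, 60)
  expect_true(all(r$final$pos >= 0 & r$final$pos <= 80))
})

test_that("de-differentiation fraction is computed from the division log", {
  log <- data.frame(
    mother_type = c("differentiated", "stem", "differentiated",
                    "differentiated", "stem"),
    daughter1_type = c("stem", "stem", "stem", "differentiated", "stem"),
    daughter2_type = c("stem", "stem", "differentiated", "differentiated",
                       "differentiated"))
  log$dedifferentiation <- is_dedifferentiation(
    log$mother_type, log$daughter1_type, log$daughter2_type)
  # brute-force enumeration: only the first row qualifies
  expect_equal(sum(log$dedifferentiation), 1)
  expect_equal(dedifferentiation_fraction(log), 100 * 1 / 5)
  big <- data.frame(dedifferentiation = c(rep(TRUE, 18), rep(FALSE, 982)))
  expect_equal(dedifferentiation_fraction(big), 1.8)
  none <- data.frame(dedifferentiation = logical(10))
  expect_equal(dedifferentiation_fraction(none), 0)
  empty <- data.frame(dedifferentiation = logical(0))
  expect_warning(v <- dedifferentiation_fraction(empty), "no division")
  expect_true(is.na(v))
})

test_that("population snapshots round-trip through CSV", {
  r <- small_run()
  tab <- population_table(r$final)
  f <- tempfile(fileext = ".csv")
  write.csv(tab, f, row.names = FALSE)
  back <- read.csv(f, stringsAsFactors = FALSE)
  expect_equal(back$x, tab$x)
  expect_equal(back$type, tab$type)
  expect_equal(back$M_CD133, tab$M_CD133)
  unlink(f)
  # snapshot stride stores intermediate population tables
  cfg <- simulation_config(stop_count = 40, snapshot_stride = 50,
                           fate = fate_config(differentiation_threshold = 0.003))
  rs <- run_simulation(cfg, seed = 6)
  expect_gt(length(rs$snapshots), 0)
  expect_true(all(sapply(rs$snapshots, nrow) >= 15))
  # population sizes never decrease over snapshots
  expect_true(!is.unsorted(sapply(rs$snapshots, nrow)))
})

test_that("the scan driver classifies grid points against the ranges", {
  grid <- data.frame(Th = c(0.003, 0.004), gamma = c(0.3, 0.3))
  base <- simulation_config(stop_count = 250, scenario = "contact")
  out <- run_scan(grid, base, replicates = 2)
  expect_equal(nrow(out), 2)
  expect_true(all(c("percentage_mean", "moran_mean", "entropy_sd",
                    "centrality_class", "acceptable") %in% names(out)))
  expect_true(all(out$percentage_class %in%
                    c("below", "within", "above", NA)))
  expect_type(out$acceptable, "logical")
})

test_that("configurations round-trip through the key-value file", {
  cfg <- simulation_config(
    stop_count = 4321, scenario = "diffusive", gamma = 0.45,
    diffusion = diffusion_config(q = 0.2, delta = 1.5, epsilon = 0.005,
                                 perception = "stem", include_self = FALSE),
    fate = fate_config(differentiation_threshold = 0.0035,
                       growth_rate = 0.04),
    motility = "motile",
    rules = velocity_rules(0.3, v_SS = 0.016, v_SD = 0, v_DD = 0.016),
    params = gene_params(k1 = c(2, 1, 1)),
    theta = interaction_matrix(matrix(c(15, -40, -2, -40, 15, 250,
                                        0, 1, 0), 3, 3, byrow = TRUE)))
  f <- tempfile(fileext = ".txt")
  write_sim_config(cfg, f)
  back <- read_sim_config(f)
  expect_equal(back$stop_count, 4321)
  expect_equal(back$scenario, "diffusive")
  expect_equal(back$gamma, 0.45)
  expect_equal(back$diffusion, cfg$diffusion)
  expect_equal(back$fate, cfg$fate)
  expect_equal(back$rules, cfg$rules)
  expect_equal(back$params, cfg$params)
  expect_equal(back$theta, cfg$theta)
  unlink(f)
  # unknown keys and malformed values are rejected with clear messages
  writeLines(c("dt = 0.1", "bogus_key = 3"), f)
  expect_error(read_sim_config(f), "unknown configuration key")
  writeLines(c("dt = zero"), f)
  expect_error(read_sim_config(f), "non-numeric")
  unlink(f)
})

test_that("the command-line front end runs its subcommands", {
  cli <- system.file("scripts", "pdtsim", package = "pdtsim")
  expect_true(nzchar(cli))
  pat <- tempfile(fileext = ".csv")
  out1 <- system2("Rscript", c(cli, "make-pattern", "--structure",
                               "clustered", "--n", "300", "--out", pat,
                               "--seed", "3"), stdout = TRUE)
  expect_true(file.exists(pat))
  out2 <- system2("Rscript", c(cli, "stats", "--table", pat),
                  stdout = TRUE, stderr = TRUE)
  expect_true(any(grepl("percentage", out2)))
  unlink(pat)
})

test_that("contrived index values classify as in the range comparison", {
  ranges <- experimental_ranges()
  vals <- c(percentage = 1.0, moran = 0.2, entropy = 0.1, centrality = 0.8)
  cls <- vapply(names(ranges), function(nm) classify(vals[[nm]],
                                                     ranges[[nm]]),
                character(1))
  expect_equal(unname(cls), c("below", "within", "within", "within"))
  expect_false(all(cls == "within"))
})
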