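fake_segment <- function(lambda, dt = 1) {
  structure(list(lambda = lambda, time = seq_along(lambda) - 1, dt = dt,
                 record_every = 1L), class = "trajectory_segment")
}

fake_path <- function(lambda_max, multiplicity = 1, end = "A") {
  p <- tis_path(NULL, NULL, time = 0:1, lambda = c(-1, lambda_max),
                endpoints = c("A", end), multiplicity = multiplicity)
  p$lambda_max <- lambda_max
  p
}

fake_ensemble <- function(paths, lambda_i) {
  structure(list(condition = cond_interface(lambda_i), paths = paths,
                 n_attempted = 10L, n_accepted = 5L, acceptance_rate = 0.5,
                 seed_lineage = "test"), class = "path_ensemble")
}

test_that("effective flux counts one crossing per excursion", {
  # sawtooth: rises above lambda_A then returns to the well, 5 times in 10 ps
  one <- c(seq(-1, -0.5, length.out = 1000),
           seq(-0.5, -1, length.out = 1000))
  seg <- fake_segment(rep(one, 5))
  res <- compute_flux_factor(seg, lambda_A = -0.8, lambda_B = 0.8)
  expect_equal(res$flux, 5e11, tolerance = 0.01)
  # never leaving deep A: zero flux
  calm <- fake_segment(rep(-1.1, 5000))
  expect_equal(compute_flux_factor(calm)$flux, 0)
})

test_that("conditionals are multiplicity-weighted crossing fractions", {
  ens1 <- fake_ensemble(list(fake_path(-0.3, 3), fake_path(-0.55, 1)), -0.6)
  ens2 <- fake_ensemble(list(fake_path(0.9, 1, end = "B")), -0.4)
  probs <- estimate_conditionals(list(ens1, ens2), grid = c(-0.6, -0.4))
  expect_equal(probs$conditional, 0.75)
  expect_equal(attr(probs, "final_leg"), 1)
  all_cross <- fake_ensemble(list(fake_path(0.1, 2), fake_path(0.2, 1)),
                             -0.6)
  p2 <- estimate_conditionals(list(all_cross, ens2), c(-0.6, -0.4))
  expect_equal(p2$conditional, 1)
  expect_error(estimate_conditionals(list(ens1), c(-0.6, -0.4)),
               "one ensemble per grid point")
  expect_length(default_interface_grid(), 29)
  expect_equal(range(default_interface_grid()), c(-0.8, 0))
})

test_that("rate assembly is the exact product identity", {
  probs <- crossing_probabilities(c(-0.8, -0.4, 0), c(0.5, 0.2),
                                  final_leg = 0.01)
  rate <- assemble_rate(1e12, probs)
  expect_identical(rate$k, 1e12 * 0.5 * 0.2 * 0.01)
  id <- assemble_rate(7e11, crossing_probabilities(c(-1, 0), 1,
                                                   final_leg = 1))
  expect_identical(id$k, 7e11)
  easy <- assemble_rate(1e12, crossing_probabilities(c(-1, 0), 1,
                                                     final_leg = 1e-3))
  expect_equal(easy$k, 1e9)
  expect_error(crossing_probabilities(c(-1, 0), 0), "\\(0, 1\\]")
  expect_error(assemble_rate(-1, probs), "flux")
  expect_equal(tidy(rate)$value[4], rate$k)
})

test_that("crossing profiles: monotone cumulative curve and bottleneck tie
           rules", {
  grid <- seq(-0.8, -0.65, by = 0.05)
  flat <- crossing_probabilities(grid, rep(0.5, 3))
  prof <- crossing_profiles(flat, delta = 0.05)
  expect_true(all(diff(prof$cumulative) <= 1e-12))
  expect_equal(attr(prof, "bottleneck"), grid[1])  # ties go left
  mixed <- crossing_probabilities(grid, c(0.9, 0.2, 0.8))
  expect_equal(attr(crossing_profiles(mixed, 0.05), "bottleneck"), grid[2])
  # off-grid delta triggers log-linear resampling, staying monotone
  res <- crossing_profiles(mixed, delta = 0.025)
  expect_true(all(diff(res$cumulative) <= 1e-12))
})

test_that("decomposition about the bottleneck reconstructs the total", {
  set.seed(3)
  grid <- seq(-0.8, 0, by = 0.05)
  conds <- runif(length(grid) - 1, 0.3, 1)
  probs <- crossing_probabilities(grid, conds, final_leg = 0.7)
  dec <- decompose_rate(probs, split = -0.4)
  expect_equal(dec$p_to_bottleneck * dec$p_from_bottleneck,
               dec$total_probability, tolerance = 1e-12)
  at_a <- decompose_rate(probs, split = -0.8)
  expect_identical(at_a$p_to_bottleneck, 1)
  expect_error(decompose_rate(probs, split = -0.43), "grid")
})

test_that("replicate aggregation and Eyring conversions match closed
           forms", {
  agg <- aggregate_replicates(c(1, 2, 3))
  expect_equal(agg$mean, 2)
  expect_equal(agg$sem, 1 / sqrt(3))
  expect_equal(aggregate_replicates(rep(4, 5))$sem, 0)
  expect_error(aggregate_replicates(5), ">= 2")
  expect_equal(eyring_rate(0, 300), 1.380649e-23 * 300 / 6.62607015e-34)
  expect_equal(eyring_rate(0, 300), 6.25e12, tolerance = 1e-3)
  expect_equal(eyring_ratio(10, 10), 1)
  rt_ln10 <- 0.0019872041 * 300 * log(10)
  expect_equal(eyring_ratio(20 - rt_ln10, 20), 10)
  expect_error(eyring_rate(5, 0), "temperature")
})

test_that("brute-force rate agrees with the strong-friction Kramers
           estimate within an order-unity factor", {
  dw <- make_double_well(barrier_height = 4, n_env = 0)
  p <- langevin_params(friction = 50, seed = 13)
  segs <- run_equilibrium_well(dw, duration_ps = 8000, n_replicas = 6,
                               params = p, record_every = 2L)
  est <- transition_rate(segs)
  # Kramers, spatial-diffusion regime: (omega_a * omega_b / (2 pi gamma))
  # * exp(-beta dV); curvature 8 h / w^2 at well and (negative) barrier
  curv <- 8 * 4 / 1
  omega <- sqrt(4.184e-4 * curv / 12)          # 1/fs
  gamma_fs <- 50e-3
  k_kram <- omega^2 / (2 * pi * gamma_fs) * exp(-4 / kT_kcal(300)) * 1e15
  expect_gt(est$events, 20)
  expect_lt(abs(log(est$k / k_kram)), log(3))
})

test_that("rate report writes interfaces, conditionals, and the summary", {
  probs <- crossing_probabilities(c(-0.8, -0.4, 0), c(0.5, 0.2),
                                  final_leg = 0.5)
  rate <- assemble_rate(1e12, probs)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_rate_report(rate, path)
  lines <- readLines(path)
  expect_true(any(grepl("k_per_s", lines)))
  tab <- utils::read.delim(path, comment.char = "#")
  expect_equal(nrow(tab), 3)
})
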