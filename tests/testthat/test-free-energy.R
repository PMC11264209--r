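test_that("window centers follow the dense/coarse placement rule", {
  centers <- generate_window_centers()
  expect_equal(centers, -rev(centers))  # symmetric about zero
  inner <- centers[abs(centers) < 0.5 - 1e-9]
  expect_equal(diff(inner), rep(0.0325, length(inner) - 1),
               tolerance = 1e-9)
  outer_gaps <- diff(centers[centers >= 0.45])
  expect_true(all(outer_gaps <= 0.0975 + 1e-9))
  # independent enumeration of the documented rule
  inner_pos <- seq(0, 0.5 - 1e-12, by = 0.0325)
  n_inner <- 2 * length(inner_pos) - 1
  last <- max(inner_pos)
  n_outer <- 2 * length(seq(last + 0.0975, 1.2, by = 0.0975))
  expect_length(centers, n_inner + n_outer)
  expect_error(generate_window_centers(range = c(0, 0.001)), "narrower")
})

test_that("umbrella windows run for the mode's duration and keep samples
           near the restraint", {
  h <- make_harmonic(k = 5)
  p <- langevin_params(seed = 3)
  win <- run_umbrella_window(h, center = 0.3, force_constant = 200,
                             mode = "screening", params = p)
  expect_length(win$samples, 5000)
  det <- run_umbrella_window(h, center = 0, force_constant = 200,
                             mode = "detailed", params = p,
                             duration_ps = 10, discard_ps = 5)
  expect_length(det$samples, 5000)
  # near-flat potential: the bias dominates and centers the samples
  flat <- make_harmonic(k = 1e-4)
  w2 <- run_umbrella_window(flat, center = 0.4, force_constant = 200,
                            mode = "screening", params = p,
                            initial_state = particle_state(0.4, 0))
  expect_equal(mean(w2$samples), 0.4, tolerance = 3 * sd(w2$samples) /
                 sqrt(length(w2$samples) / 50) + 0.005)
  expect_error(run_umbrella_window(h, 0, 200, "screening", p,
                                   duration_ps = 1, discard_ps = 2),
               "discard")
})

test_that("degenerate WHAM equals the log-histogram of a single unbiased
           window", {
  set.seed(5)
  samples <- rnorm(20000, sd = 0.4)
  win <- structure(list(center = 0, force_constant = 0, half_factor = FALSE,
                        samples = samples, mode = "screening", dt = 1,
                        equilibration_discard_ps = 0),
                   class = "umbrella_window")
  prof <- solve_wham(list(win), n_bins = 40, temperature = 300)
  # reference: -kT log(counts) on the same bins, anchored at zero
  edges <- seq(min(samples) - 1e-9, max(samples) + 1e-9, length.out = 41)
  counts <- tabulate(findInterval(samples, edges, rightmost.closed = TRUE),
                     nbins = 40)
  ref <- -kT_kcal(300) * log(counts[counts > 0])
  ref <- ref - min(ref)
  expect_equal(prof$free_energy, ref, tolerance = 1e-9)
})

test_that("WHAM recovers an analytic harmonic PMF and is invariant to
           window duplication", {
  h <- make_harmonic(k = 5)
  p <- langevin_params(seed = 11)
  centers <- generate_window_centers(range = c(-0.9, 0.9))
  wins <- run_umbrella_series(h, centers, force_constant = 200,
                              mode = "detailed", params = p,
                              duration_ps = 60, discard_ps = 20)
  prof <- solve_wham(wins, temperature = 300)
  sel <- abs(prof$lambda) <= 0.8
  resid <- prof$free_energy[sel] - 0.5 * 5 * prof$lambda[sel]^2
  resid <- resid - mean(resid)
  expect_lt(sqrt(mean(resid^2)), 0.1)
  expect_equal(min(prof$free_energy), 0)
  dup <- solve_wham(c(wins, wins), temperature = 300)
  expect_equal(dup$free_energy, prof$free_energy, tolerance = 1e-6)
})

test_that("disconnected window histograms raise a gap-naming error", {
  mkwin <- function(center, samples) {
    structure(list(center = center, force_constant = 200,
                   half_factor = FALSE, samples = samples,
                   mode = "screening", dt = 1,
                   equilibration_discard_ps = 0),
              class = "umbrella_window")
  }
  a <- mkwin(-0.5, rnorm(500, -0.5, 0.01))
  b <- mkwin(0.5, rnorm(500, 0.5, 0.01))
  expect_error(solve_wham(list(a, b), n_bins = 100), "disconnected")
})

test_that("barrier extraction handles flat profiles and replicates", {
  flat <- structure(tibble::tibble(lambda = seq(-1, 1, 0.1),
                                   free_energy = 0),
                    class = c("pmf_profile", "tbl_df", "tbl", "data.frame"))
  expect_equal(estimate_barrier(flat)$barrier, 0)
  reps <- lapply(1:3, function(i) {
    structure(tibble::tibble(lambda = seq(-1, 1, 0.1),
                             free_energy = abs(seq(-1, 1, 0.1)) * 0 +
                               ifelse(abs(seq(-1, 1, 0.1)) < 0.3, 4 + i * 0.1,
                                      0)),
              class = c("pmf_profile", "tbl_df", "tbl", "data.frame"))
  })
  out <- estimate_barrier(reps)
  expect_equal(out$n, 3)
  expect_equal(out$barrier, 4.2)
  expect_equal(out$sem, sd(c(4.1, 4.2, 4.3)) / sqrt(3))
  expect_error(estimate_barrier(flat, reactant_region = c(5, 6)), "empty")
})

test_that("screening-mode barriers rank-correlate with planted barrier
           differences", {
  heights <- c(3, 4, 5)
  dgs <- vapply(seq_along(heights), function(i) {
    sys <- make_double_well(barrier_height = heights[i], n_env = 1)
    wins <- run_umbrella_series(sys, generate_window_centers(),
                                force_constant = 200, mode = "screening",
                                params = langevin_params(seed = 20 + i))
    prof <- solve_wham(wins, temperature = 300)
    estimate_barrier(prof, c(-1.1, -0.85), c(-0.15, 0.15))$barrier
  }, numeric(1))
  expect_identical(order(dgs), order(heights))
})
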