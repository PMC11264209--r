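test_that("double well has the requested barrier and validates parameters", {
  dw <- make_double_well(barrier_height = 5, well_centers = c(-1, 1),
                         n_env = 2)
  at <- function(lam) system_potential(dw, c(lam, 0, 0))
  expect_equal(at(0) - at(-1), 5)
  expect_equal(at(1), at(-1))
  expect_error(make_double_well(barrier_height = 0), "positive")
  expect_error(make_double_well(well_centers = c(1, 1)), "distinct")
})

test_that("analytic gradients match central finite differences", {
  expect_silent(check_gradient(fix_double_well(), n_states = 100))
  expect_silent(check_gradient(make_harmonic(k = 7), n_states = 50))
  mm <- fix_mimic_family()$system_factory("A")
  expect_silent(check_gradient(mm, n_states = 100))
})

test_that("uncoupled environment coordinate is Boltzmann-distributed", {
  dw <- make_double_well(barrier_height = 4, n_env = 1, coupling = 0,
                         k_env = 1.5)
  p <- langevin_params(friction = 10, seed = 11)
  seg <- integrate_system(dw, well_state(dw, "A", seed = 1), 4e5, p,
                          save_frames = TRUE)
  env <- seg$frames_pos[-(1:5000), 2]
  expect_equal(var(env), kT_kcal(300) / 1.5, tolerance = 0.08)
  expect_lt(abs(mean(env)), 0.03)
})

test_that("equilibrium lambda marginal in the well matches quadrature", {
  dw <- fix_double_well()
  p <- langevin_params(friction = 10, seed = 3)
  seg <- integrate_system(dw, well_state(dw, "A", seed = 2), 6e5, p)
  lam <- seg$lambda[seg$lambda < -0.2]  # stay in the reactant well
  # direct quadrature of exp(-V/kT) restricted to the same region
  grid <- seq(-1.8, -0.2, length.out = 600)
  dens <- exp(-vapply(grid, function(l)
    system_potential(dw, c(l, 0)), numeric(1)) / kT_kcal(300))
  cdf <- cumsum(dens) / sum(dens)
  emp <- ecdf(lam)(grid)
  expect_lt(max(abs(emp - cdf)), 0.03)
})

test_that("migration mimic geometry and ground-truth metadata", {
  mm <- make_migration_mimic(n_env = 2, gate_strength = 4, seed = 2)
  # symmetric configuration: d(D,M) = d(M,A) gives lambda = 0
  pos <- c(-1.8, 0, 0, 0, 0.3, 0, 1.8, 0, 0, mm$tethers)
  expect_equal(system_lambda(mm, pos), 0)
  expect_identical(mm$metadata$gate_particle, 4L)
  expect_match(mm$metadata$informative_feature, "gate")
  expect_error(make_migration_mimic(n_env = 0), ">= 1")
  # same seed gives bit-identical systems
  expect_identical(make_migration_mimic(seed = 9),
                   make_migration_mimic(seed = 9))
})

test_that("planted gate signal is recoverable by logistic regression on
           brute-force excursions", {
  mm <- make_migration_mimic(n_env = 1, gate_strength = 4, seed = 1)
  # crossings are rare: enrich the successes by case-control harvesting
  # (outcome-dependent sampling leaves the logistic slope unbiased)
  fails <- harvest_excursion_paths(mm, cond_interface(-0.4), 250,
                                   langevin_params(seed = 23),
                                   max_steps = 2.5e7)
  hits <- harvest_excursion_paths(mm, cond_R(), 15,
                                  langevin_params(seed = 24),
                                  max_steps = 6e7)
  paths <- c(fails, hits)
  gate <- vapply(paths, function(pp) {
    i <- which(pp$lambda >= -0.5)[1]
    if (is.na(i)) i <- which.max(pp$lambda)
    sqrt(sum((pp$frames_pos[i, 10:12] - pp$frames_pos[i, 1:3])^2))
  }, numeric(1))
  success <- vapply(paths, function(pp) pp$endpoints[2] == "B", logical(1))
  fit <- suppressWarnings(glm(success ~ gate, family = binomial()))
  expect_gt(coef(fit)["gate"], 0)
  lrt <- anova(fit, test = "Chisq")
  expect_lt(lrt[["Pr(>Chi)"]][2], 0.01)
})

test_that("zero gate strength removes the gate signal", {
  mm <- make_migration_mimic(n_env = 1, gate_strength = 0, seed = 1)
  paths <- harvest_excursion_paths(mm, cond_interface(-0.4), 200,
                                   langevin_params(seed = 29),
                                   max_steps = 2e7)
  gate <- vapply(paths, function(pp) {
    i <- which.max(pp$lambda)
    sqrt(sum((pp$frames_pos[i, 10:12] - pp$frames_pos[i, 1:3])^2))
  }, numeric(1))
  success <- vapply(paths, function(pp) pp$endpoints[2] == "B", logical(1))
  expect_lt(abs(auroc(gate, success) - 0.5), 0.12)
})

test_that("toy design space enumerates, repeats, and plants effects", {
  sp <- make_toy_design_space(1, 2, effect_table_seed = 4)
  expect_length(sp$alphabet, 2)
  expect_identical(sp$wt_sequence, "A")
  sp2 <- make_toy_design_space(3, 3, effect_table_seed = 7)
  sp3 <- make_toy_design_space(3, 3, effect_table_seed = 7)
  s <- c("B", "A", "C")
  expect_identical(sp2$energy_model(s, 2), sp3$energy_model(s, 2))
  # planted additive effect reads back from the generated table
  mut <- c("B", "A", "A")
  expect_equal(sp2$energy_model(mut, 3) - sp2$energy_model(sp2$wt_sequence, 3),
               sp2$tables$additive[1, 2, 3])
  expect_error(make_toy_design_space(0, 2), ">= 1")
  expect_error(make_toy_design_space(2, 1), ">= 2")
  expect_error(sp2$energy_model(c("Z", "A", "A"), 1), "outside")
})

test_that("system configs round-trip through YAML", {
  mm <- make_migration_mimic(n_env = 2, gate_strength = 4, seed = 3)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_system_config(mm, path)
  back <- read_system_config(path)
  expect_equal(unname(back$params), unname(mm$params))
  expect_equal(back$tethers, mm$tethers)
  expect_equal(back$lambda_spec$breaking, mm$lambda_spec$breaking)
  pos <- well_state(mm, "A", seed = 1)$positions
  expect_equal(system_potential(back, pos), system_potential(mm, pos))
})
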