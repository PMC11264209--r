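test_that("endpoint classification uses strict basin thresholds", {
  expect_identical(classify_endpoint(-0.9), "A")
  expect_identical(classify_endpoint(0), "neither")
  expect_identical(classify_endpoint(0.8), "neither")
  expect_identical(classify_endpoint(-0.8), "neither")
  expect_identical(classify_endpoint(0.81), "B")
  expect_identical(classify_endpoint(c(-1, 1), lambda_A = -0.5,
                                     lambda_B = 0.5), c("A", "B"))
  expect_error(classify_endpoint(NaN))
})

test_that("ensemble conditions accept and reject the right paths", {
  r_path <- tis_path(NULL, NULL, 0:2, c(-0.9, 0, 0.9), c("A", "B"))
  nr_path <- tis_path(NULL, NULL, 0:2, c(-0.9, -0.3, -0.9), c("A", "A"))
  shallow <- tis_path(NULL, NULL, 0:2, c(-0.9, -0.7, -0.9), c("A", "A"))
  expect_true(path_satisfies(r_path, cond_R()))
  expect_false(path_satisfies(r_path, cond_NR(-0.4)))  # B-enders never NR
  expect_true(path_satisfies(nr_path, cond_NR(-0.4)))
  expect_false(path_satisfies(shallow, cond_NR(-0.4)))
  expect_true(path_satisfies(r_path, cond_interface(-0.2)))
  expect_false(path_satisfies(shallow, cond_interface(-0.4)))
  expect_error(tis_path(NULL, NULL, 0, 0, c("A", "A"), multiplicity = 0),
               ">= 1")
})

test_that("seed paths connect the basins or fail with the attempt count", {
  sp <- fix_dw_seed_path()
  expect_identical(sp$endpoints, c("A", "B"))
  expect_identical(classify_endpoint(sp$lambda[1]), "A")
  expect_identical(classify_endpoint(sp$lambda[length(sp$lambda)]), "B")
  # states deep in A can never reconstruct an A-B path
  dw <- fix_double_well()
  expect_error(generate_seed_path(dw, list(c(-1.2, 0)),
                                  langevin_params(seed = 2),
                                  max_attempts = 5),
               "5 attempts")
})

test_that("deterministic shooting move reproduces the current path and is
           accepted", {
  dw <- fix_double_well()
  p0 <- langevin_params(friction = 0, seed = 3)
  # a deterministic ballistic path over the barrier
  st <- particle_state(c(0, 0), c(0.02, 0))
  path <- propagate_two_sided(dw, st, p0)
  mv <- shooting_move(path, dw, p0, sigma_p = 0, condition = cond_R(),
                      move_seed = 11)
  expect_true(mv$accepted)
  expect_equal(mv$path$lambda, path$lambda, tolerance = 1e-12)
})

test_that("interface ensembles honor the multiplicity accounting and the
           crossing condition", {
  dw <- fix_double_well()
  sp <- fix_dw_seed_path()
  ens <- sample_interface_ensemble(dw, sp, lambda_i = -0.4, n_moves = 400,
                                   n_equil = 150,
                                   params = langevin_params(seed = 7),
                                   sigma_p = 0.2)
  expect_equal(total_multiplicity(ens), 250)
  expect_true(all(vapply(ens$paths, function(pp)
    pp$lambda_max >= -0.4, logical(1))))
  expect_true(all(vapply(ens$paths, function(pp)
    pp$endpoints[1] == "A", logical(1))))
  expect_gte(ens$acceptance_rate, 0)
  expect_lte(ens$acceptance_rate, 1)
  expect_lte(length(ens$paths), ens$n_accepted + 1L)
  # n_moves = n_equil + 1 leaves a single counted move
  tiny <- sample_interface_ensemble(dw, sp, -0.4, n_moves = 11, n_equil = 10,
                                    params = langevin_params(seed = 8))
  expect_equal(total_multiplicity(tiny), 1)
  shallow <- tis_path(NULL, NULL, 0:1, c(-0.9, -0.85), c("A", "A"))
  expect_error(sample_interface_ensemble(dw, shallow, -0.4, 10, 5,
                                         langevin_params(seed = 1)),
               "condition")
  expect_error(sample_interface_ensemble(dw, sp, -0.4, n_moves = 10,
                                         n_equil = 10,
                                         params = langevin_params(seed = 1)),
               "n_equil")
})

test_that("sampled interface ensembles match brute-force excursion
           statistics (detailed balance)", {
  dw <- fix_double_well()
  bf <- harvest_excursion_paths(dw, cond_interface(-0.4), 300,
                                langevin_params(seed = 77),
                                max_steps = 2.5e7)
  lmax_bf <- vapply(bf, function(x) x$lambda_max, numeric(1))
  ens <- sample_interface_ensemble(dw, fix_dw_seed_path(), -0.4,
                                   n_moves = 3000, n_equil = 800,
                                   params = langevin_params(seed = 5),
                                   sigma_p = 0.2)
  lmax_mc <- unlist(lapply(ens$paths, function(pp)
    rep(pp$lambda_max, pp$multiplicity)))
  d_crit <- 1.36 * sqrt(1 / length(lmax_bf) + 1 / length(lmax_mc))
  ks <- suppressWarnings(stats::ks.test(lmax_bf, lmax_mc)$statistic)
  expect_lt(unname(ks), d_crit * 1.5)
  # the sampled conditional matches the brute-force fraction
  expect_lt(abs(mean(lmax_mc >= 0) - mean(lmax_bf >= 0)), 0.07)
})

test_that("pathway ensembles enforce their type conditions", {
  ens <- fix_mimic_ensembles()
  for (e in ens$r)
    expect_true(all(vapply(e$paths, path_satisfies, logical(1),
                           condition = cond_R())))
  for (e in ens$nr)
    expect_true(all(vapply(e$paths, path_satisfies, logical(1),
                           condition = cond_NR(-0.4))))
  r_path <- ens$r[[1]]$paths[[1]]
  expect_error(
    sample_pathway_ensembles(ens$wt, list(r_path), "R", n_moves = 5,
                             n_equil = 1, n_ensembles = 1,
                             params = langevin_params(seed = 1)),
    NA)
})

test_that("time alignment anchors t = 0 at the last compression trough", {
  # synthetic path: breaking distance has troughs at t = 5 and t = 9 fs
  d <- c(2, 1.8, 1.6, 1.5, 1.6, 1.4, 1.6, 1.7, 1.6, 1.45, 1.8, 2.2, 2.6, 3)
  lam <- seq(-0.9, 0.9, length.out = length(d))
  # embed d as the D-M distance of a 2-particle frame set
  pos <- cbind(0, 0, 0, d, 0, 0)
  path <- tis_path(pos, pos * 0, time = seq_along(d) - 1, lambda = lam,
                   endpoints = c("A", "B"))
  al <- align_time_zero(path, breaking = c(1, 2))
  expect_equal(al$time[10], 0)  # the t = 9 trough (index 10) wins
  again <- align_time_zero(al, breaking = c(1, 2))
  expect_identical(again$time, al$time)
  mono <- tis_path(cbind(0, 0, 0, seq(1, 3, length.out = 10), 0, 0),
                   matrix(0, 10, 6), 0:9,
                   seq(-0.9, 0.9, length.out = 10), c("A", "B"))
  expect_error(align_time_zero(mono, c(1, 2)), "alignment error")
})

test_that("window frames are weighted by multiplicity over half-open
           windows", {
  pos <- matrix(rnorm(60), 10, 6)
  mk <- function(mult) {
    p <- tis_path(pos, pos * 0, time = seq(-45, 0, by = 5),
                  lambda = seq(-0.9, -0.3, length.out = 10),
                  endpoints = c("A", "A"), multiplicity = mult)
    p$uid <- paste0("u", mult)
    p
  }
  ens <- structure(list(condition = cond_NR(-0.4),
                        paths = list(mk(4L), mk(1L)), n_attempted = 1L,
                        n_accepted = 1L, acceptance_rate = 1,
                        seed_lineage = "w"), class = "path_ensemble")
  fr <- sample_window_frames(ens, window = c(-30, 0), frames_per_path = 1,
                             seed = 2)
  expect_equal(nrow(fr), 2)
  expect_setequal(fr$weight, c(4, 1))
  expect_true(all(fr$time >= -30 & fr$time < 0))  # t = 0 excluded
  many <- sample_window_frames(ens, c(-30, 0), frames_per_path = 3, seed = 2)
  expect_lte(nrow(many), 6)
  expect_warning(sample_window_frames(ens, c(100, 130)), "skipped")
})
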