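# a small controlled objective: conformation ids map into planted tables
controlled_spec <- function(space, r_ids = 1:3, nr_ids = 4:6) {
  design_objective_spec(as.list(r_ids), as.list(nr_ids),
                        space$energy_model, space$wt_sequence)
}

test_that("the wild type scores exactly zero and stability flags follow the
           thresholds", {
  em <- function(sequence, conformation) {
    base <- if (identical(sequence, c("A"))) 0 else -1  # mutant lowers E_R
    if (conformation <= 3) base else 0
  }
  spec <- design_objective_spec(as.list(1:3), as.list(4:6), em, "A")
  wt <- score_objective("A", spec)
  expect_identical(wt$score, 0)
  mut <- score_objective("B", spec)
  expect_equal(mut$score, -3)
  expect_true(mut$stability_ok)
  # raising reactive energies by 6 total violates the sum-based bound
  em2 <- function(sequence, conformation) {
    if (conformation > 3) return(0)
    if (identical(sequence, c("B"))) 2 else 0
  }
  spec2 <- design_objective_spec(as.list(1:3), as.list(4:6), em2, "A")
  expect_false(score_objective("B", spec2)$stability_ok)
  # per-structure reading: each +2 rise is within the 5 kcal/mol bound
  expect_true(score_objective("B", spec2,
                              stability_mode = "per_structure")$stability_ok)
})

test_that("a planted best mutant ranks first; window 0 keeps only optima", {
  sp <- make_toy_design_space(1, 2, effect_table_seed = 11)
  spec <- controlled_spec(sp)
  res <- search_designs(sp, spec, window = 50)
  expect_equal(nrow(res), 2)
  expect_equal(res$rank, 1:2)
  best <- res$sequence[1]
  only <- search_designs(sp, spec, window = 0)
  expect_identical(only$sequence, best)
  expect_identical(res$score[res$sequence == "A"], 0)
})

test_that("branch and bound reproduces exhaustive enumeration exactly", {
  for (dims in list(c(3, 4), c(6, 3))) {
    sp <- make_toy_design_space(dims[1], dims[2],
                                effect_table_seed = sum(dims))
    spec <- controlled_spec(sp)
    ex <- search_designs(sp, spec, window = 10, mode = "exhaustive")
    bb <- search_designs(sp, spec, window = 10, mode = "branch_and_bound")
    expect_setequal(ex$sequence, bb$sequence)
    expect_equal(ex$f[order(ex$sequence)], bb$f[order(bb$sequence)],
                 tolerance = 1e-9)
  }
})

test_that("window and stability constraints exclude constructed
           counterexamples", {
  # token B is 30 kcal/mol worse on the objective: outside any 20 window
  em <- function(sequence, conformation) {
    if (conformation > 1) return(0)
    if (sequence[1] == "B") 30 else 0
  }
  space <- list(sites = 1L, alphabet = c("A", "B"), wt_sequence = "A",
                energy_model = em, tables = NULL)
  spec <- design_objective_spec(list(1), list(2), em, "A")
  res <- search_designs(space, spec, window = 20)
  expect_false("B" %in% res$sequence)
  # token C destabilizes the reactive structure by 6: stability-infeasible
  em2 <- function(sequence, conformation) {
    if (conformation > 1) return(0)
    switch(sequence[1], A = 0, C = 6)
  }
  space2 <- list(sites = 1L, alphabet = c("A", "C"), wt_sequence = "A",
                 energy_model = em2, tables = NULL)
  spec2 <- design_objective_spec(list(1), list(2), em2, "A")
  res2 <- search_designs(space2, spec2, window = 20, stability_limit = 5)
  expect_false("C" %in% res2$sequence)
})

test_that("objective is invariant to a constant shift and monotone in
           reactive energies", {
  sp <- make_toy_design_space(2, 3, effect_table_seed = 5)
  spec <- controlled_spec(sp)
  shifted <- design_objective_spec(
    spec$reactive, spec$nonreactive,
    function(s, c) sp$energy_model(s, c) + 42, sp$wt_sequence)
  s <- c("B", "C")
  expect_equal(score_objective(s, spec)$score,
               score_objective(s, shifted)$score, tolerance = 1e-9)
})

test_that("representative structures follow combined model confidence with
           reproducible ties", {
  frames <- tibble::tibble(
    path_uid = paste0("p", 1:8), frame_index = 1:8,
    label = rep(c("R", "NR"), each = 4),
    f1 = c(3, 2, 1, 0, 0, -1, -2, -3), weight = 1)
  lin <- function(kind) structure(
    list(kind = kind, features = "f1", selected = "f1",
         params = if (kind == "LR") list(intercept = 0, beta = c(f1 = 2))
                  else NULL,
         center = c(f1 = 0), scale = c(f1 = 1), cv_metrics = NULL,
         window = NULL, schema = NULL, threshold = 0.5),
    class = "trained_model")
  lr <- lin("LR")
  nn <- lin("LR")  # same linear scorer for both slots
  sel <- select_representative_structures(frames, lr, nn, n_per_class = 3)
  expect_identical(sel$reactive$path_uid, c("p1", "p2", "p3"))
  expect_identical(sel$nonreactive$path_uid, c("p8", "p7", "p6"))
  sel2 <- select_representative_structures(frames, lr, nn, n_per_class = 3)
  expect_identical(sel$reactive, sel2$reactive)
  expect_error(select_representative_structures(frames[1:2, ], lr, nn, 3),
               "selection error")
})

test_that("prioritization tiers combine the three screening criteria", {
  ref <- tibble::tibble(sequence = "WT", score = 0, frac_lr = 0.1,
                        frac_nn = 0.1, norm_lr = 1, norm_nn = 1,
                        dg_screen = 5, dg_reason = NA)
  all3 <- tibble::tibble(sequence = "M1", score = -2, frac_lr = 0.2,
                         frac_nn = 0.2, norm_lr = 2, norm_nn = 2,
                         dg_screen = 4, dg_reason = NA)
  none <- tibble::tibble(sequence = "M2", score = 3, frac_lr = 0.05,
                         frac_nn = 0.05, norm_lr = 0.5, norm_nn = 0.5,
                         dg_screen = 7, dg_reason = NA)
  two <- tibble::tibble(sequence = "M3", score = -1, frac_lr = 0.2,
                        frac_nn = 0.2, norm_lr = 2, norm_nn = 2,
                        dg_screen = 9, dg_reason = NA)
  out <- prioritize(dplyr::bind_rows(ref, all3, none, two), reference = ref)
  expect_identical(out$sequence[out$tier == 1], "M1")
  expect_true("M3" %in% out$sequence[out$tier == 2])
  expect_true(all(c("WT", "M2") %in% out$sequence[out$tier == 3]))
  expect_identical(out$sequence[1], "M1")
})

test_that("screening records degrade gracefully when the PMF fails", {
  fam <- fix_mimic_family()
  models <- fix_mimic_models()
  rec <- screen_candidate("A", fam$system_factory, models,
                          params = langevin_params(seed = 3),
                          n_replicas = 1, duration_ps = 1,
                          pmf_centers = c(-1.2, 1.2),  # disconnected
                          pmf_force_constant = 400)
  expect_true(is.na(rec$dg_screen))
  expect_match(rec$dg_reason, "disconnected")
})
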