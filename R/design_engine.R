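#' Multistate sequence design
#'
#' Selects representative reactive-like and nonreactive-like structures with
#' the trained classifiers, scores sequences with the multistate objective
#' \deqn{f(s) = \sum_{i=1}^{N_R} E_{R,i}(s) - \sum_{i=1}^{N_{NR}} E_{NR,i}(s)}
#' (reported relative to the wild type, whose score is exactly 0), enforces
#' the stability constraint (reactive-structure energies no more than 5
#' kcal/mol less stable than wild type), searches a design space
#' exhaustively or by branch and bound, and compiles screening records and
#' priorities.
#'
#' @name design_engine
NULL

#' Select representative structures by model confidence
#'
#' The reactive set is the top `n_per_class` frames by combined model
#' confidence (mean of the LR and NN reactive probabilities) among
#' truly-reactive-labeled frames; the nonreactive set symmetrically uses
#' nonreactive confidence among truly-nonreactive frames. Deterministic:
#' ties break by path identifier then frame index.
#'
#' @param frames A frames tibble with `label` and features or `positions`.
#' @param lr,nn Trained models sharing the feature schema.
#' @param n_per_class Structures per class (default 3).
#' @return `list(reactive = , nonreactive = )` of tibble rows with a
#'   `confidence` column.
#' @export
select_representative_structures <- function(frames, lr, nn,
                                             n_per_class = 3) {
  p <- (predict(lr, frames) + predict(nn, frames)) / 2
  frames$confidence <- p
  pick <- function(lab, conf) {
    sub <- frames[frames$label == lab, ]
    if (nrow(sub) < n_per_class)
      stop(sprintf("selection error: only %d %s-labeled frames", nrow(sub),
                   lab), call. = FALSE)
    key <- if (conf == "reactive") -sub$confidence else sub$confidence
    ord <- order(key, sub$path_uid, sub$frame_index)
    sub[ord[seq_len(n_per_class)], ]
  }
  list(reactive = pick("R", "reactive"),
       nonreactive = pick("NR", "nonreactive"))
}

#' Specify the design objective
#'
#' @param reactive_structures,nonreactive_structures Conformations passed to
#'   the energy model (conformation ids for a toy space, or coordinate
#'   vectors / frame rows for potential-based models). At least one each;
#'   the full-scale default is three per class.
#' @param energy_model Deterministic function `(sequence, conformation) ->`
#'   energy in kcal/mol.
#' @param wt_sequence Wild-type token vector.
#' @return A `design_objective_spec`.
#' @export
design_objective_spec <- function(reactive_structures,
                                  nonreactive_structures, energy_model,
                                  wt_sequence) {
  if (length(reactive_structures) < 1 || length(nonreactive_structures) < 1)
    abort_param("need at least one structure per class")
  structure(list(reactive = reactive_structures,
                 nonreactive = nonreactive_structures,
                 energy_model = energy_model, wt_sequence = wt_sequence),
            class = "design_objective_spec")
}

objective_f <- function(sequence, spec) {
  er <- vapply(spec$reactive, function(c) spec$energy_model(sequence, c),
               numeric(1))
  en <- vapply(spec$nonreactive, function(c) spec$energy_model(sequence, c),
               numeric(1))
  list(f = sum(er) - sum(en), e_reactive = er, e_nonreactive = en)
}

#' Score one sequence against the design objective
#'
#' `score = f(s) - f(WT)`; the wild type scores exactly 0. Stability is
#' checked on the summed reactive-structure energies by default
#' (`sum(E_R(s)) <= sum(E_R(WT)) + stability_limit`), or per structure.
#'
#' @param sequence Token vector.
#' @param spec A `design_objective_spec`.
#' @param stability_limit kcal/mol (default 5).
#' @param stability_mode `"sum"` or `"per_structure"`.
#' @return A one-row tibble: `sequence`, `f`, `score`, `stability_ok`,
#'   `within_window` (`NA` until a search provides the optimum).
#' @export
score_objective <- function(sequence, spec, stability_limit = 5,
                            stability_mode = c("sum", "per_structure")) {
  stability_mode <- match.arg(stability_mode)
  o <- objective_f(sequence, spec)
  wt <- objective_f(spec$wt_sequence, spec)
  stab <- if (stability_mode == "sum") {
    sum(o$e_reactive) <= sum(wt$e_reactive) + stability_limit
  } else {
    all(o$e_reactive <= wt$e_reactive + stability_limit)
  }
  tibble::tibble(sequence = paste(sequence, collapse = ""),
                 f = o$f, score = o$f - wt$f, stability_ok = stab,
                 within_window = NA)
}

#' Search a design space
#'
#' Returns every stability-feasible sequence whose objective lies within
#' `window` kcal/mol of the best feasible sequence found, ranked ascending
#' by score. Branch and bound (available when the space carries the toy
#' effect tables) returns results identical to exhaustive enumeration.
#'
#' @param space A `toy_design_space` (or any list with `sites`, `alphabet`,
#'   `wt_sequence`, `energy_model`).
#' @param spec A `design_objective_spec` whose conformations the space's
#'   energy model understands.
#' @param window Collection window above the optimum, kcal/mol (default 20).
#' @param stability_limit Stability bound, kcal/mol (default 5).
#' @param mode `"exhaustive"` or `"branch_and_bound"`.
#' @param stability_mode `"sum"` or `"per_structure"`.
#' @return A tibble of `design_result`s ranked by score (wild type scores
#'   0 by construction), with columns `sequence`, `f`, `score`,
#'   `stability_ok`, `within_window`, `rank`.
#' @export
search_designs <- function(space, spec, window = 20, stability_limit = 5,
                           mode = c("exhaustive", "branch_and_bound"),
                           stability_mode = c("sum", "per_structure")) {
  mode <- match.arg(mode)
  stability_mode <- match.arg(stability_mode)
  if (window < 0) abort_param("window must be >= 0")
  if (mode == "branch_and_bound") {
    if (is.null(space$tables))
      abort_param(paste("branch_and_bound requires a table-backed space;",
                        "use exhaustive for callable energy models"))
    res <- bnb_search(space, spec, window, stability_limit, stability_mode)
  } else {
    res <- exhaustive_search(space, spec, window, stability_limit,
                             stability_mode)
  }
  if (nrow(res) == 0) {
    message("no feasible sequence found")
    return(res)
  }
  res <- res[order(res$score, res$sequence), ]
  res$rank <- seq_len(nrow(res))
  res
}

enumerate_sequences <- function(space) {
  n_sites <- length(space$sites)
  grid <- do.call(expand.grid,
                  c(rep(list(space$alphabet), n_sites),
                    stringsAsFactors = FALSE))
  if (nrow(grid) > 2e5)
    abort_param("space too large for exhaustive enumeration")
  lapply(seq_len(nrow(grid)), function(i) as.character(unlist(grid[i, ])))
}

exhaustive_search <- function(space, spec, window, stability_limit,
                              stability_mode) {
  if (!is.null(space$tables))
    return(exhaustive_search_tables(space, spec, window, stability_limit,
                                    stability_mode))
  seqs <- enumerate_sequences(space)
  wt <- objective_f(spec$wt_sequence, spec)
  rows <- purrr::map_dfr(seqs, function(s) {
    o <- objective_f(s, spec)
    stab <- if (stability_mode == "sum")
      sum(o$e_reactive) <= sum(wt$e_reactive) + stability_limit
    else all(o$e_reactive <= wt$e_reactive + stability_limit)
    tibble::tibble(sequence = paste(s, collapse = ""), f = o$f,
                   score = o$f - wt$f, stability_ok = stab)
  })
  feas <- rows[rows$stability_ok, ]
  if (nrow(feas) == 0) return(feas)
  fmin <- min(feas$f)
  out <- feas[feas$f <= fmin + window + 1e-12, ]
  out$within_window <- TRUE
  out
}

# vectorized enumeration over the toy effect tables
exhaustive_search_tables <- function(space, spec, window, stability_limit,
                                     stability_mode) {
  tb <- space$tables
  n_sites <- length(space$sites)
  n_tok <- length(space$alphabet)
  rset <- as.integer(unlist(spec$reactive))
  nset <- as.integer(unlist(spec$nonreactive))
  tok_grid <- as.matrix(do.call(expand.grid,
                                rep(list(seq_len(n_tok)), n_sites)))
  if (nrow(tok_grid) > 2e5)
    abort_param("space too large for exhaustive enumeration")
  # per-conformation energies for every sequence
  E <- matrix(0, nrow(tok_grid), length(tb$base))
  for (cid in seq_along(tb$base)) {
    e <- rep(tb$base[cid], nrow(tok_grid))
    for (i in seq_len(n_sites)) e <- e + tb$additive[i, tok_grid[, i], cid]
    if (n_sites > 1) {
      pscl <- tb$pscale[cid]
      for (i in seq_len(n_sites - 1)) for (j in (i + 1):n_sites)
        e <- e + pscl * tb$pairwise[i, j, , ][cbind(tok_grid[, i],
                                                    tok_grid[, j])]
    }
    E[, cid] <- e
  }
  f <- rowSums(E[, rset, drop = FALSE]) - rowSums(E[, nset, drop = FALSE])
  er_sum <- rowSums(E[, rset, drop = FALSE])
  wt <- objective_f(spec$wt_sequence, spec)
  stab <- if (stability_mode == "sum") {
    er_sum <= sum(wt$e_reactive) + stability_limit
  } else {
    rowSums(sweep(E[, rset, drop = FALSE], 2,
                  wt$e_reactive + stability_limit, ">")) == 0
  }
  seq_str <- apply(tok_grid, 1, function(t)
    paste(space$alphabet[t], collapse = ""))
  rows <- tibble::tibble(sequence = seq_str, f = f, score = f - wt$f,
                         stability_ok = stab)
  feas <- rows[rows$stability_ok, ]
  if (nrow(feas) == 0) return(feas)
  fmin <- min(feas$f)
  out <- feas[feas$f <= fmin + window + 1e-12, ]
  out$within_window <- TRUE
  out
}

# table-backed branch and bound; admissible bound from per-site and
# per-pair minima of the objective contributions
bnb_search <- function(space, spec, window, stability_limit,
                       stability_mode) {
  tb <- space$tables
  n_sites <- length(space$sites)
  n_tok <- length(space$alphabet)
  rset <- as.integer(unlist(spec$reactive))
  nset <- as.integer(unlist(spec$nonreactive))
  # objective coefficients
  base_f <- sum(tb$base[rset]) - sum(tb$base[nset])
  A <- matrix(0, n_sites, n_tok)
  for (i in seq_len(n_sites)) for (t in seq_len(n_tok))
    A[i, t] <- sum(tb$additive[i, t, rset]) - sum(tb$additive[i, t, nset])
  pmul <- sum(tb$pscale[rset]) - sum(tb$pscale[nset])
  # suffix bounds
  minA <- apply(A, 1, min)
  minP_into <- numeric(n_sites)   # for site j: sum over i<j of min pair term
  if (n_sites > 1) for (j in 2:n_sites) {
    s <- 0
    for (i in 1:(j - 1)) s <- s + min(tb$pairwise[i, j, , ] * pmul)
    minP_into[j] <- s
  }
  suffix <- rev(cumsum(rev(minA + minP_into)))
  suffix <- c(suffix, 0)  # suffix[d+1] = bound for sites > d
  wt <- objective_f(spec$wt_sequence, spec)
  best <- wt$f
  results <- list()
  assign_tok <- integer(n_sites)
  recurse <- function(depth, partial) {
    if (depth == n_sites) {
      s <- space$alphabet[assign_tok]
      o <- objective_f(s, spec)
      stab <- if (stability_mode == "sum")
        sum(o$e_reactive) <= sum(wt$e_reactive) + stability_limit
      else all(o$e_reactive <= wt$e_reactive + stability_limit)
      if (stab) {
        if (o$f < best) best <<- o$f
        results[[length(results) + 1L]] <<- tibble::tibble(
          sequence = paste(s, collapse = ""), f = o$f,
          score = o$f - wt$f, stability_ok = TRUE)
      }
      return(invisible())
    }
    d <- depth + 1L
    for (t in seq_len(n_tok)) {
      contrib <- A[d, t]
      if (depth > 0) for (i in seq_len(depth))
        contrib <- contrib + tb$pairwise[i, d, assign_tok[i], t] * pmul
      newp <- partial + contrib
      if (newp + suffix[d + 1L] > best + window + 1e-12) next
      assign_tok[d] <<- t
      recurse(d, newp)
    }
  }
  recurse(0L, base_f)
  res <- dplyr::bind_rows(results)
  if (nrow(res) == 0) return(res)
  res <- res[res$f <= best + window + 1e-12, ]
  res$within_window <- TRUE
  res
}

# ---- screening --------------------------------------------------------------

#' Screen a candidate sequence
#'
#' Builds the candidate's system, runs equilibrium reactant-well dynamics
#' and computes the fraction of time steps classified reactive-like by the
#' LR and NN models, estimates the screening-mode barrier height from a
#' rapid umbrella/WHAM calculation, and (optionally) the design objective
#' score. Fractions are normalized by a reference record when given.
#'
#' @param sequence Token vector.
#' @param system_factory Function mapping a sequence to a `model_system`.
#' @param models `list(lr = , nn = )` trained models.
#' @param objective_spec Optional `design_objective_spec`.
#' @param reference Optional reference `screening_record` (for
#'   normalization).
#' @param params A `langevin_params`.
#' @param n_replicas,duration_ps Equilibrium-run design (full scale: 30 x
#'   400 ps).
#' @param sample_every Frame-thinning stride for classification.
#' @param pmf_centers Umbrella centers (default [generate_window_centers()]).
#' @param pmf_force_constant Umbrella force constant, kcal/(mol A^2).
#' @param barrier_args Arguments passed to [estimate_barrier()].
#' @return A one-row `screening_record` tibble.
#' @export
screen_candidate <- function(sequence, system_factory, models,
                             objective_spec = NULL, reference = NULL,
                             params = langevin_params(),
                             n_replicas = 3, duration_ps = 10,
                             sample_every = 20, pmf_centers = NULL,
                             pmf_force_constant = 200,
                             barrier_args = list()) {
  sys <- system_factory(sequence)
  segs <- run_equilibrium_well(sys, duration_ps, n_replicas, params,
                               save_frames = TRUE)
  frames <- dplyr::bind_rows(lapply(seq_along(segs), function(i) {
    fp <- segs[[i]]$frames_pos
    idx <- seq(1, nrow(fp), by = sample_every)
    tibble::tibble(path_uid = paste0("eq", i), frame_index = idx,
                   weight = 1,
                   positions = lapply(idx, function(r) fp[r, ]))
  }))
  frac_lr <- reactive_fraction(models$lr, frames)
  frac_nn <- reactive_fraction(models$nn, frames)
  dg <- NA_real_; dg_reason <- NA_character_
  pmf_res <- tryCatch({
    centers <- pmf_centers %||% generate_window_centers()
    wins <- run_umbrella_series(sys, centers, pmf_force_constant,
                                mode = "screening", params = params)
    prof <- solve_wham(wins, temperature = sys$temperature)
    do.call(estimate_barrier, c(list(prof), barrier_args))$barrier
  }, error = function(e) {
    dg_reason <<- conditionMessage(e)
    NA_real_
  })
  dg <- pmf_res
  score <- if (!is.null(objective_spec))
    score_objective(sequence, objective_spec)$score else NA_real_
  rec <- tibble::tibble(
    sequence = paste(sequence, collapse = ""), score = score,
    frac_lr = frac_lr, frac_nn = frac_nn,
    norm_lr = if (!is.null(reference))
      normalize_by_reference(frac_lr, reference$frac_lr) else NA_real_,
    norm_nn = if (!is.null(reference))
      normalize_by_reference(frac_nn, reference$frac_nn) else NA_real_,
    dg_screen = dg, dg_reason = dg_reason)
  class(rec) <- c("screening_record", class(rec))
  rec
}

#' Prioritize screening records
#'
#' Tier 1: favorable objective (score < 0) AND increased reactive-like
#' population under both models AND screening barrier at or below the
#' reference. Tier 2: any two of the three. Tier 3: the rest. Stable sort
#' within tier by objective score.
#'
#' @param records A tibble of screening records (rbind of
#'   [screen_candidate()] outputs).
#' @param reference The reference record (for normalization and the barrier
#'   comparison); defaults to the row whose normalized fractions are 1.
#' @return The records with `tier` and `priority_rank` columns, sorted.
#' @export
prioritize <- function(records, reference = NULL) {
  ref <- reference %||% records[which(records$norm_lr == 1 &
                                        records$norm_nn == 1)[1], ]
  crit_obj <- !is.na(records$score) & records$score < 0
  crit_pop <- !is.na(records$norm_lr) & !is.na(records$norm_nn) &
    records$norm_lr > 1 & records$norm_nn > 1
  crit_dg <- !is.na(records$dg_screen) & !is.na(ref$dg_screen) &
    records$dg_screen <= ref$dg_screen
  n_met <- crit_obj + crit_pop + crit_dg
  records$tier <- dplyr::case_when(n_met == 3 ~ 1L, n_met == 2 ~ 2L,
                                   TRUE ~ 3L)
  ord <- order(records$tier, records$score)
  records <- records[ord, ]
  records$priority_rank <- seq_len(nrow(records))
  records
}

# ---- surrogate mutant family ------------------------------------------------

#' A surrogate variant family over the migration mimic
#'
#' A one-site design space whose "mutations" shift the gate particle's
#' tether away from (positive effects) or toward (negative) the donor
#' particle while the barrier-modulation midpoint `d_ref` stays at the
#' wild-type value. A positive tether shift populates favourable gate
#' configurations more often, lowering the effective barrier: the planted
#' "faster" mutant. The returned space's energy model evaluates the
#' variant's potential at a conformation's coordinates.
#'
#' @param tether_shifts Named numeric vector of x-shifts (Angstrom) per
#'   token; the first entry is the wild type and should be 0.
#' @param ... Arguments for [make_migration_mimic()].
#' @return `list(space, system_factory, wt_sequence)`.
#' @export
make_mimic_family <- function(tether_shifts = c(A = 0, B = 2.0), ...) {
  args <- list(...)
  wt_sys <- do.call(make_migration_mimic, args)
  d_ref_wt <- wt_sys$params[["d_ref"]]
  system_factory <- function(sequence) {
    tok <- sequence[1]
    if (!tok %in% names(tether_shifts))
      abort_param("sequence has tokens outside the family")
    sys <- wt_sys
    sys$tethers[1] <- sys$tethers[1] + tether_shifts[[tok]]
    sys$params[["d_ref"]] <- d_ref_wt
    sys$metadata$variant <- tok
    sys
  }
  energy_model <- function(sequence, conformation) {
    pos <- if (is.list(conformation)) conformation$positions else
      as.double(conformation)
    system_potential(system_factory(sequence), pos)
  }
  space <- structure(list(sites = 1L, alphabet = names(tether_shifts),
                          wt_sequence = names(tether_shifts)[1],
                          energy_model = energy_model, tables = NULL),
                     class = "design_space")
  list(space = space, system_factory = system_factory,
       wt_sequence = names(tether_shifts)[1])
}
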