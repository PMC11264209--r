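#' Transition path and interface sampling
#'
#' Seed-path discovery, shooting-move Monte Carlo, interface ensembles for
#' rate constants, pathway-type ensembles (reactive R and nonreactive
#' NR_threshold), time alignment at the last compression of the breaking
#' bond, and weighted frame extraction from time windows.
#'
#' @name path_sampling
NULL

#' Construct a path object
#'
#' A time-ordered sequence of system states with its lambda series, endpoint
#' labels and Monte-Carlo multiplicity.
#'
#' @param frames_pos,frames_vel Matrices (n_frames x n_coord) of positions
#'   and velocities; may be `NULL` for frame-stripped paths.
#' @param time Frame times, fs.
#' @param lambda Lambda series, Angstrom.
#' @param endpoints Two labels in `"A"`, `"B"`, `"neither"`.
#' @param multiplicity Monte-Carlo repeat count (>= 1).
#' @param non_committal Whether either side failed to commit to a basin.
#' @param shoot_index Frame index of the shooting point, if any.
#' @return A `tis_path`.
#' @export
tis_path <- function(frames_pos, frames_vel, time, lambda, endpoints,
                     multiplicity = 1L, non_committal = FALSE,
                     shoot_index = NA_integer_) {
  if (multiplicity < 1) abort_param("`multiplicity` must be >= 1")
  structure(list(frames_pos = frames_pos, frames_vel = frames_vel,
                 time = time, lambda = lambda, endpoints = endpoints,
                 lambda_max = max(lambda), multiplicity = multiplicity,
                 non_committal = non_committal, shoot_index = shoot_index,
                 uid = NA_character_),
            class = "tis_path")
}

#' @export
print.tis_path <- function(x, ...) {
  cat("<tis_path> ", length(x$lambda), " frames (",
    x$endpoints[1], " -> ", x$endpoints[2], "), lambda_max = ",
    round(x$lambda_max, 3), ", multiplicity = ", x$multiplicity,
    if (x$non_committal) " [non-committal]", "\n", sep = "")
  invisible(x)
}

#' Classify a lambda value into basins
#'
#' State A is the reactant well (`lambda < lambda_A`), state B the product
#' well (`lambda > lambda_B`); both inequalities strict, so a boundary value
#' is `"neither"`.
#'
#' @param lambda_value Lambda value(s), Angstrom.
#' @param lambda_A,lambda_B Basin thresholds (defaults -0.8 and 0.8).
#' @return Character vector in `"A"`, `"B"`, `"neither"`.
#' @export
classify_endpoint <- function(lambda_value, lambda_A = -0.8, lambda_B = 0.8) {
  stopifnot(all(is.finite(lambda_value)))
  ifelse(lambda_value < lambda_A, "A",
         ifelse(lambda_value > lambda_B, "B", "neither"))
}

reverse_path <- function(path) {
  n <- length(path$lambda)
  tis_path(
    frames_pos = if (!is.null(path$frames_pos))
      path$frames_pos[n:1, , drop = FALSE],
    frames_vel = if (!is.null(path$frames_vel))
      -path$frames_vel[n:1, , drop = FALSE],
    time = path$time[1] + (path$time[n] - rev(path$time)),
    lambda = rev(path$lambda), endpoints = rev(path$endpoints),
    multiplicity = path$multiplicity
  )
}

strip_frames <- function(path) {
  path$frames_pos <- NULL
  path$frames_vel <- NULL
  path
}

# ---- ensemble conditions ----------------------------------------------------

#' Path-ensemble conditions
#'
#' `cond_interface(lambda_i)`: the path starts in A and reaches at least
#' `lambda_i` (paths that reach B are retained: they cross all higher
#' interfaces). `cond_R()`: endpoints (A, B). `cond_NR(threshold)`:
#' endpoints (A, A) and `lambda_max >= threshold` (default -0.4 Angstrom;
#' paths reaching B are never NR).
#'
#' @param lambda_i Interface position, Angstrom.
#' @param threshold NR progress threshold, Angstrom.
#' @return A `path_condition`.
#' @export
cond_interface <- function(lambda_i) {
  structure(list(type = "interface", lambda_i = lambda_i),
            class = "path_condition")
}

#' @rdname cond_interface
#' @export
cond_R <- function() structure(list(type = "R"), class = "path_condition")

#' @rdname cond_interface
#' @export
cond_NR <- function(threshold = -0.4) {
  structure(list(type = "NR", threshold = threshold),
            class = "path_condition")
}

#' Does a path satisfy an ensemble condition?
#' @param path A `tis_path`.
#' @param condition A `path_condition`.
#' @return Logical.
#' @export
path_satisfies <- function(path, condition) {
  if (path$non_committal) return(FALSE)
  switch(condition$type,
    interface = identical(path$endpoints[1], "A") &&
      path$lambda_max >= condition$lambda_i,
    R = identical(path$endpoints, c("A", "B")),
    NR = identical(path$endpoints, c("A", "A")) &&
      path$lambda_max >= condition$threshold,
    any = TRUE,
    abort_param("unknown condition type"))
}

# ---- seed paths -------------------------------------------------------------

#' Generate a seed path from barrier-top states
#'
#' Draws transition-state-like configurations (e.g. sampled from umbrella
#' windows near lambda = 0), redraws Maxwell-Boltzmann velocities, and
#' regenerates two-sided paths until one connects A to B; paths found as
#' (B, A) are time-reversed. Optionally equilibrated with additional
#' shooting moves before use (the full-scale protocol uses 2000).
#'
#' @param system A `model_system`.
#' @param barrier_states A list of `particle_state`s near the barrier (their
#'   velocities are redrawn), or position vectors.
#' @param params A `langevin_params`.
#' @param max_attempts Attempt budget before failing.
#' @param n_equilibrate Shooting moves applied to the found seed (condition:
#'   reactive endpoints).
#' @param sigma_p Momentum-perturbation scale for the equilibration moves.
#' @param lambda_A,lambda_B Basin thresholds.
#' @param max_steps Per-side propagation budget.
#' @return A `tis_path` with endpoints (A, B).
#' @export
generate_seed_path <- function(system, barrier_states, params,
                               max_attempts = 200, n_equilibrate = 0,
                               sigma_p = 0.2, lambda_A = -0.8,
                               lambda_B = 0.8, max_steps = 20000) {
  if (!is.list(barrier_states) || inherits(barrier_states, "particle_state"))
    barrier_states <- list(barrier_states)
  for (a in seq_len(max_attempts)) {
    bs <- barrier_states[[((a - 1L) %% length(barrier_states)) + 1L]]
    pos <- if (inherits(bs, "particle_state")) bs$positions else as.double(bs)
    vel <- maxwell_velocities(system, seed = seed_stream(params$seed, 41, a))
    p <- params
    p$seed <- seed_stream(params$seed, 42, a)
    path <- propagate_two_sided(system, particle_state(pos, vel), p,
                                lambda_A, lambda_B, max_steps)
    if (path$non_committal) next
    if (identical(sort(path$endpoints), c("A", "B"))) {
      if (identical(path$endpoints, c("B", "A"))) path <- reverse_path(path)
      if (n_equilibrate > 0) {
        cond <- cond_R()
        for (m in seq_len(n_equilibrate)) {
          mv <- shooting_move(path, system, params, sigma_p, cond,
                              move_seed = seed_stream(params$seed, 43, a, m),
                              lambda_A = lambda_A, lambda_B = lambda_B,
                              max_steps = max_steps)
          path <- mv$path
        }
        path$multiplicity <- 1L
      }
      return(path)
    }
  }
  stop(sprintf("no A<->B seed path found in %d attempts", max_attempts),
       call. = FALSE)
}

# ---- shooting moves ---------------------------------------------------------

#' One TIS shooting move
#'
#' A frame is selected uniformly from the current path, its momenta are
#' perturbed by Gaussian displacements of scale `sigma_p` (in units of the
#' thermal velocity of each coordinate), and a candidate path is generated
#' by two-sided propagation. The candidate is accepted iff it satisfies the
#' ensemble condition and passes a Metropolis factor
#' `exp(-beta * dKE) * N_old / N_new` accounting for the kinetic-energy
#' change of the perturbation and the uniform frame-selection proposal on
#' paths of different length. On rejection the current path's multiplicity
#' is incremented. Non-committal candidates count as rejections. In the
#' deterministic limit (`sigma_p = 0`, `friction = 0`) the candidate
#' reproduces the current path and is accepted.
#'
#' @param current The current `tis_path` (must carry frames).
#' @param system A `model_system`.
#' @param params A `langevin_params`.
#' @param sigma_p Momentum perturbation scale (dimensionless).
#' @param condition The ensemble `path_condition`.
#' @param move_seed Integer seed for this move's random choices.
#' @param lambda_A,lambda_B Basin thresholds.
#' @param max_steps Per-side propagation budget.
#' @return `list(path = , accepted = , candidate = )`; `path` is the new
#'   current path.
#' @export
shooting_move <- function(current, system, params, sigma_p, condition,
                          move_seed, lambda_A = -0.8, lambda_B = 0.8,
                          max_steps = 20000) {
  if (is.null(current$frames_pos))
    abort_param("current path carries no frames; cannot shoot")
  set.seed(as.integer(move_seed %% 2147483647))
  n_old <- length(current$lambda)
  j <- sample.int(n_old, 1)
  pos <- current$frames_pos[j, ]
  vel <- current$frames_vel[j, ]
  kT <- kT_kcal(params$temperature)
  vth <- sqrt(.acc_unit * kT / system$masses_coord)
  dvel <- if (sigma_p > 0) sigma_p * vth * rnorm(length(vel)) else 0
  vel_new <- vel + dvel
  ke <- function(v) sum(0.5 * system$masses_coord * v^2) / .acc_unit
  d_ke <- ke(vel_new) - ke(vel)
  u_acc <- runif(1)
  p <- params
  p$seed <- seed_stream(move_seed, 5)
  cand <- propagate_two_sided(system, particle_state(pos, vel_new), p,
                              lambda_A, lambda_B, max_steps)
  ok <- !cand$non_committal && path_satisfies(cand, condition)
  if (ok) {
    p_acc <- exp(-d_ke / kT) * n_old / length(cand$lambda)
    ok <- u_acc < min(1, p_acc)
  }
  if (ok) {
    cand$multiplicity <- 1L
    list(path = cand, accepted = TRUE, candidate = cand)
  } else {
    current$multiplicity <- current$multiplicity + 1L
    list(path = current, accepted = FALSE, candidate = cand)
  }
}

# ---- ensembles --------------------------------------------------------------

new_path_ensemble <- function(condition, paths, n_attempted, n_accepted,
                              seed_lineage) {
  structure(list(condition = condition, paths = paths,
                 n_attempted = n_attempted, n_accepted = n_accepted,
                 acceptance_rate = if (n_attempted > 0)
                   n_accepted / n_attempted else NA_real_,
                 seed_lineage = seed_lineage),
            class = "path_ensemble")
}

#' @export
print.path_ensemble <- function(x, ...) {
  cat("<path_ensemble> condition: ", x$condition$type,
      if (x$condition$type == "interface")
        paste0(" (lambda_i = ", x$condition$lambda_i, ")"),
      if (x$condition$type == "NR")
        paste0(" (threshold = ", x$condition$threshold, ")"),
      "\n  ", length(x$paths), " unique paths, total multiplicity ",
      total_multiplicity(x), ", acceptance ",
      round(100 * x$acceptance_rate, 1), "%\n", sep = "")
  invisible(x)
}

#' Total Monte-Carlo multiplicity of an ensemble
#' @param ensemble A `path_ensemble`.
#' @return Sum of path multiplicities.
#' @export
total_multiplicity <- function(ensemble) {
  sum(vapply(ensemble$paths, function(p) p$multiplicity, numeric(1)))
}

# shared Markov-chain driver for ensemble sampling
run_shooting_chain <- function(system, seed_path, condition, n_moves, n_equil,
                               params, sigma_p, store_frames, lambda_A,
                               lambda_B, max_steps, lineage) {
  if (n_equil >= n_moves) abort_param("`n_equil` must be < `n_moves`")
  if (!path_satisfies(seed_path, condition))
    abort_param("seed path does not satisfy the ensemble condition")
  cur <- seed_path
  cur$multiplicity <- 1L
  archive <- list()
  n_att <- 0L; n_acc <- 0L; uid_counter <- 0L
  archive_path <- function(p) {
    uid_counter <<- uid_counter + 1L
    p$uid <- paste0(lineage, "#", uid_counter)
    if (!store_frames) p <- strip_frames(p)
    archive[[length(archive) + 1L]] <<- p
  }
  for (m in seq_len(n_moves)) {
    if (m == n_equil + 1L) cur$multiplicity <- 0L
    mv <- shooting_move(cur, system, params, sigma_p, condition,
                        move_seed = seed_stream(params$seed, 61, m),
                        lambda_A = lambda_A, lambda_B = lambda_B,
                        max_steps = max_steps)
    if (m > n_equil) {
      n_att <- n_att + 1L
      if (mv$accepted) {
        n_acc <- n_acc + 1L
        if (cur$multiplicity > 0L) archive_path(cur)
        cur <- mv$path
      } else {
        cur <- mv$path
      }
    } else {
      cur <- mv$path
    }
  }
  if (cur$multiplicity > 0L) archive_path(cur)
  new_path_ensemble(condition, archive, n_att, n_acc, lineage)
}

#' Sample one interface ensemble
#'
#' Shooting-move Monte Carlo under the condition "starts in A and reaches at
#' least `lambda_i`". The full-scale protocol attempts 6000 moves per
#' ensemble with the first 3000 reserved for equilibration and not counted;
#' post-equilibration multiplicities sum to `n_moves - n_equil`.
#'
#' @param system A `model_system`.
#' @param seed_path A path satisfying the condition (e.g. a reactive seed).
#' @param lambda_i Interface position, Angstrom.
#' @param n_moves,n_equil Total and equilibration move counts.
#' @param params A `langevin_params` (its seed defines the move seeds).
#' @param sigma_p Momentum perturbation scale.
#' @param store_frames Keep full frames on archived paths (memory-heavy).
#' @param lambda_A,lambda_B Basin thresholds.
#' @param max_steps Per-side propagation budget.
#' @return A `path_ensemble`.
#' @export
sample_interface_ensemble <- function(system, seed_path, lambda_i,
                                      n_moves = 6000, n_equil = 3000,
                                      params = langevin_params(),
                                      sigma_p = 0.2, store_frames = FALSE,
                                      lambda_A = -0.8, lambda_B = 0.8,
                                      max_steps = 20000) {
  cond <- cond_interface(lambda_i)
  run_shooting_chain(system, seed_path, cond, n_moves, n_equil, params,
                     sigma_p, store_frames, lambda_A, lambda_B, max_steps,
                     lineage = paste0("iface", lambda_i, "_s", params$seed))
}

#' Sample pathway-type ensembles (R or NR)
#'
#' Constructs ensembles of reactive paths (endpoints A -> B) or nonreactive
#' paths that reach at least `nr_threshold` before returning to the reactant
#' well (endpoints A -> A). For NR ensembles started from a reactive seed,
#' an NR seed is first derived by unconstrained shooting until the condition
#' is met.
#'
#' @param system A `model_system`.
#' @param seed_paths List of seed `tis_path`s (cycled over ensembles).
#' @param type `"R"` or `"NR"`.
#' @param nr_threshold NR progress threshold, Angstrom (default -0.4).
#' @param n_moves,n_equil Move counts per ensemble.
#' @param n_ensembles Number of independent ensembles (full scale: 20).
#' @param params A `langevin_params`.
#' @param sigma_p Momentum perturbation scale.
#' @param store_frames Keep frames (needed for feature extraction).
#' @param lambda_A,lambda_B Basin thresholds.
#' @param max_steps Per-side propagation budget.
#' @return List of `path_ensemble`s.
#' @export
sample_pathway_ensembles <- function(system, seed_paths, type = c("R", "NR"),
                                     nr_threshold = -0.4, n_moves = 500,
                                     n_equil = 100, n_ensembles = 4,
                                     params = langevin_params(),
                                     sigma_p = 0.2, store_frames = TRUE,
                                     lambda_A = -0.8, lambda_B = 0.8,
                                     max_steps = 20000) {
  type <- match.arg(type)
  cond <- if (type == "R") cond_R() else cond_NR(nr_threshold)
  if (!is.list(seed_paths)) seed_paths <- list(seed_paths)
  lapply(seq_len(n_ensembles), function(e) {
    sp <- seed_paths[[((e - 1L) %% length(seed_paths)) + 1L]]
    p <- params
    p$seed <- seed_stream(params$seed, 71, e)
    if (!path_satisfies(sp, cond)) {
      if (type == "R")
        abort_param("seed path does not end in B; cannot seed an R ensemble")
      sp <- derive_seed_for_condition(system, sp, cond, p, sigma_p,
                                      lambda_A, lambda_B, max_steps)
    }
    run_shooting_chain(system, sp, cond, n_moves, n_equil, p, sigma_p,
                       store_frames, lambda_A, lambda_B, max_steps,
                       lineage = paste0(type, "_e", e, "_s", p$seed))
  })
}

derive_seed_for_condition <- function(system, start_path, condition, params,
                                      sigma_p, lambda_A, lambda_B, max_steps,
                                      max_attempts = 2000) {
  for (m in seq_len(max_attempts)) {
    mv <- shooting_move(start_path, system, params, sigma_p,
                        condition = structure(list(type = "any"),
                                              class = "path_condition"),
                        move_seed = seed_stream(params$seed, 81, m),
                        lambda_A = lambda_A, lambda_B = lambda_B,
                        max_steps = max_steps)
    cand <- mv$candidate
    if (!cand$non_committal && path_satisfies(cand, condition)) {
      cand$multiplicity <- 1L
      return(cand)
    }
    if (!cand$non_committal &&
        identical(sort(cand$endpoints), c("A", "B"))) {
      start_path <- if (identical(cand$endpoints, c("B", "A")))
        reverse_path(cand) else cand
      start_path$multiplicity <- 1L
    }
  }
  stop("could not derive a seed path for the requested condition",
       call. = FALSE)
}

#' Harvest excursion paths from direct well dynamics
#'
#' Runs unconstrained reactant-well dynamics and extracts every excursion
#' (segment from the last in-A frame through the next basin entry) that
#' satisfies the requested condition, as frame-complete paths. On surrogate
#' systems this provides unbiased, mutually independent seed paths for the
#' shooting-move chains -- valuable because path-space Monte Carlo mixes
#' slowly along environment coordinates that relax more slowly than a
#' path's duration.
#'
#' @param system A `model_system`.
#' @param condition A `path_condition` (`cond_R()`, `cond_NR()`, or
#'   `cond_interface()`).
#' @param n_paths Paths to collect.
#' @param params A `langevin_params`.
#' @param max_steps Total step budget across chunks.
#' @param chunk_steps Steps per chunk (memory control).
#' @param lambda_A,lambda_B Basin thresholds.
#' @return A list of `tis_path`s (may be shorter than `n_paths` if the
#'   budget runs out; errors if none found).
#' @export
harvest_excursion_paths <- function(system, condition, n_paths = 20,
                                    params = langevin_params(),
                                    max_steps = 2e7, chunk_steps = 5e5,
                                    lambda_A = -0.8, lambda_B = 0.8) {
  st <- well_state(system, "A", seed = seed_stream(params$seed, 901))
  out <- list()
  used <- 0
  ch <- 0L
  while (length(out) < n_paths && used < max_steps) {
    ch <- ch + 1L
    p <- params
    p$seed <- seed_stream(params$seed, 902, ch)
    seg <- integrate_system(system, st, as.integer(chunk_steps), p,
                            save_frames = TRUE)
    st <- seg$final_state
    used <- used + chunk_steps
    lam <- seg$lambda
    state <- ifelse(lam < lambda_A, 1L, ifelse(lam > lambda_B, 2L, 0L))
    nz <- which(state != 0L)
    if (length(nz) < 2) next
    starts <- nz[-length(nz)]
    ends <- nz[-1]
    keep <- (ends - starts) > 1L & state[starts] == 1L
    for (j in which(keep)) {
      rng <- starts[j]:ends[j]
      lab_end <- if (state[ends[j]] == 2L) "B" else "A"
      path <- tis_path(seg$frames_pos[rng, , drop = FALSE],
                       seg$frames_vel[rng, , drop = FALSE],
                       time = seg$time[rng] - seg$time[rng[1]],
                       lambda = lam[rng], endpoints = c("A", lab_end))
      if (path_satisfies(path, condition)) {
        out[[length(out) + 1L]] <- path
        if (length(out) >= n_paths) break
      }
    }
  }
  if (length(out) == 0)
    stop("no qualifying excursion found within the step budget",
         call. = FALSE)
  out
}

# ---- alignment and window sampling ------------------------------------------

#' Align a path's time axis at the last breaking-bond compression
#'
#' Sets t = 0 at the last local minimum of the breaking-bond distance
#' preceding the final rupture (for reactive paths, the terminal entry into
#' B) or preceding the frame of maximal lambda (for nonreactive paths). The
#' operation is idempotent.
#'
#' @param path A `tis_path` with frames.
#' @param breaking Pair of particle indices for the breaking bond (3D
#'   systems), or `NULL` for scalar-order-parameter systems, where the
#'   lambda series itself serves as the breaking-distance proxy.
#' @return The path with shifted times and an `aligned` flag.
#' @export
align_time_zero <- function(path, breaking = NULL) {
  d <- breaking_distance_series(path, breaking)
  anchor <- if (identical(path$endpoints, c("A", "B"))) length(d)
            else which.max(path$lambda)
  if (anchor < 3) stop("path too short to align", call. = FALSE)
  i <- 2:(anchor - 1L)
  is_min <- d[i] < d[i - 1L] & d[i] <= d[i + 1L]
  if (!any(is_min))
    stop("alignment error: no local minimum of the breaking distance ",
         "before the anchor", call. = FALSE)
  t0_idx <- max(i[is_min])
  path$time <- path$time - path$time[t0_idx]
  path$aligned <- TRUE
  path$t0_index <- t0_idx
  path
}

breaking_distance_series <- function(path, breaking) {
  if (is.null(breaking)) return(path$lambda)
  if (is.null(path$frames_pos))
    abort_param("path carries no frames; cannot compute bond distances")
  i <- 3L * (breaking[1] - 1L) + 1:3
  j <- 3L * (breaking[2] - 1L) + 1:3
  sqrt(rowSums((path$frames_pos[, i, drop = FALSE] -
                path$frames_pos[, j, drop = FALSE])^2))
}

#' Sample weighted frames from a time window
#'
#' For each unique path in the given (time-aligned) ensembles,
#' `frames_per_path` frames are drawn uniformly from the half-open window
#' `[t_lo, t_hi)` and carry the path's Monte-Carlo multiplicity as weight.
#' Paths with no frames in the window are skipped with a warning.
#'
#' @param ensembles A `path_ensemble` or list of them.
#' @param window `c(t_lo, t_hi)` in fs (default matches the -160 to -130 fs
#'   analysis window).
#' @param frames_per_path Frames drawn per unique path.
#' @param seed Integer seed for the draws.
#' @return A tibble with columns `ensemble`, `path_uid`, `label`,
#'   `frame_index`, `time`, `weight` and a `positions` list-column.
#' @export
sample_window_frames <- function(ensembles, window = c(-160, -130),
                                 frames_per_path = 1L, seed = 1L) {
  if (inherits(ensembles, "path_ensemble")) ensembles <- list(ensembles)
  rows <- list()
  skipped <- 0L
  k <- 0L
  for (e in seq_along(ensembles)) {
    ens <- ensembles[[e]]
    label <- switch(ens$condition$type, R = "R", NR = "NR",
                    ens$condition$type)
    for (p in ens$paths) {
      idx <- which(p$time >= window[1] & p$time < window[2])
      if (length(idx) == 0) { skipped <- skipped + 1L; next }
      set.seed(as.integer(seed_stream(seed, e, k) %% 2147483647))
      k <- k + 1L
      pick <- if (length(idx) <= frames_per_path) idx
              else idx[sample.int(length(idx), frames_per_path)]
      for (fi in pick) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          ensemble = ens$seed_lineage, path_uid = p$uid, label = label,
          frame_index = fi, time = p$time[fi],
          weight = as.double(p$multiplicity),
          positions = list(p$frames_pos[fi, ]))
      }
    }
  }
  if (skipped > 0)
    warning(sprintf("%d path(s) had no frames in the window and were skipped",
                    skipped), call. = FALSE)
  if (length(rows) == 0) return(tibble::tibble(
    ensemble = character(), path_uid = character(), label = character(),
    frame_index = integer(), time = double(), weight = double(),
    positions = list()))
  dplyr::bind_rows(rows)
}
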