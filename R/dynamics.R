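#' Langevin dynamics
#'
#' BAOAB Langevin propagation of model systems at a 1 fs default time step
#' with friction 1 ps^-1 near 300 K, including two-sided propagation for
#' shooting moves and long equilibrium runs for flux and population
#' measurements. At zero friction the scheme reduces to velocity Verlet, so
#' deterministic propagation is available for audit.
#'
#' @name dynamics
NULL

#' Langevin integration parameters
#'
#' @param dt Time step, fs (> 0).
#' @param friction Friction coefficient, 1/ps (>= 0; 0 = deterministic NVE).
#' @param temperature Bath temperature, K.
#' @param seed Integer master seed; every propagation derives sub-seeds from
#'   it, so identical inputs give bit-identical trajectories.
#' @return A `langevin_params` object.
#' @export
langevin_params <- function(dt = 1, friction = 1, temperature = 300,
                            seed = 1L) {
  if (dt <= 0) abort_param("`dt` must be > 0")
  if (friction < 0) abort_param("`friction` must be >= 0")
  structure(list(dt = dt, friction = friction, temperature = temperature,
                 seed = seed), class = "langevin_params")
}

#' Phase-space state of a system
#'
#' @param positions Coordinates, Angstrom.
#' @param velocities Velocities, Angstrom/fs.
#' @param time Time stamp, fs.
#' @return A `particle_state`.
#' @export
particle_state <- function(positions, velocities, time = 0) {
  if (length(positions) != length(velocities))
    abort_param("positions and velocities must have equal length")
  if (!is.finite(time)) abort_param("time must be finite")
  structure(list(positions = as.double(positions),
                 velocities = as.double(velocities), time = time),
            class = "particle_state")
}

#' Reverse the momenta of a state
#'
#' An involution: reversing twice restores the state exactly.
#' @param state A `particle_state`.
#' @return The state with negated velocities.
#' @export
momentum_reverse <- function(state) {
  state$velocities <- -state$velocities
  state
}

#' Propagate a system for a fixed number of steps
#'
#' @param system A `model_system`.
#' @param state Initial `particle_state`.
#' @param n_steps Number of steps (>= 1).
#' @param params A `langevin_params`.
#' @param save_frames Keep every frame's positions/velocities.
#' @param record_every Record lambda every this many steps.
#' @param bias Optional harmonic umbrella bias `list(k, center)` applied to
#'   lambda as `k * (lambda - center)^2`.
#' @return A `trajectory_segment`: lambda series at `dt * record_every`
#'   spacing (n_steps/record_every + 1 values including the initial state),
#'   times, the final state, the mean kinetic energy per degree of freedom
#'   (kcal/mol), and optionally all frames.
#' @export
integrate_system <- function(system, state, n_steps, params,
                             save_frames = FALSE, record_every = 1L,
                             bias = NULL) {
  if (n_steps < 1) abort_param("`n_steps` must be >= 1")
  bias_k <- if (is.null(bias)) -1 else bias$k
  bias_c <- if (is.null(bias)) 0 else bias$center
  res <- cpp_integrate(cpp_spec(system), state$positions, state$velocities,
                       as.integer(n_steps), params$dt, params$friction,
                       params$temperature, as.double(params$seed),
                       bias_k, bias_c, as.integer(record_every), save_frames)
  if (isTRUE(res$error))
    stop(sprintf("integration blow-up (non-finite energy) at step %d",
                 res$step), call. = FALSE)
  seg <- list(
    lambda = res$lambda,
    time = state$time + params$dt * record_every *
      (seq_along(res$lambda) - 1),
    dt = params$dt, record_every = record_every,
    final_state = particle_state(res$pos, res$vel,
                                 time = state$time + n_steps * params$dt),
    mean_ke_per_dof = res$mean_ke_per_dof,
    temperature_kinetic = 2 * res$mean_ke_per_dof / .kB
  )
  if (save_frames) {
    seg$frames_pos <- res$frames_pos
    seg$frames_vel <- res$frames_vel
  }
  class(seg) <- "trajectory_segment"
  seg
}

#' @export
print.trajectory_segment <- function(x, ...) {
  cat("<trajectory_segment> ", length(x$lambda), " recorded frames, dt = ",
      x$dt, " fs\n  lambda range [", round(min(x$lambda), 3), ", ",
      round(max(x$lambda), 3), "], kinetic T = ",
      round(x$temperature_kinetic, 1), " K\n", sep = "")
  invisible(x)
}

#' Export a lambda series as plain text
#'
#' Two columns: time (fs) and lambda (Angstrom), tab-separated with a header.
#' @param segment A `trajectory_segment` (or a path).
#' @param path Output file.
#' @export
write_lambda_series <- function(segment, path) {
  df <- data.frame(time_fs = segment$time, lambda_A = segment$lambda)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# propagate until entering basin A or B; internal building block
propagate_to_basin <- function(system, state, params, lambda_A, lambda_B,
                               max_steps, seed, save_frames = TRUE) {
  res <- cpp_propagate_to_basin(cpp_spec(system), state$positions,
                                state$velocities, lambda_A, lambda_B,
                                as.integer(max_steps), params$dt,
                                params$friction, params$temperature,
                                as.double(seed), save_frames)
  if (isTRUE(res$error))
    stop(sprintf("integration blow-up at step %d", res$step), call. = FALSE)
  res
}

#' Two-sided propagation from a phase-space point
#'
#' Generates a trial path for shooting moves: forward Langevin propagation
#' from `state` until entering basin A or B, plus a backward segment obtained
#' by forward propagation from the momentum-reversed state (with fresh noise)
#' which is then time-reversed and concatenated; the shared midpoint appears
#' once. If either side fails to reach a basin within `max_steps` the result
#' is flagged non-committal rather than raising an error.
#'
#' @param system A `model_system`.
#' @param state The shooting `particle_state`.
#' @param params A `langevin_params`; its seed (plus `seed_offset`) controls
#'   both noise streams.
#' @param lambda_A,lambda_B Basin thresholds (state A: lambda < lambda_A;
#'   state B: lambda > lambda_B; strict).
#' @param max_steps Per-side step budget.
#' @param seed_offset Offset mixed into the derived noise seeds.
#' @return A `tis_path`; see [tis_path()].
#' @export
propagate_two_sided <- function(system, state, params, lambda_A = -0.8,
                                lambda_B = 0.8, max_steps = 20000,
                                seed_offset = 0) {
  sf <- seed_stream(params$seed, 101, seed_offset)
  sb <- seed_stream(params$seed, 202, seed_offset)
  fwd <- propagate_to_basin(system, state, params, lambda_A, lambda_B,
                            max_steps, sf)
  bwd <- propagate_to_basin(system, momentum_reverse(state), params,
                            lambda_A, lambda_B, max_steps, sb)
  non_committal <- fwd$outcome == 0L || bwd$outcome == 0L
  nb <- length(bwd$lambda)
  # time-reverse the backward segment (reverse order, negate velocities),
  # drop its copy of the shared midpoint from the forward side
  pos <- rbind(bwd$frames_pos[nb:1, , drop = FALSE],
               fwd$frames_pos[-1, , drop = FALSE])
  vel <- rbind(-bwd$frames_vel[nb:1, , drop = FALSE],
               fwd$frames_vel[-1, , drop = FALSE])
  lambda <- c(bwd$lambda[nb:1], fwd$lambda[-1])
  time <- params$dt * (seq_along(lambda) - 1)
  lab <- function(outc) c("neither", "A", "B")[outc + 1L]
  tis_path(pos, vel, time, lambda,
           endpoints = c(lab(bwd$outcome), lab(fwd$outcome)),
           non_committal = non_committal,
           shoot_index = nb)
}

#' Equilibrium reactant-well trajectories
#'
#' Independent replicas of reactant-well dynamics used for the flux factor
#' and equilibrium population measurements. The default protocol is 30
#' replicas of 400 ps; surrogate-scale runs configure both down.
#'
#' @param system A `model_system`.
#' @param duration_ps Duration per replica, ps.
#' @param n_replicas Number of independent replicas (distinct noise
#'   sub-seeds).
#' @param params A `langevin_params`.
#' @param well Which well to start in.
#' @param initial_states Optional list of `particle_state`s (defaults to the
#'   well minimum with per-replica Maxwell velocities). States must start
#'   inside the well.
#' @param save_frames Keep frames (memory-heavy; off by default).
#' @param record_every Lambda recording stride.
#' @return A list of `trajectory_segment`s.
#' @export
run_equilibrium_well <- function(system, duration_ps = 400, n_replicas = 30,
                                 params = langevin_params(), well = "A",
                                 initial_states = NULL, save_frames = FALSE,
                                 record_every = 1L) {
  n_steps <- max(1L, as.integer(round(duration_ps * 1000 / params$dt)))
  lapply(seq_len(n_replicas), function(i) {
    st <- if (is.null(initial_states)) {
      well_state(system, well, seed = seed_stream(params$seed, 7, i))
    } else {
      initial_states[[((i - 1L) %% length(initial_states)) + 1L]]
    }
    lam0 <- system_lambda(system, st$positions)
    ok <- if (well == "A") lam0 < 0 else lam0 > 0
    if (!ok) abort_param("initial state is outside the requested well")
    p <- params
    p$seed <- seed_stream(params$seed, 11, i)
    integrate_system(system, st, n_steps, p, save_frames = save_frames,
                     record_every = record_every)
  })
}
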