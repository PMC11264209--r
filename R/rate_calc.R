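#' Rate-constant assembly and decomposition
#'
#' The TIS rate constant is assembled as
#' \deqn{k = \Phi_A \, P(\lambda_B|\lambda_A), \quad
#'       P(\lambda_B|\lambda_A) = P(\lambda_B|\lambda_n)
#'       \prod_{i=1}^{n-1} P(\lambda_{i+1}|\lambda_i)}
#' from the effective flux factor through the reactant-well boundary and the
#' product of conditional interface-crossing probabilities. This module also
#' produces cumulative-crossing and incremental-progress profiles (whose
#' minimum locates the kinetic bottleneck), the rate decomposition about the
#' bottleneck, replicate aggregation, and Eyring-equation conversions.
#'
#' @name rate_calc
NULL

#' Effective positive flux through the reactant-well boundary
#'
#' Counts effective positive crossings of `lambda_A` in reactant-well
#' trajectories: one count per excursion out of A (the trajectory must
#' return below `lambda_A` before the next crossing can count), divided by
#' the total time assigned to state A (assignment is history-based; time
#' after entering B is excluded until the next return to A).
#'
#' @param well_trajectories List of `trajectory_segment`s (or a single one).
#' @param lambda_A Reactant boundary, Angstrom.
#' @param lambda_B Product boundary, Angstrom.
#' @return A list with `flux` (1/s, pooled over trajectories), `sem` (1/s,
#'   over per-trajectory fluxes; `NA` for a single trajectory) and a
#'   `per_trajectory` tibble.
#' @export
compute_flux_factor <- function(well_trajectories, lambda_A = -0.8,
                                lambda_B = 0.8) {
  if (inherits(well_trajectories, "trajectory_segment"))
    well_trajectories <- list(well_trajectories)
  per <- purrr::map_dfr(seq_along(well_trajectories), function(i) {
    seg <- well_trajectories[[i]]
    res <- cpp_effective_crossings(seg$lambda, lambda_A, lambda_B)
    dt_fs <- seg$dt * seg$record_every
    t_A_fs <- res$steps_assigned_A * dt_fs
    tibble::tibble(trajectory = i, crossings = res$crossings,
                   time_in_A_fs = t_A_fs,
                   flux_per_s = ifelse(t_A_fs > 0,
                                       res$crossings / t_A_fs * 1e15, NA))
  })
  total_t <- sum(per$time_in_A_fs)
  if (total_t <= 0) abort_param("zero time assigned to state A")
  flux <- sum(per$crossings) / total_t * 1e15
  sem_v <- if (nrow(per) >= 2) sem(per$flux_per_s) else NA_real_
  list(flux = flux, sem = sem_v, per_trajectory = per)
}

#' Transition-counting rate from long unconstrained trajectories
#'
#' The direct (brute-force) estimate used to cross-check TIS: the number of
#' A -> B transitions divided by the total time assigned to state A
#' (history-based assignment: the system belongs to A from its last entry
#' into `lambda < lambda_A` until it first crosses `lambda > lambda_B`).
#'
#' @param trajectories List of `trajectory_segment`s (long free runs).
#' @param lambda_A,lambda_B Basin thresholds.
#' @return A list with `k` (1/s, pooled), `sem` (over per-trajectory rates),
#'   `events` (total A -> B transitions) and a `per_trajectory` tibble.
#' @export
transition_rate <- function(trajectories, lambda_A = -0.8, lambda_B = 0.8) {
  if (inherits(trajectories, "trajectory_segment"))
    trajectories <- list(trajectories)
  per <- purrr::map_dfr(seq_along(trajectories), function(i) {
    seg <- trajectories[[i]]
    res <- cpp_effective_crossings(seg$lambda, lambda_A, lambda_B)
    t_A <- res$steps_assigned_A * seg$dt * seg$record_every
    tibble::tibble(trajectory = i, events = res$ab_transitions,
                   time_in_A_fs = t_A,
                   k_per_s = ifelse(t_A > 0, res$ab_transitions / t_A * 1e15,
                                    NA))
  })
  total_t <- sum(per$time_in_A_fs)
  if (total_t <= 0) abort_param("zero time assigned to state A")
  list(k = sum(per$events) / total_t * 1e15,
       sem = if (nrow(per) >= 2) sem(per$k_per_s) else NA_real_,
       events = sum(per$events), per_trajectory = per)
}

#' Estimate interface conditional probabilities from ensembles
#'
#' For ensemble i (condition: reaches `grid[i]`), the conditional
#' `P(grid[i+1] | grid[i])` is the multiplicity-weighted fraction of its
#' paths with `lambda_max >= grid[i+1]`. The default full-scale grid has 29
#' interfaces from -0.8 to 0 Angstrom. The final leg `P(lambda_B |
#' grid[n])` is estimated from the last ensemble as the weighted fraction of
#' its paths that reach B.
#'
#' @param ensembles List of interface `path_ensemble`s, one per grid point.
#' @param grid Strictly increasing interface positions, Angstrom.
#' @param lambda_B Product boundary for the final leg.
#' @return A `crossing_probabilities` object: a tibble with columns
#'   `lambda_i`, `lambda_next`, `conditional`, plus attributes `grid` and
#'   `final_leg`.
#' @export
estimate_conditionals <- function(ensembles, grid, lambda_B = 0.8) {
  if (length(ensembles) != length(grid))
    abort_param("need one ensemble per grid point")
  if (any(diff(grid) <= 0)) abort_param("grid must be strictly increasing")
  weighted_frac <- function(ens, thr) {
    w <- vapply(ens$paths, function(p) p$multiplicity, numeric(1))
    if (sum(w) == 0)
      stop(sprintf("empty ensemble at interface %.4g", thr), call. = FALSE)
    hit <- vapply(ens$paths, function(p) p$lambda_max >= thr, logical(1))
    # half-count floor: a finite sample with zero crossings estimates the
    # conditional as at most 1/(2N), keeping the product defined
    max(sum(w[hit]) / sum(w), 0.5 / sum(w))
  }
  n <- length(grid)
  conds <- vapply(seq_len(n - 1L), function(i) {
    weighted_frac(ensembles[[i]], grid[i + 1L])
  }, numeric(1))
  final_leg <- weighted_frac_B(ensembles[[n]], lambda_B)
  out <- tibble::tibble(lambda_i = grid[-n], lambda_next = grid[-1],
                        conditional = conds)
  structure(out, grid = grid, final_leg = final_leg, lambda_B = lambda_B,
            class = c("crossing_probabilities", class(out)))
}

weighted_frac_B <- function(ens, lambda_B) {
  w <- vapply(ens$paths, function(p) p$multiplicity, numeric(1))
  if (sum(w) == 0) stop("empty final interface ensemble", call. = FALSE)
  hit <- vapply(ens$paths, function(p) {
    identical(p$endpoints[2], "B") || p$lambda_max >= lambda_B
  }, logical(1))
  max(sum(w[hit]) / sum(w), 0.5 / sum(w))
}

#' Build crossing probabilities directly from conditional values
#'
#' @param grid Strictly increasing interfaces, Angstrom.
#' @param conditionals Values of `P(grid[i+1] | grid[i])`, length
#'   `length(grid) - 1`, each in (0, 1].
#' @param final_leg `P(lambda_B | grid[n])`.
#' @param lambda_B Product boundary.
#' @return A `crossing_probabilities` object.
#' @export
crossing_probabilities <- function(grid, conditionals, final_leg = 1,
                                   lambda_B = 0.8) {
  if (any(diff(grid) <= 0)) abort_param("grid must be strictly increasing")
  if (length(conditionals) != length(grid) - 1L)
    abort_param("need length(grid) - 1 conditionals")
  if (any(conditionals <= 0 | conditionals > 1))
    abort_param("conditionals must lie in (0, 1]")
  out <- tibble::tibble(lambda_i = grid[-length(grid)],
                        lambda_next = grid[-1], conditional = conditionals)
  structure(out, grid = grid, final_leg = final_leg, lambda_B = lambda_B,
            class = c("crossing_probabilities", class(out)))
}

#' The default interface grid
#'
#' 29 interfaces spanning -0.8 to 0 Angstrom, mirroring the full-scale
#' protocol; both count and range are configurable.
#' @param n Number of interfaces.
#' @param from,to Range, Angstrom.
#' @return Numeric vector of interface positions.
#' @export
default_interface_grid <- function(n = 29, from = -0.8, to = 0) {
  seq(from, to, length.out = n)
}

#' Assemble a TIS rate constant
#'
#' `k = flux * final_leg * prod(conditionals)` exactly.
#'
#' @param flux Flux factor, 1/s (> 0), or the list returned by
#'   [compute_flux_factor()].
#' @param probs A `crossing_probabilities` object.
#' @param final_leg Optional override of `P(lambda_B | lambda_n)`.
#' @return A `rate_estimate`: flux, total probability, k (1/s).
#' @export
assemble_rate <- function(flux, probs, final_leg = NULL) {
  if (is.list(flux)) flux <- flux$flux
  fl <- final_leg %||% attr(probs, "final_leg")
  conds <- probs$conditional
  if (flux <= 0) abort_param("flux must be > 0")
  if (any(c(conds, fl) <= 0) || any(c(conds, fl) > 1))
    abort_param("all probability factors must lie in (0, 1]")
  total <- fl * prod(conds)
  structure(list(flux = flux, total_probability = total, k = flux * total,
                 final_leg = fl, conditionals = conds,
                 grid = attr(probs, "grid")),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat("<rate_estimate> k = ", format(x$k, digits = 4), " 1/s  (flux ",
      format(x$flux, digits = 4), " 1/s x P ",
      format(x$total_probability, digits = 4), ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.rate_estimate <- function(x, ...) {
  tibble::tibble(term = c("flux", "total_probability", "final_leg", "k"),
                 value = c(x$flux, x$total_probability, x$final_leg, x$k))
}

#' @export
glance.rate_estimate <- function(x, ...) {
  tibble::tibble(k = x$k, flux = x$flux,
                 total_probability = x$total_probability,
                 n_interfaces = length(x$grid))
}

#' Cumulative and incremental crossing profiles
#'
#' The cumulative curve is `P(lambda | lambda_A)`, nonincreasing in lambda;
#' the incremental curve is `P(lambda + delta | lambda)`, and the bottleneck
#' is its argmin (ties broken toward smaller lambda). If `delta` does not
#' match the grid spacing the cumulative curve is resampled by log-linear
#' interpolation onto a `delta`-spaced grid.
#'
#' @param probs A `crossing_probabilities` object.
#' @param delta Progress increment, Angstrom (default 0.05).
#' @return A tibble with columns `lambda`, `cumulative`, `incremental`
#'   (`NA` on the last point), with attribute `bottleneck`.
#' @export
crossing_profiles <- function(probs, delta = 0.05) {
  grid <- attr(probs, "grid")
  cum <- c(1, cumprod(probs$conditional))
  sp <- diff(grid)
  if (max(abs(sp - delta)) > 1e-9) {
    new_grid <- seq(grid[1], grid[length(grid)], by = delta)
    logc <- approx(grid, log(cum), xout = new_grid, rule = 2)$y
    grid <- new_grid
    cum <- exp(logc)
  }
  inc <- c(cum[-1] / cum[-length(cum)], NA_real_)
  out <- tibble::tibble(lambda = grid, cumulative = cum, incremental = inc)
  finite_inc <- inc[seq_len(length(inc) - 1L)]
  bn <- grid[which.min(finite_inc)]   # which.min takes the first = smaller lambda
  attr(out, "bottleneck") <- bn
  attr(out, "delta") <- delta
  class(out) <- c("crossing_profiles", class(out))
  out
}

#' Decompose the crossing probability about a bottleneck
#'
#' Splits `P(lambda_B | lambda_A)` into the probability of reaching the
#' bottleneck (default lambda = -0.4 Angstrom) and the probability of
#' proceeding from it to B. The product of the two legs reconstructs the
#' total probability to floating-point accuracy.
#'
#' @param probs A `crossing_probabilities` object.
#' @param split Bottleneck position; must be on the grid.
#' @param final_leg Optional override of the final leg.
#' @return A `rate_decomposition` list.
#' @export
decompose_rate <- function(probs, split = -0.4, final_leg = NULL) {
  grid <- attr(probs, "grid")
  fl <- final_leg %||% attr(probs, "final_leg")
  j <- which(abs(grid - split) < 1e-9)
  if (length(j) != 1)
    abort_param("`split` must coincide with one grid interface")
  below <- probs$lambda_next <= split + 1e-9
  p_to <- prod(probs$conditional[below])
  p_from <- prod(probs$conditional[!below]) * fl
  structure(list(split = split, p_to_bottleneck = p_to,
                 p_from_bottleneck = p_from,
                 total_probability = fl * prod(probs$conditional)),
            class = "rate_decomposition")
}

#' @export
print.rate_decomposition <- function(x, ...) {
  cat("<rate_decomposition> split at lambda = ", x$split, "\n  P(to) = ",
      format(x$p_to_bottleneck, digits = 4), "  P(from) = ",
      format(x$p_from_bottleneck, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Aggregate replicate rate estimates
#'
#' The full-scale design is 3 seed trajectories x 3 repeats = 9 independent
#' estimates, summarized as mean and flat SEM.
#'
#' @param ks Numeric vector of rate constants (>= 2 values).
#' @return A tibble with `mean`, `sem`, `n`.
#' @export
aggregate_replicates <- function(ks) {
  if (length(ks) < 2) abort_param("need >= 2 replicates for a SEM")
  tibble::tibble(mean = mean(ks), sem = sem(ks), n = length(ks))
}

#' Eyring rate and rate ratios from barrier heights
#'
#' `eyring_rate()` gives `k = (k_B T / h) exp(-dG / RT)` in 1/s;
#' `eyring_ratio()` the fold change `exp(-(dG_mut - dG_wt) / RT)`.
#'
#' @param delta_g,dg_mut,dg_wt Free energies of activation, kcal/mol.
#' @param temperature Temperature, K (> 0).
#' @return Rate in 1/s, or a dimensionless fold change.
#' @export
eyring_rate <- function(delta_g, temperature = 300) {
  if (temperature <= 0) abort_param("temperature must be > 0")
  (.kB_SI * temperature / .h_SI) * exp(-delta_g / (.kB * temperature))
}

#' @rdname eyring_rate
#' @export
eyring_ratio <- function(dg_mut, dg_wt, temperature = 300) {
  exp(-(dg_mut - dg_wt) / (.kB * temperature))
}

#' Write a rate report as delimited text
#'
#' One row per interface (lambda, conditional, cumulative) plus a summary
#' block (flux, total probability, k).
#' @param rate A `rate_estimate`.
#' @param path Output file.
#' @export
write_rate_report <- function(rate, path) {
  df <- data.frame(lambda = rate$grid,
                   conditional = c(NA, rate$conditionals),
                   cumulative = c(1, cumprod(rate$conditionals)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# flux_per_s\t%.8g", rate$flux), con)
  writeLines(sprintf("# final_leg\t%.8g", rate$final_leg), con)
  writeLines(sprintf("# k_per_s\t%.8g", rate$k), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
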