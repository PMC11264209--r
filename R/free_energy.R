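#' Umbrella sampling and WHAM
#'
#' Potential-of-mean-force (PMF) profiles along lambda from harmonically
#' biased windows unbiased with the weighted histogram analysis method
#' (WHAM), in a fast screening mode (5 ps per window, no equilibration) and
#' an accurate detailed mode (100 ps per window, first 50 ps discarded),
#' with barrier-height extraction. The restraint convention is
#' `V_bias = k_f (lambda - center)^2` with `k_f = 200 kcal/(mol A^2)` by
#' default (no 1/2 factor; a switch is provided since the convention is
#' implementation-specific).
#'
#' @name free_energy
NULL

#' Umbrella window centers along lambda
#'
#' Centers are symmetric about zero, spaced `inner_spacing` apart for
#' `|lambda| < inner_bound` and `outer_spacing` apart outside, covering
#' `range` (defaults: -1.2 to 1.2 Angstrom, 0.0325 / 0.0975 Angstrom
#' spacings, bound 0.5 Angstrom).
#'
#' @param range Two-element lambda range, Angstrom.
#' @param inner_spacing,outer_spacing Window spacings, Angstrom (> 0).
#' @param inner_bound Dense-region half-width, Angstrom.
#' @return Sorted numeric vector of centers.
#' @export
generate_window_centers <- function(range = c(-1.2, 1.2),
                                    inner_spacing = 0.0325,
                                    outer_spacing = 0.0975,
                                    inner_bound = 0.5) {
  if (inner_spacing <= 0 || outer_spacing <= 0)
    abort_param("spacings must be > 0")
  if (diff(range) < min(inner_spacing, outer_spacing))
    abort_param("range narrower than one window spacing")
  inner <- seq(0, inner_bound - 1e-12, by = inner_spacing)
  last_inner <- inner[length(inner)]
  outer <- seq(last_inner + outer_spacing, max(abs(range)) + 1e-12,
               by = outer_spacing)
  outer <- outer[outer <= max(abs(range)) + 1e-9]
  pos <- c(inner, outer)
  centers <- sort(unique(c(-pos, pos)))
  centers[centers >= range[1] - 1e-9 & centers <= range[2] + 1e-9]
}

#' Run one umbrella window
#'
#' Adds the harmonic lambda restraint to the system potential during
#' Langevin integration and records the biased lambda samples at every
#' step after the equilibration discard.
#'
#' @param system A `model_system`.
#' @param center Restraint center, Angstrom.
#' @param force_constant Restraint force constant, kcal/(mol A^2) (>= 0;
#'   0 gives an unbiased window).
#' @param mode `"screening"` (5 ps, no discard) or `"detailed"` (100 ps,
#'   first 50 ps discarded); durations configurable via `duration_ps` and
#'   `discard_ps`.
#' @param params A `langevin_params`.
#' @param duration_ps,discard_ps Overrides of the mode's duration/discard.
#' @param initial_state Starting `particle_state`; defaults to the reactant
#'   well state.
#' @param half_factor If `TRUE` the restraint is `0.5 k (lambda - c)^2`.
#' @return An `umbrella_window` with the retained samples and final state.
#' @export
run_umbrella_window <- function(system, center, force_constant = 200,
                                mode = c("screening", "detailed"),
                                params = langevin_params(),
                                duration_ps = NULL, discard_ps = NULL,
                                initial_state = NULL, half_factor = FALSE) {
  mode <- match.arg(mode)
  if (force_constant < 0) abort_param("force_constant must be >= 0")
  dur <- duration_ps %||% if (mode == "screening") 5 else 100
  dis <- discard_ps %||% if (mode == "screening") 0 else 50
  if (dis >= dur) abort_param("discard must be shorter than the duration")
  st <- initial_state %||% well_state(system, "A",
                                      seed = seed_stream(params$seed, 3))
  n_steps <- as.integer(round(dur * 1000 / params$dt))
  k_eff <- if (half_factor) force_constant / 2 else force_constant
  seg <- integrate_system(system, st, n_steps, params,
                          bias = if (force_constant > 0)
                            list(k = k_eff, center = center) else NULL)
  keep <- seg$time - st$time > dis * 1000
  structure(list(center = center, force_constant = force_constant,
                 half_factor = half_factor, samples = seg$lambda[keep],
                 mode = mode, dt = params$dt,
                 equilibration_discard_ps = dis,
                 final_state = seg$final_state),
            class = "umbrella_window")
}

#' Run a series of umbrella windows with sequential initialization
#'
#' Windows are visited outward from the center nearest the initial state's
#' lambda; each window starts from its neighbour's final state (a steered
#' walk-out), which keeps every window near its restraint center even in
#' screening mode.
#'
#' @inheritParams run_umbrella_window
#' @param centers Restraint centers (see [generate_window_centers()]).
#' @return List of `umbrella_window`s in `centers` order.
#' @export
run_umbrella_series <- function(system, centers, force_constant = 200,
                                mode = c("screening", "detailed"),
                                params = langevin_params(),
                                duration_ps = NULL, discard_ps = NULL,
                                initial_state = NULL, half_factor = FALSE) {
  mode <- match.arg(mode)
  centers <- sort(centers)
  st0 <- initial_state %||% well_state(system, "A",
                                       seed = seed_stream(params$seed, 3))
  lam0 <- system_lambda(system, st0$positions)
  start <- which.min(abs(centers - lam0))
  out <- vector("list", length(centers))
  run_one <- function(i, st) {
    p <- params
    p$seed <- seed_stream(params$seed, 91, i)
    run_umbrella_window(system, centers[i], force_constant, mode, p,
                        duration_ps, discard_ps, initial_state = st,
                        half_factor = half_factor)
  }
  out[[start]] <- run_one(start, st0)
  if (start < length(centers)) for (i in (start + 1):length(centers))
    out[[i]] <- run_one(i, out[[i - 1]]$final_state)
  if (start > 1) for (i in (start - 1):1)
    out[[i]] <- run_one(i, out[[i + 1]]$final_state)
  out
}

#' Solve the WHAM equations
#'
#' Self-consistent iteration of the window free energies and unbiased bin
#' probabilities until the maximum change in window free energies falls
#' below `tol` (kcal/mol); the profile is anchored so its minimum is zero.
#' Non-overlapping window histograms raise a disconnected-histogram error
#' naming the gap.
#'
#' @param windows List of `umbrella_window`s.
#' @param n_bins Number of bins (default from `bin_width`).
#' @param temperature Temperature, K.
#' @param tol Convergence tolerance on window free energies, kcal/mol.
#' @param max_iter Iteration budget.
#' @param bin_width Bin width, Angstrom (default half the smallest window
#'   spacing, or a 200-bin grid for a single window).
#' @return A `pmf_profile`: tibble with `lambda` and `free_energy`
#'   (kcal/mol), with attributes `mode`, `converged`, `n_iter`.
#' @export
solve_wham <- function(windows, n_bins = NULL, temperature = 300,
                       tol = 1e-7, max_iter = 1e5, bin_width = NULL) {
  kT <- kT_kcal(temperature)
  all_s <- unlist(lapply(windows, `[[`, "samples"))
  rng <- range(all_s)
  if (is.null(bin_width) && is.null(n_bins)) {
    cs <- sort(unique(vapply(windows, `[[`, numeric(1), "center")))
    bin_width <- if (length(cs) > 1) min(diff(cs)) / 2 else diff(rng) / 200
  }
  if (is.null(n_bins)) n_bins <- max(10L, ceiling(diff(rng) / bin_width))
  edges <- seq(rng[1] - 1e-9, rng[2] + 1e-9, length.out = n_bins + 1L)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  W <- length(windows)
  H <- matrix(0, nrow = W, ncol = n_bins)   # counts per window x bin
  N <- numeric(W)
  for (i in seq_len(W)) {
    idx <- findInterval(windows[[i]]$samples, edges,
                        rightmost.closed = TRUE)
    idx <- idx[idx >= 1L & idx <= n_bins]
    H[i, ] <- tabulate(idx, nbins = n_bins)
    N[i] <- length(windows[[i]]$samples)
  }
  check_window_overlap(H, windows, mids)
  # bias energies at bin centers
  U <- matrix(0, nrow = W, ncol = n_bins)
  for (i in seq_len(W)) {
    wi <- windows[[i]]
    if (wi$force_constant > 0) {
      pref <- if (isTRUE(wi$half_factor)) 0.5 else 1
      U[i, ] <- pref * wi$force_constant * (mids - wi$center)^2
    }
  }
  B <- exp(-U / kT)                         # Boltzmann factors
  Htot <- colSums(H)
  f <- numeric(W)                            # window free energies, kcal/mol
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    denom <- colSums(N * exp(f / kT) * B)    # recycles N, f over rows
    p <- ifelse(denom > 0, Htot / denom, 0)
    f_new <- -kT * log(pmax(B %*% p, 1e-300))
    f_new <- f_new - f_new[1]
    d <- max(abs(f_new - f))
    f <- as.numeric(f_new)
    if (d < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop(sprintf("WHAM did not converge in %d iterations (residual %.3g)",
                 as.integer(max_iter), d), call. = FALSE)
  keep <- p > 0
  fe <- -kT * log(p[keep])
  fe <- fe - min(fe)
  out <- tibble::tibble(lambda = mids[keep], free_energy = fe)
  structure(out, mode = windows[[1]]$mode, converged = converged,
            n_iter = iter, temperature = temperature,
            class = c("pmf_profile", class(out)))
}

check_window_overlap <- function(H, windows, mids) {
  occupied <- H > 0
  # windows sorted by center; each consecutive pair must share a bin
  ord <- order(vapply(windows, `[[`, numeric(1), "center"))
  if (length(ord) < 2) return(invisible(TRUE))
  for (k in seq_len(length(ord) - 1L)) {
    a <- ord[k]; b <- ord[k + 1L]
    if (!any(occupied[a, ] & occupied[b, ]))
      stop(sprintf(paste0("disconnected histograms: windows centered at ",
                          "%.4g and %.4g share no bins"),
                   windows[[a]]$center, windows[[b]]$center), call. = FALSE)
  }
  invisible(TRUE)
}

#' Barrier height from a PMF profile
#'
#' `dG = max(F over barrier_region) - min(F over reactant_region)`; with a
#' list of replicate profiles the mean and SEM are reported (the full-scale
#' convention uses n = 3 replicates).
#'
#' @param profile A `pmf_profile` or list of replicate profiles.
#' @param reactant_region,barrier_region Lambda intervals `c(lo, hi)`.
#' @return A tibble with `barrier`, `sem`, `n`.
#' @export
estimate_barrier <- function(profile, reactant_region = c(-1.2, -0.6),
                             barrier_region = c(-0.3, 0.3)) {
  profiles <- if (inherits(profile, "pmf_profile")) list(profile) else profile
  one <- function(pr) {
    rr <- pr$free_energy[pr$lambda >= reactant_region[1] &
                           pr$lambda <= reactant_region[2]]
    br <- pr$free_energy[pr$lambda >= barrier_region[1] &
                           pr$lambda <= barrier_region[2]]
    if (length(rr) == 0 || length(br) == 0)
      abort_param("empty reactant or barrier region on the PMF grid")
    max(br) - min(rr)
  }
  vals <- vapply(profiles, one, numeric(1))
  tibble::tibble(barrier = mean(vals),
                 sem = if (length(vals) >= 2) sem(vals) else NA_real_,
                 n = length(vals))
}

#' @export
tidy.pmf_profile <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.pmf_profile <- function(x, ...) {
  tibble::tibble(mode = attr(x, "mode"), n_bins = nrow(x),
                 converged = attr(x, "converged"),
                 n_iter = attr(x, "n_iter"))
}

#' Plot a PMF profile
#' @param object A `pmf_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pmf_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lambda,
                                       y = .data$free_energy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(lambda ~ ("Å")),
                  y = "free energy (kcal/mol)",
                  title = paste0("PMF (", attr(object, "mode"), " mode)")) +
    ggplot2::theme_minimal()
}

#' Plot crossing profiles
#' @param object The tibble returned by [crossing_profiles()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.crossing_profiles <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            c("cumulative", "incremental"),
                            names_to = "curve", values_to = "p")
  ggplot2::ggplot(df[is.finite(df$p), ],
                  ggplot2::aes(x = .data$lambda, y = .data$p)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~curve, scales = "free_y") +
    ggplot2::geom_vline(xintercept = attr(object, "bottleneck"),
                        linetype = "dashed") +
    ggplot2::labs(x = expression(lambda ~ ("Å")), y = "probability") +
    ggplot2::theme_minimal()
}

#' Write a PMF as two-column delimited text
#' @param profile A `pmf_profile`.
#' @param path Output file.
#' @export
write_pmf <- function(profile, path) {
  utils::write.table(data.frame(lambda = profile$lambda,
                                free_energy_kcal_mol = profile$free_energy),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
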