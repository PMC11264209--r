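#' Surrogate model systems
#'
#' Desk-scale dynamical systems with the statistical structure the rare-event
#' pipeline assumes: a scalar order parameter \eqn{\lambda} separating a
#' reactant well (state A) from a product well (state B) over a barrier,
#' environment degrees of freedom, and -- for the migration mimic -- a planted
#' "gate" coordinate that modulates the instantaneous barrier so that reactive
#' and nonreactive barrier approaches are statistically distinguishable.
#'
#' A `model_system` carries a compiled potential-energy kind plus parameters,
#' per-coordinate masses (amu), an order-parameter definition, a temperature
#' (K), and free-text particle metadata. Energies are kcal/mol, lengths
#' Angstrom, times fs.
#'
#' @name model_systems
NULL

new_model_system <- function(kind, kind_name, n_coord, masses_coord, params,
                             tethers = numeric(0), lambda_spec, temperature,
                             metadata = list(), seed = 1L) {
  stopifnot(length(masses_coord) == n_coord, all(masses_coord > 0))
  sys <- list(
    kind = as.integer(kind), kind_name = kind_name,
    n_coord = as.integer(n_coord),
    masses_coord = as.double(masses_coord),
    params = setNames(as.double(params), names(params)),
    tethers = as.double(tethers),
    lambda_spec = lambda_spec, temperature = temperature,
    metadata = metadata, seed = seed
  )
  class(sys) <- "model_system"
  sys
}

#' @export
print.model_system <- function(x, ...) {
  cat("<model_system> ", x$kind_name, "\n", sep = "")
  cat("  coordinates: ", x$n_coord, "  temperature: ", x$temperature, " K\n",
      sep = "")
  lam <- x$lambda_spec
  if (identical(lam$type, "scalar")) {
    cat("  lambda: scalar coordinate", lam$coord, "\n")
  } else {
    cat("  lambda: d(", paste(lam$breaking, collapse = ","), ") - d(",
        paste(lam$forming, collapse = ","), ") [particle pairs]\n", sep = "")
  }
  invisible(x)
}

# internal: list passed to the C++ routines
cpp_spec <- function(system) {
  list(kind = system$kind, n_coord = system$n_coord,
       masses_coord = system$masses_coord, params = system$params,
       tethers = system$tethers)
}

#' Potential energy, gradient and order parameter of a system state
#'
#' @param system A `model_system`.
#' @param positions Numeric vector of coordinates (Angstrom).
#' @return `system_potential()` the energy in kcal/mol; `system_gradient()`
#'   the per-coordinate gradient dV/dx (kcal/mol/Angstrom); `system_lambda()`
#'   the order parameter in Angstrom.
#' @export
system_potential <- function(system, positions) {
  stopifnot(length(positions) == system$n_coord)
  cpp_potential(cpp_spec(system), as.double(positions))
}

#' @rdname system_potential
#' @export
system_gradient <- function(system, positions) {
  stopifnot(length(positions) == system$n_coord)
  cpp_gradient(cpp_spec(system), as.double(positions))
}

#' @rdname system_potential
#' @export
system_lambda <- function(system, positions) {
  stopifnot(length(positions) == system$n_coord)
  cpp_lambda(cpp_spec(system), as.double(positions))
}

#' Double-well surrogate with harmonically coupled environment
#'
#' The order parameter is the first coordinate; its potential is a quartic
#' double well with minima at `well_centers` and a barrier of `barrier_height`
#' at the midpoint. `n_env` environment coordinates are harmonic
#' (`k_env`, kcal/mol/A^2) with an optional bilinear coupling to the order
#' parameter (`coupling`, dimensionless; the coupling term is
#' `coupling * k_env * (x - midpoint) * y_j`).
#'
#' @param barrier_height Barrier height, kcal/mol (> 0).
#' @param well_centers Two distinct lambda values for the minima (Angstrom).
#' @param n_env Number of environment coordinates (>= 0).
#' @param coupling Dimensionless environment coupling.
#' @param seed Integer seed recorded on the system (system itself is
#'   deterministic).
#' @param k_env Environment spring constant, kcal/mol/A^2.
#' @param mass Per-coordinate mass, amu.
#' @param temperature Temperature in K.
#' @return A `model_system`.
#' @export
make_double_well <- function(barrier_height = 4, well_centers = c(-1, 1),
                             n_env = 1, coupling = 0, seed = 1L,
                             k_env = 1.5, mass = 12, temperature = 300) {
  if (barrier_height <= 0) abort_param("`barrier_height` must be positive")
  if (length(well_centers) != 2 || well_centers[1] == well_centers[2])
    abort_param("`well_centers` must be two distinct values")
  if (n_env < 0) abort_param("`n_env` must be >= 0")
  well_centers <- sort(well_centers)
  n_coord <- 1L + as.integer(n_env)
  new_model_system(
    kind = 1L, kind_name = "double_well",
    n_coord = n_coord, masses_coord = rep(mass, n_coord),
    params = c(barrier_height, well_centers[1], well_centers[2],
               coupling, k_env),
    lambda_spec = list(type = "scalar", coord = 1L),
    temperature = temperature,
    metadata = list(coords = c("lambda", if (n_env > 0)
      paste0("env", seq_len(n_env))),
      barrier_height = barrier_height, well_centers = well_centers,
      k_env = k_env, coupling = coupling),
    seed = seed
  )
}

#' One-dimensional harmonic reference system
#'
#' Used as an analytic oracle for umbrella sampling / WHAM: the potential of
#' mean force along lambda is exactly `0.5 * k * (lambda - x0)^2`.
#'
#' @param k Spring constant, kcal/mol/A^2.
#' @param x0 Minimum position, Angstrom.
#' @param mass Mass, amu.
#' @param temperature Temperature in K.
#' @return A `model_system`.
#' @export
make_harmonic <- function(k = 5, x0 = 0, mass = 12, temperature = 300) {
  if (k <= 0) abort_param("`k` must be positive")
  new_model_system(
    kind = 2L, kind_name = "harmonic_1d", n_coord = 1L,
    masses_coord = mass, params = c(k, x0),
    lambda_spec = list(type = "scalar", coord = 1L),
    temperature = temperature,
    metadata = list(coords = "lambda", k = k, x0 = x0), seed = 1L
  )
}

#' Bond-migration mimic with a planted gate coordinate
#'
#' Three particles D (donor), M (migrating, light / hydride-like), A
#' (acceptor) in 3D with \eqn{\lambda = d(D,M) - d(M,A)}: the D--M bond
#' breaks as the M--A bond forms. The potential is a two-state bond-exchange
#' (adiabatic ground state of two diabatic surfaces, each a Morse bond plus
#' an exponential repulsion from the other partner), so the bonds vibrate
#' realistically and exchange over a barrier whose height is calibrated to
#' `barrier_height` (the intrinsic value with the gate fully unfavourable).
#' D and A are tethered at (-d0, 0, 0) and (d0, 0, 0). `n_env` environment
#' particles are tethered at reproducibly random points; the first is the
#' *gate*: a product-side wall of height up to `gate_strength` (kcal/mol),
#' modulated by a bounded switch on the gate--D distance, blocks the exit
#' channel when the gate is closed (small gate--D distance) and vanishes
#' when it is open. Crossing attempts with a closed gate bounce back into
#' the reactant well, so reactive approaches are statistically
#' distinguishable from nonreactive ones in prereaction windows while the
#' probability of merely reaching the bottleneck stays gate-neutral. The
#' ground truth (gate particle index and the informative distance feature)
#' is recorded in the metadata.
#'
#' @param n_env Number of environment particles (>= 1; the first is the gate).
#' @param gate_strength Maximum barrier reduction from the gate, kcal/mol.
#' @param seed Integer seed for the reproducible tether placement.
#' @param barrier_height Intrinsic barrier (gate unfavourable), kcal/mol.
#' @param d0 Half distance between the D and A tether points, Angstrom;
#'   with the default bond length 1.2 Angstrom the wells sit near
#'   `lambda = +/- 2 (d0 - 1.2)`.
#' @param k_env Environment tether spring constant, kcal/mol/A^2.
#' @param gate_mass Gate particle mass, amu. Together with `gate_k` this
#'   sets the gate relaxation time (a few hundred fs): slow enough to stay
#'   correlated over a prereaction window, fast enough to decorrelate along
#'   a shooting-move chain.
#' @param gate_k Gate tether spring constant, kcal/mol/A^2. Soft by default
#'   so the gate's thermal spread straddles the barrier switch and the
#'   crossing outcome is close to gate-determined.
#' @param exothermicity Product-state stabilization, kcal/mol. Shifts the
#'   intrinsic barrier top toward the reactant side (Hammond-like), so the
#'   gate wall just past the top decides success or failure.
#' @param temperature Temperature in K.
#' @return A `model_system` with particle metadata.
#' @export
make_migration_mimic <- function(n_env = 4, gate_strength = 4, seed = 1L,
                                 barrier_height = 5, d0 = 1.8, k_env = 1.5,
                                 gate_mass = 1, gate_k = 0.4,
                                 exothermicity = 4, temperature = 300) {
  if (n_env < 1) abort_param("`n_env` must be >= 1")
  if (barrier_height <= 0) abort_param("`barrier_height` must be positive")
  n_particles <- 3L + as.integer(n_env)
  n_coord <- 3L * n_particles
  # the migrating particle is light (hydride-like): the breaking bond shows
  # fast compression troughs that anchor the time alignment
  masses_p <- c(12, 2, 12, gate_mass, rep(20, n_env - 1))
  # reproducible tether points: gate fixed near D's side, others spread out
  rng <- local({ set.seed(seed); list(th = runif(n_env - 1, 0, 2 * pi),
                                      ph = runif(n_env - 1, -0.5, 0.5)) })
  tethers <- matrix(0, nrow = n_env, ncol = 3)
  tethers[1, ] <- c(0, 2.5, 0)
  if (n_env > 1) {
    rt <- 3.5
    tethers[-1, ] <- cbind(rt * cos(rng$th), rt * sin(rng$th), 2 * rng$ph)
  }
  # switch midpoint just over one thermal standard deviation above the
  # median equilibrium gate-donor distance: the wall is down only for
  # favourable-tail gate configurations, so reactive events are strongly
  # gate-selected and tether mutations have kinetic leverage
  sd_g <- sqrt(.kB * temperature / gate_k)
  d_ref <- sqrt(sum((tethers[1, ] - c(-d0, 0, 0))^2) + 3 * sd_g^2) +
    1.2 * sd_g
  bond <- list(De = 80, a_morse = 1.4, r0 = 1.2, eps_rep = 30,
               rho_rep = 0.5)
  C <- calibrate_exchange_coupling(barrier_height, d0, bond, exothermicity)
  params <- c(d0 = d0, k_tether = 100, k_perp = 20,
              De = bond$De, a_morse = bond$a_morse, r0 = bond$r0,
              eps_rep = bond$eps_rep, rho_rep = bond$rho_rep, C = C,
              gate_strength = gate_strength, d_ref = d_ref,
              sigma_g = 0.5, w_bump = 0.1, bump_center = 0.2,
              k_env = k_env, n_env = n_env, gate_k = gate_k,
              exothermicity = exothermicity)
  names_p <- c("D", "M", "A", paste0("env", seq_len(n_env)))
  new_model_system(
    kind = 3L, kind_name = "migration_mimic",
    n_coord = n_coord, masses_coord = rep(masses_p, each = 3L),
    params = params, tethers = as.double(t(tethers)),
    lambda_spec = list(type = "pairs", breaking = c(1L, 2L),
                       forming = c(2L, 3L)),
    temperature = temperature,
    metadata = list(
      particles = names_p, masses = masses_p,
      tethers = tethers, d_ref = d_ref,
      gate_particle = 4L, gate_strength = gate_strength,
      informative_feature = "d_gate_D",
      gate_truth = paste0("barrier lowered by up to ", gate_strength,
                          " kcal/mol when d(env1, D) exceeds ", round(d_ref, 3),
                          " A")
    ),
    seed = seed
  )
}

# solve for the two-state coupling C that gives the requested intrinsic
# collinear barrier (gate term off, tethers at rest)
calibrate_exchange_coupling <- function(barrier_height, d0, bond,
                                        exothermicity = 0) {
  collinear_barrier <- function(C) {
    spec <- list(kind = 3L, n_coord = 12L, masses_coord = rep(1, 12),
                 params = c(d0, 100, 20, bond$De, bond$a_morse, bond$r0,
                            bond$eps_rep, bond$rho_rep, C, 0, 1, 0.5,
                            0.1, 0.2, 1.5, 1, 0.4, exothermicity),
                 tethers = c(0, 2.5, 0))
    xs <- seq(-d0 + 0.3, d0 - 0.3, length.out = 201)
    v <- vapply(xs, function(x)
      cpp_potential(spec, c(-d0, 0, 0, x, 0, 0, d0, 0, 0, 0, 2.5, 0)),
      numeric(1))
    max(v[abs(xs) < 0.5]) - min(v[xs < -0.3])   # from the reactant well
  }
  f <- function(C) collinear_barrier(C) - barrier_height
  lo <- 0.5; hi <- bond$De
  if (f(lo) < 0)
    abort_param("requested barrier too high for the bond model")
  stats::uniroot(f, c(lo, hi), tol = 1e-6)$root
}

#' Equilibrium-well starting state for a system
#'
#' Positions at the requested well's minimum-energy configuration plus
#' Maxwell-Boltzmann velocities at the system temperature.
#'
#' @param system A `model_system`.
#' @param well `"A"` (reactant, lambda < 0) or `"B"` (product).
#' @param seed Integer seed for the velocity draw.
#' @return A `particle_state`.
#' @export
well_state <- function(system, well = c("A", "B"), seed = 1L) {
  well <- match.arg(well)
  pos <- minimum_positions(system, well)
  vel <- maxwell_velocities(system, seed)
  particle_state(pos, vel)
}

minimum_positions <- function(system, well = "A") {
  if (system$kind == 1L) {
    c(if (well == "A") system$params[2] else system$params[3],
      rep(0, system$n_coord - 1L))
  } else if (system$kind == 2L) {
    system$params[2]
  } else {
    p <- system$params
    d0 <- p[1]; r0 <- p[6]
    xM <- if (well == "A") -(d0 - r0) else (d0 - r0)
    pos <- c(-d0, 0, 0, xM, 0, 0, d0, 0, 0, system$tethers)
    # refine with a few relaxation steps on M's x coordinate
    f <- function(x) {
      pos[4] <- x
      cpp_potential(cpp_spec(system), pos)
    }
    opt <- optim(xM, f, method = "Brent",
                 lower = if (well == "A") -d0 else 0,
                 upper = if (well == "A") 0 else d0)
    pos[4] <- opt$par
    pos
  }
}

#' Maxwell-Boltzmann velocity draw for a system
#' @param system A `model_system`.
#' @param seed Integer seed.
#' @return Velocity vector, Angstrom/fs.
#' @export
maxwell_velocities <- function(system, seed = 1L) {
  kT <- kT_kcal(system$temperature)
  set.seed(as.integer(seed %% 2147483647))
  rnorm(system$n_coord) * sqrt(.acc_unit * kT / system$masses_coord)
}

#' Finite-difference gradient check
#'
#' Verifies that the analytic gradient matches central finite differences of
#' the potential on random configurations.
#'
#' @param system A `model_system`.
#' @param n_states Number of random configurations.
#' @param rel_tol Relative tolerance.
#' @param h Finite-difference step, Angstrom.
#' @param seed Seed for the random configurations.
#' @return Invisibly, the maximum relative deviation; errors if above
#'   `rel_tol`.
#' @export
check_gradient <- function(system, n_states = 100, rel_tol = 1e-5,
                           h = 1e-5, seed = 1L) {
  set.seed(seed)
  base <- minimum_positions(system, "A")
  worst <- 0
  for (s in seq_len(n_states)) {
    x <- base + rnorm(system$n_coord, sd = 0.3)
    g <- system_gradient(system, x)
    gfd <- vapply(seq_len(system$n_coord), function(i) {
      xp <- x; xm <- x
      xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
      (system_potential(system, xp) - system_potential(system, xm)) / (2 * h)
    }, numeric(1))
    scale <- max(abs(g), abs(gfd), 1)
    worst <- max(worst, max(abs(g - gfd)) / scale)
  }
  if (worst > rel_tol)
    stop(sprintf("gradient check failed: max relative deviation %.3g", worst),
         call. = FALSE)
  invisible(worst)
}

# ---- toy design space -------------------------------------------------------

#' Toy sequence-design space with planted mutational effects
#'
#' A finite sequence space over `n_sites` positions and `alphabet_size`
#' tokens per site, with a reproducible random additive + pairwise effect
#' table over `n_conformations` conformation classes. The deterministic
#' energy model is
#' `E(s, c) = base[c] + sum_i add[i, s_i, c] + pscale[c] * sum_{i<j}
#' pair[i, j, s_i, s_j]` (kcal/mol). The wild type is token 1 at every site.
#'
#' @param n_sites Number of mutable sites (>= 1).
#' @param alphabet_size Tokens per site (>= 2).
#' @param effect_table_seed Seed for the planted effect tables.
#' @param n_conformations Number of conformation classes carrying energies.
#' @param additive_sd,pairwise_sd Effect-size scales, kcal/mol.
#' @return A `toy_design_space` with elements `sites`, `alphabet`,
#'   `wt_sequence`, `energy_model(sequence, conformation)` and the raw tables.
#' @export
make_toy_design_space <- function(n_sites, alphabet_size, effect_table_seed = 1L,
                                  n_conformations = 6, additive_sd = 2,
                                  pairwise_sd = 0.5) {
  if (n_sites < 1) abort_param("`n_sites` must be >= 1")
  if (alphabet_size < 2) abort_param("`alphabet_size` must be >= 2")
  set.seed(effect_table_seed)
  alphabet <- LETTERS[seq_len(alphabet_size)]
  base <- rnorm(n_conformations, sd = 1)
  add <- array(rnorm(n_sites * alphabet_size * n_conformations,
                     sd = additive_sd),
               dim = c(n_sites, alphabet_size, n_conformations))
  add[, 1, ] <- 0  # wild-type token is the reference at every site
  pair <- array(0, dim = c(n_sites, n_sites, alphabet_size, alphabet_size))
  if (n_sites > 1) {
    for (i in seq_len(n_sites - 1)) for (j in seq((i + 1), n_sites)) {
      m <- matrix(rnorm(alphabet_size^2, sd = pairwise_sd),
                  alphabet_size, alphabet_size)
      m[1, ] <- 0; m[, 1] <- 0
      pair[i, j, , ] <- m
    }
  }
  pscale <- runif(n_conformations, 0.5, 1.5)
  wt <- rep(alphabet[1], n_sites)
  tok_idx <- function(sequence) match(sequence, alphabet)
  energy_model <- function(sequence, conformation) {
    ti <- tok_idx(sequence)
    if (anyNA(ti) || length(ti) != n_sites)
      abort_param("sequence has tokens outside the space")
    c_id <- as.integer(conformation)
    if (c_id < 1 || c_id > n_conformations)
      abort_param("conformation id outside the space")
    e <- base[c_id] + sum(add[cbind(seq_len(n_sites), ti, c_id)])
    if (n_sites > 1) {
      for (i in seq_len(n_sites - 1)) for (j in seq((i + 1), n_sites))
        e <- e + pscale[c_id] * pair[i, j, ti[i], ti[j]]
    }
    e
  }
  out <- list(
    sites = seq_len(n_sites), alphabet = alphabet, wt_sequence = wt,
    energy_model = energy_model,
    tables = list(base = base, additive = add, pairwise = pair,
                  pscale = pscale),
    n_conformations = n_conformations, seed = effect_table_seed
  )
  class(out) <- "toy_design_space"
  out
}

#' @export
print.toy_design_space <- function(x, ...) {
  cat("<toy_design_space> ", length(x$sites), " sites x ",
      length(x$alphabet), " tokens (",
      format(length(x$alphabet)^length(x$sites), big.mark = ","),
      " sequences), ", x$n_conformations, " conformation classes\n", sep = "")
  invisible(x)
}

# ---- config serialization ---------------------------------------------------

#' Read or write a system definition as a structured text config
#'
#' Built-in systems round-trip through YAML (kind, parameters, masses,
#' lambda definition, temperature, seed).
#'
#' @param system A `model_system`.
#' @param path File path.
#' @return `read_system_config()` returns the reconstructed `model_system`.
#' @export
write_system_config <- function(system, path) {
  cfg <- list(kind = system$kind_name, n_coord = system$n_coord,
              masses_coord = system$masses_coord, params = unname(system$params),
              tethers = system$tethers, lambda_spec = system$lambda_spec,
              temperature = system$temperature, seed = system$seed,
              particles = system$metadata$particles %||%
                system$metadata$coords)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_system_config
#' @export
read_system_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  kind <- match(cfg$kind, c("double_well", "harmonic_1d", "migration_mimic"))
  if (is.na(kind)) abort_param(paste("unknown system kind:", cfg$kind))
  lam <- cfg$lambda_spec
  if (!is.null(lam$breaking)) {
    lam$breaking <- as.integer(lam$breaking)
    lam$forming <- as.integer(lam$forming)
  }
  new_model_system(
    kind = kind, kind_name = cfg$kind, n_coord = cfg$n_coord,
    masses_coord = as.double(unlist(cfg$masses_coord)),
    params = as.double(unlist(cfg$params)),
    tethers = as.double(unlist(cfg$tethers)),
    lambda_spec = lam, temperature = cfg$temperature,
    metadata = list(particles = unlist(cfg$particles)),
    seed = cfg$seed
  )
}

#' Read coordinates from a PDB file
#'
#' Thin wrapper over [bio3d::read.pdb()] returning an n x 3 coordinate matrix
#' (Angstrom) with atom names, for feature extraction on real structures.
#' Residue numbering is preserved 1-based as in the file.
#'
#' @param path Path to a PDB file.
#' @return A list with `coords` (n x 3 matrix), `atom` (data frame of PDB
#'   atom records).
#' @export
read_pdb_coords <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("reading PDB files requires the bio3d package", call. = FALSE)
  pdb <- bio3d::read.pdb(path)
  coords <- matrix(pdb$xyz, ncol = 3, byrow = TRUE)
  colnames(coords) <- c("x", "y", "z")
  list(coords = coords, atom = pdb$atom)
}
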