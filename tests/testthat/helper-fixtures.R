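# Shared fixtures, built once per test session and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

fix_double_well <- function() {
  fixture("dw", function() make_double_well(barrier_height = 4, n_env = 1))
}

fix_dw_seed_path <- function() {
  fixture("dw_seed", function() {
    generate_seed_path(fix_double_well(), list(c(0, 0)),
                       langevin_params(seed = 5))
  })
}

fix_mimic_family <- function() {
  fixture("family", function() {
    make_mimic_family(n_env = 3, gate_strength = 4, seed = 1)
  })
}

# WT pathway ensembles (R and NR) with frames, aligned lazily by consumers
fix_mimic_ensembles <- function() {
  fixture("mimic_ens", function() {
    fam <- fix_mimic_family()
    wt <- fam$system_factory("A")
    p <- langevin_params(seed = 5)
    seeds_r <- harvest_excursion_paths(wt, cond_R(), 6, p, max_steps = 6e7)
    seeds_nr <- harvest_excursion_paths(wt, cond_NR(-0.4), 6,
                                        langevin_params(seed = 17),
                                        max_steps = 6e7)
    r <- sample_pathway_ensembles(wt, seeds_r, "R", n_moves = 600,
                                  n_equil = 150, n_ensembles = 6,
                                  params = p, sigma_p = 0.25)
    nr <- sample_pathway_ensembles(wt, seeds_nr, "NR", n_moves = 600,
                                   n_equil = 150, n_ensembles = 6,
                                   params = p, sigma_p = 0.25)
    list(r = r, nr = nr, wt = wt)
  })
}

fix_mimic_dataset <- function() {
  fixture("mimic_ds", function() {
    ens <- fix_mimic_ensembles()
    suppressWarnings(build_dataset(ens$r, ens$nr, mimic_schema(ens$wt),
                                   window = c(-30, 0), breaking = c(1, 2),
                                   seed = 3))
  })
}

fix_mimic_models <- function() {
  fixture("mimic_models", function() {
    ds <- fix_mimic_dataset()
    list(lr = train_lr(ds, "all", seed = 3),
         nn = train_nn(ds, "all", epochs = 150, seed = 3))
  })
}

# small synthetic labeled dataset with a single informative feature
make_synthetic_dataset <- function(n_paths = 60, p = 6, signal = 2,
                                   seed = 1, informative = 1,
                                   xor_pair = NULL) {
  set.seed(seed)
  y <- rep(c(TRUE, FALSE), length.out = n_paths)
  X <- matrix(rnorm(n_paths * p), n_paths, p)
  colnames(X) <- paste0("f", seq_len(p))
  if (is.null(xor_pair)) {
    X[, informative] <- X[, informative] + signal * ifelse(y, 1, -1)
  } else {
    a <- sample(c(-1, 1), n_paths, replace = TRUE)
    b <- ifelse(y, a, -a)
    X[, xor_pair[1]] <- a + 0.2 * rnorm(n_paths)
    X[, xor_pair[2]] <- b + 0.2 * rnorm(n_paths)
  }
  out <- tibble::tibble(path_uid = paste0("p", seq_len(n_paths)),
                        label = ifelse(y, "R", "NR"),
                        weight = 1, time = 0)
  out <- dplyr::bind_cols(out, tibble::as_tibble(X))
  structure(out, schema = NULL, window = c(-30, 0),
            class = c("labeled_dataset", class(out)))
}

binom_ci <- function(x, n) {
  p <- x / n
  p + c(-1.96, 1.96) * sqrt(p * (1 - p) / n)
}

# place a point at a given distance/angle for criterion geometry
rotate_frame <- function(coords, seed = 1) {
  set.seed(seed)
  th <- runif(3, 0, 2 * pi)
  Rx <- matrix(c(1, 0, 0, 0, cos(th[1]), -sin(th[1]),
                 0, sin(th[1]), cos(th[1])), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cos(th[2]), 0, sin(th[2]), 0, 1, 0,
                 -sin(th[2]), 0, cos(th[2])), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cos(th[3]), -sin(th[3]), 0, sin(th[3]), cos(th[3]), 0,
                 0, 0, 1), 3, 3, byrow = TRUE)
  shift <- runif(3, -5, 5)
  sweep(coords %*% t(Rx %*% Ry %*% Rz), 2, -shift)
}
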