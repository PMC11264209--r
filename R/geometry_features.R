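#' Geometric features and reactive-like criteria
#'
#' Order-parameter and structural-feature computation on single-frame
#' coordinates: interatomic distances (Angstrom), angles and torsions
#' (degrees), the minimum-absolute-dihedral feature over a hydrogen set, and
#' the three boolean reactive-like criteria (hydrogen bond present, rotated
#' side chain, eclipsed conformation) used to compare variants. All features
#' are invariant under rigid rotations and translations.
#'
#' @name geometry_features
NULL

as_coord_matrix <- function(frame) {
  if (is.matrix(frame)) {
    if (ncol(frame) != 3) abort_param("coordinate matrix must be n x 3")
    return(frame)
  }
  if (length(frame) %% 3 != 0)
    abort_param("coordinate vector length must be a multiple of 3")
  matrix(frame, ncol = 3, byrow = TRUE)
}

vdist <- function(a, b) {
  d <- sqrt(sum((a - b)^2))
  if (d < 1e-12) abort_param("coincident atoms: distance undefined")
  d
}

# angle at vertex j between rays j->i and j->k, degrees in [0, 180]
vangle <- function(pi_, pj, pk) {
  u <- pi_ - pj; v <- pk - pj
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-12 || nv < 1e-12)
    abort_param("undefined angle: coincident atoms at the vertex")
  ct <- sum(u * v) / (nu * nv)
  acos(pmin(1, pmax(-1, ct))) * 180 / pi
}

# signed dihedral i-j-k-l in degrees (-180, 180]
vdihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- pracma_cross(b1, b2); n2 <- pracma_cross(b2, b3)
  nn1 <- sqrt(sum(n1^2)); nn2 <- sqrt(sum(n2^2))
  if (nn1 < 1e-12 || nn2 < 1e-12)
    abort_param("undefined dihedral: collinear atoms")
  m1 <- pracma_cross(n1, b2 / sqrt(sum(b2^2)))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# angle between undirected axes, folded into [0, 90]
axis_angle <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-12 || nv < 1e-12) abort_param("degenerate axis")
  ct <- abs(sum(u * v)) / (nu * nv)
  acos(pmin(1, ct)) * 180 / pi
}

#' Order parameter from a coordinate frame
#'
#' `lambda = d(breaking) - d(forming)` in Angstrom.
#'
#' @param frame Coordinates (n x 3 matrix or length-3n vector).
#' @param breaking,forming Atom index pairs (1-based; the shared center atom
#'   may repeat across pairs).
#' @return Lambda in Angstrom.
#' @export
compute_lambda <- function(frame, breaking, forming) {
  x <- as_coord_matrix(frame)
  vdist(x[breaking[1], ], x[breaking[2], ]) -
    vdist(x[forming[1], ], x[forming[2], ])
}

# ---- feature schema ---------------------------------------------------------

#' Build a feature schema
#'
#' An ordered list of named feature definitions created with
#' [feature_distance()], [feature_angle()], [feature_dihedral()] and
#' [feature_min_dihedral()]. The full-scale schema has 70 features; the
#' schema here is user-configurable, with the minimum-dihedral kind built in
#' for the substrate-conformation features.
#'
#' @param ... Feature definitions (or a single list of them).
#' @return A `feature_schema`.
#' @export
feature_schema <- function(...) {
  defs <- list(...)
  if (length(defs) == 1 && is.list(defs[[1]]) && is.null(defs[[1]]$kind))
    defs <- defs[[1]]
  nm <- vapply(defs, `[[`, character(1), "name")
  if (anyDuplicated(nm)) abort_param("feature names must be unique")
  structure(defs, names = nm, class = "feature_schema")
}

#' @export
print.feature_schema <- function(x, ...) {
  cat("<feature_schema> ", length(x), " features: ",
      paste(utils::head(names(x), 8), collapse = ", "),
      if (length(x) > 8) ", ...", "\n", sep = "")
  invisible(x)
}

#' Feature definitions
#'
#' @param name Unique feature name.
#' @param i,j,k,l 1-based atom indices.
#' @param h_set Indices of the hydrogen set for the minimum-dihedral kind.
#' @return A feature definition for [feature_schema()].
#' @export
feature_distance <- function(name, i, j)
  list(name = name, kind = "distance", idx = c(i, j))

#' @rdname feature_distance
#' @export
feature_angle <- function(name, i, j, k)
  list(name = name, kind = "angle", idx = c(i, j, k))

#' @rdname feature_distance
#' @export
feature_dihedral <- function(name, i, j, k, l)
  list(name = name, kind = "dihedral", idx = c(i, j, k, l))

#' @rdname feature_distance
#' @export
feature_min_dihedral <- function(name, i, j, k, h_set)
  list(name = name, kind = "min_dihedral", idx = c(i, j, k),
       h_set = h_set)

#' Evaluate a feature schema on one frame
#'
#' Distances in Angstrom; angles in degrees within \[0, 180\]; dihedrals as
#' absolute torsion magnitude in \[0, 180\] by default (signed mode for
#' diagnostics); the minimum-dihedral kind returns the minimum absolute
#' dihedral over its hydrogen set.
#'
#' @param frame Coordinates (n x 3 matrix or length-3n vector).
#' @param schema A `feature_schema`.
#' @param signed Report signed dihedrals in (-180, 180].
#' @return Named numeric vector in schema order.
#' @export
compute_features <- function(frame, schema, signed = FALSE) {
  x <- as_coord_matrix(frame)
  vapply(schema, function(d) {
    ii <- d$idx
    switch(d$kind,
      distance = vdist(x[ii[1], ], x[ii[2], ]),
      angle = vangle(x[ii[1], ], x[ii[2], ], x[ii[3], ]),
      dihedral = {
        v <- vdihedral(x[ii[1], ], x[ii[2], ], x[ii[3], ], x[ii[4], ])
        if (signed) v else abs(v)
      },
      min_dihedral = min(vapply(d$h_set, function(h)
        abs(vdihedral(x[ii[1], ], x[ii[2], ], x[ii[3], ], x[h, ])),
        numeric(1))),
      abort_param("unknown feature kind"))
  }, numeric(1))
}

#' Evaluate a schema over many frames
#'
#' @param frames A list of frames, or the tibble returned by
#'   [sample_window_frames()] (its `positions` list-column is used and the
#'   feature columns are appended).
#' @param schema A `feature_schema`.
#' @return A tibble of feature columns (plus the input columns when `frames`
#'   is a window-frame tibble).
#' @export
compute_feature_matrix <- function(frames, schema) {
  if (is.data.frame(frames)) {
    feats <- purrr::map(frames$positions, compute_features, schema = schema)
    fm <- tibble::as_tibble(do.call(rbind, feats))
    return(dplyr::bind_cols(frames, fm))
  }
  feats <- purrr::map(frames, compute_features, schema = schema)
  tibble::as_tibble(do.call(rbind, feats))
}

#' A default feature schema for the migration mimic
#'
#' Pairwise distances among D, M, A, every environment particle's distance
#' to D and to M, and the D-M-A bond angle. The planted gate feature is
#' `d_gate_D` (the first environment particle's distance to D).
#'
#' @param system A migration-mimic `model_system`.
#' @return A `feature_schema`.
#' @export
mimic_schema <- function(system) {
  n_env <- as.integer(system$params[["n_env"]])
  defs <- list(
    feature_distance("d_D_M", 1, 2),
    feature_distance("d_M_A", 2, 3),
    feature_distance("d_D_A", 1, 3),
    feature_angle("ang_D_M_A", 1, 2, 3))
  for (j in seq_len(n_env)) {
    nm <- if (j == 1) "d_gate_D" else paste0("d_env", j, "_D")
    defs <- c(defs, list(feature_distance(nm, 3 + j, 1),
                         feature_distance(paste0("d_env", j, "_M"), 3 + j, 2)))
  }
  feature_schema(defs)
}

# ---- reactive-like criteria -------------------------------------------------

#' Evaluate the three reactive-like structural criteria on a frame
#'
#' Hydrogen bond present: donated-proton-to-acceptor distance < 2.3
#' Angstrom, donor-axis angle within 30 deg of 180 deg, and
#' acceptor-carbonyl angle within 30 deg of 120 deg (all three required;
#' strict inequalities). Rotated side chain: angle between the two
#' undirected axes (folded into \[0, 90\] deg) < 75 deg. Eclipsed
#' conformation: minimum absolute dihedral over the listed
#' oxygen--carbon--carbon--hydrogen quadruples < 30 deg.
#'
#' @param frame Coordinates (n x 3 matrix or length-3n vector).
#' @param roles Named list of atom roles: `hb_donor`, `hb_hydrogen`,
#'   `hb_acceptor`, `hb_acceptor_partner` (carbonyl carbon) for the hydrogen
#'   bond; `rot_axis1`, `rot_axis2` (index pairs) for the rotated criterion;
#'   `ecl_quads` (list of `list(i, j, k, h_set)` min-dihedral quadruples)
#'   for the eclipse criterion. Criteria with missing roles are reported
#'   `NA`.
#' @param hb_dist,hb_donor_tol,hb_acceptor_tol,rot_max,ecl_max Thresholds
#'   (defaults 2.3 Angstrom; 30 deg about 180 deg; 30 deg about 120 deg;
#'   75 deg; 30 deg).
#' @return A one-row tibble with logical columns `hbond_present`, `rotated`,
#'   `eclipsed`.
#' @export
evaluate_criteria <- function(frame, roles, hb_dist = 2.3,
                              hb_donor_tol = 30, hb_acceptor_tol = 30,
                              rot_max = 75, ecl_max = 30) {
  x <- as_coord_matrix(frame)
  hb <- NA
  if (!is.null(roles$hb_donor) && !is.null(roles$hb_hydrogen) &&
      !is.null(roles$hb_acceptor) && !is.null(roles$hb_acceptor_partner)) {
    d_ha <- vdist(x[roles$hb_hydrogen, ], x[roles$hb_acceptor, ])
    a_donor <- vangle(x[roles$hb_donor, ], x[roles$hb_hydrogen, ],
                      x[roles$hb_acceptor, ])
    a_acc <- vangle(x[roles$hb_hydrogen, ], x[roles$hb_acceptor, ],
                    x[roles$hb_acceptor_partner, ])
    hb <- d_ha < hb_dist &&
      abs(a_donor - 180) < hb_donor_tol &&
      abs(a_acc - 120) < hb_acceptor_tol
  }
  rot <- NA
  if (!is.null(roles$rot_axis1) && !is.null(roles$rot_axis2)) {
    u <- x[roles$rot_axis1[2], ] - x[roles$rot_axis1[1], ]
    v <- x[roles$rot_axis2[2], ] - x[roles$rot_axis2[1], ]
    rot <- axis_angle(u, v) < rot_max
  }
  ecl <- NA
  if (!is.null(roles$ecl_quads)) {
    dmin <- min(vapply(roles$ecl_quads, function(q) {
      min(vapply(q$h_set, function(h)
        abs(vdihedral(x[q$i, ], x[q$j, ], x[q$k, ], x[h, ])), numeric(1)))
    }, numeric(1)))
    ecl <- dmin < ecl_max
  }
  tibble::tibble(hbond_present = hb, rotated = rot, eclipsed = ecl)
}

#' Weighted criterion populations across frames
#'
#' The weighted fraction of frames satisfying each criterion, optionally
#' normalized by a reference variant's fractions (the reference row of the
#' population table is 1 by construction).
#'
#' @param frames List of frames, or a window-frame tibble with a `positions`
#'   list-column and (optionally) a `weight` column.
#' @param roles Atom-role map; see [evaluate_criteria()].
#' @param weights Nonnegative weights, not all zero (default: the tibble's
#'   `weight` column, else 1).
#' @param reference Optional named fractions to normalize by.
#' @param ... Threshold overrides passed to [evaluate_criteria()].
#' @return A tibble with `criterion`, `fraction` and (if `reference` given)
#'   `normalized`.
#' @export
criterion_population <- function(frames, roles, weights = NULL,
                                 reference = NULL, ...) {
  if (is.data.frame(frames)) {
    weights <- weights %||% frames$weight
    frames <- frames$positions
  }
  weights <- weights %||% rep(1, length(frames))
  if (any(weights < 0) || sum(weights) <= 0)
    abort_param("weights must be nonnegative with positive total")
  rep_tbl <- purrr::map_dfr(frames, evaluate_criteria, roles = roles, ...)
  frac <- vapply(rep_tbl, function(col) {
    ok <- !is.na(col)
    if (!any(ok)) return(NA_real_)
    sum(weights[ok] * col[ok]) / sum(weights[ok])
  }, numeric(1))
  out <- tibble::tibble(criterion = names(frac), fraction = unname(frac))
  if (!is.null(reference)) {
    ref <- reference[out$criterion]
    out$normalized <- out$fraction / as.numeric(ref)
  }
  out
}
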