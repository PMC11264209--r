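test_that("lambda from coordinates: arithmetic, symmetry, antisymmetry", {
  fr <- rbind(c(0, 0, 0), c(2, 0, 0), c(2, 1.5, 0))
  expect_equal(compute_lambda(fr, c(1, 2), c(2, 3)), 0.5)
  sym <- rbind(c(-1, 0, 0), c(0, 0, 0), c(1, 0, 0))
  expect_equal(compute_lambda(sym, c(1, 2), c(2, 3)), 0)
  expect_equal(compute_lambda(fr, c(2, 3), c(1, 2)), -0.5)
  expect_error(compute_lambda(rbind(c(0, 0, 0), c(0, 0, 0)), c(1, 2),
                              c(1, 2)), "coincident")
})

test_that("feature primitives: angle, dihedral, min-dihedral", {
  fr <- rbind(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(1, 1, 0))
  sc <- feature_schema(feature_angle("a", 1, 2, 3),
                       feature_dihedral("d", 3, 2, 1, 4))
  v <- compute_features(fr, sc)
  expect_equal(unname(v["a"]), 90)
  # planar cis quadruple has dihedral 0
  cis <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  expect_equal(unname(compute_features(
    cis, feature_schema(feature_dihedral("d", 1, 2, 3, 4)))["d"]), 0)
  # min-dihedral over a hydrogen set picks the 0-placed hydrogen
  h0 <- c(1, 1, 0)                      # eclipsed with atom 1
  h120 <- c(1, -0.5, sqrt(3) / 2)       # rotated by 120 degrees
  frm <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), h0, h120)
  mv <- compute_features(frm, feature_schema(
    feature_min_dihedral("m", 1, 2, 3, h_set = c(4, 5))))
  expect_equal(unname(mv["m"]), 0, tolerance = 1e-9)
  # min_dihedral never exceeds any member of its set
  each <- vapply(c(4, 5), function(h) unname(compute_features(
    frm, feature_schema(feature_dihedral("d", 1, 2, 3, h)))["d"]),
    numeric(1))
  expect_true(all(mv["m"] <= each + 1e-12))
  expect_error(feature_schema(feature_distance("x", 1, 2),
                              feature_distance("x", 1, 3)), "unique")
  expect_error(compute_features(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                                feature_schema(feature_angle("a", 1, 2, 3))),
               NA) # 180 degrees is defined
  collinear <- rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0))
  expect_error(compute_features(collinear,
                                feature_schema(feature_angle("a", 1, 2, 3))),
               "coincident|undefined")
})

test_that("all features are invariant under rigid transforms", {
  set.seed(8)
  fr <- matrix(rnorm(18), 6, 3)
  sc <- feature_schema(feature_distance("d", 1, 2),
                       feature_angle("a", 1, 2, 3),
                       feature_dihedral("t", 1, 2, 3, 4),
                       feature_min_dihedral("m", 1, 2, 3, h_set = c(5, 6)))
  ref <- compute_features(fr, sc)
  for (s in 1:10) {
    rot <- compute_features(rotate_frame(fr, seed = s), sc)
    expect_equal(rot, ref, tolerance = 1e-9)
  }
})

# geometry with exact control over the hydrogen-bond criterion
hbond_frame <- function(dist_ha, donor_angle = 180, acceptor_angle = 120) {
  H <- c(0, 0, 0)
  N <- c(0, 0, -1)
  th <- (180 - donor_angle) * pi / 180
  A <- dist_ha * c(sin(th), 0, cos(th))
  u <- (H - A) / sqrt(sum((H - A)^2))
  ph <- acceptor_angle * pi / 180
  perp <- c(u[3], 0, -u[1])
  C <- A + cos(ph) * u + sin(ph) * perp
  rbind(N, H, A, C)
}

test_that("criterion thresholds are strict, per the stated rules", {
  roles <- list(hb_donor = 1, hb_hydrogen = 2, hb_acceptor = 3,
                hb_acceptor_partner = 4)
  expect_false(evaluate_criteria(hbond_frame(2.3), roles)$hbond_present)
  expect_true(evaluate_criteria(hbond_frame(2.29), roles)$hbond_present)
  expect_false(evaluate_criteria(hbond_frame(2.0, donor_angle = 149.9),
                                 roles)$hbond_present)
  expect_true(evaluate_criteria(hbond_frame(2.0, donor_angle = 150.1),
                                roles)$hbond_present)
  expect_false(evaluate_criteria(hbond_frame(2.0, acceptor_angle = 150.1),
                                 roles)$hbond_present)
  expect_true(evaluate_criteria(hbond_frame(2.0, acceptor_angle = 149.9),
                                roles)$hbond_present)
  # rotated side chain: angle between undirected axes, folded to [0, 90]
  rot_frame <- function(theta) {
    th <- theta * pi / 180
    rbind(c(0, 0, 0), c(1, 0, 0), c(0, 0, 2), c(cos(th), sin(th), 2))
  }
  rroles <- list(rot_axis1 = c(1, 2), rot_axis2 = c(3, 4))
  expect_true(evaluate_criteria(rot_frame(74.9), rroles)$rotated)
  expect_false(evaluate_criteria(rot_frame(75.1), rroles)$rotated)
  expect_true(evaluate_criteria(rot_frame(180 - 74.9), rroles)$rotated)
  # eclipsed: minimum dihedral over quadruples, threshold 30 strict
  ecl_frame <- function(tau) {
    th <- tau * pi / 180
    rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0),
          c(1, cos(th), sin(th)))
  }
  eroles <- list(ecl_quads = list(list(i = 1, j = 2, k = 3, h_set = 4)))
  expect_true(evaluate_criteria(ecl_frame(29), eroles)$eclipsed)
  expect_false(evaluate_criteria(ecl_frame(31), eroles)$eclipsed)
  # missing roles disable a criterion rather than erroring
  part <- evaluate_criteria(hbond_frame(2.0), list(rot_axis1 = c(1, 2),
                                                   rot_axis2 = c(3, 4)))
  expect_true(is.na(part$hbond_present))
  expect_true(is.na(part$eclipsed))
})

test_that("shrinking the hydrogen-bond distance never turns the criterion
           off", {
  roles <- list(hb_donor = 1, hb_hydrogen = 2, hb_acceptor = 3,
                hb_acceptor_partner = 4)
  dists <- seq(2.6, 0.8, by = -0.2)
  status <- vapply(dists, function(d)
    evaluate_criteria(hbond_frame(d), roles)$hbond_present, logical(1))
  expect_false(any(diff(status) < 0))  # once on, stays on as d shrinks
})

test_that("criterion populations are weighted fractions with reference
           normalization", {
  roles <- list(rot_axis1 = c(1, 2), rot_axis2 = c(3, 4))
  f_true <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 0, 2), c(1, 0.1, 2))
  f_false <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 0, 2), c(0.1, 1, 2))
  pop <- criterion_population(list(f_true, f_false), roles,
                              weights = c(3, 1))
  expect_equal(pop$fraction[pop$criterion == "rotated"], 0.75)
  all_true <- criterion_population(list(f_true, f_true), roles)
  expect_equal(all_true$fraction[all_true$criterion == "rotated"], 1)
  ref <- setNames(pop$fraction, pop$criterion)
  norm <- criterion_population(list(f_true, f_false), roles,
                               weights = c(3, 1), reference = ref)
  expect_equal(norm$normalized[norm$criterion == "rotated"], 1)
  expect_error(criterion_population(list(f_true), roles, weights = 0),
               "positive total")
})
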