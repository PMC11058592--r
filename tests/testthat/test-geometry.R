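test_that("superposing a structure on itself is the identity", {
  set.seed(1)
  P <- matrix(rnorm(30), 10, 3)
  fit <- kabsch_superpose(P, P)
  expect_equal(fit$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-9)
  expect_equal(fit$translation, c(0, 0, 0), tolerance = 1e-9)
})

test_that("an exact rigid motion is recovered to 1e-9 with rmsd 0", {
  set.seed(2)
  P <- matrix(rnorm(15), 5, 3)
  th <- pi / 2
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
               3, 3, byrow = TRUE)
  Q <- sweep(P %*% t(Rz), 2, c(5, 0, 0), `+`)
  fit <- kabsch_superpose(P, Q)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(fit$rotation, Rz, tolerance = 1e-9)
  expect_equal(fit$translation, c(5, 0, 0), tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-12)
})

test_that("superposition rmsd is symmetric and rejects degenerate input", {
  set.seed(3)
  for (i in 1:5) {
    A <- matrix(rnorm(18), 6, 3)
    B <- matrix(rnorm(18), 6, 3)
    expect_equal(kabsch_superpose(A, B)$rmsd, kabsch_superpose(B, A)$rmsd,
                 tolerance = 1e-9)
  }
  expect_error(kabsch_superpose(matrix(rnorm(6), 2, 3), matrix(rnorm(6), 2, 3)),
               class = "loopshift_error_too_few_atoms")
  line <- cbind(0:4, 0, 0)
  expect_error(kabsch_superpose(line, line + 1),
               class = "loopshift_error_degenerate")
})

test_that("kabsch matches the brute-force rotation-grid oracle on random pairs", {
  set.seed(4)
  for (i in 1:5) {
    P <- matrix(rnorm(15), 5, 3)
    Q <- matrix(rnorm(15), 5, 3)
    expect_equal(kabsch_superpose(P, Q)$rmsd, oracle_min_rmsd(P, Q),
                 tolerance = 1e-6)
  }
})

test_that("rmsd_series is zero on the reference and d/sqrt(n) for one displaced atom", {
  sim <- quick_sim(seed = 5, n_replicas = 1, n_frames = 1, noise_sigma = 0,
                   transition_matrix = diag(3), start_state = "closed")
  ens <- sim$ensemble
  ref <- sim$references$closed
  rs <- rmsd_series(ens, ref)
  expect_true(all(rs$rmsd < 1e-9))
  # displace one loop (measure) atom by d; fit atoms untouched
  d <- 2.0
  n_meas <- length(ref$loop_selection)
  row <- atom_set(ref$loop_selection[1])
  ens2 <- ens
  ens2$coords[loopshift:::atom_rows(ens$topology, row), 1, 1, 1] <-
    ens2$coords[loopshift:::atom_rows(ens$topology, row), 1, 1, 1] + d
  rs2 <- rmsd_series(ens2, ref)
  expect_equal(rs2$rmsd, d / sqrt(n_meas), tolerance = 1e-9)
})

test_that("rmsd_series is invariant under one global rigid motion of all frames", {
  sim <- quick_sim(seed = 6, n_replicas = 1, n_frames = 10)
  base <- rmsd_series(sim$ensemble, sim$references$closed)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  moved <- sim$ensemble
  for (f in 1:10) {
    moved$coords[, , f, 1] <- sweep(moved$coords[, , f, 1] %*% t(R), 2,
                                    c(3, -2, 8), `+`)
  }
  expect_equal(rmsd_series(moved, sim$references$closed)$rmsd, base$rmsd,
               tolerance = 1e-9)
})

test_that("noisy-loop RMSD agrees with an independent quaternion refit per frame", {
  sim <- quick_sim(seed = 7, n_replicas = 1, n_frames = 200,
                   start_state = "closed")
  ref <- sim$references$closed
  rs <- rmsd_series(sim$ensemble, ref)
  top <- sim$topology
  fr <- loopshift:::atom_rows(top, ref$fit_selection)
  mr <- loopshift:::atom_rows(top, ref$loop_selection)
  oracle <- vapply(seq_len(200), function(f) {
    P <- sim$ensemble$coords[, , f, 1]
    fit <- horn_superpose(P[fr, ], ref$coords[fr, ])
    Pm <- sweep(P[mr, ] %*% t(fit$rotation), 2, fit$translation, `+`)
    sqrt(mean(rowSums((Pm - ref$coords[mr, ])^2)))
  }, numeric(1))
  expect_equal(rs$rmsd, oracle, tolerance = 1e-8)
  # mean RMSD of a sigma = 0.3 closed ensemble sits near sigma * sqrt(3)
  expect_equal(mean(rs$rmsd[sim$labels$label == "closed"]), 0.3 * sqrt(3),
               tolerance = 0.05)
})

test_that("centre-of-mass distances follow hand computations", {
  top <- topology(tibble::tibble(
    atom_id = 1:3, atom_name = c("CA", "CA", "CA"),
    residue_index = 1:3, residue_name = "ALA", chain_id = "A",
    element = "C", mass = c(1, 1, 1)))
  coords <- array(0, dim = c(3, 3, 2, 1))
  coords[1, , 1, 1] <- c(0, 0, 0); coords[2, , 1, 1] <- c(2, 0, 0)
  coords[3, , 1, 1] <- c(5, 0, 0)
  coords[, , 2, 1] <- coords[, , 1, 1]
  ens <- replica_ensemble(top, coords, 100)
  d <- com_distance_series(ens, atom_set(1:2), atom_set(3))
  expect_equal(d$dist, c(4, 4))
  expect_equal(com_distance_series(ens, atom_set(1:2), atom_set(1:2))$dist,
               c(0, 0))
  # mass weighting: masses {12, 1} at 0 and 13 -> COM at 1
  top2 <- topology(tibble::tibble(
    atom_id = 1:3, atom_name = "CA", residue_index = 1:3,
    residue_name = "ALA", chain_id = "A", element = "C",
    mass = c(12, 1, 1)))
  coords2 <- array(0, dim = c(3, 3, 1, 1))
  coords2[1, , 1, 1] <- c(0, 0, 0); coords2[2, , 1, 1] <- c(13, 0, 0)
  coords2[3, , 1, 1] <- c(10, 0, 0)
  ens2 <- replica_ensemble(top2, coords2, 100)
  expect_equal(com_distance_series(ens2, atom_set(1:2), atom_set(3))$dist, 9)
  expect_error(com_distance_series(ens, atom_set(integer(0)), atom_set(1)),
               class = "loopshift_error_selection_mismatch")
})

test_that("dihedral angles: trans plane, analytic +60 twist, periodicity", {
  p1 <- c(1, 0, 0); p2 <- c(0, 0, 0); p3 <- c(0, 1, 0)
  expect_equal(dihedral_angle(p1, p2, p3, c(-1, 1, 0)), 180)
  # rotate the 4th atom by +60 degrees about the 2-3 bond from the trans position
  rot_about_y <- function(p, deg) {
    th <- deg * pi / 180
    c(cos(th) * p[1] + sin(th) * p[3], p[2], -sin(th) * p[1] + cos(th) * p[3])
  }
  # hand-built +60 degree twist away from the cis (0 degree) arrangement
  expect_equal(dihedral_angle(p1, p2, p3, rot_about_y(c(1, 1, 0), 60)), 60,
               tolerance = 1e-6)
  # convention agrees with an established implementation
  expect_equal(dihedral_angle(p1, p2, p3, rot_about_y(c(1, 1, 0), 60)),
               bio3d::torsion.xyz(c(p1, p2, p3, rot_about_y(c(1, 1, 0), 60)),
                                  atm.inc = 4)[1],
               tolerance = 1e-6, ignore_attr = TRUE)
  # periodicity: a full turn reproduces the angle
  expect_equal(dihedral_angle(p1, p2, p3, rot_about_y(c(-1, 1, 0), 360)), 180,
               tolerance = 1e-6)
})

test_that("terminal residues give NA phi without error; helix interior is not disallowed", {
  sim <- quick_sim(seed = 8, n_replicas = 1, n_frames = 3, atoms = "full",
                   n_residues = 12, loop_start = 4, loop_end = 8)
  first <- backbone_dihedrals(sim$ensemble, 1)
  expect_true(all(is.na(first$phi)))
  expect_true(all(is.na(first$region)))
  mid <- backbone_dihedrals(sim$ensemble, 2)
  expect_true(all(!is.na(mid$phi)))
  expect_true(all(!is.na(mid$psi)))
  expect_true(all(mid$region %in% c("favored", "allowed", "disallowed")))
})

test_that("the Ramachandran mask classifies canonical secondary-structure angles", {
  expect_equal(classify_rama(-60, -45), "favored")     # alpha helix
  expect_equal(classify_rama(-120, 130), "favored")    # beta sheet
  expect_equal(classify_rama(60, 40), "allowed")       # left-handed alpha
  expect_equal(classify_rama(120, -120), "disallowed")
  expect_true(is.na(classify_rama(NA, 10)))
})
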