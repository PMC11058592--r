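# small hand-built topology with named donors/acceptors and hydrogens
hb_topology <- function() {
  topology(tibble::tibble(
    atom_id = 1:7,
    atom_name = c("N", "H", "CA", "O", "N", "CA", "O"),
    element = c("N", "H", "C", "O", "N", "C", "O"),
    residue_index = c(1, 1, 1, 1, 5, 5, 5),
    residue_name = c("ALA", "ALA", "ALA", "ALA", "GLY", "GLY", "GLY"),
    chain_id = "A", mass = 1))
}

test_that("an ideal linear N-H...O bond is detected and a 5 A pair is not", {
  top <- hb_topology()
  coords <- rbind(
    c(0, 0, 0),    # N donor (res 1)
    c(1, 0, 0),    # H on the N-O axis
    c(0, 2, 0),    # CA
    c(-2, -2, 0),  # O of res 1 (far)
    c(9, 9, 9), c(10, 9, 9),
    c(2.9, 0, 0))  # acceptor O of res 5, 2.9 A from N, linear
  found <- detect_hbonds(coords, top)
  expect_equal(nrow(found), 1)
  expect_equal(found$kind, "hbond")
  expect_equal(c(found$res_i, found$res_j), c(1, 5))
  # same geometry at 5.0 A: nothing
  coords[7, ] <- c(5, 0, 0)
  expect_equal(nrow(detect_hbonds(coords, top)), 0)
  # bent arrangement below the angle cutoff: nothing
  coords[7, ] <- c(0, 2.9, 0)  # D-H...A angle 45 degrees
  expect_equal(nrow(detect_hbonds(coords, top)), 0)
})

test_that("a proline backbone nitrogen is never reported as a donor", {
  top <- topology(tibble::tibble(
    atom_id = 1:3,
    atom_name = c("N", "CA", "O"),
    element = c("N", "C", "O"),
    residue_index = c(1, 1, 5),
    residue_name = c("PRO", "PRO", "ALA"),
    chain_id = "A", mass = 1))
  coords <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(0, 2.9, 0))
  found <- detect_hbonds(coords, top, heavy_only = TRUE)
  expect_equal(nrow(found), 0)
  # the same geometry with a non-proline donor is detected
  top2 <- top; top2$residue_name[1:2] <- "ALA"
  expect_equal(nrow(detect_hbonds(coords, topology(top2), heavy_only = TRUE)), 1)
})

test_that("hydrogen-free topologies require the heavy-atom fallback", {
  sim <- quick_sim(seed = 201, n_replicas = 1, n_frames = 1, atoms = "full",
                   n_residues = 10, loop_start = 4, loop_end = 7)
  co <- frame_coords(sim$ensemble, 1, 1)
  expect_error(detect_hbonds(co, sim$topology),
               class = "loopshift_error_no_hydrogens")
  expect_silent(detect_hbonds(co, sim$topology, heavy_only = TRUE))
})

test_that("the heavy-atom detector equals an exhaustive pairwise scan on random frames", {
  set.seed(211)
  seqs <- c("SER", "GLN", "ALA", "TRP", "PRO", "GLU", "ASP", "LYS", "ARG",
            "THR", "ASN", "GLY")
  spec <- loop_system_spec(n_residues = 12, loop_start = 4, loop_end = 8,
                           atoms = "full", sequence = seqs,
                           n_replicas = 1, n_frames = 25, noise_sigma = 1.2,
                           seed = 211)
  sim <- simulate_loop_ensemble(spec)
  for (f in seq_len(25)) {
    co <- frame_coords(sim$ensemble, 1, f)
    got <- detect_hbonds(co, sim$topology, heavy_only = TRUE)
    expect_identical(key_strings(got), hbond_scan_oracle(co, sim$topology))
  }
})

test_that("contacts and salt bridges follow their distance definitions", {
  top <- topology(tibble::tibble(
    atom_id = 1:4,
    atom_name = c("NH1", "CB", "OE1", "CB"),
    element = c("N", "C", "O", "C"),
    residue_index = c(1, 1, 5, 5),
    residue_name = c("ARG", "ARG", "GLU", "GLU"),
    chain_id = "A", mass = 1))
  # guanidinium N within 3.5 A of carboxylate O -> salt bridge
  coords <- rbind(c(0, 0, 0), c(1, 1, 0), c(3.4, 0, 0), c(4, 1, 0))
  found <- detect_contacts(coords, top)
  expect_true("saltbridge" %in% found$kind)
  # 20 A apart: nothing
  far <- coords; far[3:4, 1] <- far[3:4, 1] + 20
  expect_equal(nrow(detect_contacts(far, top)), 0)
})

test_that("occupancies recover planted bonds and respect state conditioning", {
  seqs <- rep("ALA", 14); seqs[4] <- "SER"; seqs[11] <- "GLN"
  spec <- loop_system_spec(n_residues = 14, loop_start = 6, loop_end = 9,
                           atoms = "full", sequence = seqs,
                           n_replicas = 2, n_frames = 400, seed = 221)
  sim <- simulate_loop_ensemble(spec)
  rules <- tibble::tibble(res_i = 4, atom_i = "OG", res_j = 11, atom_j = "NE2",
                          state = "closed", occupancy = 0.6)
  ens <- plant_interactions(sim$ensemble, sim$labels, rules, seed = 5)
  occ <- interaction_occupancy(ens, sim$labels, detect = "hbond",
                               heavy_only = TRUE)
  hit <- occ[occ$res_i == 4 & occ$atom_i == "OG" & occ$res_j == 11 &
               occ$atom_j == "NE2" & occ$state == "closed", ]
  n_pres <- sum(hit$n_present); n_tot <- sum(hit$n_frames)
  ci <- qbinom(c(0.005, 0.995), n_tot, 0.6) / n_tot
  expect_gte(n_pres / n_tot, ci[1])
  expect_lte(n_pres / n_tot, ci[2])
  # occupancy 1 rule is found in every frame of its state; 0 never
  rules2 <- tibble::tibble(res_i = c(4, 4), atom_i = "OG",
                           res_j = c(11, 13), atom_j = c("NE2", "O"),
                           state = c("open", "wide_open"),
                           occupancy = c(1, 0))
  ens2 <- plant_interactions(sim$ensemble, sim$labels, rules2, seed = 6)
  occ2 <- interaction_occupancy(ens2, sim$labels, detect = "hbond",
                                heavy_only = TRUE)
  full <- occ2[occ2$res_i == 4 & occ2$atom_i == "OG" & occ2$res_j == 11 &
                 occ2$atom_j == "NE2" & occ2$state == "open", ]
  expect_true(nrow(full) > 0 && all(full$occupancy == 1))
  none <- occ2[occ2$res_i == 4 & occ2$atom_i == "OG" & occ2$res_j == 13 &
                 occ2$atom_j == "O" & occ2$state == "wide_open", ]
  expect_equal(nrow(none), 0)
})

test_that("states with no frames are omitted with a warning", {
  sim <- quick_sim(seed = 231, n_replicas = 1, n_frames = 20, atoms = "full",
                   n_residues = 10, loop_start = 4, loop_end = 7,
                   transition_matrix = diag(3), start_state = "closed")
  w <- testthat::capture_warnings(
    occ <- interaction_occupancy(sim$ensemble, sim$labels, detect = "hbond",
                                 heavy_only = TRUE))
  # both unvisited states are reported
  expect_true(any(grepl("'open' has no frames", w)))
  expect_true(any(grepl("'wide_open' has no frames", w)))
  expect_false("open" %in% occ$state)
  expect_true(all(occ$state == "closed"))
})

test_that("network differences are antisymmetric and treat missing keys as zero", {
  seqs <- rep("ALA", 14); seqs[4] <- "SER"; seqs[11] <- "GLN"
  spec <- loop_system_spec(n_residues = 14, loop_start = 6, loop_end = 9,
                           atoms = "full", sequence = seqs,
                           n_replicas = 2, n_frames = 200, seed = 241)
  sim <- simulate_loop_ensemble(spec)
  rules_a <- tibble::tibble(res_i = 4, atom_i = "OG", res_j = 11, atom_j = "NE2",
                            state = "closed", occupancy = 0.9)
  rules_b <- rules_a; rules_b$occupancy <- 0.1
  ens_a <- plant_interactions(sim$ensemble, sim$labels, rules_a, seed = 7)
  ens_b <- plant_interactions(sim$ensemble, sim$labels, rules_b, seed = 8)
  occ_a <- interaction_occupancy(ens_a, sim$labels, detect = "hbond", heavy_only = TRUE)
  occ_b <- interaction_occupancy(ens_b, sim$labels, detect = "hbond", heavy_only = TRUE)
  diff_ab <- network_difference(occ_a, occ_b, "closed")
  diff_ba <- network_difference(occ_b, occ_a, "closed")
  expect_equal(diff_ab$delta, -diff_ba$delta[match(
    paste(diff_ab$res_i, diff_ab$atom_i, diff_ab$res_j, diff_ab$atom_j),
    paste(diff_ba$res_i, diff_ba$atom_i, diff_ba$res_j, diff_ba$atom_j))])
  # the planted 0.9-vs-0.1 bond is the rank-1 difference
  top_row <- diff_ab[diff_ab$rank == 1, ]
  expect_equal(c(top_row$res_i, top_row$res_j), c(4, 11))
  expect_equal(top_row$delta, 0.8, tolerance = 0.15)
  # identical inputs: all deltas zero
  diff_aa <- network_difference(occ_a, occ_a, "closed")
  expect_true(all(diff_aa$delta == 0))
  # key present in one table only contributes its full occupancy
  expect_true(all(abs(diff_ab$delta) <= 1))
  expect_error(network_difference(occ_a, occ_b, "nonexistent"),
               class = "loopshift_error_missing_state")
})

test_that("residue projection double-counts each interaction once per partner", {
  seqs <- rep("ALA", 14); seqs[4] <- "SER"; seqs[11] <- "GLN"
  spec <- loop_system_spec(n_residues = 14, loop_start = 6, loop_end = 9,
                           atoms = "full", sequence = seqs,
                           n_replicas = 2, n_frames = 100, seed = 251)
  sim <- simulate_loop_ensemble(spec)
  rules <- tibble::tibble(res_i = 4, atom_i = "OG", res_j = 11, atom_j = "NE2",
                          state = "closed", occupancy = 1)
  ens <- plant_interactions(sim$ensemble, sim$labels, rules, seed = 9)
  occ_a <- interaction_occupancy(ens, sim$labels, detect = "hbond", heavy_only = TRUE)
  occ_b <- interaction_occupancy(sim$ensemble, sim$labels, detect = "hbond",
                                 heavy_only = TRUE)
  diff <- network_difference(occ_a, occ_b, "closed")
  proj <- residue_projection(diff)
  expect_equal(sum(proj$score), 2 * sum(abs(diff$delta)), tolerance = 1e-12)
  expect_equal(nrow(residue_projection(diff[0, ])), 0)
})

test_that("conflicting planting rules on one atom are rejected", {
  sim <- quick_sim(seed = 261, n_replicas = 1, n_frames = 10, atoms = "full",
                   n_residues = 10, loop_start = 4, loop_end = 7,
                   sequence = c(rep("ALA", 3), "SER", rep("ALA", 5), "GLN"))
  rules <- tibble::tibble(res_i = c(4, 5), atom_i = c("OG", "O"),
                          res_j = c(10, 10), atom_j = "NE2",
                          state = "closed", occupancy = 1)
  expect_error(plant_interactions(sim$ensemble, sim$labels, rules),
               class = "loopshift_error_conflicting_rules")
})
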