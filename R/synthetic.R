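#' Row-stochastic transition matrix with a prescribed stationary law
#'
#' Builds `P = (1 - mixing) I + mixing 1 pi^T`: with probability `mixing`
#' the chain redraws its state from `pi`, otherwise it stays. The
#' stationary distribution is exactly `pi` for any `mixing` in `(0, 1]`,
#' which makes ground-truth populations available in closed form.
#'
#' @param pi Stationary probabilities (non-negative, summing to 1) over the
#'   states `closed, open, wide_open` (length 3) or including `other`
#'   (length 4).
#' @param mixing Redraw probability per step (default 0.05).
#' @return Row-stochastic matrix with dimnames set to the state names.
#' @export
stationary_transition_matrix <- function(pi, mixing = 0.05) {
  pi <- pi / sum(pi)
  k <- length(pi)
  states <- state_levels[seq_len(k)]
  P <- (1 - mixing) * diag(k) + mixing * matrix(pi, k, k, byrow = TRUE)
  dimnames(P) <- list(states, states)
  P
}

#' Stationary distribution of a transition matrix (eigen-analysis)
#'
#' Left Perron eigenvector of a row-stochastic matrix, normalised to sum
#' to 1. Used as the independent oracle for empirical state populations.
#'
#' @param P Row-stochastic square matrix.
#' @return Named probability vector.
#' @export
stationary_distribution <- function(P) {
  if (any(abs(rowSums(P) - 1) > 1e-12)) {
    ls_abort("transition matrix rows must sum to 1",
             class = "loopshift_error_bad_spec")
  }
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  stats::setNames(v, rownames(P))
}

#' Specification of a synthetic mobile-loop system
#'
#' Describes the protein-with-mobile-loop model the generator emulates: a
#' rigid helical scaffold whose loop residues interconvert among closed /
#' open / wide-open reference geometries under a discrete-state Markov
#' chain, with independent Gaussian positional noise per frame. Defaults
#' follow the study conditions the pipeline targets: 15 replicas of 5000
#' frames 100 ps apart, and a closed-to-wide-open loop displacement of
#' 10 Angstrom.
#'
#' @param n_residues Number of residues in the chain (default 60).
#' @param loop_start,loop_end Residue span of the mobile loop (default
#'   25-34).
#' @param displacement Maximal closed-to-wide-open Calpha displacement in
#'   Angstrom (default 10).
#' @param noise_sigma Per-axis Gaussian positional noise, Angstrom
#'   (default 0.3).
#' @param sigma_overrides Optional named vector (names = residue indices)
#'   of per-residue noise sigmas, for planting flexibility differences.
#' @param transition_matrix Row-stochastic state-transition matrix; default
#'   [stationary_transition_matrix()] with uniform stationary law.
#' @param n_replicas,n_frames Ensemble size (defaults 15 and 5000).
#' @param frame_interval_ps Frame spacing, ps (default 100).
#' @param atoms `"calpha"` for a Calpha-only model or `"full"` for a
#'   reduced all-atom model (N, CA, C, O, CB and one sidechain tip atom
#'   per residue, enough for dihedrals and interaction detection).
#' @param sequence Optional 3-letter residue codes (length `n_residues`);
#'   default all `"ALA"`.
#' @param start_state Initial chain state, or `"stationary"` to draw it
#'   from the stationary law (default `"stationary"`).
#' @param seed Integer seed; all generator output is a pure function of
#'   the spec including this seed.
#' @return A validated spec (list, class `loop_system_spec`).
#' @export
loop_system_spec <- function(n_residues = 60, loop_start = 25, loop_end = 34,
                             displacement = 10, noise_sigma = 0.3,
                             sigma_overrides = NULL,
                             transition_matrix = stationary_transition_matrix(rep(1 / 3, 3)),
                             n_replicas = 15, n_frames = 5000,
                             frame_interval_ps = 100,
                             atoms = c("calpha", "full"),
                             sequence = NULL,
                             start_state = "stationary",
                             seed = 1) {
  atoms <- match.arg(atoms)
  if (loop_start > loop_end || loop_start < 2 || loop_end >= n_residues) {
    ls_abort("loop span must be non-empty and inside the chain",
             class = "loopshift_error_bad_spec")
  }
  if (noise_sigma < 0 || displacement < 0) {
    ls_abort("noise_sigma and displacement must be >= 0",
             class = "loopshift_error_bad_spec")
  }
  if (any(abs(rowSums(transition_matrix) - 1) > 1e-12)) {
    ls_abort("transition matrix rows must sum to 1",
             class = "loopshift_error_bad_spec")
  }
  if (is.null(rownames(transition_matrix))) {
    states <- state_levels[seq_len(nrow(transition_matrix))]
    dimnames(transition_matrix) <- list(states, states)
  }
  sequence <- sequence %||% rep("ALA", n_residues)
  stopifnot(length(sequence) == n_residues)
  structure(list(n_residues = n_residues, loop_start = loop_start,
                 loop_end = loop_end, displacement = displacement,
                 noise_sigma = noise_sigma, sigma_overrides = sigma_overrides,
                 transition_matrix = transition_matrix,
                 n_replicas = n_replicas, n_frames = n_frames,
                 frame_interval_ps = frame_interval_ps, atoms = atoms,
                 sequence = sequence, start_state = start_state, seed = seed),
            class = "loop_system_spec")
}

# one sidechain tip atom per residue type (reduced representation)
tip_atom_names <- c(SER = "OG", THR = "OG1", TYR = "OH", CYS = "SG",
                    TRP = "NE1", LYS = "NZ", ARG = "NH1", GLN = "NE2",
                    ASN = "ND2", HIS = "NE2", ASP = "OD1", GLU = "OE1",
                    MET = "SD")

# scaffold geometry: ideal helical Calpha trace with backbone and sidechain
# pseudo-atoms placed from local geometry
scaffold_coords <- function(spec) {
  n <- spec$n_residues
  theta <- (seq_len(n) - 1) * 100 * pi / 180
  ca <- cbind(2.3 * cos(theta), 2.3 * sin(theta), 1.5 * (seq_len(n) - 1))
  out_dir <- cbind(cos(theta), sin(theta), 0)  # radial, unit
  if (spec$atoms == "calpha") {
    return(list(ca = ca, out_dir = out_dir))
  }
  prev <- rbind(ca[1, ] - (ca[2, ] - ca[1, ]), ca[-n, ])
  nxt <- rbind(ca[-1, ], ca[n, ] + (ca[n, ] - ca[n - 1, ]))
  N <- ca + 0.38 * (prev - ca) + 0.25 * out_dir
  C <- ca + 0.38 * (nxt - ca) + 0.25 * out_dir
  O <- C + 1.23 * out_dir
  CB <- ca + 1.53 * out_dir
  tip <- ca + 2.6 * out_dir
  list(ca = ca, N = N, C = C, O = O, CB = CB, tip = tip, out_dir = out_dir)
}

#' Build the three loop reference states and their shared topology
#'
#' The scaffold is identical across states; loop residues are displaced
#' rigidly along a smooth arc whose maximal Calpha displacement is 0
#' (closed), half scale (open), and the full displacement scale
#' (wide-open). Deterministic given the spec.
#'
#' @param spec A [loop_system_spec()].
#' @return List with `topology` and `references` (named list of three
#'   [reference_state()]s with loop and fit selections attached).
#' @export
make_reference_states <- function(spec) {
  geo <- scaffold_coords(spec)
  n <- spec$n_residues
  loop <- seq(spec$loop_start, spec$loop_end)
  seq3 <- spec$sequence
  rows <- list()
  add <- function(name, res, coords, element = NULL) {
    rows[[length(rows) + 1]] <<- tibble(
      atom_name = name, residue_index = res,
      residue_name = seq3[res], chain_id = "A",
      x = coords[1], y = coords[2], z = coords[3])
  }
  for (i in seq_len(n)) {
    if (spec$atoms == "full") {
      add("N", i, geo$N[i, ])
      add("CA", i, geo$ca[i, ])
      add("C", i, geo$C[i, ])
      add("O", i, geo$O[i, ])
      if (seq3[i] != "GLY") add("CB", i, geo$CB[i, ])
      tip <- tip_atom_names[seq3[i]]
      if (!is.na(tip)) add(tip, i, geo$tip[i, ])
    } else {
      add("CA", i, geo$ca[i, ])
    }
  }
  tab <- bind_rows(rows)
  tab$atom_id <- seq_len(nrow(tab))
  top <- topology(tab[, c("atom_id", "atom_name", "residue_index",
                          "residue_name", "chain_id")])
  base <- unname(as.matrix(tab[, c("x", "y", "z")]))
  # smooth displacement arc over the loop, normalised so the peak equals
  # the displacement scale exactly
  t_loop <- (loop - spec$loop_start + 1) / (length(loop) + 1)
  wgt <- sin(pi * t_loop)
  wgt <- wgt / max(wgt)
  bump_of <- function(scale) {
    shift <- matrix(0, nrow(tab), 3)
    for (k in seq_along(loop)) {
      sel <- tab$residue_index == loop[k]
      shift[sel, ] <- matrix(scale * wgt[k] * geo$out_dir[loop[k], ],
                             sum(sel), 3, byrow = TRUE)
    }
    base + shift
  }
  loop_sel <- select_atoms(top, atom_names = "CA", residue_index = loop,
                           label = "loop CA")
  fit_sel <- select_atoms(top, atom_names = "CA", exclude_residues = loop,
                          label = "non-loop CA")
  refs <- list(
    closed = reference_state("closed", top, bump_of(0), loop_sel, fit_sel),
    open = reference_state("open", top, bump_of(spec$displacement / 2),
                           loop_sel, fit_sel),
    wide_open = reference_state("wide_open", top, bump_of(spec$displacement),
                                loop_sel, fit_sel)
  )
  list(topology = top, references = refs)
}

# simulate one Markov chain path of length n from transition matrix P
markov_path <- function(P, n, start) {
  k <- nrow(P)
  path <- integer(n)
  path[1] <- start
  if (n == 1) return(path)
  u <- stats::runif(n)
  cum <- t(apply(P, 1, cumsum))
  for (t in 2:n) {
    path[t] <- findInterval(u[t], cum[path[t - 1], ]) + 1L
  }
  path
}

#' Simulate a multi-replica loop ensemble with known state labels
#'
#' Per replica, a discrete-state Markov chain over closed / open /
#' wide_open decides which reference geometry each frame is built from;
#' frame coordinates are that reference plus independent per-atom Gaussian
#' noise (per-residue sigma overrides plant flexibility differences). The
#' true labels are returned alongside the ensemble, so every downstream
#' stage can be checked against ground truth. Fully deterministic given
#' the spec's seed (each replica draws from a sub-seed via
#' [derive_seeds()]).
#'
#' @param spec A [loop_system_spec()].
#' @param refs Output of [make_reference_states()] for `spec` (built on the
#'   fly if omitted).
#' @return List with `ensemble` (a [replica_ensemble()]), `labels` (tibble
#'   `(replica, frame, label)` of true states), `references`, `topology`.
#' @export
simulate_loop_ensemble <- function(spec, refs = NULL) {
  refs <- refs %||% make_reference_states(spec)
  top <- refs$topology
  ref_coords <- lapply(refs$references, function(r) r$coords)
  P <- spec$transition_matrix
  k <- nrow(P)
  pi_stat <- stationary_distribution(P)
  n_atoms <- nrow(top)
  sig <- rep(spec$noise_sigma, n_atoms)
  if (!is.null(spec$sigma_overrides)) {
    ridx <- as.integer(names(spec$sigma_overrides))
    hit <- match(top$residue_index, ridx)
    sig[!is.na(hit)] <- spec$sigma_overrides[hit[!is.na(hit)]]
  }
  coords <- array(0, dim = c(n_atoms, 3, spec$n_frames, spec$n_replicas))
  labels <- matrix(0L, spec$n_frames, spec$n_replicas)
  seeds <- derive_seeds(spec$seed, spec$n_replicas)
  for (r in seq_len(spec$n_replicas)) {
    set.seed(seeds[r])
    start <- if (identical(spec$start_state, "stationary")) {
      sample.int(k, 1, prob = pi_stat)
    } else {
      match(spec$start_state, rownames(P))
    }
    path <- markov_path(P, spec$n_frames, start)
    labels[, r] <- path
    noise <- array(stats::rnorm(n_atoms * 3 * spec$n_frames, sd = sig),
                   dim = c(n_atoms, 3, spec$n_frames))
    for (f in seq_len(spec$n_frames)) {
      coords[, , f, r] <- ref_coords[[path[f]]] + noise[, , f]
    }
  }
  ens <- replica_ensemble(top, coords, spec$frame_interval_ps)
  lab <- tibble(replica = rep(seq_len(spec$n_replicas), each = spec$n_frames),
                frame = rep(seq_len(spec$n_frames), times = spec$n_replicas),
                label = factor(rownames(P)[as.integer(labels)],
                               levels = state_levels))
  list(ensemble = ens, labels = lab, references = refs$references,
       topology = top)
}

#' Plant state-conditioned interactions into an ensemble
#'
#' In frames whose true label matches a rule's state, the rule's second
#' atom is moved (with the given per-frame probability) to ideal
#' hydrogen-bonding distance (2.9 Angstrom) from the first atom, and
#' otherwise pushed beyond detection range (6.5 Angstrom). Each atom may
#' appear in at most one rule.
#'
#' @param ensemble A [replica_ensemble()].
#' @param labels True state labels, as from [simulate_loop_ensemble()].
#' @param rules Tibble with columns `res_i, atom_i, res_j, atom_j, state,
#'   occupancy` (chain A assumed).
#' @param seed Integer seed for the per-frame Bernoulli draws.
#' @return The modified [replica_ensemble()].
#' @export
plant_interactions <- function(ensemble, labels, rules, seed = 1) {
  rules <- as_tibble(rules)
  if (any(rules$occupancy < 0 | rules$occupancy > 1)) {
    ls_abort("occupancies must lie in [0, 1]", class = "loopshift_error_bad_spec")
  }
  top <- ensemble$topology
  row_of <- function(res, name) {
    w <- which(top$residue_index == res & top$atom_name == name)
    if (length(w) == 0) {
      ls_abort(sprintf("rule atom %s of residue %d not in topology", name, res),
               class = "loopshift_error_selection_mismatch")
    }
    w[1]
  }
  moved <- paste(rules$res_j, rules$atom_j)
  anchors <- paste(rules$res_i, rules$atom_i)
  if (anyDuplicated(moved) || any(moved %in% anchors)) {
    ls_abort("conflicting rules: an atom may appear in at most one rule",
             class = "loopshift_error_conflicting_rules")
  }
  seeds <- derive_seeds(seed, nrow(rules))
  lab_mat <- matrix(as.character(labels$label), ensemble$n_frames,
                    ensemble$n_replicas)
  for (k in seq_len(nrow(rules))) {
    set.seed(seeds[k])
    ri <- row_of(rules$res_i[k], rules$atom_i[k])
    rj <- row_of(rules$res_j[k], rules$atom_j[k])
    for (r in seq_len(ensemble$n_replicas)) {
      frames <- which(lab_mat[, r] == rules$state[k])
      if (length(frames) == 0) next
      present <- stats::runif(length(frames)) < rules$occupancy[k]
      for (idx in seq_along(frames)) {
        f <- frames[idx]
        pi_ <- ensemble$coords[ri, , f, r]
        pj <- ensemble$coords[rj, , f, r]
        dir <- pj - pi_
        nrm <- sqrt(sum(dir^2))
        if (nrm < 1e-8) dir <- c(1, 0, 0) else dir <- dir / nrm
        d <- if (present[idx]) 2.9 else 6.5
        ensemble$coords[rj, , f, r] <- pi_ + d * dir
      }
    }
  }
  ensemble
}

#' Specification of a two-diabat EVB model system
#'
#' Harmonic diabats `V1 = k1/2 (x - x01)^2` and `V2 = k2/2 (x - x02)^2 +
#' dE` on a 1-D coordinate, with constant coupling `h12` and gas shift
#' `alpha`, sampled over a ladder of mapping windows by Metropolis Monte
#' Carlo. Defaults give a 51-window ladder at 298 K.
#'
#' @param k1,k2 Force constants, kcal/mol/A^2 (default 100).
#' @param x01,x02 Diabat minima (defaults -0.5 and 0.5).
#' @param dE Product-minimum offset, kcal/mol (default 0).
#' @param h12 Coupling, kcal/mol (default 2).
#' @param alpha Gas shift added to V2, kcal/mol (default 0).
#' @param n_windows Number of evenly spaced lambda windows (default 51).
#' @param samples_per_window Recorded samples per window (default 1000).
#' @param burn_in Discarded equilibration steps per window (default 200).
#' @param temperature Kelvin (default 298).
#' @param seed Integer seed.
#' @return List of class `diabat_spec`.
#' @export
diabat_spec <- function(k1 = 100, k2 = 100, x01 = -0.5, x02 = 0.5, dE = 0,
                        h12 = 2, alpha = 0, n_windows = 51,
                        samples_per_window = 1000, burn_in = 200,
                        temperature = 298, seed = 1) {
  if (k1 <= 0 || k2 <= 0) {
    ls_abort("force constants must be > 0", class = "loopshift_error_bad_spec")
  }
  if (samples_per_window <= 0) {
    ls_abort("samples_per_window must be > 0", class = "loopshift_error_bad_spec")
  }
  structure(list(k1 = k1, k2 = k2, x01 = x01, x02 = x02, dE = dE,
                 h12 = h12, alpha = alpha,
                 lambdas = seq(0, 1, length.out = n_windows),
                 samples_per_window = samples_per_window, burn_in = burn_in,
                 temperature = temperature, seed = seed),
            class = "diabat_spec")
}

diabat_v1 <- function(spec, x) 0.5 * spec$k1 * (x - spec$x01)^2
diabat_v2 <- function(spec, x) 0.5 * spec$k2 * (x - spec$x02)^2 + spec$dE

#' Sample a mapping series from a diabat spec
#'
#' All windows advance as parallel Metropolis chains on their mapping
#' potentials `E_m(x) = (1 - lambda_m) V1 + lambda_m (V2 + alpha)`, each
#' started at its mapping-potential minimum; burn-in is discarded. Emitted
#' per frame are the diabatic energies `(E1, E2) = (V1(x), V2(x))`.
#' Bit-identical across runs for the same spec.
#'
#' @param spec A [diabat_spec()].
#' @return Mapping-series tibble `(window, lambda, frame, e1, e2)` with the
#'   acceptance rate per window in `attr(, "acceptance")`.
#' @export
simulate_mapping_series <- function(spec) {
  lam <- spec$lambdas
  M <- length(lam)
  kT <- KB_KCAL * spec$temperature
  e_map <- function(x, l) (1 - l) * diabat_v1(spec, x) +
    l * (diabat_v2(spec, x) + spec$alpha)
  # start each chain at the analytic minimum of its mapping potential
  kmix <- (1 - lam) * spec$k1 + lam * spec$k2
  x <- ((1 - lam) * spec$k1 * spec$x01 + lam * spec$k2 * spec$x02) / kmix
  step <- 2.4 * sqrt(kT / max(spec$k1, spec$k2))
  set.seed(spec$seed)
  n_keep <- spec$samples_per_window
  total <- spec$burn_in + n_keep
  kept <- matrix(0, n_keep, M)
  acc <- numeric(M)
  e_cur <- e_map(x, lam)
  for (it in seq_len(total)) {
    prop <- x + step * stats::rnorm(M)
    e_prop <- e_map(prop, lam)
    take <- stats::runif(M) < exp(-(e_prop - e_cur) / kT)
    x[take] <- prop[take]
    e_cur[take] <- e_prop[take]
    if (it > spec$burn_in) {
      kept[it - spec$burn_in, ] <- x
      acc <- acc + take
    }
  }
  out <- tibble(window = rep(seq_len(M), each = n_keep),
                lambda = rep(lam, each = n_keep),
                frame = rep(seq_len(n_keep), times = M),
                e1 = diabat_v1(spec, as.numeric(kept)),
                e2 = diabat_v2(spec, as.numeric(kept)))
  attr(out, "acceptance") <- acc / n_keep
  attr(out, "temperature") <- spec$temperature
  out
}

#' Dense-grid oracle for the EVB barrier of a diabat spec
#'
#' Evaluates the adiabatic ground surface `E_g(x)` on a dense grid
#' (spacing at most 1e-3 of the domain) and reads off the interior
#' barrier relative to the reactant (lower-x) minimum and the
#' product-minimum offset. Independent of the umbrella estimator.
#'
#' @param spec A [diabat_spec()].
#' @return List `(dg_activation, dg_reaction, x_ts)`.
#' @export
analytic_barrier <- function(spec) {
  lo <- min(spec$x01, spec$x02) - 1.5
  hi <- max(spec$x01, spec$x02) + 1.5
  x <- seq(lo, hi, length.out = 4001)
  eg <- evb_ground_energy(diabat_v1(spec, x), diabat_v2(spec, x),
                          spec$h12, spec$alpha)
  ext <- profile_extrema(x, eg)
  list(dg_activation = ext$barrier - ext$reactant_min,
       dg_reaction = ext$product_min - ext$reactant_min,
       x_ts = ext$x_ts)
}

#' Simulate per-residue LRA group-energy series
#'
#' Draws `u_ts - u_rs` as `Normal(effect_i, noise_sd^2)` independently per
#' frame for both the RS and TS endpoint ensembles; the expected LRA
#' contribution of residue `i` is then `effect_i / epsilon_in`.
#'
#' @param n_frames Frames per ensemble.
#' @param effects Named numeric vector (names = residue indices) of mean
#'   perturbation energies, kcal/mol.
#' @param noise_sd Per-frame noise standard deviation (default 1).
#' @param seed Integer seed.
#' @return Group-energy tibble `(ensemble, frame, residue_index, u_rs,
#'   u_ts)`.
#' @export
simulate_group_energies <- function(n_frames, effects, noise_sd = 1, seed = 1) {
  if (noise_sd < 0) {
    ls_abort("noise_sd must be >= 0", class = "loopshift_error_bad_spec")
  }
  set.seed(seed)
  ridx <- as.integer(names(effects))
  grid <- tidyr::crossing(ensemble = c("RS", "TS"), frame = seq_len(n_frames),
                          residue_index = ridx)
  grid |>
    mutate(u_rs = stats::rnorm(n(), 0, 1),
           du = stats::rnorm(n(), effects[match(.data$residue_index, ridx)],
                             noise_sd),
           u_ts = .data$u_rs + .data$du) |>
    select(-"du")
}

#' Replicate RMSF values drawn from the estimator's exact null law
#'
#' Under isotropic per-axis Gaussian noise with standard deviation
#' `sigma`, the RMSF estimator over `F` frames satisfies `RMSF^2 =
#' sigma^2 chi^2_{3(F-1)} / F`. This draws per-replica, per-residue RMSF
#' values directly from that law -- the same distribution the full
#' coordinate pipeline produces for a rigid scaffold -- so large
#' statistical calibrations (many simulated cohorts) are cheap.
#'
#' @param n_replicas Number of replicas.
#' @param n_frames Frames per replica (`F` above).
#' @param sigma Per-residue noise sigma (vector, one per residue).
#' @param residue_index Residue labels (default `seq_along(sigma)`).
#' @return An `rmsf_matrix` tibble `(replica, residue_index, rmsf)`.
#' @export
simulate_rmsf_replicates <- function(n_replicas, n_frames, sigma,
                                     residue_index = seq_along(sigma)) {
  n_res <- length(sigma)
  out <- tibble(
    replica = rep(seq_len(n_replicas), each = n_res),
    residue_index = rep(residue_index, times = n_replicas),
    rmsf = rep(sigma, times = n_replicas) *
      sqrt(stats::rchisq(n_replicas * n_res, df = 3 * (n_frames - 1)) / n_frames)
  )
  attr(out, "alignment_spec") <- "closed-form null draw (no alignment)"
  class(out) <- c("rmsf_matrix", class(out))
  out
}
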