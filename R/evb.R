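KB_KCAL <- 0.0019872041  # Boltzmann constant, kcal/mol/K

#' EVB mapping potential
#'
#' Linear mixing of the two diabatic energies, `E_m = (1 - lambda) E1 +
#' lambda E2`, the potential that drives sampling from reactant (`lambda =
#' 0`) to product (`lambda = 1`).
#'
#' @param e1,e2 Diabatic energies, kcal/mol (vectorised).
#' @param lam Mixing parameter in `[0, 1]`.
#' @return `E_m` in kcal/mol.
#' @export
mapping_energy <- function(e1, e2, lam) {
  if (any(lam < 0 | lam > 1)) {
    ls_abort("lambda must lie in [0, 1]", class = "loopshift_error_bad_lambda")
  }
  (1 - lam) * e1 + lam * e2
}

#' Adiabatic EVB ground-state energy
#'
#' Lower eigenvalue of the two-state EVB Hamiltonian with constant
#' off-diagonal coupling: `E_g = (E1 + E2')/2 - sqrt(((E1 - E2')/2)^2 +
#' H12^2)` with `E2' = E2 + alpha` (gas-phase shift).
#'
#' @param e1,e2 Diabatic energies, kcal/mol (vectorised).
#' @param h12 Off-diagonal coupling, kcal/mol, `>= 0`.
#' @param alpha Gas-phase shift added to `e2` (default 0).
#' @return Ground-state energy, kcal/mol. Always `<= min(e1, e2 + alpha)`,
#'   with equality iff `h12 = 0`.
#' @export
evb_ground_energy <- function(e1, e2, h12, alpha = 0) {
  if (any(h12 < 0)) {
    ls_abort("H12 must be >= 0", class = "loopshift_error_bad_spec")
  }
  e2p <- e2 + alpha
  0.5 * (e1 + e2p) - sqrt(0.25 * (e1 - e2p)^2 + h12^2)
}

# validate / normalise a mapping series tibble
check_mapping_series <- function(series) {
  series <- as_tibble(series)
  need <- c("window", "lambda", "frame", "e1", "e2")
  if (!all(need %in% names(series))) {
    ls_abort(paste("mapping series needs columns:", paste(need, collapse = ", ")),
             class = "loopshift_error_malformed_table")
  }
  lam <- series |> distinct(.data$window, .data$lambda) |> arrange(.data$window)
  if (any(diff(lam$lambda) <= 0)) {
    ls_abort("window lambdas must be strictly increasing",
             class = "loopshift_error_bad_lambda")
  }
  if (abs(lam$lambda[1]) > 1e-12 || abs(lam$lambda[nrow(lam)] - 1) > 1e-12) {
    ls_abort("lambda ladder must span 0 and 1", class = "loopshift_error_bad_lambda")
  }
  if (!all(is.finite(series$e1)) || !all(is.finite(series$e2))) {
    ls_abort("diabatic energies must be finite", class = "loopshift_error_bad_coords")
  }
  list(series = series, lambdas = lam$lambda, windows = lam$window)
}

# overflow-guarded -kT log mean exp(-du/kT)
log_mean_exp_dg <- function(du, kT) {
  s <- min(du)
  s - kT * log(mean(exp(-(du - s) / kT)))
}

#' Free-energy ladder over the mapping windows (Zwanzig / FEP)
#'
#' Between adjacent windows the free-energy increment is the exponential
#' average `dG(m -> m+1) = -kT log < exp(-(E_{m+1} - E_m)/kT) >_m`, with
#' `E_m` the mapping energies of window `m`'s frames; the cumulative sum is
#' anchored at `lambda = 0`. Both the forward and the reverse (evaluated in
#' window `m+1`'s ensemble) estimates are reported; their agreement is the
#' standard overlap diagnostic.
#'
#' @param series Mapping series: tibble `(window, lambda, frame, e1, e2)`
#'   with strictly increasing lambdas spanning `[0, 1]`.
#' @param temperature Temperature in K (default 298).
#' @return Tibble of class `fep_ladder`: `(window, lambda, dg_forward,
#'   dg_reverse)` cumulative free energies anchored at 0 for `lambda = 0`.
#' @export
fep_ladder <- function(series, temperature = 298) {
  chk <- check_mapping_series(series)
  series <- chk$series
  lambdas <- chk$lambdas; windows <- chk$windows
  if (length(lambdas) < 2) {
    ls_abort("need at least 2 windows", class = "loopshift_error_bad_lambda")
  }
  kT <- KB_KCAL * temperature
  sizes <- series |> count(.data$window)
  if (any(sizes$n < 10)) {
    rlang::warn("some mapping windows have fewer than 10 frames")
  }
  by_win <- split(series[, c("e1", "e2")], factor(series$window, levels = windows))
  M <- length(lambdas)
  inc_fwd <- inc_rev <- numeric(M - 1)
  for (m in seq_len(M - 1)) {
    wm <- by_win[[m]]; wn <- by_win[[m + 1]]
    # forward: perturb window m's frames to window m+1's potential
    du_f <- mapping_energy(wm$e1, wm$e2, lambdas[m + 1]) -
      mapping_energy(wm$e1, wm$e2, lambdas[m])
    inc_fwd[m] <- log_mean_exp_dg(du_f, kT)
    # reverse: perturb window m+1's frames back to window m's potential
    du_r <- mapping_energy(wn$e1, wn$e2, lambdas[m]) -
      mapping_energy(wn$e1, wn$e2, lambdas[m + 1])
    inc_rev[m] <- log_mean_exp_dg(du_r, kT)
  }
  out <- tibble(window = windows, lambda = lambdas,
                dg_forward = c(0, cumsum(inc_fwd)),
                dg_reverse = c(0, cumsum(-inc_rev)))
  attr(out, "temperature") <- temperature
  class(out) <- c("fep_ladder", class(out))
  out
}

#' EVB free-energy profile along the energy-gap coordinate
#'
#' Standard umbrella reconstruction: with the gap coordinate `x = E1 -
#' (E2 + alpha)` (reactant at negative `x`), each window `m` contributes
#' `dg(x_b) = dG_m - kT log < 1{x in b} exp(-(E_g - E_m)/kT) >_m` to every
#' bin it visits; overlapping windows are combined by count weighting. The
#' activation free energy is the profile maximum between the reactant and
#' product minima relative to the reactant minimum, and the reaction free
#' energy the product-minimum offset.
#'
#' @param series Mapping series as in [fep_ladder()].
#' @param h12 Off-diagonal coupling, kcal/mol.
#' @param alpha Gas-phase shift added to `e2` (default 0).
#' @param ladder Optional precomputed [fep_ladder()] for `series`.
#' @param n_bins Number of gap-coordinate bins (default 80; fine enough
#'   that bin-width discretisation bias of the extrema is negligible while
#'   keeping per-bin occupancy well above `min_count` at the default
#'   sampling).
#' @param temperature Temperature in K (default 298).
#' @param min_count Bins entered by fewer frames are dropped (default 10).
#' @return Tibble of class `free_energy_profile`: `(bin_center, dg,
#'   count)`, with `dg` shifted so the reactant minimum is 0 and
#'   attributes `dg_activation`, `dg_reaction`, `x_ts`.
#' @export
umbrella_profile <- function(series, h12, alpha = 0, ladder = NULL,
                             n_bins = 80, temperature = 298, min_count = 10) {
  chk <- check_mapping_series(series)
  series <- chk$series
  lambdas <- chk$lambdas; windows <- chk$windows
  if (is.null(ladder)) ladder <- fep_ladder(series, temperature)
  kT <- KB_KCAL * temperature
  x <- series$e1 - (series$e2 + alpha)
  edges <- seq(min(x), max(x), length.out = n_bins + 1)
  bin <- pmin(findInterval(x, edges, rightmost.closed = TRUE), n_bins)
  eg <- evb_ground_energy(series$e1, series$e2, h12, alpha)
  em <- mapping_energy(series$e1, series$e2,
                       lambdas[match(series$window, windows)])
  dg_m <- ladder$dg_forward[match(series$window, ladder$window)]
  wexp <- -(eg - em) / kT
  # per (window, bin): dG_m - kT log mean(1{bin} exp(...)), count-weighted
  dat <- tibble(window = series$window, bin = bin, wexp = wexp, dg_m = dg_m)
  win_n <- dat |> count(.data$window, name = "n_win")
  contrib <- dat |>
    group_by(.data$window, .data$bin) |>
    summarise(dg_m = first(.data$dg_m),
              n_bin = n(),
              lse = {
                s <- max(.data$wexp)
                s + log(sum(exp(.data$wexp - s)))
              },
              .groups = "drop") |>
    left_join(win_n, by = "window") |>
    mutate(dg_bin = .data$dg_m - KB_KCAL * temperature *
             (.data$lse - log(.data$n_win)))
  prof <- contrib |>
    group_by(.data$bin) |>
    summarise(dg = sum(.data$n_bin * .data$dg_bin) / sum(.data$n_bin),
              count = sum(.data$n_bin), .groups = "drop") |>
    filter(.data$count >= min_count) |>
    mutate(bin_center = (edges[.data$bin] + edges[.data$bin + 1]) / 2) |>
    arrange(.data$bin_center) |>
    select("bin_center", "dg", "count")
  if (nrow(prof) < 3) {
    ls_abort("too few populated bins for a profile",
             class = "loopshift_error_undersampled")
  }
  # require the barrier to stand clear of bin-level statistical ripple
  ext <- profile_extrema(prof$bin_center, prof$dg, prominence = 0.25)
  prof$dg <- prof$dg - ext$reactant_min
  attr(prof, "dg_activation") <- ext$barrier - ext$reactant_min
  attr(prof, "dg_reaction") <- ext$product_min - ext$reactant_min
  attr(prof, "x_ts") <- ext$x_ts
  attr(prof, "temperature") <- temperature
  attr(prof, "h12") <- h12
  attr(prof, "alpha") <- alpha
  class(prof) <- c("free_energy_profile", class(prof))
  prof
}

# locate reactant minimum (x < x_ts), interior barrier top, product minimum
# on a sampled profile; classed error when there is no interior barrier.
# `prominence` guards sampled profiles against statistical ripples being
# read as a barrier (0 for analytic grids)
profile_extrema <- function(x, g, prominence = 0) {
  n <- length(g)
  # interior local maxima
  is_max <- c(FALSE, g[2:(n - 1)] > g[1:(n - 2)] & g[2:(n - 1)] >= g[3:n], FALSE)
  cand <- which(is_max)
  # require points lower by at least `prominence` on both sides
  cand <- cand[vapply(cand, function(i) {
    min(g[1:(i - 1)]) < g[i] - prominence &&
      min(g[(i + 1):n]) < g[i] - prominence
  }, logical(1))]
  if (length(cand) == 0) {
    ls_abort("no interior barrier: free-energy profile is monotone",
             class = "loopshift_error_no_barrier")
  }
  top <- cand[which.max(g[cand])]
  # quadratic refinement of each extremum: the vertex of the parabola
  # through the discrete extremum and its neighbours removes the
  # bin-discretisation bias of reading extrema off bin centres
  vertex <- function(i) {
    if (i <= 1 || i >= n) return(g[i])
    denom <- g[i - 1] - 2 * g[i] + g[i + 1]
    if (abs(denom) < 1e-12) return(g[i])
    g[i] - (g[i - 1] - g[i + 1])^2 / (8 * denom)
  }
  i_r <- which.min(g[1:(top - 1)])
  i_p <- top + which.min(g[(top + 1):n])
  list(reactant_min = vertex(i_r),
       product_min = vertex(i_p),
       barrier = vertex(top),
       x_ts = x[top])
}

#' @export
glance.free_energy_profile <- function(x, ...) {
  tibble(dg_activation = attr(x, "dg_activation"),
         dg_reaction = attr(x, "dg_reaction"),
         x_ts = attr(x, "x_ts"),
         temperature = attr(x, "temperature"))
}

#' @export
tidy.free_energy_profile <- function(x, ...) as_tibble(x)

#' Linear-response-approximation per-residue electrostatic contributions
#'
#' For each residue `i`, the contribution to the activation barrier is the
#' LRA half-sum `0.5 * (<u_i^TS - u_i^RS>_RS + <u_i^TS - u_i^RS>_TS) /
#' epsilon_in`, where the perturbation energy is evaluated with both
#' charge sets on both endpoint ensembles and `epsilon_in` is the internal
#' dielectric scaling (default 4).
#'
#' @param series Tibble `(ensemble, frame, residue_index, u_rs, u_ts)`
#'   where `ensemble` is `"RS"` or `"TS"` and `u_rs`/`u_ts` are the
#'   interaction energies evaluated with reactant-state and
#'   transition-state charges, kcal/mol.
#' @param epsilon_in Internal dielectric constant, `> 0` (default 4).
#' @return Tibble `(residue_index, ddg_elec)` of class `lra_report`, with
#'   `epsilon_in` recorded as an attribute.
#' @export
lra_group_contribution <- function(series, epsilon_in = 4) {
  series <- as_tibble(series)
  need <- c("ensemble", "frame", "residue_index", "u_rs", "u_ts")
  if (!all(need %in% names(series))) {
    ls_abort(paste("LRA series needs columns:", paste(need, collapse = ", ")),
             class = "loopshift_error_malformed_table")
  }
  if (epsilon_in <= 0) {
    ls_abort("epsilon_in must be > 0", class = "loopshift_error_bad_spec")
  }
  ens <- unique(series$ensemble)
  if (!all(c("RS", "TS") %in% ens)) {
    ls_abort("both RS and TS ensembles are required",
             class = "loopshift_error_missing_state")
  }
  means <- series |>
    mutate(du = .data$u_ts - .data$u_rs) |>
    group_by(.data$residue_index, .data$ensemble) |>
    summarise(mean_du = mean(.data$du), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "ensemble", values_from = "mean_du")
  out <- means |>
    transmute(residue_index = .data$residue_index,
              ddg_elec = 0.5 * (.data$RS + .data$TS) / epsilon_in)
  attr(out, "epsilon_in") <- epsilon_in
  class(out) <- c("lra_report", class(out))
  out
}
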