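state_levels <- c("closed", "open", "wide_open", "other")

# join the three per-frame RMSD series, aborting if misaligned
join_rmsd_series <- function(rmsd_closed, rmsd_open, rmsd_wide_open) {
  a <- rename(as_tibble(rmsd_closed), rmsd_closed = "rmsd")
  b <- rename(as_tibble(rmsd_open), rmsd_open = "rmsd")
  c_ <- rename(as_tibble(rmsd_wide_open), rmsd_wide_open = "rmsd")
  j <- inner_join(a, b, by = c("replica", "frame")) |>
    inner_join(c_, by = c("replica", "frame"))
  if (nrow(j) != nrow(a) || nrow(j) != nrow(b) || nrow(j) != nrow(c_)) {
    ls_abort("RMSD series are not aligned on (replica, frame)",
             class = "loopshift_error_misaligned_series")
  }
  j
}

#' Label frames by loop conformational state
#'
#' Each frame is assigned the state whose reference it is closest to
#' (argmin of the three RMSDs), provided that RMSD is within the state's
#' cutoff; otherwise the frame is `other`. Exact ties are broken by the
#' fixed priority closed > open > wide_open, so labelling is deterministic.
#'
#' @param rmsd_closed,rmsd_open,rmsd_wide_open Tibbles `(replica, frame,
#'   rmsd)` as from [rmsd_series()], aligned on `(replica, frame)`.
#' @param cutoffs Named numeric vector of per-state RMSD cutoffs in
#'   Angstrom, names `closed`, `open`, `wide_open`. All default to 1.5.
#' @return Tibble `(replica, frame, label, rmsd_closed, rmsd_open,
#'   rmsd_wide_open)` of class `state_labels`; `label` is a factor over
#'   closed/open/wide_open/other. Cutoffs used are stored in
#'   `attr(, "thresholds_used")`.
#' @export
label_states <- function(rmsd_closed, rmsd_open, rmsd_wide_open,
                         cutoffs = c(closed = 1.5, open = 1.5, wide_open = 1.5)) {
  if (any(cutoffs <= 0) || !all(c("closed", "open", "wide_open") %in% names(cutoffs))) {
    ls_abort("cutoffs must be positive and named closed/open/wide_open",
             class = "loopshift_error_bad_spec")
  }
  j <- join_rmsd_series(rmsd_closed, rmsd_open, rmsd_wide_open)
  m <- cbind(j$rmsd_closed, j$rmsd_open, j$rmsd_wide_open)
  win <- max.col(-m, ties.method = "first")  # column order encodes tie priority
  win_rmsd <- m[cbind(seq_len(nrow(m)), win)]
  win_state <- state_levels[win]
  lab <- ifelse(win_rmsd <= cutoffs[win_state], win_state, "other")
  out <- j
  out$label <- factor(lab, levels = state_levels)
  out <- relocate(out, "replica", "frame", "label")
  attr(out, "thresholds_used") <- cutoffs
  class(out) <- c("state_labels", class(out))
  out
}

#' RMSD histogram with edges anchored at zero
#'
#' Uniform bins of width `bin_width` starting at 0.0 and extended to cover
#' the series maximum, so bin boundaries are reproducible across runs and
#' variants. Bins are left-closed, right-open, except the last which is
#' closed.
#'
#' @param series Numeric RMSD values, or a tibble with an `rmsd` column.
#' @param bin_width Bin width in Angstrom (default 0.16).
#' @return Tibble `(bin_lo, bin_hi, count, prob, density)` of class
#'   `loopshift_histogram`; `count` sums to the number of frames and `prob`
#'   to 1.
#' @export
rmsd_histogram <- function(series, bin_width = 0.16) {
  x <- if (is.data.frame(series)) series$rmsd else as.numeric(series)
  if (length(x) == 0) {
    ls_abort("empty RMSD series", class = "loopshift_error_empty_series")
  }
  if (bin_width <= 0) {
    ls_abort("bin_width must be > 0", class = "loopshift_error_bad_spec")
  }
  n_bins <- max(1L, as.integer(floor(max(x) / bin_width)) + 1L)
  edges <- seq(0, by = bin_width, length.out = n_bins + 1L)
  idx <- pmin(findInterval(x, edges, rightmost.closed = TRUE), n_bins)
  counts <- tabulate(idx, nbins = n_bins)
  out <- tibble(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                count = counts,
                prob = counts / length(x),
                density = counts / (length(x) * bin_width))
  attr(out, "bin_width") <- bin_width
  attr(out, "n") <- length(x)
  class(out) <- c("loopshift_histogram", class(out))
  out
}

#' Fraction of frames at or below an RMSD cutoff
#'
#' The comparison is inclusive (`rmsd <= cutoff`). Given a bare numeric
#' vector the pooled fraction is returned as a single number; given a
#' `(replica, frame, rmsd)` tibble, per-replica rows plus a `pooled` row
#' are returned.
#'
#' @param series Numeric vector or tibble `(replica, frame, rmsd)`.
#' @param cutoff Positive cutoff in Angstrom.
#' @return A number, or a tibble `(replica, n_frames, fraction)` in which
#'   `replica` is character and includes `"pooled"`.
#' @export
fraction_below <- function(series, cutoff) {
  if (cutoff <= 0) {
    ls_abort("cutoff must be > 0", class = "loopshift_error_bad_spec")
  }
  if (!is.data.frame(series)) {
    if (length(series) == 0) {
      ls_abort("empty RMSD series", class = "loopshift_error_empty_series")
    }
    return(mean(series <= cutoff))
  }
  if (nrow(series) == 0) {
    ls_abort("empty RMSD series", class = "loopshift_error_empty_series")
  }
  per <- series |>
    group_by(replica = as.character(.data$replica)) |>
    summarise(n_frames = n(), fraction = mean(.data$rmsd <= cutoff),
              .groups = "drop")
  bind_rows(per, tibble(replica = "pooled", n_frames = nrow(series),
                        fraction = mean(series$rmsd <= cutoff)))
}

#' Per-state populations with between-replica standard errors
#'
#' Pooled fractions are frame-weighted means over all frames; the standard
#' error of each pooled fraction is the between-replica standard deviation
#' of the per-replica fractions divided by `sqrt(n_replicas)` (replicas,
#' not frames, are the statistical unit).
#'
#' @param labels A `state_labels` tibble (or any tibble with `replica` and
#'   `label` columns).
#' @return Tibble `(state, pooled_fraction, se)` of class
#'   `state_populations`; per-replica fractions are in
#'   `attr(, "per_replica")`.
#' @export
state_populations <- function(labels) {
  if (nrow(labels) == 0) {
    ls_abort("empty label series", class = "loopshift_error_empty_series")
  }
  lab <- factor(labels$label, levels = state_levels)
  per <- tibble(replica = labels$replica, label = lab) |>
    count(.data$replica, .data$label, .drop = FALSE) |>
    group_by(.data$replica) |>
    mutate(fraction = .data$n / sum(.data$n)) |>
    ungroup() |>
    select(replica = "replica", state = "label", fraction = "fraction")
  n_rep <- length(unique(per$replica))
  pooled <- tibble(state = factor(state_levels, levels = state_levels),
                   pooled_fraction = as.numeric(
                     table(lab)[state_levels] / length(lab)))
  se <- per |>
    group_by(.data$state) |>
    summarise(se = stats::sd(.data$fraction) / sqrt(n_rep), .groups = "drop")
  se$se[is.na(se$se)] <- 0
  out <- left_join(pooled, se, by = "state")
  attr(out, "per_replica") <- per
  attr(out, "n_replicas") <- n_rep
  class(out) <- c("state_populations", class(out))
  out
}

#' @importFrom generics tidy
#' @export
tidy.state_populations <- function(x, ...) {
  attr(x, "per_replica")
}

#' @export
glance.state_populations <- function(x, ...) {
  wide <- stats::setNames(as.list(x$pooled_fraction), as.character(x$state))
  as_tibble(c(wide, list(n_replicas = attr(x, "n_replicas"))))
}

#' Productive-closure analysis over a terminal trajectory window
#'
#' For each replica, the mean RMSD-to-closed and the mean centre-of-mass
#' distance (e.g. catalytic arginine side chain to phospho-cysteine) over
#' the last `window` frames are computed; a replica is `closed` when its
#' mean RMSD is at or below `rmsd_cut` and `productive` when its mean
#' distance is at or below `dist_cut`. The joint table supports asking
#' whether closure occurs only in productive replicas.
#'
#' @param rmsd_closed Tibble `(replica, frame, rmsd)`.
#' @param com_dist Tibble `(replica, frame, dist)`, aligned with
#'   `rmsd_closed`.
#' @param window Number of terminal frames (e.g. the frames spanning the
#'   last 5 ns); must not exceed the trajectory length.
#' @param rmsd_cut,dist_cut Cutoffs in Angstrom.
#' @return Tibble `(replica, mean_rmsd, mean_dist, closed, productive)` of
#'   class `closure_outcome`, with the window and cutoffs in attributes.
#' @export
closure_analysis <- function(rmsd_closed, com_dist, window, rmsd_cut, dist_cut) {
  j <- inner_join(as_tibble(rmsd_closed), as_tibble(com_dist),
                  by = c("replica", "frame"))
  if (nrow(j) != nrow(rmsd_closed)) {
    ls_abort("RMSD and distance series are not aligned",
             class = "loopshift_error_misaligned_series")
  }
  n_frames <- j |> count(.data$replica) |> pull(n) |> min()
  if (window > n_frames || window < 1) {
    ls_abort(sprintf("window (%d) exceeds trajectory length (%d frames)",
                     window, n_frames),
             class = "loopshift_error_bad_window")
  }
  out <- j |>
    group_by(.data$replica) |>
    arrange(.data$frame, .by_group = TRUE) |>
    slice_tail(n = window) |>
    summarise(mean_rmsd = mean(.data$rmsd), mean_dist = mean(.data$dist),
              .groups = "drop") |>
    mutate(closed = .data$mean_rmsd <= rmsd_cut,
           productive = .data$mean_dist <= dist_cut)
  attr(out, "window") <- window
  attr(out, "cutoffs") <- c(rmsd = rmsd_cut, dist = dist_cut)
  class(out) <- c("closure_outcome", class(out))
  out
}
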