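#' Per-replica, per-residue RMSF
#'
#' For each replica, frames are superposed on the replica's mean structure
#' over the `fit` atoms using a two-pass scheme (align to the raw mean,
#' recompute the mean from the aligned frames, align once more), then
#' `RMSF_i = sqrt(mean_f |r_i(f) - <r_i>|^2)` is evaluated for each
#' selected atom (conventionally one Calpha per residue). Optionally only
#' frames carrying a given conformational-state label are used; replicas
#' losing all (or all but one) frames to the filter are dropped with a
#' warning.
#'
#' @param ensemble A [replica_ensemble()].
#' @param selection [atom_set()] of atoms whose RMSF is reported (one CA
#'   per residue for the standard per-residue profile).
#' @param fit [atom_set()] used for superposition; defaults to
#'   `selection`. Superposing on non-loop Calpha atoms isolates local
#'   fluctuations from global motion.
#' @param labels Optional `state_labels` tibble for state filtering.
#' @param state Optional state name; with `labels`, only frames in this
#'   state are used.
#' @return Tibble `(replica, residue_index, rmsf)` of class `rmsf_matrix`
#'   (Angstrom), with the alignment description in
#'   `attr(, "alignment_spec")`.
#' @export
rmsf_per_replica <- function(ensemble, selection, fit = NULL,
                             labels = NULL, state = NULL) {
  top <- ensemble$topology
  fit <- fit %||% selection
  sel_rows <- atom_rows(top, selection)
  fit_rows <- atom_rows(top, fit)
  res_idx <- top$residue_index[sel_rows]
  nR <- ensemble$n_replicas
  keep_frames <- function(r) {
    if (is.null(labels) || is.null(state)) return(seq_len(ensemble$n_frames))
    labels$frame[labels$replica == r & labels$label == state]
  }
  w <- rep(1, length(fit_rows))
  pieces <- list()
  dropped <- integer(0)
  for (r in seq_len(nR)) {
    frames <- keep_frames(r)
    if (length(frames) < 2) {
      dropped <- c(dropped, r)
      next
    }
    nf <- length(frames)
    raw <- ensemble$coords[, , frames, r, drop = FALSE]
    dim(raw) <- dim(raw)[1:3]
    # pass 1: align to the raw mean; pass 2: align to the mean of the
    # pass-1-aligned frames
    mean_ref <- apply(raw, c(1, 2), mean)
    aligned <- array(0, dim = dim(raw))
    for (pass in 1:2) {
      for (f in seq_len(nf)) {
        kab <- kabsch_core(raw[fit_rows, , f], mean_ref[fit_rows, , drop = FALSE], w)
        aligned[, , f] <- sweep(raw[, , f] %*% t(kab$rotation), 2,
                                kab$translation, `+`)
      }
      mean_ref <- apply(aligned, c(1, 2), mean)
    }
    dev2 <- sweep(aligned[sel_rows, , , drop = FALSE], c(1, 2),
                  mean_ref[sel_rows, , drop = FALSE])^2
    rmsf <- sqrt(apply(dev2, 1, sum) / nf)
    pieces[[length(pieces) + 1]] <- tibble(replica = r,
                                           residue_index = res_idx,
                                           rmsf = rmsf)
  }
  if (length(dropped) > 0) {
    rlang::warn(paste("replicas dropped by state filter (fewer than 2 frames):",
                      paste(dropped, collapse = ", ")))
  }
  if (length(pieces) < 2) {
    ls_abort("fewer than 2 replicas survive the state filter",
             class = "loopshift_error_too_few_replicas")
  }
  out <- bind_rows(pieces)
  attr(out, "alignment_spec") <- sprintf(
    "two-pass mean-structure fit on %d atoms (%s)%s",
    length(fit_rows), attr(fit, "label") %||% "fit selection",
    if (!is.null(state)) paste0("; frames restricted to state ", state) else "")
  class(out) <- c("rmsf_matrix", class(out))
  out
}

# residue axis of an rmsf_matrix, in first-appearance order
rmsf_residues <- function(mat) {
  unique(mat$residue_index)
}

check_rmsf_axes <- function(mat_a, mat_b) {
  if (!identical(rmsf_residues(mat_a), rmsf_residues(mat_b))) {
    ls_abort("RMSF matrices are on different residue axes",
             class = "loopshift_error_axis_mismatch")
  }
}

#' Per-residue mean RMSF difference between two variants
#'
#' Positive values mean the residue is more flexible in variant A.
#'
#' @param mat_a,mat_b `rmsf_matrix` tibbles on the same residue axis.
#' @return Tibble `(residue_index, mean_delta)`, Angstrom (A minus B).
#' @export
delta_rmsf <- function(mat_a, mat_b) {
  check_rmsf_axes(mat_a, mat_b)
  ma <- mat_a |> group_by(.data$residue_index) |>
    summarise(mean_a = mean(.data$rmsf), .groups = "drop")
  mb <- mat_b |> group_by(.data$residue_index) |>
    summarise(mean_b = mean(.data$rmsf), .groups = "drop")
  inner_join(ma, mb, by = "residue_index") |>
    transmute(residue_index = .data$residue_index,
              mean_delta = .data$mean_a - .data$mean_b)
}

# one two-sample t-test with the degenerate-variance convention:
# both groups constant and equal -> p = 1; constant but different -> p = 0
safe_ttest <- function(a, b, var_equal) {
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (isTRUE(all.equal(mean(a), mean(b)))) {
      return(list(statistic = 0, df = NA_real_, p_value = 1))
    }
    return(list(statistic = Inf * sign(mean(a) - mean(b)),
                df = NA_real_, p_value = 0))
  }
  tt <- stats::t.test(a, b, var.equal = var_equal)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}

#' Per-residue two-sided t-tests on replicate RMSF values
#'
#' Replicas are the statistical unit: for each residue, the per-replica
#' RMSF values of the two variants form the two samples. Welch's unequal-
#' variance test is the default; Student's pooled-variance test is
#' available for exactness checks.
#'
#' @param mat_a,mat_b `rmsf_matrix` tibbles on the same residue axis, each
#'   with at least 2 replicas.
#' @param variant `"welch"` (default) or `"student"`.
#' @return Tibble `(residue_index, statistic, df, p_value)`.
#' @export
per_residue_ttest <- function(mat_a, mat_b, variant = c("welch", "student")) {
  variant <- match.arg(variant)
  check_rmsf_axes(mat_a, mat_b)
  if (length(unique(mat_a$replica)) < 2 || length(unique(mat_b$replica)) < 2) {
    ls_abort("each group needs at least 2 replicas",
             class = "loopshift_error_too_few_replicas")
  }
  var_equal <- variant == "student"
  res <- rmsf_residues(mat_a)
  la <- split(mat_a$rmsf, factor(mat_a$residue_index, levels = res))
  lb <- split(mat_b$rmsf, factor(mat_b$residue_index, levels = res))
  rows <- purrr::map2(la, lb, function(a, b) safe_ttest(a, b, var_equal))
  tibble(residue_index = res,
         statistic = unname(purrr::map_dbl(rows, "statistic")),
         df = unname(purrr::map_dbl(rows, "df")),
         p_value = unname(purrr::map_dbl(rows, "p_value")))
}

#' Benjamini-Hochberg step-up control of the false discovery rate
#'
#' Flags are the classical step-up rule (reject the `k` smallest p-values
#' where `k` is the largest rank with `p_(k) <= k * fdr / m`); q-values are
#' the monotone-adjusted `p * m / rank`. Both are computed through
#' `stats::p.adjust(method = "BH")`, whose adjusted values make the step-up
#' rule equivalent to `q <= fdr`. Ties share ranks stably.
#'
#' @param p_values Numeric p-values in `[0, 1]`; `NA`/`NaN` are rejected.
#' @param fdr Target false discovery rate in `(0, 1)` (default 0.05).
#' @return Tibble `(p_value, q_value, significant)` in input order.
#' @export
benjamini_hochberg <- function(p_values, fdr = 0.05) {
  if (anyNA(p_values)) {
    ls_abort("NA/NaN p-values are not allowed", class = "loopshift_error_bad_pvalues")
  }
  if (any(p_values < 0 | p_values > 1)) {
    ls_abort("p-values must lie in [0, 1]", class = "loopshift_error_bad_pvalues")
  }
  if (fdr <= 0 || fdr >= 1) {
    ls_abort("fdr must lie in (0, 1)", class = "loopshift_error_bad_spec")
  }
  q <- stats::p.adjust(p_values, method = "BH")
  tibble(p_value = as.numeric(p_values), q_value = q, significant = q <= fdr)
}

#' Per-residue flexibility-difference significance report
#'
#' Combines [delta_rmsf()], [per_residue_ttest()] and
#' [benjamini_hochberg()] into one row per residue. Non-significant
#' residues keep their delta but are flagged `FALSE`; the structure
#' projection written by [project_significance()] carries 0 for them.
#'
#' @param mat_a,mat_b `rmsf_matrix` tibbles on the same residue axis.
#' @param fdr False discovery rate (default 0.05).
#' @param variant t-test variant, see [per_residue_ttest()].
#' @param top Optional topology supplying residue names.
#' @return Tibble `(residue_index, residue_name, mean_delta, statistic,
#'   df, p_value, q_value, significant)` of class `delta_rmsf_report`.
#' @export
significance_report <- function(mat_a, mat_b, fdr = 0.05,
                                variant = c("welch", "student"), top = NULL) {
  variant <- match.arg(variant)
  delta <- delta_rmsf(mat_a, mat_b)
  tests <- per_residue_ttest(mat_a, mat_b, variant)
  bh <- benjamini_hochberg(tests$p_value, fdr)
  out <- delta |>
    inner_join(tests, by = "residue_index") |>
    mutate(q_value = bh$q_value, significant = bh$significant)
  if (!is.null(top)) {
    out <- left_join(out, distinct(residues(top), .data$residue_index,
                                   .data$residue_name),
                     by = "residue_index") |>
      relocate("residue_name", .after = "residue_index")
  } else {
    out$residue_name <- NA_character_
    out <- relocate(out, "residue_name", .after = "residue_index")
  }
  attr(out, "fdr") <- fdr
  attr(out, "test_variant") <- variant
  class(out) <- c("delta_rmsf_report", class(out))
  out
}

#' @export
glance.delta_rmsf_report <- function(x, ...) {
  tibble(n_residues = nrow(x), n_significant = sum(x$significant),
         fdr = attr(x, "fdr"), test_variant = attr(x, "test_variant"))
}

#' Write a significance report as TSV
#'
#' @param report A `delta_rmsf_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_significance_report <- function(report, path) {
  readr::write_tsv(as_tibble(report), path)
  invisible(path)
}

#' Project significant flexibility differences onto a structure
#'
#' Writes a PDB whose B-factors carry `mean_delta` for significant residues
#' and 0 elsewhere (so colouring shows "equally rigid or no significant
#' difference" as white).
#'
#' @param report A `delta_rmsf_report`.
#' @param top Topology of the structure to annotate.
#' @param coords `(n_atoms, 3)` coordinates to write.
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
project_significance <- function(report, top, coords, path) {
  scores <- ifelse(report$significant, report$mean_delta, 0)
  names(scores) <- report$residue_index
  write_per_residue_scores(top, coords, scores, path)
}
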