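# preset generator scales
preset_fields <- function(preset) {
  switch(preset,
    "full-scale" = list(n_replicas = 15, n_frames = 5000, atoms = "calpha"),
    "quick" = list(n_replicas = 3, n_frames = 500, atoms = "calpha"),
    ls_abort(paste("unknown preset:", preset), class = "loopshift_error_bad_config")
  )
}

default_config <- function() {
  list(
    seed = 1,
    preset = "quick",
    variants = list(a = list()),
    cutoffs = c(closed = 1.5, open = 1.5, wide_open = 1.5),
    bin_width = 0.16,
    fraction_cutoffs = c(1.5, 2.0),
    fdr = 0.05,
    ttest = "welch",
    rmsf_state = NULL,
    network_state = "wide_open",
    detector = list(type = "hbond", heavy_only = TRUE, d_max = 3.5,
                    angle_min = 135),
    evb = NULL,
    lra = NULL,
    stages = c("simulate", "states")
  )
}

#' Build and validate a pipeline configuration
#'
#' A configuration is a plain named list (readable from YAML) merged over
#' the package defaults and schema-checked before any computation. The
#' merged effective configuration is echoed into the run report, so every
#' run is auditable.
#'
#' @param config A named list of settings, or a path to a YAML file.
#' @return Validated config list of class `loopshift_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) {
    ls_abort("config must be a list or a YAML path",
             class = "loopshift_error_bad_config")
  }
  cfg <- utils::modifyList(default_config(), config)
  cfg$cutoffs <- unlist(cfg$cutoffs)
  if (!all(c("closed", "open", "wide_open") %in% names(cfg$cutoffs)) ||
      any(cfg$cutoffs <= 0)) {
    ls_abort("cutoffs must be positive and named closed/open/wide_open",
             class = "loopshift_error_bad_config")
  }
  if (cfg$fdr <= 0 || cfg$fdr >= 1) {
    ls_abort("fdr must lie in (0, 1)", class = "loopshift_error_bad_config")
  }
  if (!cfg$ttest %in% c("welch", "student")) {
    ls_abort("ttest must be 'welch' or 'student'",
             class = "loopshift_error_bad_config")
  }
  known_stages <- c("simulate", "states", "rmsf_diff", "network_diff",
                    "evb_map", "lra")
  bad <- setdiff(cfg$stages, known_stages)
  if (length(bad) > 0) {
    ls_abort(paste("unknown stages:", paste(bad, collapse = ", ")),
             class = "loopshift_error_bad_config")
  }
  preset_fields(cfg$preset)  # validates the preset name
  if (length(cfg$variants) < 1 || is.null(names(cfg$variants))) {
    ls_abort("variants must be a named list", class = "loopshift_error_bad_config")
  }
  class(cfg) <- c("loopshift_config", class(cfg))
  cfg
}

variant_spec <- function(cfg, overrides, seed) {
  fields <- utils::modifyList(preset_fields(cfg$preset), as.list(overrides))
  fields$seed <- seed
  # YAML delivers vectors as lists; coerce the ones the spec needs
  if (!is.null(fields$sigma_overrides)) {
    fields$sigma_overrides <- unlist(fields$sigma_overrides)
  }
  if (!is.null(fields$sequence)) {
    fields$sequence <- unlist(fields$sequence)
  }
  if (!is.null(fields$stationary)) {
    fields$transition_matrix <- stationary_transition_matrix(
      unlist(fields$stationary), fields$mixing %||% 0.05)
    fields$stationary <- NULL
    fields$mixing <- NULL
  }
  do.call(loop_system_spec, fields)
}

write_if <- function(tab, outdir, name) {
  if (!is.null(outdir)) {
    readr::write_tsv(as_tibble(tab), file.path(outdir, name))
  }
}

#' Run the analysis pipeline on synthetic ensembles
#'
#' Executes the requested stages in dependency order: `simulate` (generate
#' each variant's ensemble), `states` (RMSD to the three references,
#' labelling, histograms, populations, cutoff fractions), `rmsf_diff`
#' (per-replica RMSF per variant; the A-vs-B significance report when two
#' variants are configured), `network_diff` (state-conditioned interaction
#' occupancies; the A-vs-B difference with two variants), `evb_map`
#' (mapping-series sampling, free-energy ladder and profile) and `lra`
#' (group contributions). With an output directory every numeric table is
#' written as TSV and a JSON run report (config echo, package version,
#' per-stage wall-clock, warnings) alongside; identical config and seed
#' reproduce every output byte.
#'
#' @param config A [run_config()] (or list / YAML path coerced through it).
#' @param outdir Optional output directory (created if needed).
#' @return A `loopshift_run` list: `$variants` (per-variant results),
#'   `$rmsf_report`, `$network_diff`, `$evb`, `$lra`, `$report`.
#' @export
run_pipeline <- function(config = list(), outdir = NULL) {
  cfg <- if (inherits(config, "loopshift_config")) config else run_config(config)
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  res <- list(variants = list(), report = list(
    package_version = as.character(utils::packageVersion("loopshift")),
    config = unclass(cfg), stages = list(), warnings = character(0)))
  note_warning <- function(w) {
    res$report$warnings <<- c(res$report$warnings, conditionMessage(w))
    rlang::cnd_muffle(w)
  }
  timed <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- withCallingHandlers(expr, warning = note_warning)
    res$report$stages[[stage]] <<- list(seconds = round(
      proc.time()[["elapsed"]] - t0, 3))
    out
  }
  stages <- cfg$stages
  v_seeds <- derive_seeds(cfg$seed, length(cfg$variants) + 2)

  if ("simulate" %in% stages) {
    res$variants <- timed("simulate", {
      purrr::imap(cfg$variants, function(ov, name) {
        i <- match(name, names(cfg$variants))
        spec <- variant_spec(cfg, ov %||% list(), v_seeds[i])
        sim <- simulate_loop_ensemble(spec)
        list(name = name, spec = spec, sim = sim)
      })
    })
  }

  if ("states" %in% stages) {
    res$variants <- timed("states", {
      purrr::map(res$variants, function(v) {
        refs <- v$sim$references
        rs <- purrr::map(refs, function(ref) rmsd_series(v$sim$ensemble, ref))
        labels <- label_states(rs$closed, rs$open, rs$wide_open,
                               cutoffs = cfg$cutoffs)
        v$rmsd <- rs
        v$labels <- labels
        v$populations <- state_populations(labels)
        v$histogram <- rmsd_histogram(rs$closed, bin_width = cfg$bin_width)
        v$fractions <- purrr::map_dfr(cfg$fraction_cutoffs, function(cut) {
          mutate(fraction_below(rs$closed, cut), cutoff = cut)
        })
        write_if(as_tibble(labels)[, c("replica", "frame", "label")],
                 outdir, paste0("labels_", v$name, ".tsv"))
        write_if(v$histogram, outdir, paste0("hist_closed_", v$name, ".tsv"))
        write_if(v$populations, outdir, paste0("populations_", v$name, ".tsv"))
        write_if(v$fractions, outdir, paste0("fractions_", v$name, ".tsv"))
        v
      })
    })
  }

  if ("rmsf_diff" %in% stages) {
    res <- timed("rmsf_diff", {
      res$variants <- purrr::map(res$variants, function(v) {
        top <- v$sim$topology
        sel <- select_atoms(top, atom_names = "CA", label = "all CA")
        fit <- v$sim$references$closed$fit_selection
        v$rmsf <- rmsf_per_replica(v$sim$ensemble, sel, fit = fit,
                                   labels = if (!is.null(cfg$rmsf_state)) v$labels,
                                   state = cfg$rmsf_state)
        v
      })
      if (length(res$variants) >= 2) {
        a <- res$variants[[1]]; b <- res$variants[[2]]
        res$rmsf_report <- significance_report(
          a$rmsf, b$rmsf, fdr = cfg$fdr, variant = cfg$ttest,
          top = a$sim$topology)
        write_if(res$rmsf_report, outdir, "delta_rmsf_report.tsv")
      }
      res
    })
  }

  if ("network_diff" %in% stages) {
    res <- timed("network_diff", {
      det <- cfg$detector
      res$variants <- purrr::map(res$variants, function(v) {
        v$occupancy <- interaction_occupancy(
          v$sim$ensemble, v$labels, detect = det$type,
          d_max = det$d_max, angle_min = det$angle_min,
          heavy_only = isTRUE(det$heavy_only))
        v
      })
      if (length(res$variants) >= 2) {
        res$network_diff <- network_difference(
          res$variants[[1]]$occupancy, res$variants[[2]]$occupancy,
          state = cfg$network_state)
        write_if(res$network_diff, outdir, "network_diff.tsv")
      }
      res
    })
  }

  if ("evb_map" %in% stages) {
    res$evb <- timed("evb_map", {
      ev <- utils::modifyList(list(seed = v_seeds[length(cfg$variants) + 1]),
                              as.list(cfg$evb %||% list()))
      spec <- do.call(diabat_spec, ev)
      series <- simulate_mapping_series(spec)
      ladder <- fep_ladder(series, temperature = spec$temperature)
      profile <- umbrella_profile(series, h12 = spec$h12, alpha = spec$alpha,
                                  ladder = ladder,
                                  temperature = spec$temperature)
      write_if(ladder, outdir, "evb_ladder.tsv")
      write_if(profile, outdir, "evb_profile.tsv")
      list(spec = spec, series = series, ladder = ladder, profile = profile,
           oracle = analytic_barrier(spec))
    })
  }

  if ("lra" %in% stages) {
    res$lra <- timed("lra", {
      lr <- as.list(cfg$lra %||% list())
      effects <- unlist(lr$effects %||% c("1" = 2, "2" = -1, "3" = 0))
      series <- simulate_group_energies(
        n_frames = lr$n_frames %||% 2000, effects = effects,
        noise_sd = lr$noise_sd %||% 1,
        seed = v_seeds[length(cfg$variants) + 2])
      report <- lra_group_contribution(series, epsilon_in = lr$epsilon_in %||% 4)
      write_if(report, outdir, "lra_report.tsv")
      list(series = series, report = report)
    })
  }

  if (!is.null(outdir)) {
    report <- res$report
    report$config$variants <- purrr::map(report$config$variants,
                                         function(v) as.list(v %||% list()))
    jsonlite::write_json(report, file.path(outdir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  class(res) <- "loopshift_run"
  res
}

#' @export
print.loopshift_run <- function(x, ...) {
  cat(sprintf("<loopshift_run> %d variant(s); stages: %s\n",
              length(x$variants),
              paste(names(x$report$stages), collapse = ", ")))
  invisible(x)
}

#' Compare two completed pipeline runs
#'
#' Joins the state-population tables (with a 3-standard-error separation
#' call per state), recomputes the delta-RMSF significance report between
#' the first variant of each run, and differences their interaction
#' networks per shared state. Network keys join by position (chain and
#' residue index), so loop substitutions with different residue names
#' still compare.
#'
#' @param run_a,run_b `loopshift_run` objects whose first variants are the
#'   two systems to compare.
#' @param state State for the network difference (default `"wide_open"`).
#' @param fdr,ttest Settings for the significance report.
#' @return List of class `variant_comparison`: `$populations`,
#'   `$rmsf_report` (when both runs carry RMSF matrices), `$network_diff`
#'   (when both carry occupancy tables).
#' @export
compare_variants <- function(run_a, run_b, state = "wide_open",
                             fdr = 0.05, ttest = "welch") {
  va <- run_a$variants[[1]]; vb <- run_b$variants[[1]]
  if (is.null(va$populations) || is.null(vb$populations)) {
    ls_abort("both runs must have completed the states stage",
             class = "loopshift_error_bad_config")
  }
  pops <- inner_join(
    rename(as_tibble(va$populations), fraction_a = "pooled_fraction", se_a = "se"),
    rename(as_tibble(vb$populations), fraction_b = "pooled_fraction", se_b = "se"),
    by = "state") |>
    mutate(separated = abs(.data$fraction_a - .data$fraction_b) >
             3 * (.data$se_a + .data$se_b))
  out <- list(populations = pops)
  if (!is.null(va$rmsf) && !is.null(vb$rmsf)) {
    if (!identical(rmsf_residues(va$rmsf), rmsf_residues(vb$rmsf))) {
      ls_abort("runs have incompatible residue axes",
               class = "loopshift_error_axis_mismatch")
    }
    out$rmsf_report <- significance_report(va$rmsf, vb$rmsf, fdr = fdr,
                                           variant = ttest,
                                           top = va$sim$topology)
  }
  if (!is.null(va$occupancy) && !is.null(vb$occupancy)) {
    out$network_diff <- network_difference(va$occupancy, vb$occupancy, state)
  }
  class(out) <- "variant_comparison"
  out
}

#' @export
print.variant_comparison <- function(x, ...) {
  cat("<variant_comparison>\n")
  print(x$populations)
  invisible(x)
}
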