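#' Read a structure from a PDB file
#'
#' Parses one MODEL of a (possibly multi-model) PDB file into a topology and
#' a single-frame coordinate matrix. ATOM and HETATM records are both kept:
#' non-standard chemistry (e.g. a phospho-cysteine reaction intermediate) is
#' treated as ordinary atoms. Residue identity is `(chain_id,
#' residue_index)`; insertion codes are rejected.
#'
#' @param path Path to a PDB file.
#' @param model_index 1-based MODEL to extract (default 1).
#' @return List with elements `topology` (a [topology()]) and `coords`
#'   (`(n_atoms, 3)` matrix, Angstrom).
#' @export
read_structure <- function(path, model_index = 1) {
  if (!file.exists(path)) {
    ls_abort(paste("no such file:", path), class = "loopshift_error_missing_file")
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) {
      ls_abort(paste("malformed PDB file:", conditionMessage(e)),
               class = "loopshift_error_malformed_pdb")
    }
  )
  if (is.null(pdb$atom) || nrow(pdb$atom) == 0) {
    ls_abort("no ATOM/HETATM records found; not a PDB file",
             class = "loopshift_error_malformed_pdb")
  }
  ins <- pdb$atom$insert
  if (!is.null(ins) && any(!is.na(ins) & ins != "")) {
    ls_abort("insertion codes are not supported; renumber the structure",
             class = "loopshift_error_insertion_code")
  }
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  n_models <- nrow(xyz)
  if (model_index < 1 || model_index > n_models) {
    ls_abort(sprintf("model_index %d out of range (file has %d model(s))",
                     model_index, n_models),
             class = "loopshift_error_model_out_of_range")
  }
  coords <- matrix(xyz[model_index, ], ncol = 3, byrow = TRUE)
  if (!all(is.finite(coords))) {
    ls_abort("non-numeric coordinate columns in PDB file",
             class = "loopshift_error_malformed_pdb")
  }
  chain <- pdb$atom$chain
  chain[is.na(chain) | chain == ""] <- "A"
  elem <- pdb$atom$elesy
  if (is.null(elem)) elem <- rep(NA_character_, nrow(pdb$atom))
  bad <- is.na(elem) | trimws(elem) == ""
  elem[bad] <- infer_element(pdb$atom$elety[bad])
  top <- topology(tibble(
    atom_id = as.integer(pdb$atom$eleno),
    atom_name = trimws(pdb$atom$elety),
    element = toupper(trimws(elem)),
    residue_index = as.integer(pdb$atom$resno),
    residue_name = trimws(pdb$atom$resid),
    chain_id = chain
  ))
  list(topology = top, coords = coords)
}

#' Write a structure (optionally multi-model) to a PDB file
#'
#' @param top A [topology()].
#' @param coords `(n_atoms, 3)` matrix, or a list of such matrices to write
#'   as consecutive MODELs.
#' @param path Output path.
#' @param b Optional per-atom temperature factors (recycled 0 otherwise).
#' @return `path`, invisibly.
#' @export
write_structure <- function(top, coords, path, b = NULL) {
  if (is.matrix(coords)) coords <- list(coords)
  n <- nrow(top)
  if (is.null(b)) b <- rep(0, n)
  # clamp into the fixed-width %6.2f temperature-factor column
  b <- pmin(pmax(b, -99.99), 999.99)
  xyz <- do.call(rbind, lapply(coords, function(m) {
    if (nrow(m) != n) {
      ls_abort("coordinate/topology atom-count mismatch",
               class = "loopshift_error_atom_mismatch")
    }
    as.numeric(t(m))
  }))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = top$residue_index, resid = top$residue_name,
                   eleno = top$atom_id, elety = top$atom_name,
                   chain = top$chain_id, b = b)
  invisible(path)
}

# --- tabular frame format -------------------------------------------------
# one row per atom per frame: replica, frame, atom_id, x, y, z (TSV header,
# 6-decimal coordinates); chosen so synthetic ensembles are diffable text

tabular_cols <- c("replica", "frame", "atom_id", "x", "y", "z")

is_tabular_frames <- function(path) {
  first <- readLines(path, n = 1)
  identical(strsplit(trimws(first), "[\t,]")[[1]][1:3], tabular_cols[1:3])
}

#' Write one replica of an ensemble in the tabular frame format
#'
#' @param ensemble A [replica_ensemble()].
#' @param replica Replica index to write.
#' @param path Output path (TSV).
#' @return `path`, invisibly.
#' @export
write_frames_tsv <- function(ensemble, replica, path) {
  n_atoms <- nrow(ensemble$topology)
  frames <- seq_len(ensemble$n_frames)
  xs <- sprintf("%.6f", as.numeric(ensemble$coords[, 1, , replica]))
  ys <- sprintf("%.6f", as.numeric(ensemble$coords[, 2, , replica]))
  zs <- sprintf("%.6f", as.numeric(ensemble$coords[, 3, , replica]))
  tab <- tibble(
    replica = replica,
    frame = rep(frames, each = n_atoms),
    atom_id = rep(ensemble$topology$atom_id, times = ensemble$n_frames),
    x = xs, y = ys, z = zs
  )
  readr::write_tsv(tab, path)
  invisible(path)
}

read_tabular_replica <- function(path, top, replica_label) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(tabular_cols, names(tab))
  if (length(missing) > 0) {
    ls_abort(paste0("tabular frame file ", path, " lacks columns: ",
                    paste(missing, collapse = ", ")),
             class = "loopshift_error_malformed_table")
  }
  frames <- sort(unique(as.integer(tab$frame)))
  if (!identical(frames, seq(frames[1], by = 1L,
                             length.out = length(frames)))) {
    ls_abort(paste0("non-contiguous frame numbering in ", path,
                    " (replica ", replica_label, ")"),
             class = "loopshift_error_frame_gap")
  }
  n_atoms <- nrow(top)
  counts <- table(tab$frame)
  bad <- names(counts)[counts != n_atoms]
  if (length(bad) > 0) {
    ls_abort(sprintf(
      "atom-count mismatch vs topology (%d atoms) in replica %s, frame %s of %s",
      n_atoms, replica_label, bad[1], path),
      class = "loopshift_error_atom_mismatch")
  }
  tab <- arrange(tab, .data$frame, match(.data$atom_id, top$atom_id))
  if (anyNA(match(tab$atom_id, top$atom_id))) {
    ls_abort(sprintf("unknown atom ids in %s (replica %s)", path, replica_label),
             class = "loopshift_error_atom_mismatch")
  }
  arr <- array(0, dim = c(n_atoms, 3, length(frames)))
  arr[, 1, ] <- tab$x
  arr[, 2, ] <- tab$y
  arr[, 3, ] <- tab$z
  arr
}

read_pdb_replica <- function(path, top, replica_label) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) {
      ls_abort(paste("malformed PDB file:", conditionMessage(e)),
               class = "loopshift_error_malformed_pdb")
    }
  )
  xyz <- pdb$xyz
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) != 3 * nrow(top)) {
    ls_abort(sprintf(
      "atom-count mismatch vs topology (%d atoms) in replica %s (%s has %d)",
      nrow(top), replica_label, path, ncol(xyz) / 3),
      class = "loopshift_error_atom_mismatch")
  }
  arr <- array(0, dim = c(nrow(top), 3, nrow(xyz)))
  for (m in seq_len(nrow(xyz))) {
    arr[, , m] <- matrix(xyz[m, ], ncol = 3, byrow = TRUE)
  }
  arr
}

#' Read a multi-replica ensemble
#'
#' One replica per input path. Each path may be a multi-model PDB file or a
#' tabular frame file (TSV with header `replica, frame, atom_id, x, y, z`);
#' formats may be mixed across paths. The same frames delivered in either
#' format parse to identical ensembles (up to the tabular format's 6-decimal
#' printed precision).
#'
#' @param top The shared [topology()].
#' @param paths Character vector of per-replica files.
#' @param frame_interval_ps Time between frames, ps.
#' @return A [replica_ensemble()] with `n_replicas = length(paths)`.
#' @export
read_ensemble <- function(top, paths, frame_interval_ps = 100) {
  reps <- lapply(seq_along(paths), function(i) {
    path <- paths[i]
    if (!file.exists(path)) {
      ls_abort(paste("no such file:", path), class = "loopshift_error_missing_file")
    }
    if (is_tabular_frames(path)) {
      read_tabular_replica(path, top, i)
    } else {
      read_pdb_replica(path, top, i)
    }
  })
  n_frames <- unique(vapply(reps, function(a) dim(a)[3], numeric(1)))
  if (length(n_frames) != 1) {
    ls_abort("replicas have differing frame counts",
             class = "loopshift_error_frame_gap")
  }
  coords <- array(0, dim = c(nrow(top), 3, n_frames, length(paths)))
  for (i in seq_along(reps)) coords[, , , i] <- reps[[i]]
  replica_ensemble(top, coords, frame_interval_ps)
}

#' Project per-residue scores onto a structure's temperature factors
#'
#' Writes a PDB file whose B-factor column carries each atom's residue score
#' (0.00 for unscored residues), for colouring in any structure viewer.
#' Scores are clamped to the fixed-width column; values with `|score| <
#' 1000` survive a round trip to 2 decimals.
#'
#' @param top A [topology()].
#' @param coords `(n_atoms, 3)` coordinate matrix.
#' @param scores Named numeric vector (names = residue indices) or a data
#'   frame with columns `residue_index` and `score`.
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
write_per_residue_scores <- function(top, coords, scores, path) {
  if (is.data.frame(scores)) {
    scores <- stats::setNames(scores$score, scores$residue_index)
  }
  ridx <- as.integer(names(scores))
  unknown <- setdiff(ridx, top$residue_index)
  if (length(unknown) > 0) {
    ls_abort(paste("scores given for residues absent from topology:",
                   paste(unknown, collapse = ", ")),
             class = "loopshift_error_unknown_residue")
  }
  b <- rep(0, nrow(top))
  hit <- match(top$residue_index, ridx)
  b[!is.na(hit)] <- scores[hit[!is.na(hit)]]
  write_structure(top, coords, path, b = b)
}

#' Read back the temperature-factor column of a PDB file
#'
#' Companion to [write_per_residue_scores()]: returns one score per residue
#' (the B-factor of its first atom).
#'
#' @param path PDB path.
#' @return Tibble with `residue_index`, `score`.
#' @export
read_per_residue_scores <- function(path) {
  if (!file.exists(path)) {
    ls_abort(paste("no such file:", path), class = "loopshift_error_missing_file")
  }
  pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE))
  tibble(residue_index = as.integer(pdb$atom$resno), score = pdb$atom$b) |>
    group_by(.data$residue_index) |>
    summarise(score = first(.data$score), .groups = "drop")
}
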