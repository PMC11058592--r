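#' Build a topology table
#'
#' A topology is the atom-level description shared by every frame of an
#' ensemble: one row per atom with its identifiers, residue assignment and
#' mass. It is an ordinary tibble (class `loopshift_topology`) so it can be
#' filtered and joined with dplyr verbs.
#'
#' @param atoms A data frame with columns `atom_id` (unique integers),
#'   `atom_name`, `residue_index`, `residue_name` (3-letter code),
#'   `chain_id`, and optionally `element` and `mass` (amu). Missing elements
#'   are inferred from atom names; missing masses from elements.
#' @return A tibble with one row per atom, in input order.
#' @export
topology <- function(atoms) {
  atoms <- as_tibble(atoms)
  required <- c("atom_id", "atom_name", "residue_index", "residue_name", "chain_id")
  missing <- setdiff(required, names(atoms))
  if (length(missing) > 0) {
    ls_abort(paste("topology is missing columns:", paste(missing, collapse = ", ")),
             class = "loopshift_error_bad_topology")
  }
  if (anyDuplicated(atoms$atom_id)) {
    ls_abort("atom_ids must be unique", class = "loopshift_error_bad_topology")
  }
  if (!("element" %in% names(atoms))) {
    atoms$element <- infer_element(atoms$atom_name)
  }
  if (!("mass" %in% names(atoms))) {
    atoms$mass <- element_mass(atoms$element)
  }
  if (any(!is.finite(atoms$mass)) || any(atoms$mass <= 0)) {
    ls_abort("atom masses must be positive and finite",
             class = "loopshift_error_bad_topology")
  }
  # residue numbering must be non-decreasing within each chain
  by_chain <- split(atoms$residue_index, atoms$chain_id)
  if (any(vapply(by_chain, function(r) any(diff(r) < 0), logical(1)))) {
    ls_abort("residue_index must be non-decreasing within a chain",
             class = "loopshift_error_bad_topology")
  }
  atoms <- atoms[, c("atom_id", "atom_name", "element", "residue_index",
                     "residue_name", "chain_id", "mass")]
  class(atoms) <- c("loopshift_topology", class(atoms))
  atoms
}

#' Residue table of a topology
#'
#' @param top A topology.
#' @return Tibble with one row per residue: `chain_id`, `residue_index`,
#'   `residue_name`, in topology order.
#' @export
residues <- function(top) {
  distinct(as_tibble(top), .data$chain_id, .data$residue_index, .data$residue_name)
}

#' Atom selection
#'
#' A labelled, sorted set of atom ids used to address subsets of a topology
#' (loop atoms, fit atoms, centre-of-mass groups, ...).
#'
#' @param indices Atom ids (integers); duplicates are removed.
#' @param label Short description carried into output metadata.
#' @return Sorted integer vector with class `loopshift_atom_set`.
#' @export
atom_set <- function(indices, label = "") {
  idx <- sort(unique(as.integer(indices)))
  structure(idx, label = label, class = "loopshift_atom_set")
}

#' Select atoms by name and/or residue
#'
#' Convenience wrapper building an [atom_set()] from a topology.
#'
#' @param top A topology.
#' @param atom_names Keep only these atom names (`NULL` = all).
#' @param residue_index Keep only these residue indices (`NULL` = all).
#' @param exclude_residues Drop these residue indices.
#' @param label Selection label.
#' @return An [atom_set()].
#' @export
select_atoms <- function(top, atom_names = NULL, residue_index = NULL,
                         exclude_residues = NULL, label = "") {
  keep <- rep(TRUE, nrow(top))
  if (!is.null(atom_names)) keep <- keep & top$atom_name %in% atom_names
  if (!is.null(residue_index)) keep <- keep & top$residue_index %in% residue_index
  if (!is.null(exclude_residues)) keep <- keep & !(top$residue_index %in% exclude_residues)
  atom_set(top$atom_id[keep], label = label)
}

# map atom ids to row indices of a topology, with a classed error on miss
atom_rows <- function(top, ids) {
  rows <- match(as.integer(ids), top$atom_id)
  if (anyNA(rows)) {
    ls_abort(paste("atom ids not present in topology:",
                   paste(ids[is.na(rows)], collapse = ", ")),
             class = "loopshift_error_selection_mismatch")
  }
  rows
}

#' Construct a replica ensemble
#'
#' The universal container of the package: multi-replica, multi-frame
#' coordinates bound to one topology. Coordinates are stored as a numeric
#' array with dimensions `(n_atoms, 3, n_frames, n_replicas)` in Angstrom.
#'
#' @param top A topology.
#' @param coords Numeric array `(n_atoms, 3, n_frames, n_replicas)`.
#' @param frame_interval_ps Time between stored frames in picoseconds.
#' @return An object of class `replica_ensemble`.
#' @export
replica_ensemble <- function(top, coords, frame_interval_ps = 100) {
  d <- dim(coords)
  if (length(d) != 4 || d[1] != nrow(top) || d[2] != 3) {
    ls_abort("coords must be an (n_atoms, 3, n_frames, n_replicas) array matching the topology",
             class = "loopshift_error_atom_mismatch")
  }
  if (!all(is.finite(coords))) {
    ls_abort("coordinates must be finite", class = "loopshift_error_bad_coords")
  }
  if (!is.numeric(frame_interval_ps) || frame_interval_ps <= 0) {
    ls_abort("frame_interval_ps must be > 0", class = "loopshift_error_bad_spec")
  }
  structure(
    list(topology = top, coords = coords,
         n_frames = d[3], n_replicas = d[4],
         frame_interval_ps = frame_interval_ps),
    class = "replica_ensemble"
  )
}

#' @export
print.replica_ensemble <- function(x, ...) {
  cat(sprintf("<replica_ensemble> %d atoms, %d replicas x %d frames (%g ps apart)\n",
              nrow(x$topology), x$n_replicas, x$n_frames, x$frame_interval_ps))
  invisible(x)
}

#' Extract one frame as an atoms-by-3 coordinate matrix
#'
#' @param ensemble A [replica_ensemble()].
#' @param replica,frame 1-based indices.
#' @return Numeric matrix `(n_atoms, 3)`.
#' @export
frame_coords <- function(ensemble, replica, frame) {
  ensemble$coords[, , frame, replica, drop = TRUE]
}

#' Reference conformational state
#'
#' A single-frame structure (closed / open / wide_open) on the shared
#' topology, together with the loop selection it defines and the fit
#' selection used for superposition.
#'
#' @param name One of `"closed"`, `"open"`, `"wide_open"`.
#' @param top The shared topology.
#' @param coords `(n_atoms, 3)` coordinate matrix in Angstrom.
#' @param loop_selection [atom_set()] of mobile-loop atoms (non-empty).
#' @param fit_selection [atom_set()] used for superposition.
#' @return Object of class `reference_state`.
#' @export
reference_state <- function(name, top, coords, loop_selection, fit_selection) {
  name <- match.arg(name, c("closed", "open", "wide_open"))
  if (length(loop_selection) == 0) {
    ls_abort("loop_selection must be non-empty", class = "loopshift_error_bad_spec")
  }
  atom_rows(top, loop_selection)
  atom_rows(top, fit_selection)
  if (!is.matrix(coords) || nrow(coords) != nrow(top) || ncol(coords) != 3) {
    ls_abort("reference coords must be an (n_atoms, 3) matrix on the topology",
             class = "loopshift_error_atom_mismatch")
  }
  structure(list(name = name, topology = top, coords = coords,
                 loop_selection = loop_selection, fit_selection = fit_selection),
            class = "reference_state")
}
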