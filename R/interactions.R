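# ---- donor / acceptor / charge chemistry tables --------------------------
# heavy-atom hydrogen-bonding roles by residue and atom name; backbone N is
# a donor for every residue except proline (no amide hydrogen), backbone O
# is always an acceptor

sidechain_donors <- tibble::tribble(
  ~residue_name, ~atom_name,
  "SER", "OG",  "THR", "OG1", "TYR", "OH",  "CYS", "SG",
  "TRP", "NE1", "LYS", "NZ",  "ARG", "NE",  "ARG", "NH1", "ARG", "NH2",
  "GLN", "NE2", "ASN", "ND2", "HIS", "ND1", "HIS", "NE2"
)

sidechain_acceptors <- tibble::tribble(
  ~residue_name, ~atom_name,
  "ASP", "OD1", "ASP", "OD2", "GLU", "OE1", "GLU", "OE2",
  "ASN", "OD1", "GLN", "OE1", "SER", "OG",  "THR", "OG1",
  "TYR", "OH",  "HIS", "ND1", "HIS", "NE2", "MET", "SD"
)

charged_atoms <- tibble::tribble(
  ~residue_name, ~atom_name, ~charge,
  "ARG", "NE", 1,  "ARG", "NH1", 1, "ARG", "NH2", 1, "LYS", "NZ", 1,
  "ASP", "OD1", -1, "ASP", "OD2", -1, "GLU", "OE1", -1, "GLU", "OE2", -1
)

backbone_names <- c("N", "CA", "C", "O")

# rows of a topology eligible as H-bond donors / acceptors
donor_rows <- function(top) {
  bb <- which(top$atom_name == "N" & top$residue_name != "PRO")
  sc <- which(paste(top$residue_name, top$atom_name) %in%
                paste(sidechain_donors$residue_name, sidechain_donors$atom_name))
  sort(unique(c(bb, sc)))
}

acceptor_rows <- function(top) {
  bb <- which(top$atom_name == "O")
  sc <- which(paste(top$residue_name, top$atom_name) %in%
                paste(sidechain_acceptors$residue_name, sidechain_acceptors$atom_name))
  sort(unique(c(bb, sc)))
}

# canonical interaction key: partner i is the lower (chain, residue_index);
# keys compare across variants by position, residue names are carried along
canonical_key <- function(kind, chain_1, res_1, name_1, atom_1,
                          chain_2, res_2, name_2, atom_2,
                          backbone_1, backbone_2) {
  swap <- (chain_2 < chain_1) | (chain_2 == chain_1 & res_2 < res_1)
  tibble(
    kind = kind,
    chain_i = ifelse(swap, chain_2, chain_1),
    res_i = ifelse(swap, res_2, res_1),
    resname_i = ifelse(swap, name_2, name_1),
    atom_i = ifelse(swap, atom_2, atom_1),
    backbone_i = ifelse(swap, backbone_2, backbone_1),
    chain_j = ifelse(swap, chain_1, chain_2),
    res_j = ifelse(swap, res_1, res_2),
    resname_j = ifelse(swap, name_1, name_2),
    atom_j = ifelse(swap, atom_1, atom_2),
    backbone_j = ifelse(swap, backbone_1, backbone_2)
  )
}

key_cols <- c("kind", "chain_i", "res_i", "atom_i", "chain_j", "res_j", "atom_j")

key_string <- function(tab) {
  paste(tab$kind, tab$chain_i, tab$res_i, tab$atom_i,
        tab$chain_j, tab$res_j, tab$atom_j, sep = "|")
}

#' Detect hydrogen bonds in one frame
#'
#' A hydrogen bond is reported when the donor-acceptor heavy-atom distance
#' is at most `d_max` and (when hydrogens are present) some donor-bound
#' hydrogen makes a D-H...A angle of at least `angle_min`. With
#' `heavy_only = TRUE` the angle criterion is skipped, for heavy-atom-only
#' (e.g. synthetic) models. A proline backbone nitrogen is never a donor.
#' Pairs within one residue are reported only when exactly one partner is a
#' backbone atom, and backbone-backbone pairs of residues fewer than three
#' positions apart in the same chain are suppressed (covalently enforced
#' geometry, not hydrogen bonding).
#'
#' @param coords `(n_atoms, 3)` single-frame coordinates.
#' @param top The topology.
#' @param d_max Donor-acceptor heavy-atom distance cutoff, Angstrom
#'   (default 3.5).
#' @param angle_min Minimum D-H...A angle in degrees (default 135).
#' @param heavy_only Skip the hydrogen/angle criterion (default `FALSE`).
#' @return Tibble of canonical interaction keys (`kind = "hbond"`).
#' @export
detect_hbonds <- function(coords, top, d_max = 3.5, angle_min = 135,
                          heavy_only = FALSE) {
  don <- donor_rows(top); acc <- acceptor_rows(top)
  empty <- canonical_key(character(0), character(0), integer(0), character(0),
                         character(0), character(0), integer(0), character(0),
                         character(0), logical(0), logical(0))
  if (length(don) == 0 || length(acc) == 0) return(empty)
  hyd <- which(top$element == "H")
  if (!heavy_only && length(hyd) == 0) {
    ls_abort(paste("no hydrogens in topology; use heavy_only = TRUE for",
                   "heavy-atom-only models"),
             class = "loopshift_error_no_hydrogens")
  }
  d2 <- outer(rowSums(coords[don, , drop = FALSE]^2),
              rowSums(coords[acc, , drop = FALSE]^2), `+`) -
    2 * coords[don, , drop = FALSE] %*% t(coords[acc, , drop = FALSE])
  d2[d2 < 0] <- 0
  dmat <- sqrt(d2)
  hits <- which(dmat <= d_max, arr.ind = TRUE)
  if (nrow(hits) == 0) return(empty)
  di <- don[hits[, 1]]; ai <- acc[hits[, 2]]
  same_res <- top$residue_index[di] == top$residue_index[ai] &
    top$chain_id[di] == top$chain_id[ai]
  bb_d <- top$atom_name[di] %in% backbone_names
  bb_a <- top$atom_name[ai] %in% backbone_names
  keep <- !(same_res & (bb_d == bb_a))
  near_seq <- top$chain_id[di] == top$chain_id[ai] &
    abs(top$residue_index[di] - top$residue_index[ai]) < 3
  keep <- keep & !(bb_d & bb_a & near_seq) & di != ai
  di <- di[keep]; ai <- ai[keep]
  if (length(di) == 0) return(empty)
  if (!heavy_only) {
    ok <- vapply(seq_along(di), function(k) {
      d <- di[k]
      hs <- hyd[top$residue_index[hyd] == top$residue_index[d] &
                  top$chain_id[hyd] == top$chain_id[d]]
      if (length(hs) > 0) {
        dh <- sqrt(rowSums((coords[hs, , drop = FALSE] -
                              matrix(coords[d, ], length(hs), 3, byrow = TRUE))^2))
        hs <- hs[dh <= 1.3]
      }
      if (length(hs) == 0) return(FALSE)
      any(vapply(hs, function(h) {
        v1 <- coords[d, ] - coords[h, ]
        v2 <- coords[ai[k], ] - coords[h, ]
        ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                   sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
        ang >= angle_min
      }, logical(1)))
    }, logical(1))
    di <- di[ok]; ai <- ai[ok]
  }
  if (length(di) == 0) return(empty)
  distinct(canonical_key("hbond",
                         top$chain_id[di], top$residue_index[di],
                         top$residue_name[di], top$atom_name[di],
                         top$chain_id[ai], top$residue_index[ai],
                         top$residue_name[ai], top$atom_name[ai],
                         top$atom_name[di] %in% backbone_names,
                         top$atom_name[ai] %in% backbone_names))
}

#' Detect sidechain contacts and salt bridges in one frame
#'
#' A contact is a residue pair with any heavy sidechain-sidechain atom
#' distance at most `d_max`; the closest atom pair is recorded. Pairs of
#' oppositely charged sidechain groups within `salt_bridge_d` are reported
#' as `saltbridge` instead.
#'
#' @param coords `(n_atoms, 3)` single-frame coordinates.
#' @param top The topology.
#' @param d_max Contact distance cutoff, Angstrom (default 4.5).
#' @param salt_bridge_d Salt-bridge cutoff, Angstrom (default 4.0).
#' @return Tibble of canonical interaction keys.
#' @export
detect_contacts <- function(coords, top, d_max = 4.5, salt_bridge_d = 4.0) {
  sc <- which(!(top$atom_name %in% backbone_names) & top$element != "H")
  empty <- canonical_key(character(0), character(0), integer(0), character(0),
                         character(0), character(0), integer(0), character(0),
                         character(0), logical(0), logical(0))
  if (length(sc) < 2) return(empty)
  d2 <- outer(rowSums(coords[sc, , drop = FALSE]^2),
              rowSums(coords[sc, , drop = FALSE]^2), `+`) -
    2 * coords[sc, , drop = FALSE] %*% t(coords[sc, , drop = FALSE])
  hits <- which(d2 <= d_max^2, arr.ind = TRUE)
  hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
  if (nrow(hits) == 0) return(empty)
  i <- sc[hits[, 1]]; j <- sc[hits[, 2]]
  dist <- sqrt(pmax(0, d2[hits]))
  cross_res <- !(top$residue_index[i] == top$residue_index[j] &
                   top$chain_id[i] == top$chain_id[j])
  i <- i[cross_res]; j <- j[cross_res]; dist <- dist[cross_res]
  if (length(i) == 0) return(empty)
  chg <- stats::setNames(charged_atoms$charge,
                         paste(charged_atoms$residue_name, charged_atoms$atom_name))
  qi <- chg[paste(top$residue_name[i], top$atom_name[i])]
  qj <- chg[paste(top$residue_name[j], top$atom_name[j])]
  is_sb <- !is.na(qi) & !is.na(qj) & qi * qj < 0 & dist <= salt_bridge_d
  tab <- canonical_key(ifelse(is_sb, "saltbridge", "contact"),
                       top$chain_id[i], top$residue_index[i],
                       top$residue_name[i], top$atom_name[i],
                       top$chain_id[j], top$residue_index[j],
                       top$residue_name[j], top$atom_name[j],
                       FALSE, FALSE)
  tab$dist <- dist
  # one key per residue pair and kind: keep the closest atom pair
  tab |>
    group_by(.data$kind, .data$chain_i, .data$res_i, .data$chain_j, .data$res_j) |>
    slice_min(.data$dist, n = 1, with_ties = FALSE) |>
    ungroup() |>
    select(-"dist")
}

#' State-conditioned interaction occupancies across an ensemble
#'
#' Runs a per-frame detector over every frame, conditioning on the frame's
#' conformational-state label; frames labelled `other` are discarded. The
#' occupancy of an interaction in a state is the fraction of that state's
#' frames in which it is detected, reported per replica (pooled values are
#' frame-weighted means, computed by [network_difference()]).
#'
#' @param ensemble A [replica_ensemble()].
#' @param labels A `state_labels` tibble aligned to the ensemble.
#' @param detect `"hbond"`, `"contact"`, or both.
#' @param states States to tabulate (default all of closed/open/wide_open);
#'   states with zero frames are omitted with a warning.
#' @param ... Passed to the detectors ([detect_hbonds()],
#'   [detect_contacts()]), e.g. `heavy_only = TRUE`.
#' @return Tibble of class `occupancy_table`: canonical key columns plus
#'   `(state, replica, n_present, n_frames, occupancy)`.
#' @export
interaction_occupancy <- function(ensemble, labels,
                                  detect = c("hbond", "contact"),
                                  states = c("closed", "open", "wide_open"),
                                  ...) {
  detect <- match.arg(detect, several.ok = TRUE)
  if (nrow(labels) != ensemble$n_replicas * ensemble$n_frames) {
    ls_abort("labels are not aligned to the ensemble",
             class = "loopshift_error_misaligned_series")
  }
  top <- ensemble$topology
  lab <- labels
  counts <- list()
  frame_totals <- list()
  for (st in states) {
    sel <- lab[lab$label == st, ]
    if (nrow(sel) == 0) {
      rlang::warn(paste0("state '", st, "' has no frames; omitted"))
      next
    }
    for (r in unique(sel$replica)) {
      frames <- sel$frame[sel$replica == r]
      frame_totals[[length(frame_totals) + 1]] <-
        tibble(state = st, replica = r, n_frames = length(frames))
      for (f in frames) {
        co <- ensemble$coords[, , f, r]
        found <- list()
        if ("hbond" %in% detect) found <- c(found, list(detect_hbonds(co, top, ...)))
        if ("contact" %in% detect) found <- c(found, list(detect_contacts(co, top)))
        found <- bind_rows(found)
        if (nrow(found) > 0) {
          found$state <- st; found$replica <- r
          counts[[length(counts) + 1]] <- found
        }
      }
    }
  }
  totals <- bind_rows(frame_totals)
  if (length(counts) == 0) {
    out <- canonical_key(character(0), character(0), integer(0), character(0),
                         character(0), character(0), integer(0), character(0),
                         character(0), logical(0), logical(0))
    out$state <- character(0)
    out$replica <- integer(0)
    out$n_present <- integer(0)
    out$n_frames <- integer(0)
    out$occupancy <- numeric(0)
    attr(out, "frame_totals") <- totals
    class(out) <- c("occupancy_table", class(out))
    return(out)
  }
  out <- bind_rows(counts) |>
    group_by(across(all_of(c(key_cols, "resname_i", "resname_j",
                             "backbone_i", "backbone_j", "state", "replica")))) |>
    summarise(n_present = n(), .groups = "drop") |>
    left_join(totals, by = c("state", "replica")) |>
    mutate(occupancy = .data$n_present / .data$n_frames)
  attr(out, "frame_totals") <- totals
  class(out) <- c("occupancy_table", class(out))
  out
}

# pooled (frame-weighted) occupancy per key for one state, plus the
# between-replica spread; keys never seen in a replica count as occupancy 0
pooled_occupancy <- function(tab, state) {
  totals <- attr(tab, "frame_totals")
  totals <- totals[totals$state == state, ]
  n_total <- sum(totals$n_frames)
  tab <- as_tibble(tab)
  if (nrow(tab) > 0) tab <- tab[tab$state == state, ]
  if (nrow(tab) == 0) {
    empty <- canonical_key(character(0), character(0), integer(0), character(0),
                           character(0), character(0), integer(0), character(0),
                           character(0), logical(0), logical(0))
    empty$key <- character(0)
    empty$occupancy <- numeric(0)
    empty$sd <- numeric(0)
    return(empty[, c(key_cols, "resname_i", "resname_j", "key", "occupancy", "sd")])
  }
  keys <- distinct(tab[, c(key_cols, "resname_i", "resname_j")])
  keys$key <- key_string(keys)
  tab$key <- key_string(tab)
  # complete over replicas so absent (key, replica) pairs are zero
  full <- tidyr::crossing(key = keys$key, replica = totals$replica) |>
    left_join(tab[, c("key", "replica", "n_present")], by = c("key", "replica")) |>
    mutate(n_present = tidyr::replace_na(.data$n_present, 0L)) |>
    left_join(totals[, c("replica", "n_frames")], by = "replica")
  pooled <- full |>
    group_by(.data$key) |>
    summarise(occupancy = sum(.data$n_present) / n_total,
              sd = stats::sd(.data$n_present / .data$n_frames),
              .groups = "drop")
  left_join(keys, pooled, by = "key")
}

#' Between-variant interaction network difference within one state
#'
#' Keys are unioned across the two occupancy tables (missing = occupancy
#' 0); `delta = occupancy_a - occupancy_b`, ranked by `|delta|` descending
#' with a deterministic tie-break on the canonical key.
#'
#' @param tab_a,tab_b `occupancy_table`s for variants A and B.
#' @param state State to difference; must be present in at least one table.
#' @return Tibble of class `network_diff`: key columns,
#'   `occupancy_a`, `occupancy_b`, `sd_a`, `sd_b`, `delta`, `rank`.
#' @export
network_difference <- function(tab_a, tab_b, state) {
  in_a <- nrow(tab_a) > 0 && state %in% tab_a$state
  in_b <- nrow(tab_b) > 0 && state %in% tab_b$state
  if (!in_a && !in_b) {
    ls_abort(paste0("state '", state, "' absent from both occupancy tables"),
             class = "loopshift_error_missing_state")
  }
  pa <- pooled_occupancy(tab_a, state)
  pb <- pooled_occupancy(tab_b, state)
  joined <- full_join(
    rename(pa, occupancy_a = "occupancy", sd_a = "sd", resname_i_a = "resname_i",
           resname_j_a = "resname_j"),
    rename(pb, occupancy_b = "occupancy", sd_b = "sd", resname_i_b = "resname_i",
           resname_j_b = "resname_j"),
    by = c("key", key_cols)
  ) |>
    mutate(occupancy_a = tidyr::replace_na(.data$occupancy_a, 0),
           occupancy_b = tidyr::replace_na(.data$occupancy_b, 0),
           delta = .data$occupancy_a - .data$occupancy_b) |>
    arrange(desc(abs(.data$delta)), .data$key) |>
    mutate(rank = dplyr::row_number()) |>
    select(-"key")
  attr(joined, "state") <- state
  class(joined) <- c("network_diff", class(joined))
  joined
}

#' Per-residue projection of a network difference
#'
#' Each residue's score is the sum of `|delta|` over the interactions it
#' participates in (so the grand total over residues is twice the summed
#' `|delta|`). Suitable for [write_per_residue_scores()].
#'
#' @param diff A `network_diff`.
#' @return Tibble `(chain_id, residue_index, score)`.
#' @export
residue_projection <- function(diff) {
  if (nrow(diff) == 0) {
    return(tibble(chain_id = character(0), residue_index = integer(0),
                  score = numeric(0)))
  }
  bind_rows(
    tibble(chain_id = diff$chain_i, residue_index = diff$res_i,
           score = abs(diff$delta)),
    tibble(chain_id = diff$chain_j, residue_index = diff$res_j,
           score = abs(diff$delta))
  ) |>
    group_by(.data$chain_id, .data$residue_index) |>
    summarise(score = sum(.data$score), .groups = "drop")
}
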