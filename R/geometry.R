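#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares proper rotation and translation taking `mobile` onto
#' `reference`, with optional per-atom weights. Reflections are excluded:
#' the returned rotation always has determinant +1.
#'
#' @param mobile,reference `(n, 3)` coordinate matrices on the same atom
#'   selection, `n >= 3` and not collinear.
#' @param weights Optional per-atom weights (e.g. masses); unit weights by
#'   default, matching common Calpha-RMSD practice.
#' @return Object of class `loopshift_superposition`: list with `rotation`
#'   (3x3, det +1), `translation` (length-3, Angstrom), `rmsd` (Angstrom).
#'   The transform maps a mobile point `p` to `rotation %*% p + translation`.
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) < 3) {
    ls_abort("superposition needs at least 3 atoms",
             class = "loopshift_error_too_few_atoms")
  }
  if (!all(dim(mobile) == dim(reference))) {
    ls_abort("mobile and reference selections differ in length",
             class = "loopshift_error_selection_mismatch")
  }
  w <- if (is.null(weights)) rep(1, nrow(mobile)) else as.numeric(weights)
  # collinearity check: centred coordinates must span at least a plane
  pc <- sweep(mobile, 2, colSums(mobile * w) / sum(w))
  if (qr(pc)$rank < 2) {
    ls_abort("degenerate (collinear) atom configuration",
             class = "loopshift_error_degenerate")
  }
  fit <- kabsch_core(mobile, reference, w)
  structure(fit, class = "loopshift_superposition")
}

# weighted Kabsch on raw matrices; no validation (hot path)
kabsch_core <- function(P, Q, w) {
  sw <- sum(w)
  pbar <- colSums(P * w) / sw
  qbar <- colSums(Q * w) / sw
  Pc <- sweep(P, 2, pbar)
  Qc <- sweep(Q, 2, qbar)
  H <- crossprod(Pc * w, Qc)  # 3x3 cross-covariance
  sv <- svd(H)
  s <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, s)) %*% t(sv$u)
  # rmsd from the transformed coordinates (the trace identity cancels
  # catastrophically near zero)
  msd <- sum(w * (Pc %*% t(R) - Qc)^2) / sw
  list(rotation = R, translation = as.numeric(qbar - R %*% pbar),
       rmsd = sqrt(msd))
}

#' @export
print.loopshift_superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd = %.6f A\n", x$rmsd))
  invisible(x)
}

#' @importFrom generics glance
#' @export
glance.loopshift_superposition <- function(x, ...) {
  tibble(rmsd = x$rmsd, det_rotation = det(x$rotation))
}

#' Apply a superposition to coordinates
#'
#' @param fit A `loopshift_superposition`.
#' @param coords `(n, 3)` matrix.
#' @return Transformed `(n, 3)` matrix.
#' @export
apply_superposition <- function(fit, coords) {
  sweep(as.matrix(coords) %*% t(fit$rotation), 2, fit$translation, `+`)
}

#' Per-frame RMSD of an ensemble to a reference state
#'
#' Every frame is first superposed on the reference over the `fit` atoms
#' (unit weights by default), then the RMSD is measured over the `measure`
#' atoms. Using a fit set that excludes the mobile loop and a measure set of
#' loop Calpha atoms isolates loop motion from global tumbling; both
#' selections are echoed in the result's attributes.
#'
#' @param ensemble A [replica_ensemble()].
#' @param reference A [reference_state()] (or a bare `(n_atoms, 3)` matrix).
#' @param fit [atom_set()] used for superposition (defaults to the
#'   reference's `fit_selection`).
#' @param measure [atom_set()] over which RMSD is reported (defaults to the
#'   reference's `loop_selection`).
#' @param mass_weighted Mass-weight the superposition (default `FALSE`).
#' @return Tibble `(replica, frame, rmsd)`, Angstrom.
#' @export
rmsd_series <- function(ensemble, reference, fit = NULL, measure = NULL,
                        mass_weighted = FALSE) {
  top <- ensemble$topology
  if (inherits(reference, "reference_state")) {
    ref_coords <- reference$coords
    fit <- fit %||% reference$fit_selection
    measure <- measure %||% reference$loop_selection
    ref_name <- reference$name
  } else {
    ref_coords <- as.matrix(reference)
    ref_name <- "reference"
    if (is.null(fit) || is.null(measure)) {
      ls_abort("fit and measure selections are required with a bare reference matrix",
               class = "loopshift_error_selection_mismatch")
    }
  }
  if (length(fit) == 0 || length(measure) == 0) {
    ls_abort("fit and measure selections must be non-empty",
             class = "loopshift_error_selection_mismatch")
  }
  fr <- atom_rows(top, fit)
  mr <- atom_rows(top, measure)
  w <- if (mass_weighted) top$mass[fr] else rep(1, length(fr))
  Qf <- ref_coords[fr, , drop = FALSE]
  Qm <- ref_coords[mr, , drop = FALSE]
  nR <- ensemble$n_replicas; nF <- ensemble$n_frames
  out <- matrix(0, nF, nR)
  nm <- length(mr)
  for (r in seq_len(nR)) {
    for (f in seq_len(nF)) {
      P <- ensemble$coords[, , f, r]
      kab <- kabsch_core(P[fr, , drop = FALSE], Qf, w)
      Pm <- sweep(P[mr, , drop = FALSE] %*% t(kab$rotation), 2,
                  kab$translation, `+`)
      out[f, r] <- sqrt(sum((Pm - Qm)^2) / nm)
    }
  }
  res <- tibble(replica = rep(seq_len(nR), each = nF),
                frame = rep(seq_len(nF), times = nR),
                rmsd = as.numeric(out))
  attr(res, "reference") <- ref_name
  attr(res, "fit") <- attr(fit, "label") %||% ""
  attr(res, "measure") <- attr(measure, "label") %||% ""
  res
}

#' Centre-of-mass distance between two selections, per frame
#'
#' @param ensemble A [replica_ensemble()].
#' @param sel_a,sel_b Non-empty [atom_set()]s.
#' @return Tibble `(replica, frame, dist)`, Angstrom.
#' @export
com_distance_series <- function(ensemble, sel_a, sel_b) {
  if (length(sel_a) == 0 || length(sel_b) == 0) {
    ls_abort("selections must be non-empty", class = "loopshift_error_selection_mismatch")
  }
  top <- ensemble$topology
  ra <- atom_rows(top, sel_a); rb <- atom_rows(top, sel_b)
  ma <- top$mass[ra]; mb <- top$mass[rb]
  nR <- ensemble$n_replicas; nF <- ensemble$n_frames
  out <- matrix(0, nF, nR)
  for (r in seq_len(nR)) {
    # contract masses against (atoms, 3 * n_frames) slabs in one product
    xa <- matrix(ensemble$coords[ra, , , r], nrow = length(ra))
    xb <- matrix(ensemble$coords[rb, , , r], nrow = length(rb))
    ca <- matrix(crossprod(xa, ma) / sum(ma), nrow = 3)  # 3 x n_frames
    cb <- matrix(crossprod(xb, mb) / sum(mb), nrow = 3)
    out[, r] <- sqrt(colSums((ca - cb)^2))
  }
  tibble(replica = rep(seq_len(nR), each = nF),
         frame = rep(seq_len(nF), times = nR),
         dist = as.numeric(out))
}

#' Dihedral angle of four points
#'
#' Standard sign convention: the angle is the signed rotation of the
#' 1-2 bond projection onto the 3-4 bond projection about the 2-3 axis,
#' in degrees in `(-180, 180]`.
#'
#' @param p1,p2,p3,p4 Length-3 vectors, or `(n, 3)` matrices for `n`
#'   configurations at once.
#' @return Numeric vector of angles in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  as_m <- function(p) if (is.matrix(p)) p else matrix(p, nrow = 1)
  p1 <- as_m(p1); p2 <- as_m(p2); p3 <- as_m(p3); p4 <- as_m(p4)
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  cross <- function(a, b) cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                                a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  b2n <- b2 / sqrt(rowSums(b2^2))
  x <- rowSums(n1 * n2)
  y <- rowSums(cross(n1, n2) * b2n)
  ang <- atan2(y, x) * 180 / pi
  ang[ang <= -180] <- ang[ang <= -180] + 360
  ang
}

#' Coarse Ramachandran mask
#'
#' A swappable, deliberately coarse rectangular partition of the phi/psi
#' plane into favored / allowed / disallowed regions; only the
#' disallowed-or-not call is load-bearing downstream. Rows are checked in
#' order and the first match wins.
#'
#' @return Tibble `(region, phi_min, phi_max, psi_min, psi_max)`.
#' @export
default_rama_mask <- function() {
  tibble::tribble(
    ~region,    ~phi_min, ~phi_max, ~psi_min, ~psi_max,
    "favored",  -180,     -45,       90,       180,    # beta sheet
    "favored",  -180,     -45,     -180,     -150,     # beta (psi wrap)
    "favored",  -160,     -45,      -70,       -5,     # right-handed alpha
    "allowed",  -180,     -20,       60,       180,
    "allowed",  -180,     -20,     -180,     -140,
    "allowed",  -180,     -20,      -90,       30,
    "allowed",    20,       95,      -30,       90     # left-handed alpha
  )
}

#' Classify phi/psi pairs against a Ramachandran mask
#'
#' @param phi,psi Angles in degrees (`NA` allowed).
#' @param mask A mask as from [default_rama_mask()].
#' @return Character vector in `{favored, allowed, disallowed, NA}`.
#' @export
classify_rama <- function(phi, psi, mask = default_rama_mask()) {
  out <- rep(NA_character_, length(phi))
  ok <- !is.na(phi) & !is.na(psi)
  out[ok] <- "disallowed"
  for (k in rev(seq_len(nrow(mask)))) {  # reverse so earlier rows win
    m <- mask[k, ]
    hit <- ok & phi >= m$phi_min & phi <= m$phi_max &
      psi >= m$psi_min & psi <= m$psi_max
    out[hit] <- m$region
  }
  out
}

#' Backbone phi/psi series for one residue
#'
#' Resolves C(i-1), N, CA, C, N(i+1) by atom name within the residue's
#' chain. At a chain terminus the undefined angle (and the region) is `NA`;
#' no error is raised.
#'
#' @param ensemble A [replica_ensemble()].
#' @param residue_index Residue to analyse.
#' @param chain_id Chain (default: the first chain containing the residue).
#' @param mask Ramachandran mask, see [default_rama_mask()].
#' @return Tibble `(replica, frame, phi, psi, region)`.
#' @export
backbone_dihedrals <- function(ensemble, residue_index, chain_id = NULL,
                               mask = default_rama_mask()) {
  top <- ensemble$topology
  if (is.null(chain_id)) {
    chain_id <- top$chain_id[top$residue_index == residue_index][1]
  }
  row_of <- function(res, name) {
    w <- which(top$residue_index == res & top$chain_id == chain_id &
                 top$atom_name == name)
    if (length(w) == 0) NA_integer_ else w[1]
  }
  iN <- row_of(residue_index, "N"); iCA <- row_of(residue_index, "CA")
  iC <- row_of(residue_index, "C")
  iCm <- row_of(residue_index - 1, "C"); iNp <- row_of(residue_index + 1, "N")
  if (is.na(iN) || is.na(iCA) || is.na(iC)) {
    ls_abort(sprintf("residue %d lacks N/CA/C backbone atoms", residue_index),
             class = "loopshift_error_selection_mismatch")
  }
  nR <- ensemble$n_replicas; nF <- ensemble$n_frames
  grab <- function(row) {
    if (is.na(row)) return(NULL)
    t(matrix(ensemble$coords[row, , , ], nrow = 3))  # (nF*nR) x 3
  }
  Nc <- grab(iN); CAc <- grab(iCA); Cc <- grab(iC)
  phi <- if (!is.na(iCm)) dihedral_angle(grab(iCm), Nc, CAc, Cc) else rep(NA_real_, nF * nR)
  psi <- if (!is.na(iNp)) dihedral_angle(Nc, CAc, Cc, grab(iNp)) else rep(NA_real_, nF * nR)
  tibble(replica = rep(seq_len(nR), each = nF),
         frame = rep(seq_len(nF), times = nR),
         phi = phi, psi = psi,
         region = classify_rama(phi, psi, mask))
}
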