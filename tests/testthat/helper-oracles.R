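# Independent oracles used across the suite. These deliberately avoid the
# package's computational paths: the rotation oracle is a pure grid search,
# the BH oracle a literal step-up evaluation, the interaction oracle an
# explicit double loop.

euler_rotation <- function(a, b, g) {
  ca <- cos(a); sa <- sin(a); cb <- cos(b); sb <- sin(b)
  cg <- cos(g); sg <- sin(g)
  Rz1 <- matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cb, 0, sb, 0, 1, 0, -sb, 0, cb), 3, 3, byrow = TRUE)
  Rz2 <- matrix(c(cg, -sg, 0, sg, cg, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Rz1 %*% Ry %*% Rz2
}

# minimum RMSD over rotations by coarse Euler grid + nested grid refinement
# (grid evaluations only; no SVD anywhere)
oracle_min_rmsd <- function(P, Q) {
  Pc <- scale(P, scale = FALSE)
  Qc <- scale(Q, scale = FALSE)
  n <- nrow(P)
  msd <- function(a, b, g) sum((Pc %*% t(euler_rotation(a, b, g)) - Qc)^2) / n
  best <- c(0, 0, 0); best_v <- Inf
  for (a in seq(0, 2 * pi, length.out = 19)[-19]) {
    for (b in seq(0, pi, length.out = 10)) {
      for (g in seq(0, 2 * pi, length.out = 19)[-19]) {
        v <- msd(a, b, g)
        if (v < best_v) { best_v <- v; best <- c(a, b, g) }
      }
    }
  }
  step <- 2 * pi / 18
  for (iter in 1:40) {
    grid <- seq(-step, step, length.out = 5)
    for (da in grid) for (db in grid) for (dg in grid) {
      v <- msd(best[1] + da, best[2] + db, best[3] + dg)
      if (v < best_v) { best_v <- v; best <- best + c(da, db, dg) }
    }
    step <- step * 0.5
  }
  sqrt(best_v)
}

# Horn's closed-form quaternion superposition: an independent reimplementation
# of the optimal rigid fit (eigen of the 4x4 profile matrix, no SVD)
horn_superpose <- function(P, Q) {
  pbar <- colMeans(P); qbar <- colMeans(Q)
  Pc <- sweep(P, 2, pbar); Qc <- sweep(Q, 2, qbar)
  S <- t(Pc) %*% Qc
  N <- matrix(c(
    S[1,1]+S[2,2]+S[3,3], S[2,3]-S[3,2],        S[3,1]-S[1,3],        S[1,2]-S[2,1],
    S[2,3]-S[3,2],        S[1,1]-S[2,2]-S[3,3], S[1,2]+S[2,1],        S[3,1]+S[1,3],
    S[3,1]-S[1,3],        S[1,2]+S[2,1],       -S[1,1]+S[2,2]-S[3,3], S[2,3]+S[3,2],
    S[1,2]-S[2,1],        S[3,1]+S[1,3],        S[2,3]+S[3,2],       -S[1,1]-S[2,2]+S[3,3]
  ), 4, 4, byrow = TRUE)
  q <- eigen(N, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1-2*(y^2+z^2), 2*(x*y-w*z),   2*(x*z+w*y),
    2*(x*y+w*z),   1-2*(x^2+z^2), 2*(y*z-w*x),
    2*(x*z-w*y),   2*(y*z+w*x),   1-2*(x^2+y^2)
  ), 3, 3, byrow = TRUE)
  list(rotation = R, translation = as.numeric(qbar - R %*% pbar))
}

# literal Benjamini-Hochberg step-up: largest k with p_(k) <= k * fdr / m,
# reject every p at or below that order statistic
bh_oracle_flags <- function(p, fdr) {
  m <- length(p)
  ps <- sort(p)
  ok <- which(ps <= seq_len(m) * fdr / m)
  if (length(ok) == 0) return(rep(FALSE, m))
  p <= ps[max(ok)]
}

# closed-form two-sample pooled-variance t statistic and p-value
student_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(statistic = t, df = df, p_value = 2 * pt(-abs(t), df))
}

# exhaustive geometric hydrogen-bond scan (heavy-atom criterion), written
# as plain nested loops over the donor/acceptor tables
hbond_scan_oracle <- function(coords, top, d_max = 3.5) {
  donors <- acceptors <- integer(0)
  sd_tab <- paste(loopshift:::sidechain_donors$residue_name,
                  loopshift:::sidechain_donors$atom_name)
  sa_tab <- paste(loopshift:::sidechain_acceptors$residue_name,
                  loopshift:::sidechain_acceptors$atom_name)
  for (i in seq_len(nrow(top))) {
    key <- paste(top$residue_name[i], top$atom_name[i])
    if ((top$atom_name[i] == "N" && top$residue_name[i] != "PRO") ||
        key %in% sd_tab) donors <- c(donors, i)
    if (top$atom_name[i] == "O" || key %in% sa_tab) acceptors <- c(acceptors, i)
  }
  bb <- c("N", "CA", "C", "O")
  out <- character(0)
  for (d in donors) {
    for (a in acceptors) {
      if (d == a) next
      same_res <- top$residue_index[d] == top$residue_index[a] &&
        top$chain_id[d] == top$chain_id[a]
      d_bb <- top$atom_name[d] %in% bb
      a_bb <- top$atom_name[a] %in% bb
      if (same_res && d_bb == a_bb) next
      if (d_bb && a_bb && top$chain_id[d] == top$chain_id[a] &&
          abs(top$residue_index[d] - top$residue_index[a]) < 3) next
      dist <- sqrt(sum((coords[d, ] - coords[a, ])^2))
      if (dist <= d_max) {
        lo <- if (top$residue_index[d] <= top$residue_index[a]) c(d, a) else c(a, d)
        if (top$residue_index[d] == top$residue_index[a] &&
            top$chain_id[d] > top$chain_id[a]) lo <- c(a, d)
        out <- c(out, paste("hbond", top$chain_id[lo[1]], top$residue_index[lo[1]],
                            top$atom_name[lo[1]], top$chain_id[lo[2]],
                            top$residue_index[lo[2]], top$atom_name[lo[2]],
                            sep = "|"))
      }
    }
  }
  sort(unique(out))
}

key_strings <- function(tab) {
  sort(paste(tab$kind, tab$chain_i, tab$res_i, tab$atom_i,
             tab$chain_j, tab$res_j, tab$atom_j, sep = "|"))
}

# small hand-writable PDB text, fixed-width per the standard
pdb_lines <- function(coords, atom_names = NULL, res_idx = NULL,
                      res_names = NULL, chain = "A", model = NULL) {
  n <- nrow(coords)
  atom_names <- atom_names %||% rep("CA", n)
  res_idx <- res_idx %||% seq_len(n)
  res_names <- res_names %||% rep("ALA", n)
  body <- vapply(seq_len(n), function(i) {
    sprintf("ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            i, atom_names[i], res_names[i], chain, res_idx[i],
            coords[i, 1], coords[i, 2], coords[i, 3])
  }, character(1))
  if (is.null(model)) c(body, "END") else c(sprintf("MODEL     %4d", model), body, "ENDMDL")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# tiny two-variant synthetic cohort used by several tests
quick_sim <- function(seed = 1, n_replicas = 3, n_frames = 300, ...) {
  spec <- loop_system_spec(n_replicas = n_replicas, n_frames = n_frames,
                           seed = seed, ...)
  simulate_loop_ensemble(spec)
}
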