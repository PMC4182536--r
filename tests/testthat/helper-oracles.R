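# Independent oracles and small fixture builders used across the suite.

# Horn's closed-form quaternion solution to the weighted orthogonal
# Procrustes problem; independent of the SVD route in the package.
horn_superpose <- function(mobile, reference, weights = NULL) {
  P <- as.matrix(mobile); Q <- as.matrix(reference)
  n <- nrow(P)
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  cp <- colSums(P * w); cq <- colSums(Q * w)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  M <- t(Pc * w) %*% Qc
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy, Szx - Sxz, Sxy - Syx,
    Syz - Szy, Sxx - Syy - Szz, Sxy + Syx, Szx + Sxz,
    Szx - Sxz, Sxy + Syx, -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx, Szx + Sxz, Syz + Szy, -Sxx - Syy + Szz), 4, 4, byrow = TRUE)
  ev <- eigen(N, symmetric = TRUE)
  q <- ev$vectors[, 1]
  q0 <- q[1]; qx <- q[2]; qy <- q[3]; qz <- q[4]
  R <- matrix(c(
    q0^2 + qx^2 - qy^2 - qz^2, 2 * (qx * qy - q0 * qz), 2 * (qx * qz + q0 * qy),
    2 * (qx * qy + q0 * qz), q0^2 - qx^2 + qy^2 - qz^2, 2 * (qy * qz - q0 * qx),
    2 * (qx * qz - q0 * qy), 2 * (qy * qz + q0 * qx), q0^2 - qx^2 - qy^2 + qz^2),
    3, 3, byrow = TRUE)
  diff <- Pc %*% t(R) - Qc
  list(rmsd = sqrt(sum(w * rowSums(diff^2))), rotation = t(R))
}

# Exhaustive double-loop contact probability (atoms x atoms x frames).
brute_contact_probability <- function(traj, chain_a, chain_b, cutoff,
                                      atom_policy = "all") {
  at <- traj$topology
  keep <- if (atom_policy == "heavy") at$element != "H" else rep(TRUE, nrow(at))
  ia <- which(at$chain == chain_a & keep)
  ib <- which(at$chain == chain_b & keep)
  res_a <- unique(at$resid[ia]); res_b <- unique(at$resid[ib])
  nf <- n_frames(traj)
  count_for <- function(res, own, other_idx) {
    cnt <- 0L
    rows <- own[at$resid[own] == res]
    for (f in seq_len(nf)) {
      hit <- FALSE
      for (i in rows) {
        for (j in other_idx) {
          d <- sqrt(sum((traj$coords[i, , f] - traj$coords[j, , f])^2))
          if (d <= cutoff) { hit <- TRUE; break }
        }
        if (hit) break
      }
      cnt <- cnt + hit
    }
    cnt / nf
  }
  list(a = vapply(res_a, count_for, numeric(1), own = ia, other_idx = ib),
       b = vapply(res_b, count_for, numeric(1), own = ib, other_idx = ia),
       res_a = res_a, res_b = res_b)
}

# Analytic solvent-accessible area of two overlapping spheres (radii are
# already solvent-expanded): each sphere loses a cap of height
# h_i = R_i - (d^2 + R_i^2 - R_j^2) / (2 d).
two_sphere_sas <- function(R1, R2, d) {
  if (d >= R1 + R2) return(4 * pi * (R1^2 + R2^2))
  h1 <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  h2 <- R2 - (d^2 + R2^2 - R1^2) / (2 * d)
  4 * pi * R1^2 - 2 * pi * R1 * h1 + 4 * pi * R2^2 - 2 * pi * R2 * h2
}

# Frame with arbitrary point atoms.
point_frame <- function(xyz, chain = "A", resid = seq_len(nrow(xyz)),
                        element = "C", name = "CA", resname = "ALA",
                        time = NA_real_) {
  n <- nrow(xyz)
  at <- atom_table(seq_len(n), rep_len(name, n), rep_len(resname, n),
                   resid, rep_len(chain, n), element = rep_len(element, n))
  structure_frame(at, xyz, time = time)
}

# Random tiny two-chain system for exact-equality checks.
random_tiny_system <- function(n_res_a = 3, n_res_b = 3, atoms_per_res = 2,
                               nf = 3, spread = 0.6) {
  na <- n_res_a * atoms_per_res; nb <- n_res_b * atoms_per_res
  at <- atom_table(
    seq_len(na + nb), rep("CA", na + nb), rep("ALA", na + nb),
    c(rep(seq_len(n_res_a), each = atoms_per_res),
      rep(seq_len(n_res_b), each = atoms_per_res)),
    c(rep("A", na), rep("B", nb)), element = rep("C", na + nb))
  coords <- array(stats::runif((na + nb) * 3 * nf, 0, spread),
                  c(na + nb, 3, nf))
  trajectory(at, coords, times = seq_len(nf))
}

rand_rotation <- function() {
  q <- stats::rnorm(4); q <- q / sqrt(sum(q^2))
  q0 <- q[1]; qx <- q[2]; qy <- q[3]; qz <- q[4]
  matrix(c(
    q0^2 + qx^2 - qy^2 - qz^2, 2 * (qx * qy - q0 * qz), 2 * (qx * qz + q0 * qy),
    2 * (qx * qy + q0 * qz), q0^2 - qx^2 + qy^2 - qz^2, 2 * (qy * qz - q0 * qx),
    2 * (qx * qz - q0 * qy), 2 * (qy * qz + q0 * qx), q0^2 - qx^2 - qy^2 + qz^2),
    3, 3, byrow = TRUE)
}

apply_rigid <- function(traj, R, t) {
  for (f in seq_len(n_frames(traj))) {
    traj$coords[, , f] <- sweep(traj$coords[, , f] %*% R, 2, t, "+")
  }
  traj
}
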