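# Superposition and scalar geometric observables.

#' Mass-weighted Kabsch superposition
#'
#' Finds the proper rotation and translation minimizing the mass-weighted
#' RMSD between two coordinate sets, via SVD of the weighted covariance with
#' the usual determinant correction against improper rotations.
#'
#' The aligned mobile set is `sweep(mobile, 2, trans_pre) %*% rotation`
#' translated onto the reference centroid; use [apply_superposition()].
#'
#' @param mobile,reference n x 3 matrices (nm), equal n >= 3, non-collinear.
#' @param weights Per-atom weights (typically masses); default uniform.
#' @return List of class `superposition_result`: `rotation` (3 x 3, det +1),
#'   `translation` (length-3, nm), `rmsd` (nm). `translation` is defined so
#'   that `aligned = mobile %*% rotation + translation` (row vectors).
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  P <- as.matrix(mobile); Q <- as.matrix(reference)
  if (!all(dim(P) == dim(Q)) || ncol(P) != 3L) {
    stop("mobile and reference must be equal-size n x 3 matrices")
  }
  n <- nrow(P)
  if (n < 3L) stop("degenerate geometry: need >= 3 atoms to superpose")
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  cp <- colSums(P * w); cq <- colSums(Q * w)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  # collinearity check: rank of the weighted point cloud
  if (qr(Pc * sqrt(w))$rank < 2L || qr(Qc * sqrt(w))$rank < 2L) {
    stop("degenerate geometry: collinear coordinates cannot be superposed")
  }
  H <- t(Pc * w) %*% Qc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  R <- t(R)  # acting on row vectors: aligned = Pc %*% R
  diff <- Pc %*% R - Qc
  rmsd <- sqrt(sum(w * rowSums(diff^2)))
  structure(list(rotation = R, translation = as.numeric(cq - cp %*% R),
                 rmsd = rmsd),
            class = "superposition_result")
}

#' Apply a superposition result to coordinates
#'
#' @param coords n x 3 matrix.
#' @param sup A `superposition_result`.
#' @return Transformed n x 3 matrix.
#' @export
apply_superposition <- function(coords, sup) {
  sweep(as.matrix(coords) %*% sup$rotation, 2, -sup$translation)
}

#' Per-frame RMSD against a reference structure
#'
#' Each frame is mass-weighted superposed on the selection before the RMSD
#' is evaluated on that same selection.
#'
#' @param traj A trajectory.
#' @param reference A structure_frame with the same topology.
#' @param selection Atom indices used both to fit and to measure.
#' @return A [scalar_series()] (nm).
#' @export
rmsd_series <- function(traj, reference, selection = seq_len(n_atoms(traj))) {
  if (!length(selection)) stop("empty selection")
  ref <- reference$coords[selection, , drop = FALSE]
  w <- traj$topology$mass[selection]
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    kabsch_superpose(traj$coords[selection, , f], ref, w)$rmsd
  }, numeric(1))
  scalar_series(traj$times, vals, "RMSD (nm)")
}

#' Per-residue RMSF profile
#'
#' Two-pass iterated-mean reference: frames are first fitted (mass-weighted,
#' on `fit_selection`) to frame 1 and averaged; every frame is then refitted
#' to that mean structure and the mean is recomputed. RMSF is
#' `sqrt(<|r_i - <r_i>|^2>)` for one reported atom per residue.
#'
#' @param traj A trajectory with >= 2 frames.
#' @param fit_selection Atom indices for the superposition fit (e.g. the
#'   globular core C-alphas, so a mobile region does not deflate itself).
#' @param report_atoms Atom indices to report, one per residue (default: all
#'   C-alpha atoms). With `per_atom_mode = "residue-mean"` all atoms of each
#'   residue are averaged (mass-weighted) instead.
#' @param per_atom_mode `"atom"` or `"residue-mean"`.
#' @return A data.frame of class `fluctuation_profile`: chain, resid,
#'   rmsf (nm), plus attribute `fit_selection`.
#' @export
rmsf_profile <- function(traj, fit_selection = seq_len(n_atoms(traj)),
                         report_atoms = NULL,
                         per_atom_mode = c("atom", "residue-mean")) {
  per_atom_mode <- match.arg(per_atom_mode)
  nf <- n_frames(traj)
  if (nf < 2L) stop("RMSF needs at least 2 frames")
  if (!length(fit_selection)) stop("empty fit selection")
  at <- traj$topology
  w <- at$mass[fit_selection]

  fit_all <- function(ref_sel) {
    arr <- traj$coords
    out <- array(NA_real_, dim(arr))
    for (f in seq_len(nf)) {
      sup <- kabsch_superpose(arr[fit_selection, , f], ref_sel, w)
      out[, , f] <- apply_superposition(arr[, , f], sup)
    }
    out
  }
  # pass 1: fit to frame 1, average; pass 2: refit to the mean
  aligned <- fit_all(traj$coords[fit_selection, , 1])
  mean1 <- apply(aligned, c(1, 2), mean)
  traj2 <- traj; traj2$coords <- aligned
  aligned <- local({
    arr <- traj2$coords; out <- array(NA_real_, dim(arr))
    for (f in seq_len(nf)) {
      sup <- kabsch_superpose(arr[fit_selection, , f],
                              mean1[fit_selection, , drop = FALSE], w)
      out[, , f] <- apply_superposition(arr[, , f], sup)
    }
    out
  })
  mstruct <- apply(aligned, c(1, 2), mean)
  dev2 <- aligned
  for (f in seq_len(nf)) dev2[, , f] <- (aligned[, , f] - mstruct)^2
  msf_atom <- apply(dev2, 1, sum) / nf  # summed over x,y,z per atom

  if (per_atom_mode == "atom") {
    if (is.null(report_atoms)) {
      report_atoms <- which(at$name == "CA")
      if (!length(report_atoms)) stop("no CA atoms; supply report_atoms")
    }
    prof <- data.frame(chain = at$chain[report_atoms],
                       resid = at$resid[report_atoms],
                       rmsf = sqrt(msf_atom[report_atoms]))
  } else {
    key <- paste(at$chain, at$resid, sep = ":")
    agg <- tapply(seq_len(nrow(at)), key, function(idx) {
      sqrt(sum(at$mass[idx] * msf_atom[idx]) / sum(at$mass[idx]))
    })
    parts <- do.call(rbind, strsplit(names(agg), ":"))
    prof <- data.frame(chain = parts[, 1], resid = as.integer(parts[, 2]),
                       rmsf = as.numeric(agg))
    prof <- prof[order(prof$chain, prof$resid), ]
    rownames(prof) <- NULL
  }
  attr(prof, "fit_selection") <- fit_selection
  class(prof) <- c("fluctuation_profile", "data.frame")
  prof
}

#' Centre of mass of a coordinate selection
#'
#' @param frame A structure_frame.
#' @param selection Atom indices.
#' @param mass_weighted Use atomic masses (default) or plain average.
#' @return Length-3 numeric (nm).
#' @export
center_of_mass <- function(frame, selection = seq_len(nrow(frame$atoms)),
                           mass_weighted = TRUE) {
  if (!length(selection)) stop("empty selection")
  xyz <- frame$coords[selection, , drop = FALSE]
  w <- if (mass_weighted) frame$atoms$mass[selection] else rep(1, length(selection))
  colSums(xyz * (w / sum(w)))
}

#' Radius of gyration
#'
#' `RG = sqrt(sum m_i |r_i - r_com|^2 / sum m_i)`; the geometric variant
#' uses unit masses.
#'
#' @param frame A structure_frame.
#' @param selection Atom indices (default all).
#' @param mass_weighted Logical.
#' @return RG in nm.
#' @export
radius_of_gyration <- function(frame, selection = seq_len(nrow(frame$atoms)),
                               mass_weighted = TRUE) {
  if (!length(selection)) stop("empty selection")
  xyz <- frame$coords[selection, , drop = FALSE]
  w <- if (mass_weighted) frame$atoms$mass[selection] else rep(1, length(selection))
  w <- w / sum(w)
  com <- colSums(xyz * w)
  sqrt(sum(w * rowSums(sweep(xyz, 2, com)^2)))
}

#' Per-frame radius-of-gyration series
#'
#' @inheritParams radius_of_gyration
#' @param traj A trajectory.
#' @return A [scalar_series()] (nm).
#' @export
rg_series <- function(traj, selection = seq_len(n_atoms(traj)),
                      mass_weighted = TRUE) {
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    radius_of_gyration(get_frame(traj, f), selection, mass_weighted)
  }, numeric(1))
  scalar_series(traj$times, vals, "RG (nm)")
}

#' Distance between a region's COM and a body's COM, per frame
#'
#' @param traj A trajectory.
#' @param region A [region_spec()] (e.g. helix alpha-4, residues 84-87).
#' @param whole Atom indices of the reference body (e.g. the whole monomer);
#'   default: all atoms on the region's chain.
#' @param mass_weighted Logical.
#' @return A [scalar_series()] (nm).
#' @export
region_com_distance <- function(traj, region, whole = NULL,
                                mass_weighted = TRUE) {
  sel_region <- resolve_region(traj, region)
  if (is.null(whole)) whole <- which(traj$topology$chain == region$chain)
  if (!all(sel_region %in% whole)) {
    stop("region atoms are not a subset of the reference body")
  }
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    fr <- get_frame(traj, f)
    sqrt(sum((center_of_mass(fr, sel_region, mass_weighted) -
                center_of_mass(fr, whole, mass_weighted))^2))
  }, numeric(1))
  scalar_series(traj$times, vals, sprintf("d(%s, COM) (nm)", region$label))
}
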