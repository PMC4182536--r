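# Inter-monomer contacts and surface-based interface measures.
#
# A residue of monomer A is "in contact" in a snapshot when the minimum
# distance between its atoms and the atoms of ANY residue of monomer B is
# less than or equal to the cutoff (0.28 nm by default, roughly one water
# diameter; threshold inclusive). The contact probability is the number of
# contact snapshots divided by the number of snapshots, an exact rational.

.cross_d2 <- function(A, B) {
  # squared Euclidean distances, |a|^2 + |b|^2 - 2 a.b expansion
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  d2
}

.exact_d2 <- function(a, b) sum((a - b)^2)

.policy_keep <- function(atoms, atom_policy) {
  if (atom_policy == "heavy") atoms$element != "H" else rep(TRUE, nrow(atoms))
}

#' Minimum inter-residue atom distance
#'
#' @param frame A structure_frame.
#' @param res_a,res_b Residues as `list(chain =, resid =)`.
#' @param atom_policy `"all"` (every atom present) or `"heavy"` (exclude H).
#' @return Minimum pairwise distance in nm.
#' @export
residue_min_distance <- function(frame, res_a, res_b,
                                 atom_policy = c("all", "heavy")) {
  atom_policy <- match.arg(atom_policy)
  at <- frame$atoms
  keep <- .policy_keep(at, atom_policy)
  ia <- which(at$chain == res_a$chain & at$resid == res_a$resid & keep)
  ib <- which(at$chain == res_b$chain & at$resid == res_b$resid & keep)
  if (!length(ia) || !length(ib)) {
    stop("residue with zero selected atoms under policy '", atom_policy, "'")
  }
  A <- frame$coords[ia, , drop = FALSE]; B <- frame$coords[ib, , drop = FALSE]
  d2 <- .cross_d2(A, B)
  ij <- arrayInd(which.min(d2), dim(d2))
  # recompute the winning pair by direct subtraction: exact at the threshold
  sqrt(.exact_d2(A[ij[1], ], B[ij[2], ]))
}

.chain_residues <- function(atoms, chain, keep) {
  idx <- which(atoms$chain == chain & keep)
  if (!length(idx)) stop("chain '", chain, "' has no atoms under this policy")
  resid <- atoms$resid[idx]
  ures <- unique(resid)
  list(idx = idx, res_of_atom = match(resid, ures), resids = ures,
       resnames = atoms$resname[idx][match(ures, resid)])
}

# Per-atom minimum squared distance to the other set, with the argmin,
# then reduced to per-residue minima. Winning pairs are recomputed by
# direct subtraction so threshold comparisons are exact.
.residue_min_to_partner <- function(A, B, res_of_a) {
  d2 <- .cross_d2(A, B)
  jmin <- max.col(-d2, ties.method = "first")
  amin <- d2[cbind(seq_len(nrow(A)), jmin)]
  vapply(split(seq_len(nrow(A)), res_of_a), function(rows) {
    i <- rows[which.min(amin[rows])]
    .exact_d2(A[i, ], B[jmin[i], ])
  }, numeric(1))
}

#' Per-residue inter-monomer contact probability
#'
#' For each residue and frame, the residue is in contact iff its minimum
#' distance to any residue of the partner chain is <= `cutoff` (inclusive).
#' Probability = contact frames / total frames (exact integer counting).
#'
#' @param traj A trajectory containing both chains.
#' @param chain_a,chain_b Distinct chain ids.
#' @param cutoff Contact cutoff in nm (default 0.28).
#' @param atom_policy `"all"` or `"heavy"`; with hydrogen-containing models
#'   the heavy-atom policy matches the water-diameter reading of the cutoff.
#' @return Object of class `contact_profile`: list with data.frames `a` and
#'   `b` (chain, resid, resname, count, probability), `cutoff`, `n_frames`,
#'   `atom_policy`.
#' @export
contact_probability <- function(traj, chain_a, chain_b, cutoff = 0.28,
                                atom_policy = c("all", "heavy")) {
  atom_policy <- match.arg(atom_policy)
  if (identical(chain_a, chain_b)) stop("chain_a and chain_b must differ")
  nf <- n_frames(traj)
  if (nf < 1L) stop("trajectory has no frames")
  at <- traj$topology
  keep <- .policy_keep(at, atom_policy)
  ca <- .chain_residues(at, chain_a, keep)
  cb <- .chain_residues(at, chain_b, keep)
  cut2 <- cutoff^2
  counts_a <- integer(length(ca$resids))
  counts_b <- integer(length(cb$resids))
  for (f in seq_len(nf)) {
    X <- traj$coords[, , f]
    A <- X[ca$idx, , drop = FALSE]
    B <- X[cb$idx, , drop = FALSE]
    counts_a <- counts_a +
      (.residue_min_to_partner(A, B, ca$res_of_atom) <= cut2)
    counts_b <- counts_b +
      (.residue_min_to_partner(B, A, cb$res_of_atom) <= cut2)
  }
  mk <- function(ch, cc, counts) data.frame(
    chain = ch, resid = cc$resids, resname = cc$resnames,
    count = as.integer(counts), probability = as.integer(counts) / nf)
  structure(list(a = mk(chain_a, ca, counts_a), b = mk(chain_b, cb, counts_b),
                 cutoff = cutoff, n_frames = nf, atom_policy = atom_policy),
            class = "contact_profile")
}

#' Residue-residue contact frequency map
#'
#' Entry (i, j) is the fraction of frames in which the minimum atom distance
#' between residue i of chain A and residue j of chain B is <= `cutoff`.
#' The any-partner contact probability of residue i is therefore at least
#' the row maximum of its map row (union of events).
#'
#' @inheritParams contact_probability
#' @return Object of class `contact_map`: `freq` matrix (rows = chain A
#'   residues, columns = chain B residues, dimnames = resids), `cutoff`,
#'   `n_frames`, `atom_policy`.
#' @export
contact_map <- function(traj, chain_a, chain_b, cutoff = 0.28,
                        atom_policy = c("all", "heavy")) {
  atom_policy <- match.arg(atom_policy)
  if (identical(chain_a, chain_b)) stop("chain_a and chain_b must differ")
  nf <- n_frames(traj)
  if (nf < 1L) stop("trajectory has no frames")
  at <- traj$topology
  keep <- .policy_keep(at, atom_policy)
  ca <- .chain_residues(at, chain_a, keep)
  cb <- .chain_residues(at, chain_b, keep)
  cut2 <- cutoff^2
  nra <- length(ca$resids); nrb <- length(cb$resids)
  counts <- matrix(0L, nra, nrb,
                   dimnames = list(ca$resids, cb$resids))
  rows_a <- split(seq_along(ca$idx), ca$res_of_atom)
  cols_b <- split(seq_along(cb$idx), cb$res_of_atom)
  for (f in seq_len(nf)) {
    X <- traj$coords[, , f]
    A <- X[ca$idx, , drop = FALSE]
    B <- X[cb$idx, , drop = FALSE]
    d2 <- .cross_d2(A, B)
    # reduce columns to per-B-residue minima, then rows to per-A-residue
    m1 <- vapply(cols_b, function(cc) {
      if (length(cc) == 1L) d2[, cc] else do.call(pmin, asplit(d2[, cc, drop = FALSE], 2))
    }, numeric(length(ca$idx)))
    m2 <- t(vapply(rows_a, function(rr) {
      if (length(rr) == 1L) m1[rr, ] else do.call(pmin, asplit(m1[rr, , drop = FALSE], 1))
    }, numeric(nrb)))
    counts <- counts + (m2 <= cut2)
  }
  structure(list(freq = counts / nf, cutoff = cutoff, n_frames = nf,
                 atom_policy = atom_policy),
            class = "contact_map")
}

#' Ranked interface residue table
#'
#' Residues whose any-partner contact probability reaches `threshold`,
#' with their most frequent partner residue and side-chain polarity classes.
#' Ranking is by descending probability, ties broken by residue id.
#'
#' @param profiles A `contact_profile` (both monomers are tabulated).
#' @param map The matching `contact_map`.
#' @param threshold Minimum probability to include (default 0.25).
#' @return data.frame: chain, resid, resname, probability, polarity,
#'   partner_chain, partner_resid, partner_resname, partner_freq,
#'   partner_polarity.
#' @export
interface_table <- function(profiles, map, threshold = 0.25) {
  one_side <- function(df, freq, partner_resids, partner_resnames,
                       partner_chain, by_row) {
    sel <- which(df$probability >= threshold)
    if (!length(sel)) return(NULL)
    rows <- lapply(sel, function(i) {
      v <- if (by_row) freq[i, ] else freq[, i]
      j <- which.max(v)
      data.frame(chain = df$chain[i], resid = df$resid[i],
                 resname = df$resname[i], probability = df$probability[i],
                 polarity = residue_polarity(df$resname[i]),
                 partner_chain = partner_chain,
                 partner_resid = partner_resids[j],
                 partner_resname = partner_resnames[j],
                 partner_freq = as.numeric(v[j]),
                 partner_polarity = residue_polarity(partner_resnames[j]))
    })
    do.call(rbind, rows)
  }
  chain_a <- profiles$a$chain[1]; chain_b <- profiles$b$chain[1]
  tab <- rbind(
    one_side(profiles$a, map$freq, profiles$b$resid, profiles$b$resname,
             chain_b, by_row = TRUE),
    one_side(profiles$b, map$freq, profiles$a$resid, profiles$a$resname,
             chain_a, by_row = FALSE)
  )
  if (is.null(tab)) {
    tab <- data.frame(chain = character(), resid = integer(),
                      resname = character(), probability = numeric(),
                      polarity = character(), partner_chain = character(),
                      partner_resid = integer(), partner_resname = character(),
                      partner_freq = numeric(), partner_polarity = character())
  }
  tab <- tab[order(-tab$probability, tab$resid), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

# Deterministic golden-section spiral point set on the unit sphere; no RNG,
# so SAS values are bit-reproducible for a given n.
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Counts, for every atom, test points on its solvent-expanded sphere
#' (radius vdW + probe) that fall outside all neighbouring expanded spheres.
#' Per-atom area = exposed fraction x 4 pi (r + probe)^2. The point set is a
#' deterministic golden-section spiral, so results are reproducible bit for
#' bit at fixed `n_points`.
#'
#' @param frame A structure_frame.
#' @param selection Atom indices to include (default all). Atoms outside the
#'   selection do not occlude.
#' @param probe Probe radius in nm (default 0.14, a water radius).
#' @param n_points Test points per atom (default 960).
#' @return Object of class `sas_result`: `area` (per selected atom, nm^2),
#'   `total` (nm^2), `probe`, `n_points`, `selection`.
#' @export
shrake_rupley_sas <- function(frame, selection = seq_len(nrow(frame$atoms)),
                              probe = 0.14, n_points = 960L) {
  if (!length(selection)) stop("empty selection")
  at <- frame$atoms
  lab <- paste0(at$chain[selection], at$resid[selection], ":", at$name[selection])
  radii <- vdw_radius(at$element[selection], context = lab)
  xyz <- frame$coords[selection, , drop = FALSE]
  n <- length(selection)
  pts <- .sphere_points(n_points)
  rext <- radii + probe
  area <- numeric(n)
  maxr <- max(rext)
  for (i in seq_len(n)) {
    d2_nb <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2_nb < (rext[i] + maxr)^2 & seq_len(n) != i)
    nb <- nb[d2_nb[nb] < (rext[i] + rext[nb])^2]
    p <- sweep(pts * rext[i], 2, xyz[i, ], "+")
    if (length(nb)) {
      buried <- rep(FALSE, n_points)
      for (j in nb) {
        if (all(buried)) break
        d2 <- rowSums(sweep(p, 2, xyz[j, ])^2)
        buried <- buried | (d2 < rext[j]^2)
      }
      frac <- sum(!buried) / n_points
    } else frac <- 1
    area[i] <- frac * 4 * pi * rext[i]^2
  }
  structure(list(area = area, total = sum(area), probe = probe,
                 n_points = as.integer(n_points), selection = selection),
            class = "sas_result")
}

#' Buried contact surface between two chains
#'
#' `CS = (SAS(A alone) + SAS(B alone) - SAS(A and B together)) / 2`;
#' the factor 1/2 assigns half of the buried area to each partner
#' (disable with `halve = FALSE` to get the total buried area).
#'
#' @param frame A structure_frame containing both chains.
#' @param chain_a,chain_b Chain ids.
#' @param probe Probe radius (nm).
#' @param n_points Test points per atom.
#' @param halve Logical; see above.
#' @return Contact surface in nm^2.
#' @export
contact_surface_area <- function(frame, chain_a, chain_b, probe = 0.14,
                                 n_points = 960L, halve = TRUE) {
  ia <- which(frame$atoms$chain == chain_a)
  ib <- which(frame$atoms$chain == chain_b)
  if (!length(ia) || !length(ib)) stop("both chains must contain atoms")
  sa <- shrake_rupley_sas(frame, ia, probe, n_points)$total
  sb <- shrake_rupley_sas(frame, ib, probe, n_points)$total
  sab <- shrake_rupley_sas(frame, c(ia, ib), probe, n_points)$total
  cs <- sa + sb - sab
  if (halve) cs / 2 else cs
}

#' Per-frame contact surface series
#'
#' @inheritParams contact_surface_area
#' @param traj A trajectory.
#' @return A [scalar_series()] (nm^2).
#' @export
contact_surface_series <- function(traj, chain_a, chain_b, probe = 0.14,
                                   n_points = 960L, halve = TRUE) {
  vals <- vapply(seq_len(n_frames(traj)), function(f) {
    contact_surface_area(get_frame(traj, f), chain_a, chain_b, probe,
                         n_points, halve)
  }, numeric(1))
  scalar_series(traj$times, vals, "contact surface (nm^2)")
}
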