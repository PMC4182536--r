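# Backbone dihedrals, Ramachandran classification and a hydrogen-bond-based
# secondary-structure assigner in the Kabsch-Sander tradition.

#' Torsion angle of four points
#'
#' IUPAC sign convention; returns degrees in (-180, 180].
#'
#' @param p1,p2,p3,p4 Length-3 coordinates (nm).
#' @return Angle in degrees. Collinear inner atoms are an error.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (sum(n1^2) < 1e-16 || sum(n2^2) < 1e-16) {
    stop("undefined dihedral: collinear atoms")
  }
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  x <- sum(n1 * n2); y <- sum(m1 * n2) / sqrt(sum(b2^2))
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

.chain_backbone <- function(frame, chain) {
  at <- frame$atoms
  idx <- which(at$chain == chain)
  if (!length(idx)) stop("chain '", chain, "' not present")
  resids <- unique(at$resid[idx])
  pick <- function(rid, nm) {
    j <- idx[at$resid[idx] == rid & at$name[idx] == nm]
    if (length(j)) j[1] else NA_integer_
  }
  list(resids = resids,
       resnames = vapply(resids, function(r) at$resname[idx[at$resid[idx] == r][1]], character(1)),
       N = vapply(resids, pick, integer(1), nm = "N"),
       CA = vapply(resids, pick, integer(1), nm = "CA"),
       C = vapply(resids, pick, integer(1), nm = "C"),
       O = vapply(resids, pick, integer(1), nm = "O"),
       H = vapply(resids, pick, integer(1), nm = "H"))
}

# A peptide bond is considered broken when the C(i-1)-N(i) distance strays
# far from the covalent 0.133 nm; dihedrals across a break are undefined and
# hydrogen-bond patterns may not span it.
.PEPTIDE_BREAK <- 0.25  # nm

.chain_breaks <- function(xyz, bb) {
  n <- length(bb$resids)
  if (n < 2L) return(logical(0))
  vapply(2:n, function(i) {
    if (is.na(bb$C[i - 1]) || is.na(bb$N[i])) return(TRUE)
    sqrt(sum((xyz[bb$C[i - 1], ] - xyz[bb$N[i], ])^2)) > .PEPTIDE_BREAK
  }, logical(1))  # break_before[i - 1]: TRUE if bond (i-1)->i is broken
}

#' Backbone phi/psi dihedrals of one chain
#'
#' phi = C(i-1)-N-CA-C, psi = N-CA-C-N(i+1). Terminal,
#' missing-atom, or chain-break dihedrals (peptide C-N distance
#' beyond 0.25 nm) are returned as `NA` with their `*_defined` flag set
#' `FALSE`, never silently dropped.
#'
#' @param frame A structure_frame.
#' @param chain Chain id.
#' @return data.frame: chain, resid, resname, phi, psi, phi_defined,
#'   psi_defined (degrees).
#' @export
backbone_dihedrals <- function(frame, chain) {
  bb <- .chain_backbone(frame, chain)
  n <- length(bb$resids)
  xyz <- frame$coords
  brk <- .chain_breaks(xyz, bb)  # brk[i-1]: bond (i-1)->i broken
  phi <- psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i > 1 && !brk[i - 1] &&
        !anyNA(c(bb$C[i - 1], bb$N[i], bb$CA[i], bb$C[i]))) {
      phi[i] <- dihedral_angle(xyz[bb$C[i - 1], ], xyz[bb$N[i], ],
                               xyz[bb$CA[i], ], xyz[bb$C[i], ])
    }
    if (i < n && !brk[i] &&
        !anyNA(c(bb$N[i], bb$CA[i], bb$C[i], bb$N[i + 1]))) {
      psi[i] <- dihedral_angle(xyz[bb$N[i], ], xyz[bb$CA[i], ],
                               xyz[bb$C[i], ], xyz[bb$N[i + 1], ])
    }
  }
  data.frame(chain = chain, resid = bb$resids, resname = bb$resnames,
             phi = phi, psi = psi,
             phi_defined = !is.na(phi), psi_defined = !is.na(psi))
}

#' Default Ramachandran region map
#'
#' A rectangular-polygon approximation of the classic core /
#' additional-allowed / generous regions, with dedicated maps for glycine
#' and proline. Shipped as a data file
#' (`extdata/rama_regions.csv`) so it can be substituted.
#'
#' @param path Optional path to an alternative region CSV.
#' @return data.frame: res_class, region, phi_min, phi_max, psi_min, psi_max.
#' @export
default_rama_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "rama_regions.csv", package = "dimerlens")
  }
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Classify backbone dihedrals into Ramachandran regions
#'
#' Region lookup is ordered core, allowed, generous; anything outside is
#' disallowed. Glycine and proline use their own maps. Undefined dihedrals
#' are excluded from the summary denominator.
#'
#' @param records Output of [backbone_dihedrals()] (rows from several frames
#'   may be concatenated).
#' @param region_map Region rectangles (default [default_rama_map()]).
#' @return List: `labels` (records plus a `region` column) and
#'   `favored_fraction` (fraction of defined residues in core or allowed).
#' @export
ramachandran_classify <- function(records, region_map = default_rama_map()) {
  cls <- ifelse(records$resname == "GLY", "gly",
                ifelse(records$resname == "PRO", "pro", "general"))
  region <- rep(NA_character_, nrow(records))
  ok <- records$phi_defined & records$psi_defined
  for (i in which(ok)) {
    sub <- region_map[region_map$res_class == cls[i], , drop = FALSE]
    lab <- "disallowed"
    for (reg in c("core", "allowed", "generous")) {
      rr <- sub[sub$region == reg, , drop = FALSE]
      hit <- records$phi[i] >= rr$phi_min & records$phi[i] <= rr$phi_max &
        records$psi[i] >= rr$psi_min & records$psi[i] <= rr$psi_max
      if (any(hit)) { lab <- reg; break }
    }
    region[i] <- lab
  }
  labels <- records
  labels$region <- region
  favored <- mean(region[ok] %in% c("core", "allowed"))
  list(labels = labels, favored_fraction = favored)
}

# Kabsch-Sander electrostatic H-bond energy (kcal/mol); distances in
# angstrom inside, coordinates come in as nm.
.ks_energy <- function(rON, rCH, rOH, rCN) {
  0.084 * 332 * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
}

.assign_ss_chain <- function(frame, chain) {
  bb <- .chain_backbone(frame, chain)
  n <- length(bb$resids)
  if (n < 5L) {
    warning("chain ", chain, " has fewer than 5 residues; all coil")
    return(data.frame(chain = chain, resid = bb$resids,
                      ss = rep("C", n), stringsAsFactors = FALSE))
  }
  if (anyNA(bb$N) || anyNA(bb$CA) || anyNA(bb$C) || anyNA(bb$O)) {
    stop("secondary-structure assignment needs N, CA, C, O for every residue")
  }
  xyz <- frame$coords
  brk <- .chain_breaks(xyz, bb)  # brk[i-1]: bond (i-1)->i broken
  Np <- xyz[bb$N, , drop = FALSE]; CAp <- xyz[bb$CA, , drop = FALSE]
  Cp <- xyz[bb$C, , drop = FALSE]; Op <- xyz[bb$O, , drop = FALSE]
  # Amide H: taken from the file when present, else placed 0.1 nm from N
  # opposite the preceding C=O direction. The chain's first residue (and the
  # first residue after a chain break) gets no H and cannot donate.
  Hp <- matrix(NA_real_, n, 3)
  for (i in 2:n) {
    if (!is.na(bb$H[i])) {
      Hp[i, ] <- xyz[bb$H[i], ]
    } else if (!brk[i - 1]) {
      u <- Cp[i - 1, ] - Op[i - 1, ]
      Hp[i, ] <- Np[i, ] + 0.1 * u / sqrt(sum(u^2))
    }
  }
  # candidate donor/acceptor pairs: CA-CA within 0.9 nm, |i-j| >= 3 in
  # either direction but never closer than 2 in sequence
  d2ca <- .cross_d2(CAp, CAp)
  cand <- which(d2ca < 0.81, arr.ind = TRUE)
  cand <- cand[abs(cand[, 1] - cand[, 2]) >= 3L, , drop = FALSE]
  hb <- matrix(FALSE, n, n)  # hb[acceptor i (C=O), donor j (N-H)]
  if (nrow(cand)) {
    acc <- cand[, 1]; don <- cand[, 2]
    has_h <- !is.na(Hp[don, 1])
    acc <- acc[has_h]; don <- don[has_h]
    if (length(acc)) {
      dist <- function(P, Q) sqrt(rowSums((P - Q)^2)) * 10  # nm -> angstrom
      E <- .ks_energy(dist(Op[acc, , drop = FALSE], Np[don, , drop = FALSE]),
                      dist(Cp[acc, , drop = FALSE], Hp[don, , drop = FALSE]),
                      dist(Op[acc, , drop = FALSE], Hp[don, , drop = FALSE]),
                      dist(Cp[acc, , drop = FALSE], Np[don, , drop = FALSE]))
      bond <- E < -0.5
      hb[cbind(acc[bond], don[bond])] <- TRUE
    }
  }
  # sequential turns may not span a chain break
  span_ok <- function(i, k) {
    vapply(i, function(ii) !any(brk[seq(ii, ii + k - 1)]), logical(1))
  }
  turn <- function(k) {
    idx <- seq_len(n - k)
    v <- rep(FALSE, n)
    v[idx] <- hb[cbind(idx, idx + k)] & span_ok(idx, k)
    v
  }
  t3 <- turn(3); t4 <- turn(4); t5 <- turn(5)
  helix <- rep(FALSE, n)
  mark <- function(tn, span) {
    for (i in which(tn)) {
      if (i > 1 && tn[i - 1]) helix[i:(i + span - 1)] <<- TRUE
    }
  }
  mark(t4, 4L)  # alpha
  mark(t3, 3L)  # 3-10, folded into helix for the 3-state view
  mark(t5, 5L)  # pi, likewise
  # bridges (parallel / antiparallel); both partners become sheet unless
  # already helix (helix takes priority)
  sheet <- rep(FALSE, n)
  Hb <- function(i, j) {
    ok <- i >= 1 & i <= n & j >= 1 & j <= n
    out <- rep(FALSE, length(i))
    out[ok] <- hb[cbind(i[ok], j[ok])]
    out
  }
  pairs <- which(d2ca < 0.81, arr.ind = TRUE)
  pairs <- pairs[pairs[, 2] - pairs[, 1] >= 3L, , drop = FALSE]
  if (nrow(pairs)) {
    i <- pairs[, 1]; j <- pairs[, 2]
    par <- (Hb(i - 1, j) & Hb(j, i + 1)) | (Hb(j - 1, i) & Hb(i, j + 1))
    anti <- (Hb(i, j) & Hb(j, i)) | (Hb(i - 1, j + 1) & Hb(j - 1, i + 1))
    br <- par | anti
    sheet[unique(c(i[br], j[br]))] <- TRUE
  }
  ss <- ifelse(helix, "H", ifelse(sheet, "E", "C"))
  data.frame(chain = chain, resid = bb$resids, ss = ss,
             stringsAsFactors = FALSE)
}

#' Assign 3-state secondary structure to one frame
#'
#' Hydrogen bonds are detected with the Kabsch-Sander electrostatic energy
#' (bond iff E < -0.5 kcal/mol); runs of consecutive n-turns give helix
#' (alpha, 3-10 and pi all fold into H for the 3-state view), parallel and
#' antiparallel bridge patterns give sheet, everything else is coil.
#' Chains shorter than 5 residues are all coil, with a warning.
#'
#' @param frame A structure_frame.
#' @param chains Chain ids to assign (default all).
#' @return data.frame: chain, resid, ss in {"H", "E", "C"}.
#' @export
assign_secondary_structure <- function(frame, chains = NULL) {
  if (is.null(chains)) chains <- unique(frame$atoms$chain)
  do.call(rbind, lapply(chains, function(ch) .assign_ss_chain(frame, ch)))
}

#' Per-residue secondary-structure occupancies over a trajectory
#'
#' @param traj A trajectory.
#' @param chain Chain id.
#' @return data.frame of class `ss_profile`: chain, resid, helix, sheet,
#'   coil (fractions summing to 1 per residue), with `n_frames` attribute.
#' @export
ss_profile <- function(traj, chain) {
  nf <- n_frames(traj)
  counts <- NULL
  for (f in seq_len(nf)) {
    ss <- .assign_ss_chain(get_frame(traj, f), chain)
    if (is.null(counts)) {
      counts <- data.frame(chain = ss$chain, resid = ss$resid,
                           H = 0L, E = 0L, C = 0L)
    }
    counts$H <- counts$H + (ss$ss == "H")
    counts$E <- counts$E + (ss$ss == "E")
    counts$C <- counts$C + (ss$ss == "C")
  }
  prof <- data.frame(chain = counts$chain, resid = counts$resid,
                     helix = counts$H / nf, sheet = counts$E / nf,
                     coil = counts$C / nf)
  attr(prof, "n_frames") <- nf
  class(prof) <- c("ss_profile", "data.frame")
  prof
}

#' Helix-fraction difference between two conditions over a region
#'
#' Helix fraction under condition b minus condition a, per residue of the
#' region; negative values mean helix loss in b.
#'
#' @param profile_a,profile_b [ss_profile()] outputs (conditions a and b).
#' @param region A [region_spec()]. Chain matching uses the profiles' own
#'   chain column when the region chain is absent from a profile computed on
#'   a renamed monomer.
#' @return data.frame: resid, helix_a, helix_b, delta_helix.
#' @export
helix_loss_fraction <- function(profile_a, profile_b, region) {
  sel <- function(p) {
    rows <- p$resid >= region$first_resid & p$resid <= region$last_resid
    if (region$chain %in% p$chain) rows <- rows & p$chain == region$chain
    p[rows, , drop = FALSE]
  }
  a <- sel(profile_a); b <- sel(profile_b)
  if (!nrow(a) || !identical(a$resid, b$resid)) {
    stop("profiles cover different residue sets over region '",
         region$label, "'")
  }
  data.frame(resid = a$resid, helix_a = a$helix, helix_b = b$helix,
             delta_helix = b$helix - a$helix)
}
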