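# Seeded synthetic two-chain trajectory generator.
#
# The generator plants ground truth *geometrically*: contacts are realized by
# placing partner-residue atoms at 0.9 x cutoff from the target residue
# (non-contacts stay far), compactness states by radially scaling the hairpin
# about the chain's centre of mass to hit an exact per-frame RG target,
# helix-coil switching by rebuilding a dihedral block in place (downstream
# atoms stay anchored), and region exposure by displacing the region outward
# along the COM axis. Scaling and anchored rebuilds deliberately sacrifice
# bond-geometry realism away from the probed observables; they are test
# devices, not physical models, and are documented as such.

.BB <- list(
  b_NCA = 0.1458, b_CAC = 0.1525, b_CN = 0.1329, b_CO = 0.1231,
  b_CACB = 0.1530,
  a_NCAC = 111.0, a_CACN = 116.2, a_CNCA = 121.7, a_CACO = 120.8,
  a_NCACB = 110.4, t_CB = -122.6, omega = 180
)

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Natural-extension (NeRF) placement: position D so that |C-D| = bond,
# angle(B,C,D) = angle_deg and torsion(A,B,C,D) = torsion_deg.
.nerf <- function(A, B, C, bond, angle_deg, torsion_deg) {
  th <- angle_deg * pi / 180; ph <- -torsion_deg * pi / 180
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  n <- .cross3(B - A, bc)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-12) stop("collinear reference atoms in internal-coordinate build")
  n <- n / nn
  m <- .cross3(n, bc)
  d <- bond * c(-cos(th), sin(th) * cos(ph), sin(th) * sin(ph))
  C + d[1] * bc + d[2] * m + d[3] * n
}

#' Build an ideal peptide backbone from internal coordinates
#'
#' Places N, CA, C, O and (except glycine) a CB side-chain proxy from
#' standard bond lengths and angles, reproducing the requested phi/psi
#' dihedrals (omega fixed trans). `phi[1]` is undefined for the first
#' residue and ignored; `psi[n]` only orients the final carbonyl.
#'
#' @param sequence One-letter string or vector of 3-letter residue codes.
#' @param phi,psi Per-residue dihedrals in degrees (recycled if length 1).
#' @param chain Chain id for the atom table.
#' @return A [structure_frame()].
#' @export
build_ideal_backbone <- function(sequence, phi = -57, psi = -47, chain = "A") {
  res3 <- if (length(sequence) == 1L) {
    one_to_three(sequence)  # a single string is a 1-letter sequence
  } else if (all(nchar(sequence) == 3L)) {
    toupper(sequence)       # a vector is 3-letter residue codes
  } else one_to_three(paste(sequence, collapse = ""))
  n <- length(res3)
  phi <- rep_len(phi, n); psi <- rep_len(psi, n)
  g <- .BB
  N <- CA <- C <- O <- CB <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_NCA, 0, 0)
  aa <- g$a_NCAC * pi / 180
  C[1, ] <- CA[1, ] + g$b_CAC * c(-cos(aa), sin(aa), 0)
  for (i in seq_len(n)) {
    if (i < n) {
      N[i + 1, ] <- .nerf(N[i, ], CA[i, ], C[i, ], g$b_CN, g$a_CACN, psi[i])
      CA[i + 1, ] <- .nerf(CA[i, ], C[i, ], N[i + 1, ], g$b_NCA, g$a_CNCA, g$omega)
      C[i + 1, ] <- .nerf(C[i, ], N[i + 1, ], CA[i + 1, ], g$b_CAC, g$a_NCAC,
                          phi[i + 1])
    }
    O[i, ] <- .nerf(N[i, ], CA[i, ], C[i, ], g$b_CO, g$a_CACO, psi[i] + 180)
    if (res3[i] != "GLY") {
      CB[i, ] <- .nerf(C[i, ], N[i, ], CA[i, ], g$b_CACB, g$a_NCACB, g$t_CB)
    }
  }
  nm <- c("N", "CA", "C", "O", "CB")
  rows <- lapply(seq_len(n), function(i) {
    have <- if (res3[i] == "GLY") 1:4 else 1:5
    data.frame(name = nm[have], resname = res3[i], resid = i,
               x = c(N[i, 1], CA[i, 1], C[i, 1], O[i, 1], CB[i, 1])[have],
               y = c(N[i, 2], CA[i, 2], C[i, 2], O[i, 2], CB[i, 2])[have],
               z = c(N[i, 3], CA[i, 3], C[i, 3], O[i, 3], CB[i, 3])[have])
  })
  df <- do.call(rbind, rows)
  atoms <- atom_table(seq_len(nrow(df)), df$name, df$resname, df$resid,
                      chain = rep(chain, nrow(df)))
  structure_frame(atoms, cbind(df$x, df$y, df$z))
}

#' Build an ideal two-strand antiparallel beta hairpin
#'
#' Two ideal strands placed antiparallel in hydrogen-bonding registry
#' (0.48 nm inter-strand offset, second strand rolled by pi), joined by a
#' short connector whose peptide bond is deliberately broken; the
#' secondary-structure code treats the break like a chain end.
#'
#' @param n_per_strand Residues per strand (>= 4).
#' @param sequence_unit Residue used throughout (default "A").
#' @param chain Chain id.
#' @return A [structure_frame()].
#' @export
build_ideal_hairpin <- function(n_per_strand, sequence_unit = "A",
                                chain = "A") {
  if (n_per_strand < 4) stop("need >= 4 residues per strand")
  res3 <- rep(one_to_three(sequence_unit), n_per_strand)
  rise <- 0.34
  L <- rise * (n_per_strand - 1)
  s1 <- .place_segment(res3, "strand", p0 = c(0, 0, 0), dir = c(0, -1, 0),
                       roll = 0)
  s2 <- .place_segment(res3, "strand", p0 = c(0.48, -L - 0.5, 0),
                       dir = c(0, 1, 0), roll = pi)
  a1 <- s1$atoms; a2 <- s2$atoms
  a2$resid <- a2$resid + n_per_strand
  atoms <- rbind(a1, a2)
  atoms$serial <- seq_len(nrow(atoms))
  atoms$chain <- chain
  class(atoms) <- c("dimer_atoms", "data.frame")
  structure_frame(atoms, rbind(s1$coords, s2$coords))
}

# Dihedral recipes used by the generator's fold and its toggled states.
.DIHEDRALS <- list(
  helix = c(-57, -47),
  strand = c(-120, 120),
  ppii = c(-75, 145),
  turn1 = c(-60, -30), turn2 = c(-90, 0),    # type-I-like turn
  turnL1 = c(60, 30), turnL2 = c(90, 0)      # mirror-image turn
)

# ---- compact synthetic fold ------------------------------------------------
#
# The monomer is assembled from ideal secondary-structure units (built by
# internal coordinates) that are rigidly placed into a compact bundle; the
# peptide bond is deliberately broken at the turns (the dihedral and
# secondary-structure code detects such breaks and treats them like chain
# ends, as for real broken chains). This is a test device: it yields a
# protein-sized object with a protruding hairpin arm, surface helices and
# clean planted dihedrals, not a physical fold.

# rotation (for row vectors: x %*% M) taking direction a onto direction b
.rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- .cross3(a, b); s2 <- sum(v^2); c <- sum(a * b)
  if (s2 < 1e-14) {
    if (c > 0) return(diag(3))
    # opposite directions: rotate pi about any perpendicular axis
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- .cross3(a, p); v <- v / sqrt(sum(v^2))
    K <- rbind(c(0, -v[3], v[2]), c(v[3], 0, -v[1]), c(-v[2], v[1], 0))
    R <- diag(3) + 2 * K %*% K
    return(t(R))
  }
  K <- rbind(c(0, -v[3], v[2]), c(v[3], 0, -v[1]), c(-v[2], v[1], 0))
  R <- diag(3) + K + K %*% K * ((1 - c) / s2)
  t(R)
}

.rotation_about <- function(axis, ang) {
  axis <- axis / sqrt(sum(axis^2))
  K <- rbind(c(0, -axis[3], axis[2]), c(axis[3], 0, -axis[1]),
             c(-axis[2], axis[1], 0))
  t(diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K)
}

# Segment layout of the 182-residue synthetic monomer; landmark numbering
# follows the Josephin-Domain vocabulary (hairpin 31-62 as a protruding
# two-strand arm, alpha-4 84-87 on a surface helix, Arg101/Arg103, Lys128,
# Asp145, C-terminal tail 178-182). p0/dir place each unit's first C-alpha;
# turn rows (kind "turn") are auto-routed between their neighbours.
.jd_layout <- function() {
  seg <- function(first, last, kind, p0 = NULL, dir = NULL, roll = 0) {
    list(first = first, last = last, kind = kind, p0 = p0, dir = dir,
         roll = roll)
  }
  list(
    seg(1, 5, "ppii", p0 = c(-0.9, 0.4, -0.9), dir = c(0, 0, 1)),
    seg(6, 25, "helix", p0 = c(0, 0, -1.45), dir = c(0, 0, 1)),
    seg(26, 30, "turn"),
    seg(31, 44, "strand", p0 = c(-0.6, -0.7, 0.25), dir = c(0, -1, 0)),
    seg(45, 48, "turn"),
    seg(49, 62, "strand", p0 = c(-0.6 + 0.48, -5.15, 0.25), dir = c(0, 1, 0),
        roll = pi),
    seg(63, 66, "turn"),
    seg(67, 79, "helix", p0 = c(1.0, 0, 0.95), dir = c(0, 0, -1)),
    seg(80, 81, "turn"),
    seg(82, 95, "helix", p0 = c(2.0, 0, -1.0), dir = c(0, 0, 1)),
    seg(96, 99, "turn"),
    seg(100, 115, "helix", p0 = c(0, 1.0, 1.1), dir = c(0, 0, -1)),
    seg(116, 119, "turn"),
    seg(120, 135, "helix", p0 = c(0.5, 2.0, -1.1), dir = c(0, 0, 1)),
    seg(136, 139, "turn"),
    seg(140, 155, "helix", p0 = c(2.0, 1.0, 1.1), dir = c(0, 0, -1)),
    seg(156, 159, "turn"),
    seg(160, 170, "helix", p0 = c(1.0, 1.0, -0.75), dir = c(0, 0, 1)),
    seg(171, 182, "ppii", p0 = c(3.1, 1.7, -1.5), dir = c(0.1, 0.25, 1))
  )
}

.seg_dihedrals <- function(kind, k) {
  d <- .DIHEDRALS
  base <- switch(kind, helix = d$helix, strand = d$strand, d$ppii)
  list(phi = rep(base[1], k), psi = rep(base[2], k))
}

# Build one segment's atoms in standard orientation and rigid-place them.
.place_segment <- function(seq3, kind, p0, dir, roll) {
  k <- length(seq3)
  dh <- .seg_dihedrals(kind, k)
  unit <- build_ideal_backbone(seq3, dh$phi, dh$psi)
  xyz <- unit$coords
  ca <- which(unit$atoms$name == "CA")
  if (k > 1) {
    axis <- xyz[ca[k], ] - xyz[ca[1], ]
    M <- .rotation_between(axis, dir)
    if (roll != 0) M <- M %*% .rotation_about(dir, roll)
  } else M <- diag(3)
  xyz <- sweep(xyz, 2, xyz[ca[1], ]) %*% M
  list(atoms = unit$atoms, coords = sweep(xyz, 2, p0, "+"), ca_first = p0,
       ca_last = p0 + if (k > 1) (xyz[ca[k], ] - xyz[ca[1], ]) else 0)
}

# Assemble the compact monomer fold for a 182-residue sequence.
.jd_fold <- function(sequence, chain = "A") {
  res3 <- one_to_three(sequence)
  layout <- .jd_layout()
  n <- nchar(sequence)
  if (layout[[length(layout)]]$last != n) {
    stop("the compact fold layout requires a 182-residue sequence")
  }
  placed <- vector("list", length(layout))
  # first pass: fixed segments
  for (i in seq_along(layout)) {
    sg <- layout[[i]]
    if (sg$kind == "turn") next
    placed[[i]] <- .place_segment(res3[sg$first:sg$last], sg$kind, sg$p0,
                                  sg$dir, sg$roll)
  }
  # second pass: route turns between their placed neighbours
  for (i in seq_along(layout)) {
    sg <- layout[[i]]
    if (sg$kind != "turn") next
    from <- placed[[i - 1]]$ca_last
    to <- placed[[i + 1]]$ca_first
    u <- to - from; L <- sqrt(sum(u^2)); u <- u / L
    k <- sg$last - sg$first + 1L
    p0 <- from + u * min(0.38, L / (k + 1))
    placed[[i]] <- .place_segment(res3[sg$first:sg$last], "ppii", p0, u, 0)
  }
  atoms_list <- lapply(seq_along(layout), function(i) {
    a <- placed[[i]]$atoms
    a$resid <- a$resid + as.integer(layout[[i]]$first) - 1L
    a
  })
  atoms <- do.call(rbind, atoms_list)
  coords <- do.call(rbind, lapply(placed, `[[`, "coords"))
  atoms$serial <- seq_len(nrow(atoms))
  atoms$chain <- chain
  class(atoms) <- c("dimer_atoms", "data.frame")
  structure_frame(atoms, coords)
}

.jd_sequence <- function(mutant = FALSE) {
  base <- strsplit(paste(rep("ASTLEKVNFQ", 19), collapse = ""), "")[[1]][1:182]
  landmarks <- c(`31` = "V", `57` = "D", `62` = "L", `77` = "I", `78` = "Q",
                 `84` = "L", `87` = "W", `101` = "R", `103` = "R",
                 `128` = "K", `145` = "D", `178` = "L", `182` = "R",
                 `20` = "N", `24` = "S", `53` = "E", `60` = "K")
  base[as.integer(names(landmarks))] <- landmarks
  if (mutant) base[c(101, 103)] <- "A"
  paste(base, collapse = "")
}

#' Specification of a synthetic planted trajectory
#'
#' Collects every planted ground-truth element: the per-frame count
#' realization of each plan is exact (a probability p over n frames means
#' exactly `round(p * n)` planted frames), while the seeded jitter only
#' perturbs within a validated bound that cannot flip a planted contact.
#'
#' @param n_frames Number of frames.
#' @param frame_dt Frame spacing in ps (default 50, the ensemble sampling
#'   interval the analyses assume).
#' @param seed Integer seed; identical spec + seed gives identical output.
#' @param sequence_a,sequence_b One-letter sequences (182-residue synthetic
#'   monomer by default).
#' @param dimer Generate a two-chain system (chains A and B)?
#' @param contact_plan data.frame(resid_a, resid_b, p): chain-A residues
#'   planted in contact with the given chain-B partner in exactly
#'   `round(p * n_frames)` frames.
#' @param rg_plan list(means, sds, weights): per-state chain-A radius of
#'   gyration targets (nm); a per-frame target drawn from the state's normal
#'   is realized exactly by hairpin scaling. `NULL` disables.
#' @param hairpin c(first, last) residues scaled for the RG plan.
#' @param ss_plan list(first, last, coil_fraction): helix block toggled to
#'   coil dihedrals in exactly that fraction of frames. `NULL` disables.
#' @param exposure_plan list(first, last, delta, fraction, couple_to_ss):
#'   outward COM displacement (nm) of the region in that fraction of frames;
#'   when coupled, the exposure frames are the coil frames.
#' @param rmsf_plan list(first, last, sigma, mode): extra per-axis Gaussian
#'   displacement (nm) of the region, planting RMSF = sigma * sqrt(3).
#'   `mode = "rigid"` (default) draws one displacement vector per frame for
#'   the whole region, preserving its internal geometry (and hence its
#'   secondary structure when the region's edges sit on chain breaks);
#'   `mode = "atomwise"` jitters every atom independently.
#' @param jitter_sigma Global per-axis jitter SD (nm), truncated at 3 sigma.
#' @param contact_cutoff Cutoff the contact plan is built against (nm).
#' @return Object of class `plant_spec`.
#' @export
plant_spec <- function(n_frames = 1000L, frame_dt = 50, seed = 1L,
                       sequence_a = .jd_sequence(),
                       sequence_b = .jd_sequence(),
                       dimer = TRUE,
                       contact_plan = NULL,
                       rg_plan = NULL,
                       hairpin = c(31L, 62L),
                       ss_plan = NULL,
                       exposure_plan = NULL,
                       rmsf_plan = NULL,
                       jitter_sigma = 0.002,
                       contact_cutoff = 0.28) {
  spec <- list(n_frames = as.integer(n_frames), frame_dt = frame_dt,
               seed = as.integer(seed), sequence_a = sequence_a,
               sequence_b = sequence_b, dimer = dimer,
               contact_plan = contact_plan, rg_plan = rg_plan,
               hairpin = as.integer(hairpin), ss_plan = ss_plan,
               exposure_plan = exposure_plan, rmsf_plan = rmsf_plan,
               jitter_sigma = jitter_sigma, contact_cutoff = contact_cutoff)
  class(spec) <- "plant_spec"
  validate_plant_spec(spec)
  spec
}

#' @rdname plant_spec
#' @param spec A `plant_spec`.
#' @export
validate_plant_spec <- function(spec) {
  if (spec$n_frames < 1L) stop("n_frames must be >= 1")
  if (!is.null(spec$contact_plan)) {
    if (!spec$dimer) stop("contact_plan requires a dimer")
    p <- spec$contact_plan$p
    if (any(p < 0 | p > 1)) stop("contact probabilities must lie in [0, 1]")
  }
  if (!is.null(spec$rg_plan)) {
    m <- spec$rg_plan$means
    if (any(m <= 0)) stop("rg means must be positive")
    if (length(m) > 1 && any(duplicated(m))) stop("rg means must be distinct")
    if (length(spec$rg_plan$weights) != length(m) ||
        abs(sum(spec$rg_plan$weights) - 1) > 1e-9) {
      stop("rg weights must match means and sum to 1")
    }
  }
  # truncated jitter bound: two atoms can approach by at most
  # 2 * 3 sigma * sqrt(3); that must stay below the 0.1 * cutoff margin
  # between the planted distance (0.9 cutoff) and the cutoff
  if (2 * 3 * spec$jitter_sigma * sqrt(3) >= 0.1 * spec$contact_cutoff) {
    stop("jitter_sigma large enough to flip a planted contact; reduce it")
  }
  if (!is.null(spec$rmsf_plan) && !is.null(spec$contact_plan)) {
    reg <- spec$rmsf_plan$first:spec$rmsf_plan$last
    if (any(spec$contact_plan$resid_a %in% reg)) {
      stop("rmsf_plan region overlaps contact_plan targets")
    }
  }
  invisible(spec)
}

#' Canned study conditions for the default synthetic monomer/dimer
#'
#' `"bound"`: wild-type-like dimer with the interface plan
#' (Arg101 0.65 against Asp57, Lys128 0.55, Asp145 0.50, C-terminal
#' Leu178/Arg182 0.40), bimodal RG (1.73/1.65 nm, 50/50), 35% helix-coil
#' switching of the 84-87 block and coupled exposure.
#' `"mutant"`: Ala101/Ala103 dimer with the reduced plan (0.25/0.18/0.18,
#' C-terminal 0.60) and RG 1.71/1.61, helix conserved.
#' `"single"`: lone monomer, unimodal RG 1.71 (sd 0.03), helix conserved,
#' alpha-4 fluctuation level 0.2 nm planted by rigid displacement of its
#' helix unit (82-95).
#'
#' @param condition One of "bound", "mutant", "single".
#' @param seed Integer seed.
#' @param n_frames Number of frames (default 1000).
#' @param ... Overrides passed to [plant_spec()].
#' @return A `plant_spec`.
#' @export
default_plant_spec <- function(condition = c("bound", "mutant", "single"),
                               seed = 1L, n_frames = 1000L, ...) {
  condition <- match.arg(condition)
  args <- switch(condition,
    bound = list(
      contact_plan = data.frame(
        resid_a = c(101L, 128L, 145L, 178L, 182L),
        resid_b = c(57L, 60L, 53L, 20L, 24L),
        p = c(0.65, 0.55, 0.50, 0.40, 0.40)),
      rg_plan = list(means = c(1.73, 1.65), sds = c(0.02, 0.02),
                     weights = c(0.5, 0.5)),
      ss_plan = list(first = 84L, last = 87L, coil_fraction = 0.35),
      exposure_plan = list(first = 84L, last = 87L, delta = 0.6,
                           fraction = 0.35, couple_to_ss = TRUE)),
    mutant = list(
      sequence_a = .jd_sequence(mutant = TRUE),
      sequence_b = .jd_sequence(mutant = TRUE),
      contact_plan = data.frame(
        resid_a = c(101L, 128L, 145L, 178L, 182L),
        resid_b = c(57L, 60L, 53L, 20L, 24L),
        p = c(0.25, 0.18, 0.18, 0.60, 0.60)),
      rg_plan = list(means = c(1.71, 1.61), sds = c(0.02, 0.02),
                     weights = c(0.5, 0.5)),
      rmsf_plan = list(first = 82L, last = 95L, sigma = 0.2 / sqrt(3))),
    single = list(
      dimer = FALSE,
      rg_plan = list(means = 1.71, sds = 0.03, weights = 1),
      rmsf_plan = list(first = 82L, last = 95L, sigma = 0.2 / sqrt(3)))
  )
  user <- list(...)
  args[names(user)] <- user
  do.call(plant_spec, c(list(n_frames = n_frames, seed = seed), args))
}

# ---- internal construction helpers ----------------------------------------

.backbone_index <- function(atoms, chain) {
  idx <- which(atoms$chain == chain)
  resids <- unique(atoms$resid[idx])
  find <- function(nm) vapply(resids, function(r) {
    j <- idx[atoms$resid[idx] == r & atoms$name[idx] == nm]
    if (length(j)) j[1] else NA_integer_
  }, integer(1))
  list(resids = resids, N = find("N"), CA = find("CA"), C = find("C"),
       O = find("O"), CB = find("CB"))
}

# Rebuild the phi/psi of a residue block in place. Atoms downstream of the
# block keep their template positions (anchored rebuild; the C(last)-N(last+1)
# bond is deliberately broken). Returns the modified coordinate matrix.
.rebuild_block <- function(coords, bb, first, last, phi_new, psi_new) {
  g <- .BB
  i0 <- match(first, bb$resids)
  i1 <- match(last, bb$resids)
  for (k in seq(i0, i1)) {
    r <- k - i0 + 1L
    prevC <- if (k > 1) coords[bb$C[k - 1], ] else NULL
    if (is.null(prevC)) stop("ss block cannot start at the chain's first residue")
    coords[bb$C[k], ] <- .nerf(prevC, coords[bb$N[k], ], coords[bb$CA[k], ],
                               g$b_CAC, g$a_NCAC, phi_new[r])
    coords[bb$O[k], ] <- .nerf(coords[bb$N[k], ], coords[bb$CA[k], ],
                               coords[bb$C[k], ], g$b_CO, g$a_CACO,
                               psi_new[r] + 180)
    if (!is.na(bb$CB[k])) {
      coords[bb$CB[k], ] <- .nerf(coords[bb$C[k], ], coords[bb$N[k], ],
                                  coords[bb$CA[k], ], g$b_CACB, g$a_NCACB,
                                  g$t_CB)
    }
    if (k < i1) {
      coords[bb$N[k + 1], ] <- .nerf(coords[bb$N[k], ], coords[bb$CA[k], ],
                                     coords[bb$C[k], ], g$b_CN, g$a_CACN,
                                     psi_new[r])
      coords[bb$CA[k + 1], ] <- .nerf(coords[bb$CA[k], ], coords[bb$C[k], ],
                                      coords[bb$N[k + 1], ], g$b_NCA,
                                      g$a_CNCA, g$omega)
    }
  }
  coords
}

# Radial hairpin scaling factor that realizes an exact RG target.
# With masses m, COM c and hairpin subset P scaled r -> c + s (r - c):
# RG(s)^2 = s^2 (Shp/M - |w|^2) + 2 s |w|^2 + (Score/M - |w|^2)
# where w = sum_P m (r - c) / M. Returns the positive root nearest 1.
.solve_hairpin_scale <- function(xyz, mass, hp_rows, target) {
  M <- sum(mass)
  com <- colSums(xyz * mass) / M
  d <- sweep(xyz, 2, com)
  r2 <- rowSums(d^2)
  Shp <- sum(mass[hp_rows] * r2[hp_rows])
  Score <- sum(mass * r2) - Shp
  w <- colSums(d[hp_rows, , drop = FALSE] * mass[hp_rows]) / M
  w2 <- sum(w^2)
  A <- Shp / M - w2; B <- 2 * w2; C <- Score / M - w2 - target^2
  disc <- B^2 - 4 * A * C
  if (disc < 0 || abs(A) < 1e-14) {
    stop(sprintf("RG target %.3f nm unreachable by hairpin scaling", target))
  }
  roots <- c((-B + sqrt(disc)) / (2 * A), (-B - sqrt(disc)) / (2 * A))
  roots <- roots[roots > 0]
  if (!length(roots)) {
    stop(sprintf("RG target %.3f nm unreachable by hairpin scaling", target))
  }
  list(s = roots[which.min(abs(roots - 1))], com = com)
}

.apply_hairpin_scale <- function(xyz, hp_rows, s, com) {
  xyz[hp_rows, ] <- sweep(sweep(xyz[hp_rows, , drop = FALSE], 2, com) * s,
                          2, com, "+")
  xyz
}

# Rigid translation of a partner residue along a direction u so its minimum
# distance to the target residue equals d_plant, with clearance from every
# other chain-A atom. Returns the translated coordinates or NULL.
.place_contact_residue <- function(bres, tgt, others, u, d_plant, clearance) {
  proj <- as.numeric(tgt %*% u)
  pA <- tgt[which.max(proj), ]
  anchor <- colMeans(bres)
  dmin_at <- function(t) {
    moved <- sweep(bres, 2, pA + t * u - anchor, "+")
    sqrt(min(.cross_d2(moved, tgt)))
  }
  lo <- 0; hi <- 2
  if (dmin_at(lo) > d_plant) lo <- -1
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (dmin_at(mid) < d_plant) lo <- mid else hi <- mid
  }
  t_star <- (lo + hi) / 2
  moved <- sweep(bres, 2, pA + t_star * u - anchor, "+")
  if (abs(sqrt(min(.cross_d2(moved, tgt))) - d_plant) > 1e-4) return(NULL)
  if (nrow(others) && min(.cross_d2(moved, others)) < clearance^2) return(NULL)
  moved
}

.rotate_about <- function(u, axis, ang) {
  axis <- axis / sqrt(sum(axis^2))
  u * cos(ang) + .cross3(axis, u) * sin(ang) + axis * sum(axis * u) * (1 - cos(ang))
}

# exact-count Bernoulli schedule: exactly round(p * n) planted frames
.schedule <- function(n, p) {
  k <- round(p * n)
  sel <- rep(FALSE, n)
  if (k > 0) sel[sample.int(n, k)] <- TRUE
  sel
}

#' Generate a planted synthetic trajectory with ground truth
#'
#' Deterministic for a fixed spec and seed; the caller's RNG state is left
#' untouched. See [plant_spec()] for what is planted and how. The generator
#' verifies its own plants (planted contact distances at 0.9 x cutoff,
#' clearance everywhere else, exact schedule counts) and fails rather than
#' emit a trajectory whose ground-truth tables are wrong.
#'
#' @param spec A [plant_spec()].
#' @return List of class `planted_trajectory`: `trajectory`, and `truth`
#'   (list: `frames` per-frame table, `contacts` per-plan summary,
#'   `contact_schedule` frame x plan logical matrix, `spec`).
#' @export
generate_dimer_trajectory <- function(spec) {
  validate_plant_spec(spec)
  nfr <- spec$n_frames
  build_chain <- function(sequence, chain) {
    if (nchar(sequence) == 182L) .jd_fold(sequence, chain = chain)
    else build_ideal_backbone(sequence, .DIHEDRALS$ppii[1],
                              .DIHEDRALS$ppii[2], chain = chain)
  }
  frameA <- build_chain(spec$sequence_a, "A")
  atomsA <- frameA$atoms
  bbA <- .backbone_index(atomsA, "A")
  baseA <- frameA$coords
  nA <- nrow(baseA)

  # coil-state variant of the toggled block (anchored rebuild)
  coilA <- NULL
  if (!is.null(spec$ss_plan)) {
    blk <- spec$ss_plan$first:spec$ss_plan$last
    coil <- .DIHEDRALS$ppii
    coilA <- .rebuild_block(baseA, bbA, spec$ss_plan$first, spec$ss_plan$last,
                            rep(coil[1], length(blk)), rep(coil[2], length(blk)))
  }

  # chain B: template fold translated well clear of A along +x
  if (spec$dimer) {
    frameB <- build_chain(spec$sequence_b, "B")
    atomsB <- frameB$atoms
    gap <- 4  # nm of clear space between the chains at rest
    shift <- c(max(baseA[, 1]) - min(frameB$coords[, 1]) + gap, 0, 0)
    baseB <- sweep(frameB$coords, 2, shift, "+")
    atomsB$serial <- atomsB$serial + nA
    atoms <- rbind(atomsA, atomsB)
    class(atoms) <- c("dimer_atoms", "data.frame")
  } else {
    atoms <- atomsA
    baseB <- NULL
  }
  massA <- atomsA$mass
  hp_rows <- which(atomsA$resid >= spec$hairpin[1] &
                     atomsA$resid <= spec$hairpin[2])

  res_rows_A <- split(seq_len(nA), atomsA$resid)

  out <- NULL
  truth_frames <- NULL
  contact_sched <- NULL
  .with_preserved_rng(spec$seed, {
    # schedules (exact counts)
    ss_coil <- if (!is.null(spec$ss_plan)) {
      .schedule(nfr, spec$ss_plan$coil_fraction)
    } else rep(FALSE, nfr)
    exposure <- if (!is.null(spec$exposure_plan)) {
      if (isTRUE(spec$exposure_plan$couple_to_ss) && !is.null(spec$ss_plan)) {
        ss_coil
      } else .schedule(nfr, spec$exposure_plan$fraction)
    } else rep(FALSE, nfr)
    if (!is.null(spec$rg_plan)) {
      k <- length(spec$rg_plan$means)
      if (k == 1L) {
        rg_state <- rep(1L, nfr)
      } else {
        n1 <- round(spec$rg_plan$weights[1] * nfr)
        rg_state <- rep(2L, nfr)
        rg_state[sample.int(nfr, n1)] <- 1L
      }
      rg_target <- stats::rnorm(nfr, spec$rg_plan$means[rg_state],
                                spec$rg_plan$sds[rg_state])
    } else {
      rg_state <- rep(NA_integer_, nfr); rg_target <- rep(NA_real_, nfr)
    }
    n_plans <- if (!is.null(spec$contact_plan)) nrow(spec$contact_plan) else 0L
    contact_sched <- matrix(FALSE, nfr, max(n_plans, 1L))
    if (n_plans) {
      for (j in seq_len(n_plans)) {
        contact_sched[, j] <- .schedule(nfr, spec$contact_plan$p[j])
      }
    }

    rmsf_rows <- if (!is.null(spec$rmsf_plan)) {
      which(atomsA$resid >= spec$rmsf_plan$first &
              atomsA$resid <= spec$rmsf_plan$last)
    } else integer(0)
    exp_rows <- if (!is.null(spec$exposure_plan)) {
      which(atomsA$resid >= spec$exposure_plan$first &
              atomsA$resid <= spec$exposure_plan$last)
    } else integer(0)

    n_total <- nA + if (spec$dimer) nrow(baseB) else 0L
    out <- array(NA_real_, c(n_total, 3L, nfr))
    rg_real <- com_dist <- rep(NA_real_, nfr)

    rtrunc <- function(n, sd) {
      v <- stats::rnorm(n, 0, sd)
      pmin(pmax(v, -3 * sd), 3 * sd)
    }

    for (f in seq_len(nfr)) {
      A <- if (ss_coil[f] && !is.null(coilA)) coilA else baseA
      if (exposure[f]) {
        comA <- colSums(A * massA) / sum(massA)
        comR <- colSums(A[exp_rows, , drop = FALSE] * massA[exp_rows]) /
          sum(massA[exp_rows])
        u <- comR - comA; u <- u / sqrt(sum(u^2))
        A[exp_rows, ] <- sweep(A[exp_rows, , drop = FALSE], 2,
                               spec$exposure_plan$delta * u, "+")
      }
      if (!is.null(spec$rg_plan)) {
        sol <- .solve_hairpin_scale(A, massA, hp_rows, rg_target[f])
        A <- .apply_hairpin_scale(A, hp_rows, sol$s, sol$com)
      }
      # jitter last among chain-internal effects
      if (spec$jitter_sigma > 0) {
        A <- A + matrix(rtrunc(3 * nA, spec$jitter_sigma), nA, 3)
      }
      if (length(rmsf_rows) && !is.null(spec$rmsf_plan$sigma) &&
          spec$rmsf_plan$sigma > 0) {
        mode <- spec$rmsf_plan$mode
        if (is.null(mode) || mode == "rigid") {
          A[rmsf_rows, ] <- sweep(A[rmsf_rows, , drop = FALSE], 2,
                                  stats::rnorm(3, 0, spec$rmsf_plan$sigma),
                                  "+")
        } else {
          A[rmsf_rows, ] <- A[rmsf_rows, ] +
            matrix(stats::rnorm(3 * length(rmsf_rows), 0,
                                spec$rmsf_plan$sigma),
                   length(rmsf_rows), 3)
        }
      }
      rg_real[f] <- {
        w <- massA / sum(massA)
        cm <- colSums(A * w)
        sqrt(sum(w * rowSums(sweep(A, 2, cm)^2)))
      }
      if (length(exp_rows)) {
        cm <- colSums(A * massA) / sum(massA)
        cr <- colSums(A[exp_rows, , drop = FALSE] * massA[exp_rows]) /
          sum(massA[exp_rows])
        com_dist[f] <- sqrt(sum((cr - cm)^2))
      }
      if (spec$dimer) {
        B <- baseB + matrix(rtrunc(3 * nrow(baseB), spec$jitter_sigma),
                            nrow(baseB), 3)
        # teleport planted partner residues into contact (exact geometry)
        if (n_plans) {
          comA_now <- colSums(A * massA) / sum(massA)
          for (j in seq_len(n_plans)) {
            if (!contact_sched[f, j]) next
            ra <- spec$contact_plan$resid_a[j]
            rb <- spec$contact_plan$resid_b[j]
            tgt_rows <- res_rows_A[[as.character(ra)]]
            tgt <- A[tgt_rows, , drop = FALSE]
            others <- A[-tgt_rows, , drop = FALSE]
            b_rows <- which(atomsB$resid == rb)
            bres <- B[b_rows, , drop = FALSE]
            u0 <- colMeans(tgt) - comA_now; u0 <- u0 / sqrt(sum(u0^2))
            placed <- NULL
            axes <- list(c(0, 0, 1), c(0, 1, 0), c(1, 0, 0))
            for (ang in c(0, 0.35, -0.35, 0.7, -0.7, 1.1, -1.1)) {
              for (ax in axes) {
                u <- if (ang == 0) u0 else .rotate_about(u0, unlist(ax), ang)
                placed <- .place_contact_residue(
                  bres, tgt, others, u, 0.9 * spec$contact_cutoff,
                  clearance = 0.35)
                if (!is.null(placed)) break
              }
              if (!is.null(placed)) break
            }
            if (is.null(placed)) {
              stop(sprintf(
                "cannot realize planted contact %d-%d in frame %d", ra, rb, f))
            }
            B[b_rows, ] <- placed
          }
        }
        # chains must stay clear of each other at rest
        home_rows <- if (n_plans) {
          in_contact <- unlist(lapply(which(contact_sched[f, ]), function(j) {
            which(atomsB$resid == spec$contact_plan$resid_b[j])
          }))
          setdiff(seq_len(nrow(B)), in_contact)
        } else seq_len(nrow(B))
        if (min(B[home_rows, 1]) - max(A[, 1]) < 3 * spec$contact_cutoff) {
          stop("chain separation violated; enlarge the inter-chain gap")
        }
        out[, , f] <- rbind(A, B)
      } else {
        out[, , f] <- A
      }
    }
    truth_frames <- data.frame(
      frame = seq_len(nfr), time_ps = (seq_len(nfr) - 1) * spec$frame_dt,
      ss_state = ifelse(ss_coil, "coil", "helix"),
      exposed = exposure,
      rg_state = if (!is.null(spec$rg_plan) && length(spec$rg_plan$means) > 1) {
        c("open", "closed")[rg_state]
      } else if (!is.null(spec$rg_plan)) "single" else NA_character_,
      rg_target = rg_target, rg_realized = rg_real,
      com_dist = com_dist)
  })

  contacts <- if (!is.null(spec$contact_plan)) {
    cnt <- as.integer(colSums(contact_sched)[seq_len(nrow(spec$contact_plan))])
    data.frame(spec$contact_plan, n_contact = cnt, probability = cnt / nfr)
  } else NULL

  traj <- trajectory(atoms, out, times = (seq_len(nfr) - 1) * spec$frame_dt)
  structure(list(trajectory = traj,
                 truth = list(frames = truth_frames, contacts = contacts,
                              contact_schedule = contact_sched, spec = spec)),
            class = "planted_trajectory")
}

#' Write a synthetic bundle (trajectory + ground truth) to disk
#'
#' Emits `trajectory.pdb` (multi-model), `frames.csv` and `contacts.csv`
#' (ground truth), `contact_schedule.csv` and `spec.yaml` (the spec echoed).
#' Two runs with the same spec and seed produce byte-identical files.
#'
#' @param spec A [plant_spec()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the list of written paths.
#' @export
write_fixture_bundle <- function(spec, outdir) {
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(outdir)) stop("cannot create output dir: ", outdir)
  }
  gen <- generate_dimer_trajectory(spec)
  paths <- c(
    pdb = file.path(outdir, "trajectory.pdb"),
    frames = file.path(outdir, "frames.csv"),
    contacts = file.path(outdir, "contacts.csv"),
    schedule = file.path(outdir, "contact_schedule.csv"),
    spec = file.path(outdir, "spec.yaml"))
  write_multimodel_pdb(gen$trajectory, paths["pdb"])
  utils::write.csv(gen$truth$frames, paths["frames"], row.names = FALSE)
  if (!is.null(gen$truth$contacts)) {
    utils::write.csv(gen$truth$contacts, paths["contacts"], row.names = FALSE)
    utils::write.csv(as.data.frame(gen$truth$contact_schedule * 1L),
                     paths["schedule"], row.names = FALSE)
  }
  sp <- gen$truth$spec
  sp$contact_plan <- if (!is.null(sp$contact_plan)) as.list(sp$contact_plan)
  yaml::write_yaml(unclass(sp), paths["spec"])
  invisible(as.list(paths))
}
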