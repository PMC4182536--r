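# Multi-model PDB and GRO input/output.
#
# Unit convention: everything this package exposes is nm and ps; angstroms
# exist only inside the PDB reader/writer below.

.parse_pdb_atoms <- function(lines, line_numbers) {
  # Vectorized fixed-column parse of ATOM records; errors name the 1-based
  # line number of the first malformed record.
  field <- function(a, b) substr(lines, a, b)
  num <- function(a, b, what) {
    txt <- field(a, b)
    v <- suppressWarnings(as.numeric(txt))
    bad <- which(is.na(v) | !nzchar(trimws(txt)))
    if (length(bad)) {
      stop(sprintf("malformed ATOM record at line %d: bad %s field '%s'",
                   line_numbers[bad[1]], what, txt[bad[1]]), call. = FALSE)
    }
    v
  }
  short <- which(nchar(lines) < 54L)
  if (length(short)) {
    stop(sprintf("malformed ATOM record at line %d: line shorter than 54 columns",
                 line_numbers[short[1]]), call. = FALSE)
  }
  data.frame(
    serial = as.integer(num(7, 11, "serial")),
    name = field(13, 16),
    altloc = field(17, 17),
    resname = trimws(field(18, 20)),
    chain = field(22, 22),
    resid = as.integer(num(23, 26, "resid")),
    x = num(31, 38, "x"), y = num(39, 46, "y"), z = num(47, 54, "z"),
    occ = {
      txt <- field(55, 60)
      v <- suppressWarnings(as.numeric(txt))
      v[is.na(v)] <- 1
      v
    },
    element = trimws(field(77, 78)),
    stringsAsFactors = FALSE
  )
}

.resolve_altloc <- function(df) {
  # Keep the highest-occupancy alternate location per atom site; ties go to
  # the first record encountered. Sites are keyed by chain/resid/name/resname.
  has_alt <- df$altloc != " " & df$altloc != ""
  if (!any(has_alt)) return(df)
  key <- paste(df$chain, df$resid, df$name, df$resname, sep = "\r")
  keep <- rep(TRUE, nrow(df))
  for (k in unique(key[has_alt])) {
    idx <- which(key == k)
    if (length(idx) > 1L) {
      best <- idx[which.max(df$occ[idx])]  # which.max = first on ties
      keep[setdiff(idx, best)] <- FALSE
    }
  }
  df[keep, , drop = FALSE]
}

#' Read a multi-model PDB file into a trajectory
#'
#' Understands the NMR-ensemble dialect (MODEL/ENDMDL blocks) as well as
#' plain single-model files. Coordinates are converted from angstrom to nm.
#' Alternate locations are resolved to the highest-occupancy record
#' (ties: first encountered). Atom order is preserved as in the file.
#'
#' @param path PDB file path.
#' @return A [trajectory()] with one frame per MODEL (times are `NA`:
#'   PDB models carry no time stamps).
#' @export
read_multimodel_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  "
  if (!any(is_atom)) stop("no ATOM records in ", path)
  model_id <- cumsum(rec == "MODEL ")
  # Implicit single model when no MODEL records precede the atoms
  model_of_atom <- model_id[is_atom]
  if (all(model_of_atom == 0L)) model_of_atom <- rep(1L, sum(is_atom))
  if (any(model_of_atom == 0L)) {
    stop("ATOM records found outside MODEL blocks in a multi-model file")
  }
  atoms_all <- .parse_pdb_atoms(lines[is_atom], which(is_atom))
  frames <- split(seq_len(nrow(atoms_all)), model_of_atom)
  parsed <- lapply(frames, function(idx) .resolve_altloc(atoms_all[idx, , drop = FALSE]))
  counts <- vapply(parsed, nrow, integer(1))
  if (length(unique(counts)) != 1L) {
    stop(sprintf("inconsistent atom counts across models: %s",
                 paste(unique(counts), collapse = ", ")))
  }
  first <- parsed[[1]]
  sig <- function(d) paste(d$name, d$resid, d$chain, d$resname, collapse = "|")
  if (!all(vapply(parsed, sig, character(1)) == sig(first))) {
    stop("atom identity differs across models")
  }
  atoms <- atom_table(first$serial, first$name, first$resname, first$resid,
                      first$chain, element = first$element)
  coords <- array(NA_real_, c(nrow(first), 3L, length(parsed)))
  for (i in seq_along(parsed)) {
    coords[, , i] <- cbind(parsed[[i]]$x, parsed[[i]]$y, parsed[[i]]$z) / 10
  }
  trajectory(atoms, coords, times = rep(NA_real_, length(parsed)))
}

#' Read a GROMACS GRO coordinate file
#'
#' Fixed-column GRO layout; coordinates are already nm. Velocity columns,
#' when present, are ignored.
#'
#' @param path GRO file path.
#' @return A [structure_frame()].
#' @export
read_gro <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) stop("truncated GRO file: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n)) stop("malformed GRO atom-count line (line 2)")
  if (length(lines) < 2L + n + 1L) stop("GRO file shorter than declared atom count")
  al <- lines[3:(2 + n)]
  bad <- which(nchar(al) < 44L)
  if (length(bad)) {
    stop(sprintf("malformed GRO atom line at line %d: wrong column widths",
                 bad[1] + 2L))
  }
  num <- function(a, b, what) {
    v <- suppressWarnings(as.numeric(substr(al, a, b)))
    if (anyNA(v)) {
      stop(sprintf("malformed GRO atom line at line %d: bad %s field",
                   which(is.na(v))[1] + 2L, what))
    }
    v
  }
  resid <- as.integer(num(1, 5, "resid"))
  resname <- trimws(substr(al, 6, 10))
  name <- trimws(substr(al, 11, 15))
  x <- num(21, 28, "x"); y <- num(29, 36, "y"); z <- num(37, 44, "z")
  atoms <- atom_table(seq_len(n), name, resname, resid, chain = rep("A", n))
  structure_frame(atoms, cbind(x, y, z))
}

#' Write a trajectory as a multi-model PDB file
#'
#' Inverse of [read_multimodel_pdb()] up to PDB fixed-point precision
#' (0.001 angstrom). Chain ids, residue ids and atom names are preserved.
#'
#' @param traj A trajectory (>= 1 frame).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(traj, path) {
  if (!inherits(traj, "trajectory")) stop("traj must be a trajectory")
  nf <- n_frames(traj)
  if (nf < 1L || n_atoms(traj) < 1L) stop("cannot write an empty trajectory")
  at <- traj$topology
  if (any(at$resid > 9999L)) stop("resid > 9999 overflows the PDB field")
  if (any(at$serial > 99999L)) stop("serial > 99999 overflows the PDB field")
  pad_name <- ifelse(nchar(at$name) < 4L, sprintf(" %-3s", at$name), at$name)
  chain_last <- c(at$chain[-1] != at$chain[-nrow(at)], TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nf)) {
    xyz <- traj$coords[, , f, drop = TRUE] * 10  # nm -> angstrom
    lines <- sprintf(
      "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      at$serial, pad_name, at$resname, at$chain, at$resid,
      xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, at$element)
    lines[chain_last] <- paste0(lines[chain_last], "\nTER")
    writeLines(c(sprintf("MODEL     %4d", f), lines, "ENDMDL"), con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Select frames by time window and stride
#'
#' Keeps the frames nearest to the target times
#' `t_start, t_start + stride, ..., t_end` (tolerance `stride/2`).
#'
#' @param traj A trajectory with non-`NA` times.
#' @param t_start,t_end Window bounds in ps, `t_start <= t_end`.
#' @param stride Sampling interval in ps, > 0.
#' @return The sub-trajectory; an empty selection is an error.
#' @export
select_frames <- function(traj, t_start, t_end, stride) {
  if (t_start > t_end) stop("t_start must be <= t_end")
  if (stride <= 0) stop("stride must be > 0")
  if (all(is.na(traj$times))) stop("trajectory has no frame times")
  targets <- seq(t_start, t_end, by = stride)
  idx <- vapply(targets, function(tt) {
    d <- abs(traj$times - tt)
    j <- which.min(d)
    if (d[j] <= stride / 2 + 1e-9) j else NA_integer_
  }, integer(1))
  idx <- unique(idx[!is.na(idx)])
  if (!length(idx)) {
    stop("empty frame selection: window [", t_start, ", ", t_end,
         "] ps matches no frames")
  }
  trajectory(traj$topology, traj$coords[, , idx, drop = FALSE],
             times = traj$times[idx])
}

#' Resolve a residue region to atom indices
#'
#' @param x A trajectory or structure_frame.
#' @param region A [region_spec()].
#' @return Integer atom indices (row numbers of the topology).
#' @export
resolve_region <- function(x, region) {
  at <- if (inherits(x, "trajectory")) x$topology else x$atoms
  if (!region$chain %in% at$chain) {
    stop("chain '", region$chain, "' not present in topology")
  }
  idx <- which(at$chain == region$chain &
                 at$resid >= region$first_resid &
                 at$resid <= region$last_resid)
  if (!length(idx)) {
    stop("region '", region$label, "' matches no atoms on chain ",
         region$chain)
  }
  idx
}
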