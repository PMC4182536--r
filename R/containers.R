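#' Atom table constructor
#'
#' The topology shared by all frames of a trajectory: one row per atom with
#' serial, name, element, residue name, residue id (1-based, as in the source
#' file), chain id and atomic mass (u).
#'
#' @param serial Integer atom serials.
#' @param name Atom names.
#' @param resname 3-letter residue codes.
#' @param resid Integer residue ids.
#' @param chain Chain identifiers.
#' @param element Element symbols; inferred from `name` when missing.
#' @param mass Atomic masses (u); looked up from `element` when missing.
#' @return A data.frame of class `dimer_atoms`.
#' @export
atom_table <- function(serial, name, resname, resid, chain,
                       element = NULL, mass = NULL) {
  n <- length(serial)
  stopifnot(length(name) == n, length(resname) == n,
            length(resid) == n, length(chain) == n)
  if (is.null(element) || all(!nzchar(trimws(element)))) {
    element <- infer_element(name)
  } else {
    element <- toupper(trimws(element))
    blank <- !nzchar(element)
    if (any(blank)) element[blank] <- infer_element(name[blank])
  }
  if (is.null(mass)) mass <- element_mass(element)
  if (any(!is.finite(mass)) || any(mass <= 0)) stop("atom masses must be > 0")
  at <- data.frame(
    serial = as.integer(serial), name = trimws(as.character(name)),
    element = element, resname = toupper(trimws(as.character(resname))),
    resid = as.integer(resid), chain = as.character(chain),
    mass = as.numeric(mass), stringsAsFactors = FALSE
  )
  class(at) <- c("dimer_atoms", "data.frame")
  at
}

#' Single-conformation container
#'
#' @param atoms An atom table (see [atom_table()]).
#' @param coords Numeric n_atoms x 3 matrix, nanometres.
#' @param time Frame time in ps, or `NA` for static models.
#' @return Object of class `structure_frame`.
#' @export
structure_frame <- function(atoms, coords, time = NA_real_) {
  coords <- as.matrix(coords)
  if (nrow(coords) != nrow(atoms) || ncol(coords) != 3L) {
    stop("coords must be an n_atoms x 3 matrix matching the atom table")
  }
  if (!all(is.finite(coords))) stop("coordinates must all be finite")
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(list(atoms = atoms, coords = coords, time = as.numeric(time)),
            class = "structure_frame")
}

#' Trajectory container
#'
#' Ordered conformations sharing one topology. Coordinates are held as an
#' `n_atoms x 3 x n_frames` array in nm; times are in ps and must be
#' non-decreasing.
#'
#' @param atoms Atom table (the shared topology).
#' @param coords `n_atoms x 3 x n_frames` array, or a list of n x 3 matrices.
#' @param times Numeric vector of frame times (ps).
#' @return Object of class `trajectory`.
#' @export
trajectory <- function(atoms, coords, times = NULL) {
  if (is.list(coords)) {
    coords <- array(unlist(coords, use.names = FALSE),
                    dim = c(nrow(coords[[1]]), 3L, length(coords)))
  }
  if (length(dim(coords)) == 2L) coords <- array(coords, c(dim(coords), 1L))
  n_frames <- dim(coords)[3]
  if (dim(coords)[1] != nrow(atoms) || dim(coords)[2] != 3L) {
    stop("coords array must be n_atoms x 3 x n_frames")
  }
  if (!all(is.finite(coords))) stop("coordinates must all be finite")
  if (is.null(times)) times <- rep(NA_real_, n_frames)
  times <- as.numeric(times)
  if (length(times) != n_frames) stop("one time per frame required")
  tt <- times[!is.na(times)]
  if (length(tt) > 1 && any(diff(tt) < 0)) {
    stop("frame times must be non-decreasing")
  }
  structure(list(topology = atoms, coords = coords, times = times),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d atoms, %d frames, chains: %s\n",
              n_atoms(x), n_frames(x),
              paste(unique(x$topology$chain), collapse = ", ")))
  if (!all(is.na(x$times))) {
    cat(sprintf("  time %.6g .. %.6g ps\n",
                min(x$times, na.rm = TRUE), max(x$times, na.rm = TRUE)))
  }
  invisible(x)
}

#' @export
print.structure_frame <- function(x, ...) {
  cat(sprintf("<structure_frame> %d atoms, chains: %s\n", nrow(x$atoms),
              paste(unique(x$atoms$chain), collapse = ", ")))
  invisible(x)
}

#' Number of frames / atoms
#' @param traj A trajectory.
#' @return Integer count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' @rdname n_frames
#' @export
n_atoms <- function(traj) dim(traj$coords)[1]

#' Extract one frame of a trajectory
#'
#' @param traj A trajectory.
#' @param i Frame index (1-based).
#' @return A `structure_frame`.
#' @export
get_frame <- function(traj, i) {
  if (i < 1 || i > n_frames(traj)) stop("frame index out of range")
  structure_frame(traj$topology, traj$coords[, , i, drop = TRUE],
                  time = traj$times[i])
}

#' Named contiguous residue range on one chain
#'
#' @param label Human-readable region name (e.g. "hairpin").
#' @param chain Chain identifier.
#' @param first_resid,last_resid Inclusive residue-id bounds,
#'   `first_resid <= last_resid`.
#' @return Object of class `region_spec`.
#' @export
region_spec <- function(label, chain, first_resid, last_resid) {
  first_resid <- as.integer(first_resid); last_resid <- as.integer(last_resid)
  if (first_resid > last_resid) {
    stop("region '", label, "': first_resid must be <= last_resid")
  }
  structure(list(label = label, chain = as.character(chain),
                 first_resid = first_resid, last_resid = last_resid),
            class = "region_spec")
}

#' Time series of a scalar observable
#'
#' @param times Frame times (ps).
#' @param values Observable values (units in `label`).
#' @param label Description, e.g. "RG (nm)".
#' @return Object of class `scalar_series`.
#' @export
scalar_series <- function(times, values, label = "") {
  if (length(times) != length(values)) stop("times and values lengths differ")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 label = label), class = "scalar_series")
}

#' @export
as.data.frame.scalar_series <- function(x, ...) {
  data.frame(time_ps = x$times, value = x$values)
}
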