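#' @keywords internal
"_PACKAGE"

# Standard atomic masses (u), keyed by element symbol. Sources: IUPAC 2021
# conventional values, rounded to 3 decimals.
.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, SE = 78.971, FE = 55.845, ZN = 65.38, MG = 24.305,
  CA = 40.078, "NA" = 22.990, K = 39.098, CL = 35.45, F = 18.998
)

# Bondi van der Waals radii (nm) used for solvent-accessible surface.
# Elements missing here raise an error naming the atom rather than
# defaulting silently.
.vdw_radii <- c(
  H = 0.120, C = 0.170, N = 0.155, O = 0.152, S = 0.180,
  P = 0.180, SE = 0.190, F = 0.147, CL = 0.175
)

.amino3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL"
)

# Side-chain polarity classes used by the interface table. Histidine is
# grouped with the charged class (titratable); tryptophan and tyrosine with
# the polar class (H-bonding aromatics).
.polarity_class <- c(
  ARG = "charged", LYS = "charged", ASP = "charged", GLU = "charged",
  HIS = "charged",
  SER = "polar", THR = "polar", ASN = "polar", GLN = "polar",
  TYR = "polar", CYS = "polar", TRP = "polar",
  ALA = "hydrophobic", VAL = "hydrophobic", LEU = "hydrophobic",
  ILE = "hydrophobic", PRO = "hydrophobic", PHE = "hydrophobic",
  MET = "hydrophobic", GLY = "hydrophobic"
)

#' Infer the element symbol from a PDB atom name
#'
#' Applies PDB v3 naming rules for files whose element column is blank:
#' a name starting in column 13 with a digit or space is element = first
#' alphabetic character; two-character elements occupy columns 13-14.
#' Hydrogen names such as "1HB " or "HD21" map to H.
#'
#' @param name Atom name, as the 4-character PDB field or a trimmed string.
#' @return Element symbol (upper case), e.g. "C", "N", "FE".
#' @export
infer_element <- function(name) {
  vapply(as.character(name), function(nm) {
    raw <- nm
    trimmed <- gsub(" ", "", raw)
    if (!nzchar(trimmed)) stop("empty atom name; cannot infer element")
    if (grepl("^[0-9]", trimmed)) {
      # e.g. "1HB2": digit prefix means hydrogen variants
      return("H")
    }
    # Four-character padded names where the first column is occupied are
    # candidates for two-letter elements (FE, ZN, CL, ...)
    two <- toupper(substr(trimmed, 1, 2))
    if (nchar(raw) == 4L && substr(raw, 1, 1) != " " &&
        two %in% names(.element_masses) && !two %in% c("CA", "NA")) {
      return(two)
    }
    toupper(substr(trimmed, 1, 1))
  }, character(1), USE.NAMES = FALSE)
}

#' Atomic mass for an element symbol
#'
#' @param element Element symbol(s).
#' @return Mass in u. Unknown elements are an error, never a silent zero.
#' @export
element_mass <- function(element) {
  el <- toupper(as.character(element))
  m <- .element_masses[el]
  if (anyNA(m)) {
    stop("no standard mass for element(s): ",
         paste(unique(el[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

#' Van der Waals radius for an element symbol
#'
#' @param element Element symbol(s).
#' @param context Optional atom labels used in the error message.
#' @return Radius in nm.
#' @export
vdw_radius <- function(element, context = element) {
  el <- toupper(as.character(element))
  r <- .vdw_radii[el]
  if (anyNA(r)) {
    bad <- which(is.na(r))[1]
    stop("no van der Waals radius for atom '", context[bad],
         "' (element ", el[bad], ")")
  }
  unname(r)
}

#' Side-chain polarity class of a residue
#'
#' @param resname 3-letter residue code(s).
#' @return "charged", "polar" or "hydrophobic"; unknown codes return "other".
#' @export
residue_polarity <- function(resname) {
  cls <- .polarity_class[toupper(as.character(resname))]
  cls[is.na(cls)] <- "other"
  unname(cls)
}

one_to_three <- function(seq1) {
  codes <- .amino3[strsplit(toupper(seq1), "")[[1]]]
  if (anyNA(codes)) stop("unknown residue code in sequence")
  unname(codes)
}
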