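#' Chemical reference tables
#'
#' Standard atomic weights, van der Waals radii, canonical heavy-atom sets
#' per residue type, and theoretical maximum accessible areas used to
#' normalize absolute surface area into relative surface accessibility
#' (RSA).
#'
#' @name chemistry-tables
#' @keywords internal
NULL

# IUPAC 2021 standard atomic weights, elements seen in protein heavy atoms
# (H listed for completeness; hydrogens are excluded from all computation).
.atomic_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999,
  S = 32.06, SE = 78.971, P = 30.974
)

# van der Waals radii (Angstrom) for the SASA engine; Bondi-style values
# used by most accessibility programs.
.vdw_radii <- c(
  C = 1.70, N = 1.55, O = 1.52, S = 1.80, SE = 1.90, P = 1.80, H = 1.20
)
.vdw_default <- 1.70

.backbone_atoms <- c("N", "CA", "C", "O", "OXT")

.standard_residues <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)

# Canonical heavy side-chain atoms per residue type (PDB v3 naming); used
# only to flag incomplete side chains, never to reject atoms.
.sidechain_atoms <- list(
  ALA = "CB",
  ARG = c("CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"),
  ASN = c("CB", "CG", "OD1", "ND2"),
  ASP = c("CB", "CG", "OD1", "OD2"),
  CYS = c("CB", "SG"),
  GLN = c("CB", "CG", "CD", "OE1", "NE2"),
  GLU = c("CB", "CG", "CD", "OE1", "OE2"),
  GLY = character(0),
  HIS = c("CB", "CG", "ND1", "CD2", "CE1", "NE2"),
  ILE = c("CB", "CG1", "CG2", "CD1"),
  LEU = c("CB", "CG", "CD1", "CD2"),
  LYS = c("CB", "CG", "CD", "CE", "NZ"),
  MET = c("CB", "CG", "SD", "CE"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  PRO = c("CB", "CG", "CD"),
  SER = c("CB", "OG"),
  THR = c("CB", "OG1", "CG2"),
  TRP = c("CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH"),
  VAL = c("CB", "CG1", "CG2")
)

.aa_three_to_one <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
  GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
  MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
  TYR = "Y", VAL = "V"
)
.aa_one_to_three <- stats::setNames(names(.aa_three_to_one), .aa_three_to_one)

#' Theoretical maximum accessible areas (Gly-X-Gly tripeptide)
#'
#' Per-residue-type maximum solvent-accessible surface area, in square
#' Angstrom, computed for residue X in an extended Gly-X-Gly tripeptide
#' (theoretical values of Tien et al. 2013, PLoS ONE 8:e80635). Dividing a
#' residue's absolute accessible area by this reference and multiplying by
#' 100 gives the relative surface accessibility (RSA) in percent. Observed
#' areas in real structures can exceed the reference, so RSA above 100% is
#' legitimate and is never clamped.
#'
#' @return A named numeric vector over the 20 standard three-letter residue
#'   codes, in square Angstrom.
#' @examples
#' reference_areas()[["GLY"]]
#' @export
reference_areas <- function() {
  c(
    ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0, CYS = 167.0,
    GLN = 225.0, GLU = 223.0, GLY = 104.0, HIS = 224.0, ILE = 197.0,
    LEU = 201.0, LYS = 236.0, MET = 224.0, PHE = 240.0, PRO = 159.0,
    SER = 155.0, THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0
  )
}

# Resolve element symbols to masses; unknown elements error (the parser
# guarantees elements come from the standard table).
atom_mass <- function(element) {
  m <- .atomic_masses[toupper(element)]
  if (anyNA(m)) {
    stop("no atomic mass for element(s): ",
         paste(unique(element[is.na(m)]), collapse = ", "), call. = FALSE)
  }
  unname(m)
}

# Resolve element symbols to van der Waals radii.
# on_unknown: "default" substitutes .vdw_default with a warning, "error" stops.
atom_radius <- function(element, on_unknown = c("default", "error")) {
  on_unknown <- match.arg(on_unknown)
  r <- .vdw_radii[toupper(element)]
  if (anyNA(r)) {
    bad <- unique(element[is.na(r)])
    if (on_unknown == "error") {
      stop("no van der Waals radius for element(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    warning("no van der Waals radius for element(s) ",
            paste(bad, collapse = ", "), "; using default ",
            .vdw_default, " A", call. = FALSE)
    r[is.na(r)] <- .vdw_default
  }
  unname(r)
}

# Element from a PDB atom name when the element column is absent/blank:
# strip digits/primes, take the leading letters; two-letter SE for MSE-style
# names is not needed for standard residues, so the first character suffices.
element_from_name <- function(name) {
  nm <- gsub("[0-9']", "", trimws(name))
  first <- toupper(substr(nm, 1L, 1L))
  ifelse(first %in% c("C", "N", "O", "S", "P", "H"), first, toupper(nm))
}
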