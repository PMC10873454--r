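# Fixed chemical reference tables used by the detectors and SASA.

#' Amino-acid code conversion
#'
#' Convert between 3-letter and 1-letter amino-acid codes. Non-standard
#' residues map to `NA` (or `"X"` for [aa321()] when `x_for_unknown = TRUE`).
#'
#' @param x character vector of residue codes.
#' @param x_for_unknown return `"X"` instead of `NA` for unknown codes.
#' @return character vector of converted codes.
#' @export
aa321 <- function(x, x_for_unknown = FALSE) {
  out <- unname(.aa3to1[toupper(x)])
  if (x_for_unknown) out[is.na(out)] <- "X"
  out
}

#' @rdname aa321
#' @export
aa123 <- function(x) unname(.aa1to3[toupper(x)])

.aa3to1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)
.aa1to3 <- stats::setNames(names(.aa3to1), .aa3to1)

.standard_aa3 <- names(.aa3to1)

# Default heavy-atom Van der Waals radii (Angstrom); versioned in output
# metadata by build_rin().
.default_vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

# Theoretical maximum accessible surface areas (Angstrom^2) per residue type,
# Tien et al. (2013), used to normalise per-residue SASA.
.max_sasa_tien2013 <- c(
  ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0, CYS = 167.0,
  GLN = 225.0, GLU = 223.0, GLY = 104.0, HIS = 224.0, ILE = 197.0,
  LEU = 201.0, LYS = 236.0, MET = 224.0, PHE = 240.0, PRO = 159.0,
  SER = 155.0, THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0
)

# Hydrogen-bond capability tables: heavy N/O atoms only; backbone N is a
# donor (except proline), backbone O (and OXT) acceptors; side-chain atoms
# per standard chemistry. Hydroxyls and histidine ring nitrogens are both.
.hbond_donors <- list(
  backbone = "N", # all residues except PRO
  ARG = c("NE", "NH1", "NH2"),
  ASN = "ND2",
  GLN = "NE2",
  HIS = c("ND1", "NE2"),
  LYS = "NZ",
  SER = "OG",
  THR = "OG1",
  TRP = "NE1",
  TYR = "OH"
)

.hbond_acceptors <- list(
  backbone = c("O", "OXT"),
  ASN = "OD1",
  ASP = c("OD1", "OD2"),
  GLN = "OE1",
  GLU = c("OE1", "OE2"),
  HIS = c("ND1", "NE2"),
  SER = "OG",
  THR = "OG1",
  TYR = "OH"
)

# Charged-group atoms for ionic (salt-bridge) detection. Chain termini are
# handled separately: the first residue's backbone N is positive, OXT is
# negative wherever present.
.ionic_negative <- list(
  ASP = c("OD1", "OD2"),
  GLU = c("OE1", "OE2")
)
.ionic_positive <- list(
  LYS = "NZ",
  ARG = c("NE", "NH1", "NH2"),
  HIS = c("ND1", "NE2")
)

# Aromatic ring definitions (heavy atoms whose centroid defines the ring).
.aromatic_rings <- list(
  PHE = list(ring = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(ring = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  HIS = list(ring = c("CG", "ND1", "CD2", "CE1", "NE2")),
  TRP = list(
    ring5 = c("CG", "CD1", "CD2", "NE1", "CE2"),
    ring6 = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")
  )
)

# Backbone atom names (everything else on a residue counts as side chain).
.backbone_atoms <- c("N", "CA", "C", "O", "OXT")

.water_resnames <- c("HOH", "WAT", "DOD", "H2O")

# Infer an element symbol from a PDB atom name when the element column is
# absent or blank.
.element_from_name <- function(elety) {
  nm <- gsub("[^A-Za-z]", "", toupper(elety))
  first <- substr(nm, 1, 1)
  two <- substr(nm, 1, 2)
  el <- first
  el[two == "SE"] <- "SE"
  el[two == "FE"] <- "FE"
  el[two == "ZN"] <- "ZN"
  el[two == "MG"] <- "MG"
  # names like "1HB" start with a digit that gsub removed; HG/HD/HE on
  # standard residues are hydrogens, not mercury/helium
  el[first == "H"] <- "H"
  el
}
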