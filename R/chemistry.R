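# Residue polarity/hydrophobicity classes and the atom groups each
# interaction type is measured between.  Classes follow the six-way
# colouring used in interface diagrams of the NF-Y histone-fold
# literature: aliphatic, negatively charged, positively charged, polar,
# aromatic, and proline on its own.

RESIDUE_CLASS <- c(
  GLY = "aliphatic", ALA = "aliphatic", VAL = "aliphatic",
  LEU = "aliphatic", ILE = "aliphatic", MET = "aliphatic",
  ASP = "negative", GLU = "negative",
  LYS = "positive", ARG = "positive", HIS = "positive",
  SER = "polar", THR = "polar", ASN = "polar", GLN = "polar", CYS = "polar",
  PHE = "aromatic", TRP = "aromatic", TYR = "aromatic",
  PRO = "proline")

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

# side-chain H-bond donors / acceptors per residue; His ring nitrogens
# count as both (no protonation model), Asn/Gln N donate only and O
# accept only, Ser/Thr/Tyr hydroxyls both donate and accept, Met SD and
# Cys SG are sulphur partners picked up by the 4.0-A sulphur cutoff.
SIDECHAIN_DONORS <- list(
  SER = "OG", THR = "OG1", CYS = "SG", TYR = "OH", ASN = "ND2",
  GLN = "NE2", LYS = "NZ", ARG = c("NE", "NH1", "NH2"),
  HIS = c("ND1", "NE2"), TRP = "NE1")

SIDECHAIN_ACCEPTORS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), ASN = "OD1",
  GLN = "OE1", SER = "OG", THR = "OG1", TYR = "OH",
  HIS = c("ND1", "NE2"), MET = "SD", CYS = "SG")

# side-chain heavy atoms of the charged group, for ionic contacts
IONIZABLE_ATOMS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
  LYS = "NZ", ARG = c("NE", "CZ", "NH1", "NH2"),
  HIS = c("ND1", "NE2"))

RING_ATOMS <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"))

#' Classify a residue by polarity and hydrophobicity
#'
#' Maps each of the 20 standard amino acids to exactly one of six
#' classes: `aliphatic` (G, A, V, L, I, M), `negative` (D, E),
#' `positive` (K, R, H), `polar` (S, T, N, Q, C), `aromatic` (F, W, Y)
#' and `proline` (P).
#'
#' @param name 3-letter residue code(s)
#' @return character vector of class labels
#' @examples
#' classifyResidue("LYS")   # positive
#' classifyResidue(c("PRO", "SER"))
#' @export
classifyResidue <- function(name) {
  name <- toupper(name)
  bad <- !name %in% names(RESIDUE_CLASS)
  if (any(bad))
    stop("not a standard amino acid: ", paste(unique(name[bad]), collapse = ", "))
  unname(RESIDUE_CLASS[name])
}

.centroid <- function(m) colMeans(m[, c("x", "y", "z"), drop = FALSE])

#' Atom groups used for interaction typing
#'
#' For one protein residue, returns the atom sets each interaction type
#' is measured between: side-chain carbons (plus Met SD) for
#' hydrophobic contacts, H-bond donor and acceptor atoms (side chain
#' per residue type, plus backbone N as donor and backbone O/OXT as
#' acceptor), charged-group heavy atoms for ionic contacts, cation
#' centers (Lys NZ, the Arg guanidinium centroid over NE/CZ/NH1/NH2,
#' the His ring centroid) and the aromatic ring centroid
#' (Phe/Tyr/His/Trp).  Groups are computed from the atoms present;
#' missing side-chain atoms trigger a warning, not an error.
#'
#' @param residue a residue atom table from [getResidue()]
#' @return list with elements `hydrophobic` (atom table), `donors`,
#'   `acceptors` (atom tables with an `element` column), `ionizable`
#'   (atom table), `cationCenters` (matrix of points, 0 rows if none),
#'   `ringCentroid` (point or `NULL`), `class`
#' @export
chemGroups <- function(residue) {
  if (!identical(attr(residue, "kind"), "protein"))
    stop("chemGroups requires a protein residue")
  rn <- attr(residue, "resname")
  expected <- character(0)

  side <- residue[!(residue$atom %in% BACKBONE_ATOMS), , drop = FALSE]
  hydrophobic <- side[side$element == "C" |
                      (rn == "MET" & side$atom == "SD"), , drop = FALSE]

  don <- SIDECHAIN_DONORS[[rn]]
  acc <- SIDECHAIN_ACCEPTORS[[rn]]
  donors <- residue[residue$atom %in% c("N", don), , drop = FALSE]
  acceptors <- residue[residue$atom %in% c("O", "OXT", acc), , drop = FALSE]
  expected <- c(expected, don, acc)

  ion <- IONIZABLE_ATOMS[[rn]]
  ionizable <- residue[residue$atom %in% ion, , drop = FALSE]
  expected <- c(expected, ion)

  ringCentroid <- NULL
  ring <- RING_ATOMS[[rn]]
  if (!is.null(ring)) {
    ra <- residue[residue$atom %in% ring, , drop = FALSE]
    if (nrow(ra) > 0) ringCentroid <- .centroid(ra)
    expected <- c(expected, ring)
  }

  cationCenters <- matrix(numeric(0), ncol = 3,
                          dimnames = list(NULL, c("x", "y", "z")))
  if (rn == "LYS") {
    nz <- residue[residue$atom == "NZ", , drop = FALSE]
    if (nrow(nz)) cationCenters <- rbind(cationCenters, .centroid(nz))
    expected <- c(expected, "NZ")
  } else if (rn == "ARG") {
    gu <- residue[residue$atom %in% c("NE", "CZ", "NH1", "NH2"), , drop = FALSE]
    if (nrow(gu)) cationCenters <- rbind(cationCenters, .centroid(gu))
  } else if (rn == "HIS" && !is.null(ringCentroid)) {
    cationCenters <- rbind(cationCenters, ringCentroid)
  }

  missing <- setdiff(unique(expected), residue$atom)
  if (length(missing))
    warning("residue ", rn, " ",
            residueKeyString(attr(residue, "chain"),
                             attr(residue, "seqid"),
                             attr(residue, "icode")),
            " lacks atoms: ", paste(missing, collapse = ", "),
            "; groups computed from available atoms")

  list(hydrophobic = hydrophobic, donors = donors, acceptors = acceptors,
       ionizable = ionizable, cationCenters = cationCenters,
       ringCentroid = ringCentroid, class = unname(RESIDUE_CLASS[rn]))
}
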