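#' @import methods
NULL

AA3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
         GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
         LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
         SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

NUC3 <- c("DA", "DT", "DG", "DC", "DU", "A", "C", "G", "U", "T")

# modified residues mapped to their standard parent
HET_PARENT <- c(MSE = "MET")

WATER_NAMES <- c("HOH", "WAT", "DOD", "H2O")

TWO_LETTER_ELEMENTS <- c("FE", "ZN", "MG", "MN", "CL", "BR", "NA",
                         "CU", "NI", "CO", "SE", "CD", "HG", "MO")

residueKeyString <- function(chain, seqid, icode) {
  if (length(chain) == 0) return(character(0))
  paste0(chain, ":", seqid, ifelse(icode == "", "", icode))
}

#' ProteinStructure: a parsed macromolecular structure
#'
#' Heavy-atom model of a (multi-chain) structure as read from a PDB file.
#' Atoms are stored as a flat table; residues are identified by the triple
#' (chain, author seq id, insertion code).  Hydrogens and waters are never
#' present.  Residue `kind` is `"protein"` for the 20 standard amino acids
#' (after mapping modified residues such as MSE to their parent),
#' `"nucleic"` for standard DNA/RNA residue names, `"other"` otherwise.
#'
#' @slot id free-text structure identifier (e.g. a PDB code)
#' @slot atoms data.frame with columns `chain`, `seqid` (integer, author
#'   numbering), `icode` (insertion code, `""` if none), `resname`,
#'   `kind`, `atom`, `element`, `x`, `y`, `z`
#' @export
setClass("ProteinStructure",
  representation(id = "character", atoms = "data.frame"))

setValidity("ProteinStructure", function(object) {
  a <- object@atoms
  need <- c("chain", "seqid", "icode", "resname", "kind",
            "atom", "element", "x", "y", "z")
  if (!all(need %in% names(a)))
    return(paste("atoms table lacks columns:",
                 paste(setdiff(need, names(a)), collapse = ", ")))
  if (nrow(a) == 0) return("structure has no atoms")
  if (any(a$element == "H" | a$element == "D"))
    return("hydrogen atoms must be dropped at parse time")
  key <- paste(a$chain, a$seqid, a$icode, a$atom)
  if (anyDuplicated(key))
    return("duplicate (chain, seqid, icode, atom) records")
  TRUE
})

#' ResidueSet: an ordered selection of residues from one structure
#'
#' @slot structure the [ProteinStructure] the members belong to
#' @slot members data.frame with columns `chain`, `seqid`, `icode`;
#'   every row resolves to an existing residue, order is meaningful
#' @export
setClass("ResidueSet",
  representation(structure = "ProteinStructure", members = "data.frame"))

setValidity("ResidueSet", function(object) {
  m <- object@members
  if (!all(c("chain", "seqid", "icode") %in% names(m)))
    return("members needs columns chain, seqid, icode")
  have <- unique(residueKeyString(object@structure@atoms$chain,
                                  object@structure@atoms$seqid,
                                  object@structure@atoms$icode))
  want <- residueKeyString(m$chain, m$seqid, m$icode)
  if (!all(want %in% have))
    return(paste("unresolved residues:",
                 paste(setdiff(want, have), collapse = ", ")))
  if (anyDuplicated(want)) return("duplicate members")
  TRUE
})

#' InteractionCutoffs: distance thresholds for interaction typing
#'
#' Defaults are the heavy-atom cutoffs used throughout: 5 A for
#' hydrophobic contacts, 6 A for ionic and cation-pi interactions,
#' 3.5 A for hydrogen bonds with an O/N donor and 4.0 A when sulphur
#' is involved, and 5 A for flagging protein residues in contact
#' with DNA.
#'
#' @slot hydrophobic,ionic,cationPi,hbondNO,hbondS,dnaContact numeric, Angstrom
#' @export
setClass("InteractionCutoffs",
  representation(hydrophobic = "numeric", ionic = "numeric",
                 cationPi = "numeric", hbondNO = "numeric",
                 hbondS = "numeric", dnaContact = "numeric"))

setValidity("InteractionCutoffs", function(object) {
  v <- c(object@hydrophobic, object@ionic, object@cationPi,
         object@hbondNO, object@hbondS, object@dnaContact)
  if (length(v) != 6 || any(!is.finite(v)) || any(v <= 0))
    return("all six cutoffs must be single positive numbers")
  TRUE
})

#' ContactMap: typed contacts across one interface
#'
#' @slot structureId structure of origin
#' @slot contacts data.frame, one row per (residue pair, type):
#'   `chain_a`, `seq_a`, `icode_a`, `resname_a`, `chain_b`, `seq_b`,
#'   `icode_b`, `resname_b`, `type` (hydrophobic|ionic|hbond|cation_pi),
#'   `distance` (minimal qualifying distance, Angstrom)
#' @slot sideA,sideB member tables of the two (disjoint) residue sets
#' @slot dnaFlags data.frame `chain`, `seqid`, `icode`, `side`, `flag`;
#'   one row for every residue of both sides
#' @export
setClass("ContactMap",
  representation(structureId = "character", contacts = "data.frame",
                 sideA = "data.frame", sideB = "data.frame",
                 dnaFlags = "data.frame"))

setValidity("ContactMap", function(object) {
  ct <- object@contacts
  if (nrow(ct)) {
    key <- paste(ct$chain_a, ct$seq_a, ct$icode_a,
                 ct$chain_b, ct$seq_b, ct$icode_b, ct$type)
    if (anyDuplicated(key)) return("duplicate (pair, type) contacts")
  }
  if (nrow(object@dnaFlags) !=
      nrow(object@sideA) + nrow(object@sideB))
    return("dnaFlags must cover every residue of both sides")
  TRUE
})

#' ComparativeMap: contacts shared between two structures
#'
#' Result of translating one contact map onto another through a residue
#' mapping: each contact is labelled `both`, `a_only` or `b_only`
#' (the solid / broken / dashed semantics of comparative interface
#' diagrams).
#'
#' @slot idA,idB the two structure ids
#' @slot contacts data.frame: contact columns as in [ContactMap] (in the
#'   coordinates of the structure the contact was observed in) plus
#'   `membership`
#' @export
setClass("ComparativeMap",
  representation(idA = "character", idB = "character",
                 contacts = "data.frame"))

setValidity("ComparativeMap", function(object) {
  ct <- object@contacts
  if (nrow(ct) && !all(ct$membership %in% c("both", "a_only", "b_only")))
    return("membership must be both|a_only|b_only")
  TRUE
})

#' ConsensusPattern: a degenerate, PROSITE-like sequence pattern
#'
#' Ordered positions, each a set of allowed residues or a wildcard.
#' The text dialect prints fixed positions as a single letter,
#' alternative sets as `[X/Y]`, and the wildcard as `-`; a wildcard
#' matches any letter including `X`, a set never matches `X`.
#'
#' @slot positions list; each element a character vector of allowed
#'   one-letter codes, or `NA_character_` for a wildcard
#' @slot text canonical rendering
#' @export
setClass("ConsensusPattern",
  representation(positions = "list", text = "character"))

setValidity("ConsensusPattern", function(object) {
  p <- object@positions
  if (length(p) < 1) return("pattern must have >= 1 position")
  ok <- vapply(p, function(s) {
    (length(s) == 1 && is.na(s)) ||
      (length(s) >= 1 && all(s %in% c(LETTERS)))
  }, logical(1))
  if (!all(ok)) return("each position is a letter set or NA (wildcard)")
  TRUE
})

#' AlignmentBlock: ungapped equal-length alignment rows
#'
#' @slot rows character vector of >= 2 equal-length ungapped segments
#' @slot sourceIds provenance: sequence id per row
#' @slot starts 1-based start position of each row in its source
#' @export
setClass("AlignmentBlock",
  representation(rows = "character", sourceIds = "character",
                 starts = "integer"))

setValidity("AlignmentBlock", function(object) {
  r <- object@rows
  if (length(r) < 2) return("block needs >= 2 rows")
  if (length(unique(nchar(r))) != 1) return("rows must have equal length")
  if (any(grepl("[-.]", r))) return("rows must be ungapped")
  if (length(object@sourceIds) != length(r) ||
      length(object@starts) != length(r))
    return("sourceIds and starts must parallel rows")
  TRUE
})

#' FragmentRegistry: peptide constructs and their binding outcomes
#'
#' A registry of named peptide spans of parent proteins (1-based,
#' inclusive, in the parent's numbering) together with per-partner
#' pull-down outcomes.
#'
#' @slot parents data.frame `id`, `length` (NA when unknown)
#' @slot fragments data.frame `id`, `parent`, `start`, `end`,
#'   `partner`, `outcome` (binds|no_binding|not_tested), `note`
#' @export
setClass("FragmentRegistry",
  representation(parents = "data.frame", fragments = "data.frame"))

setValidity("FragmentRegistry", function(object) {
  fr <- object@fragments
  need <- c("id", "parent", "start", "end", "partner", "outcome", "note")
  if (!all(need %in% names(fr)))
    return("fragments table lacks required columns")
  if (!all(fr$outcome %in% c("binds", "no_binding", "not_tested")))
    return("outcome must be binds|no_binding|not_tested")
  if (any(fr$start < 1 | fr$end < fr$start))
    return("need 1 <= start <= end")
  sp <- unique(fr[, c("id", "start", "end")])
  if (anyDuplicated(sp$id)) return("a fragment id maps to two spans")
  bad <- !fr$parent %in% object@parents$id
  if (any(bad))
    return(paste("unknown parent:", paste(unique(fr$parent[bad]), collapse = ", ")))
  len <- object@parents$length[match(fr$parent, object@parents$id)]
  over <- !is.na(len) & fr$end > len
  if (any(over)) return("fragment end exceeds parent length")
  TRUE
})

#' BindingSiteProposal: interface contacts transferred onto a peptide
#'
#' @slot peptideId id of the candidate peptide
#' @slot entries data.frame: `pep_pos` (position in the peptide's parent
#'   numbering), `pep_res` (one-letter code), `src_chain`, `src_seq`,
#'   `src_res` (source segment residue the contact was observed on),
#'   `partner_chain`, `partner_seq`, `partner_res`, `type`, `membership`
#' @export
setClass("BindingSiteProposal",
  representation(peptideId = "character", entries = "data.frame"))

setValidity("BindingSiteProposal", function(object) {
  e <- object@entries
  need <- c("pep_pos", "pep_res", "src_chain", "src_seq", "src_res",
            "partner_chain", "partner_seq", "partner_res",
            "type", "membership")
  if (!all(need %in% names(e)))
    return("entries table lacks required columns")
  TRUE
})
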