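# Cross-structure comparison of contact maps through a user-supplied
# residue correspondence (the solid / broken / dashed semantics:
# shared, first-structure-only, second-structure-only).

.normMapping <- function(mapping) {
  m <- as.data.frame(mapping, stringsAsFactors = FALSE)
  need <- c("chain_a", "seq_a", "chain_b", "seq_b")
  if (!all(need %in% names(m)))
    stop("mapping needs columns chain_a, seq_a, chain_b, seq_b")
  if (is.null(m$icode_a)) m$icode_a <- ""
  if (is.null(m$icode_b)) m$icode_b <- ""
  ka <- residueKeyString(m$chain_a, m$seq_a, m$icode_a)
  kb <- residueKeyString(m$chain_b, m$seq_b, m$icode_b)
  if (anyDuplicated(ka) || anyDuplicated(kb))
    stop("residue mapping must be one-to-one")
  list(m = m, ka = ka, kb = kb)
}

#' Compare two contact maps through a residue mapping
#'
#' A contact of one map is `shared` ("both") when, after translating
#' its two residues through the mapping, a contact with the same
#' residue pair and the same interaction type exists in the other map
#' (distances are ignored).  Contacts involving unmapped residues, and
#' contacts whose translated pair/type is absent from the other map,
#' fall into `a_only` / `b_only`.
#'
#' @param mapA,mapB [ContactMap]s of the two structures
#' @param mapping data.frame with columns `chain_a`, `seq_a`,
#'   `chain_b`, `seq_b` (optional `icode_a`, `icode_b`), one row per
#'   corresponding residue pair; must be one-to-one
#' @return a [ComparativeMap]
#' @export
compareMaps <- function(mapA, mapB, mapping) {
  stopifnot(is(mapA, "ContactMap"), is(mapB, "ContactMap"))
  nm <- .normMapping(mapping)

  pairKey <- function(k1, k2, type) {
    a <- pmin(k1, k2); b <- pmax(k1, k2)
    paste(a, b, type)
  }
  ctKeys <- function(ct, translate = NULL) {
    if (nrow(ct) == 0) return(character(0))
    k1 <- residueKeyString(ct$chain_a, ct$seq_a, ct$icode_a)
    k2 <- residueKeyString(ct$chain_b, ct$seq_b, ct$icode_b)
    if (!is.null(translate)) {
      k1 <- translate[k1]; k2 <- translate[k2]
    }
    ifelse(is.na(k1) | is.na(k2), NA_character_,
           pairKey(k1, k2, ct$type))
  }
  a2b <- stats::setNames(nm$kb, nm$ka)
  ctA <- contacts(mapA); ctB <- contacts(mapB)
  keyAinB <- ctKeys(ctA, a2b)       # A contacts in B coordinates
  keyB <- ctKeys(ctB)
  sharedA <- !is.na(keyAinB) & keyAinB %in% keyB
  sharedB <- keyB %in% keyAinB[sharedA]

  addMem <- function(ct, mem) {
    if (nrow(ct) == 0) {
      ct$membership <- character(0)
      ct$source <- character(0)
      return(ct)
    }
    ct$membership <- mem
    ct
  }
  outA <- addMem(ctA, ifelse(sharedA, "both", "a_only"))
  outA$source <- rep(mapA@structureId, nrow(outA))
  outB <- addMem(ctB[!sharedB, , drop = FALSE], "b_only")
  outB$source <- rep(mapB@structureId, nrow(outB))
  rownames(outB) <- NULL
  new("ComparativeMap", idA = mapA@structureId, idB = mapB@structureId,
      contacts = rbind(outA, outB))
}

#' @rdname ComparativeMap-class
#' @param x a ComparativeMap
#' @export
setMethod("contacts", "ComparativeMap", function(x) x@contacts)

#' @rdname ComparativeMap-class
#' @export
sharedContacts <- function(x) {
  stopifnot(is(x, "ComparativeMap"))
  x@contacts[x@contacts$membership == "both", , drop = FALSE]
}

#' @rdname ComparativeMap-class
#' @export
onlyA <- function(x) {
  stopifnot(is(x, "ComparativeMap"))
  x@contacts[x@contacts$membership == "a_only", , drop = FALSE]
}

#' @rdname ComparativeMap-class
#' @export
onlyB <- function(x) {
  stopifnot(is(x, "ComparativeMap"))
  x@contacts[x@contacts$membership == "b_only", , drop = FALSE]
}

setMethod("show", "ComparativeMap", function(object) {
  ct <- object@contacts
  cat("ComparativeMap \"", object@idA, "\" vs \"", object@idB, "\": ",
      sum(ct$membership == "both"), " shared, ",
      sum(ct$membership == "a_only"), " in ", object@idA, " only, ",
      sum(ct$membership == "b_only"), " in ", object@idB, " only\n",
      sep = "")
})

#' Build a residue mapping from an ungapped chain alignment
#'
#' Slides the shorter chain sequence over the longer one (identity
#' scoring, no gaps) and pairs residues positionally at the best
#' offset — a pragmatic helper for numbering differences between
#' crystal structures of the same complex.
#'
#' @param structA,structB [ProteinStructure]s
#' @param chainA,chainB chain ids to align
#' @return mapping data.frame usable by [compareMaps()]
#' @export
mappingFromAlignment <- function(structA, chainA, structB, chainB) {
  sa <- selectResidues(structA, chainA)
  sb <- selectResidues(structB, chainB)
  seqA <- residueSequence(sa)
  seqB <- residueSequence(sb)
  swap <- nchar(seqA) > nchar(seqB)
  al <- if (swap) alignSegment(seqB, seqA, classAware = FALSE)
        else alignSegment(seqA, seqB, classAware = FALSE)
  shortM <- if (swap) sb@members else sa@members
  longM <- if (swap) sa@members else sb@members
  idx <- al$offset + seq_len(nrow(shortM)) - 1L
  keep <- idx >= 1 & idx <= nrow(longM)
  shortM <- shortM[keep, , drop = FALSE]
  longM <- longM[idx[keep], , drop = FALSE]
  if (swap) { tmp <- shortM; shortM <- longM; longM <- tmp }
  data.frame(chain_a = shortM$chain, seq_a = shortM$seqid,
             icode_a = shortM$icode,
             chain_b = longM$chain, seq_b = longM$seqid,
             icode_b = longM$icode, stringsAsFactors = FALSE)
}

#' Comparative map as a flat export table
#'
#' Mirrors [contactTable()] with an added `membership` column
#' (`both`, `a_only`, `b_only`) and a `source` structure column.
#'
#' @param x a [ComparativeMap]
#' @return data.frame
#' @export
comparativeTable <- function(x) {
  stopifnot(is(x, "ComparativeMap"))
  ct <- x@contacts
  data.frame(
    source = ct$source,
    chain_a = ct$chain_a, seq_a = paste0(ct$seq_a, ct$icode_a),
    resname_a = ct$resname_a,
    chain_b = ct$chain_b, seq_b = paste0(ct$seq_b, ct$icode_b),
    resname_b = ct$resname_b, type = ct$type,
    distance_angstrom = round(ct$distance, 3),
    membership = ct$membership, stringsAsFactors = FALSE)
}
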