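# Alignment-based transfer of interface contacts from a donor segment
# (the NF-YB N-terminal region in the motivating analysis) onto an
# aligned candidate peptide, proposing where the peptide would touch
# the partner subunit.

#' Transfer a segment's contacts onto an aligned peptide
#'
#' For every contact of a donor-segment residue whose partner chain is
#' in `partnerFilter`, emits a proposal entry at the peptide position
#' the alignment maps that residue to.  Interaction types are copied
#' verbatim (the proposal is positional, not energetic); a message is
#' emitted when the peptide residue's polarity class differs from the
#' donor residue's.  Contacts on segment residues outside the aligned
#' window are skipped with a message.
#'
#' @param alignment a `segmentAlignment` from [alignSegment()], peptide
#'   vs the segment's sequence (the alignment target must cover the
#'   segment)
#' @param segment a [ResidueSet]: the donor span, ordered; must appear
#'   as a side of `map`
#' @param map a [ContactMap] or [ComparativeMap]
#' @param partnerFilter chains whose contacts are transferred (default:
#'   all partner chains in the map)
#' @param peptideStart parent-numbering position of the peptide's first
#'   residue (e.g. 5 for QQS-5-11), default 1
#' @return a [BindingSiteProposal]
#' @export
transferSites <- function(alignment, segment, map, partnerFilter = NULL,
                          peptideStart = 1L) {
  stopifnot(inherits(alignment, "segmentAlignment"),
            is(segment, "ResidueSet"))
  ct <- if (is(map, "ComparativeMap")) contacts(map)
        else if (is(map, "ContactMap")) {
          x <- contacts(map); x$membership <- rep(NA_character_, nrow(x)); x
        } else stop("map must be a ContactMap or ComparativeMap")

  segM <- segment@members
  segKeys <- residueKeyString(segM$chain, segM$seqid, segM$icode)
  segSeq <- residueSequence(segment)
  if (nchar(alignment$target) != nchar(segSeq) ||
      alignment$target != segSeq)
    stop("alignment target does not cover the segment (expected ",
         segSeq, ", got ", alignment$target, ")")

  if (is(map, "ContactMap")) {
    sidesA <- residueKeyString(map@sideA$chain, map@sideA$seqid,
                               map@sideA$icode)
    sidesB <- residueKeyString(map@sideB$chain, map@sideB$seqid,
                               map@sideB$icode)
    if (!all(segKeys %in% c(sidesA, sidesB)))
      stop("segment is not a subset of the map's sides")
  } else if (nrow(ct)) {
    mapKeys <- c(residueKeyString(ct$chain_a, ct$seq_a, ct$icode_a),
                 residueKeyString(ct$chain_b, ct$seq_b, ct$icode_b))
    if (!any(segKeys %in% mapKeys))
      warning("no comparative contact involves the segment")
  }

  np <- nchar(alignment$peptide)
  pepChars <- strsplit(alignment$peptide, "")[[1]]
  entries <- list()
  skipped <- 0L
  for (r in seq_len(nrow(ct))) {
    keyA <- residueKeyString(ct$chain_a[r], ct$seq_a[r], ct$icode_a[r])
    keyB <- residueKeyString(ct$chain_b[r], ct$seq_b[r], ct$icode_b[r])
    if (keyA %in% segKeys) {
      segKey <- keyA; segRes <- ct$resname_a[r]
      pChain <- ct$chain_b[r]; pSeq <- ct$seq_b[r]; pRes <- ct$resname_b[r]
    } else if (keyB %in% segKeys) {
      segKey <- keyB; segRes <- ct$resname_b[r]
      pChain <- ct$chain_a[r]; pSeq <- ct$seq_a[r]; pRes <- ct$resname_a[r]
    } else next
    if (!is.null(partnerFilter) && !pChain %in% partnerFilter) next

    j <- match(segKey, segKeys)               # ordinal in the segment
    i <- j - alignment$offset + 1L            # peptide index
    if (i < 1 || i > np) { skipped <- skipped + 1L; next }
    entries[[length(entries) + 1L]] <- data.frame(
      pep_pos = peptideStart + i - 1L,
      pep_res = pepChars[i],
      src_chain = segM$chain[j], src_seq = segM$seqid[j],
      src_res = segRes,
      partner_chain = pChain, partner_seq = pSeq, partner_res = pRes,
      type = ct$type[r], membership = ct$membership[r],
      stringsAsFactors = FALSE)
  }
  if (skipped)
    message(skipped, " contact(s) on unaligned segment residues skipped")

  e <- if (length(entries)) do.call(rbind, entries) else
    data.frame(pep_pos = integer(0), pep_res = character(0),
               src_chain = character(0), src_seq = integer(0),
               src_res = character(0), partner_chain = character(0),
               partner_seq = integer(0), partner_res = character(0),
               type = character(0), membership = character(0),
               stringsAsFactors = FALSE)
  if (nrow(e)) {
    pepCls <- CLASS1[e$pep_res]
    srcCls <- unname(RESIDUE_CLASS[e$src_res])
    diffc <- !is.na(pepCls) & !is.na(srcCls) & pepCls != srcCls
    if (any(diffc))
      message("peptide residue class differs from donor at position(s) ",
              paste(unique(e$pep_pos[diffc]), collapse = ", "))
  }
  rownames(e) <- NULL
  new("BindingSiteProposal", peptideId = alignment$peptideId, entries = e)
}

#' @rdname BindingSiteProposal-class
#' @export
setMethod("proposalEntries", "BindingSiteProposal", function(x) x@entries)

setMethod("show", "BindingSiteProposal", function(object) {
  e <- object@entries
  cat("BindingSiteProposal for ", object@peptideId, ": ",
      nrow(e), " transferred contact(s)", sep = "")
  if (nrow(e))
    cat(" over peptide positions ", min(e$pep_pos), "-",
        max(e$pep_pos), sep = "")
  cat("\n")
})

#' Two-site topology: motif spans and the linker between them
#'
#' Given the proposals for an N-terminal and a C-terminal binding
#' motif on the same peptide, reports both motif spans and the
#' inter-motif linker (last N-motif position + 1 to first C-motif
#' position - 1).  Overlapping proposals (including the same proposal
#' twice) are an error.
#'
#' @param proposalN,proposalC [BindingSiteProposal]s on one peptide
#' @param peptideLength full parent peptide length (for the report)
#' @return list: `nSpan`, `cSpan` (c(start, end)), `linkerStart`,
#'   `linkerEnd`, `linkerLength`, `peptideLength`
#' @export
linkerReport <- function(proposalN, proposalC, peptideLength) {
  stopifnot(is(proposalN, "BindingSiteProposal"),
            is(proposalC, "BindingSiteProposal"))
  pn <- proposalN@entries$pep_pos
  pc <- proposalC@entries$pep_pos
  if (!length(pn) || !length(pc))
    stop("both proposals must contain entries")
  nSpan <- c(min(pn), max(pn))
  cSpan <- c(min(pc), max(pc))
  if (nSpan[1] > cSpan[1]) { tmp <- nSpan; nSpan <- cSpan; cSpan <- tmp }
  if (nSpan[2] >= cSpan[1])
    stop("proposal spans overlap (", nSpan[1], "-", nSpan[2], " vs ",
         cSpan[1], "-", cSpan[2], ")")
  linkerStart <- nSpan[2] + 1L
  linkerEnd <- cSpan[1] - 1L
  list(nSpan = nSpan, cSpan = cSpan,
       linkerStart = if (linkerStart <= linkerEnd) linkerStart else NA_integer_,
       linkerEnd = if (linkerStart <= linkerEnd) linkerEnd else NA_integer_,
       linkerLength = max(0L, linkerEnd - linkerStart + 1L),
       peptideLength = peptideLength)
}

#' Write a binding-site proposal as TSV
#'
#' @param proposal a [BindingSiteProposal]
#' @param file output path
#' @export
writeProposal <- function(proposal, file) {
  e <- proposalEntries(proposal)
  utils::write.table(e, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(e)
}
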