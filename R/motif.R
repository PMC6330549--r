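# Degenerate consensus patterns in a compact PROSITE-like dialect:
# fixed positions print as a single letter, alternative sets as
# [X/Y/...], and a single-position wildcard as "-".  A wildcard
# matches any letter including X; a set never matches X.

AA1 <- unname(AA3)
CLASS1 <- stats::setNames(unname(RESIDUE_CLASS[names(AA3)]), unname(AA3))

#' Parse a degenerate consensus pattern
#'
#' @param text pattern string, e.g. `"R[E/D]Q[D/E]-[Y/F/W][L/V]"`
#' @return a [ConsensusPattern]
#' @examples
#' p <- parsePattern("R[E/D]Q[D/E]-[Y/F/W][L/V]")
#' patternText(p)
#' @export
parsePattern <- function(text) {
  stopifnot(is.character(text), length(text) == 1, nzchar(text))
  chars <- strsplit(text, "")[[1]]
  positions <- list()
  i <- 1
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "-") {
      positions <- c(positions, list(NA_character_))
      i <- i + 1
    } else if (ch == "[") {
      j <- i + 1
      while (j <= length(chars) && chars[j] != "]") j <- j + 1
      if (j > length(chars))
        stop("unbalanced bracket in pattern: ", text)
      inner <- if (j - i > 1)
        paste(chars[(i + 1):(j - 1)], collapse = "") else ""
      alts <- strsplit(inner, "/", fixed = TRUE)[[1]]
      alts <- alts[nzchar(alts)]
      nSlots <- length(strsplit(paste0(inner, "|"), "/", fixed = TRUE)[[1]])
      if (length(alts) == 0 || length(alts) < nSlots ||
          !all(alts %in% setdiff(LETTERS, "X")))
        stop("malformed alternative set [", inner, "] in pattern: ", text)
      positions <- c(positions, list(alts))
      i <- j + 1
    } else if (ch %in% setdiff(LETTERS, "X")) {
      positions <- c(positions, list(ch))
      i <- i + 1
    } else {
      stop("unexpected character '", ch, "' in pattern: ", text)
    }
  }
  newPattern(positions)
}

#' @rdname ConsensusPattern-class
#' @param positions list of letter sets / `NA` wildcards
#' @export
newPattern <- function(positions) {
  render <- vapply(positions, function(s) {
    if (length(s) == 1 && is.na(s)) return("-")
    if (length(s) == 1) return(s)
    paste0("[", paste(s, collapse = "/"), "]")
  }, character(1))
  new("ConsensusPattern", positions = positions,
      text = paste(render, collapse = ""))
}

#' @rdname ConsensusPattern-class
#' @export
setMethod("patternText", "ConsensusPattern", function(x) x@text)

#' @rdname ConsensusPattern-class
#' @export
setMethod("patternPositions", "ConsensusPattern", function(x) x@positions)

setMethod("length", "ConsensusPattern", function(x) length(x@positions))

setMethod("show", "ConsensusPattern", function(object) {
  cat("ConsensusPattern of length ", length(object@positions), ": ",
      object@text, "\n", sep = "")
})

# does pattern match seq at 1-based position pos (pattern fits)?
.matchAt <- function(positions, seqChars, pos) {
  for (k in seq_along(positions)) {
    s <- positions[[k]]
    ch <- seqChars[pos + k - 1]
    if (length(s) == 1 && is.na(s)) next        # wildcard, matches X too
    if (!ch %in% s) return(FALSE)               # sets never match X
  }
  TRUE
}

#' Derive a degenerate consensus from an ungapped alignment block
#'
#' Per column: one distinct residue gives a fixed letter; up to
#' `maxAlternatives` distinct residues give an alternative set ordered
#' by column frequency then alphabetically; more give a wildcard.  By
#' construction every row of the block matches the derived pattern.
#'
#' @param block an [AlignmentBlock]
#' @param maxAlternatives maximum set size before a column degrades to
#'   a wildcard (default 3)
#' @return a [ConsensusPattern]
#' @examples
#' b <- alignmentBlock(c("REQEIYV", "RDQDAWL"))
#' patternText(deriveConsensus(b))
#' @export
deriveConsensus <- function(block, maxAlternatives = 3) {
  stopifnot(is(block, "AlignmentBlock"))
  rows <- block@rows
  L <- nchar(rows[1])
  mat <- do.call(rbind, strsplit(rows, ""))
  positions <- lapply(seq_len(L), function(j) {
    col <- mat[, j]
    tb <- sort(table(col), decreasing = TRUE)
    # frequency descending, ties alphabetical
    lv <- names(tb)[order(-as.integer(tb), names(tb))]
    if (length(lv) == 1) lv
    else if (length(lv) <= maxAlternatives) lv
    else NA_character_
  })
  newPattern(positions)
}

#' Construct an alignment block
#'
#' @param rows character vector of >= 2 equal-length ungapped segments
#' @param sourceIds optional provenance ids (default `row1`, `row2`, ...)
#' @param starts optional 1-based start positions in the sources
#' @return an [AlignmentBlock]
#' @export
alignmentBlock <- function(rows, sourceIds = NULL, starts = NULL) {
  rows <- toupper(rows)
  if (is.null(sourceIds)) sourceIds <- paste0("row", seq_along(rows))
  if (is.null(starts)) starts <- rep(1L, length(rows))
  new("AlignmentBlock", rows = rows, sourceIds = sourceIds,
      starts = as.integer(starts))
}

setMethod("show", "AlignmentBlock", function(object) {
  cat("AlignmentBlock: ", length(object@rows), " rows x ",
      nchar(object@rows[1]), " columns\n", sep = "")
  for (i in seq_along(object@rows))
    cat("  ", format(object@sourceIds[i], width = 12), " ",
        object@rows[i], "\n", sep = "")
})

#' Scan one sequence for a pattern
#'
#' Tests every start offset; overlapping hits are all reported.
#'
#' @param pattern a [ConsensusPattern]
#' @param seq amino-acid string (alphabet: 20 letters plus X)
#' @param id record id for the hit table
#' @return data.frame `record_id`, `start`, `end`, `match` (0 rows when
#'   nothing matches or the pattern is longer than the sequence)
#' @examples
#' scanSequence(parsePattern("R[E/D]Q[D/E]-[Y/F/W][L/V]"), "REQEIYV")
#' @export
scanSequence <- function(pattern, seq, id = "seq") {
  stopifnot(is(pattern, "ConsensusPattern"))
  seq <- toupper(seq)
  L <- length(pattern@positions)
  n <- nchar(seq)
  empty <- data.frame(record_id = character(0), start = integer(0),
                      end = integer(0), match = character(0),
                      stringsAsFactors = FALSE)
  if (n < L || n == 0) return(empty)
  chars <- strsplit(seq, "")[[1]]
  hit <- vapply(seq_len(n - L + 1), function(p)
    .matchAt(pattern@positions, chars, p), logical(1))
  starts <- which(hit)
  if (!length(starts)) return(empty)
  data.frame(record_id = id, start = starts, end = starts + L - 1L,
             match = vapply(starts, function(p)
               substr(seq, p, p + L - 1L), character(1)),
             stringsAsFactors = FALSE)
}

#' Scan a FASTA database for a pattern with exclusion filters
#'
#' A record contributes hits only if it matches the query pattern and
#' matches none of the exclusion patterns anywhere (e.g. to discard
#' histone-like sequences).  Hits are ordered by record, then position.
#'
#' @param pattern a [ConsensusPattern]
#' @param records FASTA path, character vector of sequences (named), or
#'   a `Biostrings::AAStringSet`
#' @param exclusion list of [ConsensusPattern]s (may be empty)
#' @return data.frame as in [scanSequence()] plus `pattern_text`
#' @export
scanDatabase <- function(pattern, records, exclusion = list()) {
  stopifnot(is(pattern, "ConsensusPattern"))
  if (is(exclusion, "ConsensusPattern")) exclusion <- list(exclusion)
  seqs <- .asSequences(records)
  out <- list()
  for (i in seq_along(seqs)) {
    s <- seqs[i]
    excluded <- any(vapply(exclusion, function(ex)
      nrow(scanSequence(ex, s, "x")) > 0, logical(1)))
    if (excluded) next
    h <- scanSequence(pattern, s, names(seqs)[i])
    if (nrow(h)) out[[length(out) + 1L]] <- h
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(record_id = character(0), start = integer(0),
               end = integer(0), match = character(0),
               stringsAsFactors = FALSE)
  res$pattern_text <- rep(pattern@text, nrow(res))
  rownames(res) <- NULL
  res
}

.asSequences <- function(records) {
  if (is(records, "AAStringSet")) {
    seqs <- as.character(records)
  } else if (is.character(records) && length(records) == 1 &&
             !grepl("\n", records) && file.exists(records)) {
    ss <- tryCatch(Biostrings::readAAStringSet(records),
                   error = function(e)
                     stop("unreadable FASTA ", records, ": ",
                          conditionMessage(e)))
    seqs <- as.character(ss)
  } else if (is.character(records)) {
    seqs <- records
    if (is.null(names(seqs)))
      names(seqs) <- paste0("seq", seq_along(seqs))
  } else stop("records must be a FASTA path, sequences, or AAStringSet")
  # id = first whitespace-separated token of the header
  names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1)
  toupper(seqs)
}

#' Ungapped best-offset alignment of a peptide against a target
#'
#' Slides the peptide over the target without gaps.  Column score: 2
#' for identity, 1 for residues of the same polarity class (when
#' `classAware`), 0 otherwise.  Ties break to the smallest offset.
#'
#' @param peptide,target amino-acid strings (peptide no longer than
#'   target); names are taken from `peptideId`/`targetId`
#' @param classAware score 1 for same-class columns (default TRUE)
#' @param peptideId,targetId ids carried into the result
#' @return list of class `segmentAlignment`: `offset` (1-based start in
#'   the target), `score`, `labels` (per peptide position:
#'   `identity`/`class`/`mismatch`), `peptide`, `target`, ids
#' @examples
#' alignSegment("REQEIYV", "GGRDQDAWLGG")
#' @export
alignSegment <- function(peptide, target, classAware = TRUE,
                         peptideId = "peptide", targetId = "target") {
  peptide <- toupper(peptide); target <- toupper(target)
  if (!nzchar(peptide) || !nzchar(target))
    stop("empty sequence")
  np <- nchar(peptide); nt <- nchar(target)
  if (np > nt)
    stop("peptide longer than target")
  pc <- strsplit(peptide, "")[[1]]
  tc <- strsplit(target, "")[[1]]
  colScore <- function(a, b) {
    if (a == b) return(2)
    if (classAware && !is.na(CLASS1[a]) && !is.na(CLASS1[b]) &&
        CLASS1[a] == CLASS1[b]) return(1)
    0
  }
  best <- -1; bestOff <- 1L
  for (off in seq_len(nt - np + 1L)) {
    sc <- sum(vapply(seq_len(np), function(k)
      colScore(pc[k], tc[off + k - 1]), numeric(1)))
    if (sc > best) { best <- sc; bestOff <- off }
  }
  labels <- vapply(seq_len(np), function(k) {
    a <- pc[k]; b <- tc[bestOff + k - 1]
    if (a == b) "identity"
    else if (classAware && !is.na(CLASS1[a]) && !is.na(CLASS1[b]) &&
             CLASS1[a] == CLASS1[b]) "class"
    else "mismatch"
  }, character(1))
  structure(list(offset = bestOff, score = best, labels = labels,
                 peptide = peptide, target = target,
                 peptideId = peptideId, targetId = targetId,
                 classAware = classAware),
            class = "segmentAlignment")
}

#' @export
print.segmentAlignment <- function(x, ...) {
  pad <- paste(rep(" ", x$offset - 1), collapse = "")
  cat("segmentAlignment ", x$peptideId, " vs ", x$targetId,
      " (offset ", x$offset, ", score ", x$score, ")\n", sep = "")
  cat("  ", x$target, "\n  ", pad, x$peptide, "\n  ", pad,
      paste(c(identity = "|", class = ":",
              mismatch = ".")[x$labels], collapse = ""), "\n", sep = "")
  invisible(x)
}

#' Write motif hits as TSV
#'
#' @param hits hit table from [scanSequence()]/[scanDatabase()]
#' @param file output path
#' @export
writeHits <- function(hits, file) {
  utils::write.table(hits, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(hits)
}
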