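# Pragmatic fixed-column PDB reader: ATOM/HETATM/TER/MODEL/ENDMDL only,
# heavy atoms, author numbering.  Everything downstream (interaction
# typing, DNA flags) is a heavy-atom analysis, so hydrogens are dropped
# at the door; waters likewise.

.inferElement <- function(name, raw13) {
  nm <- gsub("[^A-Za-z]", "", name)
  if (!nzchar(nm)) return("X")
  two <- toupper(substr(nm, 1, 2))
  # a name starting in column 13 signals a two-letter element symbol
  if (raw13 != " " && nchar(nm) >= 2 && two %in% TWO_LETTER_ELEMENTS)
    return(paste0(substr(two, 1, 1), tolower(substr(two, 2, 2))))
  toupper(substr(nm, 1, 1))
}

#' Read a PDB file into a ProteinStructure
#'
#' Parses ATOM/HETATM records (fixed columns).  Hydrogens (and
#' deuteriums) and water residues are discarded; for residues with
#' alternate locations only the highest-occupancy altloc is kept
#' (ties: first seen); only the first MODEL of a multi-model file is
#' read.  Modified amino acids with a known parent (e.g. MSE) are
#' renamed to the parent and typed as protein; residues whose name is a
#' standard nucleotide code are typed nucleic; anything else is typed
#' `other`.  A missing element column is tolerated (the element is
#' inferred from the atom name).
#'
#' @param input path to a PDB file, or the file's content as a character
#'   vector of lines (or one string containing newlines)
#' @param id structure id; defaults to the file base name or `"structure"`
#' @return a [ProteinStructure]
#' @examples
#' toy <- makeToyStructure(
#'   list(plantedContact("LEU", "A", 1, "LEU", "B", 1, "hydrophobic", 4.5)),
#'   decoys = 0, seed = 1)
#' s <- readPDB(toy$text, id = "toy")
#' residueTable(s)
#' @export
readPDB <- function(input, id = NULL) {
  if (length(input) == 1 && !grepl("\n", input) && file.exists(input)) {
    if (is.null(id))
      id <- sub("\\.(pdb|ent)$", "", basename(input), ignore.case = TRUE)
    lines <- readLines(input, warn = FALSE)
  } else {
    lines <- unlist(strsplit(input, "\n", fixed = TRUE), use.names = FALSE)
  }
  if (is.null(id)) id <- "structure"
  if (length(lines) == 0)
    stop("empty PDB input")

  rec <- substr(lines, 1, 6)
  # keep only the first model when MODEL records are present
  imodel <- which(trimws(rec) == "MODEL")
  if (length(imodel) >= 2)
    lines <- lines[seq_len(imodel[2] - 1)]
  iend <- which(substr(lines, 1, 6) == "ENDMDL")
  if (length(iend) >= 1)
    lines <- lines[seq_len(iend[1] - 1)]

  isAtom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(isAtom))
    stop("no ATOM or HETATM records found")
  ln <- which(isAtom)
  al <- lines[ln]

  short <- nchar(al) < 54
  if (any(short))
    stop("malformed ATOM/HETATM record (line ", ln[which(short)[1]],
         "): fewer than 54 columns")

  f <- function(a, b) trimws(substr(al, a, b))
  name    <- f(13, 16)
  altloc  <- substr(al, 17, 17)
  resname <- f(18, 20)
  chain   <- substr(al, 22, 22)
  seqtxt  <- f(23, 26)
  icode   <- trimws(substr(al, 27, 27))
  xs <- f(31, 38); ys <- f(39, 46); zs <- f(47, 54)
  occtxt  <- trimws(substr(al, 55, 60))
  eltxt   <- trimws(substr(al, 77, 78))

  num <- function(v, what) {
    out <- suppressWarnings(as.numeric(v))
    bad <- is.na(out) & nzchar(v)
    if (any(bad))
      stop("malformed ", what, " field at line ", ln[which(bad)[1]])
    out
  }
  x <- num(xs, "x"); y <- num(ys, "y"); z <- num(zs, "z")
  if (anyNA(x) || anyNA(y) || anyNA(z))
    stop("missing coordinate at line ",
         ln[which(is.na(x) | is.na(y) | is.na(z))[1]])
  seqid <- suppressWarnings(as.integer(seqtxt))
  if (anyNA(seqid))
    stop("malformed residue number at line ", ln[which(is.na(seqid))[1]])
  occ <- num(occtxt, "occupancy")
  occ[is.na(occ)] <- 1

  element <- toupper(eltxt)
  miss <- !nzchar(element)
  if (any(miss))
    element[miss] <- mapply(.inferElement, name[miss],
                            substr(al[miss], 13, 13))
  element <- ifelse(nchar(element) == 2,
                    paste0(substr(element, 1, 1),
                           tolower(substr(element, 2, 2))),
                    element)

  keep <- !(element %in% c("H", "D")) & !(resname %in% WATER_NAMES)
  a <- data.frame(chain = chain, seqid = seqid, icode = icode,
                  resname = resname, atom = name, altloc = altloc,
                  occ = occ, element = element, x = x, y = y, z = z,
                  stringsAsFactors = FALSE)[keep, , drop = FALSE]
  if (nrow(a) == 0)
    stop("no heavy, non-water atoms in input")

  mapped <- HET_PARENT[a$resname]
  a$resname[!is.na(mapped)] <- mapped[!is.na(mapped)]
  a$kind <- ifelse(a$resname %in% names(AA3), "protein",
            ifelse(a$resname %in% NUC3, "nucleic", "other"))

  # altloc resolution per residue: keep blank altloc atoms plus the
  # highest-occupancy label (first seen wins ties)
  rk <- residueKeyString(a$chain, a$seqid, a$icode)
  keepRow <- rep(TRUE, nrow(a))
  for (k in unique(rk[a$altloc != " "])) {
    i <- which(rk == k & a$altloc != " ")
    labs <- unique(a$altloc[i])
    best <- labs[which.max(vapply(labs, function(L)
      max(a$occ[i][a$altloc[i] == L]), numeric(1)))]
    keepRow[i[a$altloc[i] != best]] <- FALSE
  }
  a <- a[keepRow, , drop = FALSE]
  dup <- duplicated(paste(residueKeyString(a$chain, a$seqid, a$icode), a$atom))
  a <- a[!dup, , drop = FALSE]

  # order: chain by first appearance, then seqid, then icode, then record order
  chlev <- unique(a$chain)
  a <- a[order(match(a$chain, chlev), a$seqid, a$icode), , drop = FALSE]
  a$altloc <- NULL
  a$occ <- NULL
  rownames(a) <- NULL
  new("ProteinStructure", id = id, atoms = a)
}

#' Write a ProteinStructure as PDB text
#'
#' @param x a [ProteinStructure]
#' @param file optional path; when `NULL` the lines are returned invisibly
#' @return character vector of PDB lines, invisibly
#' @export
writePDB <- function(x, file = NULL) {
  a <- atomRecords(x)
  fmtName <- function(n) {
    ifelse(nchar(n) >= 4, substr(n, 1, 4), sprintf(" %-3s", n))
  }
  lines <- character(0)
  nser <- 0L
  for (ch in unique(a$chain)) {
    sub <- a[a$chain == ch, , drop = FALSE]
    rectype <- ifelse(sub$kind %in% c("protein", "nucleic"),
                      "ATOM  ", "HETATM")
    ser <- nser + seq_len(nrow(sub))
    nser <- nser + nrow(sub)
    lines <- c(lines, sprintf(
      "%s%5d %s %3s %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      rectype, ser, fmtName(sub$atom), sub$resname, ch, sub$seqid,
      ifelse(sub$icode == "", " ", sub$icode),
      sub$x, sub$y, sub$z, 1, 0,
      sprintf("%2s", toupper(sub$element))))
    lines <- c(lines, "TER")
  }
  lines <- c(lines, "END")
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}

#' Select residues of a chain by an author-numbered span
#'
#' Spans are 1-based and inclusive in the author (PDB) numbering;
#' residues absent from the span are silently skipped, so gaps in the
#' numbering are allowed and an empty selection is permitted.
#' Insertion-coded residues compare on the integer part of their number.
#'
#' @param x a [ProteinStructure]
#' @param chain chain identifier (must exist)
#' @param span `"all"`, or `c(start, end)` in author numbering
#' @return a [ResidueSet] ordered by residue number
#' @examples
#' toy <- makeToyStructure(
#'   list(plantedContact("LYS", "B", 51, "GLU", "C", 10, "ionic", 5.5)),
#'   decoys = 0, seed = 1)
#' s <- readPDB(toy$text)
#' selectResidues(s, "B", c(51, 57))
#' @export
selectResidues <- function(x, chain, span = "all") {
  stopifnot(is(x, "ProteinStructure"))
  rt <- residueTable(x)
  if (!chain %in% rt$chain)
    stop("unknown chain: ", chain)
  rt <- rt[rt$chain == chain, , drop = FALSE]
  if (!identical(span, "all")) {
    if (!is.numeric(span) || length(span) != 2 || span[2] < span[1])
      stop("span must be \"all\" or c(start, end) with start <= end")
    rt <- rt[rt$seqid >= span[1] & rt$seqid <= span[2], , drop = FALSE]
  }
  rt <- rt[order(rt$seqid, rt$icode), , drop = FALSE]
  new("ResidueSet", structure = x,
      members = data.frame(chain = rt$chain, seqid = rt$seqid,
                           icode = rt$icode, stringsAsFactors = FALSE))
}

#' Extract one residue's atom table
#'
#' @param x a [ProteinStructure]
#' @param chain,seqid,icode residue identifier (author numbering)
#' @return data.frame of the residue's atoms with attributes `resname`,
#'   `kind`, `chain`, `seqid`, `icode`
#' @export
getResidue <- function(x, chain, seqid, icode = "") {
  a <- atomRecords(x)
  sel <- a$chain == chain & a$seqid == seqid & a$icode == icode
  if (!any(sel))
    stop("no residue ", residueKeyString(chain, seqid, icode))
  r <- a[sel, , drop = FALSE]
  attr(r, "resname") <- r$resname[1]
  attr(r, "kind") <- r$kind[1]
  attr(r, "chain") <- chain
  attr(r, "seqid") <- seqid
  attr(r, "icode") <- icode
  r
}

#' One-letter sequence of a residue selection
#'
#' Non-protein residues render as `X`.
#'
#' @param set a [ResidueSet]
#' @return single character string
#' @export
residueSequence <- function(set) {
  stopifnot(is(set, "ResidueSet"))
  rt <- residueTable(set@structure)
  key <- residueKeyString(rt$chain, rt$seqid, rt$icode)
  m <- set@members
  want <- residueKeyString(m$chain, m$seqid, m$icode)
  rn <- rt$resname[match(want, key)]
  letters1 <- unname(AA3[rn])
  letters1[is.na(letters1)] <- "X"
  paste(letters1, collapse = "")
}

#' @rdname ProteinStructure-class
#' @export
setMethod("structureId", "ProteinStructure", function(x) x@id)

#' @rdname ProteinStructure-class
#' @export
setMethod("atomRecords", "ProteinStructure", function(x) x@atoms)

#' @rdname ProteinStructure-class
#' @export
setMethod("residueTable", "ProteinStructure", function(x) {
  a <- x@atoms
  key <- residueKeyString(a$chain, a$seqid, a$icode)
  first <- !duplicated(key)
  out <- a[first, c("chain", "seqid", "icode", "resname", "kind")]
  out$natoms <- as.integer(table(key)[key[first]])
  rownames(out) <- NULL
  out
})

setMethod("show", "ProteinStructure", function(object) {
  rt <- residueTable(object)
  cat("ProteinStructure \"", object@id, "\": ",
      nrow(rt), " residues (",
      sum(rt$kind == "protein"), " protein, ",
      sum(rt$kind == "nucleic"), " nucleic), ",
      nrow(object@atoms), " heavy atoms in chain(s) ",
      paste(unique(rt$chain), collapse = ", "), "\n", sep = "")
})

setMethod("show", "ResidueSet", function(object) {
  m <- object@members
  cat("ResidueSet of ", nrow(m), " residue(s) from \"",
      object@structure@id, "\"", sep = "")
  if (nrow(m))
    cat(": ", paste(utils::head(
      residueKeyString(m$chain, m$seqid, m$icode), 8), collapse = " "),
      if (nrow(m) > 8) " ..." else "", sep = "")
  cat("\n")
})

#' @rdname ResidueSet-class
#' @param x a ResidueSet
#' @export
residueMembers <- function(x) {
  stopifnot(is(x, "ResidueSet"))
  x@members
}

setMethod("length", "ResidueSet", function(x) nrow(x@members))
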