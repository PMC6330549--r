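# Typed residue-residue interaction detection across an interface.
# All rules are distance rules on heavy atoms (or group centroids for
# cation-pi); no angular terms.

#' Construct interaction distance cutoffs
#'
#' @param hydrophobic,ionic,cationPi,hbondNO,hbondS,dnaContact cutoffs in
#'   Angstrom; the defaults (5, 6, 6, 3.5, 4, 5) are the standard values
#'   used for histone-fold interface maps
#' @return an [InteractionCutoffs]
#' @export
interactionCutoffs <- function(hydrophobic = 5, ionic = 6, cationPi = 6,
                               hbondNO = 3.5, hbondS = 4, dnaContact = 5) {
  new("InteractionCutoffs", hydrophobic = hydrophobic, ionic = ionic,
      cationPi = cationPi, hbondNO = hbondNO, hbondS = hbondS,
      dnaContact = dnaContact)
}

setMethod("show", "InteractionCutoffs", function(object) {
  cat(sprintf(paste0(
    "InteractionCutoffs (A): hydrophobic %.2f, ionic %.2f, cation-pi %.2f,",
    " hbond %.2f (%.2f with S), DNA %.2f\n"),
    object@hydrophobic, object@ionic, object@cationPi,
    object@hbondNO, object@hbondS, object@dnaContact))
})

.coordMat <- function(df) {
  as.matrix(df[, c("x", "y", "z"), drop = FALSE])
}

# all pairwise distances between two point matrices
.pdist <- function(A, B) {
  if (nrow(A) == 0 || nrow(B) == 0)
    return(matrix(numeric(0), nrow(A), nrow(B)))
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

.minDist <- function(A, B) {
  d <- .pdist(A, B)
  if (length(d) == 0) Inf else min(d)
}

#' Detect typed interactions between two protein residues
#'
#' Applies the four distance rules: a hydrophobic contact when the
#' minimum distance between the residues' side-chain carbon (plus Met
#' SD) atoms is within the hydrophobic cutoff; an ionic contact when
#' one residue is negatively and the other positively charged and
#' their charged-group heavy atoms come within the ionic cutoff; a
#' hydrogen bond when a donor of one residue and an acceptor of the
#' other are within 3.5 A (4.0 A when sulphur is involved, see
#' `sulfurEitherPartner`); a cation-pi interaction when a cation
#' center of one residue and the aromatic ring centroid of the other
#' are within the cation-pi cutoff.  A pair may carry several types at
#' once (e.g. a salt bridge is ionic + hbond); each type records its
#' minimal qualifying distance.
#'
#' @param resA,resB residue atom tables from [getResidue()] (protein)
#' @param cutoffs an [InteractionCutoffs]
#' @param sulfurEitherPartner if `TRUE` (default) the 4.0-A sulphur
#'   cutoff applies when either the donor or the acceptor is sulphur;
#'   if `FALSE` only a sulphur donor widens the cutoff
#' @return data.frame with columns `type` and `distance` (0 rows when
#'   no rule fires)
#' @export
detectContactTypes <- function(resA, resB, cutoffs = interactionCutoffs(),
                               sulfurEitherPartner = TRUE) {
  if (!identical(attr(resA, "kind"), "protein") ||
      !identical(attr(resB, "kind"), "protein"))
    stop("both residues must be protein")
  ga <- chemGroups(resA)
  gb <- chemGroups(resB)
  .typeDistances(ga, gb, cutoffs, sulfurEitherPartner)
}

# core rule evaluation on two precomputed chem-group lists
.typeDistances <- function(ga, gb, cutoffs, sulfurEitherPartner = TRUE) {
  types <- character(0); dists <- numeric(0)

  d <- .minDist(.coordMat(ga$hydrophobic), .coordMat(gb$hydrophobic))
  if (d <= cutoffs@hydrophobic) {
    types <- c(types, "hydrophobic"); dists <- c(dists, d)
  }

  cls <- c(ga$class, gb$class)
  if (setequal(cls, c("negative", "positive"))) {
    d <- .minDist(.coordMat(ga$ionizable), .coordMat(gb$ionizable))
    if (d <= cutoffs@ionic) {
      types <- c(types, "ionic"); dists <- c(dists, d)
    }
  }

  hb <- .hbondMin(ga$donors, gb$acceptors, cutoffs, sulfurEitherPartner)
  hb <- min(hb, .hbondMin(gb$donors, ga$acceptors, cutoffs,
                          sulfurEitherPartner))
  if (is.finite(hb)) {
    types <- c(types, "hbond"); dists <- c(dists, hb)
  }

  cp <- Inf
  if (!is.null(gb$ringCentroid) && nrow(ga$cationCenters))
    cp <- min(cp, .minDist(ga$cationCenters,
                           matrix(gb$ringCentroid, 1, 3,
                                  dimnames = list(NULL, c("x", "y", "z")))))
  if (!is.null(ga$ringCentroid) && nrow(gb$cationCenters))
    cp <- min(cp, .minDist(gb$cationCenters,
                           matrix(ga$ringCentroid, 1, 3,
                                  dimnames = list(NULL, c("x", "y", "z")))))
  if (cp <= cutoffs@cationPi) {
    types <- c(types, "cation_pi"); dists <- c(dists, cp)
  }

  data.frame(type = types, distance = dists, stringsAsFactors = FALSE)
}

# minimal qualifying donor->acceptor distance, honouring the
# element-conditional sulphur cutoff; Inf when nothing qualifies
.hbondMin <- function(donors, acceptors, cutoffs, sulfurEitherPartner) {
  if (nrow(donors) == 0 || nrow(acceptors) == 0) return(Inf)
  d <- .pdist(.coordMat(donors), .coordMat(acceptors))
  sD <- donors$element == "S"
  sA <- acceptors$element == "S"
  lim <- matrix(cutoffs@hbondNO, nrow(donors), nrow(acceptors))
  if (sulfurEitherPartner) {
    lim[sD, ] <- cutoffs@hbondS
    lim[, sA] <- cutoffs@hbondS
  } else {
    lim[sD, ] <- cutoffs@hbondS
  }
  ok <- d <= lim
  if (!any(ok)) return(Inf)
  min(d[ok])
}

#' Build a typed contact map across two residue sets
#'
#' Evaluates every cross-pair of protein residues between two disjoint
#' selections of one structure and records each qualifying interaction
#' type with its minimal qualifying distance.  Non-protein residues in
#' the selections are skipped.  When a DNA selection is supplied, every
#' residue of both sides is flagged if any of its heavy atoms lies
#' within the DNA-contact cutoff of any DNA heavy atom.
#'
#' @param sideA,sideB disjoint [ResidueSet]s of the same structure
#' @param cutoffs an [InteractionCutoffs]
#' @param dna optional [ResidueSet] of nucleic residues (or `NULL`)
#' @param sulfurEitherPartner see [detectContactTypes()]
#' @return a [ContactMap]
#' @examples
#' toy <- makeToyStructure(
#'   list(plantedContact("LYS", "B", 51, "GLU", "C", 10, "ionic", 5.5)),
#'   decoys = 2, seed = 3)
#' s <- readPDB(toy$text)
#' m <- buildContactMap(selectResidues(s, "B"), selectResidues(s, "C"))
#' contacts(m)
#' @export
buildContactMap <- function(sideA, sideB, cutoffs = interactionCutoffs(),
                            dna = NULL, sulfurEitherPartner = TRUE) {
  stopifnot(is(sideA, "ResidueSet"), is(sideB, "ResidueSet"))
  s <- sideA@structure
  if (!identical(structureId(s), structureId(sideB@structure)))
    stop("sides must come from the same structure")
  ka <- residueKeyString(sideA@members$chain, sideA@members$seqid,
                         sideA@members$icode)
  kb <- residueKeyString(sideB@members$chain, sideB@members$seqid,
                         sideB@members$icode)
  if (length(intersect(ka, kb)))
    stop("sides overlap: ", paste(intersect(ka, kb), collapse = ", "))

  rt <- residueTable(s)
  rtKey <- residueKeyString(rt$chain, rt$seqid, rt$icode)
  kindOf <- function(k) rt$kind[match(k, rtKey)]
  resnameOf <- function(k) rt$resname[match(k, rtKey)]

  protA <- sideA@members[kindOf(ka) == "protein", , drop = FALSE]
  protB <- sideB@members[kindOf(kb) == "protein", , drop = FALSE]

  grp <- function(m) {
    lapply(seq_len(nrow(m)), function(i)
      chemGroups(getResidue(s, m$chain[i], m$seqid[i], m$icode[i])))
  }
  gA <- grp(protA); gB <- grp(protB)

  # residue centroids: pairs far beyond any cutoff are skipped outright
  cen <- function(m) {
    t(vapply(seq_len(nrow(m)), function(i) {
      r <- getResidue(s, m$chain[i], m$seqid[i], m$icode[i])
      c(mean(r$x), mean(r$y), mean(r$z))
    }, numeric(3)))
  }
  cenA <- cen(protA); cenB <- cen(protB)
  reach <- max(cutoffs@hydrophobic, cutoffs@ionic, cutoffs@cationPi,
               cutoffs@hbondNO, cutoffs@hbondS) + 24

  rows <- vector("list", nrow(protA) * nrow(protB))
  n <- 0L
  for (i in seq_len(nrow(protA))) {
    for (j in seq_len(nrow(protB))) {
      if (sqrt(sum((cenA[i, ] - cenB[j, ])^2)) > reach) next
      td <- .typeDistances(gA[[i]], gB[[j]], cutoffs, sulfurEitherPartner)
      if (nrow(td)) {
        n <- n + 1L
        rows[[n]] <- data.frame(
          chain_a = protA$chain[i], seq_a = protA$seqid[i],
          icode_a = protA$icode[i],
          resname_a = resnameOf(residueKeyString(protA$chain[i],
                                                 protA$seqid[i],
                                                 protA$icode[i])),
          chain_b = protB$chain[j], seq_b = protB$seqid[j],
          icode_b = protB$icode[j],
          resname_b = resnameOf(residueKeyString(protB$chain[j],
                                                 protB$seqid[j],
                                                 protB$icode[j])),
          type = td$type, distance = td$distance,
          stringsAsFactors = FALSE)
      }
    }
  }
  ct <- if (n) do.call(rbind, rows[seq_len(n)]) else
    data.frame(chain_a = character(0), seq_a = integer(0),
               icode_a = character(0), resname_a = character(0),
               chain_b = character(0), seq_b = integer(0),
               icode_b = character(0), resname_b = character(0),
               type = character(0), distance = numeric(0),
               stringsAsFactors = FALSE)

  dnaXYZ <- NULL
  if (!is.null(dna) && length(dna) > 0) {
    dm <- dna@members
    dk <- residueKeyString(dm$chain, dm$seqid, dm$icode)
    dm <- dm[kindOf(dk) == "nucleic", , drop = FALSE]
    if (nrow(dm)) {
      a <- atomRecords(s)
      aKey <- residueKeyString(a$chain, a$seqid, a$icode)
      dnaXYZ <- .coordMat(a[aKey %in% residueKeyString(dm$chain, dm$seqid,
                                                       dm$icode), ,
                            drop = FALSE])
    }
  }
  flagOne <- function(m, side) {
    if (nrow(m) == 0)
      return(data.frame(chain = character(0), seqid = integer(0),
                        icode = character(0), side = character(0),
                        flag = logical(0), stringsAsFactors = FALSE))
    a <- atomRecords(s)
    aKey <- residueKeyString(a$chain, a$seqid, a$icode)
    fl <- vapply(seq_len(nrow(m)), function(i) {
      if (is.null(dnaXYZ)) return(FALSE)
      xyz <- .coordMat(a[aKey == residueKeyString(m$chain[i], m$seqid[i],
                                                  m$icode[i]), ,
                         drop = FALSE])
      .minDist(xyz, dnaXYZ) <= cutoffs@dnaContact
    }, logical(1))
    data.frame(chain = m$chain, seqid = m$seqid, icode = m$icode,
               side = side, flag = fl, stringsAsFactors = FALSE)
  }
  flags <- rbind(flagOne(sideA@members, "A"), flagOne(sideB@members, "B"))

  new("ContactMap", structureId = structureId(s), contacts = ct,
      sideA = sideA@members, sideB = sideB@members, dnaFlags = flags)
}

#' @rdname ContactMap-class
#' @export
setMethod("contacts", "ContactMap", function(x) x@contacts)

#' @rdname ContactMap-class
#' @export
setMethod("dnaFlags", "ContactMap", function(x) x@dnaFlags)

setMethod("show", "ContactMap", function(object) {
  ct <- object@contacts
  cat("ContactMap on \"", object@structureId, "\": ",
      nrow(object@sideA), " x ", nrow(object@sideB), " residues, ",
      nrow(ct), " typed contact(s)", sep = "")
  if (nrow(ct)) {
    tb <- table(ct$type)
    cat(" (", paste(names(tb), tb, sep = ": ", collapse = ", "), ")",
        sep = "")
  }
  cat("; ", sum(object@dnaFlags$flag), " DNA-proximal residue(s)\n",
      sep = "")
})

#' Summarize the chemical character of an interface
#'
#' For each side of a contact map: how many distinct contacting
#' residues fall in each polarity class, and which fraction of the
#' side's contacts are hydrophobic-type.  A side is labelled
#' "predominantly hydrophobic" when more than half of its contacts are
#' hydrophobic; an empty map yields zero counts and no label.
#'
#' @param map a [ContactMap]
#' @return list with elements `A` and `B`, each a list of
#'   `classCounts` (named integer vector over the six classes),
#'   `hydrophobicFraction`, and `label` (`NA` when not predominantly
#'   hydrophobic or the map is empty)
#' @export
interfaceCharacter <- function(map) {
  stopifnot(is(map, "ContactMap"))
  ct <- contacts(map)
  classes <- c("aliphatic", "negative", "positive", "polar",
               "aromatic", "proline")
  one <- function(chainCol, seqCol, icodeCol, resCol) {
    counts <- stats::setNames(integer(length(classes)), classes)
    frac <- NA_real_; label <- NA_character_
    if (nrow(ct)) {
      u <- !duplicated(paste(ct[[chainCol]], ct[[seqCol]], ct[[icodeCol]]))
      cls <- classifyResidue(ct[[resCol]][u])
      tb <- table(factor(cls, levels = classes))
      counts[names(tb)] <- as.integer(tb)
      frac <- mean(ct$type == "hydrophobic")
      if (frac > 0.5) label <- "predominantly hydrophobic"
    } else frac <- 0
    list(classCounts = counts, hydrophobicFraction = frac, label = label)
  }
  list(A = one("chain_a", "seq_a", "icode_a", "resname_a"),
       B = one("chain_b", "seq_b", "icode_b", "resname_b"))
}

#' Contact map as a flat export table
#'
#' @param map a [ContactMap]
#' @return data.frame with columns `structure_id`, `chain_a`, `seq_a`,
#'   `resname_a`, `chain_b`, `seq_b`, `resname_b`, `type`,
#'   `distance_angstrom`, `dna_flag_a`, `dna_flag_b` (insertion codes
#'   are appended to the residue numbers)
#' @export
contactTable <- function(map) {
  stopifnot(is(map, "ContactMap"))
  ct <- contacts(map)
  fl <- dnaFlags(map)
  fkey <- residueKeyString(fl$chain, fl$seqid, fl$icode)
  flagOf <- function(ch, sq, ic) {
    out <- fl$flag[match(residueKeyString(ch, sq, ic), fkey)]
    out[is.na(out)] <- FALSE
    out
  }
  data.frame(
    structure_id = rep(map@structureId, nrow(ct)),
    chain_a = ct$chain_a, seq_a = paste0(ct$seq_a, ct$icode_a),
    resname_a = ct$resname_a,
    chain_b = ct$chain_b, seq_b = paste0(ct$seq_b, ct$icode_b),
    resname_b = ct$resname_b,
    type = ct$type, distance_angstrom = round(ct$distance, 3),
    dna_flag_a = flagOf(ct$chain_a, ct$seq_a, ct$icode_a),
    dna_flag_b = flagOf(ct$chain_b, ct$seq_b, ct$icode_b),
    stringsAsFactors = FALSE)
}

#' Write a contact map as TSV
#'
#' @param map a [ContactMap]
#' @param file output path
#' @return the table, invisibly
#' @export
writeContactTable <- function(map, file) {
  tab <- contactTable(map)
  tab$distance_angstrom <- sprintf("%.3f", tab$distance_angstrom)
  utils::write.table(tab, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(tab)
}
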