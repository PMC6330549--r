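# Fixture generators: toy multi-chain structures with planted typed
# contacts (plus decoy pairs and an optional DNA stub), FASTA databases
# with planted motifs, and alignment blocks with known consensus.  All
# generators are pure functions of (spec, seed).
#
# Geometry strategy: each residue pair lives in its own 40-A grid cell,
# far outside every cutoff from all other pairs.  Both residues are
# built from idealized side-chain templates, centred on the head group
# that defines the requested interaction type, and separated along x by
# a numerically solved translation so the type-defining group distance
# equals the target within 0.01 A.  A deterministic orientation search
# plus a post-placement audit guarantee that no unintended interaction
# type qualifies within its cutoff plus the margin.

.withSeed <- function(seed, fn) {
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hadSeed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  fn()
}

.rotX <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a),
                              0, -sin(a), cos(a)), 3, 3)
.rotY <- function(a) matrix(c(cos(a), 0, -sin(a), 0, 1, 0,
                              sin(a), 0, cos(a)), 3, 3)
.rotZ <- function(a) matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0,
                              0, 0, 1), 3, 3)

# idealized heavy-atom templates, side chain extending toward +x
.tpl <- function(...) {
  m <- rbind(...)
  data.frame(atom = m[, 1], element = m[, 2],
             x = as.numeric(m[, 3]), y = as.numeric(m[, 4]),
             z = as.numeric(m[, 5]), stringsAsFactors = FALSE)
}

.BB <- rbind(c("N", "N", "0.0", "0.0", "0.0"),
             c("CA", "C", "1.5", "0.0", "0.0"),
             c("C", "C", "2.2", "1.3", "0.0"),
             c("O", "O", "1.7", "2.4", "0.0"))

TEMPLATES <- list(
  GLY = .tpl(.BB),
  ALA = .tpl(.BB, c("CB", "C", "2.3", "-1.3", "0.5")),
  VAL = .tpl(.BB, c("CB", "C", "2.3", "-1.3", "0.4"),
             c("CG1", "C", "3.7", "-1.6", "0.4"),
             c("CG2", "C", "1.9", "-2.5", "1.1")),
  LEU = .tpl(.BB, c("CB", "C", "2.3", "-1.3", "0.4"),
             c("CG", "C", "3.7", "-1.5", "0.4"),
             c("CD1", "C", "4.5", "-0.9", "1.5"),
             c("CD2", "C", "4.5", "-1.5", "-1.0")),
  SER = .tpl(.BB, c("CB", "C", "2.3", "-1.3", "0.4"),
             c("OG", "O", "3.6", "-1.6", "0.4")),
  THR = .tpl(.BB, c("CB", "C", "2.3", "-1.3", "0.4"),
             c("OG1", "O", "3.6", "-1.7", "0.4"),
             c("CG2", "C", "2.0", "-2.6", "1.1")),
  CYS = .tpl(.BB, c("CB", "C", "2.3", "-1.3", "0.4"),
             c("SG", "S", "3.9", "-1.7", "0.4")),
  ASN = .tpl(.BB, c("CB", "C", "2.3", "-1.3", "0.4"),
             c("CG", "C", "3.7", "-1.5", "0.4"),
             c("OD1", "O", "4.4", "-0.6", "1.0"),
             c("ND2", "N", "4.3", "-2.6", "0.0")),
  ASP = .tpl(.BB, c("CB", "C", "2.3", "-1.3", "0.4"),
             c("CG", "C", "3.7", "-1.5", "0.4"),
             c("OD1", "O", "4.4", "-0.6", "1.0"),
             c("OD2", "O", "4.3", "-2.6", "0.0")),
  GLU = .tpl(.BB, c("CB", "C", "2.3", "-1.3", "0.4"),
             c("CG", "C", "3.7", "-1.5", "0.4"),
             c("CD", "C", "5.1", "-1.7", "0.4"),
             c("OE1", "O", "5.8", "-0.8", "0.9"),
             c("OE2", "O", "5.6", "-2.8", "0.0")),
  LYS = .tpl(.BB, c("CB", "C", "2.3", "-1.3", "0.4"),
             c("CG", "C", "3.7", "-1.5", "0.4"),
             c("CD", "C", "5.1", "-1.7", "0.4"),
             c("CE", "C", "6.5", "-1.9", "0.4"),
             c("NZ", "N", "7.9", "-2.1", "0.4")),
  ARG = .tpl(.BB, c("CB", "C", "2.3", "-1.3", "0.4"),
             c("CG", "C", "3.7", "-1.5", "0.4"),
             c("CD", "C", "5.1", "-1.7", "0.4"),
             c("NE", "N", "6.5", "-1.9", "0.4"),
             c("CZ", "C", "7.8", "-2.1", "0.4"),
             c("NH1", "N", "8.5", "-1.3", "1.2"),
             c("NH2", "N", "8.4", "-3.1", "-0.3")),
  MET = .tpl(.BB, c("CB", "C", "2.3", "-1.3", "0.4"),
             c("CG", "C", "3.7", "-1.5", "0.4"),
             c("SD", "S", "5.2", "-1.8", "0.4"),
             c("CE", "C", "6.3", "-0.7", "0.9")),
  PHE = .tpl(.BB, c("CB", "C", "2.3", "-1.3", "0.4"),
             c("CG", "C", "3.7", "-1.5", "0.4"),
             c("CD1", "C", "4.4", "-0.29", "0.4"),
             c("CD2", "C", "4.4", "-2.71", "0.4"),
             c("CE1", "C", "5.8", "-0.29", "0.4"),
             c("CE2", "C", "5.8", "-2.71", "0.4"),
             c("CZ", "C", "6.5", "-1.5", "0.4")),
  TYR = .tpl(.BB, c("CB", "C", "2.3", "-1.3", "0.4"),
             c("CG", "C", "3.7", "-1.5", "0.4"),
             c("CD1", "C", "4.4", "-0.29", "0.4"),
             c("CD2", "C", "4.4", "-2.71", "0.4"),
             c("CE1", "C", "5.8", "-0.29", "0.4"),
             c("CE2", "C", "5.8", "-2.71", "0.4"),
             c("CZ", "C", "6.5", "-1.5", "0.4"),
             c("OH", "O", "7.9", "-1.5", "0.4")),
  HIS = .tpl(.BB, c("CB", "C", "2.3", "-1.3", "0.4"),
             c("CG", "C", "3.7", "-1.5", "0.4"),
             c("ND1", "N", "4.5", "-0.45", "0.4"),
             c("CD2", "C", "4.6", "-2.5", "0.4"),
             c("CE1", "C", "5.8", "-0.85", "0.4"),
             c("NE2", "N", "5.9", "-2.2", "0.4")))

.NUC_TPL <- list(
  DA = .tpl(c("P", "P", "0.0", "0.0", "0.0"),
            c("O5'", "O", "1.5", "0.6", "0.0"),
            c("C5'", "C", "2.7", "-0.2", "0.2"),
            c("C4'", "C", "4.0", "0.3", "0.5"),
            c("N9", "N", "5.2", "-0.5", "0.8"),
            c("C8", "C", "6.3", "0.2", "1.0")),
  DT = .tpl(c("P", "P", "0.0", "0.0", "0.0"),
            c("O5'", "O", "1.5", "0.6", "0.0"),
            c("C5'", "C", "2.7", "-0.2", "0.2"),
            c("C4'", "C", "4.0", "0.3", "0.5"),
            c("N1", "N", "5.2", "-0.5", "0.8"),
            c("C7", "C", "6.3", "0.2", "1.0")),
  DG = .tpl(c("P", "P", "0.0", "0.0", "0.0"),
            c("O5'", "O", "1.5", "0.6", "0.0"),
            c("C5'", "C", "2.7", "-0.2", "0.2"),
            c("C4'", "C", "4.0", "0.3", "0.5"),
            c("N9", "N", "5.2", "-0.5", "0.8"),
            c("O6", "O", "6.3", "0.2", "1.0")),
  DC = .tpl(c("P", "P", "0.0", "0.0", "0.0"),
            c("O5'", "O", "1.5", "0.6", "0.0"),
            c("C5'", "C", "2.7", "-0.2", "0.2"),
            c("C4'", "C", "4.0", "0.3", "0.5"),
            c("N1", "N", "5.2", "-0.5", "0.8"),
            c("O2", "O", "6.3", "0.2", "1.0")))

#' Describe one planted residue pair for [makeToyStructure()]
#'
#' @param resnameA,chainA,seqA first residue (3-letter name, chain,
#'   author number)
#' @param resnameB,chainB,seqB second residue; ignored for type
#'   `"dna_contact"` (the partner is the DNA stub)
#' @param type `hydrophobic`, `ionic`, `hbond`, `cation_pi`, or
#'   `dna_contact`
#' @param distance target distance (A) for the type-defining group;
#'   may be larger than the cutoff to plant a deliberate near-miss
#' @param margin clearance (A) required of every other interaction
#'   type beyond its cutoff (default 0.5)
#' @return a planted-contact spec (list)
#' @export
plantedContact <- function(resnameA, chainA, seqA,
                           resnameB = NA, chainB = NA, seqB = NA,
                           type, distance, margin = 0.5) {
  stopifnot(type %in% c("hydrophobic", "ionic", "hbond", "cation_pi",
                        "dna_contact"),
            distance > 0, margin > 0)
  list(resnameA = toupper(resnameA), chainA = chainA,
       seqA = as.integer(seqA),
       resnameB = if (is.na(resnameB)) NA_character_ else toupper(resnameB),
       chainB = chainB, seqB = if (is.na(seqB)) NA_integer_
       else as.integer(seqB),
       type = type, distance = distance, margin = margin)
}

.mkResDf <- function(resname, chain, seqid, coords) {
  kind <- if (resname %in% names(AA3)) "protein"
          else if (resname %in% NUC3) "nucleic" else "other"
  data.frame(chain = chain, seqid = as.integer(seqid), icode = "",
             resname = resname, kind = kind,
             atom = coords$atom, element = coords$element,
             x = coords$x, y = coords$y, z = coords$z,
             stringsAsFactors = FALSE)
}

.asResidue <- function(df) {
  attr(df, "resname") <- df$resname[1]
  attr(df, "kind") <- df$kind[1]
  attr(df, "chain") <- df$chain[1]
  attr(df, "seqid") <- df$seqid[1]
  attr(df, "icode") <- ""
  df
}

# point sets used by the generator's own audit
.groupPoints <- function(df) {
  g <- suppressWarnings(chemGroups(.asResidue(df)))
  mat <- function(x) {
    m <- .coordMat(x)
    if (!is.null(x$atom)) rownames(m) <- x$atom
    m
  }
  don <- g$donors; acc <- g$acceptors
  list(hydrophobic = mat(g$hydrophobic),
       ionizable = mat(g$ionizable),
       donNO = mat(don[don$element != "S", , drop = FALSE]),
       donS = mat(don[don$element == "S", , drop = FALSE]),
       accNO = mat(acc[acc$element != "S", , drop = FALSE]),
       accS = mat(acc[acc$element == "S", , drop = FALSE]),
       cation = g$cationCenters,
       ring = if (is.null(g$ringCentroid))
         matrix(numeric(0), 0, 3) else matrix(g$ringCentroid, 1, 3),
       all = mat(df), class = g$class)
}

# rigid transform of a group-point list (rotation then translation);
# derived points (centroids) commute with rigid motions
.gpTransform <- function(gp, R = NULL, t = c(0, 0, 0)) {
  for (nm in c("hydrophobic", "ionizable", "donNO", "donS",
               "accNO", "accS", "cation", "ring", "all")) {
    m <- gp[[nm]]
    if (nrow(m)) {
      if (!is.null(R)) m <- m %*% t(R)
      m <- sweep(m, 2, -t)
      gp[[nm]] <- m
    }
  }
  gp
}

# minimal distances of every interaction channel between two residues,
# given their group-point lists
.measureAll <- function(a, b) {
  hb <- function(d1, a1, d2, a2)
    min(.minDist(d1, a1), .minDist(d2, a2))
  list(
    hydrophobic = .minDist(a$hydrophobic, b$hydrophobic),
    ionic = if (setequal(c(a$class, b$class), c("negative", "positive")))
      .minDist(a$ionizable, b$ionizable) else Inf,
    hbondNO = hb(a$donNO, b$accNO, b$donNO, a$accNO),
    hbondS = min(hb(a$donS, b$accNO, b$donS, a$accNO),
                 hb(a$donNO, b$accS, b$donNO, a$accS),
                 hb(a$donS, b$accS, b$donS, a$accS)),
    cationPi = min(.minDist(a$cation, b$ring), .minDist(b$cation, a$ring)))
}

# which channels qualify under the cutoffs, with minimal distances
.qualify <- function(meas, cutoffs) {
  out <- list()
  if (meas$hydrophobic <= cutoffs@hydrophobic)
    out$hydrophobic <- meas$hydrophobic
  if (meas$ionic <= cutoffs@ionic) out$ionic <- meas$ionic
  hb <- Inf
  if (meas$hbondNO <= cutoffs@hbondNO) hb <- meas$hbondNO
  if (meas$hbondS <= cutoffs@hbondS) hb <- min(hb, meas$hbondS)
  if (is.finite(hb)) out$hbond <- hb
  if (meas$cationPi <= cutoffs@cationPi) out$cation_pi <- meas$cationPi
  out
}

# the controlled point sets for a planted type (A side, B side),
# given group-point lists
.controlGroups <- function(a, b, type) {
  switch(type,
    hydrophobic = list(A = a$hydrophobic, B = b$hydrophobic),
    ionic = list(A = a$ionizable, B = b$ionizable),
    hbond = {
      # prefer side-chain donors/acceptors over the backbone so the
      # solved separation controls the intended partner atoms
      scDon <- rbind(a$donNO[rownames(a$donNO) != "N", , drop = FALSE],
                     a$donS)
      dA <- if (nrow(scDon)) scDon else rbind(a$donNO, a$donS)
      scAcc <- rbind(b$accNO[!rownames(b$accNO) %in% c("O", "OXT"), ,
                             drop = FALSE], b$accS)
      aB <- if (nrow(scAcc)) scAcc else rbind(b$accNO, b$accS)
      list(A = dA, B = aB)
    },
    cation_pi = list(A = a$cation, B = b$ring),
    dna_contact = list(A = a$all, B = b$all),
    stop("unknown planted type: ", type))
}

.translate <- function(df, v) {
  df$x <- df$x + v[1]; df$y <- df$y + v[2]; df$z <- df$z + v[3]
  df
}

.rotate <- function(df, R) {
  m <- .coordMat(df) %*% t(R)
  df$x <- m[, 1]; df$y <- m[, 2]; df$z <- m[, 3]
  df
}

# solve the x-separation so the min distance between control groups
# equals target; returns NA when no admissible root exists
.solveSep <- function(PA, PB, target) {
  if (nrow(PA) == 0 || nrow(PB) == 0) return(NA_real_)
  f <- function(t) {
    Bt <- PB; Bt[, 1] <- Bt[, 1] + t
    .minDist(PA, Bt) - target
  }
  grid <- seq(0, 60, by = 0.5)
  fv <- vapply(grid, f, numeric(1))
  # rightmost ascending crossing = the root with the pair pulled apart
  idx <- which(fv[-length(fv)] <= 0 & fv[-1] > 0)
  if (!length(idx)) return(NA_real_)
  i <- max(idx)
  stats::uniroot(f, c(grid[i], grid[i + 1]), tol = 1e-9)$root
}

.ORIENTATIONS <- local({
  out <- list()
  for (ry in c(0, 90, -90, 45, -45, 30, -30)) {
    for (rx in c(0, 60, 120, 180, 240, 300)) {
      out[[length(out) + 1L]] <-
        .rotZ(pi) %*% .rotY(ry * pi / 180) %*% .rotX(rx * pi / 180)
    }
  }
  out
})

# build one planted pair in local coordinates (A head at origin,
# separation along +x); audited so exactly the expected channels fire
.placePair <- function(spec, cutoffs) {
  tplA <- TEMPLATES[[spec$resnameA]]
  tplB <- TEMPLATES[[spec$resnameB]]
  if (is.null(tplA) || is.null(tplB))
    stop("no template for residue ",
         spec$resnameA, "/", spec$resnameB)
  dfA0 <- .mkResDf(spec$resnameA, spec$chainA, spec$seqA, tplA)
  dfB0 <- .mkResDf(spec$resnameB, spec$chainB, spec$seqB, tplB)

  gpA0 <- .groupPoints(dfA0); gpB0 <- .groupPoints(dfB0)
  ctrl0 <- .controlGroups(gpA0, gpB0, spec$type)
  if (nrow(ctrl0$A) == 0 || nrow(ctrl0$B) == 0)
    stop("residues ", spec$resnameA, "/", spec$resnameB,
         " lack the groups for a ", spec$type, " contact")
  headA <- colMeans(ctrl0$A)
  headB <- colMeans(ctrl0$B)
  dfA <- .translate(dfA0, -headA)
  gpA <- .gpTransform(gpA0, t = -headA)
  gpBc <- .gpTransform(gpB0, t = -headB)

  lim <- c(hydrophobic = cutoffs@hydrophobic, ionic = cutoffs@ionic,
           hbondNO = cutoffs@hbondNO, hbondS = cutoffs@hbondS,
           cationPi = cutoffs@cationPi)
  want <- if (spec$type == "hbond") "hbond" else spec$type
  plantedChan <- switch(spec$type,
    hydrophobic = "hydrophobic", ionic = "ionic",
    hbond = c("hbondNO", "hbondS"), cation_pi = "cationPi")
  intendedLim <- switch(spec$type,
    hydrophobic = cutoffs@hydrophobic, ionic = cutoffs@ionic,
    cation_pi = cutoffs@cationPi,
    hbond = if (nrow(gpA0$donS) + nrow(gpB0$accS) +
                nrow(gpB0$donS) + nrow(gpA0$accS) > 0)
      cutoffs@hbondS else cutoffs@hbondNO)
  intentInside <- spec$distance <= intendedLim + 1e-9

  for (R in .ORIENTATIONS) {
    gpBr <- .gpTransform(gpBc, R = R)
    ctrl <- .controlGroups(gpA, gpBr, spec$type)
    sep <- .solveSep(ctrl$A, ctrl$B, spec$distance)
    if (is.na(sep)) next
    gpB <- .gpTransform(gpBr, t = c(sep, 0, 0))

    meas <- .measureAll(gpA, gpB)
    q <- .qualify(meas, cutoffs)
    inside <- want %in% names(q)
    if (inside != intentInside) next
    # every non-planted channel must be clear of its cutoff by margin;
    # for a requested near-miss the planted channel must be clear too
    chanOK <- TRUE
    for (ch in names(lim)) {
      if (inside && ch %in% plantedChan) next
      if (meas[[ch]] < lim[[ch]] + spec$margin) { chanOK <- FALSE; break }
    }
    if (!chanOK) next
    if (inside) {
      if (!identical(names(q), want)) next
      if (abs(q[[want]] - spec$distance) > 0.02) next
    }
    contact <- if (inside)
      data.frame(type = want, distance = q[[want]],
                 stringsAsFactors = FALSE)
    else data.frame(type = character(0), distance = numeric(0),
                    stringsAsFactors = FALSE)
    dfB <- .translate(.rotate(.translate(dfB0, -headB), R),
                      c(sep, 0, 0))
    return(list(A = dfA, B = dfB, contact = contact))
  }
  stop("unsatisfiable planted contact spec: ", spec$resnameA, " ",
       spec$chainA, spec$seqA, " / ", spec$resnameB, " ",
       spec$chainB, spec$seqB, " ", spec$type, " at ",
       spec$distance, " A")
}

#' Generate a toy PDB structure with planted typed contacts
#'
#' Builds one residue pair per planted spec (each pair isolated in its
#' own 40-A grid cell), `decoys` additional residue pairs with every
#' interaction channel at least `margin` outside its cutoff, and
#' optionally a 4-nucleotide DNA stub for DNA-flag tests (`dna_contact`
#' specs place their residue at the target distance from the stub).
#' The same seed always yields byte-identical output.
#'
#' @param specs list of [plantedContact()] specs
#' @param decoys number of decoy residue pairs
#' @param dna add the DNA stub?  Forced `TRUE` when a `dna_contact`
#'   spec is present
#' @param seed integer seed (decoy residue identities)
#' @param cutoffs an [InteractionCutoffs] (geometry is audited against
#'   these)
#' @param decoyChains two chain ids for the decoy pairs
#' @param margin decoy clearance beyond each cutoff (A)
#' @return list: `text` (PDB file content, one string), `structure`
#'   (the assembled [ProteinStructure]), `truth` (list of `contacts` —
#'   the expected typed-contact table — and `dnaFlags` — expected
#'   per-protein-residue DNA proximity)
#' @export
makeToyStructure <- function(specs, decoys = 0, dna = FALSE, seed = 1,
                             cutoffs = interactionCutoffs(),
                             decoyChains = c("B", "C"), margin = 0.5) {
  .withSeed(seed, function() {
    isDna <- if (length(specs))
      vapply(specs, function(s) s$type == "dna_contact", logical(1))
    else logical(0)
    if (any(isDna)) dna <- TRUE

    pool <- c("ALA", "LEU", "VAL", "SER", "THR", "ASN", "GLY",
              "LYS", "GLU", "ASP", "ARG", "PHE", "TYR", "HIS", "MET")
    decoySpecs <- if (decoys > 0) lapply(seq_len(decoys), function(i) {
      plantedContact(sample(pool, 1), decoyChains[1], 900L + i,
                     sample(pool, 1), decoyChains[2], 950L + i,
                     type = "hydrophobic",
                     distance = cutoffs@hydrophobic, margin = margin)
    }) else list()

    cellAt <- function(i) c(40 * ((i - 1) %% 5), 40 * ((i - 1) %/% 5), 0)
    allRes <- list()
    truthRows <- list()
    cell <- 0L

    addPair <- function(dfA, dfB, center) {
      mid <- (colMeans(.coordMat(dfA)) + colMeans(.coordMat(dfB))) / 2
      list(.translate(dfA, center - mid), .translate(dfB, center - mid))
    }

    for (s in specs[!isDna]) {
      cell <- cell + 1L
      pl <- .placePair(s, cutoffs)
      pr <- addPair(pl$A, pl$B, cellAt(cell))
      allRes <- c(allRes, pr)
      if (nrow(pl$contact))
        truthRows[[length(truthRows) + 1L]] <- data.frame(
          chain_a = s$chainA, seq_a = s$seqA, resname_a = s$resnameA,
          chain_b = s$chainB, seq_b = s$seqB, resname_b = s$resnameB,
          type = pl$contact$type, distance = pl$contact$distance,
          stringsAsFactors = FALSE)
    }

    for (s in decoySpecs) {
      cell <- cell + 1L
      pl <- .placeDecoy(s, cutoffs, margin)
      pr <- addPair(pl$A, pl$B, cellAt(cell))
      allRes <- c(allRes, pr)
    }

    dnaDfs <- list()
    dnaTruth <- list()
    if (dna) {
      cell <- cell + 1L
      stubCenter <- cellAt(cell)
      nts <- c("DA", "DT", "DG", "DC")
      for (k in seq_along(nts)) {
        df <- .mkResDf(nts[k], "D", k, .NUC_TPL[[nts[k]]])
        dnaDfs[[k]] <- .translate(df, stubCenter + c(0, 0, 3.4 * (k - 1)))
      }
      stubXYZ <- do.call(rbind, lapply(dnaDfs, .coordMat))
      for (s in specs[isDna]) {
        tpl <- TEMPLATES[[s$resnameA]]
        if (is.null(tpl)) stop("no template for ", s$resnameA)
        df <- .mkResDf(s$resnameA, s$chainA, s$seqA, tpl)
        df <- .translate(df, -colMeans(.coordMat(df)))
        PA <- stubXYZ
        # approach the stub from +x
        f <- function(t) {
          dft <- .translate(df, stubCenter + c(t, 0, 0))
          .minDist(.coordMat(dft), PA) - s$distance
        }
        grid <- seq(0, 60, 0.5)
        fv <- vapply(grid, f, numeric(1))
        idx <- which(fv[-length(fv)] <= 0 & fv[-1] > 0)
        if (!length(idx))
          stop("unsatisfiable dna_contact spec for ", s$resnameA)
        t0 <- stats::uniroot(f, c(grid[max(idx)], grid[max(idx) + 1]),
                             tol = 1e-9)$root
        allRes <- c(allRes, list(.translate(df, stubCenter + c(t0, 0, 0))))
      }
    }

    resKeys <- vapply(c(allRes, dnaDfs), function(d)
      paste(d$chain[1], d$seqid[1]), character(1))
    if (anyDuplicated(resKeys))
      stop("duplicate residue ids across specs: ",
           paste(unique(resKeys[duplicated(resKeys)]), collapse = ", "))
    atoms <- do.call(rbind, c(allRes, dnaDfs))
    chlev <- sort(unique(atoms$chain))
    atoms <- atoms[order(match(atoms$chain, chlev), atoms$seqid), ,
                   drop = FALSE]
    atoms$x <- round(atoms$x, 3)
    atoms$y <- round(atoms$y, 3)
    atoms$z <- round(atoms$z, 3)
    rownames(atoms) <- NULL
    struct <- new("ProteinStructure", id = "toy", atoms = atoms)

    truth <- if (length(truthRows)) do.call(rbind, truthRows) else
      data.frame(chain_a = character(0), seq_a = integer(0),
                 resname_a = character(0), chain_b = character(0),
                 seq_b = integer(0), resname_b = character(0),
                 type = character(0), distance = numeric(0),
                 stringsAsFactors = FALSE)

    prot <- atoms[atoms$kind == "protein", c("chain", "seqid")]
    prot <- unique(prot)
    dnaFlagTruth <- data.frame(
      chain = prot$chain, seqid = prot$seqid,
      flag = vapply(seq_len(nrow(prot)), function(i) {
        any(isDna & vapply(specs, function(s)
          s$type == "dna_contact" && s$chainA == prot$chain[i] &&
          s$seqA == prot$seqid[i] &&
          s$distance <= cutoffs@dnaContact, logical(1)))
      }, logical(1)), stringsAsFactors = FALSE)

    list(text = paste(writePDB(struct), collapse = "\n"),
         structure = struct,
         truth = list(contacts = truth, dnaFlags = dnaFlagTruth))
  })
}

# decoy pair: both residues well outside every cutoff
.placeDecoy <- function(spec, cutoffs, margin) {
  tplA <- TEMPLATES[[spec$resnameA]]
  tplB <- TEMPLATES[[spec$resnameB]]
  dfA <- .mkResDf(spec$resnameA, spec$chainA, spec$seqA, tplA)
  dfB <- .mkResDf(spec$resnameB, spec$chainB, spec$seqB, tplB)
  dfA <- .translate(dfA, -colMeans(.coordMat(dfA)))
  dfB <- .rotate(.translate(dfB, -colMeans(.coordMat(dfB))), .rotZ(pi))
  gpA <- .groupPoints(dfA)
  gpB <- .groupPoints(dfB)
  lim <- c(cutoffs@hydrophobic, cutoffs@ionic, cutoffs@hbondNO,
           cutoffs@hbondS, cutoffs@cationPi)
  for (t in seq(max(lim) + margin + 4, 30, by = 1)) {
    dfBt <- .translate(dfB, c(t, 0, 0))
    meas <- .measureAll(gpA, .gpTransform(gpB, t = c(t, 0, 0)))
    clear <- meas$hydrophobic >= cutoffs@hydrophobic + margin &&
      meas$ionic >= cutoffs@ionic + margin &&
      meas$hbondNO >= cutoffs@hbondNO + margin &&
      meas$hbondS >= cutoffs@hbondS + margin &&
      meas$cationPi >= cutoffs@cationPi + margin
    if (clear) return(list(A = dfA, B = dfBt))
  }
  stop("could not place decoy pair clear of all cutoffs")
}

#' Generate a FASTA database with planted motifs
#'
#' Draws uniform random background sequences, overwrites planted
#' pattern realizations at recorded positions, and re-draws any
#' background window that accidentally matches a planted or exclusion
#' pattern, so the truth table is exact.  Records carrying each planted
#' pattern are disjoint; `exclusionTagged` of the first pattern's
#' carriers additionally receive the exclusion motif.
#'
#' @param nRecords number of records
#' @param planted list of `list(pattern=, count=)`; `pattern` may be a
#'   [ConsensusPattern] or a pattern string
#' @param exclusionTagged how many carriers of the first planted
#'   pattern also get the exclusion motif
#' @param exclusionPattern pattern (or string) for the exclusion motif;
#'   required when `exclusionTagged > 0`
#' @param lengthRange `c(min, max)` record lengths
#' @param seed integer seed
#' @return list: `text` (FASTA content, one string, 60-column wrap),
#'   `truth` (data.frame `record_id`, `pattern_text`, `start`, `role`)
#' @export
makeMotifDb <- function(nRecords, planted = list(), exclusionTagged = 0,
                        exclusionPattern = NULL,
                        lengthRange = c(60, 80), seed = 1) {
  asPat <- function(p) if (is(p, "ConsensusPattern")) p else parsePattern(p)
  planted <- lapply(planted, function(p)
    list(pattern = asPat(p$pattern), count = p$count))
  if (exclusionTagged > 0) {
    if (is.null(exclusionPattern))
      stop("exclusionPattern required when exclusionTagged > 0")
    exclusionPattern <- asPat(exclusionPattern)
  }
  total <- sum(vapply(planted, `[[`, numeric(1), "count"))
  if (length(planted) && total > nRecords)
    stop("impossible planting: ", total, " carriers > ", nRecords,
         " records")
  maxLen <- max(c(0, vapply(planted, function(p)
    length(p$pattern), integer(1)),
    if (!is.null(exclusionPattern)) length(exclusionPattern) else 0L))
  if (maxLen > lengthRange[1])
    stop("pattern longer than the minimum record length")

  .withSeed(seed, function() {
    lens <- sample(seq(lengthRange[1], lengthRange[2]), nRecords,
                   replace = TRUE)
    seqs <- vapply(lens, function(L)
      paste(sample(AA1, L, replace = TRUE), collapse = ""),
      character(1))
    ids <- sprintf("synrec%02d", seq_len(nRecords))
    names(seqs) <- ids

    realize <- function(pat) {
      paste(vapply(pat@positions, function(s) {
        if (length(s) == 1 && is.na(s)) sample(AA1, 1) else sample(s, 1)[1]
      }, character(1)), collapse = "")
    }

    perm <- sample(nRecords)
    truth <- list()
    plantedWin <- lapply(seq_len(nRecords), function(i) integer(0))
    cursor <- 0L
    plant <- function(i, pat, role) {
      L <- length(pat)
      n <- nchar(seqs[[i]])
      starts <- setdiff(seq_len(n - L + 1), unlist(lapply(
        plantedWin[[i]], function(p) (p - L + 1):(p + L - 1))))
      starts <- starts[starts >= 1]
      if (!length(starts)) stop("no room to plant in record ", ids[i])
      st <- sample(starts, 1)
      substr(seqs[[i]], st, st + L - 1) <<- realize(pat)
      plantedWin[[i]] <<- c(plantedWin[[i]], st:(st + L - 1))
      truth[[length(truth) + 1L]] <<- data.frame(
        record_id = ids[i], pattern_text = patternText(pat),
        start = st, role = role, stringsAsFactors = FALSE)
      st
    }
    carriers1 <- integer(0)
    for (k in seq_along(planted)) {
      cnt <- planted[[k]]$count
      if (cnt == 0) next
      recs <- perm[(cursor + 1):(cursor + cnt)]
      cursor <- cursor + cnt
      if (k == 1) carriers1 <- recs
      for (i in recs) plant(i, planted[[k]]$pattern, "query")
    }
    if (exclusionTagged > 0) {
      recs <- if (length(carriers1)) carriers1[seq_len(exclusionTagged)]
              else perm[seq_len(exclusionTagged)]
      for (i in recs) plant(i, exclusionPattern, "exclusion")
    }

    truthDf <- if (length(truth)) do.call(rbind, truth) else
      data.frame(record_id = character(0), pattern_text = character(0),
                 start = integer(0), role = character(0),
                 stringsAsFactors = FALSE)

    # scrub accidental background matches so the truth table is exact
    pats <- c(lapply(planted, `[[`, "pattern"),
              if (!is.null(exclusionPattern)) list(exclusionPattern))
    for (iter in seq_len(200)) {
      dirty <- FALSE
      for (p in pats) {
        for (i in seq_len(nRecords)) {
          hits <- scanSequence(p, seqs[[i]], ids[i])
          exp <- truthDf$start[truthDf$record_id == ids[i] &
                               truthDf$pattern_text == patternText(p)]
          bad <- setdiff(hits$start, exp)
          for (st in bad) {
            win <- st:(st + length(p) - 1)
            free <- setdiff(win, plantedWin[[i]])
            if (!length(free))
              stop("cannot scrub accidental match in ", ids[i])
            for (pos in free)
              substr(seqs[[i]], pos, pos) <- sample(AA1, 1)
            dirty <- TRUE
          }
        }
      }
      if (!dirty) break
      if (iter == 200) stop("failed to scrub accidental matches")
    }

    wrap <- function(s) {
      n <- nchar(s)
      starts <- seq(1, n, 60)
      paste(vapply(starts, function(a)
        substr(s, a, min(a + 59, n)), character(1)), collapse = "\n")
    }
    fasta <- paste(vapply(seq_len(nRecords), function(i)
      paste0(">", ids[i], "\n", wrap(seqs[[i]])), character(1)),
      collapse = "\n")
    list(text = fasta, truth = truthDf)
  })
}

#' Generate an alignment block whose consensus is known
#'
#' Samples each column from the pattern's allowed set (wildcards are
#' uniform over the 20 letters), making sure every member of every
#' alternative set is witnessed by at least one row.
#'
#' @param pattern a [ConsensusPattern] (or string)
#' @param nRows number of rows (must be >= the largest set size)
#' @param seed integer seed
#' @param maxAlternatives the consensus rule's set-size limit
#' @return list: `block` (an [AlignmentBlock]), `expected` (the pattern
#'   [deriveConsensus()] should recover, built from the realized
#'   column sets)
#' @export
makeAlignmentBlock <- function(pattern, nRows, seed = 1,
                               maxAlternatives = 3) {
  if (!is(pattern, "ConsensusPattern")) pattern <- parsePattern(pattern)
  if (nRows < 2) stop("need >= 2 rows")
  maxSet <- max(vapply(pattern@positions, function(s)
    if (length(s) == 1 && is.na(s)) 1L else length(s), integer(1)))
  if (nRows < maxSet)
    stop("nRows too small to witness a set of size ", maxSet)
  .withSeed(seed, function() {
    L <- length(pattern@positions)
    mat <- matrix("", nRows, L)
    for (j in seq_len(L)) {
      s <- pattern@positions[[j]]
      if (length(s) == 1 && is.na(s)) {
        mat[, j] <- sample(AA1, nRows, replace = TRUE)
      } else {
        col <- c(sample(s), sample(s, nRows - length(s), replace = TRUE))
        mat[, j] <- sample(col)       # shuffle witness positions
      }
    }
    rows <- apply(mat, 1, paste, collapse = "")
    realized <- lapply(seq_len(L), function(j) {
      tb <- sort(table(mat[, j]), decreasing = TRUE)
      lv <- names(tb)[order(-as.integer(tb), names(tb))]
      if (length(lv) <= maxAlternatives) lv else NA_character_
    })
    list(block = alignmentBlock(rows,
                                sourceIds = paste0("sim", seq_len(nRows))),
         expected = newPattern(realized))
  })
}

#' Paired synthetic complexes with overlapping planted truth
#'
#' Emulates two crystal forms of the same histone-fold complex: two
#' structures sharing chain/residue numbering (chain B donor segments
#' 51-57 and 62-70, chain C partner residues, a DNA stub in the first
#' structure), with planted contacts that are partly shared and partly
#' specific to one structure, so comparative maps and binding-site
#' transfer can be validated against an exact truth table.  The two
#' donor segments pair with the 7- and 9-residue candidate peptides of
#' the QQS analysis (QQS-5-11 `REQEIYV`, QQS-41-49 `VARLKMRVI`).
#'
#' @param seed integer seed (decoy placement)
#' @return list: `a`, `b` ([makeToyStructure()] results), `segments`
#'   (spans on chain B), `peptides` (id, seq, parent_start), and
#'   `membership` — the expected both/a_only/b_only label per planted
#'   donor residue
#' @export
makePairedComplex <- function(seed = 1) {
  near <- function(...) plantedContact(..., margin = 0.3)
  segA <- list(
    plantedContact("ARG", "B", 51, "ASP", "C", 10, "ionic", 5.0),
    plantedContact("GLU", "B", 52, "LYS", "C", 11, "ionic", 5.5),
    plantedContact("SER", "B", 53, "ASP", "C", 12, "hbond", 3.2),
    plantedContact("LEU", "B", 54, "LEU", "C", 13, "hydrophobic", 4.5),
    near("VAL", "B", 55, "ALA", "C", 14, type = "hydrophobic",
         distance = 5.8),
    plantedContact("LYS", "B", 56, "PHE", "C", 15, "cation_pi", 5.0),
    plantedContact("THR", "B", 57, "GLU", "C", 16, "hbond", 3.4),
    plantedContact("VAL", "B", 62, "LEU", "C", 30, "hydrophobic", 4.3),
    plantedContact("ALA", "B", 63, "VAL", "C", 31, "hydrophobic", 4.6),
    plantedContact("ARG", "B", 64, "GLU", "C", 32, "ionic", 5.2),
    plantedContact("LEU", "B", 65, "LEU", "C", 33, "hydrophobic", 4.8),
    plantedContact("LYS", "B", 66, "ASP", "C", 34, "ionic", 5.8),
    plantedContact("MET", "B", 67, "LEU", "C", 35, "hydrophobic", 4.4),
    plantedContact("ARG", "B", 68, "PHE", "C", 36, "cation_pi", 5.5),
    near("VAL", "B", 69, "VAL", "C", 37, type = "hydrophobic",
         distance = 5.6),
    plantedContact("LEU", "B", 70, "ALA", "C", 38, "hydrophobic", 4.7),
    plantedContact("SER", "C", 40, type = "dna_contact", distance = 4.0))
  segB <- list(
    plantedContact("ARG", "B", 51, "ASP", "C", 10, "ionic", 5.0),
    plantedContact("GLU", "B", 52, "LYS", "C", 11, "ionic", 5.5),
    plantedContact("SER", "B", 53, "ASP", "C", 12, "hbond", 3.2),
    plantedContact("LEU", "B", 54, "LEU", "C", 13, "hydrophobic", 4.5),
    plantedContact("VAL", "B", 55, "ALA", "C", 14, "hydrophobic", 4.2),
    plantedContact("LYS", "B", 56, "PHE", "C", 15, "cation_pi", 5.0),
    near("THR", "B", 57, "GLU", "C", 16, type = "hbond", distance = 4.6),
    plantedContact("VAL", "B", 62, "LEU", "C", 30, "hydrophobic", 4.3),
    plantedContact("ALA", "B", 63, "VAL", "C", 31, "hydrophobic", 4.6),
    plantedContact("ARG", "B", 64, "GLU", "C", 32, "ionic", 5.2),
    plantedContact("LEU", "B", 65, "LEU", "C", 33, "hydrophobic", 4.8),
    plantedContact("LYS", "B", 66, "ASP", "C", 34, "ionic", 5.8),
    plantedContact("MET", "B", 67, "LEU", "C", 35, "hydrophobic", 4.4),
    near("ARG", "B", 68, "PHE", "C", 36, type = "cation_pi",
         distance = 6.8),
    plantedContact("VAL", "B", 69, "VAL", "C", 37, "hydrophobic", 4.1),
    plantedContact("LEU", "B", 70, "ALA", "C", 38, "hydrophobic", 4.7),
    plantedContact("SER", "C", 40, type = "dna_contact", distance = 8.0))
  membership <- data.frame(
    seq_b_res = c(51:57, 62:70),
    membership = c("both", "both", "both", "both", "b_only", "both",
                   "a_only", "both", "both", "both", "both", "both",
                   "both", "a_only", "b_only", "both"),
    stringsAsFactors = FALSE)
  list(
    a = makeToyStructure(segA, decoys = 4, dna = TRUE, seed = seed),
    b = makeToyStructure(segB, decoys = 4, dna = TRUE,
                         seed = seed + 1000L),
    segments = list(c(51, 57), c(62, 70)),
    peptides = list(
      list(id = "QQS-5-11", seq = "REQEIYV", parent_start = 5L),
      list(id = "QQS-41-49", seq = "VARLKMRVI", parent_start = 41L)),
    membership = membership)
}
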