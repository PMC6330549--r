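# Independent brute-force implementation of the interaction rules,
# written as literal loops over atom pairs with its own chemistry
# tables.  Used to cross-check buildContactMap.

.orc_class <- c(G = "aliphatic", A = "aliphatic", V = "aliphatic",
                L = "aliphatic", I = "aliphatic", M = "aliphatic",
                D = "negative", E = "negative",
                K = "positive", R = "positive", H = "positive",
                S = "polar", T = "polar", N = "polar", Q = "polar",
                C = "polar", F = "aromatic", W = "aromatic",
                Y = "aromatic", P = "proline")
.orc_one <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
              GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
              LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
              SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
.orc_don <- list(SER = "OG", THR = "OG1", CYS = "SG", TYR = "OH",
                 ASN = "ND2", GLN = "NE2", LYS = "NZ",
                 ARG = c("NE", "NH1", "NH2"), HIS = c("ND1", "NE2"),
                 TRP = "NE1")
.orc_acc <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
                 ASN = "OD1", GLN = "OE1", SER = "OG", THR = "OG1",
                 TYR = "OH", HIS = c("ND1", "NE2"), MET = "SD",
                 CYS = "SG")
.orc_ion <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
                 LYS = "NZ", ARG = c("NE", "CZ", "NH1", "NH2"),
                 HIS = c("ND1", "NE2"))
.orc_ring <- list(PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
                  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
                  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
                  TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3",
                          "CZ2", "CZ3", "CH2"))

.orc_d <- function(p, q) sqrt(sum((p - q)^2))

.orc_xyz <- function(res, names) {
  res[res$atom %in% names, c("x", "y", "z"), drop = FALSE]
}

# all typed contacts between two residue atom tables, literal rules
oracle_pair <- function(ra, rb, co = list(hydrophobic = 5, ionic = 6,
                                          cation_pi = 6, hb_no = 3.5,
                                          hb_s = 4)) {
  out <- data.frame(type = character(0), distance = numeric(0))
  na <- ra$resname[1]; nb <- rb$resname[1]
  bb <- c("N", "CA", "C", "O", "OXT")

  hyd <- function(r) {
    sc <- r[!(r$atom %in% bb), , drop = FALSE]
    sc <- sc[sc$element == "C" | (r$resname[1] == "MET" & sc$atom == "SD"),
             , drop = FALSE]
    sc
  }
  best <- Inf
  ha <- hyd(ra); hb_ <- hyd(rb)
  for (i in seq_len(nrow(ha))) for (j in seq_len(nrow(hb_))) {
    d <- .orc_d(as.numeric(ha[i, c("x", "y", "z")]),
                as.numeric(hb_[j, c("x", "y", "z")]))
    if (d < best) best <- d
  }
  if (best <= co$hydrophobic)
    out <- rbind(out, data.frame(type = "hydrophobic", distance = best))

  ca <- .orc_class[.orc_one[na]]; cb <- .orc_class[.orc_one[nb]]
  if (setequal(c(ca, cb), c("negative", "positive"))) {
    ia <- .orc_xyz(ra, .orc_ion[[na]]); ib <- .orc_xyz(rb, .orc_ion[[nb]])
    best <- Inf
    for (i in seq_len(nrow(ia))) for (j in seq_len(nrow(ib))) {
      d <- .orc_d(as.numeric(ia[i, ]), as.numeric(ib[j, ]))
      if (d < best) best <- d
    }
    if (best <= co$ionic)
      out <- rbind(out, data.frame(type = "ionic", distance = best))
  }

  donors <- function(r, n) r[r$atom %in% c("N", .orc_don[[n]]), ,
                             drop = FALSE]
  accs <- function(r, n) r[r$atom %in% c("O", "OXT", .orc_acc[[n]]), ,
                           drop = FALSE]
  best <- Inf
  for (dir in 1:2) {
    dn <- if (dir == 1) donors(ra, na) else donors(rb, nb)
    ac <- if (dir == 1) accs(rb, nb) else accs(ra, na)
    for (i in seq_len(nrow(dn))) for (j in seq_len(nrow(ac))) {
      d <- .orc_d(as.numeric(dn[i, c("x", "y", "z")]),
                  as.numeric(ac[j, c("x", "y", "z")]))
      lim <- if (dn$element[i] == "S" || ac$element[j] == "S")
        co$hb_s else co$hb_no
      if (d <= lim && d < best) best <- d
    }
  }
  if (is.finite(best))
    out <- rbind(out, data.frame(type = "hbond", distance = best))

  cat_pts <- function(r, n) {
    pts <- list()
    if (n == "LYS") {
      m <- .orc_xyz(r, "NZ"); if (nrow(m)) pts <- c(pts, list(colMeans(m)))
    } else if (n == "ARG") {
      m <- .orc_xyz(r, c("NE", "CZ", "NH1", "NH2"))
      if (nrow(m)) pts <- c(pts, list(colMeans(m)))
    } else if (n == "HIS") {
      m <- .orc_xyz(r, .orc_ring[["HIS"]])
      if (nrow(m)) pts <- c(pts, list(colMeans(m)))
    }
    pts
  }
  ring_pt <- function(r, n) {
    if (is.null(.orc_ring[[n]])) return(NULL)
    m <- .orc_xyz(r, .orc_ring[[n]])
    if (nrow(m)) colMeans(m) else NULL
  }
  best <- Inf
  for (dir in 1:2) {
    cats <- if (dir == 1) cat_pts(ra, na) else cat_pts(rb, nb)
    ring <- if (dir == 1) ring_pt(rb, nb) else ring_pt(ra, na)
    if (is.null(ring)) next
    for (p in cats) {
      d <- .orc_d(p, ring)
      if (d < best) best <- d
    }
  }
  if (best <= co$cation_pi)
    out <- rbind(out, data.frame(type = "cation_pi", distance = best))
  out
}

# full brute-force contact map over two residue sets of a structure
oracle_map <- function(struct, sideA, sideB) {
  at <- atomRecords(struct)
  getres <- function(m, i)
    at[at$chain == m$chain[i] & at$seqid == m$seqid[i] &
       at$icode == m$icode[i], , drop = FALSE]
  mA <- residueMembers(sideA); mB <- residueMembers(sideB)
  rows <- list()
  for (i in seq_len(nrow(mA))) {
    ra <- getres(mA, i)
    if (ra$kind[1] != "protein") next
    for (j in seq_len(nrow(mB))) {
      rb <- getres(mB, j)
      if (rb$kind[1] != "protein") next
      hits <- oracle_pair(ra, rb)
      if (nrow(hits))
        rows[[length(rows) + 1L]] <- data.frame(
          chain_a = mA$chain[i], seq_a = mA$seqid[i],
          chain_b = mB$chain[j], seq_b = mB$seqid[j],
          type = hits$type, distance = hits$distance,
          stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(chain_a = character(0), seq_a = integer(0),
               chain_b = character(0), seq_b = integer(0),
               type = character(0), distance = numeric(0))
}

# canonical sortable key set for comparing contact tables
contact_keys <- function(df) {
  if (!nrow(df)) return(character(0))
  sort(paste(df$chain_a, df$seq_a, df$chain_b, df$seq_b, df$type,
             round(df$distance, 2)))
}

# random toy structure with jitter: varied geometry for oracle checks
random_jittered_structure <- function(seed) {
  combos <- list(
    list("LEU", "LEU", "hydrophobic", 5.0),
    list("VAL", "ALA", "hydrophobic", 5.0),
    list("MET", "LEU", "hydrophobic", 5.0),
    list("LYS", "GLU", "ionic", 6.0),
    list("ARG", "ASP", "ionic", 6.0),
    list("HIS", "GLU", "ionic", 6.0),
    list("SER", "ASP", "hbond", 3.5),
    list("THR", "GLU", "hbond", 3.5),
    list("TYR", "ASP", "hbond", 3.5),
    list("LYS", "PHE", "cation_pi", 6.0),
    list("ARG", "TYR", "cation_pi", 6.0))
  set.seed(seed)
  n <- sample(3:6, 1)
  picks <- sample(length(combos), n, replace = TRUE)
  specs <- lapply(seq_len(n), function(k) {
    cb <- combos[[picks[k]]]
    plantedContact(cb[[1]], "B", 50 + k, cb[[2]], "C", 10 + k,
                   type = cb[[3]],
                   distance = cb[[4]] + runif(1, -1.5, 1.2),
                   margin = 0.1)
  })
  toy <- tryCatch(
    makeToyStructure(specs, decoys = 2, seed = seed),
    error = function(e) NULL)
  if (is.null(toy)) return(NULL)
  at <- atomRecords(toy$structure)
  at$x <- round(at$x + runif(nrow(at), -0.4, 0.4), 3)
  at$y <- round(at$y + runif(nrow(at), -0.4, 0.4), 3)
  at$z <- round(at$z + runif(nrow(at), -0.4, 0.4), 3)
  new("ProteinStructure", id = paste0("rand", seed), atoms = at)
}
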