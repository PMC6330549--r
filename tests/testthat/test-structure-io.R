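test_that("a one-residue glycine file parses to one protein residue", {
  lines <- gly_chain_lines("A", 1)
  s <- readPDB(lines, id = "mini")
  rt <- residueTable(s)
  expect_equal(nrow(rt), 1)
  expect_equal(rt$kind, "protein")
  expect_equal(rt$resname, "GLY")
  expect_equal(rt$natoms, 4L)
  expect_setequal(atomRecords(s)$atom, c("N", "CA", "C", "O"))
})

test_that("protein and nucleotide chains get the right residue kinds", {
  toy <- makeToyStructure(
    list(plantedContact("LEU", "A", 1, "LEU", "B", 1,
                        type = "hydrophobic", distance = 4.5)),
    decoys = 0, dna = TRUE, seed = 2)
  s <- readPDB(toy$text)
  rt <- residueTable(s)
  expect_setequal(rt$kind[rt$chain %in% c("A", "B")], "protein")
  expect_setequal(rt$kind[rt$chain == "D"], "nucleic")
  expect_setequal(rt$resname[rt$chain == "D"], c("DA", "DT", "DG", "DC"))
})

test_that("MSE maps to MET and unknown HETATM residues become other", {
  lines <- c(
    pdb_line("HETATM", 1, "N", "MSE", "A", 1, 0, 0, 0),
    pdb_line("HETATM", 2, "CA", "MSE", "A", 1, 1.5, 0, 0),
    pdb_line("HETATM", 3, "SE", "MSE", "A", 1, 3, 0, 0, element = "SE"),
    pdb_line("HETATM", 4, "C1", "LIG", "A", 2, 20, 0, 0),
    pdb_line("ATOM", 5, "O", "HOH", "W", 1, 40, 0, 0))
  s <- readPDB(lines)
  rt <- residueTable(s)
  expect_equal(rt$resname[rt$seqid == 1], "MET")
  expect_equal(rt$kind[rt$seqid == 1], "protein")
  expect_equal(rt$kind[rt$seqid == 2], "other")
  expect_false("HOH" %in% rt$resname)   # waters dropped
})

test_that("altloc keeps the highest-occupancy conformer, first on ties", {
  base <- function(occA, occB) c(
    pdb_line(serial = 1, name = "N", resname = "SER", chain = "A",
             seqid = 1, x = 0, y = 0, z = 0),
    pdb_line(serial = 2, name = "CA", resname = "SER", chain = "A",
             seqid = 1, x = 1.5, y = 0, z = 0),
    pdb_line(serial = 3, name = "OG", resname = "SER", chain = "A",
             seqid = 1, x = 3, y = 0, z = 0, occ = occA, altloc = "A"),
    pdb_line(serial = 4, name = "OG", resname = "SER", chain = "A",
             seqid = 1, x = 4, y = 0, z = 0, occ = occB, altloc = "B"))
  s <- readPDB(base(0.6, 0.4))
  og <- atomRecords(s)[atomRecords(s)$atom == "OG", ]
  expect_equal(nrow(og), 1)
  expect_equal(og$x, 3)               # altloc A (occ 0.6) retained
  s2 <- readPDB(base(0.5, 0.5))
  og2 <- atomRecords(s2)[atomRecords(s2)$atom == "OG", ]
  expect_equal(og2$x, 3)              # tie: first seen wins
})

test_that("hydrogens are dropped and elements inferred from names", {
  lines <- c(
    pdb_line(serial = 1, name = "N", resname = "GLY", chain = "A",
             seqid = 1, x = 0, y = 0, z = 0),
    pdb_line(serial = 2, name = "CA", resname = "GLY", chain = "A",
             seqid = 1, x = 1.5, y = 0, z = 0),
    pdb_line(serial = 3, name = "H", resname = "GLY", chain = "A",
             seqid = 1, x = 0.5, y = 1, z = 0),
    pdb_line(serial = 4, name = "1HA", resname = "GLY", chain = "A",
             seqid = 1, x = 2, y = 1, z = 0))
  s <- readPDB(lines)
  expect_setequal(atomRecords(s)$atom, c("N", "CA"))
  expect_setequal(atomRecords(s)$element, c("N", "C"))
})

test_that("parse errors name the offending line and empty input fails", {
  expect_error(readPDB(character(0)), "empty")
  expect_error(readPDB("REMARK nothing here"), "no ATOM")
  bad <- c(gly_chain_lines("A", 1),
           "ATOM      9  CA  GLY A   2      bad_x")
  expect_error(readPDB(bad), "line 5")
})

test_that("only the first MODEL of a multi-model file is read", {
  lines <- c("MODEL        1", gly_chain_lines("A", 1),
             "ENDMDL", "MODEL        2",
             gly_chain_lines("A", 2, offset = 100), "ENDMDL")
  s <- readPDB(lines)
  expect_equal(nrow(residueTable(s)), 1)
  expect_equal(residueTable(s)$seqid, 1L)
})

test_that("write/parse round trip preserves the residue/atom model", {
  toy <- makeToyStructure(
    list(plantedContact("LYS", "B", 51, "GLU", "C", 10,
                        type = "ionic", distance = 5.5)),
    decoys = 3, dna = TRUE, seed = 5)
  s1 <- readPDB(toy$text, id = "rt")
  s2 <- readPDB(writePDB(s1), id = "rt")
  a1 <- atomRecords(s1); a2 <- atomRecords(s2)
  expect_equal(a1[, c("chain", "seqid", "icode", "resname", "kind",
                      "atom", "element")],
               a2[, c("chain", "seqid", "icode", "resname", "kind",
                      "atom", "element")])
  expect_equal(a1$x, a2$x, tolerance = 1e-3)
  expect_equal(a1$y, a2$y, tolerance = 1e-3)
  expect_equal(a1$z, a2$z, tolerance = 1e-3)
})

test_that("parsing is insensitive to record order within a chain", {
  lines <- gly_chain_lines("A", c(3, 1, 2))
  s <- readPDB(lines)
  expect_equal(residueTable(s)$seqid, c(1L, 2L, 3L))  # ordered by seqid
  shuf <- readPDB(lines[c(9:12, 1:4, 5:8)])
  expect_equal(atomRecords(s), atomRecords(shuf))
})

test_that("agrees with bio3d's reader on a synthetic file", {
  toy <- makeToyStructure(
    list(plantedContact("ARG", "B", 51, "ASP", "C", 10,
                        type = "ionic", distance = 5.0)),
    decoys = 2, seed = 9)
  tf <- tempfile(fileext = ".pdb")
  writeLines(toy$text, tf)
  ours <- atomRecords(readPDB(tf))
  ref <- bio3d::read.pdb(tf)$atom
  expect_equal(nrow(ours), nrow(ref))
  expect_equal(sort(ours$x), sort(ref$x), tolerance = 1e-3)
  expect_equal(sort(paste(ours$chain, ours$seqid, ours$atom)),
               sort(paste(ref$chain, ref$resno, ref$elety)))
})

test_that("span selection follows author numbering with gaps allowed", {
  lines <- gly_chain_lines("B", seq(40, 100, by = 2))  # even numbers only
  s <- readPDB(lines)
  expect_equal(length(selectResidues(s, "B", c(51, 57))), 3)  # 52,54,56
  full <- readPDB(gly_chain_lines("B", 40:100))
  expect_equal(length(selectResidues(full, "B", c(51, 57))), 7)
  expect_equal(length(selectResidues(full, "B", c(200, 210))), 0)
  expect_equal(length(selectResidues(full, "B")), 61)
  expect_equal(residueMembers(selectResidues(full, "B"))$seqid, 40:100)
  expect_error(selectResidues(full, "Q"), "unknown chain")
  expect_error(selectResidues(full, "B", c(9, 3)), "span")
})

test_that("residueSequence renders protein residues as one-letter codes", {
  toy <- makeToyStructure(
    list(plantedContact("ARG", "B", 51, "ASP", "C", 10,
                        type = "ionic", distance = 5.0),
         plantedContact("LEU", "B", 52, "LEU", "C", 11,
                        type = "hydrophobic", distance = 4.5)),
    decoys = 0, seed = 1)
  s <- readPDB(toy$text)
  expect_equal(residueSequence(selectResidues(s, "B")), "RL")
})
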