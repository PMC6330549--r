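toy_residues <- function(specs, seed = 1, decoys = 0, dna = FALSE) {
  toy <- makeToyStructure(specs, decoys = decoys, dna = dna, seed = seed)
  readPDB(toy$text)
}

test_that("an ionic pair at 5.5 A is typed ionic; at 6.5 A nothing", {
  s <- toy_residues(list(plantedContact(
    "LYS", "B", 1, "GLU", "C", 2, type = "ionic", distance = 5.5)))
  td <- detectContactTypes(getResidue(s, "B", 1), getResidue(s, "C", 2))
  expect_equal(td$type, "ionic")
  expect_equal(td$distance, 5.5, tolerance = 0.02)

  s2 <- toy_residues(list(plantedContact(
    "LYS", "B", 1, "GLU", "C", 2, type = "ionic", distance = 6.5)))
  td2 <- detectContactTypes(getResidue(s2, "B", 1), getResidue(s2, "C", 2))
  expect_equal(nrow(td2), 0)
})

test_that("H-bond typing respects the 3.5 A O/N donor limit", {
  s <- toy_residues(list(plantedContact(
    "SER", "B", 1, "ASP", "C", 2, type = "hbond", distance = 3.4)))
  td <- detectContactTypes(getResidue(s, "B", 1), getResidue(s, "C", 2))
  expect_equal(td$type, "hbond")
  expect_equal(td$distance, 3.4, tolerance = 0.02)

  s2 <- toy_residues(list(plantedContact(
    "SER", "B", 1, "ASP", "C", 2, type = "hbond", distance = 3.8,
    margin = 0.15)))
  td2 <- detectContactTypes(getResidue(s2, "B", 1), getResidue(s2, "C", 2))
  expect_equal(nrow(td2), 0)
})

test_that("sulphur partners use the 4.0 A cutoff, gated by the switch", {
  # Gly backbone N donor to Met SD acceptor at 3.8 A: sulphur acceptor
  s <- toy_residues(list(plantedContact(
    "GLY", "B", 1, "MET", "C", 2, type = "hbond", distance = 3.8,
    margin = 0.15)))
  ra <- getResidue(s, "B", 1); rb <- getResidue(s, "C", 2)
  td <- detectContactTypes(ra, rb, sulfurEitherPartner = TRUE)
  expect_true("hbond" %in% td$type)
  td2 <- detectContactTypes(ra, rb, sulfurEitherPartner = FALSE)
  expect_false("hbond" %in% td2$type)   # O donor alone keys 3.5 A
})

test_that("detectContactTypes rejects non-protein residues", {
  s <- toy_residues(list(plantedContact(
    "SER", "B", 1, type = "dna_contact", distance = 4.0)), dna = TRUE)
  expect_error(
    detectContactTypes(getResidue(s, "B", 1), getResidue(s, "D", 1)),
    "protein")
})

test_that("planted contacts of all four types are recovered exactly", {
  specs <- list(
    plantedContact("LEU", "B", 51, "LEU", "C", 10,
                   type = "hydrophobic", distance = 4.5),
    plantedContact("VAL", "B", 52, "ALA", "C", 11,
                   type = "hydrophobic", distance = 4.0),
    plantedContact("LYS", "B", 53, "GLU", "C", 12,
                   type = "ionic", distance = 5.5),
    plantedContact("ARG", "B", 54, "ASP", "C", 13,
                   type = "ionic", distance = 5.0),
    plantedContact("SER", "B", 55, "ASP", "C", 14,
                   type = "hbond", distance = 3.2),
    plantedContact("LYS", "B", 56, "PHE", "C", 15,
                   type = "cation_pi", distance = 5.0))
  toy <- makeToyStructure(specs, decoys = 10, dna = TRUE, seed = 7)
  s <- readPDB(toy$text)
  m <- buildContactMap(selectResidues(s, "B"), selectResidues(s, "C"),
                       dna = selectResidues(s, "D"))
  ct <- contacts(m)
  truth <- toy$truth$contacts
  expect_equal(nrow(ct), 6)
  expect_equal(sort(paste(ct$chain_a, ct$seq_a, ct$chain_b, ct$seq_b,
                          ct$type)),
               sort(paste(truth$chain_a, truth$seq_a, truth$chain_b,
                          truth$seq_b, truth$type)))
  got <- ct$distance[order(ct$seq_a)]
  want <- truth$distance[order(truth$seq_a)]
  expect_equal(got, want, tolerance = 0.02)
  expect_true(all(ct$distance <= 6))
})

test_that("build equals the brute-force oracle on varied structures", {
  for (seed in 1:25) {
    s <- random_jittered_structure(seed)
    if (is.null(s)) next
    m <- buildContactMap(selectResidues(s, "B"), selectResidues(s, "C"))
    orc <- oracle_map(s, selectResidues(s, "B"), selectResidues(s, "C"))
    expect_equal(contact_keys(contacts(m)), contact_keys(orc),
                 info = paste("seed", seed))
  }
})

test_that("swapping sides yields the same contacts with roles swapped", {
  toy <- makePairedComplex(3)$a
  s <- readPDB(toy$text)
  m1 <- buildContactMap(selectResidues(s, "B"), selectResidues(s, "C"))
  m2 <- buildContactMap(selectResidues(s, "C"), selectResidues(s, "B"))
  c1 <- contacts(m1); c2 <- contacts(m2)
  expect_equal(
    sort(paste(c1$chain_a, c1$seq_a, c1$chain_b, c1$seq_b, c1$type,
               round(c1$distance, 3))),
    sort(paste(c2$chain_b, c2$seq_b, c2$chain_a, c2$seq_a, c2$type,
               round(c2$distance, 3))))
})

test_that("enlarging any cutoff never removes a contact of that type", {
  toy <- makePairedComplex(5)$a
  s <- readPDB(toy$text)
  sideA <- selectResidues(s, "B"); sideB <- selectResidues(s, "C")
  base <- contacts(buildContactMap(sideA, sideB))
  set.seed(42)
  for (i in 1:20) {
    co <- interactionCutoffs(
      hydrophobic = 5 + runif(1, 0, 2), ionic = 6 + runif(1, 0, 2),
      cationPi = 6 + runif(1, 0, 2), hbondNO = 3.5 + runif(1, 0, 1),
      hbondS = 4 + runif(1, 0, 1))
    big <- contacts(buildContactMap(sideA, sideB, cutoffs = co))
    expect_true(all(paste(base$seq_a, base$seq_b, base$type) %in%
                    paste(big$seq_a, big$seq_b, big$type)))
  }
})

test_that("DNA flags mark exactly the residues near the stub", {
  toy <- makeToyStructure(list(
    plantedContact("SER", "A", 5, type = "dna_contact", distance = 4.0),
    plantedContact("LEU", "A", 6, type = "dna_contact", distance = 8.0),
    plantedContact("LYS", "B", 1, "GLU", "C", 2,
                   type = "ionic", distance = 5.5)),
    decoys = 0, dna = TRUE, seed = 13)
  s <- readPDB(toy$text)
  m <- buildContactMap(selectResidues(s, "A"), selectResidues(s, "B"),
                       dna = selectResidues(s, "D"))
  fl <- dnaFlags(m)
  expect_true(fl$flag[fl$chain == "A" & fl$seqid == 5])
  expect_false(fl$flag[fl$chain == "A" & fl$seqid == 6])
  expect_false(any(fl$flag[fl$chain == "B"]))
  # empty dna set: all flags false
  m2 <- buildContactMap(selectResidues(s, "A"), selectResidues(s, "B"))
  expect_false(any(dnaFlags(m2)$flag))
  expect_equal(nrow(dnaFlags(m2)), 3)   # every residue of both sides
})

test_that("overlapping sides are rejected", {
  toy <- makeToyStructure(list(plantedContact(
    "LEU", "B", 1, "LEU", "B", 2, type = "hydrophobic", distance = 4.5)),
    seed = 1)
  s <- readPDB(toy$text)
  expect_error(buildContactMap(selectResidues(s, "B"),
                               selectResidues(s, "B")), "overlap")
})

test_that("interface character counts classes and hydrophobic fraction", {
  specs <- list(
    plantedContact("LEU", "B", 51, "LEU", "C", 10,
                   type = "hydrophobic", distance = 4.5),
    plantedContact("VAL", "B", 52, "ALA", "C", 11,
                   type = "hydrophobic", distance = 4.0),
    plantedContact("LYS", "B", 53, "GLU", "C", 12,
                   type = "ionic", distance = 5.5),
    plantedContact("ARG", "B", 54, "ASP", "C", 13,
                   type = "ionic", distance = 5.0),
    plantedContact("SER", "B", 55, "ASP", "C", 14,
                   type = "hbond", distance = 3.2),
    plantedContact("LYS", "B", 56, "PHE", "C", 15,
                   type = "cation_pi", distance = 5.0))
  toy <- makeToyStructure(specs, decoys = 0, seed = 7)
  s <- readPDB(toy$text)
  m <- buildContactMap(selectResidues(s, "B"), selectResidues(s, "C"))
  ic <- interfaceCharacter(m)
  expect_equal(ic$A$hydrophobicFraction, 2 / 6)
  expect_equal(ic$B$hydrophobicFraction, 2 / 6)
  expect_true(is.na(ic$A$label))
  expect_equal(unname(ic$A$classCounts["aliphatic"]), 2L)  # LEU, VAL
  expect_equal(unname(ic$A$classCounts["positive"]), 3L)   # LYS x2, ARG
  expect_equal(sum(ic$A$classCounts), 6L)

  # all-hydrophobic map
  m2 <- buildContactMap(
    selectResidues(s, "B", c(51, 52)), selectResidues(s, "C", c(10, 11)))
  ic2 <- interfaceCharacter(m2)
  expect_equal(ic2$A$hydrophobicFraction, 1)
  expect_equal(ic2$A$label, "predominantly hydrophobic")

  # empty map
  m3 <- buildContactMap(
    selectResidues(s, "B", c(51, 51)), selectResidues(s, "C", c(12, 12)))
  ic3 <- interfaceCharacter(m3)
  expect_equal(sum(ic3$A$classCounts), 0L)
  expect_equal(ic3$A$hydrophobicFraction, 0)
  expect_true(is.na(ic3$A$label))
})

test_that("contact tables carry the spec columns and 3-decimal TSV", {
  toy <- makePairedComplex(2)$a
  s <- readPDB(toy$text, id = "demo")
  m <- buildContactMap(selectResidues(s, "B"), selectResidues(s, "C"),
                       dna = selectResidues(s, "D"))
  tab <- contactTable(m)
  expect_named(tab, c("structure_id", "chain_a", "seq_a", "resname_a",
                      "chain_b", "seq_b", "resname_b", "type",
                      "distance_angstrom", "dna_flag_a", "dna_flag_b"))
  fl <- dnaFlags(m)
  expect_true(fl$flag[fl$chain == "C" & fl$seqid == 40])  # Ser C40 on stub
  tf <- tempfile(fileext = ".tsv")
  writeContactTable(m, tf)
  reread <- read.delim(tf)
  expect_equal(nrow(reread), nrow(tab))
})
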