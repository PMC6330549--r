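seg_fixture <- function(seed = 1) {
  specs <- list(
    plantedContact("ARG", "B", 51, "ASP", "C", 10,
                   type = "ionic", distance = 5.0),
    plantedContact("LEU", "B", 53, "LEU", "C", 12,
                   type = "hydrophobic", distance = 4.5),
    plantedContact("LYS", "B", 55, "PHE", "C", 14,
                   type = "cation_pi", distance = 5.0),
    plantedContact("SER", "B", 56, "ASP", "C", 15,
                   type = "hbond", distance = 3.2))
  toy <- makeToyStructure(specs, decoys = 0, seed = seed)
  s <- readPDB(toy$text)
  seg <- selectResidues(s, "B", c(51, 57))
  map <- buildContactMap(seg, selectResidues(s, "C"))
  list(s = s, seg = seg, map = map, truth = toy$truth$contacts)
}

test_that("identity transfer reproduces the segment's map rows", {
  fx <- seg_fixture()
  segSeq <- residueSequence(fx$seg)
  al <- alignSegment(segSeq, segSeq, peptideId = "self")
  pr <- transferSites(al, fx$seg, fx$map, partnerFilter = "C")
  e <- proposalEntries(pr)
  expect_equal(nrow(e), nrow(contacts(fx$map)))
  expect_setequal(paste(e$src_chain, e$src_seq, e$partner_chain,
                        e$partner_seq, e$type),
                  paste(fx$truth$chain_a, fx$truth$seq_a,
                        fx$truth$chain_b, fx$truth$seq_b, fx$truth$type))
  # peptide positions follow the segment ordinals
  expect_equal(e$pep_pos[order(e$src_seq)], c(1L, 2L, 3L, 4L))
})

test_that("transferred positions land at the planted truth offsets", {
  fx <- seg_fixture()
  segSeq <- residueSequence(fx$seg)       # RLKS
  al <- alignSegment(segSeq, segSeq, peptideId = "QQS-5-8")
  pr <- transferSites(al, fx$seg, fx$map, partnerFilter = "C",
                      peptideStart = 5L)
  e <- proposalEntries(pr)
  # segment residues 51,53,55,56 are ordinals 1..4 -> positions 5..8
  expect_equal(sort(e$pep_pos), c(5L, 6L, 7L, 8L))
  expect_equal(e$partner_seq[order(e$pep_pos)], c(10L, 12L, 14L, 15L))
  expect_equal(e$type[order(e$pep_pos)],
               c("ionic", "hydrophobic", "cation_pi", "hbond"))
})

test_that("transfer is equivariant under a peptide numbering shift", {
  fx <- seg_fixture()
  segSeq <- residueSequence(fx$seg)
  al <- alignSegment(segSeq, segSeq)
  p1 <- proposalEntries(transferSites(al, fx$seg, fx$map,
                                      partnerFilter = "C",
                                      peptideStart = 1L))
  p9 <- proposalEntries(transferSites(al, fx$seg, fx$map,
                                      partnerFilter = "C",
                                      peptideStart = 9L))
  expect_equal(p9$pep_pos, p1$pep_pos + 8L)
  p9$pep_pos <- p1$pep_pos
  expect_equal(p1, p9)
})

test_that("partner filters restrict and can empty a proposal", {
  fx <- seg_fixture()
  segSeq <- residueSequence(fx$seg)
  al <- alignSegment(segSeq, segSeq)
  pr <- transferSites(al, fx$seg, fx$map, partnerFilter = "Z")
  expect_equal(nrow(proposalEntries(pr)), 0)
})

test_that("class differences between peptide and donor are flagged", {
  fx <- seg_fixture()
  segSeq <- residueSequence(fx$seg)       # RLKS
  al <- alignSegment("GGGG", segSeq, peptideId = "pep")
  expect_message(
    transferSites(al, fx$seg, fx$map, partnerFilter = "C"),
    "class differs")
})

test_that("a segment absent from the map's sides is an error", {
  fx <- seg_fixture()
  narrow <- buildContactMap(selectResidues(fx$s, "B", c(51, 53)),
                            selectResidues(fx$s, "C", c(10, 12)))
  outside <- selectResidues(fx$s, "B", c(55, 57))
  segSeq <- residueSequence(outside)
  al <- alignSegment(segSeq, segSeq)
  expect_error(transferSites(al, outside, narrow), "not a subset")
})

test_that("an alignment that does not cover the segment is rejected", {
  fx <- seg_fixture()
  al <- alignSegment("RL", "RLX")         # wrong target
  expect_error(transferSites(al, fx$seg, fx$map), "cover")
})

test_that("comparative transfer carries membership labels", {
  pc <- makePairedComplex(1)
  sa <- readPDB(pc$a$text, id = "formA")
  sb <- readPDB(pc$b$text, id = "formB")
  seg <- selectResidues(sa, "B", c(51, 57))
  mapA <- buildContactMap(seg, selectResidues(sa, "C"))
  mapB <- buildContactMap(selectResidues(sb, "B", c(51, 57)),
                          selectResidues(sb, "C"))
  m <- rbind(mapA@sideA, mapA@sideB)
  mp <- data.frame(chain_a = m$chain, seq_a = m$seqid,
                   icode_a = m$icode, chain_b = m$chain,
                   seq_b = m$seqid, icode_b = m$icode)
  cmp <- compareMaps(mapA, mapB, mp)
  al <- alignSegment("REQEIYV", residueSequence(seg),
                     peptideId = "QQS-5-11")
  pr <- suppressMessages(transferSites(al, seg, cmp,
                                       partnerFilter = "C",
                                       peptideStart = 5L))
  e <- proposalEntries(pr)
  expect_equal(nrow(e), 7)
  got <- e$membership[order(e$src_seq)]
  want <- pc$membership$membership[pc$membership$seq_b_res %in% 51:57]
  expect_equal(got, want)
  expect_equal(range(e$pep_pos), c(5L, 11L))
})

test_that("the QQS two-site topology yields the 29-residue linker", {
  mk <- function(id, positions) {
    new("BindingSiteProposal", peptideId = id, entries = data.frame(
      pep_pos = positions, pep_res = "A", src_chain = "B",
      src_seq = 51L, src_res = "ALA", partner_chain = "C",
      partner_seq = 1L, partner_res = "ALA", type = "hydrophobic",
      membership = "both", stringsAsFactors = FALSE))
  }
  rep_ <- linkerReport(mk("QQS-5-11", 5:11), mk("QQS-41-49", 41:49),
                       peptideLength = 59)
  expect_equal(rep_$nSpan, c(5L, 11L))
  expect_equal(rep_$cSpan, c(41L, 49L))
  expect_equal(rep_$linkerStart, 12L)
  expect_equal(rep_$linkerEnd, 40L)
  expect_equal(rep_$linkerLength, 29L)

  adj <- linkerReport(mk("n", 5:10), mk("c", 11:20), peptideLength = 59)
  expect_equal(adj$linkerLength, 0L)
  expect_true(is.na(adj$linkerStart))

  expect_error(linkerReport(mk("n", 5:11), mk("n", 5:11), 59), "overlap")
})
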