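CONSENSUS1 <- "R[E/D]Q[D/E]-[Y/F/W][L/V]"
CONSENSUS2 <- "[V/I]-R[L/I]M[K/R]-[I/V/L]"

test_that("parsing the consensus patterns gives the stated positions", {
  p <- parsePattern(CONSENSUS1)
  expect_equal(length(p), 7)
  pos <- patternPositions(p)
  expect_equal(pos[[1]], "R")
  expect_setequal(pos[[2]], c("E", "D"))
  expect_equal(pos[[3]], "Q")
  expect_setequal(pos[[4]], c("D", "E"))
  expect_true(is.na(pos[[5]]))                  # wildcard
  expect_setequal(pos[[6]], c("Y", "F", "W"))
  expect_setequal(pos[[7]], c("L", "V"))
  expect_equal(length(parsePattern(CONSENSUS2)), 8)
  expect_equal(length(parsePattern("A")), 1)
})

test_that("parse and render round-trip on the canonical dialect", {
  for (txt in c(CONSENSUS1, CONSENSUS2, "A", "-", "AC-D[E/F]"))
    expect_equal(patternText(parsePattern(txt)), txt)
})

test_that("malformed patterns are rejected", {
  expect_error(parsePattern("[A/]"), "malformed")
  expect_error(parsePattern("[/A]"), "malformed")
  expect_error(parsePattern("[]"), "malformed")
  expect_error(parsePattern("A[B/C"), "unbalanced")
  expect_error(parsePattern("a"), "unexpected")
  expect_error(parsePattern("[X/Y]"), "malformed")  # X not allowed in sets
})

test_that("consensus derivation follows the column rule", {
  b <- alignmentBlock(c("REQEIYV", "RDQDAWL"))
  p <- deriveConsensus(b, maxAlternatives = 3)
  # ties order alphabetically within a column
  expect_equal(patternText(p), "R[D/E]Q[D/E][A/I][W/Y][L/V]")
  # every row matches its own consensus by construction
  for (row in c("REQEIYV", "RDQDAWL"))
    expect_equal(nrow(scanSequence(p, row)), 1)

  p1 <- deriveConsensus(b, maxAlternatives = 1)
  expect_equal(patternText(p1), "R-Q----")

  ident <- deriveConsensus(alignmentBlock(c("REQEIYV", "REQEIYV")))
  expect_equal(patternText(ident), "REQEIYV")

  wide <- alignmentBlock(c("A", "C", "D", "E"))
  expect_equal(patternText(deriveConsensus(wide, 3)), "-")

  expect_error(alignmentBlock("REQEIYV"), "2 rows")
  expect_error(alignmentBlock(c("AB", "ABC")), "equal length")
  expect_error(alignmentBlock(c("A-B", "AAB")), "ungapped")
})

test_that("frequency outranks alphabet when ordering alternatives", {
  b <- alignmentBlock(c("V", "V", "I"))
  expect_equal(patternText(deriveConsensus(b)), "[V/I]")
})

test_that("the first consensus hits REQEIYV exactly once at position 1", {
  hits <- scanSequence(parsePattern(CONSENSUS1), "REQEIYV")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 1L)
  expect_equal(hits$match, "REQEIYV")
  expect_equal(nrow(scanSequence(parsePattern(CONSENSUS1), "AAAAAAA")), 0)
})

test_that("overlapping hits are all reported", {
  hits <- scanSequence(parsePattern("AA"), "AAAA")
  expect_equal(hits$start, c(1L, 2L, 3L))
})

test_that("X is matched by wildcards only", {
  p <- parsePattern("[A/C]-")
  expect_equal(nrow(scanSequence(p, "AXZ")), 1)   # wildcard takes X
  expect_equal(nrow(scanSequence(p, "XA")), 0)    # set refuses X
})

test_that("degenerate scans return empty tables", {
  p <- parsePattern("AAAA")
  expect_equal(nrow(scanSequence(p, "AA")), 0)    # pattern too long
  expect_equal(nrow(scanSequence(p, "")), 0)
})

test_that("scanSequence agrees with a naive position oracle", {
  naive_scan <- function(positions, seq) {
    ch <- strsplit(seq, "")[[1]]
    L <- length(positions)
    hits <- integer(0)
    if (nchar(seq) >= L) {
      for (st in 1:(nchar(seq) - L + 1)) {
        ok <- TRUE
        for (k in 1:L) {
          s <- positions[[k]]
          if (length(s) == 1 && is.na(s)) next
          if (!(ch[st + k - 1] %in% s)) { ok <- FALSE; break }
        }
        if (ok) hits <- c(hits, st)
      }
    }
    hits
  }
  set.seed(11)
  alpha <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:200) {
    L <- sample(2:5, 1)
    pos <- lapply(seq_len(L), function(k) {
      r <- runif(1)
      if (r < 0.25) NA_character_
      else sample(alpha, sample(1:3, 1))
    })
    p <- newPattern(pos)
    seq <- paste(sample(c(alpha, "X"), sample(6:30, 1), replace = TRUE),
                 collapse = "")
    expect_equal(scanSequence(p, seq)$start,
                 naive_scan(patternPositions(p), seq),
                 info = paste("case", i, patternText(p), seq))
  }
})

test_that("database scanning honours exclusion patterns", {
  db <- makeMotifDb(
    10, planted = list(list(pattern = CONSENSUS1, count = 4)),
    exclusionTagged = 1, exclusionPattern = "KKRK", seed = 5)
  tf <- tempfile(fileext = ".fasta")
  writeLines(db$text, tf)
  q <- parsePattern(CONSENSUS1)
  hits <- scanDatabase(q, tf, exclusion = list(parsePattern("KKRK")))
  qtruth <- db$truth[db$truth$role == "query", ]
  excl <- db$truth$record_id[db$truth$role == "exclusion"]
  expect_setequal(unique(hits$record_id),
                  setdiff(qtruth$record_id, excl))
  expect_equal(length(unique(hits$record_id)), 3)
  # exact positions for surviving records
  keep <- qtruth[!qtruth$record_id %in% excl, ]
  expect_setequal(paste(hits$record_id, hits$start),
                  paste(keep$record_id, keep$start))
  # empty exclusion list: plain scan over all records
  all_hits <- scanDatabase(q, tf)
  expect_setequal(unique(all_hits$record_id), qtruth$record_id)
  # hit count is monotone non-increasing in the exclusion list
  expect_lte(nrow(hits), nrow(all_hits))
  more <- scanDatabase(q, tf, exclusion = list(parsePattern("KKRK"),
                                               parsePattern("R")))
  expect_lte(nrow(more), nrow(hits))
})

test_that("a record with neither consensus yields no hits", {
  seqs <- c(plain = "GGGGGGGGGGGGGGGG")
  expect_equal(nrow(scanDatabase(parsePattern(CONSENSUS1), seqs)), 0)
  expect_equal(nrow(scanDatabase(parsePattern(CONSENSUS2), seqs)), 0)
})

test_that("segment alignment finds identical substrings with identity labels", {
  al <- alignSegment("KLM", "AAKLMAA")
  expect_equal(al$offset, 3L)
  expect_equal(al$score, 6)
  expect_setequal(al$labels, "identity")
})

test_that("class-aware scoring picks the homologous window", {
  al <- alignSegment("REQEIYV", "GGRDQDAWLGG")
  expect_equal(al$offset, 3L)
  # columns: R=R(2), E~D(1), Q=Q(2), E~D(1), I~A(1), Y~W(1), V~L(1)
  expect_equal(al$score, 9)
  expect_equal(al$labels,
               c("identity", "class", "identity", "class", "class",
                 "class", "class"))
  # without class awareness only identities count
  al2 <- alignSegment("REQEIYV", "GGRDQDAWLGG", classAware = FALSE)
  expect_equal(al2$score, 4)
})

test_that("alignment ties break to the smallest offset", {
  al <- alignSegment("AB", "ABAB")
  expect_equal(al$offset, 1L)
  expect_error(alignSegment("", "ABC"), "empty")
  expect_error(alignSegment("ABCD", "AB"), "longer")
})
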