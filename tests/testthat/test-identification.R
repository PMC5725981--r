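# ORF extraction, candidate filtering, interrupted-SET merging and
# redundancy removal.

test_that("longest ORF extraction handles plus/minus strands and modes", {
  orf <- extract_longest_orf("ATGAAATGA", min_aa = 2)
  expect_equal(orf$peptide, "MK")
  expect_equal(orf$frame, "+1")

  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", "ATGAAATGA"),
                           "")[[1]]), collapse = "")
  orf_rc <- extract_longest_orf(rc, min_aa = 2)
  expect_equal(orf_rc$peptide, "MK")
  expect_true(startsWith(orf_rc$frame, "-"))

  # stop-to-stop mode finds ORFs with no ATG
  expect_null(extract_longest_orf("CCCCCCCCC", min_aa = 2, mode = "atg"))
  ss <- extract_longest_orf("CCCCCCCCC", min_aa = 2, mode = "stop")
  expect_equal(ss$peptide, "PPP")

  expect_error(extract_longest_orf(""), "empty")
  expect_error(extract_longest_orf("ATGXX"), "alphabet")
})

test_that("longest ORF matches the brute-force six-frame enumerator", {
  set.seed(11)
  for (i in 1:60) {
    tx <- random_transcript(300)
    got <- extract_longest_orf(tx, min_aa = 1)
    want <- oracle_longest_orf(tx)
    if (nchar(want) == 0) {
      expect_null(got)
    } else {
      # equal length by construction; equal sequence because ties at the
      # same length can only differ in frame, and both scan exhaustively
      expect_equal(nchar(got$peptide), nchar(want))
    }
  }
})

test_that("candidate filter keeps SET-hit proteins and flags odd lengths", {
  prot <- data.frame(
    protein_id = c("p1", "p2", "p3"), species = "At", locus_id = "",
    sequence = c(strrep("A", 300), strrep("A", 250), strrep("A", 260)),
    source = "proteome", stringsAsFactors = FALSE)
  hits <- make_hits(c("p1", "p3"), c("SET", "PHD"), c(10, 10), c(150, 60))
  got <- find_set_candidates(prot, hits)
  expect_equal(got$protein_id, "p1")
  # idempotent, subset of input
  hits_got <- hits[hits$protein_id %in% got$protein_id, ]
  expect_equal(find_set_candidates(got, hits_got), got)

  big <- data.frame(protein_id = "px", species = "At", locus_id = "",
                    sequence = strrep("A", 5000), source = "proteome",
                    stringsAsFactors = FALSE)
  bh <- make_hits("px", "SET", 10, 150)
  expect_warning(keep <- find_set_candidates(big, bh), "outside")
  expect_equal(nrow(keep), 1)
  expect_equal(nrow(suppressWarnings(
    find_set_candidates(big, bh, strict = TRUE))), 0)

  expect_error(find_set_candidates(prot, make_hits("nope", "SET", 1, 10)),
               "unknown protein")
  expect_equal(nrow(find_set_candidates(prot, hits[0, ])), 0)
})

test_that("interrupted SET pieces merge but tandem SET domains do not", {
  # two short pieces of one split domain: gap 50, total 130 aa
  h <- make_hits(c("p", "p"), c("SET", "SET"), c(100, 210), c(159, 279))
  m <- merge_interrupted_set(h)
  expect_equal(nrow(m), 1)
  expect_true(m$interrupted)
  expect_equal(c(m$start, m$end), c(100, 279))

  # two full-length SET domains in tandem stay separate
  t2 <- make_hits(c("q", "q"), c("SET", "SET"), c(100, 260), c(239, 399))
  expect_equal(nrow(merge_interrupted_set(t2)), 2)

  # adjacent pieces below the gap threshold stay separate too
  close <- make_hits(c("r", "r"), c("SET", "SET"), c(100, 165), c(159, 230))
  expect_equal(nrow(merge_interrupted_set(close)), 2)
})

test_that("redundancy removal keeps longest per locus then collapses
           identical SET substrings, and is idempotent", {
  mk <- function(id, locus, len, set_at, block = strrep("W", 60)) {
    data.frame(protein_id = id, species = "Cr", locus_id = locus,
               sequence = paste0(strrep("A", set_at - 1), block,
                                 strrep("G", len - set_at + 1 - 60)),
               source = "proteome", stringsAsFactors = FALSE)
  }
  prot <- rbind(mk("iso_a", "L1", 400, 50), mk("iso_b", "L1", 600, 50),
                mk("dup_1", "L2", 300, 20, block = strrep("H", 60)),
                mk("dup_2", "L3", 350, 20, block = strrep("H", 60)),
                mk("solo", "L4", 300, 90, block = strrep("Y", 60)))
  hits <- make_hits(prot$protein_id, "SET",
                    c(50, 50, 20, 20, 90), c(109, 109, 79, 79, 149))
  got <- deduplicate(prot, hits)
  expect_equal(sort(got$protein_id), c("dup_2", "iso_b", "solo"))
  expect_identical(deduplicate(got, hits), got)

  one <- mk("only", "L9", 300, 50)
  expect_equal(deduplicate(one, make_hits("only", "SET", 50, 109))$protein_id,
               "only")
})
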