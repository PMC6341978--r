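test_that("GC fraction follows the ambiguity convention", {
  expect_equal(compute_gc("ATGC"), 0.5)
  expect_equal(compute_gc("GGCC"), 1.0)
  expect_equal(compute_gc("ATNNGC"), 0.5)
  expect_equal(compute_gc("atgc"), 0.5)
  expect_error(compute_gc("NNNN"), "undefined")
  expect_error(compute_gc(""), "empty")
})

test_that("ORF finder reports both strands in forward coordinates", {
  orfs <- find_orfs("ATGAAATAA", min_codons = 2)
  expect_equal(nrow(orfs), 1L)
  expect_equal(orfs$start, 0L)
  expect_equal(orfs$end, 9L)
  expect_equal(orfs$frame, 0L)
  expect_equal(orfs$strand, "+")
  expect_equal(nrow(find_orfs("CCCCCCCCC", min_codons = 1)), 0L)
  # strand oracle: the reverse complement must carry the same ORF on '-'
  # with identical forward-strand coordinates
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("ATGAAATAA")))
  orfs_rc <- find_orfs(rc, min_codons = 2)
  expect_equal(nrow(orfs_rc), 1L)
  expect_equal(orfs_rc$start, 0L)
  expect_equal(orfs_rc$end, 9L)
  expect_equal(orfs_rc$strand, "-")
  # min_codons includes the stop codon
  expect_equal(nrow(find_orfs("ATGAAATAA", min_codons = 3)), 1L)
  expect_equal(nrow(find_orfs("ATGAAATAA", min_codons = 4)), 0L)
})

test_that("low-expression filter keeps sums at the threshold", {
  fpkm <- matrix(c(0.2, 0.29, 0.25, 0.25, 5, 5), nrow = 3, byrow = TRUE,
                 dimnames = list(c("a", "b", "c"), NULL))
  expect_equal(filter_low_expression(fpkm, 0.5), c("b", "c"))
  expect_equal(filter_low_expression(fpkm, 0), c("a", "b", "c"))
  zero <- matrix(0, 2, 3, dimnames = list(c("x", "y"), NULL))
  expect_equal(filter_low_expression(zero, 0.5), character(0))
})

test_that("reciprocal best hits honour mutual-best and the tie-break rule", {
  fwd <- data.frame(query = "q1", subject = "s1", score = 100)
  rev <- data.frame(query = "s1", subject = "q1", score = 90)
  expect_equal(reciprocal_best_hits(fwd, rev), "q1")
  rev2 <- data.frame(query = "s1", subject = "q2", score = 90)
  expect_equal(reciprocal_best_hits(fwd, rev2), character(0))
  # tie: q1 hits s1 and s2 equally; the lexicographically smaller subject
  # (s1) is chosen, and reciprocity is checked against it only
  fwd_tie <- data.frame(query = c("q1", "q1"), subject = c("s2", "s1"),
                        score = c(100, 100))
  rev_s1_q1 <- data.frame(query = c("s1", "s2"), subject = c("q1", "q1"),
                          score = c(50, 50))
  expect_equal(reciprocal_best_hits(fwd_tie, rev_s1_q1), "q1")
  # if only s2 (the losing tie) reciprocates, q1 is NOT an RBH -
  # brute-force over both tie resolutions shows only the s1 resolution
  # is consulted
  rev_s2_only <- data.frame(query = c("s1", "s2"), subject = c("qX", "q1"),
                            score = c(50, 50))
  expect_equal(reciprocal_best_hits(fwd_tie, rev_s2_only), character(0))
})

test_that("classification follows the evidence precedence and GC boundary", {
  info <- data.frame(
    id = c("t_gc_in", "t_gc_out", "t_coral", "t_symb", "t_rbh", "t_conflict",
           "t_low", "t_noorf"),
    gc = c(0.47, 0.471, 0.60, 0.30, 0.60, 0.40, 0.30, 0.30),
    low_expression = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE,
                       FALSE),
    no_orf = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  ev <- data.frame(
    query_id = c("t_coral", "t_symb", "t_rbh", "t_conflict", "t_conflict"),
    database = c("coral_reference", "symbiont_reference", "cnidarian_db",
                 "coral_reference", "symbiont_reference"),
    reciprocal = c(FALSE, FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  calls <- classify_transcripts(info, ev, gc_cutoff = 0.47)
  got <- stats::setNames(calls$label, calls$transcript_id)
  expect_equal(got[["t_gc_in"]], "host")       # inclusive boundary
  expect_equal(got[["t_gc_out"]], "discarded")
  expect_equal(got[["t_coral"]], "host")       # evidence outranks GC
  expect_equal(got[["t_symb"]], "symbiont")
  expect_equal(got[["t_rbh"]], "host")
  expect_equal(got[["t_conflict"]], "discarded")
  expect_equal(got[["t_low"]], "discarded")
  expect_equal(got[["t_noorf"]], "discarded")
  ev_codes <- stats::setNames(calls$evidence, calls$transcript_id)
  expect_equal(ev_codes[["t_gc_in"]], "gc_rule")
  expect_equal(ev_codes[["t_low"]], "low_expression")
  expect_equal(ev_codes[["t_noorf"]], "no_orf")
  expect_error(classify_transcripts(info,
                                    data.frame(query_id = "ghost",
                                               database = "coral_reference",
                                               reciprocal = FALSE)),
               "unknown")
})

test_that("every transcript gets one call; host/symbiont sets disjoint; GC cutoff monotone", {
  cfg <- tiny_config(seed = 21)
  tx <- gen_meta_transcriptome(cfg)
  calls <- classify_transcripts(tx$info, tx$evidence)
  expect_equal(nrow(calls), nrow(tx$info))
  expect_equal(anyDuplicated(calls$transcript_id), 0L)
  host <- calls$transcript_id[calls$label == "host"]
  symb <- calls$transcript_id[calls$label == "symbiont"]
  expect_length(intersect(host, symb), 0L)
  sizes <- vapply(c(0.40, 0.47, 0.55, 0.70), function(cut)
    sum(classify_transcripts(tx$info, tx$evidence,
                             gc_cutoff = cut)$label == "host"),
    numeric(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("full ortholog evidence gives perfect partition", {
  cfg <- tiny_config(seed = 31, evidence_fraction = 1)
  tx <- gen_meta_transcriptome(cfg)
  calls <- classify_transcripts(tx$info, tx$evidence)
  truth <- tx$truth$transcript_origin[calls$transcript_id]
  expect_true(all(calls$label == truth))
})

test_that("BLAST tabular reader maps the 12 standard columns", {
  line <- "q1\ts9\t98.5\t200\t3\t0\t1\t200\t11\t210\t1e-50\t370"
  path <- withr::local_tempfile(lines = line, fileext = ".tsv")
  tab <- read_blast6(path)
  expect_equal(tab$query, "q1")
  expect_equal(tab$subject, "s9")
  expect_equal(tab$score, 370)
  expect_equal(tab$evalue, 1e-50)
  bad <- withr::local_tempfile(lines = "a\tb\tc", fileext = ".tsv")
  expect_error(read_blast6(bad), "12")
})
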