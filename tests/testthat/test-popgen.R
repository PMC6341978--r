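test_that("SNP filters apply depth, call-rate and MAF rules", {
  # 17 samples; site 1: MAF 0.09 -> removed; site 2: MAF 0.2 -> kept;
  # site 3: one genotype missing (call rate 16/17 = 0.941) -> removed
  n <- 17
  g1 <- c(rep(1, 3), rep(0, 14))            # alt freq 3/34 = 0.088
  g2 <- c(rep(1, 7), rep(0, 10))            # alt freq 7/34 = 0.206
  g3 <- g2; g3[1] <- NA
  geno <- rbind(g1, g2, g3)
  flt <- filter_snps(geno, depth = NULL)
  expect_equal(unname(flt$kept), c(FALSE, TRUE, FALSE))
  # depth below 20 sets the call missing first
  depth <- matrix(30, 1, n)
  depth[1, 1] <- 19
  flt2 <- filter_snps(rbind(g2), depth = depth)
  expect_false(flt2$kept[1])                # call rate drops to 16/17
  flt3 <- filter_snps(rbind(g2), depth = matrix(20, 1, n))
  expect_true(flt3$kept[1])                 # depth exactly 20 is callable
})

test_that("synonymous annotation follows the standard code on both strands", {
  # transcript: ATG GCT AAA TAA ; ORF covers the whole sequence
  s <- "ATGGCTAAATAA"
  orf <- list(start = 0L, end = 12L, strand = "+")
  # GCT -> GCC (Ala -> Ala), third codon position
  expect_true(annotate_synonymous(6, "T", "C", orf, s))
  # GCT -> GAT (Ala -> Asp), second position
  expect_false(annotate_synonymous(5, "C", "A", orf, s))
  # outside the ORF: undetermined
  s_utr <- paste0(s, "GGGG")
  expect_true(is.na(annotate_synonymous(14, "G", "A", orf, s_utr)))
  expect_error(annotate_synonymous(99, "G", "A", orf, s), "outside")
  expect_error(annotate_synonymous(6, "A", "C", orf, s), "reference allele")
  # minus strand: the reverse complement carries the same ORF on '-'
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  orf_m <- list(start = 0L, end = 12L, strand = "-")
  expect_true(annotate_synonymous(12 + 1 - 6, "A", "G", orf_m, rc))
  expect_false(annotate_synonymous(12 + 1 - 5, "G", "T", orf_m, rc))
})

test_that("one-SNP-per-transcript thinning picks the longest isoform first", {
  iso <- data.frame(transcript_id = c("iA", "iB", "iC"),
                    gene_id = c("g1", "g1", "g2"),
                    length = c(900, 1200, 700))
  rec <- data.frame(transcript_id = c("iB", "iB", "iA", "iC"),
                    pos = c(300, 50, 10, 400))
  out <- thin_one_per_transcript(rec, iso)
  expect_equal(out$transcript_id, c("iB", "iC"))
  expect_equal(out$pos, c(50, 400))
  # SNPs only on the shorter isoform: the gene contributes nothing
  rec2 <- data.frame(transcript_id = "iA", pos = 10)
  expect_equal(nrow(thin_one_per_transcript(rec2, iso)), 0L)
  # length ties break to the lexicographically smallest isoform id
  iso_tie <- data.frame(transcript_id = c("iZ", "iY"), gene_id = "g",
                        length = c(500, 500))
  rec3 <- data.frame(transcript_id = c("iZ", "iY"), pos = c(5, 9))
  expect_equal(thin_one_per_transcript(rec3, iso_tie)$transcript_id, "iY")
  expect_error(thin_one_per_transcript(
    data.frame(transcript_id = "nope", pos = 1), iso), "no isoform")
})

test_that("WC84 components match the frozen 4-individual oracle", {
  # pop1 {AA, Aa}, pop2 {aa, aa} as alt dosages
  g <- matrix(c(2, 1, 0, 0), nrow = 1)
  est <- wc_fst(g, c("p1", "p1", "p2", "p2"))
  expect_equal(unname(est$component_sums),
               c(0.25, 0, 0.125), tolerance = 1e-12)
  expect_equal(est$theta, 2 / 3, tolerance = 1e-12)
})

test_that("WC84 limits: fixed difference 1, identical populations <= 0", {
  fixed <- matrix(c(0, 0, 2, 2), nrow = 1)
  expect_equal(wc_fst(fixed, c("a", "a", "b", "b"))$theta, 1)
  same <- rbind(c(0, 1, 0, 1), c(2, 1, 2, 1), c(1, 1, 1, 1))
  expect_lte(wc_fst(same, c("a", "a", "b", "b"))$theta, 0)
})

test_that("theta is invariant to allele relabeling and group exchange", {
  cfg <- tiny_config(seed = 19, n_snps = 150, diff_param = 0.1)
  gt <- gen_genotypes(cfg)
  th <- wc_fst(gt$geno, gt$groups)$theta
  expect_equal(wc_fst(2 - gt$geno, gt$groups)$theta, th, tolerance = 1e-12)
  swapped <- ifelse(gt$groups == "group1", "group2", "group1")
  expect_equal(wc_fst(gt$geno, swapped)$theta, th, tolerance = 1e-12)
  flip <- gt$geno
  flip[seq(1, nrow(flip), 2), ] <- 2 - flip[seq(1, nrow(flip), 2), ]
  expect_equal(wc_fst(flip, gt$groups)$theta, th, tolerance = 1e-12)
  expect_error(wc_fst(gt$geno, rep("a", ncol(gt$geno))), "two groups")
})

test_that("bootstrap CI is deterministic, degenerate on identical loci, and shrinks with loci", {
  cfg <- tiny_config(seed = 23, n_snps = 250, diff_param = 0.1,
                     n_per_group = c(8, 8))
  gt <- gen_genotypes(cfg)
  ci1 <- bootstrap_ci(gt$geno, gt$groups, n_reps = 200, seed = 5)
  ci2 <- bootstrap_ci(gt$geno, gt$groups, n_reps = 200, seed = 5)
  expect_equal(ci1$ci_low, ci2$ci_low)
  expect_equal(ci1$ci_high, ci2$ci_high)
  expect_lt(ci1$ci_low, ci1$ci_high)
  # identical loci: zero-width interval at the point estimate
  one <- matrix(c(2, 1, 0, 1, 0, 0, 2, 2), nrow = 1)
  rep_loci <- one[rep(1, 30), ]
  cid <- bootstrap_ci(rep_loci, rep(c("a", "b"), each = 4),
                      n_reps = 50, seed = 1)
  expect_equal(cid$ci_low, cid$ci_high)
  expect_equal(cid$ci_low, cid$theta)
  expect_error(bootstrap_ci(rep_loci, rep(c("a", "b"), each = 4),
                            n_reps = 1), "n_reps")
  # CI width shrinks roughly as 1/sqrt(n_loci)
  cfg_big <- tiny_config(seed = 23, n_snps = 2500, diff_param = 0.1,
                         n_per_group = c(8, 8))
  gt_big <- gen_genotypes(cfg_big)
  ci_big <- bootstrap_ci(gt_big$geno, gt_big$groups, n_reps = 200, seed = 5)
  w_small <- ci1$ci_high - ci1$ci_low
  w_big <- ci_big$ci_high - ci_big$ci_low
  ratio <- w_small / w_big
  expect_gt(ratio, sqrt(10) / 2)
  expect_lt(ratio, sqrt(10) * 2)
})

test_that("chi-square reproduces the printed association statistics", {
  site_clade <- matrix(c(6, 1, 6, 5), 2)
  t1 <- chi2_association(site_clade)
  expect_equal(round(t1$statistic, 2), 1.87)
  expect_equal(round(t1$p, 2), 0.17)
  ga_clade <- matrix(c(2, 5, 7, 4), 2)
  t2 <- chi2_association(ga_clade)
  expect_equal(round(t2$statistic, 2), 2.10)
  expect_equal(round(t2$p, 2), 0.15)
  flat <- matrix(5, 2, 2)
  t3 <- chi2_association(flat)
  expect_equal(t3$statistic, 0)
  expect_equal(t3$p, 1)
  # Yates mode shrinks the statistic
  expect_lt(chi2_association(site_clade, yates = TRUE)$statistic,
            t1$statistic)
  expect_error(chi2_association(matrix(c(0, 0, 1, 2), 2)), "margins")
})

test_that("island-model equilibrium matches the closed form", {
  expect_equal(island_model_fst(1000, 1.30e-3), 1 / (1 + 16 * 1.3),
               tolerance = 1e-12)
  expect_equal(round(island_model_fst(1000, 1.30e-3), 3), 0.046)
  expect_equal(round(island_model_fst(1000, 1.67e-3), 3), 0.036)
  expect_equal(round(island_model_fst(1000, 1.02e-3), 3), 0.058)
})

test_that("generated VCF round-trips through vcfR and is spec-conformant", {
  cfg <- tiny_config(seed = 29, n_snps = 40)
  tx <- gen_meta_transcriptome(cfg)
  gt <- gen_genotypes(cfg, tx)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gt, path)
  lines <- readLines(path)
  expect_equal(lines[1], "##fileformat=VCFv4.2")
  expect_true(any(grepl("^#CHROM\tPOS", lines)))
  expect_true(all(grepl("GT:DP", lines[!startsWith(lines, "#")])))
  back <- read_vcf_genotypes(path)
  expect_equal(unname(back$geno), unname(gt$geno))
  expect_equal(unname(back$depth), unname(gt$depth + 0))
  expect_equal(back$sites$pos, gt$sites$pos)
})

test_that("near-zero differentiation gives near-zero theta", {
  th <- vapply(1:5, function(s) {
    cfg <- tiny_config(seed = s, n_snps = 400, diff_param = 1e-6,
                       n_per_group = c(8, 8))
    gt <- gen_genotypes(cfg)
    wc_fst(gt$geno, gt$groups)$theta
  }, numeric(1))
  expect_lt(abs(mean(th)), 0.01)
})

test_that("planted synonymous status is recovered by annotation", {
  cfg <- tiny_config(seed = 31, n_snps = 80)
  tx <- gen_meta_transcriptome(cfg)
  gt <- gen_genotypes(cfg, tx)
  agree <- vapply(seq_len(nrow(gt$sites)), function(i) {
    st <- gt$sites[i, ]
    s <- tx$sequences[[st$transcript_id]]
    annotate_synonymous(st$pos, st$ref, st$alt,
                        list(start = 0L, end = nchar(s), strand = "+"),
                        s) == st$synonymous_truth
  }, logical(1))
  expect_true(all(agree))
  expect_gt(mean(gt$sites$synonymous_truth), 0.3)
  expect_lt(mean(gt$sites$synonymous_truth), 0.7)
})
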