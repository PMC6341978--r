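#' Filter SNPs by depth, call rate and minor allele frequency
#'
#' Genotype calls with depth below `depth_min` are set missing first; a site
#' is then retained iff its call rate among samples is at least `1 -
#' max_missing` and its minor allele frequency among the remaining calls is
#' at least `maf_min`. Only biallelic records are accepted (multi-allelic
#' records must be dropped upstream by the VCF reader).
#'
#' @param geno Integer matrix of alt-allele dosages (loci x samples), values
#'   0/1/2 or NA.
#' @param depth Matrix of per-genotype depths, same shape, or NULL to skip
#'   the depth rule.
#' @param maf_min Minimum minor allele frequency (default 0.1).
#' @param max_missing Maximum missing fraction (default 0.05, i.e. call rate
#'   >= 0.95).
#' @param depth_min Minimum genotype depth (default 20).
#' @return List with `geno` (filtered matrix, low-depth calls NA) and
#'   `kept` (logical vector over input loci).
#' @export
filter_snps <- function(geno, depth = NULL, maf_min = 0.1,
                        max_missing = 0.05, depth_min = 20) {
  if (!is.null(depth)) geno[depth < depth_min] <- NA
  n <- ncol(geno)
  called <- rowSums(!is.na(geno))
  p_alt <- rowSums(geno, na.rm = TRUE) / (2 * called)
  maf <- pmin(p_alt, 1 - p_alt)
  kept <- called / n >= 1 - max_missing & !is.na(maf) & maf >= maf_min
  list(geno = geno[kept, , drop = FALSE], kept = kept)
}

# Standard genetic code lookup (no alternative-initiator handling).
translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[toupper(codon)]]
  if (is.null(aa)) stop("not a codon: ", codon)
  aa
}

#' Is a SNP synonymous with respect to an ORF?
#'
#' Substitutes the alternate allele into the codon containing the SNP and
#' compares the translations (standard genetic code). SNPs outside the ORF
#' are undetermined (`NA`), and excluded from the synonymous set.
#'
#' @param pos 1-based SNP position on the transcript.
#' @param ref,alt Single reference / alternate bases (forward strand).
#' @param orf One ORF as a list/row with start, end (0-based half-open,
#'   forward-strand coordinates) and strand.
#' @param sequence Transcript sequence.
#' @return TRUE, FALSE, or NA (outside the ORF).
#' @export
annotate_synonymous <- function(pos, ref, alt, orf, sequence) {
  if (pos < 1 || pos > nchar(sequence)) stop("position outside transcript")
  p0 <- pos - 1L                           # 0-based
  if (p0 < orf$start || p0 >= orf$end) return(NA)
  seq_ref <- toupper(sequence)
  if (substr(seq_ref, pos, pos) != toupper(ref))
    stop("reference allele does not match the transcript sequence")
  if (orf$strand == "+") {
    off <- p0 - orf$start
    cstart <- orf$start + (off %/% 3L) * 3L
    cod_ref <- substr(seq_ref, cstart + 1L, cstart + 3L)
    within <- off %% 3L + 1L
    cod_alt <- cod_ref
    substr(cod_alt, within, within) <- toupper(alt)
  } else {
    rc <- revcomp(seq_ref)
    n <- nchar(seq_ref)
    p0r <- n - 1L - p0                     # position on minus strand
    start_r <- n - orf$end                 # ORF start on minus strand
    off <- p0r - start_r
    cstart <- start_r + (off %/% 3L) * 3L
    cod_ref <- substr(rc, cstart + 1L, cstart + 3L)
    within <- off %% 3L + 1L
    cod_alt <- cod_ref
    substr(cod_alt, within, within) <- revcomp(toupper(alt))
  }
  translate_codon(cod_ref) == translate_codon(cod_alt)
}

#' Thin to one SNP per transcript (first on the longest isoform)
#'
#' For each gene, only its longest isoform is considered (ties broken by
#' lexicographically smallest isoform id); among that isoform's SNPs the one
#' with the smallest position is kept. Genes whose SNPs all sit on shorter
#' isoforms contribute nothing.
#'
#' @param records data.frame with columns transcript_id (isoform id), pos,
#'   and gene_id (optional; derived from transcript_id if absent).
#' @param isoforms data.frame with columns transcript_id, gene_id, length.
#' @return The retained subset of `records`.
#' @export
thin_one_per_transcript <- function(records, isoforms) {
  if (is.null(records$gene_id)) {
    m <- match(records$transcript_id, isoforms$transcript_id)
    if (anyNA(m)) stop("SNP on transcript with no isoform length")
    records$gene_id <- isoforms$gene_id[m]
  }
  o <- order(isoforms$gene_id, -isoforms$length, isoforms$transcript_id)
  iso <- isoforms[o, , drop = FALSE]
  longest <- iso$transcript_id[!duplicated(iso$gene_id)]
  rec <- records[records$transcript_id %in% longest, , drop = FALSE]
  if (!nrow(rec)) return(rec)
  o <- order(rec$gene_id, rec$pos)
  rec <- rec[o, , drop = FALSE]
  rec[!duplicated(rec$gene_id), , drop = FALSE]
}

#' Weir-Cockerham variance components for one locus
#'
#' Computes the among-population (a), among-individuals-within-population
#' (b) and within-individual (c) components of Weir & Cockerham (1984) from
#' diploid dosages in two or more groups. Returns NA components when a group
#' has fewer than the required callable samples.
#'
#' @param dosage Numeric vector of alt dosages (0/1/2, NA allowed).
#' @param groups Factor/character of group labels, same length.
#' @return Named numeric vector c(a, b, c).
#' @keywords internal
wc_components <- function(dosage, groups) {
  ok <- !is.na(dosage)
  dosage <- dosage[ok]
  g <- factor(groups[ok])
  n_i <- as.numeric(table(g))
  r <- length(n_i)
  if (r < 2 || any(n_i < 1)) return(c(a = NA_real_, b = NA_real_,
                                      c = NA_real_))
  p_i <- tapply(dosage, g, function(x) sum(x) / (2 * length(x)))
  h_i <- tapply(dosage, g, function(x) mean(x == 1))
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n_i * p_i) / (r * nbar)
  s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n_i * h_i) / (r * nbar)
  if (nbar <= 1 || nc == 0) return(c(a = NA_real_, b = NA_real_,
                                     c = NA_real_))
  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) *
       (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 -
       (2 * nbar - 1) / (4 * nbar) * hbar)
  c_ <- hbar / 2
  c(a = a, b = b, c = c_)
}

#' Multi-locus Weir-Cockerham FST (ratio of sums)
#'
#' Estimates theta = sum(a) / sum(a + b + c) across loci, the standard
#' multi-locus Weir & Cockerham (1984) estimator. Negative estimates are
#' retained (not clamped). Loci with undefined components (e.g. a group with
#' no callable genotypes) or zero total variance are skipped and counted.
#'
#' @param geno Dosage matrix (loci x samples), values 0/1/2/NA.
#' @param groups Group labels per sample (exactly two groups).
#' @return List of class `fst_estimate`: theta, component_sums (a, b, c),
#'   n_loci (used), n_skipped, per_locus (data.frame of components).
#' @export
wc_fst <- function(geno, groups) {
  groups <- as.character(groups)
  if (length(unique(groups)) != 2L)
    stop("wc_fst requires exactly two groups")
  comp <- t(apply(geno, 1L, wc_components, groups = groups))
  tot <- rowSums(comp)
  usable <- !is.na(tot) & tot != 0
  sums <- colSums(comp[usable, , drop = FALSE])
  structure(list(theta = sums[["a"]] / sum(sums),
                 component_sums = sums,
                 n_loci = sum(usable),
                 n_skipped = sum(!usable),
                 per_locus = as.data.frame(comp)),
            class = "fst_estimate")
}

#' @export
print.fst_estimate <- function(x, ...) {
  cat(sprintf("Weir-Cockerham multi-locus FST: theta = %.4f (%d loci",
              x$theta, x$n_loci))
  if (!is.null(x$ci_low))
    cat(sprintf("; %d%% CI %.4f-%.4f, %d bootstrap reps",
                round(100 * x$level), x$ci_low, x$ci_high, x$n_bootstrap))
  cat(")\n")
  invisible(x)
}

#' Bootstrap confidence interval for multi-locus FST
#'
#' Resamples loci with replacement `n_reps` times, recomputes the
#' ratio-of-sums theta for each replicate, and returns the percentile
#' interval.
#'
#' @inheritParams wc_fst
#' @param n_reps Number of bootstrap replicates (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Optional seed for the resampling stream.
#' @return An `fst_estimate` (as [wc_fst()]) augmented with ci_low, ci_high,
#'   n_bootstrap, level.
#' @export
bootstrap_ci <- function(geno, groups, n_reps = 1000L, level = 0.95,
                         seed = NULL) {
  if (n_reps < 2L) stop("n_reps must be >= 2")
  if (nrow(geno) < 2L) stop("bootstrap needs >= 2 loci")
  est <- wc_fst(geno, groups)
  comp <- as.matrix(est$per_locus)
  tot <- rowSums(comp)
  comp <- comp[!is.na(tot) & tot != 0, , drop = FALSE]
  run <- function() {
    thetas <- vapply(seq_len(n_reps), function(i) {
      idx <- sample.int(nrow(comp), nrow(comp), replace = TRUE)
      s <- colSums(comp[idx, , drop = FALSE])
      s[["a"]] / sum(s)
    }, numeric(1))
    stats::quantile(thetas, c((1 - level) / 2, 1 - (1 - level) / 2),
                    names = FALSE, na.rm = TRUE)
  }
  q <- if (is.null(seed)) run() else with_seed(seed, run())
  est$ci_low <- q[1]
  est$ci_high <- q[2]
  est$n_bootstrap <- as.integer(n_reps)
  est$level <- level
  est
}

#' Pearson chi-square test of independence on a 2x2 table
#'
#' Wraps [stats::chisq.test()] with the continuity correction off by
#' default; the Yates-corrected statistic is available via `yates = TRUE`.
#'
#' @param table 2x2 matrix of non-negative counts; all margins must be
#'   positive.
#' @param yates Apply the Yates continuity correction (default FALSE).
#' @return List of class `contingency_test`: table, statistic, df, p,
#'   correction.
#' @export
chi2_association <- function(table, yates = FALSE) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2L), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("all margins must be positive")
  ct <- suppressWarnings(stats::chisq.test(table, correct = yates))
  structure(list(table = table,
                 statistic = unname(ct$statistic),
                 df = 1L,
                 p = unname(ct$p.value),
                 correction = yates),
            class = "contingency_test")
}

#' Equilibrium differentiation of a two-deme symmetric island model
#'
#' At migration-drift equilibrium, a symmetric island model with d demes of
#' N diploids and migration rate m per lineage per generation has
#' FST ~= 1 / (1 + 4 N m (d/(d-1))^2); for two demes this is
#' 1 / (1 + 16 N m). This closed form parameterises the Balding-Nichols
#' beta approximation used by [gen_genotypes()].
#'
#' @param N Diploid deme size.
#' @param m Migration rate per lineage per generation.
#' @param d Number of demes (default 2).
#' @return Expected equilibrium FST.
#' @export
island_model_fst <- function(N, m, d = 2) {
  1 / (1 + 4 * N * m * (d / (d - 1))^2)
}

#' Simulated multi-locus FST under a two-deme island model
#'
#' Converts the island-model parameters to their equilibrium
#' differentiation via [island_model_fst()], simulates unlinked biallelic
#' SNPs from the Balding-Nichols beta approximation at that F, applies a
#' post-simulation minor-allele-frequency filter, and returns the
#' multi-locus Weir-Cockerham estimate on exactly `n_snps` retained loci.
#'
#' @param N Diploid deme size.
#' @param m Migration rate per lineage per generation.
#' @param n_per_group Diploid sample sizes for the two demes.
#' @param n_snps Number of post-filter SNPs to use (default 2524).
#' @param maf_min Minor-allele-frequency filter (default 0.1).
#' @param seed Simulation seed.
#' @return List: theta, F_expected, n_loci.
#' @export
simulate_island_fst <- function(N, m, n_per_group, n_snps = 2524L,
                                maf_min = 0.1, seed = 1L) {
  F <- island_model_fst(N, m)
  buffer <- 1.4
  for (i in 1:6) {
    cfg <- simulation_config(seed = seed, diff_param = F,
                             n_snps = ceiling(n_snps * buffer),
                             n_per_group = n_per_group)
    gt <- gen_genotypes(cfg)
    flt <- filter_snps(gt$geno, depth = NULL, maf_min = maf_min,
                       max_missing = 1)
    if (nrow(flt$geno) >= n_snps) break
    buffer <- buffer * 1.5
  }
  if (nrow(flt$geno) < n_snps)
    stop("could not obtain enough post-filter SNPs")
  geno <- flt$geno[seq_len(n_snps), , drop = FALSE]
  est <- wc_fst(geno, gt$groups)
  list(theta = est$theta, F_expected = F, n_loci = est$n_loci)
}
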