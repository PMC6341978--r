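#' Generate diploid genotypes under the Balding-Nichols model
#'
#' For each SNP an ancestral allele frequency p ~ Uniform(0.1, 0.9) is
#' drawn; the two group frequencies are then drawn independently from
#' Beta(p(1-F)/F, (1-p)(1-F)/F) with F = `cfg$diff_param`, so that the
#' expected allele-frequency variance between groups matches F. Diploid
#' genotypes are binomial draws from the group frequency, and per-genotype
#' sequencing depths are Poisson with mean `cfg$mean_depth`.
#'
#' When `transcripts` (from [gen_meta_transcriptome()]) are supplied, SNPs
#' are placed at known codon positions inside the generated ORFs: a fraction
#' `cfg$frac_synonymous` at four-fold degenerate third codon positions
#' (synonymous by construction) and the remainder at second codon positions
#' (nonsynonymous by construction), so downstream synonymous annotation has
#' a controlled truth. Without transcripts, loci are labelled snp00001... on
#' a dummy contig.
#'
#' @param cfg A [simulation_config()].
#' @param transcripts Optional result of [gen_meta_transcriptome()].
#' @return List with
#'   \describe{
#'     \item{geno}{dosage matrix (loci x samples)}
#'     \item{depth}{depth matrix, same shape}
#'     \item{sites}{data.frame: transcript_id, pos, ref, alt,
#'       synonymous_truth}
#'     \item{groups}{group label per sample}
#'     \item{truth}{list with `true_diff_param`, `group_freqs`}
#'   }
#' @export
gen_genotypes <- function(cfg, transcripts = NULL) {
  validate_sim_config(cfg)
  with_seed(stream_seed(cfg, "genotypes"), {
    L <- cfg$n_snps
    n1 <- cfg$n_per_group[1]
    n2 <- cfg$n_per_group[2]
    F <- cfg$diff_param
    p <- stats::runif(L, 0.1, 0.9)
    shape_mult <- (1 - F) / F
    p1 <- stats::rbeta(L, p * shape_mult, (1 - p) * shape_mult)
    p2 <- stats::rbeta(L, p * shape_mult, (1 - p) * shape_mult)
    g1 <- matrix(stats::rbinom(L * n1, 2L, rep(p1, n1)), nrow = L)
    g2 <- matrix(stats::rbinom(L * n2, 2L, rep(p2, n2)), nrow = L)
    geno <- cbind(g1, g2)
    depth <- matrix(stats::rpois(length(geno), cfg$mean_depth),
                    nrow = L)
    groups <- rep(c("group1", "group2"), c(n1, n2))
    colnames(geno) <- colnames(depth) <-
      sprintf("s%02d", seq_len(n1 + n2))
    sites <- place_snp_sites(L, transcripts, cfg$frac_synonymous)
    rownames(geno) <- rownames(depth) <-
      paste(sites$transcript_id, sites$pos, sep = ":")
    list(geno = geno, depth = depth, sites = sites, groups = groups,
         truth = list(true_diff_param = F,
                      group_freqs = cbind(p1 = p1, p2 = p2)))
  })
}

# Pick SNP sites. With transcripts: synonymous SNPs at third positions of
# four-fold degenerate codons (ref stays, alt is another base: always
# synonymous); nonsynonymous SNPs at second codon positions (always changes
# the amino acid for the codons chosen).
place_snp_sites <- function(L, transcripts, frac_synonymous = 0.5) {
  if (is.null(transcripts)) {
    return(data.frame(transcript_id = sprintf("snp%05d", seq_len(L)),
                      pos = 1L, ref = "A", alt = "G",
                      synonymous_truth = NA,
                      stringsAsFactors = FALSE))
  }
  seqs <- transcripts$sequences
  ids <- sample(names(seqs), L, replace = TRUE)
  fourfold <- c("GC", "GG", "CC", "CG", "CT", "GT", "TC", "AC")
  pos <- integer(L)
  ref <- alt <- character(L)
  syn <- logical(L)
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(L)) {
    s <- seqs[[ids[i]]]
    ncod <- (nchar(s) - 6L) %/% 3L          # interior codons
    want_syn <- stats::runif(1) < frac_synonymous
    placed <- FALSE
    for (try in 1:50) {
      k <- sample.int(ncod, 1L)             # interior codon index
      cstart <- 3L + (k - 1L) * 3L          # 0-based codon start
      cod <- substr(s, cstart + 1L, cstart + 3L)
      if (want_syn) {
        if (substr(cod, 1L, 2L) %in% fourfold) {
          pos[i] <- cstart + 3L             # 1-based third position
          ref[i] <- substr(cod, 3L, 3L)
          alt[i] <- sample(setdiff(bases, ref[i]), 1L)
          syn[i] <- TRUE
          placed <- TRUE
          break
        }
      } else {
        p2 <- substr(cod, 2L, 2L)
        for (b in sample(setdiff(bases, p2))) {
          cod_alt <- cod
          substr(cod_alt, 2L, 2L) <- b
          if (cod_alt %in% c("TAA", "TAG", "TGA")) next
          if (translate_codon(cod) != translate_codon(cod_alt)) {
            pos[i] <- cstart + 2L
            ref[i] <- p2
            alt[i] <- b
            syn[i] <- FALSE
            placed <- TRUE
            break
          }
        }
        if (placed) break
      }
    }
    if (!placed) {                           # fall back to any third position
      k <- sample.int(ncod, 1L)
      cstart <- 3L + (k - 1L) * 3L
      pos[i] <- cstart + 3L
      ref[i] <- substr(s, pos[i], pos[i])
      alt[i] <- sample(setdiff(bases, ref[i]), 1L)
      cod <- substr(s, cstart + 1L, cstart + 3L)
      cod_alt <- cod
      substr(cod_alt, 3L, 3L) <- alt[i]
      syn[i] <- translate_codon(cod) == translate_codon(cod_alt)
    }
  }
  data.frame(transcript_id = ids, pos = pos, ref = ref, alt = alt,
             synonymous_truth = syn, stringsAsFactors = FALSE)
}

#' Write genotypes as a minimal VCF 4.2 file
#'
#' Emits fixed columns plus GT:DP sample fields; genotypes are unphased
#' ("0/0", "0/1", "1/1", "./.").
#'
#' @param gt Result of [gen_genotypes()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gt, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=holotrx",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", colnames(gt$geno)),
                     collapse = "\t")), con)
  gt_code <- c("0/0", "0/1", "1/1")
  field <- matrix(ifelse(is.na(gt$geno), "./.",
                         gt_code[gt$geno + 1L]),
                  nrow = nrow(gt$geno))
  field <- matrix(paste(field, gt$depth, sep = ":"),
                  nrow = nrow(gt$geno))
  lines <- paste(gt$sites$transcript_id, gt$sites$pos, ".",
                 gt$sites$ref, gt$sites$alt, ".", "PASS", ".", "GT:DP",
                 apply(field, 1L, paste, collapse = "\t"),
                 sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read a VCF file into dosage and depth matrices
#'
#' Uses vcfR to parse the file; multi-allelic and non-SNP records are
#' dropped.
#'
#' @param path VCF file (plain text or bgzipped).
#' @return List with geno (dosage matrix), depth (or NULL if no DP),
#'   sites (data.frame transcript_id, pos, ref, alt).
#' @export
read_vcf_genotypes <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  biallelic <- !grepl(",", fix[, "ALT"]) &
    nchar(fix[, "REF"]) == 1L & nchar(fix[, "ALT"]) == 1L
  gt_char <- vcfR::extract.gt(v, element = "GT")
  gt_char <- gsub("|", "/", gt_char, fixed = TRUE)
  dosage <- matrix(NA_integer_, nrow = nrow(gt_char), ncol = ncol(gt_char),
                   dimnames = dimnames(gt_char))
  dosage[gt_char == "0/0"] <- 0L
  dosage[gt_char %in% c("0/1", "1/0")] <- 1L
  dosage[gt_char == "1/1"] <- 2L
  depth <- tryCatch(
    vcfR::extract.gt(v, element = "DP", as.numeric = TRUE),
    error = function(e) NULL)
  sites <- data.frame(transcript_id = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]),
                      ref = fix[, "REF"], alt = fix[, "ALT"],
                      stringsAsFactors = FALSE)
  list(geno = dosage[biallelic, , drop = FALSE],
       depth = if (!is.null(depth)) depth[biallelic, , drop = FALSE],
       sites = sites[biallelic, , drop = FALSE])
}
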