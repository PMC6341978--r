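#!/usr/bin/env Rscript
# Generate the synthetic holobiont datasets every later step consumes:
# meta-transcriptome FASTA + homology evidence, ITS2 read pairs, count and
# FPKM matrices with planted effects, genotypes as VCF, and pfam2go-style
# annotations. Everything is reproducible from the single config written
# alongside the outputs.

suppressMessages(library(holotrx))
out <- "results/simdata"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config(
  seed = 20130114L,           # collection-season datestamp as seed
  n_host = 2000L, n_symbiont = 2000L, evidence_fraction = 0.5,
  n_samples = 24L, n_its2_reads = 2000L,
  clade_mixtures = c(0, 0.12, 0.33, 0.67, 0.91, 1),
  n_genes = 2000L, n_deg_site = 200L, n_deg_clade = 100L, lfc_effect = 2,
  module_spec = list(list(size = 100, loading = 0.8, trait = "clade"),
                     list(size = 100, loading = 0.8),
                     list(size = 100, loading = 0.8)),
  n_snps = 2600L, diff_param = 0.046, n_per_group = c(11L, 6L))
write_sim_config(cfg, file.path(out, "config.yaml"))

tx <- gen_meta_transcriptome(cfg)
write_fasta(tx$sequences, file.path(out, "meta_transcriptome.fasta"))
utils::write.table(tx$evidence, file.path(out, "homology_evidence.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(tx$info, file.path(out, "transcript_info.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

refs <- make_its2_references()
write_fasta(c(C31 = refs$refC, D1a = refs$refD),
            file.path(out, "its2_references_synthetic.fasta"))
reads <- gen_its2_reads(cfg, refs$refC, refs$refD)
write_fastq_pairs(reads$samples[[1]]$r1, reads$samples[[1]]$r2,
                  file.path(out, "its2_s01"))

sim <- gen_counts(cfg)
utils::write.table(data.frame(gene = rownames(sim$counts), sim$counts),
                   file.path(out, "counts.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(data.frame(gene = rownames(sim$fpkm),
                              round(sim$fpkm, 4)),
                   file.path(out, "fpkm.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(sim$design, file.path(out, "metadata.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

gt <- gen_genotypes(cfg, tx)
write_vcf(gt, file.path(out, "genotypes.vcf"))

ann <- gen_annotations(cfg, genes = rownames(sim$counts),
                       enriched_genes = names(
                         sim$truth$deg_labels)[sim$truth$deg_labels !=
                                                 "null"],
                       enrichment_factor = 5)
writeLines(ann$pfam2go_lines, file.path(out, "pfam2go.txt"))
utils::write.table(ann$gene_domains, file.path(out, "gene_domains.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

saveRDS(list(tx = tx, reads = reads, sim = sim, gt = gt, ann = ann,
             refs = refs, cfg = cfg),
        "scratch/simdata.rds")   # binary cache for the later steps only
cat("Simulated:", length(tx$sequences), "transcripts,",
    cfg$n_samples, "samples,", nrow(sim$counts), "genes,",
    nrow(gt$geno), "SNPs\n")
cat("Outputs under", out, "(plain text); cache under scratch/\n")
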