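#' Run the full synthetic-data workflow
#'
#' Executes the stages in order on generated data - meta-transcriptome
#' simulation and partition, ITS2 typing, differential expression,
#' coexpression network, FST, GO enrichment - and writes every per-stage
#' table plus a run manifest (seed and thresholds applied) under `out_dir`.
#' All randomness derives from `cfg$seed`, so two runs with the same config
#' produce identical bundles.
#'
#' @param cfg A [simulation_config()].
#' @param out_dir Output directory (created if needed).
#' @param stages Character vector of stages to run (default all):
#'   "partition", "typing", "dge", "network", "fst", "enrich".
#' @param gc_cutoff,alpha,mixed_threshold,n_boot Thresholds applied (and
#'   logged): GC partition cutoff, DEG FDR level, mixed-clade outlier
#'   threshold, bootstrap replicates.
#' @return Invisible list of stage results; tables and `manifest.yaml` are
#'   written under `out_dir`.
#' @export
run_pipeline <- function(cfg, out_dir,
                         stages = c("partition", "typing", "dge",
                                    "network", "fst", "enrich"),
                         gc_cutoff = 0.47, alpha = 0.05,
                         mixed_threshold = 0.25, n_boot = 200L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  wt <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)

  if ("partition" %in% stages) {
    tx <- gen_meta_transcriptome(cfg)
    calls <- classify_transcripts(tx$info, tx$evidence,
                                  gc_cutoff = gc_cutoff)
    calls$truth <- tx$truth$transcript_origin[calls$transcript_id]
    wt(calls, "partition_calls.tsv")
    res$partition <- list(calls = calls, tx = tx)
  }

  if ("typing" %in% stages) {
    refs <- make_its2_references()
    reads <- gen_its2_reads(cfg, refs$refC, refs$refD)
    ref_set <- c(C31 = refs$refC, D1a = refs$refD)
    clade_of <- c(C31 = "C", D1a = "D")
    comps <- lapply(names(reads$samples), function(s) {
      sm <- reads$samples[[s]]
      mp <- map_read_pairs(sm$r1, sm$r2, ref_set)
      uc <- count_unique_mappings(mp$alignments, names(ref_set))
      composition(uc, clade_of, sample_id = s,
                  mixed_threshold = mixed_threshold)
    })
    tab <- do.call(rbind, lapply(comps, function(x)
      data.frame(sample = x$sample_id,
                 prop_C = x$proportions[["C"]] %||% NA,
                 prop_D = x$proportions[["D"]] %||% NA,
                 dominant = x$dominant_clade,
                 mixed_outlier = x$mixed_outlier)))
    tab$true_mixture <- reads$truth$true_mixtures
    wt(tab, "clade_composition.tsv")
    res$typing <- tab
  }

  if (any(c("dge", "network", "enrich") %in% stages)) {
    sim <- gen_counts(cfg)
    res$sim_counts <- sim
  }

  if ("dge" %in% stages) {
    keep <- filter_min_count(sim$counts)
    counts <- sim$counts[keep, , drop = FALSE]
    fac <- tmm_factors(counts)
    design <- stats::model.matrix(~ site,
                                  data = transform(sim$design,
                                                   site = factor(site)))
    vw <- voom_weights(counts, fac, design)
    fit <- fit_and_moderate(vw$logcpm, vw$weights, design, c(0, 1))
    degs <- call_degs(fit, alpha = alpha)
    wt(fit$table, "dge_site.tsv")
    n_deg <- length(degs$up) + length(degs$down)
    summary <- data.frame(
      contrast = "site", n_deg = n_deg, n_genes = nrow(counts),
      deg_percent = deg_percentage(n_deg, nrow(counts)))
    wt(summary, "dge_summary.tsv")
    res$dge <- list(fit = fit, degs = degs, summary = summary)
  }

  if ("network" %in% stages) {
    keep <- filter_fpkm(sim$fpkm)
    expr <- log2(sim$fpkm[keep, , drop = FALSE] + 1)
    st <- suppressWarnings(pick_soft_threshold(expr, candidates = c(1, 2,
                                                                    4, 6)))
    a <- adjacency_matrix(expr, st$beta)
    tom <- tom_similarity(a)
    mods <- detect_modules(tom, expr)
    wt(data.frame(gene = names(mods), module = mods),
       "network_modules.tsv")
    res$network <- list(beta = st$beta, modules = mods)
  }

  if ("fst" %in% stages) {
    gt <- gen_genotypes(cfg)
    flt <- filter_snps(gt$geno, gt$depth)
    est <- bootstrap_ci(flt$geno, gt$groups, n_reps = n_boot,
                        seed = stream_seed(cfg, "genotypes") + 1L)
    wt(data.frame(theta = est$theta, ci_low = est$ci_low,
                  ci_high = est$ci_high, n_loci = est$n_loci,
                  n_bootstrap = est$n_bootstrap), "fst.tsv")
    res$fst <- est
  }

  if ("enrich" %in% stages) {
    genes <- rownames(sim$counts)
    deg_genes <- if (!is.null(res$dge))
      c(res$dge$degs$up, res$dge$degs$down) else genes[1:50]
    ann <- gen_annotations(cfg, genes = genes,
                           enriched_genes = deg_genes,
                           enrichment_factor = 5)
    p2g <- parse_pfam2go(lines = ann$pfam2go_lines)
    go <- annotate_genes_go(ann$gene_domains, p2g)
    universe <- unique(go$gene)
    test_set <- intersect(deg_genes, universe)
    if (length(test_set)) {
      enr <- hypergeom_enrich(test_set, go, universe)
      wt(filter_terms(enr, length(test_set)), "enrichment.tsv")
      res$enrich <- enr
    }
  }

  manifest <- list(seed = cfg$seed,
                   thresholds = list(gc_cutoff = gc_cutoff,
                                     mixed_threshold = mixed_threshold,
                                     fdr_alpha = alpha,
                                     maf_min = 0.1, depth_min = 20,
                                     max_missing = 0.05,
                                     n_bootstrap = n_boot),
                   stages = stages)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(res)
}
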