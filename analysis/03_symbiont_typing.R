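#!/usr/bin/env Rscript
# Quantify per-sample Symbiodinium clade composition from the simulated
# ITS2 read pairs: align both mates to the joint C31/D1a reference set,
# count each pair once for the reference it maps to uniquely, and compare
# the recovered clade-D proportions with the generator's mixtures. Also
# profile mismatched reads against the dominant reference.

suppressMessages(library(holotrx))
cache <- readRDS("scratch/simdata.rds")
reads <- cache$reads
refs <- cache$refs
dir.create("results", showWarnings = FALSE)

ref_set <- c(C31 = refs$refC, D1a = refs$refD)
clade_of <- c(C31 = "C", D1a = "D")

rows <- lapply(seq_along(reads$samples), function(i) {
  sm <- reads$samples[[i]]
  mp <- map_read_pairs(sm$r1, sm$r2, ref_set)
  uc <- count_unique_mappings(mp$alignments, names(ref_set))
  cc <- composition(uc, clade_of, sample_id = names(reads$samples)[i])
  dom_ref <- names(ref_set)[clade_of == cc$dominant_clade]
  prof <- mismatch_profile(
    mp$alignments$mismatch[mp$alignments$ref_id == dom_ref])
  data.frame(sample = cc$sample_id,
             count_C31 = uc[["C31"]], count_D1a = uc[["D1a"]],
             prop_C = round(cc$proportions[["C"]], 3),
             prop_D = round(cc$proportions[["D"]], 3),
             dominant = cc$dominant_clade,
             mixed_outlier = cc$mixed_outlier,
             true_mixture = sm$true_mixture,
             mismatch_frac = round(prof$mismatch_fraction, 3))
})
tab <- do.call(rbind, rows)
print(tab, row.names = FALSE)
cat(sprintf("Max |recovered - true| clade-D proportion: %.3f\n",
            max(abs(tab$prop_D - tab$true_mixture))))
cat("Mixed-clade outliers (secondary >= 0.25):",
    paste(tab$sample[tab$mixed_outlier], collapse = ", "), "\n")
utils::write.table(tab, "results/clade_composition.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
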