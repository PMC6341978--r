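#' Generate a pfam2go mapping and per-gene domain assignments
#'
#' Creates `n_terms` GO terms, each tied to one Pfam domain, and assigns
#' domains to genes at random. One configurable term is enriched: its domain
#' is assigned to each gene of `enriched_genes` with probability
#' `base_rate * enrichment_factor` (capped at 1) instead of `base_rate`, so
#' an `enrichment_factor` of 1 plants no signal.
#'
#' @param cfg A [simulation_config()].
#' @param genes Character vector of gene ids (default gene0001...).
#' @param n_terms Number of GO terms / domains (default 20).
#' @param base_rate Probability a given domain is assigned to a given gene
#'   (default 0.05).
#' @param enriched_genes Genes in which the enriched term is overrepresented
#'   (default none).
#' @param enrichment_factor Multiplier on `base_rate` within
#'   `enriched_genes` (default 1 = no enrichment).
#' @return List with
#'   \describe{
#'     \item{pfam2go_lines}{character vector in pfam2go flat syntax
#'       (including a comment header)}
#'     \item{gene_domains}{data.frame gene, pfam}
#'     \item{truth}{list with `enriched_term` (GO id) and
#'       `enriched_domain`}
#'   }
#' @export
gen_annotations <- function(cfg, genes = NULL, n_terms = 20,
                            base_rate = 0.05, enriched_genes = character(),
                            enrichment_factor = 1) {
  stopifnot(n_terms >= 1)
  genes <- genes %||% sprintf("gene%04d", seq_len(cfg$n_genes))
  with_seed(stream_seed(cfg, "annotations"), {
    pf <- sprintf("PF%05d", seq_len(n_terms))
    go <- sprintf("GO:%07d", seq_len(n_terms))
    go_names <- sprintf("synthetic process %d", seq_len(n_terms))
    lines <- c("!version date: synthetic",
               sprintf("Pfam:%s dom_%d > GO:%s ; %s",
                       pf, seq_len(n_terms), go_names, go))
    enr <- sample.int(n_terms, 1L)
    assign_rows <- list()
    in_enr <- genes %in% enriched_genes
    for (t in seq_len(n_terms)) {
      rate <- rep(base_rate, length(genes))
      if (t == enr) rate[in_enr] <- pmin(1, base_rate * enrichment_factor)
      hit <- stats::runif(length(genes)) < rate
      if (any(hit))
        assign_rows[[t]] <- data.frame(gene = genes[hit], pfam = pf[t],
                                       stringsAsFactors = FALSE)
    }
    list(pfam2go_lines = lines,
         gene_domains = do.call(rbind, assign_rows),
         truth = list(enriched_term = go[enr], enriched_domain = pf[enr]))
  })
}
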