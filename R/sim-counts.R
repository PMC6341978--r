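#' Balanced synthetic sample design
#'
#' Builds a sample metadata table with site (waiopae/kiholo), clade (C/D)
#' and GA disease status (healthy/ga) assigned so the three factors are
#' approximately balanced and unconfounded: clade alternates within site,
#' GA status alternates within site-by-clade cells.
#'
#' @param cfg A [simulation_config()].
#' @return data.frame: sample_id, site, clade, ga_status.
#' @export
synthetic_design <- function(cfg) {
  n <- cfg$n_samples
  site <- rep(c("waiopae", "kiholo"), length.out = n)
  ord <- order(site)
  clade <- character(n)
  ga <- character(n)
  for (s in unique(site)) {
    i <- which(site == s)
    clade[i] <- rep(c("C", "D"), length.out = length(i))
    for (cl in c("C", "D")) {
      j <- i[clade[i] == cl]
      ga[j] <- rep(c("healthy", "ga"), length.out = length(j))
    }
  }
  data.frame(sample_id = sprintf("s%02d", seq_len(n)),
             site = site, clade = clade, ga_status = ga,
             stringsAsFactors = FALSE)
}

#' Generate a count matrix with planted effects and modules
#'
#' Counts are negative binomial with mean `library size x relative
#' abundance` and dispersion `cfg$nb_dispersion`. Planted site / clade DEGs
#' shift the log2 mean by +/- `cfg$lfc_effect` in the corresponding group
#' (half up, half down). Each entry of `cfg$module_spec` plants a block of
#' genes sharing a latent Gaussian factor on the log2 scale (per-sample,
#' sd 1, scaled by the loading); a module tied to a trait uses the
#' standardized trait indicator plus noise as its factor. FPKM is computed
#' from the counts, per-gene lengths and per-sample totals.
#'
#' @param cfg A [simulation_config()].
#' @param design Sample metadata (default [synthetic_design()]); must
#'   assign each sample a site, clade and ga_status.
#' @return List with counts, fpkm (genes x samples), lengths, design, and
#'   truth (deg_labels, module_labels, mu, latent_factors).
#' @export
gen_counts <- function(cfg, design = NULL) {
  validate_sim_config(cfg)
  design <- design %||% synthetic_design(cfg)
  if (!all(c("sample_id", "site", "clade", "ga_status") %in% names(design)))
    stop("design must have sample_id, site, clade, ga_status")
  if (nrow(design) != cfg$n_samples && is.null(design))
    stop("design/sample mismatch")
  with_seed(stream_seed(cfg, "counts"), {
    G <- cfg$n_genes
    n <- nrow(design)
    gene_ids <- sprintf("gene%04d", seq_len(G))
    lengths <- stats::setNames(sample(500:3000, G, replace = TRUE),
                               gene_ids)
    base <- stats::rnorm(G, mean = 4, sd = 2)

    deg <- rep("null", G)
    nds <- min(cfg$n_deg_site, G)
    if (nds > 0)
      deg[seq_len(nds)] <- rep(c("site_up", "site_down"), length.out = nds)
    ndc <- min(cfg$n_deg_clade, G - nds)
    if (ndc > 0)
      deg[nds + seq_len(ndc)] <- rep(c("clade_up", "clade_down"),
                                     length.out = ndc)

    module <- rep(0L, G)
    next_gene <- nds + ndc + 1L
    for (m in seq_along(cfg$module_spec)) {
      sz <- cfg$module_spec[[m]]$size
      if (next_gene + sz - 1L > G)
        stop("module_spec exceeds the number of genes")
      module[next_gene:(next_gene + sz - 1L)] <- m
      next_gene <- next_gene + sz
    }

    site_ind <- as.numeric(design$site == "waiopae")
    clade_ind <- as.numeric(design$clade == "D")
    log2mu <- matrix(base, G, n)
    lfc <- cfg$lfc_effect
    log2mu[deg == "site_up", ] <- log2mu[deg == "site_up", , drop = FALSE] +
      lfc * rep(site_ind, each = sum(deg == "site_up"))
    log2mu[deg == "site_down", ] <-
      log2mu[deg == "site_down", , drop = FALSE] -
      lfc * rep(site_ind, each = sum(deg == "site_down"))
    log2mu[deg == "clade_up", ] <-
      log2mu[deg == "clade_up", , drop = FALSE] +
      lfc * rep(clade_ind, each = sum(deg == "clade_up"))
    log2mu[deg == "clade_down", ] <-
      log2mu[deg == "clade_down", , drop = FALSE] -
      lfc * rep(clade_ind, each = sum(deg == "clade_down"))

    latent <- NULL
    if (length(cfg$module_spec)) {
      latent <- matrix(0, n, length(cfg$module_spec))
      for (m in seq_along(cfg$module_spec)) {
        sp <- cfg$module_spec[[m]]
        f <- if (!is.null(sp$trait) && !is.na(sp$trait %||% NA)) {
          ind <- switch(sp$trait,
                        site = site_ind, clade = clade_ind,
                        ga = as.numeric(design$ga_status != "healthy"),
                        stop("unknown module trait: ", sp$trait))
          drop(scale(ind)) + stats::rnorm(n, sd = 0.3)
        } else stats::rnorm(n)
        latent[, m] <- f
        idx <- module == m
        log2mu[idx, ] <- log2mu[idx, , drop = FALSE] +
          sp$loading * rep(f, each = sum(idx))
      }
    }

    rel <- 2^log2mu
    rel <- sweep(rel, 2L, colSums(rel), "/")
    mu <- sweep(rel, 2L, rep(cfg$library_size, length.out = n), "*")
    counts <- matrix(stats::rnbinom(G * n, mu = mu,
                                    size = 1 / cfg$nb_dispersion),
                     G, n, dimnames = list(gene_ids, design$sample_id))
    dimnames(mu) <- dimnames(counts)
    fpkm <- fpkm_from_counts(counts, lengths)
    list(counts = counts, fpkm = fpkm, lengths = lengths, design = design,
         truth = list(deg_labels = stats::setNames(deg, gene_ids),
                      module_labels = stats::setNames(module, gene_ids),
                      mu = mu, latent_factors = latent))
  })
}

#' FPKM from counts, lengths and per-sample totals
#'
#' `fpkm = count / (length/1e3) / (column_total/1e6)` - the naive
#' fragments-per-kilobase-per-million arithmetic.
#'
#' @param counts Count matrix (genes x samples).
#' @param lengths Per-gene lengths in bases, aligned with rows.
#' @return FPKM matrix.
#' @export
fpkm_from_counts <- function(counts, lengths) {
  sweep(counts / (lengths / 1e3), 2L, colSums(counts) / 1e6, "/")
}
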