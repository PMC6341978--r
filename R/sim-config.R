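#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generators into one
#' validated list. The defaults describe the study conditions the generators
#' emulate: a meta-transcriptome with host transcripts around 40% GC and
#' symbiont transcripts around 55% GC (placing the 47% partition cutoff near
#' the optimal decision boundary), 75 bp paired-end reads with a low uniform
#' substitution error rate, negative-binomial counts for 24 samples with
#' planted site and clade effects, and Balding-Nichols genotypes with a known
#' between-group differentiation parameter.
#'
#' @param seed Integer seed; every generator call is deterministic given the
#'   config (identical config implies byte-identical outputs).
#' @param n_host,n_symbiont Number of host / symbiont transcripts.
#' @param gc_host_mean,gc_symbiont_mean,gc_sd Per-transcript GC fraction is
#'   drawn from Normal(mean, gc_sd) truncated to (0, 1).
#' @param evidence_fraction Fraction of transcripts that receive an ortholog
#'   hit to their true reference in the homology-evidence table.
#' @param read_length Read length in bases for simulated paired-end reads.
#' @param error_rate Per-base substitution probability.
#' @param n_samples Number of samples for counts and ITS2 reads.
#' @param clade_mixtures Per-sample proportion of clade-D ITS2 reads, each in
#'   \[0, 1\]; recycled to `n_samples`.
#' @param n_its2_reads ITS2 read pairs per sample.
#' @param n_genes Number of genes in the count matrix.
#' @param n_deg_site,n_deg_clade Planted differentially expressed genes for
#'   the site and clade contrasts (half up, half down).
#' @param lfc_effect Absolute log2 fold change of planted DEGs.
#' @param nb_dispersion Negative-binomial dispersion (1/size).
#' @param library_size Expected per-sample library size (counts).
#' @param module_spec List of module descriptions, each a list with elements
#'   `size` (gene count), `loading` (latent-factor loading in \[0, 1\]) and
#'   optional `trait` (`"site"`, `"clade"` or `"ga"`) tying the module's
#'   latent factor to a sample trait.
#' @param n_snps Number of biallelic SNPs to generate.
#' @param diff_param Between-group differentiation parameter F in (0, 1)
#'   (Balding-Nichols beta model).
#' @param n_per_group Diploid sample sizes for the two groups.
#' @param mean_depth Mean per-genotype sequencing depth (Poisson).
#' @param frac_synonymous Fraction of SNPs planted at synonymous codon
#'   positions when transcripts are supplied to [gen_genotypes()].
#'
#' @return A list of class `"sim_config"`.
#' @export
simulation_config <- function(seed = 1L,
                              n_host = 2000L, n_symbiont = 2000L,
                              gc_host_mean = 0.40, gc_symbiont_mean = 0.55,
                              gc_sd = 0.04,
                              evidence_fraction = 0.5,
                              read_length = 75L, error_rate = 0.003,
                              n_samples = 24L,
                              clade_mixtures = NULL,
                              n_its2_reads = 2000L,
                              n_genes = 2000L,
                              n_deg_site = 200L, n_deg_clade = 100L,
                              lfc_effect = 2, nb_dispersion = 0.1,
                              library_size = 5e5,
                              module_spec = list(),
                              n_snps = 2500L, diff_param = 0.05,
                              n_per_group = c(11L, 6L), mean_depth = 40,
                              frac_synonymous = 0.5) {
  cfg <- list(seed = as.integer(seed),
              n_host = as.integer(n_host),
              n_symbiont = as.integer(n_symbiont),
              gc_host_mean = gc_host_mean,
              gc_symbiont_mean = gc_symbiont_mean,
              gc_sd = gc_sd,
              evidence_fraction = evidence_fraction,
              read_length = as.integer(read_length),
              error_rate = error_rate,
              n_samples = as.integer(n_samples),
              clade_mixtures = clade_mixtures,
              n_its2_reads = as.integer(n_its2_reads),
              n_genes = as.integer(n_genes),
              n_deg_site = as.integer(n_deg_site),
              n_deg_clade = as.integer(n_deg_clade),
              lfc_effect = lfc_effect,
              nb_dispersion = nb_dispersion,
              library_size = library_size,
              module_spec = module_spec,
              n_snps = as.integer(n_snps),
              diff_param = diff_param,
              n_per_group = as.integer(n_per_group),
              mean_depth = mean_depth,
              frac_synonymous = frac_synonymous)
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (length(cfg$seed) != 1L || is.na(cfg$seed))
    stop("seed must be a single integer")
  for (f in c("n_host", "n_symbiont", "n_samples", "n_its2_reads",
              "n_genes", "n_snps", "read_length"))
    if (cfg[[f]] <= 0L) stop(sprintf("%s must be positive", f))
  for (f in c("gc_host_mean", "gc_symbiont_mean"))
    if (cfg[[f]] <= 0 || cfg[[f]] >= 1)
      stop(sprintf("%s must lie in (0, 1)", f))
  if (cfg$gc_sd < 0) stop("gc_sd must be non-negative")
  if (cfg$error_rate < 0 || cfg$error_rate > 1)
    stop("error_rate must lie in [0, 1]")
  if (!is.null(cfg$clade_mixtures) &&
      any(cfg$clade_mixtures < 0 | cfg$clade_mixtures > 1))
    stop("clade_mixtures must lie in [0, 1]")
  if (cfg$diff_param <= 0 || cfg$diff_param >= 1)
    stop("diff_param must lie in (0, 1)")
  if (length(cfg$n_per_group) != 2L || any(cfg$n_per_group < 2L))
    stop("n_per_group must give two group sizes >= 2")
  if (cfg$evidence_fraction < 0 || cfg$evidence_fraction > 1)
    stop("evidence_fraction must lie in [0, 1]")
  for (m in cfg$module_spec) {
    if (is.null(m$size) || is.null(m$loading))
      stop("each module_spec entry needs size and loading")
    if (m$loading < 0 || m$loading > 1)
      stop("module loading must lie in [0, 1]")
  }
  cfg
}

#' Read / write a simulation config as YAML
#'
#' One plain-text file holds the whole [simulation_config()]; the seed is
#' mandatory. `module_spec` round-trips as a list of mappings.
#'
#' @param path File path.
#' @param cfg A `sim_config` object.
#' @return `read_sim_config()` returns a validated `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$seed)) stop("config file must set a seed")
  do.call(simulation_config, raw)
}

#' @rdname read_sim_config
#' @export
write_sim_config <- function(cfg, path) {
  x <- unclass(cfg)
  x <- x[!vapply(x, is.null, logical(1))]
  yaml::write_yaml(x, path)
  invisible(path)
}

# Derive a stream-specific RNG seed from the config seed so that the
# generators are mutually independent but jointly deterministic. Kept
# below 2^31 - 1.
stream_seed <- function(cfg, stream) {
  offsets <- c(transcriptome = 1L, its2 = 2L, counts = 3L,
               genotypes = 4L, annotations = 5L)
  if (!stream %in% names(offsets)) stop("unknown stream: ", stream)
  (abs(cfg$seed) * 97L + offsets[[stream]]) %% 2147483629L
}
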