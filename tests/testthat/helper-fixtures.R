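# Small configs shared across tests. Sizes are kept at desk scale; the
# statistical recovery checks that need the full study conditions live in
# test-acceptance.R.

tiny_config <- function(seed = 1L, ...) {
  args <- list(seed = seed, n_host = 50L, n_symbiont = 50L,
               n_samples = 8L, n_its2_reads = 200L, n_genes = 120L,
               n_deg_site = 10L, n_deg_clade = 6L, n_snps = 60L,
               n_per_group = c(4L, 4L))
  over <- list(...)
  args[names(over)] <- over
  do.call(simulation_config, args)
}

its2_refs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_its2_references()
    cache
  }
})
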