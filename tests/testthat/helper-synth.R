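# Small simulated worlds shared across test files. Sizes are scaled down
# so the full suite stays fast; the acceptance tests use the full stated
# configuration.

tiny_config <- function(seed = 1, ...) {
  args <- list(n_mrna = 400L, n_lnc = 60L, n_immune_sets = 17L,
               genes_per_set = 20L, n_planted_lnc = 8L,
               n_cell_populations = 5L, markers_per_population = 4L,
               de_frac = 0.05, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(synth_config, args)
}

tiny_sim <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 1, ...) {
    key <- paste(seed, deparse(list(...)), collapse = "|")
    if (is.null(cache[[key]]))
      cache[[key]] <- generate_bundle(tiny_config(seed, ...))
    cache[[key]]
  }
})

random_collection <- function(gene_ids, n_sets = 3, size = 8, seed = 1) {
  withr::with_seed(seed, {
    sets <- lapply(seq_len(n_sets), function(i) sample(gene_ids, size))
    names(sets) <- paste0("SET", seq_len(n_sets))
    gene_set_collection(sets)
  })
}
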