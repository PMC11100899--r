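# Shared fixtures; graphs are parsed once per session via a local cache.

fixture_smiles <- c(
  methane = "C", ethane = "CC", ethanol = "CCO",
  benzene = "c1ccccc1", acetic_acid = "CC(=O)O",
  pyridine = "c1ccncc1", benzamide = "NC(=O)c1ccccc1")

fixture_graphs <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- smiles_to_graphs(fixture_smiles)
    stats::setNames(cache, names(fixture_smiles))
  }
})

# A small pool of generator molecules for property-style tests.
property_molecules <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_molecules(synth_config(n_molecules = 120L,
                                                seed = 424242L))
    }
    cache
  }
})

tiny_fp_params <- function(seed = 3L, n_layers = 2L, fp_length = 8L) {
  neuralfp_params(n_layers = n_layers, fp_length = fp_length,
                  conv_width = 5L, seed = seed)
}

# Small labelled synthetic dataset shared by trainer tests.
tiny_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synth_config(n_molecules = 300L, seed = 7L)
      cache <<- prepare_dataset(simulate_screen(cfg), hit_fraction = 0.20,
                                seed = 7L)
    }
    cache
  }
})
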