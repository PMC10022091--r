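# Shared in-code fixtures. Everything is generated programmatically under
# fixed seeds; nothing is read from disk.

# small synthetic experiment reused across tests (cached per session)
small_experiment <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generateSynergyDataset(nDrugs = 10L, nCellLines = 5L,
                                       nGenes = 25L, nRecords = 150L,
                                       seed = 31L)
    }
    cache
  }
})

tiny_encoder <- function(dim = 16L, seed = 5L) {
  smilesEncoder(encoderConfig(dim = dim, layers = 1L, heads = 2L,
                              seed = seed))
}

# access package internals (autodiff plumbing) in tests
dsn <- function(name) get(name, envir = asNamespace("dualsyn"))
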