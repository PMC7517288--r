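# Shared cache for the reciprocity-endpoint sweeps used by several
# acceptance-style tests (each endpoint is a Monte Carlo sweep; computing it
# once per session keeps the suite fast). Scale: N = 500 base networks,
# 3 structures x 25 runs per grid point, r step 0.01, cutoff 5e3 rounds.
endpoint_cache <- new.env(parent = emptyenv())

cached_endpoint <- function(model, p, beta, seed) {
  key <- paste(model, p, beta, sep = "_")
  if (is.null(endpoint_cache[[key]])) {
    endpoint_cache[[key]] <- reciprocity_endpoint(
      model, p = p, beta = beta, n = 500, runs = 25, n_hypergraphs = 3,
      tmax = 5e3, r_from = 0.5, r_step = 0.01, seed = seed)
  }
  endpoint_cache[[key]]
}
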