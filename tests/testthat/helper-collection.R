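# Shared fixture collection (expensive: runs the full differential
# expression pipeline on 6 synthetic datasets). Built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

shared_collection <- function() {
  if (is.null(.fixture_cache$coll)) {
    .fixture_cache$coll <- make_collection(n_signatures = 6, seed = 101)
  }
  .fixture_cache$coll
}

shared_library <- function() {
  if (is.null(.fixture_cache$lib)) {
    coll <- shared_collection()
    genes <- sort(unique(unlist(lapply(coll$collection$signatures,
                                       function(s) names(s$gene_coeffs)))))
    .fixture_cache$lib <- make_library(
      n_sets = 80, set_size_range = c(20, 60), background = genes,
      planted_genes = coll$truth$planted_genes, seed = 202)
  }
  .fixture_cache$lib
}

shared_compounds <- function() {
  if (is.null(.fixture_cache$cpd)) {
    coll <- shared_collection()
    .fixture_cache$cpd <- make_compound_library(
      coll$collection$signatures[[1]], n_compounds = 120, noise_sd = 0.1,
      seed = 303)
  }
  .fixture_cache$cpd
}
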