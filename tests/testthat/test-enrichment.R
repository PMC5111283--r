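test_that("hypergeometric p matches exhaustive enumeration for N <= 30", {
  worst <- 0
  for (N in c(5, 12, 20, 30)) {
    for (K in 1:N) {
      for (q in 1:N) {
        xmax <- min(K, q)
        for (x in 0:xmax) {
          p <- hypergeom_p(N, K, q, x)
          worst <- max(worst, abs(p - hyper_oracle(N, K, q, x)))
        }
      }
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("hypergeometric endpoints and the worked example are exact", {
  expect_equal(hypergeom_p(20, 5, 4, 4), 5 / 4845, tolerance = 1e-14)
  expect_equal(hypergeom_p(100, 10, 5, 0), 1)
  # K = N: every query gene is in the set, overlap is forced to q
  expect_equal(hypergeom_p(15, 15, 6, 6), 1)
  expect_error(hypergeom_p(10, 11, 3, 2), "exceed the background")
  expect_error(hypergeom_p(10, 4, 3, 5), "overlap cannot exceed")
})

test_that("hypergeometric p is non-increasing in the overlap", {
  for (seed in 1:10) {
    set.seed(seed)
    N <- sample(10:200, 1)
    K <- sample(1:N, 1)
    q <- sample(1:N, 1)
    p <- vapply(0:min(K, q), function(x) hypergeom_p(N, K, q, x), numeric(1))
    expect_true(all(diff(p) <= 1e-15))
  }
})

test_that("rank calibration is symmetric for identical sets and deterministic", {
  sets <- setNames(rep(list(sprintf("G%03d", 1:25)), 10),
                   paste0("T", 1:10))
  lib <- gene_set_library("ident", sets, background_size = 200)
  cal <- calibrate_ranks(lib, query_size = 20, n_draws = 1000, seed = 5)
  # all terms tie every draw; lexicographic tie-break spreads ranks 1..10
  # uniformly only across term names, so each term keeps a fixed rank and
  # mean ranks enumerate 1..10 -- the *average over terms* is 5.5
  expect_equal(mean(cal$mean_rank), 5.5, tolerance = 1e-9)
  expect_true(all(cal$sd_rank >= 0.1))

  cal2 <- calibrate_ranks(lib, query_size = 20, n_draws = 1000, seed = 5)
  expect_identical(cal$mean_rank, cal2$mean_rank)
  expect_error(calibrate_ranks(lib, 20, n_draws = 10), ">= 50")
})

test_that("enrichment recovers a planted term and respects the combined-score identity", {
  set.seed(11)
  background <- sprintf("G%04d", 1:1000)
  planted <- sample(background, 20)
  lib <- make_library(n_sets = 60, set_size_range = c(25, 40),
                      background = background, planted_genes = planted,
                      seed = 11)
  cal <- calibrate_ranks(lib$library, 20, n_draws = 200, seed = 12)
  res <- enrich_gene_set(planted, lib$library, cal, direction = "up")
  expect_equal(res$term[1], lib$truth$planted_term)
  expect_equal(res$rank[1], 1L)
  expect_equal(res$combined, log(res$p) * res$z)
  expect_true(all(res$p > 0 & res$p <= 1))
  expect_true(all(res$overlap <= 20))
})

test_that("at most top_n records are returned and p = 1 maps to combined = 0", {
  set.seed(13)
  background <- sprintf("G%03d", 1:300)
  sets <- lapply(1:200, function(i) sample(background, 30))
  names(sets) <- sprintf("S%03d", 1:200)
  lib <- gene_set_library("many", sets)
  cal <- calibrate_ranks(lib, 20, n_draws = 60, seed = 14)
  res <- enrich_gene_set(sample(background, 20), lib, cal)
  expect_equal(nrow(res), 50)

  # a term disjoint from the query has overlap 0 hence p = 1 and combined 0
  lib2 <- gene_set_library("two", list(HIT = background[1:20],
                                       MISS = background[101:120]),
                           background_size = 300)
  cal2 <- calibrate_ranks(lib2, 10, n_draws = 60, seed = 15)
  res2 <- enrich_gene_set(background[1:10], lib2, cal2)
  miss <- res2[res2$term == "MISS", ]
  expect_equal(miss$p, 1)
  expect_equal(miss$combined, 0)
})

test_that("empty queries yield an empty result with a warning", {
  lib <- gene_set_library("l", list(T1 = c("A", "B", "C")))
  cal <- calibrate_ranks(lib, 2, n_draws = 60, seed = 1)
  expect_warning(res <- enrich_gene_set("ZZZ", lib, cal), "empty")
  expect_equal(nrow(res), 0)
})

test_that("the enrichment matrix outer-joins up/down columns with zero fill", {
  coll <- shared_collection()
  lib <- shared_library()
  em <- build_enrichment_matrix(coll$collection, lib$library,
                                alpha = 0.01, seed = 7)
  ids <- names(coll$collection$signatures)
  expect_equal(ncol(em$values), 2 * length(ids))
  expect_setequal(colnames(em$values),
                  c(paste0(ids, "|up"), paste0(ids, "|down")))
  expect_false(anyDuplicated(rownames(em$values)) > 0)
  # every cell is either 0 (absent pair) or a retained combined score
  expect_true(all(is.finite(em$values)))
  # each column retains at most 50 terms
  expect_true(all(colSums(em$values != 0) <= 50))
  # the planted term must be present: every signature shares the theme
  expect_true(lib$truth$planted_term %in% rownames(em$values))
})

test_that("a signature with no significant genes yields all-zero columns", {
  # noise-only signature: huge p-values everywhere
  genes <- sprintf("G%04d", 1:50)
  b <- random_unit_signature(genes, 3)
  sig <- gene_signature("null_sig", b,
                        pvalues = setNames(rep(0.9, 50), genes),
                        adjusted_pvalues = setNames(rep(0.95, 50), genes))
  strong <- gene_signature(
    "strong_sig", random_unit_signature(genes, 4),
    pvalues = setNames(rep(0.001, 50), genes),
    adjusted_pvalues = setNames(rep(0.002, 50), genes))
  coll <- signature_collection("mix", list(sig, strong))
  lib <- gene_set_library("l", list(T1 = genes[1:20], T2 = genes[21:40]),
                          background_size = 50)
  em <- build_enrichment_matrix(coll, lib, alpha = 0.01, seed = 2)
  expect_true(all(em$values[, "null_sig|up"] == 0))
  expect_true(all(em$values[, "null_sig|down"] == 0))
  expect_gt(sum(em$values[, "strong_sig|up"] != 0) +
            sum(em$values[, "strong_sig|down"] != 0), 0)
})
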