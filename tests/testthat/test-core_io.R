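test_that("GMT parsing uppercases symbols, skips empty fields, rejects malformed input", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("T1\tdesc\tA\tB\tC",
               "T2\tdesc\ta\t\tb"), f)
  lib <- read_gmt(f)
  expect_setequal(lib$sets$T1, c("A", "B", "C"))
  expect_setequal(lib$sets$T2, c("A", "B"))
  expect_equal(lib$background_size, 3)

  writeLines(c("T1\tdesc\tA", "T1\tdesc\tB"), f)
  expect_error(read_gmt(f), "duplicate term")
  writeLines(c("T1\tdesc\tA", "ONLYTWO\tFIELDS"), f)
  expect_error(read_gmt(f), "line 2")
})

test_that("GMT round-trips preserve the term -> set mapping", {
  f <- withr::local_tempfile(fileext = ".gmt")
  sets <- list(ALPHA = c("TP53", "MYC", "EGFR"),
               BETA = c("GATA1", "TAL1"),
               GAMMA = c("TP53", "SOX2", "NANOG", "POU5F1"))
  lib <- gene_set_library("toy", sets)
  write_gmt(lib, f)
  back <- read_gmt(f)
  expect_setequal(names(back$sets), names(lib$sets))
  for (nm in names(sets)) expect_setequal(back$sets[[nm]], lib$sets[[nm]])
})

test_that("expression reading enforces labels, class sizes and species", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2\ts3\ts4",
               "G1\t1\t2\t3\t4",
               "G2\t2\t2\t2\t2",
               "G3\tNA\t1\t1\t1"), f)
  labs <- c(s1 = "control", s2 = "control",
            s3 = "perturbation", s4 = "perturbation")
  expect_message(ds <- read_expression(f, labs, "human"), "1 row")
  expect_equal(rownames(ds$values), c("G1", "G2"))
  expect_equal(sum(ds$class_labels == "control"), 2)

  bad <- c(s1 = "control", s2 = "perturbation",
           s3 = "perturbation", s4 = "perturbation")
  expect_error(read_expression(f, bad, "human"), ">=2")
  expect_error(suppressMessages(read_expression(f, labs, "zebrafish")),
               "human, mouse, rat")
})

test_that("probe collapsing averages probes per gene and drops unmapped probes", {
  m <- matrix(c(2, 4, 10, 6, 8, 20), nrow = 3,
              dimnames = list(c("p1", "p2", "p3"),
                              c("s1", "s2")))
  m <- cbind(m, m + 1)
  colnames(m) <- c("s1", "s2", "s3", "s4")
  ds <- toy_dataset(m)
  pm <- c(p1 = "Gene1", p2 = "gene1", p3 = "GENE2")
  out <- collapse_probes(ds, pm)
  expect_equal(rownames(out$values), c("GENE1", "GENE2"))
  expect_equal(unname(out$values["GENE1", "s1"]), 3)  # mean of 2 and 4
  expect_equal(unname(out$values["GENE2", ]), unname(m["p3", ]))

  expect_message(out2 <- collapse_probes(ds, pm[1:2]), "1 probe")
  expect_equal(attr(out2, "n_dropped"), 1L)
  expect_error(collapse_probes(ds, c(zz = "X")), "no probes in common")
})

test_that("collapsing an already-collapsed dataset with an identity map is a no-op", {
  m <- matrix(rnorm(8), 2, 4,
              dimnames = list(c("GENE1", "GENE2"), paste0("s", 1:4)))
  ds <- toy_dataset(m)
  idm <- setNames(rownames(m), rownames(m))
  out <- collapse_probes(ds, idm)
  expect_equal(out$values, ds$values)
})

test_that("ortholog mapping is identity for human, table-driven otherwise", {
  tab <- ortholog_table(c("mouse", "mouse", "rat"),
                        c("Trp53", "Myc", "Tp53"),
                        c("TP53", "MYC", "TP53"))
  mm <- map_orthologs(c("Trp53", "Myc", "Nope"), "mouse", tab)
  expect_equal(unname(mm["Trp53"]), "TP53")
  expect_equal(attr(mm, "n_dropped"), 1L)
  expect_false("Nope" %in% names(mm))

  hh <- map_orthologs(c("tp53", "Kras"), "human")
  expect_equal(unname(hh), c("TP53", "KRAS"), ignore_attr = TRUE)

  expect_error(ortholog_table("mouse", c("Myc", "MYC"), c("MYC", "MYCN")),
               "multiple targets")
})

test_that("report matrices round-trip through TSV", {
  m <- matrix(c(pi, -1.5, 1e-7, 123456.789), 2, 2,
              dimnames = list(c("GENE_A", "GENE_B"), c("sig1", "sig2")))
  am <- aggregate_matrix(m)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_report_matrix(am, f)
  expect_length(readLines(f), 3)
  back <- read_report_matrix(f)
  expect_equal(back$values, am$values, tolerance = 1e-11)
  expect_identical(rownames(back$values), rownames(m))

  expect_error(aggregate_matrix(matrix(numeric(0), 0, 0)), "non-empty")
})

test_that("signatures and collections round-trip through JSON", {
  sig1 <- gene_signature("sigA", random_unit_signature(c("TP53", "MYC", "EGFR"), 1),
                         pvalues = c(TP53 = 0.001, MYC = 0.2, EGFR = 0.6),
                         adjusted_pvalues = c(TP53 = 0.003, MYC = 0.3, EGFR = 0.6),
                         metadata = list(organism = "human", tag = "toy"))
  sig2 <- gene_signature("sigB", random_unit_signature(c("TP53", "GATA1"), 2))
  coll <- signature_collection("toy_tag", list(sig1, sig2),
                               provenance = "unit test")
  f <- withr::local_tempfile(fileext = ".json")
  write_collection_json(coll, f)
  back <- read_collection_json(f)
  expect_equal(back$tag, "toy_tag")
  expect_equal(names(back$signatures), c("sigA", "sigB"))
  expect_equal(back$signatures$sigA$gene_coeffs, sig1$gene_coeffs)
  expect_equal(back$signatures$sigA$adjusted_pvalues, sig1$adjusted_pvalues)
  expect_null(back$signatures$sigB$pvalues)
  expect_equal(back$signatures$sigA$metadata$tag, "toy")

  f2 <- withr::local_tempfile(fileext = ".json")
  write_signature_json(sig1, f2)
  expect_equal(read_signature_json(f2)$gene_coeffs, sig1$gene_coeffs)
})

test_that("domain type invariants are enforced", {
  v <- c(A = 0.6, B = 0.8)
  expect_error(gene_signature("x", c(A = 1, B = 1)), "unit norm")
  expect_error(gene_signature("x", v, pvalues = c(A = 0, B = 0.5)), "0, 1")
  expect_error(gene_signature("x", v, pvalues = c(A = 0.5, B = 0.5),
                              adjusted_pvalues = c(A = 0.1, B = 0.5)),
               ">= nominal")
  expect_error(signature_collection("t", list()), "at least one")
  s <- gene_signature("dup", v)
  expect_error(signature_collection("t", list(s, s)), "unique")
  expect_error(gene_set_library("l", list(T1 = character(0))), "non-empty")
  expect_error(compound_signature_library(c("A", "B"),
                                          list(c1 = c(0, 0))), "all-zero")
})
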