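two_block_collection <- function() {
  s1 <- gene_signature("s1", random_unit_signature(c("A", "B"), 1))
  s2 <- gene_signature("s2", random_unit_signature("C", 2))
  signature_collection("blocks", list(s1, s2))
}

test_that("the gene matrix outer-joins signatures with zero fill", {
  coll <- two_block_collection()
  gm <- build_gene_matrix(coll)
  expect_equal(dim(gm$values), c(3L, 2L))
  expect_equal(rownames(gm$values), c("A", "B", "C"))
  expect_equal(unname(gm$values[c("A", "B"), "s2"]), c(0, 0))
  expect_equal(unname(gm$values["C", "s1"]), 0)
  # present coefficients appear unchanged
  expect_equal(gm$values[c("A", "B"), "s1"],
               coll$signatures$s1$gene_coeffs[c("A", "B")])
  expect_equal(unname(abs(gm$values["C", "s2"])), 1)
})

test_that("every stored coefficient is conserved in the unfiltered matrix", {
  coll <- shared_collection()$collection
  gm <- build_gene_matrix(coll)
  for (id in names(coll$signatures)) {
    b <- coll$signatures[[id]]$gene_coeffs
    expect_equal(gm$values[names(b), id], b)
    absent <- setdiff(rownames(gm$values), names(b))
    if (length(absent)) expect_true(all(gm$values[absent, id] == 0))
  }
})

test_that("row filtering agrees with brute-force sort oracles", {
  m <- matrix(c(5, 1, -4, 0, 0, 0), nrow = 3,
              dimnames = list(c("R1", "R2", "R3"), c("c1", "c2")))
  m[, 2] <- c(0, 0, 0)
  am <- aggregate_matrix(m)
  f1 <- filter_rows(am, "sum_change", top_n = 1)
  expect_setequal(rownames(f1$values), c("R1", "R3"))

  for (seed in 1:15) {
    set.seed(seed)
    nr <- sample(5:40, 1)
    mm <- matrix(rnorm(nr * 4), nr,
                 dimnames = list(sprintf("R%02d", 1:nr), paste0("c", 1:4)))
    am <- aggregate_matrix(mm)
    k <- sample(1:3, 1)

    fs <- filter_rows(am, "sum_change", top_n = k)
    s <- rowSums(mm)
    expected <- union(names(sort(s, decreasing = TRUE))[1:k],
                      names(sort(s))[1:k])
    expect_setequal(rownames(fs$values), expected)

    fv <- filter_rows(am, "variance", top_n = k)
    v <- apply(mm, 1, var)
    expect_setequal(rownames(fv$values),
                    names(sort(v, decreasing = TRUE))[1:k])
  }
})

test_that("constant rows lose to varying rows under the variance filter", {
  m <- rbind(FLAT = rep(3, 4),
             VARY = c(1, -2, 5, 0))
  colnames(m) <- paste0("c", 1:4)
  f <- filter_rows(aggregate_matrix(m), "variance", top_n = 1)
  expect_equal(rownames(f$values), "VARY")
})

test_that("filtering more rows than exist keeps all with a warning", {
  m <- matrix(rnorm(6), 3, dimnames = list(paste0("R", 1:3), c("a", "b")))
  expect_warning(f <- filter_rows(aggregate_matrix(m), "variance", 10),
                 "keeping all")
  expect_equal(nrow(f$values), 3)
})

test_that("PCA matches a full-decomposition oracle up to component sign", {
  for (seed in 1:50) {
    set.seed(seed)
    nr <- sample(4:50, 1)
    nc <- sample(4:20, 1)
    m <- matrix(rnorm(nr * nc), nr,
                dimnames = list(sprintf("G%02d", 1:nr),
                                sprintf("s%02d", 1:nc)))
    pc <- pca_signatures(aggregate_matrix(m))
    oracle <- pca_oracle(m)
    for (j in 1:3) {
      expect_equal(abs(pc$coordinates[, j]), abs(oracle$scores[, j]),
                   tolerance = 1e-8, ignore_attr = TRUE)
      expect_equal(pc$variance_explained[j], oracle$varexp[j],
                   tolerance = 1e-8)
    }
    expect_true(all(diff(pc$variance_explained) <= 1e-12))
    expect_lte(sum(pc$variance_explained), 1 + 1e-12)
  }
})

test_that("identical signatures collapse to the origin in PCA", {
  b <- random_unit_signature(sprintf("G%02d", 1:12), 3)
  sigs <- lapply(1:4, function(i) gene_signature(paste0("s", i), b))
  gm <- build_gene_matrix(signature_collection("same", sigs))
  pc <- pca_signatures(gm)
  expect_equal(unname(pc$coordinates), matrix(0, 4, 3))
  expect_equal(pc$variance_explained, rep(0, 3))
})

test_that("PC1 separates two planted clusters", {
  genes <- sprintf("G%02d", 1:10)
  base <- random_unit_signature(genes, 4)
  mk <- function(id, shift) {
    v <- base
    v[1] <- v[1] + shift
    gene_signature(id, v / sqrt(sum(v^2)))
  }
  coll <- signature_collection("clusters", list(
    mk("a1", 0.9), mk("a2", 0.9), mk("a3", 0.92),
    mk("b1", -0.9), mk("b2", -0.9), mk("b3", -0.92)))
  pc <- pca_signatures(build_gene_matrix(coll))
  side <- sign(pc$coordinates[, 1])
  expect_equal(length(unique(side[1:3])), 1)
  expect_equal(length(unique(side[4:6])), 1)
  expect_true(side[1] != side[4])
})

test_that("clustering puts identical columns adjacent and is input-order invariant", {
  set.seed(9)
  m <- matrix(rnorm(40), 8,
              dimnames = list(sprintf("G%d", 1:8),
                              c("w", "x", "y", "z", "q")))
  m[, "y"] <- m[, "x"]  # identical pair
  am <- aggregate_matrix(m)
  ord <- cluster_order(am, "columns")
  labs <- colnames(m)[ord]
  expect_equal(abs(diff(match(c("x", "y"), labs))), 1)

  perm <- c(4, 2, 5, 1, 3)
  am2 <- aggregate_matrix(m[, perm])
  ord2 <- cluster_order(am2, "columns")
  expect_equal(colnames(m[, perm])[ord2], labs)

  expect_error(cluster_order(aggregate_matrix(m[1, , drop = FALSE]), "rows"),
               "at least 2")
})

test_that("zero-norm vectors cluster at unit distance from everything", {
  m <- rbind(A = c(1, 0, 0), B = c(0, 0, 0), C = c(1, 0.01, 0))
  colnames(m) <- paste0("s", 1:3)
  ord <- cluster_order(aggregate_matrix(m), "rows")
  labs <- rownames(m)[ord]
  # A and C are nearly identical; the zero row B is the outlier leaf
  expect_equal(abs(diff(match(c("A", "C"), labs))), 1)
})

test_that("report bundles are deterministic and respect subsets and categories", {
  coll <- shared_collection()$collection
  lib <- shared_library()$library
  cpd <- shared_compounds()$library

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  b1 <- build_report(coll, lib, cpd, seed = 3, out_dir = d1)
  b2 <- build_report(coll, lib, cpd, seed = 3, out_dir = d2)
  for (f in c("gene_matrix.tsv", "enrichment_matrix.tsv",
              "compound_matrix.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  strip_ts <- function(d) {
    j <- readLines(file.path(d, "manifest.json"))
    j[!grepl("timestamp", j)]
  }
  expect_identical(strip_ts(d1), strip_ts(d2))

  ids <- names(coll$signatures)[1:2]
  expect_warning(sub <- build_report(coll, lib, cpd, subset = ids, seed = 3),
                 "fewer than 3 signatures")
  expect_equal(colnames(sub$genes$values), ids)
  expect_equal(ncol(sub$enrichment$values), 4)
  expect_equal(colnames(sub$compounds$values), ids)

  expect_error(build_report(coll, lib, cpd, subset = c("nope")), "unknown")
  expect_error(build_report(coll, lib, cpd, category = "no_field"),
               "available fields")
  cat_bundle <- build_report(coll, lib, cpd, category = "cell_or_tissue",
                             seed = 3)
  expect_equal(length(cat_bundle$pca$categories), length(coll$signatures))
  expect_true(all(cat_bundle$pca$categories %in% c("groupA", "groupB")))
})
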