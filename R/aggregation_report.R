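#' Gene x signature coefficient matrix for a collection
#'
#' Treats each signature as a column vector of characteristic-direction
#' coefficients and concatenates the columns by outer join over the union of
#' genes; genes absent from a signature are filled with zero, meaning no
#' change in expression. Rows are sorted lexicographically.
#'
#' @param collection A [signature_collection].
#' @param alpha Optional adjusted-p threshold; when supplied, only genes
#'   significant at `alpha` contribute their coefficient (others are zero).
#'   Default `NULL` uses every stored coefficient.
#' @return An [aggregate_matrix], rows = genes, columns = signature ids.
#' @export
build_gene_matrix <- function(collection, alpha = NULL) {
  stopifnot(inherits(collection, "signature_collection"))
  ids <- collection_ids(collection)
  genes <- sort(unique(unlist(lapply(collection$signatures,
                                     function(s) names(s$gene_coeffs)),
                             use.names = FALSE)))
  m <- matrix(0, nrow = length(genes), ncol = length(ids),
              dimnames = list(genes, ids))
  for (id in ids) {
    sig <- collection$signatures[[id]]
    b <- sig$gene_coeffs
    if (!is.null(alpha)) {
      if (is.null(sig$adjusted_pvalues))
        stop("alpha filtering requires adjusted p-values on every signature")
      b <- b[sig$adjusted_pvalues[names(b)] <= alpha]
    }
    if (length(b)) m[names(b), id] <- b
  }
  aggregate_matrix(m)
}

#' Filter matrix rows by aggregate change or variance
#'
#' `sum_change` ranks rows by their row sum across signatures and keeps the
#' `top_n` most positive and `top_n` most negative rows (the most
#' consistently up- and down-regulated genes). `variance` keeps the `top_n`
#' rows with the largest row variance. Original row order is preserved; ties
#' are broken by row label.
#'
#' @param matrix An [aggregate_matrix].
#' @param statistic `"sum_change"` or `"variance"`.
#' @param top_n Rows per tail (`sum_change`) or total rows (`variance`).
#' @return A filtered [aggregate_matrix] (clustering orders dropped).
#' @export
filter_rows <- function(matrix, statistic = c("sum_change", "variance"),
                        top_n = 10) {
  stopifnot(inherits(matrix, "aggregate_matrix"))
  statistic <- match.arg(statistic)
  top_n <- as.integer(top_n)
  if (top_n < 1) stop("top_n must be >= 1")
  m <- matrix$values
  labels <- rownames(m)
  keep <- if (statistic == "sum_change") {
    s <- rowSums(m)
    if (top_n > nrow(m)) {
      warning("top_n exceeds the row count; keeping all rows")
      labels
    } else {
      up <- labels[order(-s, labels, method = "radix")][seq_len(top_n)]
      down <- labels[order(s, labels, method = "radix")][seq_len(top_n)]
      union(up, down)
    }
  } else {
    v <- apply(m, 1, stats::var)
    if (top_n >= nrow(m)) {
      if (top_n > nrow(m)) warning("top_n exceeds the row count; keeping all rows")
      labels
    } else {
      labels[order(-v, labels, method = "radix")][seq_len(top_n)]
    }
  }
  aggregate_matrix(m[labels %in% keep, , drop = FALSE])
}

#' Principal component analysis of a signature collection
#'
#' Signatures are the observations (columns of the gene matrix, transposed)
#' and genes the features; features are mean-centered but not variance
#' scaled. The top three components by singular value give each signature a
#' 3-D coordinate; missing components (fewer than three non-degenerate
#' directions) are padded with zeros. Component signs are fixed by making
#' the largest-magnitude gene loading of each component positive.
#'
#' @param matrix An [aggregate_matrix] (genes x signatures), e.g. from
#'   [build_gene_matrix()].
#' @param categories Optional named vector assigning a metadata category to
#'   each signature (carried through for plotting/grouping).
#' @return An object of class `pca_result` with `coordinates` (signatures x
#'   3 matrix), `variance_explained` (3 fractions, non-increasing) and
#'   `categories`.
#' @export
pca_signatures <- function(matrix, categories = NULL) {
  stopifnot(inherits(matrix, "aggregate_matrix"))
  m <- matrix$values
  n_sig <- ncol(m)
  if (n_sig < 3)
    warning("fewer than 3 signatures; missing components padded with zeros")
  obs <- t(m)                       # signatures x genes
  centered <- scale(obs, center = TRUE, scale = FALSE)
  total_var <- sum(centered^2)
  coords <- matrix(0, nrow = n_sig, ncol = 3,
                   dimnames = list(colnames(m), paste0("PC", 1:3)))
  varexp <- numeric(3)
  if (total_var > 0) {
    pc <- stats::prcomp(obs, center = TRUE, scale. = FALSE)
    k <- min(3L, ncol(pc$x))
    for (j in seq_len(k)) {
      flip <- sign(pc$rotation[which.max(abs(pc$rotation[, j])), j])
      if (flip < 0) {
        pc$x[, j] <- -pc$x[, j]
        pc$rotation[, j] <- -pc$rotation[, j]
      }
    }
    coords[, seq_len(k)] <- pc$x[, seq_len(k), drop = FALSE]
    varexp[seq_len(k)] <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  }
  if (!is.null(categories)) {
    if (is.null(names(categories))) names(categories) <- colnames(m)
    categories <- categories[colnames(m)]
  }
  structure(list(coordinates = coords,
                 variance_explained = varexp,
                 categories = categories),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("pca_result: %d signatures; variance explained %.1f%% / %.1f%% / %.1f%%\n",
              nrow(x$coordinates), 100 * x$variance_explained[1],
              100 * x$variance_explained[2], 100 * x$variance_explained[3]))
  invisible(x)
}

## Pairwise cosine distance (1 - cosine similarity) between the rows of `m`;
## zero-norm rows sit at distance 1 from everything.
cosine_dist <- function(m) {
  nrm <- sqrt(rowSums(m^2))
  safe <- ifelse(nrm == 0, 1, nrm)
  unit <- m / safe
  s <- tcrossprod(unit)
  s[nrm == 0, ] <- 0
  s[, nrm == 0] <- 0
  d <- 1 - s
  d[d < 0] <- 0
  diag(d) <- 0
  stats::as.dist(d)
}

#' Heatmap leaf ordering by hierarchical clustering
#'
#' Average-linkage agglomerative clustering on cosine distance over the
#' chosen axis; returns the dendrogram leaf order as a permutation of the
#' original indices. Vectors are pre-sorted by label before clustering so
#' the ordering is a function of the labeled data, not of input order.
#'
#' @param matrix An [aggregate_matrix].
#' @param axis `"rows"` or `"columns"`.
#' @return Integer permutation of `1..n` (n = number of rows or columns).
#' @export
cluster_order <- function(matrix, axis = c("rows", "columns")) {
  stopifnot(inherits(matrix, "aggregate_matrix"))
  axis <- match.arg(axis)
  m <- if (axis == "rows") matrix$values else t(matrix$values)
  if (nrow(m) < 2)
    stop("at least 2 ", axis, " required for clustering")
  labels <- rownames(m)
  ord_lab <- order(labels, method = "radix")
  m <- m[ord_lab, , drop = FALSE]
  hc <- stats::hclust(cosine_dist(m), method = "average")
  ord_lab[hc$order]
}

#' Build a full collection report bundle
#'
#' Orchestrates the three aggregate views of a signature collection — the
#' gene coefficient matrix (optionally row-filtered), the enrichment term
#' matrix and the compound similarity matrix — plus the 3-D PCA of the
#' signatures, with hierarchical row/column orderings on every matrix. An
#' optional subset of signature ids restricts the analysis (a custom
#' report); an optional metadata field categorizes the PCA points. Fully
#' deterministic given `seed`. When `out_dir` is supplied the three matrices
#' are written as TSV and a JSON manifest is emitted alongside.
#'
#' @param collection A [signature_collection] with adjusted p-values.
#' @param library A [gene_set_library] for enrichment.
#' @param compound_lib A [compound_signature_library] for matching.
#' @param alpha Adjusted-p threshold for the up/down split (default 0.01).
#' @param filter_statistic,filter_top_n Optional row filter for the gene
#'   matrix (see [filter_rows()]); `NULL` keeps all rows.
#' @param top_n Retained terms / compounds per column (default 50).
#' @param subset Optional character vector of signature ids to analyze.
#' @param category Optional metadata field name used to categorize points.
#' @param n_draws Monte-Carlo draws for rank calibration (default 200).
#' @param seed Integer seed for all stochastic steps.
#' @param out_dir Optional output directory for the manifest and TSVs.
#' @return An object of class `report_bundle`.
#' @export
build_report <- function(collection, library, compound_lib,
                         alpha = 0.01, filter_statistic = NULL,
                         filter_top_n = 10, top_n = 50, subset = NULL,
                         category = NULL, n_draws = 200, seed = 1,
                         out_dir = NULL) {
  stopifnot(inherits(collection, "signature_collection"))
  if (!is.null(subset)) {
    unknown <- setdiff(subset, collection_ids(collection))
    if (length(unknown))
      stop("unknown signature id(s) in subset: ",
           paste(unknown, collapse = ", "))
    if (length(subset) == 0) stop("subset selects zero signatures")
    collection <- signature_collection(
      collection$tag, collection$signatures[subset],
      provenance = collection$provenance)
  }
  categories <- NULL
  if (!is.null(category)) {
    fields <- sort(unique(unlist(lapply(collection$signatures,
                                        function(s) names(s$metadata)))))
    if (!category %in% fields)
      stop("unknown metadata field '", category, "'; available fields: ",
           paste(fields, collapse = ", "))
    categories <- vapply(collection$signatures, function(s) {
      v <- s$metadata[[category]]
      if (is.null(v)) NA_character_ else as.character(v)
    }, character(1))
  }
  gene_m <- build_gene_matrix(collection)
  pca <- pca_signatures(gene_m, categories = categories)
  if (!is.null(filter_statistic))
    gene_m <- filter_rows(gene_m, statistic = filter_statistic,
                          top_n = filter_top_n)
  enr_m <- build_enrichment_matrix(collection, library, alpha = alpha,
                                   top_n = top_n, n_draws = n_draws,
                                   seed = seed)
  cmp_m <- build_compound_matrix(collection, compound_lib, top_k = top_n)
  add_orders <- function(am) {
    aggregate_matrix(
      am$values,
      row_order = if (nrow(am$values) >= 2) cluster_order(am, "rows"),
      column_order = if (ncol(am$values) >= 2) cluster_order(am, "columns"))
  }
  bundle <- structure(
    list(tag = collection$tag,
         signature_ids = collection_ids(collection),
         pca = pca,
         genes = add_orders(gene_m),
         enrichment = add_orders(enr_m),
         compounds = add_orders(cmp_m),
         config = list(alpha = alpha, top_n = top_n, n_draws = n_draws,
                       seed = seed, library = library$name,
                       filter_statistic = filter_statistic,
                       filter_top_n = filter_top_n, category = category),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "report_bundle")
  if (!is.null(out_dir)) write_report(bundle, out_dir)
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("report_bundle '%s': %d signatures\n", x$tag,
              length(x$signature_ids)))
  cat(sprintf("  genes matrix:      %d x %d\n", nrow(x$genes$values),
              ncol(x$genes$values)))
  cat(sprintf("  enrichment matrix: %d x %d\n", nrow(x$enrichment$values),
              ncol(x$enrichment$values)))
  cat(sprintf("  compound matrix:   %d x %d\n", nrow(x$compounds$values),
              ncol(x$compounds$values)))
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Emits `gene_matrix.tsv`, `enrichment_matrix.tsv`, `compound_matrix.tsv`
#' and `manifest.json` (tag, signature ids, PCA block, clustering orders,
#' config echo, timestamp) into `dir`.
#'
#' @param bundle A `report_bundle` from [build_report()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(bundle, dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_report_matrix(bundle$genes, file.path(dir, "gene_matrix.tsv"))
  write_report_matrix(bundle$enrichment,
                      file.path(dir, "enrichment_matrix.tsv"))
  write_report_matrix(bundle$compounds,
                      file.path(dir, "compound_matrix.tsv"))
  manifest <- list(
    tag = bundle$tag,
    signature_ids = bundle$signature_ids,
    pca = list(
      coordinates = apply(bundle$pca$coordinates, 1, as.numeric,
                          simplify = FALSE),
      variance_explained = bundle$pca$variance_explained,
      categories = bundle$pca$categories
    ),
    orders = list(
      genes = list(rows = bundle$genes$row_order,
                   columns = bundle$genes$column_order),
      enrichment = list(rows = bundle$enrichment$row_order,
                        columns = bundle$enrichment$column_order),
      compounds = list(rows = bundle$compounds$row_order,
                       columns = bundle$compounds$column_order)
    ),
    files = c("gene_matrix.tsv", "enrichment_matrix.tsv",
              "compound_matrix.tsv"),
    config = bundle$config,
    timestamp = bundle$timestamp
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(dir)
}
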