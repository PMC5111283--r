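#' @keywords internal
"_PACKAGE"

SPECIES <- c("human", "mouse", "rat")

## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
## All stochastic operations in the package route through this so that a
## single integer seed makes a whole pipeline run reproducible.
local_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Expression dataset
#'
#' A genes (or probes) x samples matrix of log-scale expression values with a
#' control/perturbation class label per sample and a species tag. This is the
#' raw input to differential expression; rows are dropped upstream if they
#' contain missing values.
#'
#' @param values Numeric matrix, rows = probe or gene identifiers (rownames),
#'   columns = sample identifiers (colnames), log-scale expression.
#' @param class_labels Character vector, one of `"control"` /
#'   `"perturbation"` per column of `values`.
#' @param species One of `"human"`, `"mouse"`, `"rat"`.
#' @param platform_id Free-text platform identifier.
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(values, class_labels, species,
                               platform_id = "") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have row and column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate row identifiers in expression matrix")
  if (anyNA(values))
    stop("expression matrix contains missing values; drop such rows on load")
  class_labels <- as.character(class_labels)
  if (length(class_labels) != ncol(values))
    stop("`class_labels` must have one entry per sample")
  if (!all(class_labels %in% c("control", "perturbation")))
    stop("class labels must be 'control' or 'perturbation'")
  if (sum(class_labels == "control") < 2 ||
      sum(class_labels == "perturbation") < 2)
    stop(">=2 samples per class required (control and perturbation)")
  check_species(species)
  structure(
    list(values = values, class_labels = class_labels,
         species = species, platform_id = platform_id),
    class = "expression_dataset"
  )
}

check_species <- function(species) {
  if (length(species) != 1 || !species %in% SPECIES)
    stop("unsupported species '", paste(species, collapse = ","),
         "'; supported species are: ", paste(SPECIES, collapse = ", "))
  invisible(species)
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf(
    "expression_dataset: %d features x %d samples (%d control, %d perturbation), species=%s\n",
    nrow(x$values), ncol(x$values),
    sum(x$class_labels == "control"),
    sum(x$class_labels == "perturbation"), x$species))
  invisible(x)
}

#' Gene signature
#'
#' A unit-norm, signed gene-coefficient vector (the normal of the hyperplane
#' separating control from perturbation samples) with optional per-gene
#' nominal and BH-adjusted p-values and free-text metadata. A positive
#' coefficient means the gene is higher in perturbation samples.
#'
#' @param id Unique signature identifier.
#' @param gene_coeffs Named numeric vector, gene symbol -> signed
#'   coefficient; must have unit Euclidean norm (tolerance 1e-9).
#' @param pvalues,adjusted_pvalues Optional named numeric vectors over the
#'   same genes, values in (0, 1], with `adjusted_pvalues >= pvalues`.
#' @param metadata Named list of free-text fields (organism, cell type,
#'   accession ids, user tags).
#' @return An object of class `gene_signature`.
#' @export
gene_signature <- function(id, gene_coeffs, pvalues = NULL,
                           adjusted_pvalues = NULL, metadata = list()) {
  if (!is.character(id) || length(id) != 1 || !nzchar(id))
    stop("`id` must be a non-empty string")
  if (!is.numeric(gene_coeffs) || is.null(names(gene_coeffs)))
    stop("`gene_coeffs` must be a named numeric vector")
  names(gene_coeffs) <- toupper(names(gene_coeffs))
  if (anyDuplicated(names(gene_coeffs)))
    stop("duplicate gene symbols in coefficient vector")
  nrm <- sqrt(sum(gene_coeffs^2))
  if (abs(nrm - 1) > 1e-9)
    stop(sprintf("coefficient vector must have unit norm (got %.12g)", nrm))
  check_p <- function(p, what) {
    if (is.null(p)) return(NULL)
    if (is.null(names(p))) stop("`", what, "` must be named by gene")
    names(p) <- toupper(names(p))
    p <- p[names(gene_coeffs)]
    if (anyNA(p)) stop("`", what, "` missing for some genes")
    if (any(p <= 0 | p > 1)) stop("`", what, "` values must lie in (0, 1]")
    p
  }
  pvalues <- check_p(pvalues, "pvalues")
  adjusted_pvalues <- check_p(adjusted_pvalues, "adjusted_pvalues")
  if (!is.null(pvalues) && !is.null(adjusted_pvalues) &&
      any(adjusted_pvalues < pvalues - 1e-12))
    stop("adjusted p-values must be >= nominal p-values")
  structure(
    list(id = id, gene_coeffs = gene_coeffs, pvalues = pvalues,
         adjusted_pvalues = adjusted_pvalues, metadata = metadata),
    class = "gene_signature"
  )
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("gene_signature '%s': %d genes (%d up, %d down)%s\n",
              x$id, length(x$gene_coeffs), sum(x$gene_coeffs > 0),
              sum(x$gene_coeffs < 0),
              if (is.null(x$pvalues)) ", no p-values" else ""))
  invisible(x)
}

#' Signature collection
#'
#' A tagged, ordered set of gene signatures — the unit of aggregate analysis.
#'
#' @param tag Collection keyword (theme: a disease, drug, tissue, ...).
#' @param signatures List of [gene_signature] objects with unique ids.
#' @param provenance Free-text provenance notes.
#' @return An object of class `signature_collection`.
#' @export
signature_collection <- function(tag, signatures, provenance = "") {
  if (!is.character(tag) || length(tag) != 1 || !nzchar(tag))
    stop("`tag` must be a non-empty string")
  if (!is.list(signatures) || length(signatures) == 0)
    stop("collection must contain at least one signature")
  ok <- vapply(signatures, inherits, logical(1), "gene_signature")
  if (!all(ok)) stop("all elements must be gene_signature objects")
  ids <- vapply(signatures, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("signature ids must be unique in a collection")
  names(signatures) <- ids
  structure(list(tag = tag, signatures = signatures, provenance = provenance),
            class = "signature_collection")
}

#' @export
print.signature_collection <- function(x, ...) {
  cat(sprintf("signature_collection '%s': %d signatures\n",
              x$tag, length(x$signatures)))
  invisible(x)
}

collection_ids <- function(collection) names(collection$signatures)

#' Gene-set library
#'
#' Named gene sets over a declared background universe, as read from a GMT
#' file. Symbols are uppercased; the background size defaults to the number
#' of distinct genes in the library.
#'
#' @param name Library name.
#' @param sets Named list, term name -> character vector of gene symbols.
#' @param background_size Positive integer universe size `N`; defaults to the
#'   size of the union of all member genes.
#' @return An object of class `gene_set_library`.
#' @export
gene_set_library <- function(name, sets, background_size = NULL) {
  if (!is.list(sets) || length(sets) == 0 || is.null(names(sets)))
    stop("`sets` must be a non-empty named list")
  if (anyDuplicated(names(sets))) stop("duplicate term names in library")
  sets <- lapply(sets, function(g) {
    g <- unique(toupper(as.character(g)))
    g <- g[nzchar(g)]
    if (length(g) == 0) stop("every gene set must be non-empty")
    sort(g)
  })
  universe <- sort(unique(unlist(sets, use.names = FALSE)))
  if (is.null(background_size)) background_size <- length(universe)
  background_size <- as.integer(background_size)
  if (background_size < 1) stop("background_size must be positive")
  sizes <- lengths(sets)
  if (any(sizes > background_size))
    stop("a gene set exceeds the background universe size")
  structure(list(name = name, sets = sets, background_size = background_size,
                 universe = universe),
            class = "gene_set_library")
}

#' @export
print.gene_set_library <- function(x, ...) {
  cat(sprintf("gene_set_library '%s': %d sets, %d distinct genes, background N=%d\n",
              x$name, length(x$sets), length(x$universe), x$background_size))
  invisible(x)
}

#' Compound signature library
#'
#' A gene x compound matrix of signed coefficients (an L1000-style compound
#' signature library at local scale) used for mimic/reverse matching.
#'
#' @param gene_space Ordered character vector of gene symbols.
#' @param vectors Named list or matrix: one coefficient vector per compound
#'   over `gene_space`; no compound vector may be all-zero.
#' @return An object of class `compound_signature_library` whose `$matrix`
#'   element is a genes x compounds numeric matrix.
#' @export
compound_signature_library <- function(gene_space, vectors) {
  gene_space <- toupper(as.character(gene_space))
  if (anyDuplicated(gene_space)) stop("duplicate genes in gene_space")
  if (is.matrix(vectors)) {
    m <- vectors
    if (is.null(colnames(m))) stop("compound matrix must have column names")
    if (nrow(m) != length(gene_space))
      stop("vector length must match gene_space")
  } else {
    if (!is.list(vectors) || length(vectors) == 0 || is.null(names(vectors)))
      stop("`vectors` must be a non-empty named list or matrix")
    len_ok <- vapply(vectors, length, integer(1)) == length(gene_space)
    if (!all(len_ok)) stop("all vectors must have length == |gene_space|")
    m <- do.call(cbind, vectors)
  }
  rownames(m) <- gene_space
  if (anyDuplicated(colnames(m))) stop("duplicate compound ids")
  if (anyNA(m)) stop("compound vectors contain missing values")
  if (any(colSums(m^2) == 0)) stop("all-zero compound vector not allowed")
  structure(list(gene_space = gene_space, matrix = m),
            class = "compound_signature_library")
}

#' @export
print.compound_signature_library <- function(x, ...) {
  cat(sprintf("compound_signature_library: %d genes x %d compounds\n",
              nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Aggregate matrix
#'
#' A labeled dense matrix (genes, enrichment terms or compounds as rows;
#' signatures — possibly expanded to up/down columns — as columns) with
#' optional row/column orderings from hierarchical clustering.
#'
#' @param values Numeric matrix with row and column names.
#' @param row_order,column_order Optional integer permutations of the row /
#'   column indices (heatmap leaf order).
#' @return An object of class `aggregate_matrix`.
#' @export
aggregate_matrix <- function(values, row_order = NULL, column_order = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (nrow(values) == 0 || ncol(values) == 0)
    stop("aggregate matrix must be non-empty")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("aggregate matrix must be fully labeled")
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values)))
    stop("row and column labels must be unique")
  check_perm <- function(ord, n, what) {
    if (is.null(ord)) return(NULL)
    ord <- as.integer(ord)
    if (length(ord) != n || !setequal(ord, seq_len(n)))
      stop("`", what, "` must be a permutation of 1..", n)
    ord
  }
  structure(
    list(values = values,
         row_labels = rownames(values), column_labels = colnames(values),
         row_order = check_perm(row_order, nrow(values), "row_order"),
         column_order = check_perm(column_order, ncol(values), "column_order")),
    class = "aggregate_matrix"
  )
}

#' @export
print.aggregate_matrix <- function(x, ...) {
  cat(sprintf("aggregate_matrix: %d rows x %d columns%s\n",
              nrow(x$values), ncol(x$values),
              if (!is.null(x$row_order)) " (clustered)" else ""))
  invisible(x)
}

#' @export
dim.aggregate_matrix <- function(x) dim(x$values)

#' @export
as.matrix.aggregate_matrix <- function(x, ...) x$values
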