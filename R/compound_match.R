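#' Cosine similarity between a signature and a compound vector
#'
#' Computed over the intersection of the query's genes and the library gene
#' space. The similarity `s = <v, u> / (|v| |u|)` lies in `[-1, 1]`; it is
#' the `[0, 2]` cosine distance translated to the `[1, -1]` similarity
#' scale (`s = 1 - d`). Positive similarity marks a mimicker of the query
#' signature, negative a reverser.
#'
#' @param query A [gene_signature] or named numeric vector of coefficients.
#' @param compound_vector Named numeric vector over the library gene space.
#' @param min_overlap Minimum number of shared genes (default 10); below it
#'   the match is skipped (`NA` returned with a warning).
#' @return Similarity in `[-1, 1]`, or `NA` when the overlap or a vector
#'   norm on the shared genes is degenerate.
#' @export
cosine_similarity <- function(query, compound_vector, min_overlap = 10) {
  if (inherits(query, "gene_signature")) query <- query$gene_coeffs
  if (is.null(names(query)) || is.null(names(compound_vector)))
    stop("query and compound vectors must be named by gene")
  shared <- intersect(names(query), names(compound_vector))
  if (length(shared) < min_overlap) {
    warning(sprintf("only %d shared gene(s) (< min_overlap = %d); match skipped",
                    length(shared), min_overlap))
    return(NA_real_)
  }
  v <- query[shared]
  u <- compound_vector[shared]
  nv <- sqrt(sum(v^2)); nu <- sqrt(sum(u^2))
  if (nv == 0 || nu == 0) {
    warning("zero-norm restriction to shared genes; match skipped")
    return(NA_real_)
  }
  s <- sum(v * u) / (nv * nu)
  max(-1, min(1, s))
}

#' Search a compound library for mimickers and reversers
#'
#' Scores every compound by cosine similarity to the query over the shared
#' gene space, then returns the top `top_k` strictly positive similarities
#' (mimickers, descending) and the top `top_k` strictly negative ones
#' (reversers, ascending, i.e. most opposite first). Compounds with exactly
#' zero similarity, insufficient overlap, or degenerate norm appear in
#' neither list. Ties are broken by compound id.
#'
#' @param query A [gene_signature] or named coefficient vector.
#' @param library A [compound_signature_library].
#' @param top_k Maximum matches per direction (default 50).
#' @param min_overlap Minimum shared genes per compound (default 10).
#' @return List with data frames `mimickers` and `reversers`, each with
#'   columns `compound_id`, `similarity`, `mode`, `n_overlap`.
#' @export
search_compounds <- function(query, library, top_k = 50, min_overlap = 10) {
  stopifnot(inherits(library, "compound_signature_library"))
  if (inherits(query, "gene_signature")) query <- query$gene_coeffs
  if (is.null(names(query))) stop("query must be named by gene")
  names(query) <- toupper(names(query))
  shared <- intersect(names(query), library$gene_space)
  n_overlap <- length(shared)
  sims <- if (n_overlap < min_overlap) {
    warning(sprintf("only %d gene(s) shared with the library space (< %d)",
                    n_overlap, min_overlap))
    rep(NA_real_, ncol(library$matrix))
  } else {
    v <- query[shared]
    nv <- sqrt(sum(v^2))
    u <- library$matrix[shared, , drop = FALSE]
    un <- sqrt(colSums(u^2))
    s <- as.vector(crossprod(u, v)) / (nv * un)
    s[un == 0 | nv == 0] <- NA_real_
    pmax(-1, pmin(1, s))
  }
  ids <- colnames(library$matrix)
  make_side <- function(keep, decreasing, mode) {
    d <- data.frame(compound_id = ids[keep], similarity = sims[keep],
                    mode = mode, n_overlap = n_overlap,
                    stringsAsFactors = FALSE)
    ord <- order(if (decreasing) -d$similarity else d$similarity,
                 d$compound_id, method = "radix")
    d <- utils::head(d[ord, , drop = FALSE], top_k)
    rownames(d) <- NULL
    d
  }
  list(
    mimickers = make_side(!is.na(sims) & sims > 0, TRUE, "mimic"),
    reversers = make_side(!is.na(sims) & sims < 0, FALSE, "reverse")
  )
}

#' Compound x signature similarity matrix for a collection
#'
#' Searches the compound library with every signature in the collection and
#' assembles the union of all matched compounds into a matrix: positive
#' cells are mimic similarities, negative cells reverse similarities, and
#' compounds absent from a signature's lists are 0 (outer-join fill).
#'
#' @param collection A [signature_collection].
#' @param library A [compound_signature_library].
#' @param top_k Matches retained per direction per signature (default 50).
#' @param min_overlap Minimum shared genes (default 10).
#' @return An [aggregate_matrix], rows = compounds, columns = signature ids.
#' @export
build_compound_matrix <- function(collection, library, top_k = 50,
                                  min_overlap = 10) {
  stopifnot(inherits(collection, "signature_collection"))
  ids <- collection_ids(collection)
  matches <- lapply(ids, function(id) {
    search_compounds(collection$signatures[[id]], library,
                     top_k = top_k, min_overlap = min_overlap)
  })
  names(matches) <- ids
  compounds <- sort(unique(unlist(lapply(matches, function(m) {
    c(m$mimickers$compound_id, m$reversers$compound_id)
  }), use.names = FALSE)))
  if (length(compounds) == 0)
    stop("no compound matched any signature in the collection")
  m <- matrix(0, nrow = length(compounds), ncol = length(ids),
              dimnames = list(compounds, ids))
  for (id in ids) {
    for (side in c("mimickers", "reversers")) {
      d <- matches[[id]][[side]]
      if (nrow(d)) m[d$compound_id, id] <- d$similarity
    }
  }
  aggregate_matrix(m)
}
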