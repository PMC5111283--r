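#' Read a GMT gene-set library
#'
#' Parses the tab-separated GMT format (term, description, member genes...)
#' used by Enrichr-style tools. Gene symbols are uppercased; empty gene
#' fields are skipped.
#'
#' @param path Path to a GMT file.
#' @param name Library name; defaults to the file name.
#' @param background_size Universe size `N`; defaults to the union of all
#'   genes in the file.
#' @return A [gene_set_library].
#' @export
read_gmt <- function(path, name = basename(path), background_size = NULL) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("GMT file is empty: ", path)
  sets <- vector("list", length(lines))
  terms <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop(sprintf("malformed GMT line %d: expected >= 3 tab-separated fields", i))
    terms[[i]] <- fields[[1]]
    genes <- trimws(fields[-(1:2)])
    sets[[i]] <- genes[nzchar(genes)]
  }
  if (anyDuplicated(terms))
    stop("duplicate term name(s) in GMT: ",
         paste(unique(terms[duplicated(terms)]), collapse = ", "))
  names(sets) <- terms
  gene_set_library(name, sets, background_size = background_size)
}

#' Write a gene-set library to GMT
#'
#' @param library A [gene_set_library].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(library, path) {
  stopifnot(inherits(library, "gene_set_library"))
  lines <- vapply(names(library$sets), function(term) {
    paste(c(term, "na", library$sets[[term]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an expression matrix with sample class labels
#'
#' Reads a TSV of log-scale expression (row identifiers in the first column,
#' sample ids in the header). Rows containing any non-numeric or missing cell
#' are dropped, with a message reporting the count.
#'
#' @param path Path to the expression TSV.
#' @param labels Named character vector or two-column data frame mapping
#'   sample id -> `"control"` / `"perturbation"`; must cover every sample.
#' @param species One of `"human"`, `"mouse"`, `"rat"`.
#' @param platform_id Optional platform identifier.
#' @return An [expression_dataset].
#' @export
read_expression <- function(path, labels, species, platform_id = "") {
  check_species(species)
  if (!file.exists(path)) stop("expression file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 2) stop("expression TSV must have an id column and samples")
  ids <- tab[[1]]
  if (anyDuplicated(ids))
    stop("duplicate row identifiers in expression file; collapse probes after de-duplication")
  m <- as.matrix(tab[, -1, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "double")
  rownames(m) <- ids
  bad <- rowSums(is.na(m)) > 0
  if (any(bad)) {
    message(sum(bad), " row(s) with missing/non-numeric values dropped")
    m <- m[!bad, , drop = FALSE]
  }
  if (nrow(m) == 0) stop("no complete rows in expression file")
  if (is.data.frame(labels)) {
    labels <- stats::setNames(as.character(labels[[2]]),
                              as.character(labels[[1]]))
  }
  if (is.null(names(labels))) {
    if (length(labels) != ncol(m))
      stop("unnamed `labels` must have one entry per sample column")
    names(labels) <- colnames(m)
  }
  missing_lab <- setdiff(colnames(m), names(labels))
  if (length(missing_lab))
    stop("labels missing for sample(s): ", paste(missing_lab, collapse = ", "))
  expression_dataset(m, labels[colnames(m)], species, platform_id)
}

#' Read a sample label table
#'
#' Two-column TSV (sample id, class label), no header required; a header line
#' `sample<TAB>label` is tolerated.
#'
#' @param path Path to the label TSV.
#' @return Named character vector sample -> label.
#' @export
read_labels <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           colClasses = "character")
  if (ncol(tab) < 2) stop("label file must have two tab-separated columns")
  if (tolower(tab[1, 2]) %in% c("label", "class"))
    tab <- tab[-1, , drop = FALSE]
  stats::setNames(as.character(tab[[2]]), as.character(tab[[1]]))
}

#' Collapse probes to genes by averaging
#'
#' Maps probe identifiers to gene symbols and replaces multiple probes for
#' the same gene by their arithmetic mean, per sample. Probes absent from
#' `probe_map` are dropped; the drop count is reported via `message()` and
#' attached as attribute `"n_dropped"`.
#'
#' @param dataset An [expression_dataset] with probe-level rows.
#' @param probe_map Named character vector (or two-column data frame) probe
#'   -> gene symbol.
#' @return An [expression_dataset] with one row per gene (uppercase symbols).
#' @export
collapse_probes <- function(dataset, probe_map) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (is.data.frame(probe_map))
    probe_map <- stats::setNames(as.character(probe_map[[2]]),
                                 as.character(probe_map[[1]]))
  if (is.null(names(probe_map))) stop("`probe_map` must be named by probe")
  probes <- rownames(dataset$values)
  keep <- probes %in% names(probe_map)
  n_dropped <- sum(!keep)
  if (!any(keep)) stop("no probes in common with `probe_map`")
  if (n_dropped > 0)
    message(n_dropped, " probe(s) absent from probe map dropped")
  m <- dataset$values[keep, , drop = FALSE]
  genes <- toupper(unname(probe_map[rownames(m)]))
  collapsed <- rowsum(m, group = genes, reorder = TRUE) /
    as.vector(table(genes)[sort(unique(genes))])
  out <- expression_dataset(collapsed, dataset$class_labels,
                            dataset$species, dataset$platform_id)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Read an ortholog table
#'
#' Three-column TSV: species code, source symbol, human symbol (a header
#' line is tolerated). Used to translate mouse/rat symbols to their human
#' orthologs; the mapping must be deterministic (one target per key).
#'
#' @param path Path to the ortholog TSV.
#' @return An `ortholog_table`: a data frame with columns `species`,
#'   `symbol`, `human_symbol`.
#' @export
read_ortholog_table <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           colClasses = "character")
  if (ncol(tab) < 3) stop("ortholog table must have 3 tab-separated columns")
  if (tolower(tab[1, 1]) == "species") tab <- tab[-1, , drop = FALSE]
  ortholog_table(tab[[1]], tab[[2]], tab[[3]])
}

#' Construct an ortholog table
#'
#' @param species,symbol,human_symbol Parallel character vectors.
#' @return An `ortholog_table` data frame.
#' @export
ortholog_table <- function(species, symbol, human_symbol) {
  tab <- data.frame(species = tolower(as.character(species)),
                    symbol = as.character(symbol),
                    human_symbol = toupper(as.character(human_symbol)),
                    stringsAsFactors = FALSE)
  key <- paste(tab$species, toupper(tab$symbol), sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    conflict <- tapply(tab$human_symbol, key, function(x) length(unique(x)) > 1)
    if (any(conflict))
      stop("ortholog table maps a (species, symbol) key to multiple targets")
    tab <- tab[!dup, , drop = FALSE]
  }
  class(tab) <- c("ortholog_table", "data.frame")
  tab
}

#' Map gene symbols to human orthologs
#'
#' Human input is an identity mapping (uppercased). For mouse/rat, symbols
#' are looked up in the table case-insensitively; genes with no entry are
#' dropped from the returned map and the drop count is attached as attribute
#' `"n_dropped"`. Two inputs mapping to the same human symbol are allowed;
#' their expression values are averaged downstream via [collapse_probes()].
#'
#' @param genes Character vector of source symbols.
#' @param species One of `"human"`, `"mouse"`, `"rat"`.
#' @param table An `ortholog_table` (required unless `species == "human"`).
#' @return Named character vector: original symbol -> uppercase human symbol.
#' @export
map_orthologs <- function(genes, species, table = NULL) {
  check_species(species)
  genes <- as.character(genes)
  if (species == "human") {
    out <- stats::setNames(toupper(genes), genes)
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  if (is.null(table)) stop("an ortholog table is required for ", species)
  stopifnot(inherits(table, "ortholog_table"))
  sub <- table[table$species == species, , drop = FALSE]
  idx <- match(toupper(genes), toupper(sub$symbol))
  hit <- !is.na(idx)
  out <- stats::setNames(sub$human_symbol[idx[hit]], genes[hit])
  if (any(!hit))
    message(sum(!hit), " symbol(s) without a ", species,
            " ortholog entry dropped")
  attr(out, "n_dropped") <- sum(!hit)
  out
}

#' Write / read an aggregate matrix as TSV
#'
#' TSV layout: row labels in the first column (header `row`), one column per
#' signature. Values round-trip at 12 significant digits.
#'
#' @param matrix An [aggregate_matrix].
#' @param path Output path.
#' @return `path` invisibly (writer); an [aggregate_matrix] (reader). Any
#'   clustering orders are not serialized.
#' @export
write_report_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "aggregate_matrix"))
  m <- matrix$values
  header <- paste(c("row", colnames(m)), collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], formatC(m[i, ], format = "g", digits = 12)),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_report_matrix
#' @export
read_report_matrix <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- tab[[1]]
  aggregate_matrix(m)
}

#' Read a compound signature library from TSV
#'
#' First column: gene symbol; remaining columns: one coefficient column per
#' compound id.
#'
#' @param path Path to the compound library TSV.
#' @return A [compound_signature_library].
#' @export
read_compound_library <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  if (ncol(tab) < 2) stop("compound library TSV needs gene + compound columns")
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  compound_signature_library(as.character(tab[[1]]), m)
}

#' @rdname read_compound_library
#' @param library A [compound_signature_library].
#' @export
write_compound_library <- function(library, path) {
  stopifnot(inherits(library, "compound_signature_library"))
  m <- library$matrix
  header <- paste(c("gene", colnames(m)), collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], formatC(m[i, ], format = "g", digits = 12)),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

signature_to_list <- function(sig) {
  genes <- names(sig$gene_coeffs)
  list(
    id = sig$id,
    metadata = sig$metadata,
    genes = lapply(seq_along(genes), function(i) {
      list(genes[[i]],
           unname(sig$gene_coeffs[[i]]),
           if (is.null(sig$pvalues)) NA_real_ else unname(sig$pvalues[[i]]),
           if (is.null(sig$adjusted_pvalues)) NA_real_
           else unname(sig$adjusted_pvalues[[i]]))
    })
  )
}

signature_from_list <- function(x) {
  rows <- x$genes
  num_or_na <- function(v) {
    if (is.null(v) || length(v) == 0) NA_real_ else as.numeric(v)
  }
  genes <- vapply(rows, function(r) as.character(r[[1]]), character(1))
  coef <- vapply(rows, function(r) num_or_na(r[[2]]), numeric(1))
  p <- vapply(rows, function(r) num_or_na(r[[3]]), numeric(1))
  padj <- vapply(rows, function(r) num_or_na(r[[4]]), numeric(1))
  names(coef) <- genes
  gene_signature(
    id = as.character(x$id),
    gene_coeffs = coef,
    pvalues = if (all(is.na(p))) NULL else stats::setNames(p, genes),
    adjusted_pvalues = if (all(is.na(padj))) NULL
                       else stats::setNames(padj, genes),
    metadata = if (is.null(x$metadata)) list() else as.list(x$metadata)
  )
}

#' Write / read gene signatures and collections as JSON
#'
#' Signatures serialize as `{id, metadata, genes: [[symbol, coefficient, p,
#' p_adj], ...]}`; collections add `tag`, `provenance` and an ordered
#' `signatures` array.
#'
#' @param signature A [gene_signature].
#' @param collection A [signature_collection].
#' @param path File path.
#' @return The written path invisibly, or the reconstructed object.
#' @export
write_signature_json <- function(signature, path) {
  stopifnot(inherits(signature, "gene_signature"))
  jsonlite::write_json(signature_to_list(signature), path,
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_signature_json
#' @export
read_signature_json <- function(path) {
  signature_from_list(jsonlite::read_json(path))
}

#' @rdname write_signature_json
#' @export
write_collection_json <- function(collection, path) {
  stopifnot(inherits(collection, "signature_collection"))
  payload <- list(
    tag = collection$tag,
    provenance = collection$provenance,
    signatures = lapply(unname(collection$signatures), signature_to_list)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_signature_json
#' @export
read_collection_json <- function(path) {
  x <- jsonlite::read_json(path)
  signature_collection(
    tag = as.character(x$tag),
    signatures = lapply(x$signatures, signature_from_list),
    provenance = if (is.null(x$provenance)) "" else as.character(x$provenance)
  )
}
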