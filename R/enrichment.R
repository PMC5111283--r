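#' Upper-tail hypergeometric p-value for a gene-set overlap
#'
#' Probability of observing at least `overlap` genes of a `term_size`-gene
#' set in a random `query_size`-gene draw from a `background`-gene universe,
#' `P(X >= x)` for `X ~ Hypergeometric(N, K, q)`. Computed stably in log
#' space.
#'
#' @param background Universe size `N`.
#' @param term_size Gene-set size `K`.
#' @param query_size Query size `q`.
#' @param overlap Observed overlap `x`.
#' @return Upper-tail probability in (0, 1].
#' @export
hypergeom_p <- function(background, term_size, query_size, overlap) {
  N <- as.integer(background); K <- as.integer(term_size)
  q <- as.integer(query_size); x <- as.integer(overlap)
  if (K > N || q > N) stop("term/query size cannot exceed the background")
  if (x > K || x > q) stop("overlap cannot exceed term or query size")
  if (x < 0 || K < 0 || q < 0) stop("counts must be non-negative")
  if (x == 0) return(1)
  exp(stats::phyper(x - 1L, K, N - K, q, lower.tail = FALSE, log.p = TRUE))
}

## Overlap of one query with every set in the library (query already
## uppercase, intersected with the universe by the caller).
term_overlaps <- function(query, library) {
  vapply(library$sets, function(s) sum(query %in% s), integer(1))
}

## p-values for all terms given a query of size q (within the universe).
term_pvalues <- function(query, library) {
  q <- length(query)
  x <- term_overlaps(query, library)
  K <- lengths(library$sets)
  N <- library$background_size
  p <- vapply(seq_along(x), function(i) hypergeom_p(N, K[[i]], q, x[[i]]),
              numeric(1))
  stats::setNames(p, names(library$sets))
}

## Ascending-p ranks with deterministic lexicographic tie-break on term name.
p_ranks <- function(p) {
  ord <- order(p, names(p), method = "radix")
  r <- integer(length(p))
  r[ord] <- seq_along(p)
  stats::setNames(r, names(p))
}

#' Calibrate expected term ranks under random queries
#'
#' Draws `n_draws` uniform random gene sets of size `query_size` from the
#' library's background universe, ranks all terms by ascending hypergeometric
#' p-value each draw (ties broken by term name), and records the per-term
#' mean and standard deviation of rank. The standard deviation is floored at
#' 0.1. Background genes beyond the library's gene union never overlap any
#' term, so the in-union portion of each draw is sampled from
#' `Hypergeometric(M, N - M, q)` where `M` is the union size.
#'
#' @param library A [gene_set_library].
#' @param query_size Query size the calibration is for.
#' @param n_draws Number of Monte-Carlo draws (>= 50; default 200).
#' @param seed Integer seed; calibration is deterministic given the seed.
#' @return An object of class `rank_calibration` with elements `mean_rank`,
#'   `sd_rank` (named by term), `query_size`, `n_draws`, `seed`.
#' @export
calibrate_ranks <- function(library, query_size, n_draws = 200, seed = 1) {
  stopifnot(inherits(library, "gene_set_library"))
  query_size <- as.integer(query_size)
  n_draws <- as.integer(n_draws)
  if (query_size < 1 || query_size > library$background_size)
    stop("query_size must lie in [1, background_size]")
  if (n_draws < 50) stop("n_draws must be >= 50")
  n_terms <- length(library$sets)
  universe <- library$universe
  M <- length(universe)
  N <- library$background_size
  ranks <- local_seed(seed, {
    out <- matrix(0L, nrow = n_terms, ncol = n_draws)
    for (d in seq_len(n_draws)) {
      m_in <- if (N > M) stats::rhyper(1, M, N - M, query_size)
              else query_size
      query <- if (m_in > 0) sample(universe, m_in) else character(0)
      p <- if (m_in > 0) term_pvalues(query, library)
           else stats::setNames(rep(1, n_terms), names(library$sets))
      out[, d] <- p_ranks(p)
    }
    out
  })
  mu <- rowMeans(ranks)
  sdv <- apply(ranks, 1, stats::sd)
  sdv <- pmax(sdv, 0.1)
  structure(
    list(mean_rank = stats::setNames(mu, names(library$sets)),
         sd_rank = stats::setNames(sdv, names(library$sets)),
         query_size = query_size, n_draws = n_draws, seed = as.integer(seed)),
    class = "rank_calibration"
  )
}

#' @export
print.rank_calibration <- function(x, ...) {
  cat(sprintf("rank_calibration: %d terms, query size %d, %d draws\n",
              length(x$mean_rank), x$query_size, x$n_draws))
  invisible(x)
}

## Nearest-10 query-size bucket used to share calibrations, floored at 10
## and capped at the background size.
calibration_bucket <- function(query_size, background_size) {
  b <- as.integer(round(query_size / 10) * 10)
  min(max(b, 10L), as.integer(background_size))
}

#' Enrichment of one gene set against a library
#'
#' For each library term: hypergeometric upper-tail p-value of the overlap,
#' rank by ascending p (ties by term name), rank-deviation z-score
#' `z = (rank - mean_rank) / sd_rank` against the supplied calibration, and
#' combined score `c = ln(p) * z`. Negative z (better than the expected
#' rank) with `p < 1` yields a positive combined score; `p = 1` gives a
#' combined score of exactly 0. The top `top_n` records by descending
#' combined score are retained.
#'
#' @param query Character vector of gene symbols (uppercased internally);
#'   genes outside the background universe are dropped with a count.
#' @param library A [gene_set_library].
#' @param calibration A `rank_calibration` from [calibrate_ranks()].
#' @param direction `"up"` or `"down"` tag carried on the records.
#' @param top_n Maximum number of records returned (default 50).
#' @return A data frame of class `enrichment_result` with columns `term`,
#'   `overlap`, `p`, `rank`, `z`, `combined`, `direction`; zero rows (with a
#'   warning) when the query is empty after universe intersection.
#' @export
enrich_gene_set <- function(query, library, calibration,
                            direction = c("up", "down"), top_n = 50) {
  stopifnot(inherits(library, "gene_set_library"),
            inherits(calibration, "rank_calibration"))
  direction <- match.arg(direction)
  query <- unique(toupper(as.character(query)))
  in_universe <- query %in% library$universe
  n_outside <- sum(!in_universe)
  query <- query[in_universe]
  empty <- data.frame(term = character(0), overlap = integer(0),
                      p = numeric(0), rank = integer(0), z = numeric(0),
                      combined = numeric(0), direction = character(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("enrichment_result", "data.frame")
  if (length(query) == 0) {
    warning("query empty after background intersection; no enrichment computed")
    return(empty)
  }
  if (n_outside > 0)
    message(n_outside, " query gene(s) outside the background universe dropped")
  p <- term_pvalues(query, library)
  r <- p_ranks(p)
  z <- (r - calibration$mean_rank[names(p)]) / calibration$sd_rank[names(p)]
  combined <- log(p) * z
  combined[combined == 0] <- 0   # normalize IEEE negative zero
  res <- data.frame(term = names(p),
                    overlap = term_overlaps(query, library),
                    p = unname(p), rank = unname(r), z = unname(z),
                    combined = unname(combined),
                    direction = direction, stringsAsFactors = FALSE)
  res <- res[order(-res$combined, res$term, method = "radix"), , drop = FALSE]
  res <- utils::head(res, top_n)
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Term x signature enrichment matrix for a collection
#'
#' Runs the enrichment analysis twice per signature — once on its
#' significant up-regulated genes and once on its down-regulated genes (per
#' [split_up_down()]) — and concatenates the retained-term score vectors by
#' outer join, filling absent term/column pairs with zero. Columns are
#' labeled `<signature_id>|up` and `<signature_id>|down`.
#'
#' @param collection A [signature_collection] whose signatures carry
#'   adjusted p-values.
#' @param library A [gene_set_library].
#' @param alpha Adjusted-p threshold passed to [split_up_down()].
#' @param top_n Retained terms per column (default 50).
#' @param n_draws,seed Passed to [calibrate_ranks()]; calibrations are
#'   shared across query sizes in the same nearest-10 bucket.
#' @return An [aggregate_matrix] of combined scores.
#' @export
build_enrichment_matrix <- function(collection, library, alpha = 0.01,
                                    top_n = 50, n_draws = 200, seed = 1) {
  stopifnot(inherits(collection, "signature_collection"),
            inherits(library, "gene_set_library"))
  cal_cache <- new.env(parent = emptyenv())
  get_cal <- function(q) {
    bucket <- calibration_bucket(q, library$background_size)
    key <- as.character(bucket)
    if (is.null(cal_cache[[key]]))
      cal_cache[[key]] <- calibrate_ranks(library, bucket, n_draws = n_draws,
                                          seed = seed)
    cal_cache[[key]]
  }
  cols <- list()
  for (id in collection_ids(collection)) {
    sig <- collection$signatures[[id]]
    sets <- split_up_down(sig, alpha)
    for (dir in c("up", "down")) {
      genes <- sets[[dir]]
      genes <- genes[genes %in% library$universe]
      label <- paste0(id, "|", dir)
      if (length(genes) == 0) {
        cols[[label]] <- stats::setNames(numeric(0), character(0))
      } else {
        res <- enrich_gene_set(genes, library, get_cal(length(genes)),
                               direction = dir, top_n = top_n)
        cols[[label]] <- stats::setNames(res$combined, res$term)
      }
    }
  }
  all_terms <- sort(unique(unlist(lapply(cols, names), use.names = FALSE)))
  if (length(all_terms) == 0)
    stop("no enrichment terms retained for any signature")
  m <- matrix(0, nrow = length(all_terms), ncol = length(cols),
              dimnames = list(all_terms, names(cols)))
  for (j in seq_along(cols)) {
    v <- cols[[j]]
    if (length(v)) m[names(v), j] <- v
  }
  aggregate_matrix(m)
}
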