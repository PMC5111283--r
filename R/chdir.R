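#' Configuration for characteristic-direction analysis
#'
#' @param gamma Shrinkage weight in `[0, 1]` pulling the pooled within-class
#'   covariance toward a scaled identity. `gamma = 0` is the unregularized
#'   LDA solve (singular whenever genes outnumber samples); the default 0.5
#'   balances the empirical covariance and the ridge.
#' @param n_permutations Number of label permutations for the per-gene null
#'   (exhaustive enumeration is used instead when the label-assignment space
#'   is at most this large).
#' @param alpha BH-adjusted p-value threshold for calling a gene
#'   differentially expressed (default 0.01).
#' @param seed Integer seed controlling permutation sampling.
#' @return An object of class `chdir_config`.
#' @export
chdir_config <- function(gamma = 0.5, n_permutations = 1000, alpha = 0.01,
                         seed = 1) {
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma < 0 || gamma > 1)
    stop("`gamma` must lie in [0, 1]")
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stop("`alpha` must lie in (0, 1)")
  n_permutations <- as.integer(n_permutations)
  if (n_permutations < 1) stop("`n_permutations` must be positive")
  structure(list(gamma = gamma, n_permutations = n_permutations,
                 alpha = alpha, seed = as.integer(seed)),
            class = "chdir_config")
}

## Core regularized-LDA solve shared by the public function and the
## permutation null. `labels` is a character vector over columns of `x`.
## Returns the unit-norm coefficient vector in gene space.
chdir_solve <- function(x, labels, gamma) {
  n1 <- sum(labels == "control")
  n2 <- sum(labels == "perturbation")
  n <- n1 + n2
  p <- nrow(x)
  # center every sample by the global per-gene mean
  xc <- x - rowMeans(x)
  # project onto the row space of the centered data: rank <= n - 1. Keeping
  # the full rank (rather than n - 2) preserves the class-mean difference
  # exactly, so the reduced solve equals a dense gene-space solve.
  r <- min(n - 1L, p)
  sv <- svd(t(xc), nu = 0, nv = r)
  v <- sv$v                               # p x r basis of gene space
  y <- crossprod(v, xc)                   # r x n reduced data
  mu1 <- rowMeans(y[, labels == "control", drop = FALSE])
  mu2 <- rowMeans(y[, labels == "perturbation", drop = FALSE])
  d1 <- y[, labels == "control", drop = FALSE] - mu1
  d2 <- y[, labels == "perturbation", drop = FALSE] - mu2
  sigma <- (tcrossprod(d1) + tcrossprod(d2)) / (n - 2)
  nu <- sum(diag(sigma)) / r
  shrunk <- (1 - gamma) * sigma
  diag(shrunk) <- diag(shrunk) + gamma * nu
  b_red <- tryCatch(
    solve(shrunk, mu2 - mu1),
    error = function(e) stop("shrunken covariance is singular; use gamma > 0 ",
                             "(degenerate data at gamma = 0)", call. = FALSE)
  )
  b <- drop(v %*% b_red)
  nrm <- sqrt(sum(b^2))
  if (nrm == 0) stop("class means coincide; no characteristic direction")
  stats::setNames(b / nrm, rownames(x))
}

#' Characteristic-direction differential expression
#'
#' Finds the unit normal of the hyperplane that best separates control from
#' perturbation samples under regularized linear discriminant analysis. The
#' data are centered by the global per-gene mean and projected onto the row
#' space of the centered matrix; the pooled within-class covariance is shrunk
#' toward a scaled identity, `(1 - gamma) * Sigma + gamma * nu * I` with
#' `nu = trace(Sigma) / r`, and the solve `Sigma_shrunk^{-1} (mu_pert -
#' mu_ctrl)` is mapped back to gene space and normalized to unit Euclidean
#' norm. A positive coefficient means higher expression in perturbation
#' samples; each gene's coefficient is its differential-expression score.
#'
#' @param dataset An [expression_dataset] (>= 2 samples per class, >= 2
#'   genes).
#' @param config A [chdir_config].
#' @param id Identifier for the resulting signature.
#' @param metadata Optional metadata list copied onto the signature.
#' @return A [gene_signature] with coefficients only (no p-values); see
#'   [signature_pvalues()] for significance.
#' @export
characteristic_direction <- function(dataset, config = chdir_config(),
                                     id = "signature",
                                     metadata = list()) {
  stopifnot(inherits(dataset, "expression_dataset"),
            inherits(config, "chdir_config"))
  if (nrow(dataset$values) < 2) stop("at least 2 genes required")
  b <- chdir_solve(dataset$values, dataset$class_labels, config$gamma)
  metadata$organism <- metadata$organism %||% dataset$species
  gene_signature(id = id, gene_coeffs = b, metadata = metadata)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## All distinct control-class assignments for n samples with n1 controls,
## excluding the observed assignment and its complement (those reproduce the
## observed |coefficients| and would contaminate the null).
enumerate_assignments <- function(n, n1, observed) {
  combos <- utils::combn(n, n1, simplify = FALSE)
  obs <- sort(which(observed == "control"))
  comp <- sort(which(observed != "control"))
  keep <- vapply(combos, function(ix) {
    !identical(ix, obs) && !identical(ix, comp)
  }, logical(1))
  combos[keep]
}

#' Per-gene significance of a characteristic direction by permutation
#'
#' Builds a pooled permutation null: class labels are permuted (class sizes
#' preserved), the characteristic direction is recomputed for each
#' permutation, and all permuted absolute coefficients across genes are
#' pooled into one null sample. The nominal p-value of gene `g` is
#' `(1 + #\{null >= |b_g|\}) / (1 + pooled null size)`. When the space of
#' distinct label assignments has at most `n_permutations` elements it is
#' enumerated exhaustively (excluding the observed assignment and its
#' complement); otherwise assignments are sampled with replacement under the
#' configured seed.
#'
#' @param dataset The [expression_dataset] the coefficients were computed on.
#' @param b Named coefficient vector (from [characteristic_direction()]), or
#'   a [gene_signature].
#' @param config A [chdir_config]; `seed` and `n_permutations` control the
#'   null, `gamma` must match the original solve.
#' @return Named numeric vector of nominal p-values in (0, 1].
#' @export
signature_pvalues <- function(dataset, b, config = chdir_config()) {
  stopifnot(inherits(dataset, "expression_dataset"),
            inherits(config, "chdir_config"))
  if (inherits(b, "gene_signature")) b <- b$gene_coeffs
  if (!setequal(names(b), rownames(dataset$values)))
    stop("`b` must be computed on the same dataset (gene mismatch)")
  b <- b[rownames(dataset$values)]
  labels <- dataset$class_labels
  n <- length(labels)
  n1 <- sum(labels == "control")
  n_space <- choose(n, n1)
  if (n_space < 10)
    stop("class sizes too small for resampling: only ", n_space,
         " distinct label assignments exist (need >= 10)")
  x <- dataset$values
  run_perm <- function(ctrl_idx) {
    lab <- rep("perturbation", n)
    lab[ctrl_idx] <- "control"
    abs(chdir_solve(x, lab, config$gamma))
  }
  null_abs <- local_seed(config$seed, {
    if (n_space <= config$n_permutations) {
      assignments <- enumerate_assignments(n, n1, labels)
    } else {
      assignments <- replicate(config$n_permutations, {
        repeat {
          ix <- sort(sample.int(n, n1))
          lab_ok <- !identical(ix, sort(which(labels == "control"))) &&
            !identical(ix, sort(which(labels != "control")))
          if (lab_ok) break
        }
        ix
      }, simplify = FALSE)
    }
    unlist(lapply(assignments, run_perm), use.names = FALSE)
  })
  null_sorted <- sort(null_abs)
  n_null <- length(null_sorted)
  # count of null values >= |b_g| via binary search on the sorted null
  n_ge <- n_null - findInterval(abs(b) - 1e-15, null_sorted)
  stats::setNames((1 + n_ge) / (1 + n_null), names(b))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate correction of nominal p-values (all in
#' (0, 1]), returned in the original order.
#'
#' @param pvalues Numeric vector of nominal p-values.
#' @return Adjusted p-values, names preserved.
#' @export
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues) || length(pvalues) == 0)
    stop("`pvalues` must be a non-empty numeric vector")
  if (anyNA(pvalues) || any(pvalues <= 0 | pvalues > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Split a signature into significant up/down gene sets
#'
#' Up = genes with positive coefficient and adjusted p <= alpha; down = the
#' same with negative coefficient. Zero-coefficient genes land in neither
#' set; the two sets are disjoint by construction.
#'
#' @param signature A [gene_signature] carrying adjusted p-values.
#' @param alpha Adjusted-p threshold (default 0.01).
#' @return List with character vectors `up` and `down`.
#' @export
split_up_down <- function(signature, alpha = 0.01) {
  stopifnot(inherits(signature, "gene_signature"))
  if (is.null(signature$adjusted_pvalues))
    stop("signature has no adjusted p-values; run signature_pvalues + bh_adjust")
  b <- signature$gene_coeffs
  padj <- signature$adjusted_pvalues[names(b)]
  sig <- padj <= alpha
  list(up = sort(names(b)[b > 0 & sig]),
       down = sort(names(b)[b < 0 & sig]))
}

#' Full differential-expression pipeline for one dataset
#'
#' Convenience wrapper: characteristic direction, permutation p-values and
#' BH adjustment in one call.
#'
#' @inheritParams characteristic_direction
#' @return A [gene_signature] with coefficients, nominal and adjusted
#'   p-values.
#' @export
compute_signature <- function(dataset, config = chdir_config(),
                              id = "signature", metadata = list()) {
  sig <- characteristic_direction(dataset, config, id = id,
                                  metadata = metadata)
  p <- signature_pvalues(dataset, sig, config)
  gene_signature(id = sig$id, gene_coeffs = sig$gene_coeffs,
                 pvalues = p, adjusted_pvalues = bh_adjust(p),
                 metadata = sig$metadata)
}
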