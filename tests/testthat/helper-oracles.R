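# Independent oracles used across the suite. These deliberately avoid the
# code paths they check.

# Dense regularized-LDA solve in full gene space (no SVD projection).
dense_chdir_oracle <- function(x, labels, gamma = 0.5) {
  n <- ncol(x)
  p <- nrow(x)
  r <- min(n - 1, p)
  ctrl <- labels == "control"
  mu1 <- rowMeans(x[, ctrl, drop = FALSE])
  mu2 <- rowMeans(x[, !ctrl, drop = FALSE])
  d1 <- x[, ctrl, drop = FALSE] - mu1
  d2 <- x[, !ctrl, drop = FALSE] - mu2
  sigma <- (tcrossprod(d1) + tcrossprod(d2)) / (n - 2)
  nu <- sum(diag(sigma)) / r
  shrunk <- (1 - gamma) * sigma + gamma * nu * diag(p)
  b <- solve(shrunk, mu2 - mu1)
  stats::setNames(b / sqrt(sum(b^2)), rownames(x))
}

# Naive BH step-up: sort ascending, adjusted p_(i) = min over j >= i of
# min(1, p_(j) * m / j), returned in original order.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- pmin(1, ps * m / seq_len(m))
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[ord] <- adj
  names(out) <- names(p)
  out
}

# Exhaustive hypergeometric upper tail via exact log-binomials.
hyper_oracle <- function(N, K, q, x) {
  lo <- max(0, q - (N - K))
  hi <- min(K, q)
  if (x <= lo) return(1)
  i <- x:hi
  sum(exp(lchoose(K, i) + lchoose(N - K, q - i) - lchoose(N, q)))
}

# Full-decomposition PCA oracle: eigen-decomposition of the covariance of
# the centered observations.
pca_oracle <- function(m) {
  obs <- t(m)                                # signatures x genes
  centered <- scale(obs, center = TRUE, scale = FALSE)
  cv <- crossprod(centered) / (nrow(centered) - 1)
  eg <- eigen(cv, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  scores <- centered %*% eg$vectors
  list(scores = scores, varexp = ev / sum(ev))
}

random_unit_signature <- function(genes, seed) {
  set.seed(seed)
  v <- stats::rnorm(length(genes))
  stats::setNames(v / sqrt(sum(v^2)), genes)
}

# Small expression dataset with arbitrary values (helper for IO tests).
toy_dataset <- function(values, labels = c("control", "control",
                                           "perturbation", "perturbation")) {
  expression_dataset(values, labels, species = "human")
}
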