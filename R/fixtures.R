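#' Synthetic expression dataset with planted differential genes
#'
#' Baseline per-gene means are drawn from N(8, 1) (log-scale intensities);
#' every cell adds N(0, sigma) noise. Half of the planted genes get `+delta`
#' and the other half `-delta` added in the perturbation samples, so both
#' tails of the up/down split are exercised. Deterministic given `seed`.
#'
#' @param n_genes,n_control,n_perturb Matrix dimensions (>= 2 per class).
#' @param n_planted Number of differentially expressed genes to plant.
#' @param delta Planted shift in log units (> 0).
#' @param sigma Noise standard deviation.
#' @param seed Integer seed.
#' @param species Species tag (default `"human"`).
#' @return List with `dataset` (an [expression_dataset]) and `truth` (a
#'   `planted_truth` holding the planted gene names, per-gene shifts, noise
#'   level and seed).
#' @export
make_expression <- function(n_genes = 1000, n_control = 3, n_perturb = 3,
                            n_planted = 50, delta = 3, sigma = 1, seed = 1,
                            species = "human") {
  if (delta <= 0) stop("`delta` must be positive")
  if (n_planted > n_genes) stop("cannot plant more genes than exist")
  if (n_control < 2 || n_perturb < 2) stop(">=2 samples per class required")
  genes <- sprintf("G%04d", seq_len(n_genes))
  samples <- c(sprintf("ctrl_%d", seq_len(n_control)),
               sprintf("pert_%d", seq_len(n_perturb)))
  labels <- c(rep("control", n_control), rep("perturbation", n_perturb))
  out <- local_seed(seed, {
    base_mean <- stats::rnorm(n_genes, mean = 8, sd = 1)
    m <- base_mean + matrix(stats::rnorm(n_genes * length(samples),
                                         sd = sigma),
                            nrow = n_genes)
    planted <- sample(genes, n_planted)
    shift <- stats::setNames(rep(c(delta, -delta),
                                 length.out = n_planted), planted)
    pert_cols <- which(labels == "perturbation")
    m[match(planted, genes), pert_cols] <-
      m[match(planted, genes), pert_cols] + shift
    list(m = m, planted = planted, shift = shift)
  })
  dimnames(out$m) <- list(genes, samples)
  truth <- structure(
    list(planted_genes = sort(out$planted),
         shifts = out$shift[sort(out$planted)],
         up_genes = sort(names(out$shift)[out$shift > 0]),
         down_genes = sort(names(out$shift)[out$shift < 0]),
         noise_sd = sigma, seed = as.integer(seed)),
    class = "planted_truth")
  list(dataset = expression_dataset(out$m, labels, species,
                                    platform_id = "synthetic"),
       truth = truth)
}

#' @export
print.planted_truth <- function(x, ...) {
  cat("planted_truth:",
      if (!is.null(x$planted_genes)) sprintf("%d planted genes;",
                                             length(x$planted_genes)),
      if (!is.null(x$planted_term)) sprintf("term '%s';", x$planted_term),
      if (!is.null(x$planted_mimic)) sprintf("mimic '%s', reverse '%s';",
                                             x$planted_mimic,
                                             x$planted_reverse),
      sprintf("seed %d\n", x$seed))
  invisible(x)
}

#' Synthetic gene-set library with one planted term
#'
#' One set consists of the planted genes padded with random background genes
#' up to a size drawn from `set_size_range`; the remaining sets are uniform
#' draws from the background. Term names are unique; output is deterministic
#' given `seed`.
#'
#' @param n_sets Number of sets in the library.
#' @param set_size_range Integer range (length-2) of set sizes.
#' @param background Character vector: the gene universe.
#' @param planted_genes Genes to embed in the planted term (subset of
#'   `background`).
#' @param seed Integer seed.
#' @param name Library name.
#' @return List with `library` (a [gene_set_library]) and `truth` naming
#'   the planted term.
#' @export
make_library <- function(n_sets = 100, set_size_range = c(20, 100),
                         background, planted_genes, seed = 1,
                         name = "synthetic_library") {
  background <- toupper(as.character(background))
  planted_genes <- toupper(as.character(planted_genes))
  if (!all(planted_genes %in% background))
    stop("planted genes must be a subset of the background")
  if (n_sets < 1) stop("n_sets must be >= 1")
  lo <- min(set_size_range); hi <- max(set_size_range)
  sets <- local_seed(seed, {
    sizes <- sample(lo:hi, n_sets, replace = TRUE)
    out <- lapply(sizes, function(sz) sample(background, sz))
    sz1 <- max(sizes[[1]], length(planted_genes))
    pad <- sample(setdiff(background, planted_genes),
                  sz1 - length(planted_genes))
    out[[1]] <- c(planted_genes, pad)
    out
  })
  names(sets) <- sprintf("SET_%03d", seq_len(n_sets))
  lib <- gene_set_library(name, sets, background_size = length(background))
  truth <- structure(list(planted_term = "SET_001",
                          planted_genes = sort(planted_genes),
                          seed = as.integer(seed)),
                     class = "planted_truth")
  list(library = lib, truth = truth)
}

#' Synthetic compound signature library with planted mimic and reverser
#'
#' The planted mimic is the base signature plus N(0, noise_sd) noise,
#' renormalized; the planted reverser is its negation plus noise; decoy
#' compounds are i.i.d. N(0, 1) vectors, renormalized. Deterministic given
#' `seed`.
#'
#' @param base_signature A [gene_signature] or named coefficient vector
#'   defining the gene space.
#' @param n_compounds Number of decoy compounds (total library size is
#'   `n_compounds + 2`).
#' @param noise_sd Noise added to the planted pair (0 gives exact copies).
#' @param seed Integer seed.
#' @return List with `library` (a [compound_signature_library]) and `truth`
#'   naming `planted_mimic` and `planted_reverse`.
#' @export
make_compound_library <- function(base_signature, n_compounds = 200,
                                  noise_sd = 0.1, seed = 1) {
  if (inherits(base_signature, "gene_signature"))
    base_signature <- base_signature$gene_coeffs
  if (is.null(names(base_signature)))
    stop("base signature must be named by gene")
  genes <- toupper(names(base_signature))
  p <- length(base_signature)
  vec <- local_seed(seed, {
    renorm <- function(v) v / sqrt(sum(v^2))
    mimic <- renorm(base_signature + stats::rnorm(p, sd = noise_sd))
    reverse <- renorm(-base_signature + stats::rnorm(p, sd = noise_sd))
    decoys <- matrix(stats::rnorm(p * n_compounds), nrow = p)
    decoys <- apply(decoys, 2, renorm)
    m <- cbind(mimic, reverse, decoys)
    colnames(m) <- c("CPD_MIMIC", "CPD_REVERSE",
                     sprintf("CPD_%04d", seq_len(n_compounds)))
    m
  })
  lib <- compound_signature_library(genes, vec)
  truth <- structure(list(planted_mimic = "CPD_MIMIC",
                          planted_reverse = "CPD_REVERSE",
                          noise_sd = noise_sd, seed = as.integer(seed)),
                     class = "planted_truth")
  list(library = lib, truth = truth)
}

#' Synthetic signature collection with a shared planted theme
#'
#' Generates `n_signatures` expression datasets that share the same planted
#' gene set (each with its own noise realization), runs the full
#' differential-expression pipeline on each, and assembles the resulting
#' signatures into a collection. Emulates a themed collection in which the
#' same biological program recurs across independent studies.
#'
#' The defaults emulate a themed collection of well-replicated studies: 10
#' samples per arm and a planted program covering 2% of the measured genes.
#' A small planted fraction matters for the permutation-based significance
#' step: the pooled null contains the planted genes' own permuted
#' coefficients, so a dataset where a large share of genes is shifted yields
#' conservative p-values by construction.
#'
#' @param n_signatures Number of signatures (default 6).
#' @param tag Collection tag.
#' @param config A [chdir_config].
#' @param seed Integer seed; dataset `i` uses `seed + i`.
#' @inheritParams make_expression
#' @return List with `collection` (a [signature_collection]) and `truth`.
#' @export
make_collection <- function(n_signatures = 6, tag = "synthetic_theme",
                            n_genes = 1000, n_control = 10, n_perturb = 10,
                            n_planted = 20, delta = 3, sigma = 1,
                            config = chdir_config(), seed = 1) {
  if (n_signatures < 1) stop("n_signatures must be >= 1")
  first <- make_expression(n_genes, n_control, n_perturb, n_planted,
                           delta, sigma, seed = seed)
  truth <- first$truth
  sigs <- vector("list", n_signatures)
  groups <- c("groupA", "groupB")
  for (i in seq_len(n_signatures)) {
    fx <- if (i == 1) first else
      replant_expression(n_genes, n_control, n_perturb, truth, sigma,
                         seed = seed + i)
    cfg <- chdir_config(gamma = config$gamma,
                        n_permutations = config$n_permutations,
                        alpha = config$alpha, seed = config$seed + i)
    sigs[[i]] <- compute_signature(
      fx$dataset, cfg, id = sprintf("sig_%02d", i),
      metadata = list(organism = "human",
                      cell_or_tissue = groups[(i %% 2) + 1],
                      tag = tag))
  }
  list(collection = signature_collection(tag, sigs,
                                         provenance = "synthetic fixture"),
       truth = truth)
}

## Fresh noise realization around the same planted truth (shared gene names
## and shifts) so all collection members carry the same theme.
replant_expression <- function(n_genes, n_control, n_perturb, truth, sigma,
                               seed) {
  genes <- sprintf("G%04d", seq_len(n_genes))
  samples <- c(sprintf("ctrl_%d", seq_len(n_control)),
               sprintf("pert_%d", seq_len(n_perturb)))
  labels <- c(rep("control", n_control), rep("perturbation", n_perturb))
  m <- local_seed(seed, {
    base_mean <- stats::rnorm(n_genes, mean = 8, sd = 1)
    m <- base_mean + matrix(stats::rnorm(n_genes * length(samples),
                                         sd = sigma), nrow = n_genes)
    dimnames(m) <- list(genes, samples)
    pert_cols <- which(labels == "perturbation")
    m[truth$planted_genes, pert_cols] <-
      m[truth$planted_genes, pert_cols] + truth$shifts[truth$planted_genes]
    m
  })
  list(dataset = expression_dataset(m, labels, "human",
                                    platform_id = "synthetic"),
       truth = truth)
}

#' Write a complete fixture set to disk
#'
#' Emits expression TSV + label TSV, a GMT library, a compound library TSV
#' and a planted-truth JSON into `dir` — everything needed to exercise the
#' command-line pipeline end to end.
#'
#' Defaults follow the well-replicated regime of [make_collection()] (10
#' samples per arm, 2% planted genes) so that the full pipeline — including
#' the BH-thresholded up/down split — is exercised end to end.
#'
#' @param dir Output directory.
#' @param seed Integer seed.
#' @param n_genes,n_control,n_perturb,n_planted,delta,sigma Passed to
#'   [make_expression()].
#' @return Invisible list of the generated objects.
#' @export
write_fixture_bundle <- function(dir, seed = 1, n_genes = 1000,
                                 n_control = 10, n_perturb = 10,
                                 n_planted = 20, delta = 3, sigma = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fx <- make_expression(n_genes = n_genes, n_control = n_control,
                        n_perturb = n_perturb, n_planted = n_planted,
                        delta = delta, sigma = sigma, seed = seed)
  m <- fx$dataset$values
  writeLines(
    c(paste(c("gene", colnames(m)), collapse = "\t"),
      vapply(seq_len(nrow(m)), function(i) {
        paste(c(rownames(m)[i], formatC(m[i, ], format = "g", digits = 12)),
              collapse = "\t")
      }, character(1))),
    file.path(dir, "expression.tsv"))
  writeLines(paste(colnames(m), fx$dataset$class_labels, sep = "\t"),
             file.path(dir, "labels.tsv"))
  lib <- make_library(n_sets = 100, set_size_range = c(20, 60),
                      background = rownames(m),
                      planted_genes = fx$truth$planted_genes, seed = seed)
  write_gmt(lib$library, file.path(dir, "library.gmt"))
  sig <- characteristic_direction(fx$dataset, chdir_config(seed = seed))
  cpd <- make_compound_library(sig, n_compounds = 100, noise_sd = 0.1,
                               seed = seed)
  write_compound_library(cpd$library, file.path(dir, "compounds.tsv"))
  truth <- c(fx$truth[c("planted_genes", "up_genes", "down_genes",
                        "noise_sd")],
             list(planted_term = lib$truth$planted_term,
                  planted_mimic = cpd$truth$planted_mimic,
                  planted_reverse = cpd$truth$planted_reverse,
                  seed = seed))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(expression = fx, library = lib, compounds = cpd,
                 truth = truth))
}
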