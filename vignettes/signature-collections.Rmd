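---
title: "Methods: signature-collection analysis in sigvecta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature-collection analysis in sigvecta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigvecta)
```

# The model

## Characteristic-direction differential expression

Given a genes × samples matrix of log-scale expression with `n1` control and
`n2` perturbation samples, the characteristic direction is the unit normal
of the hyperplane that best separates the two classes under linear
discriminant analysis. Writing Σ for the pooled within-class covariance and
Δμ for the perturbation-minus-control mean difference, the coefficient
vector is

$$ b \propto \tilde\Sigma^{-1}\,\Delta\mu, \qquad
   \tilde\Sigma = (1-\gamma)\,\Sigma + \gamma\,\nu\,I, \qquad
   \nu = \operatorname{tr}(\Sigma)/r, \qquad \lVert b\rVert_2 = 1 . $$

A positive coefficient means higher expression under perturbation. The
method assumes roughly Gaussian within-class variation on the log scale and
a shared within-class covariance; it scores genes by their alignment with
the discriminating direction, so a gene with a modest shift that moves
*coherently* with the class split can outrank a gene with a large but noisy
fold change.

**Numerical route.** With thousands of genes and a handful of samples, Σ in
gene space is massively rank-deficient. The implementation centers each
sample by the global per-gene mean and projects onto the row space of the
centered data — the top `r = min(n1 + n2 − 1, p)` right-singular directions
— before forming Σ and solving. We keep the *full* rank of the centered data
(`n − 1`, not the within-class rank `n − 2`) deliberately: Δμ has a
component along the (n−1)-th singular direction, and retaining it makes the
projected solve algebraically identical to a direct dense solve of
$\tilde\Sigma^{-1}\Delta\mu$ in gene space. The test suite exploits this:
on small random datasets the projected solve must agree with an independent
dense solve to 1e-8 per coefficient. The solve is O(n³) in samples rather
than genes.

**Shrinkage γ** (unitless, in [0, 1], default 0.5) interpolates between the
empirical pooled covariance (γ = 0, singular whenever genes outnumber
samples) and a scaled identity (γ = 1, which reduces the direction to the
standardized mean difference). The scaling ν = tr(Σ)/r keeps the two terms
on a comparable scale. The default 0.5 gives equal weight; it is exposed in
`chdir_config()` because no single constant is canonical. At γ = 0 with
degenerate data the solve fails with an explicit error advising γ > 0.

## Per-gene significance

The significance procedure is a design choice of this package (the
up/down-stream contract only fixes the Benjamini–Hochberg 0.01 threshold,
not the test): class labels are permuted preserving class sizes, the full
characteristic direction is recomputed per permutation, and **all** permuted
absolute coefficients — across genes and permutations — are pooled into one
null sample. The nominal p-value of gene *g* is

$$ p_g = \frac{1 + \#\{\text{null} \ge |b_g|\}}{1 + \text{null size}} , $$

so p > 0 always. When the space of distinct label assignments (`choose(n,
n1)`) has at most `n_permutations` elements it is enumerated exhaustively,
excluding the observed assignment and its complement (both reproduce the
observed |coefficients| exactly and would contaminate the null); otherwise
`n_permutations` assignments (default 1000) are sampled with replacement,
rejecting those two. Fewer than 10 possible assignments is an error. BH
adjustment is the standard step-up procedure (`stats::p.adjust`), and
`split_up_down()` takes genes with adjusted p ≤ α (default 0.01), split by
coefficient sign; zero coefficients join neither set.

**Known limitation — conservativeness of the pooled null.** Because the
null pools permuted coefficients of *all* genes, genes that are truly
differential contribute their own (still large) permuted coefficients under
label-imbalanced permutations. When a large fraction of genes is shifted,
or when classes are tiny (3v3 leaves only 18 usable permutations), the null
tail is inflated and BH at 0.01 keeps few or no genes. This is a property
of the procedure, not a bug: the coefficient *ranking* is unaffected, and
recovery-by-rank is the primary contract. Significance-based splitting is
well powered in the regime the collection generator emulates (see below).

## Enrichment with a rank-calibrated combined score

For a query gene set against a GMT library over a background universe of
size N, each term of size K gets the hypergeometric upper tail
P(X ≥ x) for the overlap x (computed in log space via `stats::phyper`),
terms are ranked by ascending p with lexicographic tie-break on term name,
and the rank is standardized against a Monte-Carlo calibration:
z = (rank − μ_rank)/σ_rank, with μ and σ estimated from `n_draws` (default
200, minimum 50) uniform random queries of the same size. The combined
score is c = ln(p) · z — positive and large when a term is both
individually significant and ranked far better than its calibrated
expectation; p = 1 forces c = 0 exactly. The top 50 terms per query are
retained. Numerical guards: σ_rank is floored at 0.1 (identical or
near-deterministic rank distributions would otherwise divide by ~0), and
calibrations are shared across query sizes within a nearest-10 bucket
(floored at 10, capped at N) to bound cost. The background defaults to the
library's gene union; when a declared N exceeds the union size M, random
draws sample their in-union count from Hypergeometric(M, N − M, q), which
is distributionally exact.

Enrichment runs twice per signature — once for the significant up genes,
once for the down genes — and the per-query score vectors are outer-joined
into a term × signature matrix (columns `id|up`, `id|down`) with zeros for
absent pairs. Up and down columns are kept separate and unsigned; merging
conventions vary across tools and a display-side negation is trivially
applied downstream if wanted.

## Compound matching

A query signature is compared with each column of a compound signature
library by cosine similarity over the intersection of gene spaces (a GEO
signature and an L1000-style library never share their full spaces). The
similarity s ∈ [1, −1] is exactly the cosine distance d ∈ [0, 2] translated
by s = 1 − d. Matches need at least `min_overlap` shared genes (default
10) and a nonzero norm on the shared space; failures are skipped with a
warning rather than scored. The top 50 strictly positive similarities are
mimickers, the top 50 strictly negative are reversers (s = 0 joins
neither — "similar or opposite" implies a strict sign), ties broken by
compound id. The query uses the full coefficient vector rather than only
significant genes: cosine similarity on sparse hard-thresholded vectors is
unstable at small overlap. Negating the query swaps the two lists with
negated scores, exactly — an invariant the tests assert.

## Collection-level aggregation

The gene × signature matrix outer-joins the signatures' coefficient vectors
with zero fill (zero = "no change in expression"), rows sorted
lexicographically. Row filters: *sum of change* keeps the `top_n` most
positive and `top_n` most negative row sums (the most consistently up- and
down-regulated genes across the collection); *variance* keeps the `top_n`
most variable rows. PCA treats signatures as observations and genes as
features, mean-centers but does not variance-scale (coefficients are
already on a common unit-norm scale; scaling would inflate near-constant
genes), and reports the top three components with their
variance-explained fractions. Component signs are fixed by making each
component's largest-magnitude gene loading positive, so coordinates are
reproducible across platforms. A collection of identical signatures centers
to the zero matrix and maps to all-zero coordinates. Fewer than three
signatures pads the missing components with zeros, with a warning.

Heatmap orders come from average-linkage agglomerative clustering on cosine
distance (1 − cosine similarity; zero-norm vectors sit at distance 1 from
everything), emulating the default behavior of interactive clustergram
tools. Vectors are sorted by label before clustering, so the leaf order is
a function of the labeled data and invariant to input column order. PCA
operates on the *unfiltered* gene matrix by default; filtering is a
display-side reduction.

`build_report()` composes all views — optionally on a subset of signature
ids (a custom report) and with a metadata-field categorization of the PCA
points — and `write_report()` emits three TSV matrices plus a JSON
manifest. Two runs with the same inputs and seed are byte-identical except
for the manifest timestamp.

# The synthetic-data generator

`make_expression()` draws per-gene baseline means from N(8, 1) (typical
log2 microarray intensity scale) and adds N(0, σ) noise per cell; planted
genes receive an additive ±δ shift in perturbation samples, half up and
half down. `make_library()` embeds the planted genes in one term of an
otherwise uniform-random GMT library; `make_compound_library()` plants an
exact-up-to-noise copy and negation of a base signature among unit-norm
Gaussian decoys. All generators are bit-reproducible given a seed, and all
seeds thread through a single RNG-state-preserving helper.

The single-dataset conditions used throughout the recovery tests are 1000
genes, 50 planted at δ = 3 log-units over σ = 1 noise, 3 vs 3 samples — a
strong perturbation measured with minimal replication. The *collection*
generator instead emulates well-replicated studies: 6 signatures sharing
one planted 20-gene program among 1000 genes, 10 vs 10 samples each. The
larger arms matter for the significance step — with 10v10 the permutation
space is ~1.8e5, imbalanced permutations are rare in a 1000-draw null, and
BH at 0.01 recovers essentially the whole planted program — whereas at 3v3
the pooled null is too coarse (18 permutations) for any gene to clear the
threshold, however strong the shift.

What the generator does *not* emulate: probe-level artifacts, batch and
platform effects, correlated co-expression blocks, heavy-tailed noise, and
realistic gene-set overlap structure. Passing tests therefore demonstrate
algorithmic correctness and planted-truth recovery under the stated
Gaussian model, not robustness to the full messiness of public expression
repositories.

# Test and acceptance problem sizes

The suite validates the characteristic direction against an independent
dense-solve oracle on 200 random ≤ 6-gene datasets; hypergeometric tails
against exhaustive enumeration for all N ≤ 30; BH against a naive step-up
oracle on 1000 random vectors; PCA against a spectral-decomposition oracle
on 50 random matrices up to 50 × 20; and recovery rates over 20 generator
seeds per stage. The acceptance script reruns the planted-truth pipeline at
the same sizes over 10 seeds. These sizes were chosen so the full suite
completes in well under a minute per module while keeping Monte-Carlo
margins (binomial 99% bounds, ≥ 95% rank-1 rates) meaningful.
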