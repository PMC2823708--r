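---
title: "Unmixing tumor expression into cell states and inferring their phylogeny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unmixing tumor expression into cell states and inferring their phylogeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixphylo)
```

## The model

Tumors are evolving cell populations, and a bulk expression profile is an
average over the cell states present in the sample: remnants of earlier
progression stages, the currently dominant clone, and infiltrating normal
tissue. mixphylo models a $d \times n$ linear-scale expression matrix $M$
(genes by samples) as a convex mixture

$$ M \approx C\,F^{\top}, \qquad F \mathbf{1} = \mathbf{1}, \; F \ge 0, $$

where the columns of the $d \times k$ matrix $C$ are the expression
profiles of $k$ recurring *cell states* and row $t$ of the $n \times k$
matrix $F$ gives the fractions of sample $t$ attributed to each state.
Geometrically, every sample lies inside the simplex whose vertices are the
states; unmixing is the problem of locating that simplex from a cloud of
interior points. Linearity is the key assumption — it is defensible for
raw (linear-scale) expression, not for log-ratios, which is why the
preprocessing step exponentiates logged input before fitting.

## The fitting procedure

`unmix(M, k)` proceeds in three stages.

**Dimension reduction.** A $k$-vertex simplex is intrinsically
$(k-1)$-dimensional, so the sample cloud is first projected onto its $k-1$
leading principal axes (SVD of the gene-centered matrix), giving scores
$P$, an orthonormal basis $V$, and per-gene means $A$ with
$M \approx (PV)^\top + A$. PCA is used only as an embedding: principal
axes are *not* interpreted as cell states (states share co-regulated gene
modules and are far from orthogonal). If the centered matrix has rank
below $k-1$ the trailing dimensions are zero-padded and flagged.

**Minimum-volume enclosing simplex.** The most parsimonious component set
is taken to be the smallest simplex containing all the points — minimal
empty volume in which data could have been, but was not, observed. Since
no sub-exponential exact algorithm is known, the search is a randomized
restart heuristic:

1. *Seeding.* Pick two observed points with probability proportional to
   their distance to the $k$-th power, then grow the vertex set one
   observed point at a time with probability proportional to the volume
   (in the current affine span) of the candidate simplex, again to the
   $k$-th power. The exponent sharpens the preference for spread-out,
   well-conditioned seeds; affinely dependent candidates get zero weight.
2. *Face expansion.* Each face is the hyperplane through all vertices but
   one; a point's distance to it is signed negative on the excluded
   vertex's side (inside). Repeatedly find the globally largest positive
   distance $d_{ij}$ and translate the face's $k-1$ vertices by $d_{ij}$
   along the face's outward unit normal, which places the hyperplane
   through the violating point. Volume grows monotonically and the loop
   stops when every signed distance is at most `tol`. The translation is
   along the face *normal*: moving vertices within the face's own tangent
   plane can never enclose the violator, so the normal direction is the
   only reading of outward face translation that terminates.
3. *Restarts.* Repeat `n_restarts` times (default 100) and keep the
   smallest enclosing simplex. The restart count is deliberately decoupled
   from the sample count $n$: search effort and data size are different
   knobs.

**Components and fractions.** Vertices map back to gene space as
$C = K_{\min} V + A$. Fractions solve, per sample, the $k$ equations
"coordinates + sum-to-one" against the vertices in reduced space — exact
barycentric coordinates for enclosed points. A `fractions_space = "gene"`
switch instead solves the overdetermined gene-space system
$C f = m_t,\ \mathbf{1}^\top f = 1$ by equality-constrained least squares;
on noise-free data the two agree, and the reduced-space solve is the
default because it is exact and cheap. Tiny negative fractions from
round-off are kept in `F` as reported; `clamp_fractions()` (clamp at zero,
renormalize) is applied only where the log-domain similarity requires
non-negativity.

## Phylogeny over components

States that co-occur in the same tumors are plausibly on the same
progression pathway. For components $i, j$ the sharing similarity is

$$ s_{ij} \;=\; \log \frac{\sum_t f_{ti} f_{tj}}
   {\left(\sum_t f_{ti}\right)\left(\sum_t f_{tj}\right)}, $$

a log-ratio of co-occurrence mass to the product of marginal masses (a
correlated-sampling versus independent-sampling likelihood contrast). The
phylogeny is the spanning tree maximizing total sharing — the minimum
spanning tree under weights $-s_{ij}$. Kruskal's algorithm with ties
broken by lexicographic edge index makes the result deterministic. If two
components never co-occur the ratio is zero; $s_{ij}$ is floored at
`log(.Machine$double.eps)` to keep weights finite (any common shift of all
$s_{ij}$ leaves the tree unchanged, so the floor's exact value is
immaterial so long as it is far below real similarities). Any
normalization of the fractions by a per-row constant also cancels, which
is why the measure is scale-free across tumors.

The tree is reported unrooted — an MST has no root. `as_newick()` roots it
at a named component (typically the normal-tissue-associated one) for
display only.

**Bootstrap confidence.** `bootstrap_tree()` re-runs only the phylogeny
stage: each replicate retains each sample independently with probability
`keep_prob` (default 0.9 with `reps = 10000` — per-sample retention is
Bernoulli, not fixed-size subsampling, which is the natural reading of
"each sample preserved 90% of the time"), and an edge's confidence is its
appearance fraction across valid replicates.
Replicates with fewer than two retained samples or an emptied component
are skipped; more than half skipped is an error.

## The simulators — what they emulate and what they do not

`simulate_dataset()` states the benchmark world: component profiles with
i.i.d. standard-normal gene expression, $d = 10{,}000$ genes and
$n = 100$ samples by default, and one of two mixing protocols:

- **uniform** — every sample mixes all $k$ components with fractions drawn
  uniformly on the probability simplex (symmetric Dirichlet with unit
  concentration, via sorted-uniform spacings);
- **tree** — components sit on a breadth-first complete binary tree (node
  1 the root, parent of node $i$ is $\lfloor i/2 \rfloor$); each sample
  picks a node uniformly and mixes exactly the components on its
  root-to-node path, uniformly on that sub-simplex. At $\sigma = 0$ this
  produces the simplicial-complex geometry evolution should produce:
  branch faces joined at the root vertex.

Measurement noise is multiplicative log-normal,
$m_{ij} = (CF^\top)_{ij}\, e^{\sigma Z_{ij}}$ with $Z_{ij}$ standard
normal, so $\sigma$ is the per-entry log-scale noise ("noise fraction";
$\sigma = 1$ is signal-sized noise). At $\sigma = 0$ the signal is
returned bit-identically. Noise is independent per gene and per sample —
deliberately so, and it is why fraction recovery stays accurate even at
high $\sigma$: errors average out over thousands of genes. Correlated
gene modules, sample-wide batch effects, and platform saturation are
*not* modelled, so a green simulation test establishes correctness of the
algorithm under the stated generative model, not robustness to structured
real-array artifacts.

## Scoring against ground truth

Inferred components are aligned to true ones by the total-distance-
minimizing column matching (Euclidean distance in gene space), computed
exactly by branch-and-bound over permutations — practical because $k$ is
small by design (guarded at $k \le 10$; no linear-assignment library is
required). The same permutation is applied to fraction columns and tree
node labels. Errors are root-mean-square over *all* entries of the matched
matrices; tree accuracy is the fraction of true edges present in the
inferred tree; its chance baseline for a $k$-node tree is
$(k-1)/\binom{k}{2} = 2/k$ (67% at $k = 3$, 29% at $k = 7$), which a
Monte-Carlo test over uniformly random spanning trees (random Prüfer
sequences) confirms.

## Numerical choices

- **Containment tolerance.** `tol` defaults to $10^{-9}$ times the point-
  cloud diameter; expansion is capped at $10\,k\,n$ iterations and errors
  if exceeded (possible at `tol = 0` under round-off).
- **Degeneracy.** Candidate seeds with normalized affine volume below
  $10^{-6}$ (relative to cloud scale, per dimension) are given zero
  weight; Gram-determinant round-off sits near $\sqrt{\varepsilon}$, well
  below this cut. If every candidate weight vanishes the sampler restarts
  from scratch up to 50 times, then reports a degenerate point set.
- **Volume.** Computed by the edge-matrix determinant
  $|\det(v_i - v_0)|/(k-1)!$ — exact for a simplex in any dimension; the
  test suite cross-checks it against the independent Cayley–Menger closed
  form rather than a convex-hull library.
- **Reproducibility.** Every stochastic entry point (`simulate_dataset()`,
  `unmix()`, `bootstrap_tree()`, `run_sweep()`) takes an explicit `seed`
  and restores the caller's RNG state; sweeps derive an independent seed
  per grid cell so results are order-independent.
- **PCA signs** are arbitrary and never interpreted; all downstream
  quantities are invariant to them.

## Worked example

```{r example}
sim <- simulate_dataset(k = 3, sigma = 0.1, d = 2000, n = 100,
                        protocol = "tree", seed = 1)
fit <- unmix(sim$expression, k = 3, n_restarts = 100, seed = 2)
fit
evaluate_fit(sim, fit)
phy <- bootstrap_tree(fit$fractions, reps = 1000, keep_prob = 0.9, seed = 3)
tidy(phy)
```

```{r plots, fig.width = 6, fig.height = 4}
autoplot(fit)
autoplot(phy)
```

For cohort data shipped as log2 ratios (the usual two-channel microarray
convention), convert first. A worked target for this chain is the lung
tumor cohort at GEO accession GSE1037 — normals plus seven annotated tumor
subtypes — analysed with `k = 4` and `k = 6`:

```{r real, eval = FALSE}
M <- load_expression("expression_log2.tsv") |> preprocess_log_to_linear()
fit <- unmix(M, k = 4, n_restarts = 100, seed = 1)
summarize_fractions_by_type(fit, labels)      # mean fractions per subtype
sorted_component_gene_table(fit)              # per-component marker genes
phy <- bootstrap_tree(fit, reps = 10000, keep_prob = 0.9, seed = 2)
as_newick(phy, root = "C1")                   # rooted display form
```

## Design choices where the design was open

- **Fractions in reduced space by default.** Two formulations are natural:
  an overdetermined least-squares system over all genes, or the square
  "coordinates + normalization" system in reduced space. Both are
  implemented; reduced space is the default because for enclosed points it
  returns exact barycentric coordinates, and the two agree on clean data.
- **Restart count decoupled from $n$** (default 100): search effort should
  not silently scale with cohort size.
- **Bernoulli bootstrap retention** rather than fixed-size 90%
  subsampling: the natural reading of per-sample retention probability.
- **Matching in gene space** (not reduced space): component distances in
  gene space are the physically meaningful ones; a reduced-space option
  would be faster but is not the reference behaviour.
- **Exact permutation matching** instead of a Hungarian-algorithm
  dependency: equivalent optimum, no extra dependency, exact for the
  $k \le 10$ regime the method addresses.
- **Monotone-degradation check at reduced scale.** The validation grid at
  $d = 1{,}000$ with 3 replicates shows error growth in $k$ clearly from
  $k = 4$ upward, but $k = 3$ and $k = 4$ are statistically tied there
  (both medians $\approx 0.07$ at $\sigma = 0.1$), so the strict
  adjacent-pair ordering can fail at the first step at that scale. The
  check is kept strict rather than loosened; at the full $d = 10{,}000$
  scale the separation is clean.

## Known limitations

- The minimum-volume criterion is sensitive to outliers: a single aberrant
  sample drags a vertex outward, which dilutes fraction specificity (the
  5–20% nonspecific assignments seen on real cohorts). No shrink-wrap
  post-optimization or robust variant is attempted.
- Component count $k$ is an input, not inferred.
- The phylogeny is constrained to a tree over observed states: no missing
  (Steiner) ancestral states, no networks, no forests; sharing-based
  inference can invert the order of states along a single lineage.
- Performance degrades quickly beyond $k \approx 7$ components, consistent
  with the validation sweeps (`run_sweep()`).
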