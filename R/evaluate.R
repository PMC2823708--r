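#' Match inferred components to ground-truth components
#'
#' Maximum-weight bipartite matching of columns between the true and
#' inferred component matrices, weighted by negative Euclidean distance in
#' gene space -- i.e. the column assignment minimizing total distance.
#' Solved exactly by branch-and-bound over permutations (k is small by
#' design; guarded at `k <= 10`). Matching uses raw distances: adding a
#' common shift to all columns changes the optimum in general.
#'
#' @param C_true,C_inferred `d x k` matrices with matching shapes.
#' @return Integer permutation `perm` such that `C_inferred[, perm]` aligns
#'   column-wise with `C_true`; attribute `"cost"` holds the total distance.
#' @export
match_components <- function(C_true, C_inferred) {
  if (!all(dim(C_true) == dim(C_inferred)))
    stop("column-count (and row) mismatch between true and inferred components")
  k <- ncol(C_true)
  if (k > 10) stop("exact matching supported for k <= 10")
  D2 <- outer(colSums(C_true^2), colSums(C_inferred^2), "+") -
    2 * crossprod(C_true, C_inferred)
  D <- sqrt(pmax(D2, 0))  # round-off can leave tiny negatives for identical cols
  best <- list(cost = Inf, perm = integer(0))
  search <- function(i, used, cost, perm) {
    if (cost >= best$cost) return()
    if (i > k) { best <<- list(cost = cost, perm = perm); return() }
    for (j in order(D[i, ])) {
      if (!used[j]) {
        used[j] <- TRUE
        search(i + 1L, used, cost + D[i, j], c(perm, j))
        used[j] <- FALSE
      }
    }
  }
  search(1L, logical(k), 0, integer(0))
  structure(best$perm, cost = best$cost)
}

#' Root-mean-square error of matched components
#'
#' `sqrt(mean((C_true - C_inferred[, matching])^2))` over all `d * k`
#' entries, after aligning columns with the matching permutation.
#'
#' @param C_true,C_inferred `d x k` matrices.
#' @param matching Permutation from [match_components()]; computed if
#'   missing.
#' @return Non-negative scalar.
#' @export
rmse_components <- function(C_true, C_inferred,
                            matching = match_components(C_true, C_inferred)) {
  sqrt(mean((C_true - C_inferred[, matching, drop = FALSE])^2))
}

#' Root-mean-square error of matched mixture fractions
#'
#' Same formula as [rmse_components()] over all `n * k` fraction entries,
#' with columns aligned by the component matching.
#'
#' @param F_true,F_inferred `n x k` fraction matrices.
#' @param matching Permutation from [match_components()] (on the component
#'   matrices -- the same matching is applied to fractions).
#' @return Non-negative scalar.
#' @export
rmse_fractions <- function(F_true, F_inferred, matching) {
  stopifnot(all(dim(F_true) == dim(F_inferred)))
  sqrt(mean((F_true - F_inferred[, matching, drop = FALSE])^2))
}

# Canonical unordered edge representation: sorted pairs, one per row.
canonical_edges <- function(edges) {
  e <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

#' Fraction of true tree edges recovered
#'
#' Relabels the inferred tree's nodes through the component matching and
#' reports `|inferred edges intersect true edges| / |true edges|` over
#' unordered node pairs.
#'
#' @param tree_true,tree_inferred Edge matrices (2 columns of node indices).
#' @param matching Permutation from [match_components()]: `matching[i]` is
#'   the inferred component aligned with true component `i`. Identity if
#'   missing.
#' @return Scalar in `[0, 1]`.
#' @export
tree_edge_accuracy <- function(tree_true, tree_inferred, matching = NULL) {
  true_e <- canonical_edges(tree_true)
  inf_e <- tree_inferred
  if (!is.null(matching)) {
    relabel <- match(seq_along(matching), matching)  # inferred j -> true i
    inf_e <- cbind(relabel[inf_e[, 1]], relabel[inf_e[, 2]])
  }
  inf_e <- canonical_edges(inf_e)
  key <- function(e) paste(e[, 1], e[, 2])
  mean(key(true_e) %in% key(inf_e))
}

#' Chance baseline for tree-edge accuracy
#'
#' The expected fraction of a fixed `k`-node tree's edges found in a
#' uniformly random spanning tree: `(k - 1) / choose(k, 2) = 2 / k`
#' (each of the `choose(k, 2)` node pairs is equally likely to be among the
#' `k - 1` edges, by symmetry of the uniform distribution over spanning
#' trees of the complete graph).
#'
#' @param k Number of tree nodes (>= 2).
#' @return Scalar in `(0, 1]`; e.g. 2/3 for `k = 3`, 2/7 for `k = 7`.
#' @export
chance_edge_accuracy <- function(k) {
  stopifnot(k >= 2)
  (k - 1) / choose(k, 2)
}

#' Score an unmixing fit against simulation ground truth
#'
#' Convenience wrapper: matches components in gene space, computes both
#' RMSEs, and (for tree-protocol simulations) infers the phylogeny from the
#' fitted fractions and scores edge recovery.
#'
#' @param sim A `"mix_sim"` from [simulate_dataset()].
#' @param fit A `"mix_fit"` from [unmix()].
#' @return A one-row tibble: `rmse_C`, `rmse_F`, `tree_acc` (NA for uniform
#'   protocol), `chance_acc`.
#' @export
evaluate_fit <- function(sim, fit) {
  perm <- match_components(sim$components_true, fit$components)
  tree_acc <- NA_real_
  if (!is.null(sim$tree_true)) {
    phy <- infer_tree(sharing_similarity(fit$fractions))
    tree_acc <- tree_edge_accuracy(sim$tree_true, phy$edges, perm)
  }
  tibble::tibble(
    rmse_C = rmse_components(sim$components_true, fit$components, perm),
    rmse_F = rmse_fractions(sim$fractions_true, fit$fractions, perm),
    tree_acc = tree_acc,
    chance_acc = chance_edge_accuracy(sim$config$k))
}

#' Run a simulation-evaluation sweep over a parameter grid
#'
#' Orchestrates simulate -> unmix -> (phylogeny) -> metrics over the cross
#' product of protocols, component counts and noise levels, with `reps`
#' independent repetitions per cell. Each grid cell gets its own seed
#' derived from `seed`, so results do not depend on execution order.
#'
#' @param protocols Character subset of `c("uniform", "tree")`.
#' @param ks Integer vector of component counts.
#' @param sigmas Numeric vector of noise fractions.
#' @param reps Repetitions per grid cell (the benchmark protocol used 10).
#' @param d,n Dataset dimensions (benchmark scale: `d = 10000`, `n = 100`).
#' @param n_restarts Restarts per unmixing run.
#' @param seed Base seed for the whole sweep.
#' @return A tidy tibble with one row per (protocol, k, sigma, rep):
#'   columns `protocol`, `k`, `sigma`, `rep`, `rmse_C`, `rmse_F`,
#'   `tree_acc`, `chance_acc`.
#' @examples
#' \donttest{
#' run_sweep(protocols = "uniform", ks = 3, sigmas = c(0, 0.5),
#'           reps = 1, d = 200, n = 40, n_restarts = 20, seed = 1)
#' }
#' @export
run_sweep <- function(protocols = c("uniform", "tree"), ks = 3:7,
                      sigmas = seq(0, 1, by = 0.1), reps = 10,
                      d = 10000, n = 100, n_restarts = 100, seed = 1) {
  grid <- tidyr::expand_grid(protocol = protocols, k = ks, sigma = sigmas,
                             rep = seq_len(reps))
  grid$cell_seed <- (seed * 7919L + seq_len(nrow(grid)) * 104729L) %% 2147483647L
  res <- purrr::pmap(grid, function(protocol, k, sigma, rep, cell_seed) {
    sim <- simulate_dataset(k = k, sigma = sigma, d = d, n = n,
                            protocol = protocol, seed = cell_seed)
    fit <- unmix(sim$expression, k = k, n_restarts = n_restarts,
                 seed = cell_seed + 1L)
    evaluate_fit(sim, fit)
  })
  dplyr::bind_cols(grid[c("protocol", "k", "sigma", "rep")],
                   dplyr::bind_rows(res))
}
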