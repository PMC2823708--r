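#' Simulate cell-state component expression profiles
#'
#' Draws a `d x k` matrix of hypothetical expression profiles, one column per
#' cell-state component, with every entry an independent standard-normal
#' draw. This is the component model used by both simulation protocols:
#' components are generic dense expression signatures with no imposed
#' correlation structure, so any geometric structure in the simulated sample
#' cloud comes from the mixing process, not the components themselves.
#'
#' @param d Number of genes (rows).
#' @param k Number of components (columns).
#' @return A `d x k` numeric matrix with rownames `g0001...` and colnames
#'   `C1...Ck`.
#' @seealso [simulate_dataset()] for the full generator.
#' @export
simulate_components <- function(d, k) {
  stopifnot(d >= 1, k >= 1)
  C <- matrix(stats::rnorm(d * k), nrow = d, ncol = k)
  dimnames(C) <- list(gene_ids(d), component_ids(k))
  C
}

#' Sample mixture fractions uniformly on the simplex
#'
#' Each row is an independent draw from the uniform distribution on the
#' `(k-1)`-dimensional probability simplex (equivalently Dirichlet with unit
#' concentration), generated by the sorted-uniform spacings construction.
#'
#' @param n Number of samples (rows).
#' @param k Number of components (columns).
#' @return An `n x k` matrix whose rows are non-negative and sum to 1.
#' @export
sample_uniform_fractions <- function(n, k) {
  stopifnot(n >= 1, k >= 2)
  u <- matrix(stats::runif(n * (k - 1)), nrow = n)
  s <- t(apply(u, 1, sort))
  if (k == 2) s <- matrix(s, nrow = n)  # apply() drops to a vector for k = 2
  f <- cbind(s, 1) - cbind(0, s)
  dimnames(f) <- list(sample_ids(n), component_ids(k))
  f
}

#' Complete binary tree over k components
#'
#' Builds the breadth-first complete binary tree on nodes `1..k` used by the
#' tree-embedded simulation protocol: node 1 is the root and node `i > 1`
#' has parent `floor(i/2)`.
#'
#' @param k Number of nodes.
#' @return A `(k-1) x 2` integer matrix of edges `(parent, child)`.
#' @export
make_binary_tree <- function(k) {
  stopifnot(k >= 2)
  cbind(parent = as.integer(2:k %/% 2), child = as.integer(2:k))
}

# root-to-node path (node indices, root first) in a parent-indexed tree
tree_path <- function(node, parent) {
  path <- node
  while (node != 1L) {
    node <- parent[node]
    path <- c(node, path)
  }
  path
}

#' Sample tree-embedded mixture fractions
#'
#' Implements the evolutionary mixing protocol: each simulated tumor picks a
#' tree node uniformly at random and mixes exactly the components on the
#' root-to-node path, with fractions uniform on the sub-simplex of the
#' path's components and zero elsewhere. Root-only samples are pure root
#' component.
#'
#' @param n Number of samples.
#' @param k Number of components.
#' @param tree Edge matrix as produced by [make_binary_tree()].
#' @return An `n x k` fraction matrix; each row's support is the node set of
#'   one root-to-node path.
#' @export
sample_tree_fractions <- function(n, k, tree = make_binary_tree(k)) {
  stopifnot(n >= 1, k >= 2, nrow(tree) == k - 1)
  parent <- integer(k)
  parent[tree[, 2]] <- tree[, 1]
  f <- matrix(0, n, k, dimnames = list(sample_ids(n), component_ids(k)))
  nodes <- sample.int(k, n, replace = TRUE)
  for (i in seq_len(n)) {
    path <- tree_path(nodes[i], parent)
    m <- length(path)
    if (m == 1L) {
      f[i, path] <- 1
    } else {
      s <- sort(stats::runif(m - 1))
      f[i, path] <- c(s, 1) - c(0, s)
    }
  }
  f
}

#' Apply multiplicative log-normal measurement noise
#'
#' Multiplies every entry of the noise-free signal by `exp(sigma * Z)` with
#' `Z` independent standard normal, so `sigma` is the standard deviation of
#' the per-entry log measurement error ("noise fraction": `sigma = 1` means
#' noise on the order of signal). `sigma = 0` returns the signal unchanged
#' without consuming random draws.
#'
#' @param signal A numeric matrix (genes x samples).
#' @param sigma Non-negative noise fraction.
#' @return A matrix of the same shape; entries keep the sign of the signal.
#' @export
apply_noise <- function(signal, sigma) {
  stopifnot(is.matrix(signal), sigma >= 0)
  if (sigma == 0) return(signal)
  signal * exp(sigma * matrix(stats::rnorm(length(signal)), nrow(signal)))
}

#' Simulate a mixed tumor expression dataset with ground truth
#'
#' Generates one dataset under either protocol: standard-normal component
#' profiles, mixture fractions either uniform on the simplex (`"uniform"`)
#' or supported on root-to-node paths of a complete binary component tree
#' (`"tree"`), noise-free signal `C %*% t(F)`, then multiplicative
#' log-normal noise at level `sigma`. Defaults `d = 10000`, `n = 100` match
#' the validation grid used to benchmark the method.
#'
#' @param k Number of components (>= 2).
#' @param sigma Noise fraction (>= 0).
#' @param d Number of genes; default 10000.
#' @param n Number of samples; default 100.
#' @param protocol `"uniform"` or `"tree"`.
#' @param seed Optional integer seed; when given, the draw is reproducible
#'   and does not disturb the caller's RNG state.
#' @return An object of class `"mix_sim"`: a list with `expression`
#'   (`d x n` matrix), `components_true` (`d x k`), `fractions_true`
#'   (`n x k`), `tree_true` (edge matrix, tree protocol only, else `NULL`)
#'   and `config`.
#' @examples
#' sim <- simulate_dataset(k = 3, sigma = 0.1, d = 200, n = 40, seed = 1)
#' dim(sim$expression)
#' @export
simulate_dataset <- function(k, sigma = 0, d = 10000, n = 100,
                             protocol = c("uniform", "tree"), seed = NULL) {
  protocol <- match.arg(protocol)
  stopifnot(d >= 1, n >= 1, k >= 2, sigma >= 0)
  run <- function() {
    C <- simulate_components(d, k)
    tree <- NULL
    if (protocol == "uniform") {
      f <- sample_uniform_fractions(n, k)
    } else {
      tree <- make_binary_tree(k)
      f <- sample_tree_fractions(n, k, tree)
    }
    M <- apply_noise(C %*% t(f), sigma)
    dimnames(M) <- list(gene_ids(d), sample_ids(n))
    structure(
      list(expression = M, components_true = C, fractions_true = f,
           tree_true = tree,
           config = list(d = d, n = n, k = k, sigma = sigma,
                         protocol = protocol, seed = seed)),
      class = "mix_sim")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.mix_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Simulated %s-protocol dataset: %d genes x %d samples, k = %d, sigma = %g\n",
    cfg$protocol, cfg$d, cfg$n, cfg$k, cfg$sigma))
  invisible(x)
}

gene_ids <- function(d) sprintf("g%05d", seq_len(d))
sample_ids <- function(n) sprintf("s%03d", seq_len(n))
component_ids <- function(k) paste0("C", seq_len(k))
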