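#' Solve mixture fractions against a fitted simplex
#'
#' Expresses each sample as a convex combination of the simplex vertices.
#' In the default reduced space this solves, per sample `t`, the square
#' system `sum_j f_tj * vertex_j = p_t` together with `sum_j f_tj = 1`
#' (barycentric coordinates; exact for points inside the simplex). The
#' alternative `space = "gene"` solves the overdetermined gene-space system
#' `C f = m_t` under the same sum-to-one constraint by equality-constrained
#' least squares, matching the prose description of the original method.
#'
#' Small negative fractions from round-off are kept as-is; see
#' [clamp_fractions()] for the documented cleanup used before similarity
#' computations.
#'
#' @param S A `"mix_simplex"`.
#' @param reduced A [reduce_dimension()] result (or score matrix when
#'   `space = "reduced"`).
#' @param space `"reduced"` (default) or `"gene"`.
#' @param M Original `d x n` expression matrix; required for
#'   `space = "gene"`.
#' @return `n x k` fraction matrix; rows sum to 1 (within round-off).
#' @export
solve_mixture_fractions <- function(S, reduced, space = c("reduced", "gene"),
                                    M = NULL) {
  space <- match.arg(space)
  if (S$volume <= 0) stop("degenerate simplex (volume 0)")
  verts <- S$vertices
  k <- nrow(verts)
  if (space == "reduced") {
    P <- score_matrix(reduced)
    A <- rbind(t(verts), 1)                 # k x k: coords + normalization
    rhs <- rbind(t(P), 1)
    f <- t(qr.solve(A, rhs))
  } else {
    if (is.null(M)) stop("gene-space solving needs the expression matrix M")
    M <- as_expression_matrix(M)
    C <- components_from_simplex(S, reduced)
    # KKT system for min ||C f - m||^2 s.t. 1'f = 1, shared across samples
    kkt <- rbind(cbind(2 * crossprod(C), 1), c(rep(1, k), 0))
    rhs <- rbind(2 * crossprod(C, M), 1)
    f <- t(solve(kkt, rhs)[seq_len(k), , drop = FALSE])
  }
  sn <- if (inherits(reduced, "reduced_expression")) reduced$sample_ids
        else rownames(score_matrix(reduced))
  dimnames(f) <- list(sn, component_ids(k))
  f
}

#' Clamp negative fractions and renormalize rows
#'
#' Round-off (and points slightly outside the fitted simplex) can leave
#' small negative mixture fractions. This helper sets negatives to zero and
#' rescales each row to sum to 1; it is applied before the log-domain
#' sharing-similarity computation, where negative fractions are invalid.
#'
#' @param f An `n x k` fraction matrix.
#' @return The cleaned matrix.
#' @export
clamp_fractions <- function(f) {
  f <- pmax(f, 0)
  rs <- rowSums(f)
  if (any(rs == 0)) stop("a sample has no positive fractions after clamping")
  f / rs
}

#' Back-project simplex vertices into gene space
#'
#' Maps each vertex of the fitted simplex back through the PCA basis and
#' per-gene offsets: column `j` of the result is
#' `vertex_j %*% basis + offset`, the inferred expression profile of
#' component `j`.
#'
#' @param S A `"mix_simplex"`.
#' @param reduced The [reduce_dimension()] result holding `basis` and
#'   `offset`.
#' @return `d x k` component matrix `C`.
#' @export
components_from_simplex <- function(S, reduced) {
  if (!inherits(reduced, "reduced_expression"))
    stop("components_from_simplex needs the reduced_expression object")
  verts <- S$vertices
  stopifnot(ncol(verts) == nrow(reduced$basis))
  C <- t(verts %*% reduced$basis) + reduced$offset
  dimnames(C) <- list(reduced$gene_ids, component_ids(nrow(verts)))
  C
}

#' Unmix a tumor expression matrix into cell-state components
#'
#' The full inference: reduce the genes x samples matrix to `k - 1`
#' dimensions by PCA, fit a minimum-volume enclosing simplex to the sample
#' cloud over `n_restarts` random restarts, back-project the vertices into
#' gene space as the component expression matrix `C`, and solve each
#' sample's mixture fractions `F` against the vertices. The premise is that
#' bulk tumors are convex mixtures of a small set of recurring cell states,
#' so the tightest simplex around the data is the most parsimonious
#' component set.
#'
#' @param M `d x n` numeric matrix (genes x samples, linear scale) or a
#'   data frame with a gene-identifier first column.
#' @param k Number of components to infer (no automatic selection).
#' @param n_restarts Random restarts of the simplex search (default 100).
#' @param seed Optional integer seed making the run reproducible.
#' @param tol Containment tolerance; default `1e-9` x point-cloud diameter.
#' @param fractions_space `"reduced"` (barycentric, default) or `"gene"`
#'   (least squares over all genes).
#' @param verbose Emit a message with the winning restart and volume.
#' @return An object of class `"mix_fit"`: list with `components`
#'   (`d x k`), `fractions` (`n x k`, rows sum to 1), `simplex`, `reduced`,
#'   `volume`, `restart`, `k`, `n_restarts`, `seed`, `fractions_space`.
#' @examples
#' sim <- simulate_dataset(k = 3, sigma = 0.1, d = 300, n = 50, seed = 1)
#' fit <- unmix(sim$expression, k = 3, n_restarts = 25, seed = 2)
#' fit
#' colMeans(fit$fractions)
#' @export
unmix <- function(M, k, n_restarts = 100, seed = NULL, tol = NULL,
                  fractions_space = c("reduced", "gene"), verbose = FALSE) {
  fractions_space <- match.arg(fractions_space)
  M <- as_expression_matrix(M)
  run <- function() {
    reduced <- reduce_dimension(M, k)
    S <- fit_min_volume_simplex(reduced, k, n_restarts = n_restarts, tol = tol)
    C <- components_from_simplex(S, reduced)
    f <- solve_mixture_fractions(S, reduced, space = fractions_space, M = M)
    if (verbose)
      message(sprintf("unmix: selected restart %d of %d, volume %.6g",
                      attr(S, "restart"), n_restarts, S$volume))
    structure(
      list(components = C, fractions = f, simplex = S, reduced = reduced,
           volume = S$volume, restart = attr(S, "restart"), k = k,
           n_restarts = n_restarts, seed = seed,
           fractions_space = fractions_space),
      class = "mix_fit")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.mix_fit <- function(x, ...) {
  cat(sprintf("Unmixing fit: %d components over %d genes x %d samples\n",
              x$k, nrow(x$components), nrow(x$fractions)))
  cat(sprintf("  simplex volume %.6g (restart %d of %d)\n",
              x$volume, x$restart, x$n_restarts))
  cat("  mean fractions:",
      paste(sprintf("%s %.3f", colnames(x$fractions), colMeans(x$fractions)),
            collapse = ", "), "\n")
  invisible(x)
}
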