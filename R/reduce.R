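#' Reduce an expression matrix to simplex dimension
#'
#' Projects a linear-scale genes x samples matrix onto its `k - 1` leading
#' principal axes, the intrinsic dimension of a `k`-vertex simplex. The
#' per-gene mean over samples is removed first (the `offset`), the centered
#' matrix is decomposed by SVD, and each sample gets a `(k-1)`-vector of
#' scores ordered by decreasing explained variance, so
#' `M ~ t(scores %*% basis) + offset`.
#'
#' If the centered matrix has rank below `k - 1` the trailing score
#' dimensions are zero-padded, a warning is raised and the result is flagged
#' (`rank_deficient`).
#'
#' @param M Numeric matrix, `d` genes x `n` samples, linear scale. A data
#'   frame with a gene-identifier first column is also accepted.
#' @param k Target component count (>= 2); the reduced dimension is `k - 1`.
#' @return An object of class `"reduced_expression"`: list with `scores`
#'   (`n x (k-1)`), `basis` (`(k-1) x d`, orthonormal rows), `offset`
#'   (length `d`), `sdev` (singular values / sqrt(n-1)), `rank_deficient`,
#'   `gene_ids`, `sample_ids`, `k`.
#' @examples
#' sim <- simulate_dataset(k = 3, d = 100, n = 30, seed = 1)
#' red <- reduce_dimension(sim$expression, k = 3)
#' dim(red$scores)
#' @export
reduce_dimension <- function(M, k) {
  M <- as_expression_matrix(M)
  stopifnot(is.numeric(k), length(k) == 1, k == round(k), k >= 2)
  d <- nrow(M); n <- ncol(M)
  if (n < k) stop("insufficient samples: need n >= k (n = ", n, ", k = ", k, ")")
  if (d < k - 1) stop("need at least k - 1 genes (d = ", d, ", k = ", k, ")")
  if (any(!is.finite(M))) stop("expression matrix contains non-finite values; ",
                               "run preprocess_log_to_linear() first")
  r <- k - 1L
  offset <- rowMeans(M)
  X <- M - offset
  sv <- svd(X, nu = r, nv = r)
  tol <- max(d, n) * .Machine$double.eps * max(sv$d[1], 0)
  rank <- sum(sv$d > tol)
  scores <- sv$v * rep(sv$d[seq_len(r)], each = n)
  basis <- t(sv$u)
  rank_deficient <- rank < r
  if (rank_deficient) {
    warning("centered matrix has rank ", rank, " < k - 1 = ", r,
            "; trailing dimensions zero-padded")
    dead <- seq(rank + 1L, r)
    scores[, dead] <- 0
  }
  dimnames(scores) <- list(colnames(M), paste0("dim", seq_len(r)))
  structure(
    list(scores = scores, basis = basis, offset = offset,
         sdev = sv$d[seq_len(r)] / sqrt(max(n - 1, 1)),
         rank_deficient = rank_deficient,
         gene_ids = rownames(M), sample_ids = colnames(M), k = k),
    class = "reduced_expression")
}

#' @export
print.reduced_expression <- function(x, ...) {
  cat(sprintf("Reduced expression data: %d samples in %d dimensions (k = %d)\n",
              nrow(x$scores), ncol(x$scores), x$k))
  if (x$rank_deficient) cat("  [rank deficient: trailing dimensions zero-padded]\n")
  invisible(x)
}

# Coerce a matrix or gene-id-first-column data frame to a named matrix.
as_expression_matrix <- function(M) {
  if (is.data.frame(M)) {
    if (!is.character(M[[1]]) && !is.factor(M[[1]]))
      stop("data-frame input must have a gene-identifier first column")
    ids <- as.character(M[[1]])
    if (anyDuplicated(ids)) stop("duplicate gene IDs: ",
                                 paste(unique(ids[duplicated(ids)]), collapse = ", "))
    out <- as.matrix(M[, -1, drop = FALSE])
    rownames(out) <- ids
    storage.mode(out) <- "double"
    return(out)
  }
  if (!is.matrix(M) || !is.numeric(M)) stop("M must be a numeric matrix or data frame")
  if (is.null(rownames(M))) rownames(M) <- gene_ids(nrow(M))
  if (is.null(colnames(M))) colnames(M) <- sample_ids(ncol(M))
  M
}
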