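#' Co-occurrence sharing similarity between components
#'
#' For components `i`, `j` with mixture-fraction columns `f_.i`, `f_.j`,
#' the sharing similarity across tumors is
#' `s_ij = log( sum_t f_ti f_tj / (sum_t f_ti * sum_t f_tj) )`:
#' the log-ratio of the co-occurrence mass of the pair to the product of
#' their marginal masses. It is high when two components tend to inhabit
#' the same tumors and strongly negative when their supports are disjoint.
#' The diagonal is computed by the same formula.
#'
#' Fractions are cleaned with [clamp_fractions()] first (negatives from
#' round-off are invalid in the log domain). A pair with zero co-occurrence
#' mass gets the finite `floor` instead of `-Inf` so spanning-tree weights
#' stay finite.
#'
#' @param f `n x k` fraction matrix, or a `"mix_fit"`.
#' @param floor Value used for zero co-occurrence; default
#'   `log(.Machine$double.eps)`.
#' @return A symmetric `k x k` matrix of class `"sharing_similarity"`.
#' @examples
#' f <- rbind(c(0.5, 0.5, 0), c(0.5, 0, 0.5), c(1, 0, 0))
#' sharing_similarity(f)
#' @export
sharing_similarity <- function(f, floor = log(.Machine$double.eps)) {
  if (inherits(f, "mix_fit")) f <- f$fractions
  stopifnot(is.matrix(f), nrow(f) >= 1)
  f <- clamp_fractions(f)
  marg <- colSums(f)
  if (any(marg == 0))
    stop("component absent from all samples: ",
         paste(colnames(f)[marg == 0], collapse = ", "))
  co <- crossprod(f)                # sum_t f_ti f_tj
  s <- suppressWarnings(log(co / outer(marg, marg)))
  s[co == 0] <- floor
  s <- (s + t(s)) / 2               # enforce exact symmetry under round-off
  if (is.null(colnames(f))) dimnames(s) <- list(component_ids(ncol(f)),
                                                component_ids(ncol(f)))
  class(s) <- c("sharing_similarity", class(s))
  s
}

# Kruskal MST on the complete graph with weight -s, ties broken by
# lexicographic edge index so results are deterministic.
mst_edges <- function(s) {
  k <- nrow(s)
  pairs <- which(upper.tri(s), arr.ind = TRUE)
  w <- -s[pairs]
  if (any(!is.finite(w))) stop("non-finite similarity weights")
  ord <- order(w, pairs[, 1], pairs[, 2])
  parent <- seq_len(k)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  chosen <- matrix(0L, k - 1, 2)
  m <- 0L
  for (e in ord) {
    a <- find(pairs[e, 1]); b <- find(pairs[e, 2])
    if (a != b) {
      parent[a] <- b
      m <- m + 1L
      chosen[m, ] <- sort(c(pairs[e, 1], pairs[e, 2]))
      if (m == k - 1L) break
    }
  }
  chosen[order(chosen[, 1], chosen[, 2]), , drop = FALSE]
}

new_phylogeny <- function(edges, s, component_ids, confidence = NULL,
                          n_replicates = NULL, n_skipped = NULL,
                          pair_confidence = NULL) {
  structure(
    list(edges = edges, similarity = s, component_ids = component_ids,
         edge_confidence = confidence, n_replicates = n_replicates,
         n_skipped = n_skipped, pair_confidence = pair_confidence,
         is_connected = TRUE),
    class = "mix_phylogeny")
}

#' Infer a component phylogeny as a maximum-sharing spanning tree
#'
#' Treats the `k` components as nodes of a complete graph with edge weight
#' `-s_ij` and returns its minimum spanning tree -- equivalently the
#' spanning tree maximizing total sharing similarity across its edges. The
#' intuition: cell states that co-occur in common tumors likely lie on a
#' common progression pathway. The tree is unrooted; [as_newick()] can root
#' it for display.
#'
#' @param s A `"sharing_similarity"` matrix (or any symmetric numeric
#'   matrix), or a `"mix_fit"` (similarity computed from its fractions).
#' @return An object of class `"mix_phylogeny"`: `k - 1` edges (integer
#'   matrix, component indices), the similarity matrix, and component ids.
#' @export
infer_tree <- function(s) {
  if (inherits(s, "mix_fit")) s <- sharing_similarity(s)
  stopifnot(is.matrix(s), nrow(s) == ncol(s), nrow(s) >= 2)
  ids <- colnames(s)
  if (is.null(ids)) ids <- component_ids(ncol(s))
  new_phylogeny(mst_edges(s), s, ids)
}

#' Bootstrap edge confidence for the component phylogeny
#'
#' Re-runs only the phylogeny stage (sharing similarity + spanning tree) on
#' resampled fraction matrices: each replicate independently retains each
#' sample (row of `f`) with probability `keep_prob`, and the fraction of
#' valid replicates in which each edge appears is its confidence. Defaults
#' (`reps = 10000`, `keep_prob = 0.9`) match the protocol used for the lung
#' tumor analysis. Replicates retaining fewer than two samples or emptying a
#' component are skipped; more than 50% skipped is an error.
#'
#' @param f `n x k` fraction matrix or a `"mix_fit"`.
#' @param reps Number of bootstrap replicates.
#' @param keep_prob Per-sample retention probability in `(0, 1]`.
#' @param seed Optional integer seed.
#' @param floor Passed to [sharing_similarity()].
#' @return A `"mix_phylogeny"` for the full data (the point estimate), with
#'   `edge_confidence` for its edges, `pair_confidence` (tibble of all
#'   pairs' appearance fractions), `n_replicates` (valid) and `n_skipped`.
#' @export
bootstrap_tree <- function(f, reps = 10000, keep_prob = 0.9, seed = NULL,
                           floor = log(.Machine$double.eps)) {
  if (inherits(f, "mix_fit")) f <- f$fractions
  stopifnot(is.matrix(f), reps >= 1, keep_prob > 0, keep_prob <= 1)
  n <- nrow(f); k <- ncol(f)
  point <- infer_tree(sharing_similarity(f, floor = floor))
  run <- function() {
    counts <- matrix(0L, k, k)
    skipped <- 0L
    for (r in seq_len(reps)) {
      keep <- stats::runif(n) < keep_prob
      if (sum(keep) < 2) { skipped <- skipped + 1L; next }
      sub <- f[keep, , drop = FALSE]
      tr <- tryCatch(mst_edges(sharing_similarity(sub, floor = floor)),
                     error = function(e) NULL)
      if (is.null(tr)) { skipped <- skipped + 1L; next }
      counts[tr] <- counts[tr] + 1L
    }
    list(counts = counts, skipped = skipped)
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  valid <- reps - out$skipped
  if (out$skipped > reps / 2)
    stop("more than half of bootstrap replicates were degenerate (",
         out$skipped, " of ", reps, ")")
  conf_of <- function(e) out$counts[e[1], e[2]] / valid
  point$edge_confidence <- apply(point$edges, 1, conf_of)
  pairs <- which(upper.tri(out$counts), arr.ind = TRUE)
  point$pair_confidence <- tibble::tibble(
    from = point$component_ids[pairs[, 1]],
    to = point$component_ids[pairs[, 2]],
    confidence = out$counts[pairs] / valid)
  point$n_replicates <- valid
  point$n_skipped <- out$skipped
  point
}

#' @export
print.mix_phylogeny <- function(x, ...) {
  cat(sprintf("Component phylogeny: %d nodes, %d edges (unrooted)\n",
              length(x$component_ids), nrow(x$edges)))
  for (i in seq_len(nrow(x$edges))) {
    e <- x$edges[i, ]
    cat(sprintf("  %s -- %s  (s = %.3f%s)\n",
                x$component_ids[e[1]], x$component_ids[e[2]],
                x$similarity[e[1], e[2]],
                if (!is.null(x$edge_confidence))
                  sprintf(", confidence %.2f", x$edge_confidence[i]) else ""))
  }
  invisible(x)
}

#' Newick string for a rooted view of the component phylogeny
#'
#' The spanning tree is unrooted; for display it can be rooted at a chosen
#' component (typically the one associated with normal tissue) and
#' serialized as a Newick string with labelled internal nodes and unit
#' branch lengths.
#'
#' @param phy A `"mix_phylogeny"`.
#' @param root Component id (name) or index to root at.
#' @return A single Newick string.
#' @export
as_newick <- function(phy, root = 1) {
  ids <- phy$component_ids
  if (is.character(root)) root <- match(root, ids)
  if (is.na(root) || root < 1 || root > length(ids)) stop("unknown root component")
  adj <- lapply(seq_along(ids), function(i) integer(0))
  for (i in seq_len(nrow(phy$edges))) {
    e <- phy$edges[i, ]
    adj[[e[1]]] <- c(adj[[e[1]]], e[2])
    adj[[e[2]]] <- c(adj[[e[2]]], e[1])
  }
  descend <- function(node, from) {
    kids <- setdiff(adj[[node]], from)
    if (length(kids) == 0) return(sprintf("%s:1", ids[node]))
    sprintf("(%s)%s:1",
            paste(vapply(kids, descend, character(1), from = node),
                  collapse = ","),
            ids[node])
  }
  kids <- adj[[root]]
  sprintf("(%s)%s;",
          paste(vapply(kids, descend, character(1), from = root),
                collapse = ","),
          ids[root])
}
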