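#' @title Minimum-volume bounding simplex machinery
#' @description Internal geometry plus the exported operations that search
#'   for the tightest simplex enclosing the dimension-reduced sample cloud.
#'   The search follows the classic endmember-extraction recipe: guess k
#'   vertices among the observed points, biased towards spread-out sets,
#'   then push violated faces outward along their normals until every point
#'   is enclosed; repeat from many starts and keep the smallest simplex.
#' @name simplex
NULL

new_simplex <- function(vertices) {
  stopifnot(is.matrix(vertices), nrow(vertices) == ncol(vertices) + 1)
  structure(list(vertices = vertices, volume = simplex_volume(vertices)),
            class = "mix_simplex")
}

#' @export
print.mix_simplex <- function(x, ...) {
  cat(sprintf("Simplex: %d vertices in %d dimensions, volume %.6g\n",
              nrow(x$vertices), ncol(x$vertices), x$volume))
  invisible(x)
}

#' Volume of a k-vertex simplex in (k-1) dimensions
#'
#' `|det(v_i - v_1)| / (k-1)!` over the `k - 1` edge vectors from the first
#' vertex. Exact for a simplex and dimension-robust, unlike a convex-hull
#' call.
#'
#' @param vertices `k x (k-1)` matrix, one vertex per row.
#' @return Non-negative volume.
#' @export
simplex_volume <- function(vertices) {
  k <- nrow(vertices)
  edges <- vertices[-1, , drop = FALSE] - rep(vertices[1, ], each = k - 1)
  abs(det(edges)) / factorial(k - 1)
}

# m-dimensional volume of the simplex on the rows of `pts` (m+1 points in
# any ambient dimension), via the Gram determinant of its edge vectors.
affine_volume <- function(pts) {
  m <- nrow(pts) - 1L
  E <- pts[-1, , drop = FALSE] - rep(pts[1, ], each = m)
  g <- det(tcrossprod(E))
  sqrt(max(g, 0)) / factorial(m)
}

#' Sample a candidate simplex from the observed points
#'
#' Draws `k` distinct observed points to seed a simplex, biased towards
#' far-apart sets: the first pair of vertices is drawn from all unordered
#' point pairs with probability proportional to their distance raised to the
#' k-th power; each further vertex is drawn with probability proportional to
#' the (affine-subspace) volume of the simplex it would form with the
#' vertices chosen so far, again raised to the k-th power. Coincident or
#' affinely dependent candidates get zero weight, so returned vertices are
#' distinct and non-degenerate.
#'
#' @param reduced A [reduce_dimension()] result (or a bare score matrix).
#' @param k Number of vertices.
#' @param max_tries Number of from-scratch resamples allowed when every
#'   candidate weight is zero at some stage before erroring.
#' @return A `"mix_simplex"` whose `vertices` are `k` observed points;
#'   attribute `"indices"` records which rows of the score matrix were used.
#' @export
sample_candidate_simplex <- function(reduced, k, max_tries = 50) {
  P <- score_matrix(reduced)
  n <- nrow(P)
  stopifnot(k >= 2, ncol(P) == k - 1)
  if (n < k) stop("degenerate point set: fewer than k points")
  dd <- as.matrix(stats::dist(P))
  scale <- max(dd)
  pair_w <- dd[upper.tri(dd)]^k
  if (!any(pair_w > 0)) stop("degenerate point set: all points coincide")
  pairs <- which(upper.tri(dd), arr.ind = TRUE)
  for (try in seq_len(max_tries)) {
    sel <- pairs[sample.int(nrow(pairs), 1, prob = pair_w), ]
    ok <- TRUE
    while (length(sel) < k) {
      m <- length(sel)  # dimension of the candidate simplex being formed
      w <- vapply(seq_len(n), function(j) {
        if (j %in% sel) return(0)
        v <- affine_volume(P[c(sel, j), , drop = FALSE])
        # zero out numerically degenerate (affinely dependent) candidates:
        # Gram-determinant round-off is O(sqrt(eps) * scale^m / m!), so cut
        # well above it on the normalized volume scale
        if (v < 1e-6 * scale^m / factorial(m)) return(0)
        v^k
      }, numeric(1))
      if (!any(w > 0)) { ok <- FALSE; break }
      sel <- c(sel, sample.int(n, 1, prob = w))
    }
    if (ok) {
      s <- new_simplex(P[sel, , drop = FALSE])
      attr(s, "indices") <- unname(sel)
      return(s)
    }
  }
  stop("degenerate point set: could not sample ", k,
       " affinely independent points in ", max_tries, " attempts")
}

# Unit normal of face `i` (all vertices but i), oriented AWAY from the
# excluded vertex, together with one point on the face. Signed distance of
# a point p to the face hyperplane is then (p - v0) . normal: positive on
# the far side of the face from the excluded vertex (outside), negative on
# the same side (inside).
face_geometry <- function(vertices, i) {
  k <- nrow(vertices)
  face <- vertices[-i, , drop = FALSE]
  v0 <- face[1, ]
  if (k == 2) {
    normal <- 1
  } else {
    E <- t(face[-1, , drop = FALSE] - rep(v0, each = k - 2))  # (k-1) x (k-2)
    qrE <- qr(E)
    if (qrE$rank < k - 2) stop("degenerate face: affinely dependent vertices")
    normal <- qr.Q(qrE, complete = TRUE)[, k - 1]
  }
  if (sum(normal * (vertices[i, ] - v0)) > 0) normal <- -normal
  list(v0 = v0, normal = normal)
}

#' Signed distance from a point to a simplex face
#'
#' Euclidean distance from `p` to the hyperplane of face `face_index` (the
#' face spanned by every vertex except that one), signed negative when `p`
#' lies on the same side as the excluded vertex (inside), positive on the
#' opposite side (outside), zero on the hyperplane.
#'
#' @param S A `"mix_simplex"`.
#' @param face_index Which vertex is excluded from the face.
#' @param p Point in reduced space (length `k - 1`).
#' @return Signed scalar distance.
#' @export
signed_face_distance <- function(S, face_index, p) {
  verts <- S$vertices
  stopifnot(face_index >= 1, face_index <= nrow(verts),
            length(p) == ncol(verts))
  if (S$volume <= 0) stop("degenerate simplex (volume 0)")
  fg <- face_geometry(verts, face_index)
  sum((p - fg$v0) * fg$normal)
}

# n x k matrix of signed distances of every point (rows of P) to every face.
all_face_distances <- function(vertices, P) {
  k <- nrow(vertices)
  vapply(seq_len(k), function(i) {
    fg <- face_geometry(vertices, i)
    as.numeric((P - rep(fg$v0, each = nrow(P))) %*% fg$normal)
  }, numeric(nrow(P)))
}

#' Expand a simplex until it encloses all points
#'
#' Repeatedly finds the largest positive signed face distance over all
#' (face, point) pairs and translates the `k - 1` vertices of that face by
#' that distance along the face's outward unit normal (away from the
#' excluded vertex), which places the face hyperplane through the violating
#' point. Stops when every point has signed distance at most `tol` to every
#' face. Volume never decreases.
#'
#' @param S Starting `"mix_simplex"` (non-degenerate).
#' @param reduced A [reduce_dimension()] result or score matrix.
#' @param tol Containment tolerance; default `1e-9` times the point-cloud
#'   diameter.
#' @param max_iter Iteration cap; default `10 * k * n`. Exceeding it raises
#'   an error (possible with `tol = 0` under round-off).
#' @return The expanded `"mix_simplex"` enclosing all points.
#' @export
expand_simplex <- function(S, reduced, tol = NULL, max_iter = NULL) {
  P <- score_matrix(reduced)
  verts <- S$vertices
  k <- nrow(verts)
  if (S$volume <= 0) stop("degenerate simplex (volume 0)")
  if (is.null(tol)) tol <- default_tol(P)
  if (is.null(max_iter)) max_iter <- 10 * k * nrow(P)
  for (iter in seq_len(max_iter + 1L)) {
    dists <- all_face_distances(verts, P)
    dmax <- max(dists)
    if (dmax <= tol) return(new_simplex(verts))
    if (iter > max_iter) stop("expansion not converging after ", max_iter,
                              " iterations (largest violation ", signif(dmax, 3), ")")
    idx <- which(dists == dmax, arr.ind = TRUE)[1, ]
    i <- idx[["col"]]
    fg <- face_geometry(verts, i)
    verts[-i, ] <- verts[-i, , drop = FALSE] +
      rep(dmax * fg$normal, each = k - 1)
  }
}

default_tol <- function(P) {
  rng <- apply(P, 2, range)
  diam <- sqrt(sum((rng[2, ] - rng[1, ])^2))
  1e-9 * max(diam, 1e-12)
}

#' Fit a minimum-volume enclosing simplex by random restarts
#'
#' Runs [sample_candidate_simplex()] followed by [expand_simplex()]
#' `n_restarts` times and returns the enclosing simplex of smallest volume.
#' Restarts that fail (degenerate starting sets) are skipped; if every
#' restart fails an error is raised.
#'
#' @inheritParams expand_simplex
#' @param reduced A [reduce_dimension()] result.
#' @param k Number of vertices.
#' @param n_restarts Number of independent trials (default 100).
#' @return The best `"mix_simplex"`, with attributes `"restart"` (index of
#'   the winning trial) and `"n_failed"`.
#' @export
fit_min_volume_simplex <- function(reduced, k, n_restarts = 100,
                                   tol = NULL, max_iter = NULL) {
  stopifnot(n_restarts >= 1)
  P <- score_matrix(reduced)
  if (is.null(tol)) tol <- default_tol(P)
  best <- NULL; best_restart <- NA_integer_; n_failed <- 0L
  last_err <- NULL
  for (r in seq_len(n_restarts)) {
    trial <- tryCatch({
      cand <- sample_candidate_simplex(reduced, k)
      expand_simplex(cand, P, tol = tol, max_iter = max_iter)
    }, error = function(e) e)
    if (inherits(trial, "error")) {
      n_failed <- n_failed + 1L
      last_err <- trial
      next
    }
    if (is.null(best) || trial$volume < best$volume) {
      best <- trial
      best_restart <- r
    }
  }
  if (is.null(best)) stop("all ", n_restarts, " restarts failed; last error: ",
                          conditionMessage(last_err))
  attr(best, "restart") <- best_restart
  attr(best, "n_failed") <- n_failed
  best
}

score_matrix <- function(reduced) {
  if (inherits(reduced, "reduced_expression")) return(reduced$scores)
  if (is.matrix(reduced) && is.numeric(reduced)) return(reduced)
  stop("expected a reduced_expression object or a numeric score matrix")
}
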