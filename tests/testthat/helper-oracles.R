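# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths for the quantities they check.

# Simplex volume via the Cayley-Menger determinant (squared-distance based,
# independent of the package's edge-determinant formula).
cayley_menger_volume <- function(vertices) {
  m <- nrow(vertices) - 1L
  D2 <- as.matrix(dist(vertices))^2
  cm <- rbind(c(0, rep(1, m + 1)), cbind(1, D2))
  v2 <- (-1)^(m + 1) / (2^m * factorial(m)^2) * det(cm)
  sqrt(max(v2, 0))
}

# Barycentric coordinates of p in the simplex with rows `vertices`.
barycentric <- function(vertices, p) {
  solve(rbind(t(vertices), 1), c(p, 1))
}

# Exhaustive minimum-volume enclosing simplex: try every k-subset of the
# points as the starting candidate and expand each to enclosure.
brute_force_min_simplex <- function(P, k, tol = NULL) {
  combos <- combn(nrow(P), k)
  best <- NULL
  for (i in seq_len(ncol(combos))) {
    verts <- P[combos[, i], , drop = FALSE]
    if (simplex_volume(verts) <= 0) next
    S <- tryCatch(
      expand_simplex(structure(list(vertices = verts,
                                    volume = simplex_volume(verts)),
                               class = "mix_simplex"),
                     P, tol = tol),
      error = function(e) NULL)
    if (!is.null(S) && (is.null(best) || S$volume < best$volume)) best <- S
  }
  best
}

# Uniform random labelled tree on k nodes via a random Prufer sequence.
random_spanning_tree <- function(k) {
  if (k == 2) return(cbind(1L, 2L))
  prufer <- sample.int(k, k - 2, replace = TRUE)
  degree <- rep(1L, k)
  for (p in prufer) degree[p] <- degree[p] + 1L
  edges <- matrix(0L, k - 1, 2)
  for (i in seq_along(prufer)) {
    leaf <- min(which(degree == 1L))
    edges[i, ] <- c(leaf, prufer[i])
    degree[leaf] <- 0L
    degree[prufer[i]] <- degree[prufer[i]] - 1L
  }
  edges[k - 1, ] <- which(degree == 1L)
  edges
}

# Total-distance-minimizing column matching by explicit enumeration of all
# permutations (oracle for match_components).
enumerate_matching <- function(C_true, C_inferred) {
  k <- ncol(C_true)
  D <- as.matrix(dist(t(cbind(C_true, C_inferred))))[seq_len(k), k + seq_len(k)]
  perms <- permutations_of(k)
  costs <- apply(perms, 1, function(p) sum(D[cbind(seq_len(k), p)]))
  perms[which.min(costs), ]
}

permutations_of <- function(k) {
  if (k == 1) return(matrix(1L))
  sub <- permutations_of(k - 1L)
  do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

# Noise-free mixed dataset from explicit factors (bypasses simulate_dataset).
mixture_matrix <- function(C, f) C %*% t(f)
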