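# Geometry of the minimum-volume enclosing simplex search.

right_triangle <- function() {
  structure(list(vertices = rbind(c(0, 0), c(1, 0), c(0, 1)),
                 volume = 0.5),
            class = "mix_simplex")
}

test_that("volume matches the Cayley-Menger determinant oracle", {
  withr::with_seed(8, {
    for (k in 2:5) {
      verts <- matrix(rnorm(k * (k - 1)), k, k - 1)
      expect_equal(simplex_volume(verts), cayley_menger_volume(verts),
                   tolerance = 1e-9)
    }
  })
  expect_equal(simplex_volume(rbind(0.2, 0.8)), 0.6)  # 1-D segment length
})

test_that("candidate sampling matches brute-force selection probabilities", {
  # equilateral triangle plus centroid: enumerate the exact distribution of
  # the selected vertex set, then compare empirical frequencies
  tri <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  P <- rbind(tri, colMeans(tri))
  k <- 3

  # oracle: P(first pair) prop to dist^3; P(third | pair) prop to area^3
  dd <- as.matrix(dist(P))
  pairs <- which(upper.tri(dd), arr.ind = TRUE)
  pw <- dd[pairs]^k / sum(dd[pairs]^k)
  p_outer <- 0  # probability the selected set is exactly the 3 outer vertices
  for (e in seq_len(nrow(pairs))) {
    i <- pairs[e, 1]; j <- pairs[e, 2]
    rest <- setdiff(1:4, c(i, j))
    aw <- vapply(rest, function(r)
      cayley_menger_volume(P[c(i, j, r), ])^k, numeric(1))
    if (sum(aw) == 0) next
    if (all(c(i, j) <= 3))
      p_outer <- p_outer + pw[e] * sum(aw[rest <= 3]) / sum(aw)
  }
  # hand arithmetic: P(vertex pair) = 3 / (3 + 3 (1/sqrt(3))^3) ~ 0.839,
  # P(vertex third | vertex pair) = 1 / (1 + (1/3)^3) ~ 0.964
  expect_equal(p_outer, (1 / (1 + 3^-1.5)) * (1 / (1 + 3^-3)),
               tolerance = 1e-12)

  withr::with_seed(33, {
    centroid_used <- logical(1000)
    for (r in 1:1000) {
      s <- sample_candidate_simplex(P, k = 3)
      centroid_used[r] <- 4 %in% attr(s, "indices")
    }
  })
  # empirical frequencies agree with the enumerated distribution, and the
  # outer-vertex set dominates the centroid by design of the weighting
  expect_equal(mean(!centroid_used), p_outer, tolerance = 0.035)
  expect_gt(mean(!centroid_used), 0.75)
})

test_that("duplicated two-point clouds always return the two locations", {
  P <- matrix(rep(c(0, 1), each = 10), ncol = 1)
  withr::with_seed(2, s <- sample_candidate_simplex(P, k = 2))
  expect_setequal(as.numeric(s$vertices), c(0, 1))
  # determinism under a fixed seed
  s1 <- withr::with_seed(9, sample_candidate_simplex(P, k = 2))
  s2 <- withr::with_seed(9, sample_candidate_simplex(P, k = 2))
  expect_identical(s1$vertices, s2$vertices)
})

test_that("degenerate point sets are rejected", {
  P <- matrix(1, 10, 1)
  expect_error(sample_candidate_simplex(P, k = 2), "degenerate")
  # collinear points cannot seed a 2-D simplex
  Pc <- cbind(1:10, 2 * (1:10))
  withr::with_seed(4, expect_error(sample_candidate_simplex(Pc, k = 3),
                                   "degenerate"))
})

test_that("signed face distance has the documented sign convention", {
  S <- right_triangle()
  # face 1 (opposite the origin) is the hypotenuse; the origin is inside
  expect_equal(signed_face_distance(S, 1, c(0, 0)), -1 / sqrt(2))
  # a vertex on the queried face is at distance zero
  expect_equal(signed_face_distance(S, 1, c(1, 0)), 0)
  expect_equal(signed_face_distance(S, 2, c(0, 1)), 0)
  # the excluded vertex is always on the negative side
  for (i in 1:3)
    expect_lt(signed_face_distance(S, i, S$vertices[i, ]), 0)
  # outside beyond the hypotenuse is positive
  expect_equal(signed_face_distance(S, 1, c(1, 1)), 1 / sqrt(2))
})

test_that("expansion encloses points and traces the 1-D case by hand", {
  # segment [0.2, 0.8] expanding to points {0, 1}: exactly two face moves
  S <- structure(list(vertices = rbind(0.2, 0.8), volume = 0.6),
                 class = "mix_simplex")
  P <- rbind(0, 1)
  out <- expand_simplex(S, P, tol = 0, max_iter = 2)
  expect_equal(unname(out$vertices), rbind(0, 1))

  # already-enclosing simplex is returned unchanged
  S2 <- structure(list(vertices = rbind(-1, 2), volume = 3),
                  class = "mix_simplex")
  expect_equal(expand_simplex(S2, P)$vertices, S2$vertices)

  # shrunken triangle re-expands to contain the original vertices
  tri <- rbind(c(0, 0), c(2, 0), c(0, 2))
  centroid <- colMeans(tri)
  shrunk <- sweep(sweep(tri, 2, centroid) * 0.5, 2, centroid, "+")
  Ssh <- structure(list(vertices = shrunk, volume = simplex_volume(shrunk)),
                   class = "mix_simplex")
  out2 <- expand_simplex(Ssh, tri)
  bary <- apply(tri, 1, function(p) barycentric(out2$vertices, p))
  expect_true(all(bary >= -1e-8))
  expect_gte(out2$volume, Ssh$volume)
})

test_that("restart fitting selects the minimum volume and encloses all points", {
  withr::with_seed(11, {
    verts_true <- rbind(c(0, 0), c(4, 0), c(1, 3))
    f <- sample_uniform_fractions(500, 3)
    P <- f %*% verts_true
  })
  withr::with_seed(12, S <- fit_min_volume_simplex(P, k = 3, n_restarts = 100))
  # dense uniform sampling: recovered simplex close to the generator
  expect_lt(abs(S$volume - 6) / 6, 0.10)
  diam <- max(dist(verts_true))
  perm <- enumerate_matching(t(verts_true), t(S$vertices))
  expect_lt(max(sqrt(rowSums((verts_true - S$vertices[perm, ])^2))),
            0.1 * diam)
  # containment
  dists <- sapply(1:3, function(i)
    apply(P, 1, function(p) signed_face_distance(S, i, p)))
  expect_lte(max(dists), 1e-6)

  # n_restarts = 1 reproduces a single trial under the same seed
  s1 <- withr::with_seed(5, fit_min_volume_simplex(P, k = 3, n_restarts = 1))
  s2 <- withr::with_seed(5, {
    expand_simplex(sample_candidate_simplex(P, 3), P)
  })
  expect_equal(s1$vertices, s2$vertices)

  # the restart minimum is monotone in the number of restarts
  v5 <- withr::with_seed(6, fit_min_volume_simplex(P, 3, n_restarts = 5))$volume
  v25 <- withr::with_seed(6, fit_min_volume_simplex(P, 3, n_restarts = 25))$volume
  expect_lte(v25, v5)
})
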