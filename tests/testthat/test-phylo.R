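test_that("sharing similarity matches hand arithmetic", {
  # single sample: every finite entry collapses to log(f_i f_j / f_i f_j) = 0
  s1 <- sharing_similarity(rbind(c(0.2, 0.3, 0.5)))
  expect_true(all(s1 == 0))

  f <- rbind(c(0.5, 0.5, 0), c(0.5, 0, 0.5), c(1, 0, 0))
  s <- sharing_similarity(f)
  expect_equal(s[1, 2], log(0.25 / (2 * 0.5)))      # log(0.25)
  expect_equal(s[1, 3], log(0.25 / (2 * 0.5)))
  expect_equal(s[2, 3], log(.Machine$double.eps))   # disjoint supports: floor
  expect_equal(s[1, 1], log(1.5 / 4))               # diagonal, same formula
  expect_identical(s, t(s))

  # disjoint-support pairs approach the floor as the overlap vanishes
  eps <- 1e-9
  fd <- rbind(c(1, 0, eps) / (1 + eps), c(0, 1, eps) / (1 + eps))
  sd_ <- sharing_similarity(fd)
  expect_lt(sd_[1, 2], log(1e-15))

  expect_error(sharing_similarity(rbind(c(1, 0), c(1, 0))), "absent")
})

test_that("similarity is invariant to row scaling before normalization", {
  withr::with_seed(41, raw <- matrix(runif(60, 0.1, 2), 12, 5))
  f1 <- raw / rowSums(raw)
  scaled <- raw * runif(12, 0.5, 5)
  f2 <- scaled / rowSums(scaled)
  expect_equal(sharing_similarity(f1), sharing_similarity(f2),
               tolerance = 1e-12)
})

test_that("spanning tree maximizes sharing with deterministic ties", {
  # k = 2: the single forced edge
  phy2 <- infer_tree(matrix(0, 2, 2))
  expect_equal(unname(phy2$edges), cbind(1L, 2L), ignore_attr = TRUE)

  # K3 oracle: enumerate the three spanning trees
  s <- matrix(0, 3, 3)
  s[1, 2] <- s[2, 1] <- 5; s[1, 3] <- s[3, 1] <- 4; s[2, 3] <- s[3, 2] <- 1
  phy <- infer_tree(s)
  expect_equal(unname(phy$edges), rbind(c(1L, 2L), c(1L, 3L)))

  # shift invariance
  phy_shift <- infer_tree(s + 7)
  expect_equal(phy$edges, phy_shift$edges)

  # independent oracle on a random similarity: igraph's MST weight
  skip_if_not_installed("igraph")
  withr::with_seed(43, {
    k <- 6
    sym <- matrix(rnorm(k * k), k)
    sym <- (sym + t(sym)) / 2
  })
  phyr <- infer_tree(sym)
  g <- igraph::graph_from_adjacency_matrix(-sym, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  ig <- igraph::mst(g)
  expect_equal(sum(sym[phyr$edges]),
               -sum(igraph::E(ig)$weight), tolerance = 1e-10)

  expect_error(infer_tree(matrix(c(0, Inf, Inf, 0), 2)), "non-finite")
})

test_that("trees are structurally valid on fitted fractions", {
  sim <- simulate_dataset(k = 5, sigma = 0.2, d = 500, n = 80,
                          protocol = "tree", seed = 47)
  fit <- unmix(sim$expression, k = 5, n_restarts = 50, seed = 48)
  phy <- infer_tree(sharing_similarity(fit$fractions))
  expect_equal(nrow(phy$edges), 4)
  # connected and acyclic: union-find over the edges reaches one class
  parent <- 1:5
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in 1:4) {
    a <- find(phy$edges[i, 1]); b <- find(phy$edges[i, 2])
    expect_true(a != b)  # acyclic
    parent[a] <- b
  }
  expect_equal(length(unique(vapply(1:5, find, 1L))), 1)  # connected
})

test_that("bootstrap confidences behave at the keep_prob = 1 limit", {
  withr::with_seed(51, f <- clamp_fractions(matrix(runif(80, 0.05, 1), 20, 4)))
  phy <- bootstrap_tree(f, reps = 50, keep_prob = 1, seed = 52)
  expect_equal(phy$edge_confidence, rep(1, 3))
  expect_equal(phy$n_skipped, 0)
  # per-replicate edge mass: k - 1 edges per valid replicate
  expect_equal(sum(phy$pair_confidence$confidence), 3, tolerance = 1e-12)
})

test_that("bootstrap defaults encode the published resampling protocol", {
  fm <- formals(bootstrap_tree)
  expect_equal(fm$reps, 10000)
  expect_equal(fm$keep_prob, 0.9)
})

test_that("well-separated simulated branches get confident edges", {
  sim <- simulate_dataset(k = 3, sigma = 0.1, d = 2000, n = 100,
                          protocol = "tree", seed = 55)
  fit <- unmix(sim$expression, k = 3, n_restarts = 100, seed = 56)
  perm <- match_components(sim$components_true, fit$components)
  phy <- bootstrap_tree(fit$fractions, reps = 400, keep_prob = 0.9, seed = 57)
  expect_equal(tree_edge_accuracy(sim$tree_true, phy$edges, perm), 1)
  expect_true(all(phy$edge_confidence >= 0.9))
  expect_true(all(phy$pair_confidence$confidence >= 0 &
                    phy$pair_confidence$confidence <= 1))
})

test_that("newick serialization roots the tree for display", {
  s <- matrix(0, 3, 3)
  s[1, 2] <- s[2, 1] <- 5; s[1, 3] <- s[3, 1] <- 4; s[2, 3] <- s[3, 2] <- 1
  dimnames(s) <- list(c("A", "B", "C"), c("A", "B", "C"))
  phy <- infer_tree(s)
  nwk <- as_newick(phy, root = "A")
  expect_match(nwk, "^\\(.*\\)A;$")
  skip_if_not_installed("ape")
  tr <- ape::read.tree(text = nwk)
  expect_equal(sort(tr$tip.label), c("B", "C"))
  expect_error(as_newick(phy, root = "Z"), "unknown root")
})
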