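test_that("ARI matches brute-force pair counting and its degenerate conventions", {
  p1 <- c(1, 1, 2, 2, 3, 3)
  p2 <- c(1, 2, 2, 2, 3, 1)
  expect_equal(adjusted_rand_index(p1, p2), oracle_ari(p1, p2))
  expect_equal(adjusted_rand_index(p1, p1), 1)
  expect_equal(adjusted_rand_index(p1, c(2, 2, 3, 3, 1, 1)), 1)  # label permutation
  expect_equal(adjusted_rand_index(rep(1, 6), p2), 0)            # all-in-one
  expect_equal(adjusted_rand_index(p1, p2), adjusted_rand_index(p2, p1))
  # random partitions against the pair-counting oracle and mclust
  set.seed(41)
  for (i in 1:10) {
    a <- sample(1:4, 25, replace = TRUE)
    b <- sample(1:3, 25, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), oracle_ari(a, b))
    if (requireNamespace("mclust", quietly = TRUE))
      expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b))
  }
  # named vectors are matched by name
  n1 <- setNames(c(1, 1, 2), c("a", "b", "c"))
  n2 <- setNames(c(2, 1, 1), c("c", "a", "b"))
  expect_equal(adjusted_rand_index(n1, n2), 1)
  expect_error(adjusted_rand_index(p1, p2[1:5]), "different item sets")
})

test_that("ASW matches a per-point hand computation and cluster::silhouette", {
  # 4 points on a line: 0, 1, 10, 11 in clusters {1,1,2,2}
  D <- as.matrix(dist(c(0, 1, 10, 11)))
  lab <- c(1, 1, 2, 2)
  hand <- mean(sapply(1:4, function(i) {
    own <- setdiff(which(lab == lab[i]), i)
    a <- mean(D[i, own]); b <- mean(D[i, lab != lab[i]])
    (b - a) / max(a, b)
  }))
  expect_equal(average_silhouette_width(lab, D), hand)
  expect_gt(average_silhouette_width(lab, D), 0.85)
  skip_if_not_installed("cluster")
  set.seed(42)
  x <- c(rnorm(8), rnorm(8, 4))
  Dx <- as.matrix(dist(x))
  labx <- rep(1:2, each = 8)
  sil <- cluster::silhouette(labx, as.dist(Dx))
  expect_equal(average_silhouette_width(labx, Dx), mean(sil[, "sil_width"]))
  # random labels on structureless data stay near zero on average
  set.seed(43)
  asws <- replicate(20, {
    y <- rnorm(20)
    average_silhouette_width(sample(1:2, 20, TRUE), as.matrix(dist(y)))
  })
  expect_lt(abs(mean(asws)), 0.1)
  expect_error(average_silhouette_width(rep(1, 4), D), "single cluster")
  # singleton clusters contribute silhouette zero
  s_first3 <- sapply(1:3, function(i) {
    a <- mean(D[i, setdiff(1:3, i)]); b <- D[i, 4]
    (b - a) / max(a, b)
  })
  expect_equal(average_silhouette_width(c(1, 1, 1, 2), D), mean(c(s_first3, 0)))
})

test_that("centralities reproduce closed-form star, complete-graph and path values", {
  star <- star_adjacency(20)
  ct <- centralities(star)
  expect_equal(ct$degree[1], 1)
  expect_equal(ct$degree[2], 0.05)
  expect_equal(ct$betweenness[1], 1)
  expect_equal(ct$betweenness[2], 0)
  expect_equal(ct$closeness[1], 1)
  expect_equal(ct$closeness[2], 20 / (1 + 19 * 2))
  comp <- matrix(1, 5, 5); diag(comp) <- 0
  dimnames(comp) <- list(paste0("v", 1:5), paste0("v", 1:5))
  cc <- centralities(comp)
  expect_equal(cc$degree, rep(1, 5))
  expect_equal(cc$betweenness, rep(0, 5))
  expect_equal(cc$closeness, rep(1, 5))
  path3 <- matrix(0, 3, 3); path3[1, 2] <- path3[2, 1] <- path3[2, 3] <- path3[3, 2] <- 1
  dimnames(path3) <- list(paste0("v", 1:3), paste0("v", 1:3))
  expect_equal(centralities(path3)$betweenness[2], 1)
})

test_that("centralities are restricted to the largest connected component", {
  # a 4-clique plus a disjoint edge: the edge's nodes get all zeros
  a <- matrix(0, 6, 6)
  a[1:4, 1:4] <- 1; diag(a) <- 0
  a[5, 6] <- a[6, 5] <- 1
  dimnames(a) <- list(paste0("v", 1:6), paste0("v", 1:6))
  ct <- centralities(a)
  expect_true(all(ct[5:6, c("degree", "betweenness", "closeness")] == 0))
  expect_false(any(ct$in_lcc[5:6]))
  # equal-sized components: the one holding the smallest node index wins
  b <- matrix(0, 6, 6)
  b[1, 2] <- b[2, 1] <- b[2, 3] <- b[3, 2] <- 1   # component {1,2,3}
  b[4, 5] <- b[5, 4] <- b[5, 6] <- b[6, 5] <- 1   # component {4,5,6}
  dimnames(b) <- list(paste0("v", 1:6), paste0("v", 1:6))
  cb <- centralities(b)
  expect_true(all(cb$in_lcc[1:3]))
  expect_false(any(cb$in_lcc[4:6]))
  expect_true(all(centralities(matrix(0, 0, 0))$degree == numeric(0)))
})

test_that("hub detection takes nodes strictly above all three 95% cutoffs", {
  star <- star_adjacency(20)
  h <- detect_hubs(star)
  expect_equal(h$hubs, "v1")
  comp <- matrix(1, 6, 6); diag(comp) <- 0
  dimnames(comp) <- list(paste0("v", 1:6), paste0("v", 1:6))
  expect_length(detect_hubs(comp)$hubs, 0)   # constant centralities: none strict
  empty <- matrix(0, 3, 3, dimnames = list(paste0("v", 1:3), paste0("v", 1:3)))
  expect_length(detect_hubs(empty)$hubs, 0)
  expect_equal(formals(detect_hubs)$quantile, 0.95)
  # invariance to node relabeling
  perm <- c(3, 1, 2, 21, 4:20)
  star_p <- star[perm, perm]
  expect_setequal(detect_hubs(star_p)$hubs, "v1")
})

test_that("hub-set ranking averages per-measure ranks with first-wins ties", {
  mk <- function(deg, btw, cls) {
    ct <- data.frame(node = c("h", "x"), degree = c(deg, 0.1),
                     betweenness = c(btw, 0.1), closeness = c(cls, 0.1),
                     in_lcc = TRUE)
    list(hubs = "h", centralities = ct)
  }
  expect_equal(rank_hub_sets(list(mk(0.5, 0.5, 0.5))), 1L)
  # candidate 2 dominates on every measure
  expect_equal(rank_hub_sets(list(mk(0.4, 0.4, 0.4), mk(0.9, 0.9, 0.9))), 2L)
  # mixed ranks, hand-computed: ranks per measure (degree: 1,2,3;
  # betweenness: 3,2,1; closeness: 2,3,1) -> mean ranks 2, 7/3, 5/3 ->
  # candidate 2 wins
  cands <- list(mk(0.2, 0.9, 0.5), mk(0.5, 0.6, 0.9), mk(0.9, 0.3, 0.2))
  means <- t(sapply(cands, function(cd) unlist(cd$centralities[1, 2:4])))
  mean_ranks <- rowMeans(apply(means, 2, rank))
  expect_equal(rank_hub_sets(cands), which.max(mean_ranks))
  expect_equal(rank_hub_sets(cands), 2L)
  # full tie: first in enumeration order
  expect_equal(rank_hub_sets(list(mk(0.5, 0.5, 0.5), mk(0.5, 0.5, 0.5))), 1L)
  expect_error(rank_hub_sets(list()), "empty")
})

test_that("jaccard and family cosine similarity match their formulas", {
  expect_equal(jaccard_index(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(jaccard_index(c("a"), c("a")), 1)
  expect_equal(jaccard_index(c("a"), c("b")), 0)
  expect_equal(jaccard_index(character(0), character(0)), 1)
  tax <- data.frame(taxon_id = c("g1", "g2", "g3", "g4"),
                    genus = c("g1", "g2", "g3", "g4"),
                    family = c("fA", "fA", "fB", "fC"))
  # f_discov = (2, 1) over families (fA, fB); f_valid = (1, 1)
  expect_equal(family_cosine_similarity(c("g1", "g2", "g3"), c("g1", "g3"), tax),
               3 / (sqrt(5) * sqrt(2)))
  expect_equal(round(family_cosine_similarity(c("g1", "g2", "g3"), c("g1", "g3"), tax), 4),
               0.9487)
  expect_equal(family_cosine_similarity(c("g1", "g2"), c("g1", "g2"), tax), 1)
  expect_equal(family_cosine_similarity(c("g1"), c("g4"), tax), 0)
  expect_true(is.na(family_cosine_similarity(character(0), c("g1"), tax)))
})
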