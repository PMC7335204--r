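test_that("an all-tied graph yields no hubs under the strict-percentile rule", {
  w <- matrix(0.5, 10, 10); diag(w) <- 0
  hs <- hub_score(weighted_graph(w))
  expect_equal(hs$hub_score, rep(0L, 10))
  expect_false(any(hs$is_hub))
})

test_that("the star-plus-weak-ring centre meets all four criteria", {
  g <- star_ring_graph()
  hs <- hub_score(g)
  centre <- hs[hs$node == "hub", ]
  expect_gte(centre$hub_score, 3)
  expect_equal(centre$hub_score, 4L)
  expect_true(centre$is_hub)
  # oracle confirmation of each criterion from brute-force measures
  W <- g$weights
  D <- oracle_distances(W)
  li <- vapply(1:12, function(i) mean(D[i, -i]), numeric(1))
  expect_equal(unname(which.max(rowSums(W))), 1L)
  expect_equal(which.min(li), 1L)
  expect_equal(which.max(oracle_betweenness(W)), 1L)
  expect_equal(which.min(oracle_clustering_onnela(W)), 1L)
})

test_that("hub scores stay in 0..4 and is_hub means score >= 2", {
  set.seed(12)
  for (k in 1:10) {
    g <- weighted_graph(random_test_graph(sample(6:20, 1),
                                          density = runif(1, 0.3, 1)))
    hs <- hub_score(g)
    expect_true(all(hs$hub_score >= 0 & hs$hub_score <= 4))
    expect_equal(hs$is_hub, hs$hub_score >= 2)
    expect_equal(hs$hub_score,
                 as.integer(hs$hit_strength + hs$hit_path_length +
                              hs$hit_clustering + hs$hit_betweenness))
  }
})

test_that("with continuous tie-free measures exactly 9 of 45 nodes hit each criterion", {
  set.seed(23)
  g <- weighted_graph(random_test_graph(45, density = 1))
  hs <- hub_score(g)
  expect_equal(sum(hs$hit_strength), 9)
  expect_equal(sum(hs$hit_path_length), 9)
  expect_equal(sum(hs$hit_clustering), 9)
  # betweenness is a sum of discrete path-count fractions, so exact ties
  # can occur; the strict rule then admits fewer than 9
  expect_lte(sum(hs$hit_betweenness), 9)
  expect_gte(sum(hs$hit_betweenness), 7)
})

test_that("two disconnected uniform triangles partition into 2 modules with Q = 0.5", {
  w <- matrix(0, 6, 6)
  for (tri in list(1:3, 4:6)) {
    w[tri, tri] <- 0.7
  }
  diag(w) <- 0
  g <- weighted_graph(w)
  p <- newman_partition(g)
  expect_equal(length(unique(p$membership$module)), 2)
  expect_equal(p$q, 0.5)
  expect_equal(p$membership$module[1:3], rep(p$membership$module[1], 3))
  # exhaustive search agrees
  expect_equal(oracle_best_modularity(w)$q, 0.5)
})

test_that("a uniform complete graph is indivisible (single module, Q = 0)", {
  w <- matrix(0.3, 7, 7); diag(w) <- 0
  p <- newman_partition(weighted_graph(w))
  expect_equal(length(unique(p$membership$module)), 1)
  expect_equal(p$q, 0)
  expect_lte(oracle_best_modularity(w)$q, 1e-12)
})

test_that("spectral partition attains the exhaustive-search optimum on small graphs", {
  set.seed(41)
  parts <- lapply(4:8, set_partitions)
  names(parts) <- as.character(4:8)
  for (k in 1:30) {
    n <- sample(4:8, 1)
    W <- random_test_graph(n, density = runif(1, 0.3, 0.9))
    if (sum(W) == 0) next
    p <- newman_partition(weighted_graph(W))
    best <- oracle_best_modularity(W, parts[[as.character(n)]])
    expect_equal(p$q, best$q, tolerance = 1e-10)
  }
})

test_that("planted 3-block structure is recovered exactly (ARI = 1)", {
  g <- planted_block_graph(c(15, 15, 15), within = 0.5, between = 0.05,
                           noise_sd = 0.1, seed = 8)
  p <- newman_partition(g)
  expect_equal(oracle_ari(p$membership$module, attr(g, "planted")), 1)
})

test_that("empty graph yields the trivial single-module partition", {
  w <- matrix(0, 4, 4)
  p <- newman_partition(weighted_graph(w))
  expect_equal(p$q, 0)
  expect_equal(length(unique(p$membership$module)), 1)
})

test_that("group hub frequencies match direct counting", {
  set.seed(17)
  graphs <- lapply(1:8, function(i)
    weighted_graph(random_test_graph(10, density = 0.8)))
  groups <- rep(c("HC", "IBS"), each = 4)
  hubs <- lapply(graphs, hub_score)
  tab <- group_hub_table(hubs, groups)
  # direct counting oracle
  for (gname in c("HC", "IBS")) {
    idx <- which(groups == gname)
    manual <- rowSums(vapply(idx, function(i) hubs[[i]]$is_hub, logical(10)))
    got <- tab[tab$group == gname, ]
    got <- got[match(hubs[[1]]$node, got$node), ]
    expect_equal(got$n_hub, unname(manual))
    expect_equal(got$pct_hub, unname(100 * manual / 4))
  }
  # identical subjects give frequencies 0 or 100
  same <- group_hub_table(hubs[c(1, 1, 1)], rep("HC", 3))
  expect_true(all(same$pct_hub %in% c(0, 100)))
})

test_that("co-module frequencies count pairs correctly and ignore label permutations", {
  set.seed(19)
  graphs <- lapply(1:6, function(i)
    planted_block_graph(c(4, 4), within = 0.6, between = 0.05,
                        noise_sd = 0.2, seed = i))
  parts <- lapply(graphs, newman_partition)
  groups <- rep(c("HC", "IBS"), 3)
  cm <- comodule_matrix(parts, groups)
  # counting oracle for HC
  idx <- which(groups == "HC")
  acc <- Reduce(`+`, lapply(idx, function(i) {
    m <- parts[[i]]$membership$module
    outer(m, m, "==") * 1
  })) / length(idx)
  expect_equal(unname(cm$HC), unname(acc))
  expect_true(all(diag(cm$HC) == 1))
  # single subject: the indicator matrix itself
  cm1 <- comodule_matrix(parts[1], "HC")
  m1 <- parts[[1]]$membership$module
  expect_equal(unname(cm1$HC), unname(outer(m1, m1, "==") * 1))
  # relabelling invariance
  relab <- parts[[1]]
  relab$membership$module <- max(m1) + 1L - m1
  expect_equal(comodule_matrix(list(relab), "HC")$HC, cm1$HC)
})

test_that("consensus partition of identical subjects equals the single-subject partition", {
  g <- planted_block_graph(c(5, 5), within = 0.6, between = 0.05,
                           noise_sd = 0.1, seed = 3)
  single <- newman_partition(g)
  cons <- group_consensus_partition(list(g, g, g))
  expect_equal(cons$membership, single$membership)
  expect_equal(cons$q, single$q)
})

test_that("group hubs versus random equivalent networks flags planted hubs only", {
  set.seed(29)
  graphs <- lapply(1:6, function(i) star_ring_graph())
  out <- group_hubs(graphs, rep("HC", 6), seed = 7)
  expect_true(out$is_group_hub[out$node == "hub"])
  expect_lte(sum(out$is_group_hub), 3)
})
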