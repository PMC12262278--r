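test_that("network construction gives a simple graph over distinct bins", {
  pairs <- rbind(c(0, 1e4), c(1e4, 2e4), c(0, 1e4), c(3e4, 3e4))
  net <- graph_from_pairs(pairs)
  # duplicate edge collapsed, self pair dropped
  expect_equal(igraph::vcount(net), 3L)
  expect_equal(igraph::ecount(net), 2L)
  expect_false(igraph::any_loop(net))
  expect_false(igraph::any_multiple(net))
  # node count equals the set union of bins for a larger random set
  set.seed(3)
  p <- cbind(sample(0:99, 200, TRUE), sample(0:99, 200, TRUE)) * 1e4
  p <- p[p[, 1] != p[, 2], ]
  net2 <- graph_from_pairs(p)
  expect_equal(igraph::vcount(net2),
               length(union(p[, 1], p[, 2])))
})

test_that("disconnected cliques become separate modules; tiny ones are dropped", {
  pairs <- rbind(clique_pairs((0:4) * 1e4),
                 clique_pairs((10:14) * 1e4),
                 clique_pairs((20:22) * 1e4))  # a triangle, below min size
  mods <- detect_modules(graph_from_pairs(pairs), seed = 1)
  expect_equal(nrow(mods), 2L)
  expect_equal(mods$n_nodes, c(5L, 5L))
  expect_equal(mods$connectivity, c(10L, 10L))  # C(5,2)
  expect_equal(mods$span_start, c(0, 1e5))
  # all scores were computed; clique transitivity is 1
  expect_equal(mods$transitivity, c(1, 1))
})

test_that("module detection recovers a planted partition (ARI >= 0.9)", {
  skip_if_not_installed("mclust")
  set.seed(20)
  g <- igraph::sample_sbm(40, pref.matrix = matrix(c(0.6, 0.01, 0.01, 0.6),
                                                   2),
                          block.sizes = c(20, 20))
  igraph::V(g)$name <- as.character((0:39) * 1e4)
  g <- igraph::set_graph_attr(g, "chrom", "chrT")
  g <- igraph::set_graph_attr(g, "resolution", 1e4)
  mods <- detect_modules(g, method = "label_prop", seed = 5)
  truth <- rep(1:2, each = 20)
  found <- rep(0L, 40)
  for (i in seq_len(nrow(mods))) {
    idx <- as.numeric(module_nodes(mods, mods$module_id[i])) / 1e4 + 1
    found[idx] <- i
  }
  expect_gte(mclust::adjustedRandIndex(truth, found), 0.9)
})

test_that("label propagation with a fixed seed is reproducible", {
  tr <- synthetic_truth(seed = 2, chrom_length = 4e6, max_distance = 5e5,
                        modules = data.frame(start = c(5e5, 2e6),
                                             end = c(7e5, 2.2e6),
                                             multiplier = 5))
  sim <- simulate_contact_map(tr)
  res <- find_modules(sim$records, 1e4, include_zeros = TRUE, n_bins = 400)
  rerun <- detect_modules(res$network, seed = 42)
  expect_identical(as.data.frame(res$modules), as.data.frame(rerun))
})

test_that("retained modules partition their nodes disjointly", {
  tr <- synthetic_truth(seed = 6)
  res <- bench_pipeline(simulate_contact_map(tr)$records)
  nodes <- unlist(module_nodes(res$modules))
  expect_equal(anyDuplicated(nodes), 0L)
  expect_true(all(nodes %in% igraph::V(res$network)$name))
})

test_that("module connectivity equals exhaustive pair enumeration", {
  net <- graph_from_pairs(clique_pairs((0:4) * 1e4))
  expect_equal(module_connectivity(net, as.character((0:4) * 1e4)), 10L)
  # path a-b-c-d
  path <- graph_from_pairs(cbind((0:2) * 1e4, (1:3) * 1e4))
  expect_equal(module_connectivity(path, as.character((0:3) * 1e4)), 3L)
  # random 30-node module vs brute-force pair scan
  set.seed(8)
  p <- cbind(sample(0:29, 120, TRUE), sample(0:29, 120, TRUE)) * 1e4
  p <- unique(p[p[, 1] < p[, 2], ])
  net3 <- graph_from_pairs(p)
  sub_nodes <- as.character(sample(0:29, 18) * 1e4)
  brute <- sum(p[, 1] %in% as.numeric(sub_nodes) &
                 p[, 2] %in% as.numeric(sub_nodes))
  expect_equal(module_connectivity(net3, sub_nodes), brute)
})

test_that("module transitivity matches triplet enumeration", {
  tri <- graph_from_pairs(clique_pairs((0:2) * 1e4))
  expect_equal(module_transitivity(tri, as.character((0:2) * 1e4)), 1)
  star <- graph_from_pairs(cbind(0, (1:3) * 1e4))
  expect_equal(module_transitivity(star, as.character((0:3) * 1e4)), 0)
  # 4-cycle with one chord: 2 triangles, 8 connected triplets
  chorded <- graph_from_pairs(rbind(c(0, 1e4), c(1e4, 2e4), c(2e4, 3e4),
                                    c(0, 3e4), c(0, 2e4)))
  expect_equal(module_transitivity(chorded, as.character((0:3) * 1e4)),
               0.75)
  # random graphs vs the brute-force triple enumeration oracle
  for (s in 1:5) {
    set.seed(s)
    n <- 12
    adj <- matrix(0L, n, n)
    idx <- which(upper.tri(adj))
    on <- sample(idx, 25)
    adj[on] <- 1L
    adj <- adj + t(adj)
    pr <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
    net <- graph_from_pairs(cbind((pr[, 1] - 1) * 1e4, (pr[, 2] - 1) * 1e4))
    got <- module_transitivity(net, igraph::V(net)$name)
    keep <- (as.numeric(igraph::V(net)$name) / 1e4) + 1
    expect_equal(got, brute_transitivity(adj[keep, keep]), tolerance = 1e-12)
  }
})

test_that("module centrality equals the dense principal eigenvector", {
  # star: center scores 1, leaves equal and below 1
  star <- graph_from_pairs(cbind(0, (1:4) * 1e4))
  cen <- module_centrality(star, igraph::V(star)$name)
  expect_equal(unname(cen$scores["0"]), 1)
  leaves <- cen$scores[c("10000", "20000", "30000", "40000")]
  expect_true(all(abs(leaves - leaves[1]) < 1e-8))
  expect_true(all(leaves < 1))
  expect_equal(cen$central_node, 0)
  # cycle: regular graph, every score 1; tie broken to the smallest start
  cyc <- graph_from_pairs(rbind(cbind((0:4) * 1e4, c(1:4, 0) * 1e4)))
  cen2 <- module_centrality(cyc, igraph::V(cyc)$name)
  expect_true(all(abs(cen2$scores - 1) < 1e-8))
  expect_equal(cen2$central_node, 0)
  # random connected graphs up to 50 nodes vs dense eigendecomposition
  for (s in 1:5) {
    set.seed(s)
    n <- sample(6:50, 1)
    g <- igraph::sample_gnp(n, p = 2.5 / n)
    g <- igraph::induced_subgraph(
      g, which(igraph::components(g)$membership == 1))
    m <- igraph::vcount(g)
    if (m < 3) next
    igraph::V(g)$name <- as.character((seq_len(m) - 1) * 1e4)
    adj <- as.matrix(igraph::as_adjacency_matrix(g))
    cen3 <- module_centrality(g, igraph::V(g)$name)
    expect_lt(max(abs(cen3$scores[rownames(adj)] -
                        brute_eigencentrality(adj))), 1e-8)
  }
})

test_that("degree distribution conserves node counts and log-linear decay", {
  net <- graph_from_pairs(clique_pairs((0:4) * 1e4))
  dd <- degree_distribution(net)
  expect_equal(dd$degree, 4L)
  expect_equal(dd$count, 5L)
  expect_equal(sum(dd$count), igraph::vcount(net))
  # geometric degree sequence -> log-density slope close to log(1 - p)
  set.seed(12)
  p_geom <- 0.35
  degs <- rgeom(3000, p_geom) + 1L
  if (sum(degs) %% 2 == 1) degs[1] <- degs[1] + 1L
  g <- igraph::sample_degseq(degs, method = "configuration")
  igraph::V(g)$name <- as.character((seq_len(3000) - 1) * 1e4)
  dd2 <- degree_distribution(g)
  dd2 <- dd2[dd2$count >= 20, ]  # stable part of the tail
  slope <- stats::coef(stats::lm(log_density ~ degree, dd2))["degree"]
  expect_lt(abs(slope - log(1 - p_geom)) / abs(log(1 - p_geom)), 0.1)
})
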