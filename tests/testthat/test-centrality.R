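# Shortest paths, Brandes edge betweenness, and the ring descriptor.

test_that("path-graph distances and betweenness match hand enumeration", {
  net <- make_net(3, i = c(1, 2), j = c(2, 3), w = c(1, 1))
  sp <- shortest_path_matrix(net)
  expect_equal(sp$distances[1, 3], 2)
  expect_equal(sp$path_counts[1, 3], 1)
  bm <- betw_matrix(network_betweenness(net))
  # edge (1,2) serves pairs {1,2} and {1,3}
  expect_equal(bm[1, 2], 2)
  expect_equal(bm[2, 3], 2)
})

test_that("disconnected pairs have infinite distance and zero paths", {
  net <- make_net(4, i = c(1, 3), j = c(2, 4), w = c(1, 1))
  sp <- shortest_path_matrix(net)
  expect_equal(sp$distances[1, 3], Inf)
  expect_equal(sp$path_counts[1, 3], 0)
})

test_that("equal-cost paths split credit on the unit 4-cycle", {
  net <- make_net(4, i = c(1, 2, 3, 1), j = c(2, 3, 4, 4), w = rep(1, 4))
  bm <- betw_matrix(network_betweenness(net))
  # each edge: 1 (its endpoints) + 0.5 + 0.5 from the two opposite pairs
  for (e in list(c(1, 2), c(2, 3), c(3, 4), c(1, 4))) {
    expect_equal(bm[e[1], e[2]], 2, tolerance = 1e-12)
  }
  sp <- shortest_path_matrix(net)
  expect_equal(sp$path_counts[1, 3], 2)
})

test_that("empty graphs yield empty betweenness", {
  net <- make_net(0, integer(0), integer(0), numeric(0))
  expect_equal(nrow(network_betweenness(net)$edges), 0)
})

test_that("Brandes agrees with brute-force enumeration on random graphs", {
  withr::with_seed(99, {
    for (rep in 1:60) {
      n <- sample(4:8, 1)
      net <- random_connected_net(n, extra_edges = sample(0:3, 1))
      bm <- betw_matrix(network_betweenness(net))
      oracle <- brute_edge_betweenness(net)
      expect_lt(max(abs(bm - oracle)), 1e-9)
    }
  })
})

test_that("all-paths counting gives full credit per equal-cost path", {
  # 4-cycle: opposite pairs have two shortest paths, each deposits 1
  net <- make_net(4, i = c(1, 2, 3, 1), j = c(2, 3, 4, 4), w = rep(1, 4))
  bm <- betw_matrix(network_betweenness(net, count_mode = "all_paths"))
  for (e in list(c(1, 2), c(2, 3), c(3, 4), c(1, 4))) {
    expect_equal(bm[e[1], e[2]], 3, tolerance = 1e-12)
  }
  withr::with_seed(123, {
    for (rep in 1:15) {
      net <- random_connected_net(sample(4:7, 1), extra_edges = 2)
      bm <- betw_matrix(network_betweenness(net, count_mode = "all_paths"))
      expect_lt(max(abs(bm - brute_edge_betweenness(net, "all_paths"))), 1e-9)
    }
  })
})

test_that("distances match igraph as an independent implementation", {
  skip_if_not_installed("igraph")
  withr::with_seed(7, {
    for (rep in 1:10) {
      net <- random_connected_net(sample(5:8, 1), extra_edges = 3)
      g <- igraph::graph_from_edgelist(cbind(net$edges$i, net$edges$j),
                                       directed = FALSE)
      d_ig <- igraph::distances(g, weights = net$edges$weight)
      sp <- shortest_path_matrix(net)
      expect_lt(max(abs(sp$distances - d_ig)), 1e-9)
      eb_ig <- igraph::edge_betweenness(g, weights = net$edges$weight)
      bm <- betw_matrix(network_betweenness(net))
      expect_lt(max(abs(bm[cbind(net$edges$i, net$edges$j)] - eb_ig)), 1e-9)
    }
  })
})

test_that("on trees, total edge betweenness equals total path edge count", {
  withr::with_seed(11, {
    for (rep in 1:10) {
      n <- sample(5:9, 1)
      net <- random_connected_net(n, extra_edges = 0L)
      bm <- betw_matrix(network_betweenness(net))
      sp <- shortest_path_matrix(net)
      # unique paths on a tree: per-pair edge count via brute distances on
      # the unit-weight version of the same topology
      unit <- make_net(n, net$edges$i, net$edges$j,
                       rep(1, nrow(net$edges)))
      hops <- shortest_path_matrix(unit)$distances
      expect_equal(sum(bm) / 2, sum(hops[upper.tri(hops)]))
    }
  })
})

test_that("the star toy reproduces the hand-enumerated ring profile", {
  # ring node 4 joined to protein nodes 1-3; no other edges
  part <- fake_partition(c("residue", "residue", "residue", "ligand"),
                         resseq = c(1L, 5L, 9L, 1L))
  net <- make_net(4, i = c(1, 2, 3), j = c(4, 4, 4), w = c(1, 1, 1))
  bet <- network_betweenness(net)
  rp <- ring_betweenness(bet, part)
  expect_equal(sort(rp$profile$betweenness), c(3, 3, 3))
  expect_equal(rp$ring_sum, 9)
})

test_that("single ring-protein edge betweenness flows into the sum", {
  part <- fake_partition(c("residue", "ligand"), resseq = c(1L, 1L))
  net <- make_net(2, i = 1, j = 2, w = 0.5)
  rp <- ring_betweenness(network_betweenness(net), part)
  expect_equal(rp$ring_sum, 1)
})

test_that("a detached ring node scores zero and relabeling is harmless", {
  part <- fake_partition(c(rep("residue", 4), "ligand"),
                         resseq = c(1L, 3L, 5L, 7L, 1L))
  net <- make_net(5, i = c(1, 2, 3), j = c(2, 3, 4), w = rep(1, 3))
  rp <- ring_betweenness(network_betweenness(net), part)
  expect_equal(rp$ring_sum, 0)
  expect_equal(rp$profile$betweenness, rep(0, 4))

  # relabeling protein nodes leaves the ring sum unchanged
  net2 <- make_net(5, i = c(1, 2, 3, 1), j = c(5, 5, 5, 2), w = rep(1, 4))
  rp2 <- ring_betweenness(network_betweenness(net2), part)
  part_relab <- part
  part_relab$label[1:4] <- paste0("B:", c(11L, 13L, 15L, 17L))
  rp3 <- ring_betweenness(network_betweenness(net2), part_relab)
  expect_equal(rp2$ring_sum, rp3$ring_sum)
  # removing the ring edges forces the sum to zero
  keep <- !(net2$edges$j == 5)
  net3 <- make_net(5, net2$edges$i[keep], net2$edges$j[keep],
                   net2$edges$weight[keep])
  expect_equal(ring_betweenness(network_betweenness(net3), part)$ring_sum, 0)
})

test_that("near-tied float costs are treated as equal paths", {
  # two routes 1-2-4 and 1-3-4 differing by 1e-14
  net <- make_net(4, i = c(1, 2, 1, 3), j = c(2, 4, 3, 4),
                  w = c(0.5, 0.5, 0.5, 0.5 + 1e-14))
  sp <- shortest_path_matrix(net)
  expect_equal(sp$path_counts[1, 4], 2)
  bm <- betw_matrix(network_betweenness(net))
  expect_equal(bm[1, 2], bm[1, 3], tolerance = 1e-9)
})
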