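test_that("family aggregation applies the read and occupancy filters", {
  occ <- data.frame(
    lake_id = "L1",
    slice_index = c(1:5, 1:4, 1:6),
    taxon_id = c(rep("a", 5), rep("b", 4), rep("c", 6)),
    family = c(rep("FamLow", 5), rep("FamRare", 4), rep("FamOK", 6)),
    reads = c(rep(1L, 5),           # 5 reads total: below min_reads
              rep(250L, 4),         # 1000 reads but only 4 slices
              rep(10L, 6)),         # 60 reads in 6 slices: retained
    stringsAsFactors = FALSE
  )
  m <- aggregate_families(occ, n_slices = 10)
  expect_equal(rownames(m), "FamOK")
  expect_equal(sort(attr(m, "dropped_families")), c("FamLow", "FamRare"))
  expect_equal(sum(m), 60)
  expect_error(aggregate_families(occ[1:5, ], n_slices = 10), "no family")
})

test_that("the Spearman matrix matches pairwise expectations and BH step-up", {
  m <- rbind(f1 = c(1, 2, 3, 4, 5, 6),
             f2 = c(2, 4, 6, 8, 10, 12),   # same ranking as f1
             f3 = c(6, 5, 4, 3, 2, 1),     # reversed
             f4 = c(3, 1, 4, 1, 5, 9))
  st <- spearman_matrix(m)
  expect_equal(st$r["f1", "f2"], 1)
  expect_equal(st$r["f1", "f3"], -1)
  expect_true(isSymmetric(st$r))
  ut <- upper.tri(st$p)
  expect_true(all(st$p_adj[ut] >= st$p[ut] - 1e-15))
  expect_equal(st$p_adj[ut], oracle_bh(st$p[ut]), tolerance = 1e-12)

  set.seed(10)
  m2 <- matrix(rnorm(5 * 12), 5, 12,
               dimnames = list(sprintf("g%d", 1:5), NULL))
  st2 <- spearman_matrix(m2)
  ut2 <- upper.tri(st2$p)
  expect_equal(st2$p_adj[ut2], oracle_bh(st2$p[ut2]), tolerance = 1e-12)
  # monotone in p
  o <- order(st2$p[ut2])
  expect_true(all(diff(st2$p_adj[ut2][o]) >= -1e-15))
})

test_that("edges require both a strong positive r and a small adjusted p", {
  fams <- c("A", "B", "C", "D")
  r <- matrix(0, 4, 4, dimnames = list(fams, fams)); diag(r) <- 1
  p <- matrix(0.5, 4, 4, dimnames = list(fams, fams))
  r["A", "B"] <- r["B", "A"] <- 0.61; p["A", "B"] <- p["B", "A"] <- 0.01
  r["A", "C"] <- r["C", "A"] <- 0.90; p["A", "C"] <- p["C", "A"] <- 0.20
  r["B", "C"] <- r["C", "B"] <- -0.90; p["B", "C"] <- p["C", "B"] <- 1e-6
  net <- build_network(list(r = r, p_adj = p), 0.6, 0.05)
  expect_equal(nrow(net$edges), 1)
  expect_equal(sort(c(net$edges$family_a, net$edges$family_b)), c("A", "B"))
  # isolated nodes are kept with degree zero
  expect_setequal(net$nodes, fams)
  expect_equal(sum(igraph::degree(net$graph) == 0), 2)
})

test_that("community detection is exact on canonical graphs", {
  # two disjoint triangles split into their components
  adj <- matrix(0L, 6, 6)
  tri <- rbind(c(1, 2), c(2, 3), c(1, 3))
  for (e in 1:3) {
    adj[tri[e, 1], tri[e, 2]] <- adj[tri[e, 2], tri[e, 1]] <- 1L
    adj[tri[e, 1] + 3, tri[e, 2] + 3] <- adj[tri[e, 2] + 3, tri[e, 1] + 3] <- 1L
  }
  net <- cooc_network_from_adjacency(adj)
  part <- detect_communities(net)
  expect_equal(part$method, "exact")
  expect_equal(length(unique(part$membership)), 2)
  expect_equal(unname(part$membership[1]), unname(part$membership[2]))
  expect_false(part$membership[[1]] == part$membership[[4]])

  # a single triangle is one community
  net1 <- cooc_network_from_adjacency(adj[1:3, 1:3])
  expect_equal(length(unique(detect_communities(net1)$membership)), 1)

  # edgeless network: trivial partition with a warning
  iso <- cooc_network_from_adjacency(matrix(0L, 4, 4))
  expect_warning(triv <- detect_communities(iso), "edgeless")
  expect_equal(length(unique(triv$membership)), 4)
})

test_that("exact modularity equals exhaustive enumeration on small graphs", {
  set.seed(14)
  for (n in c(4, 5, 6, 7)) {
    adj <- random_adjacency(n)
    net <- cooc_network_from_adjacency(adj)
    part <- detect_communities(net)
    core <- which(rowSums(adj) > 0)
    oracle <- oracle_best_partition(adj[core, core, drop = FALSE])
    got <- oracle_modularity(adj[core, core, drop = FALSE],
                             part$membership[core])
    expect_equal(got, oracle$modularity, tolerance = 1e-9)
    expect_equal(part$modularity, oracle$modularity, tolerance = 1e-9)
  }
})

test_that("community metrics report internal edges and link proportions", {
  adj <- matrix(0L, 3, 3)
  adj[1, 2] <- adj[2, 1] <- adj[2, 3] <- adj[3, 2] <- adj[1, 3] <- adj[3, 1] <- 1L
  net <- cooc_network_from_adjacency(adj)
  part <- detect_communities(net)
  cm <- community_metrics(net, part)
  expect_equal(cm$communities$internal_edges, 3L)
  expect_equal(cm$communities$positive_link_pct, 100)

  # two disjoint triangles: each half of the 6 edges, 50% each
  adj2 <- matrix(0L, 6, 6)
  for (e in list(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6))) {
    adj2[e[1], e[2]] <- adj2[e[2], e[1]] <- 1L
  }
  net2 <- cooc_network_from_adjacency(adj2)
  cm2 <- community_metrics(net2, detect_communities(net2))
  expect_equal(cm2$communities$internal_edges, c(3L, 3L))
  expect_equal(cm2$communities$positive_link_pct, c(50, 50))
  expect_equal(sort(cm2$degrees$degree), rep(2L, 6))
})

test_that("the edge set is invariant to family ordering", {
  set.seed(20)
  m <- matrix(rpois(8 * 10, 20) * rbinom(8 * 10, 1, 0.8), 8, 10,
              dimnames = list(sprintf("f%d", 1:8), NULL))
  st <- spearman_matrix(m)
  net <- build_network(st, 0.3, 0.5)
  perm <- sample(8)
  st2 <- spearman_matrix(m[perm, ])
  net2 <- build_network(st2, 0.3, 0.5)
  canon <- function(e) {
    k <- paste(pmin(e$family_a, e$family_b), pmax(e$family_a, e$family_b))
    sort(k)
  }
  expect_equal(canon(net$edges), canon(net2$edges))
})

test_that("the network stage runs end to end on default synthetic data", {
  run <- default_run()
  occ <- run$sim$occurrence
  fm <- aggregate_families(occ, n_slices = 30)
  # every retained family clears both filters
  expect_true(all(rowSums(fm) >= 10))
  expect_true(all(rowSums(fm > 0) >= 5))
  st <- spearman_matrix(fm)
  net <- build_network(st, 0.6, 0.05)
  expect_setequal(net$nodes, rownames(fm))
  if (nrow(net$edges)) {
    expect_true(all(net$edges$r > 0.6 & net$edges$p_adj < 0.05))
    part <- suppressWarnings(detect_communities(net))
    expect_setequal(names(part$membership), net$nodes)
    lab <- label_communities(fm, part, 11)
    expect_true(all(lab %in% c("glacial", "holocene")))
    cm <- community_metrics(net, part)
    cross <- sum(part$membership[net$edges$family_a] !=
                   part$membership[net$edges$family_b])
    expect_equal(sum(cm$communities$internal_edges), nrow(net$edges) - cross)
  }
})
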