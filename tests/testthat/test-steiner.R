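test_that("steiner_tree handles elementary configurations", {
  g <- interactome(rbind(c("A", "B"), c("B", "C")))
  one <- steiner_tree(g, "A")
  expect_equal(one$nodes, "A")
  expect_equal(nrow(one$edges), 0L)
  expect_length(one$linker_nodes, 0L)

  pair <- steiner_tree(g, c("A", "B"))
  expect_equal(sort(pair$nodes), c("A", "B"))
  expect_equal(nrow(pair$edges), 1L)
  expect_length(pair$linker_nodes, 0L)

  expect_error(steiner_tree(g, c("Z9")), "no seeds in network")
})

test_that("star graph: hub recovered as the single linker", {
  g <- interactome(rbind(c("H", "A"), c("H", "C"), c("H", "E"),
                         c("H", "X"), c("H", "Y")))
  sn <- steiner_tree(g, c("A", "C", "E"))
  expect_setequal(sn$nodes, c("A", "C", "E", "H"))
  expect_equal(sn$linker_nodes, "H")
  expect_equal(nrow(sn$edges), 3L)
  expect_valid_tree(sn)
  # matches the exhaustive optimum here
  expect_equal(length(sn$nodes), oracle_steiner_nodes(g, c("A", "C", "E")))
})

test_that("seeds in minor components and absent seeds are excluded", {
  g <- interactome(rbind(c("A", "B"), c("B", "C"), c("X", "Y")))
  sn <- steiner_tree(g, c("A", "C", "X", "ZZ"))
  expect_setequal(sn$seed_nodes, c("A", "C"))
  expect_setequal(sn$excluded_seeds, c("X", "ZZ"))
  expect_valid_tree(sn)
})

test_that("heuristic output is a valid tree on random instances", {
  set.seed(41)
  for (rep in 1:40) {
    n <- sample(6:25, 1)
    g <- random_connected_graph(n, extra = sample(0:15, 1))
    seeds <- sample(igraph::V(g)$name, sample(2:min(6, n), 1))
    sn <- steiner_tree(g, seeds)
    expect_valid_tree(sn)
    expect_setequal(sn$seed_nodes, seeds)
    expect_length(intersect(sn$seed_nodes, sn$linker_nodes), 0L)
    # no non-seed leaves survive pruning
    if (nrow(sn$edges) > 0) {
      deg <- table(as.vector(sn$edges))
      leaves <- names(deg)[deg == 1]
      expect_true(all(leaves %in% seeds))
    }
  }
})

test_that("identical input yields identical output regardless of edge order", {
  set.seed(43)
  g <- random_connected_graph(15, extra = 12L)
  el <- igraph::as_edgelist(g, names = TRUE)
  perm <- sample(nrow(el))
  swap <- runif(nrow(el)) < 0.5
  el2 <- el
  el2[swap, ] <- el[swap, 2:1]
  g2 <- interactome(el2[perm, ])
  seeds <- c("V01", "V07", "V13")
  expect_identical(steiner_tree(g, seeds), steiner_tree(g2, seeds))
})

test_that("densify restores induced edges, keeps nodes, and is idempotent", {
  g <- interactome(rbind(c("A", "B"), c("B", "C"), c("A", "C")))
  sn <- steiner_tree(g, c("A", "B", "C"))
  expect_equal(nrow(sn$edges), 2L)      # tree on a triangle
  d1 <- densify(g, sn)
  expect_equal(nrow(d1$edges), 3L)
  expect_identical(d1$nodes, sn$nodes)
  expect_gte(nrow(d1$edges), nrow(sn$edges))
  expect_identical(densify(g, d1), d1)
  expect_false(d1$is_tree)
})

test_that("classify_nodes partitions and reports coverage", {
  g <- interactome(rbind(c("H", "A"), c("H", "C"), c("H", "E")))
  sn <- steiner_tree(g, c("A", "C", "E"))
  cls <- classify_nodes(sn, c("A", "C", "E"))
  expect_equal(cls$linkers, "H")
  expect_equal(cls$seed_coverage, 1.0)

  cls2 <- classify_nodes(sn, c("A", "C", "E", "MISSING"))
  expect_equal(cls2$seed_coverage, 3 / 4)

  all_seed <- steiner_tree(g, c("A", "H"))
  expect_length(classify_nodes(all_seed, c("A", "H"))$linkers, 0L)
})

test_that("a uniquely planted path is recovered exactly", {
  g <- make_interactome(5, 0, planted_paths = data.frame(
    from = "G000001", to = "G000002", length = 3), seed = 1)
  sn <- steiner_tree(g, c("G000001", "G000002"))
  expect_setequal(sn$linker_nodes, c("LNK0001", "LNK0002"))
  expect_equal(nrow(sn$edges), 3L)
})

test_that("planted linker chains are recovered amid sparse random background", {
  # Sparse G(n, m) background (mean degree 2) with three planted length-3
  # connector chains: the chains are almost always the unique parsimonious
  # routes, so the heuristic should pick up nearly all planted linkers.
  found <- 0L
  total <- 0L
  for (rep in 1:50) {
    ends <- sprintf("G%06d", 1:6)
    g <- make_interactome(300, 300, planted_paths = data.frame(
      from = ends[c(1, 3, 5)], to = ends[c(2, 4, 6)], length = 3),
      seed = 1000 + rep)
    sn <- steiner_tree(g, ends)
    planted <- sprintf("LNK%04d", 1:6)
    found <- found + sum(planted %in% sn$nodes)
    total <- total + length(planted)
  }
  expect_gte(found / total, 0.9)
})
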