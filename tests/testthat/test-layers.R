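# Layers, projections, modularity and similarity measures.

test_that("shared-membership projection builds co-occurrence cliques", {
  l1 <- project_shared_membership(list(P1 = c("a", "b", "c")))
  expect_setequal(l1$nodes, c("a", "b", "c"))
  expect_equal(nrow(l1$edges), 3L)   # triangle

  l2 <- project_shared_membership(list(P1 = c("a", "b"), P2 = c("b", "c")))
  expect_equal(nrow(l2$edges), 2L)
  expect_false(any(l2$edges$from == "a" & l2$edges$to == "c"))

  # co-occurrence in several groups is deduplicated
  l3 <- project_shared_membership(list(P1 = c("a", "b"), P2 = c("a", "b")))
  expect_equal(nrow(l3$edges), 1L)
  expect_equal(l3$edges$weight, 1)

  expect_error(project_shared_membership(list()), "no groups")
})

test_that("projection of k disjoint groups yields sum of within-group pair counts", {
  set.seed(42)
  for (rep in 1:5) {
    sizes <- sample(2:6, sample(2:4, 1L), replace = TRUE)
    genes <- sprintf("g%03d", seq_len(sum(sizes)))
    groups <- split(genes, rep(seq_along(sizes), sizes))
    l <- project_shared_membership(groups)
    expect_equal(nrow(l$edges), sum(choose(sizes, 2)))
  }
})

test_that("layer construction enforces the undirected, loop-free contract", {
  expect_warning(
    l <- ml_layer(data.frame(from = c("a", "b"), to = c("b", "a"))),
    "merged")
  expect_equal(nrow(l$edges), 1L)
  expect_equal(l$edges$weight, 2)
  expect_error(ml_layer(data.frame(from = "a", to = "a")), "self-loop")
  expect_error(ml_layer(data.frame(from = "a", to = "b", w = -1)), "positive")
  expect_error(ml_layer(data.frame(from = "a b", to = "b")), "whitespace")
})

test_that("layer modularity matches hand-derived and brute-force values", {
  tri <- two_triangles()
  p_true <- as_partition(c(a = 0, b = 0, c = 0, d = 1, e = 1, f = 1))
  expect_equal(layer_modularity(tri, p_true, gamma = 1), 0.5)
  expect_equal(layer_modularity(tri, p_true, gamma = 1),
               modularity_brute(tri, p_true, 1))

  # all nodes in one community: Q = 1 - gamma
  all_one <- as_partition(stats::setNames(rep(0L, 6), letters[1:6]))
  for (g in c(0.5, 1, 2.7))
    expect_equal(layer_modularity(tri, all_one, g), 1 - g)

  # singletons on a loop-free graph: strictly negative at gamma = 1
  singles <- as_partition(stats::setNames(0:5, letters[1:6]))
  expect_lt(layer_modularity(tri, singles, 1), 0)

  expect_error(layer_modularity(ml_layer(data.frame(from = character(),
                                                    to = character()),
                                         nodes = c("a", "b")), p_true, 1),
               "empty layer")
  expect_error(layer_modularity(tri, p_true, gamma = 0), "gamma")
})

test_that("layer modularity agrees with igraph on random weighted graphs", {
  set.seed(7)
  for (rep in 1:15) {
    n <- sample(5:12, 1L)
    ids <- sprintf("n%02d", seq_len(n))
    pr <- t(utils::combn(ids, 2L))
    keep <- stats::runif(nrow(pr)) < 0.5
    if (sum(keep) < 1L) next
    w <- stats::runif(sum(keep), 0.5, 3)
    lay <- ml_layer(data.frame(from = pr[keep, 1L], to = pr[keep, 2L], weight = w,
                               stringsAsFactors = FALSE), nodes = ids)
    p <- rand_partition(ids, sample(2:4, 1L), seed = 100 + rep)
    g <- igraph::graph_from_data_frame(lay$edges, directed = FALSE,
                                       vertices = data.frame(name = lay$nodes))
    gam <- sample(c(0.5, 1, 2), 1L)
    expect_equal(layer_modularity(lay, p, gam),
                 igraph::modularity(g, unclass(p)[lay$nodes] + 1L,
                                    weights = lay$edges$weight,
                                    resolution = gam),
                 tolerance = 1e-12)
  }
})

test_that("multilayer modularity is additive, relabeling-invariant and bounded", {
  set.seed(11)
  for (rep in 1:10) {
    inst <- rand_small_instance(500 + rep)
    ws <- vapply(inst$net$layers, layer_weight, numeric(1L))
    if (any(ws <= 0)) next
    nodes <- inst$net$nodes
    p <- rand_partition(nodes, 3L, seed = rep)
    gam <- inst$gamma
    q <- multilayer_modularity(inst$net, p, gam)
    expect_equal(q, sum(vapply(inst$net$layers, layer_modularity, numeric(1L),
                               partition = p, gamma = gam)),
                 tolerance = 1e-9)
    # relabeling invariance: permute labels
    perm <- sample(0:2)
    p2 <- as_partition(stats::setNames(perm[unclass(p) + 1L], names(p)))
    expect_equal(multilayer_modularity(inst$net, p2, gam), q, tolerance = 1e-12)
    expect_lte(q, length(inst$net$layers))
  }
})

test_that("zero-weight layers warn and contribute nothing", {
  tri <- two_triangles()
  empty <- ml_layer(data.frame(from = character(), to = character()),
                    nodes = letters[1:6], name = "empty")
  net <- ml_network(list(tri, empty))
  p <- as_partition(c(a = 0, b = 0, c = 0, d = 1, e = 1, f = 1))
  expect_warning(q <- multilayer_modularity(net, p, 1), "zero-weight")
  expect_equal(q, 0.5)
  expect_error(multilayer_modularity(ml_network(list(empty)), p, 1), "empty layer")
})

test_that("edge overlap report is symmetric with correct Jaccard values", {
  a <- ml_layer(data.frame(from = c("a", "b"), to = c("b", "c")), name = "A")
  b <- ml_layer(data.frame(from = c("b", "c"), to = c("c", "d")), name = "B")
  ov <- layer_edge_overlap(a, b)
  expect_equal(ov$shared_edges, 1L)
  expect_equal(ov$edge_jaccard, 1 / 3)
  ov2 <- layer_edge_overlap(b, a)
  expect_equal(ov2$edge_jaccard, ov$edge_jaccard)
  expect_equal(ov2$node_jaccard, ov$node_jaccard)

  expect_equal(layer_edge_overlap(a, a)$edge_jaccard, 1)
  c_ <- ml_layer(data.frame(from = "x", to = "y"), name = "C")
  expect_equal(layer_edge_overlap(a, c_)$edge_jaccard, 0)
})

test_that("community similarity follows the shared-interest-over-size-sum definition", {
  expect_equal(community_similarity(c("g1", "g2"), c("g2", "g3"),
                                    c("g1", "g2", "g3")), 0.25)
  s <- c("x1", "x2", "x3")
  expect_equal(community_similarity(s, s, s), 0.5)   # maximum
  expect_equal(community_similarity(c("a", "b"), c("c", "d"), c("a", "c")), 0)
  # standard Jaccard offered separately
  expect_equal(community_similarity(c("a", "b"), c("b", "c"), method = "jaccard"),
               1 / 3)
  expect_error(community_similarity(character(), character(), "a"), "empty")
})
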