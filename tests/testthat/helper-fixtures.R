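# Fixtures built in code and independent oracles used across the suite.

two_triangles <- function(name = "tri") {
  ml_layer(data.frame(from = c("a", "a", "b", "d", "d", "e"),
                      to = c("b", "c", "c", "e", "f", "f"),
                      stringsAsFactors = FALSE), name = name)
}

# two 4-cliques joined by a single bridge edge
two_cliques_bridge <- function(name = "cl") {
  g1 <- t(utils::combn(c("a", "b", "c", "d"), 2))
  g2 <- t(utils::combn(c("e", "f", "g", "h"), 2))
  ml_layer(data.frame(from = c(g1[, 1], g2[, 1], "d"),
                      to = c(g1[, 2], g2[, 2], "e"),
                      stringsAsFactors = FALSE), name = name)
}

# Seeded random small multilayer instance (Erdos-Renyi layers over a shared
# node set), as used for the optimizer-vs-oracle comparisons.
rand_small_instance <- function(seed, n_range = 4:8) {
  set.seed(seed)
  n <- sample(n_range, 1L)
  L <- sample(2:3, 1L)
  p <- stats::runif(1L, 0.3, 0.7)
  ids <- sprintf("N%02d", seq_len(n))
  pr <- t(utils::combn(ids, 2L))
  layers <- lapply(seq_len(L), function(l) {
    keep <- stats::runif(nrow(pr)) <= p
    ml_layer(data.frame(from = pr[keep, 1L], to = pr[keep, 2L],
                        stringsAsFactors = FALSE),
             nodes = ids, name = paste0("L", l))
  })
  list(net = ml_network(layers), gamma = sample(c(0.5, 1, 2), 1L))
}

rand_partition <- function(nodes, k, seed) {
  set.seed(seed)
  as_partition(stats::setNames(sample.int(k, length(nodes), replace = TRUE) - 1L,
                               nodes))
}

# Assemble an ml_sweep directly from partitions (for co-membership and module
# logic tests that do not need a detection run).
make_sweep <- function(partitions, grid = NULL) {
  partitions <- lapply(partitions, as_partition)
  structure(list(
    grid = resolution_grid(values = grid %||% seq_along(partitions)),
    partitions = partitions,
    seeds = seq_along(partitions),
    Q = rep(NA_real_, length(partitions)),
    n_communities = vapply(partitions, function(p) length(unique(unclass(p))), integer(1L)),
    nodes = names(partitions[[1L]])
  ), class = "ml_sweep")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- independent oracles -----------------------------------------------------

# Full fixed-margin enumeration of the two-sided Fisher exact p-value.
fisher_enum_oracle <- function(tab, tol = 1e-7) {
  m <- sum(tab[1L, ])
  n2 <- sum(tab[2L, ])
  k <- sum(tab[, 1L])
  xs <- max(0L, k - n2):min(k, m)
  pr <- stats::dhyper(xs, m, n2, k)
  pobs <- stats::dhyper(tab[1L, 1L], m, n2, k)
  sum(pr[pr <= pobs * (1 + tol)])
}

# Exact rank-sum p by enumeration of all assignments of the pooled sample.
ranksum_enum_oracle <- function(x, y, alternative) {
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  N <- length(pooled)
  r <- rank(pooled)
  obs <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2  # Mann-Whitney U
  sets <- utils::combn(N, length(x))
  null <- apply(sets, 2L, function(ix) sum(r[ix])) - length(x) * (length(x) + 1) / 2
  switch(alternative,
         greater = mean(null >= obs),
         less = mean(null <= obs),
         two_sided = min(1, 2 * min(mean(null >= obs), mean(null <= obs))))
}

# Direct edge/degree-count modularity, independent of the package internals.
modularity_brute <- function(layer, partition, gamma) {
  p <- as_partition(partition)
  e <- layer$edges
  W <- sum(e$weight)
  intra <- 0
  for (i in seq_len(nrow(e)))
    if (p[[e$from[i]]] == p[[e$to[i]]]) intra <- intra + e$weight[i]
  q <- intra / W
  for (lab in unique(unclass(p)[layer$nodes])) {
    members <- layer$nodes[unclass(p)[layer$nodes] == lab]
    d <- 0
    for (i in seq_len(nrow(e))) {
      if (e$from[i] %in% members) d <- d + e$weight[i]
      if (e$to[i] %in% members) d <- d + e$weight[i]
    }
    q <- q - gamma * (d / (2 * W))^2
  }
  q
}
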