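# Generalized Louvain maximization of multilayer modularity.
#
# The quality function is the sum over layers of resolution-parametrized
# Newman-Girvan modularity under one common partition. The optimizer is the
# classic two-phase scheme: seeded-shuffle local moving from singletons, then
# condensation of communities into super-nodes (intra weight becoming
# self-loops), repeated until no coarsening occurs. All tie-breaks and visit
# orders are deterministic given the seed.

# ---- compiled representation (integer node indices) ----

.compile_network <- function(net) {
  nodes <- net$nodes
  layers <- lapply(net$layers, function(l) {
    list(name = l$name,
         i = match(l$edges$from, nodes),
         j = match(l$edges$to, nodes),
         w = l$edges$weight,
         W = sum(l$edges$weight))
  })
  list(nodes = nodes, layers = unname(layers))
}

# Modularity on compiled layers for an integer label vector (any coding).
.modularity_compiled <- function(layers, lab, gamma) {
  q <- 0
  for (ly in layers) {
    if (ly$W <= 0) next
    intra <- sum(ly$w[lab[ly$i] == lab[ly$j]])
    dc <- rowsum(c(ly$w, ly$w), c(lab[ly$i], lab[ly$j]))
    q <- q + intra / ly$W - gamma * sum((dc / (2 * ly$W))^2)
  }
  q
}

# Per-layer adjacency lists for the local-moving phase. Self-loops are kept
# out of the neighbor lists (they cancel in the move gain) but count twice in
# the degree.
.build_adj <- function(layers, n) {
  lapply(layers, function(ly) {
    ns <- ly$i != ly$j
    ii <- c(ly$i[ns], ly$j[ns])
    jj <- c(ly$j[ns], ly$i[ns])
    ww <- c(ly$w[ns], ly$w[ns])
    f <- factor(ii, levels = seq_len(n))
    deg <- numeric(n)
    if (length(ii)) {
      s <- rowsum(ww, ii)
      deg[as.integer(rownames(s))] <- s[, 1L]
    }
    if (any(!ns)) {
      s <- rowsum(ly$w[!ns], ly$i[!ns])
      deg[as.integer(rownames(s))] <- deg[as.integer(rownames(s))] + 2 * s[, 1L]
    }
    list(nb = split(jj, f), wt = split(ww, f), deg = deg, W = ly$W)
  })
}

# One local-moving phase from singletons; returns labels 1..k (contiguous,
# first-appearance order over node index).
.local_move <- function(adj, n, gamma, tol = 1e-12) {
  comm <- seq_len(n)
  csize <- rep(1L, n)
  dtot <- lapply(adj, function(a) a$deg)
  L <- length(adj)
  repeat {
    ord <- sample.int(n)
    moved <- 0L
    for (v in ord) {
      cv <- comm[v]
      kl <- vector("list", L)
      cand <- integer(0)
      for (li in seq_len(L)) {
        nb <- adj[[li]]$nb[[v]]
        if (!length(nb)) next
        s <- rowsum(adj[[li]]$wt[[v]], comm[nb])
        kl[[li]] <- stats::setNames(s[, 1L], rownames(s))
        cand <- c(cand, as.integer(rownames(s)))
      }
      cand <- unique(cand)
      cand <- cand[cand != cv]
      if (csize[cv] > 1L) {
        free <- which(csize == 0L)[1L]   # exists whenever cv holds > 1 node
        cand <- c(cand, free)
      }
      if (!length(cand)) next
      dq <- numeric(length(cand))
      for (li in seq_len(L)) {
        a <- adj[[li]]
        ki <- a$deg[v]
        if (ki == 0 || a$W <= 0) next
        kv <- kl[[li]]
        k_cv <- 0
        k_c <- numeric(length(cand))
        if (!is.null(kv)) {
          hit <- match(as.character(cv), names(kv))
          if (!is.na(hit)) k_cv <- kv[[hit]]
          m <- match(as.character(cand), names(kv))
          k_c[!is.na(m)] <- kv[m[!is.na(m)]]
        }
        dq <- dq + (k_c - k_cv) / a$W -
          gamma * ki * (dtot[[li]][cand] - dtot[[li]][cv] + ki) / (2 * a$W^2)
      }
      best <- max(dq)
      if (best > tol) {
        target <- min(cand[dq == best])   # tie-break: smallest community label
        comm[v] <- target
        csize[cv] <- csize[cv] - 1L
        csize[target] <- csize[target] + 1L
        for (li in seq_len(L)) {
          ki <- adj[[li]]$deg[v]
          if (ki > 0) {
            dtot[[li]][cv] <- dtot[[li]][cv] - ki
            dtot[[li]][target] <- dtot[[li]][target] + ki
          }
        }
        moved <- moved + 1L
      }
    }
    if (moved == 0L) break
  }
  match(comm, unique(comm))
}

.condense_layers <- function(layers, lab, k) {
  lapply(layers, function(ly) {
    ci <- lab[ly$i]
    cj <- lab[ly$j]
    lo <- pmin(ci, cj)
    hi <- pmax(ci, cj)
    key <- (lo - 1) * k + hi
    s <- rowsum(ly$w, key, reorder = TRUE)
    keys <- as.numeric(rownames(s))
    list(name = ly$name,
         i = as.integer((keys - 1) %/% k) + 1L,
         j = as.integer((keys - 1) %% k) + 1L,
         w = s[, 1L], W = ly$W)
  })
}

# One full seeded run over compiled layers; RNG state is the caller's.
.louvain_once <- function(layers, n, gamma) {
  memb <- seq_len(n)
  cur <- layers
  ncur <- n
  qtrace <- numeric(0)
  repeat {
    adj <- .build_adj(cur, ncur)
    lab <- .local_move(adj, ncur, gamma)
    k <- max(lab)
    memb <- lab[memb]
    qtrace <- c(qtrace, .modularity_compiled(layers, memb, gamma))
    if (k == ncur) break
    cur <- .condense_layers(cur, lab, k)
    ncur <- k
  }
  list(memb = memb, qtrace = qtrace)
}

#' Multilayer community detection by generalized Louvain
#'
#' Maximizes [multilayer_modularity()] at resolution `gamma` over a single
#' partition shared by all layers. The algorithm starts from singletons,
#' repeatedly sweeps the nodes in a seeded random order moving each node to
#' the adjacent community (in any layer, or a fresh singleton) with the
#' largest strictly positive modularity gain (ties to the smallest community
#' label, gains below `1e-12` ignored), then condenses communities into
#' super-nodes and repeats until no coarsening happens. Identical
#' `(net, gamma, seed)` give identical partitions.
#'
#' Zero-weight layers contribute nothing and are skipped with a warning; an
#' error is raised if every layer is empty.
#'
#' @param net An [ml_network].
#' @param gamma Positive resolution parameter; larger values yield smaller
#'   communities.
#' @param seed Integer seed controlling the node visit order.
#' @param n_restarts Number of independent seeded restarts; the partition with
#'   the highest modularity is returned (default 1, a single run).
#' @return An [as_partition()] object with attributes `gamma`, `seed`, `Q`
#'   (the attained multilayer modularity) and `Q_trace` (modularity after each
#'   level, non-decreasing).
#' @seealso [louvain_monolayer()], [exhaustive_best_partition()]
#' @export
louvain_multilayer <- function(net, gamma = 1, seed = 1L, n_restarts = 1L) {
  stopifnot(inherits(net, "ml_network"))
  .check_scalar_number(gamma, "gamma", positive = TRUE)
  stopifnot(n_restarts >= 1L)
  comp <- .compile_network(net)
  ws <- vapply(comp$layers, `[[`, numeric(1L), "W")
  if (all(ws <= 0)) stop("empty layer: all layers have zero total weight", call. = FALSE)
  if (any(ws <= 0))
    warning(sprintf("skipping zero-weight layer(s): %s",
                    paste(names(net$layers)[ws <= 0], collapse = ", ")),
            call. = FALSE)
  active <- comp$layers[ws > 0]
  n <- length(comp$nodes)
  runs <- .with_seed(seed, {
    lapply(seq_len(n_restarts), function(r) {
      res <- .louvain_once(active, n, gamma)
      res$Q <- .modularity_compiled(active, res$memb, gamma)
      res
    })
  })
  best <- runs[[which.max(vapply(runs, `[[`, numeric(1L), "Q"))]]
  p <- as_partition(stats::setNames(best$memb, comp$nodes))
  attr(p, "gamma") <- gamma
  attr(p, "seed") <- as.integer(seed)
  attr(p, "Q") <- best$Q
  attr(p, "Q_trace") <- best$qtrace
  p
}

#' Monolayer community detection (Louvain)
#'
#' Single-layer special case of [louvain_multilayer()]; identical contract.
#'
#' @param layer An [ml_layer] with positive total weight.
#' @inheritParams louvain_multilayer
#' @return An `ml_partition`; see [louvain_multilayer()].
#' @export
louvain_monolayer <- function(layer, gamma = 1, seed = 1L, n_restarts = 1L) {
  stopifnot(inherits(layer, "ml_layer"))
  louvain_multilayer(ml_network(list(layer)), gamma = gamma, seed = seed,
                     n_restarts = n_restarts)
}

# Apply f to every restricted growth string (canonical set partition) of n
# items, in lexicographic order.
.rgs_apply <- function(n, f) {
  a <- rep(1L, n)
  repeat {
    f(a)
    if (n == 1L) break
    i <- n
    while (i > 1L) {
      if (a[i] <= max(a[1:(i - 1L)])) break
      i <- i - 1L
    }
    if (i == 1L) break
    a[i] <- a[i] + 1L
    if (i < n) a[(i + 1L):n] <- 1L
  }
  invisible(NULL)
}

#' Exhaustive modularity optimum on a small network
#'
#' Enumerates every set partition of the node universe (Bell-number many) and
#' returns one maximizing the multilayer modularity. Used as an independent
#' optimization oracle against which the Louvain heuristic is checked. The
#' tie-break is deterministic: partitions are enumerated as restricted growth
#' strings in lexicographic order and the first maximum is kept, i.e. the
#' lexicographically smallest canonical labeling.
#'
#' @param net An [ml_network] whose universe has at most `max_nodes` nodes.
#' @param gamma Positive resolution parameter.
#' @param max_nodes Safety bound on the universe size (default 10; Bell(10) =
#'   115975 partitions).
#' @return A list with elements `partition` (an `ml_partition`) and `Q` (the
#'   optimal modularity).
#' @export
exhaustive_best_partition <- function(net, gamma = 1, max_nodes = 10L) {
  stopifnot(inherits(net, "ml_network"))
  .check_scalar_number(gamma, "gamma", positive = TRUE)
  n <- length(net$nodes)
  if (n > max_nodes)
    stop(sprintf("node universe has %d nodes, exceeding the max_nodes bound of %d",
                 n, max_nodes), call. = FALSE)
  comp <- .compile_network(net)
  ws <- vapply(comp$layers, `[[`, numeric(1L), "W")
  if (all(ws <= 0)) stop("empty layer: all layers have zero total weight", call. = FALSE)
  active <- comp$layers[ws > 0]
  env <- new.env(parent = emptyenv())
  env$best_q <- -Inf
  env$best <- NULL
  .rgs_apply(n, function(a) {
    q <- .modularity_compiled(active, a, gamma)
    if (q > env$best_q) {
      env$best_q <- q
      env$best <- a
    }
  })
  p <- as_partition(stats::setNames(env$best, comp$nodes))
  attr(p, "gamma") <- gamma
  attr(p, "Q") <- env$best_q
  list(partition = p, Q = env$best_q)
}

#' Condense a network by a partition
#'
#' Louvain phase-2 style aggregation exposed as a public operation: each
#' community becomes a super-node named `C<label>`; weights between two
#' communities are summed into a single edge and intra-community weight
#' becomes a self-loop of the total weight, so each layer's total weight is
#' conserved and the modularity of the induced partition on the condensed
#' network equals that of the original partition on the original network.
#'
#' @param net An [ml_network].
#' @param partition A partition covering the node universe.
#' @return An [ml_network] over super-nodes, with attribute `mapping`
#'   (named character vector: original node -> super-node name).
#' @export
aggregate_communities <- function(net, partition) {
  stopifnot(inherits(net, "ml_network"))
  p <- as_partition(partition)
  if (anyNA(p[net$nodes]))
    stop("partition does not cover the node universe", call. = FALSE)
  super <- paste0("C", unclass(p))
  names(super) <- names(p)
  layers <- lapply(net$layers, function(l) {
    pres <- sort(unique(super[l$nodes]))
    if (nrow(l$edges) == 0L)
      return(ml_layer(data.frame(from = character(), to = character(),
                                 stringsAsFactors = FALSE),
                      nodes = pres, name = l$name, loops = TRUE))
    ci <- super[l$edges$from]
    cj <- super[l$edges$to]
    lo <- pmin(ci, cj)
    hi <- pmax(ci, cj)
    key <- paste(lo, hi, sep = "\r")
    w <- rowsum(l$edges$weight, key, reorder = FALSE)
    keep <- !duplicated(key)
    ml_layer(data.frame(from = lo[keep], to = hi[keep], weight = as.numeric(w),
                        stringsAsFactors = FALSE),
             nodes = pres, name = l$name, loops = TRUE)
  })
  out <- ml_network(layers)
  attr(out, "mapping") <- super
  out
}
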