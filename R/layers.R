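# Layers and multilayer networks
#
# A layer is one undirected weighted gene graph (protein interactions, shared
# pathways, shared metabolites, ...). A multilayer network stacks layers over
# the union of their node sets; a node absent from a layer is isolated there.

#' Construct a network layer
#'
#' Builds one undirected, weighted layer of a multilayer gene network from an
#' edge table. Endpoint order is irrelevant: `(a, b)` and `(b, a)` denote the
#' same edge and repeated edges are merged by summing their weights (with a
#' warning). Self-loops are rejected in user-supplied layers; they arise only
#' internally when a network is condensed by [aggregate_communities()].
#'
#' @param edges A data frame (or 2/3-column matrix) whose first two columns are
#'   gene identifiers and whose optional third column holds positive edge
#'   weights (default 1).
#' @param nodes Optional character vector of additional node identifiers, so
#'   that isolated nodes can be represented.
#' @param name Layer name.
#' @param loops Allow self-loops (internal use for condensed layers).
#' @return An object of class `ml_layer` with elements `name`, `nodes`
#'   (sorted character vector) and `edges` (canonical edge data frame).
#' @examples
#' ml_layer(data.frame(from = c("a", "b"), to = c("b", "c")), name = "ppi")
#' @export
ml_layer <- function(edges, nodes = NULL, name = "layer", loops = FALSE) {
  if (is.matrix(edges)) edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!is.data.frame(edges) || !(ncol(edges) %in% 2:3))
    stop("`edges` must be a data frame with 2 or 3 columns", call. = FALSE)
  from <- .check_gene_ids(edges[[1L]], "edges$from")
  to   <- .check_gene_ids(edges[[2L]], "edges$to")
  weight <- if (ncol(edges) >= 3L) as.numeric(edges[[3L]]) else rep(1, length(from))
  if (any(!is.finite(weight) | weight <= 0))
    stop("edge weights must be positive and finite", call. = FALSE)
  if (!loops && any(from == to)) {
    bad <- which(from == to)[1L]
    stop(sprintf("self-loop %s-%s not allowed in a user layer (edge %d)",
                 from[bad], to[bad], bad), call. = FALSE)
  }
  lo <- pmin(from, to); hi <- pmax(from, to)
  key <- paste(lo, hi, sep = "\r")
  if (anyDuplicated(key)) {
    warning(sprintf("layer '%s': %d duplicated undirected edges merged by summing weights",
                    name, sum(duplicated(key))), call. = FALSE)
    w <- rowsum(weight, key, reorder = FALSE)
    keep <- !duplicated(key)
    lo <- lo[keep]; hi <- hi[keep]; weight <- as.numeric(w)
  }
  ord <- order(lo, hi)
  nodes <- sort(unique(c(lo, hi, if (!is.null(nodes)) .check_gene_ids(nodes, "nodes"))))
  structure(list(name = as.character(name)[1L], nodes = nodes,
                 edges = data.frame(from = lo[ord], to = hi[ord], weight = weight[ord],
                                    stringsAsFactors = FALSE)),
            class = "ml_layer")
}

#' @export
print.ml_layer <- function(x, ...) {
  cat(sprintf("<ml_layer '%s'>  %d nodes, %d edges, total weight %.6g\n",
              x$name, length(x$nodes), nrow(x$edges), layer_weight(x)))
  invisible(x)
}

#' Total edge weight of a layer
#' @param layer An `ml_layer`.
#' @return Sum of edge weights (0 for an edgeless layer).
#' @export
layer_weight <- function(layer) {
  stopifnot(inherits(layer, "ml_layer"))
  sum(layer$edges$weight)
}

#' Construct a multilayer network
#'
#' Stacks layers over a shared node universe (the union of the layers' node
#' sets). All layers are clustered with a single common partition; a node
#' missing from a layer is treated there as isolated (degree 0). There are no
#' inter-layer coupling edges in this model.
#'
#' @param layers A list of [ml_layer] objects (length >= 1) with unique names.
#' @return An object of class `ml_network` with elements `layers` and `nodes`
#'   (the sorted node universe).
#' @export
ml_network <- function(layers) {
  if (inherits(layers, "ml_layer")) layers <- list(layers)
  if (!is.list(layers) || length(layers) < 1L ||
      !all(vapply(layers, inherits, logical(1L), "ml_layer")))
    stop("`layers` must be a non-empty list of ml_layer objects", call. = FALSE)
  nms <- vapply(layers, function(l) l$name, character(1L))
  if (anyDuplicated(nms))
    stop("layer names must be unique", call. = FALSE)
  names(layers) <- nms
  structure(list(layers = layers,
                 nodes = sort(unique(unlist(lapply(layers, `[[`, "nodes"), use.names = FALSE)))),
            class = "ml_network")
}

#' @export
print.ml_network <- function(x, ...) {
  cat(sprintf("<ml_network>  %d layers, %d nodes in the universe\n",
              length(x$layers), length(x$nodes)))
  for (l in x$layers)
    cat(sprintf("  %-18s %6d nodes %8d edges  W = %.6g\n",
                l$name, length(l$nodes), nrow(l$edges), layer_weight(l)))
  invisible(x)
}

#' Project a gene-set collection onto a co-membership layer
#'
#' Bipartite projection used to build the shared-pathway and shared-metabolite
#' layers: two distinct genes are connected iff they co-occur in at least one
#' group (pathway, reaction, ...). The result is unweighted (weight 1) and
#' deduplicated, so co-occurrence in several groups still yields one edge.
#'
#' @param groups A named list of character vectors, or an `ml_catalog` as
#'   returned by [read_gmt()].
#' @param name Name for the resulting layer.
#' @return An [ml_layer] whose nodes are all genes appearing in any group.
#' @examples
#' project_shared_membership(list(P1 = c("a", "b"), P2 = c("b", "c")))
#' @export
project_shared_membership <- function(groups, name = "projection") {
  if (inherits(groups, "ml_catalog")) groups <- groups$sets
  if (!is.list(groups) || length(groups) == 0L)
    stop("no groups", call. = FALSE)
  pairs <- lapply(groups, function(g) {
    g <- sort(unique(.check_gene_ids(g)))
    if (length(g) < 2L) return(NULL)
    t(utils::combn(g, 2L))
  })
  pairs <- do.call(rbind, pairs)
  all_nodes <- sort(unique(unlist(groups, use.names = FALSE)))
  if (is.null(pairs))
    return(ml_layer(data.frame(from = character(), to = character(),
                               stringsAsFactors = FALSE),
                    nodes = all_nodes, name = name))
  key <- paste(pairs[, 1L], pairs[, 2L], sep = "\r")
  keep <- !duplicated(key)
  ml_layer(data.frame(from = pairs[keep, 1L], to = pairs[keep, 2L],
                      stringsAsFactors = FALSE),
           nodes = all_nodes, name = name)
}

# Weighted degree per node of a layer; self-loops count twice.
.layer_degrees <- function(layer) {
  d <- numeric(length(layer$nodes))
  names(d) <- layer$nodes
  e <- layer$edges
  if (nrow(e)) {
    add <- rowsum(c(e$weight, e$weight), c(e$from, e$to))
    d[rownames(add)] <- add[, 1L]
  }
  d
}

#' Modularity of a partition on one layer
#'
#' Newman-Girvan modularity with a resolution parameter multiplying the null
#' term: `Q = sum_c [ w_c / W - gamma * (d_c / (2 W))^2 ]`, where `w_c` is the
#' total intra-community edge weight (self-loops counted once, with their full
#' weight), `d_c` the total weighted degree of the community's nodes
#' (self-loops contribute twice their weight) and `W` the layer's total edge
#' weight. Larger `gamma` penalizes large communities, so the optimum shifts
#' toward smaller communities as `gamma` grows.
#'
#' @param layer An [ml_layer] with total weight > 0.
#' @param partition A named community assignment covering the layer's nodes
#'   (see [as_partition()]).
#' @param gamma Positive resolution parameter.
#' @return The modularity value (a real number, at most 1 for `gamma` = 1).
#' @export
layer_modularity <- function(layer, partition, gamma = 1) {
  stopifnot(inherits(layer, "ml_layer"))
  .check_scalar_number(gamma, "gamma", positive = TRUE)
  W <- layer_weight(layer)
  if (W <= 0) stop("empty layer: total edge weight is 0", call. = FALSE)
  p <- as_partition(partition)
  lab <- p[layer$nodes]
  if (anyNA(lab))
    stop("partition does not cover all layer nodes", call. = FALSE)
  e <- layer$edges
  intra <- sum(e$weight[p[e$from] == p[e$to]])
  d <- .layer_degrees(layer)
  dc <- rowsum(d, lab)
  intra / W - gamma * sum((dc / (2 * W))^2)
}

#' Multilayer modularity of a common partition
#'
#' The multilayer quality function is additive over layers: the sum of
#' [layer_modularity()] values of the single shared partition, one term per
#' layer. Layers with zero total weight are skipped with a warning and
#' contribute 0; an error is raised if every layer is empty.
#'
#' @param net An [ml_network].
#' @param partition A named community assignment covering the node universe.
#' @param gamma Positive resolution parameter.
#' @return The summed modularity `Q(P; gamma)`.
#' @export
multilayer_modularity <- function(net, partition, gamma = 1) {
  stopifnot(inherits(net, "ml_network"))
  .check_scalar_number(gamma, "gamma", positive = TRUE)
  p <- as_partition(partition)
  if (anyNA(p[net$nodes]))
    stop("partition does not cover the node universe", call. = FALSE)
  ws <- vapply(net$layers, layer_weight, numeric(1L))
  if (all(ws <= 0)) stop("empty layer: all layers have zero total weight", call. = FALSE)
  if (any(ws <= 0))
    warning(sprintf("skipping zero-weight layer(s): %s",
                    paste(names(net$layers)[ws <= 0], collapse = ", ")),
            call. = FALSE)
  sum(vapply(net$layers[ws > 0], layer_modularity, numeric(1L),
             partition = p, gamma = gamma))
}

#' Edge and node overlap between two layers
#'
#' @param a,b Layers with at least one edge each.
#' @return A list of class `ml_overlap`: shared undirected edge count, edge
#'   Jaccard index `|Ea n Eb| / |Ea u Eb|`, and node Jaccard index. Symmetric
#'   in its arguments.
#' @export
layer_edge_overlap <- function(a, b) {
  stopifnot(inherits(a, "ml_layer"), inherits(b, "ml_layer"))
  if (nrow(a$edges) == 0L || nrow(b$edges) == 0L)
    stop("both layers must contain at least one edge", call. = FALSE)
  ka <- paste(a$edges$from, a$edges$to, sep = "\r")
  kb <- paste(b$edges$from, b$edges$to, sep = "\r")
  shared <- length(intersect(ka, kb))
  structure(list(
    layers = c(a$name, b$name),
    shared_edges = shared,
    edge_jaccard = shared / length(union(ka, kb)),
    node_jaccard = length(intersect(a$nodes, b$nodes)) /
      length(union(a$nodes, b$nodes))
  ), class = "ml_overlap")
}

#' @export
print.ml_overlap <- function(x, ...) {
  cat(sprintf("<ml_overlap> %s vs %s: %d shared edges, edge Jaccard %.4f, node Jaccard %.4f\n",
              x$layers[1L], x$layers[2L], x$shared_edges, x$edge_jaccard, x$node_jaccard))
  invisible(x)
}

#' Similarity of two communities over a set of genes of interest
#'
#' The community similarity used to compare communities found in different
#' layers: the number of shared genes of interest between the two communities
#' divided by the sum of the community sizes. The value lies in `[0, 0.5]`,
#' reaching 0.5 only for identical communities consisting entirely of genes of
#' interest. A standard Jaccard index (`|a n b| / |a u b|`, ignoring the
#' interest set) is available via `method = "jaccard"`.
#'
#' @param comm_a,comm_b Gene sets (character vectors); not both empty.
#' @param genes_of_interest Gene set restricting the shared count.
#' @param method `"interest"` (default; shared-interest over size sum) or
#'   `"jaccard"`.
#' @return A number in `[0, 0.5]` (or `[0, 1]` for `"jaccard"`).
#' @export
community_similarity <- function(comm_a, comm_b, genes_of_interest = NULL,
                                 method = c("interest", "jaccard")) {
  method <- match.arg(method)
  comm_a <- unique(as.character(comm_a))
  comm_b <- unique(as.character(comm_b))
  if (length(comm_a) == 0L && length(comm_b) == 0L)
    stop("both communities are empty", call. = FALSE)
  if (method == "jaccard")
    return(length(intersect(comm_a, comm_b)) / length(union(comm_a, comm_b)))
  if (is.null(genes_of_interest))
    stop("`genes_of_interest` is required for method = \"interest\"", call. = FALSE)
  shared <- intersect(intersect(comm_a, comm_b), unique(as.character(genes_of_interest)))
  length(shared) / (length(comm_a) + length(comm_b))
}
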