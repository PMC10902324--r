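# Partitions: a single community assignment shared by all layers.

#' Coerce to a canonical partition
#'
#' A partition is a named integer vector assigning every node exactly one
#' community label. Canonical form: nodes sorted by identifier, labels
#' relabeled to contiguous `0..(k-1)` in order of first appearance along the
#' sorted nodes. Community membership is invariant under relabeling, and all
#' package statistics depend only on membership.
#'
#' @param x A named vector (integer, numeric or character labels) or an
#'   existing `ml_partition`.
#' @return An object of class `ml_partition`.
#' @export
as_partition <- function(x) {
  if (inherits(x, "ml_partition")) return(x)
  if (is.null(names(x)) || any(!nzchar(names(x))))
    stop("a partition must be a fully named vector (names are node ids)",
         call. = FALSE)
  if (anyNA(x)) stop("partition labels must not be NA", call. = FALSE)
  if (anyDuplicated(names(x)))
    stop("duplicate node ids in partition", call. = FALSE)
  x <- x[order(names(x))]
  lab <- match(x, unique(x)) - 1L
  names(lab) <- names(x)
  structure(lab, class = "ml_partition")
}

#' @export
print.ml_partition <- function(x, ...) {
  k <- length(unique(unclass(x)))
  cat(sprintf("<ml_partition>  %d nodes in %d communities\n", length(x), k))
  if (!is.null(attr(x, "gamma")))
    cat(sprintf("  gamma = %g, seed = %s, Q = %.6f\n", attr(x, "gamma"),
                format(attr(x, "seed") %||% NA), attr(x, "Q") %||% NA_real_))
  sz <- sort(tabulate(unclass(x) + 1L), decreasing = TRUE)
  cat("  community sizes:", paste(utils::head(sz, 12L), collapse = " "),
      if (k > 12L) "..." else "", "\n")
  invisible(x)
}

#' @export
summary.ml_partition <- function(object, ...) {
  sz <- tabulate(unclass(object) + 1L)
  out <- list(n_nodes = length(object), n_communities = length(sz),
              sizes = sort(sz, decreasing = TRUE),
              gamma = attr(object, "gamma"), Q = attr(object, "Q"))
  class(out) <- "summary.ml_partition"
  out
}

#' @export
print.summary.ml_partition <- function(x, ...) {
  cat(sprintf("Partition of %d nodes into %d communities\n", x$n_nodes, x$n_communities))
  print(utils::head(x$sizes, 20L))
  invisible(x)
}

#' List the communities of a partition
#' @param partition An `ml_partition` (or coercible).
#' @return A list of character vectors of node ids, indexed by label + 1.
#' @export
partition_communities <- function(partition) {
  p <- as_partition(partition)
  split(names(p), unclass(p))
}

#' Community containing a given node
#' @param partition An `ml_partition` (or coercible).
#' @param node A single node identifier.
#' @return Character vector of all nodes sharing the node's community.
#' @export
community_of <- function(partition, node) {
  p <- as_partition(partition)
  if (!node %in% names(p)) stop(sprintf("node '%s' not in partition", node), call. = FALSE)
  names(p)[unclass(p) == unclass(p)[[node]]]
}
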