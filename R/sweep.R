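# Resolution sweep and persistence modules.
#
# Communities are detected at a grid of resolution values; genes of interest
# that share a community at >= n grid values form the thresholded
# co-membership graph, whose connected components (size >= 2) are the
# persistence modules. At n = |grid| a module's genes co-cluster over the
# entire resolution range.

#' Resolution grid for a sweep
#'
#' Default: 8 evenly spaced values `(0.5, 1.0, ..., 4.0)` covering the
#' interval `(0, 4]` where the number and composition of multilayer
#' communities change most; the even spacing within that interval is this
#' package's choice and is recorded in sweep manifests.
#'
#' @param n Number of grid values (default 8).
#' @param gamma_max Upper end of the resolution interval (default 4).
#' @param values Explicit strictly increasing positive values (overrides
#'   `n`/`gamma_max`).
#' @return An object of class `ml_grid` (numeric vector of resolutions).
#' @export
resolution_grid <- function(n = 8L, gamma_max = 4, values = NULL) {
  if (is.null(values)) {
    .check_scalar_number(gamma_max, "gamma_max", positive = TRUE)
    stopifnot(n >= 1L)
    values <- gamma_max * seq_len(n) / n
  }
  values <- as.numeric(values)
  if (any(values <= 0) || any(diff(values) <= 0))
    stop("grid values must be positive and strictly increasing", call. = FALSE)
  structure(values, class = "ml_grid")
}

#' @export
print.ml_grid <- function(x, ...) {
  cat("<ml_grid> ", paste(format(unclass(x)), collapse = " "), "\n")
  invisible(x)
}

#' Community detection across a resolution grid
#'
#' Runs [louvain_multilayer()] once per grid value. The seed for grid index
#' `i` is `seed + i - 1`, so a sweep is reproducible and any single
#' resolution can be re-run in isolation with its derived seed.
#'
#' @param net An [ml_network].
#' @param grid An [resolution_grid()] (default: 8 values on `(0, 4]`).
#' @param seed Base integer seed.
#' @param n_restarts Restarts per grid value (passed to the optimizer).
#' @return An object of class `ml_sweep`: list with `grid`, `partitions`
#'   (one `ml_partition` per value), `seeds`, `Q`, `n_communities` and
#'   `nodes` (the node universe).
#' @export
sweep_resolutions <- function(net, grid = resolution_grid(), seed = 1L,
                              n_restarts = 1L) {
  stopifnot(inherits(net, "ml_network"))
  grid <- resolution_grid(values = unclass(grid))
  seeds <- as.integer(seed) + seq_along(grid) - 1L
  partitions <- vector("list", length(grid))
  for (i in seq_along(grid)) {
    partitions[[i]] <- tryCatch(
      louvain_multilayer(net, gamma = grid[[i]], seed = seeds[[i]],
                         n_restarts = n_restarts),
      error = function(e) stop(sprintf("community detection failed at gamma = %g: %s",
                                       grid[[i]], conditionMessage(e)), call. = FALSE))
  }
  structure(list(
    grid = grid,
    partitions = partitions,
    seeds = seeds,
    Q = vapply(partitions, attr, numeric(1L), "Q"),
    n_communities = vapply(partitions, function(p) length(unique(unclass(p))), integer(1L)),
    nodes = net$nodes
  ), class = "ml_sweep")
}

#' @export
print.ml_sweep <- function(x, ...) {
  cat(sprintf("<ml_sweep>  %d resolutions over %d nodes\n",
              length(x$grid), length(x$nodes)))
  print(data.frame(gamma = unclass(x$grid), seed = x$seeds,
                   Q = round(x$Q, 4), communities = x$n_communities))
  invisible(x)
}

#' @export
summary.ml_sweep <- function(object, ...) {
  data.frame(gamma = unclass(object$grid), seed = object$seeds, Q = object$Q,
             communities = object$n_communities)
}

#' @export
plot.ml_sweep <- function(x, ...) {
  graphics::plot(unclass(x$grid), x$n_communities, type = "b", pch = 16,
                 xlab = expression(gamma), ylab = "communities",
                 main = "Community count across the resolution sweep", ...)
  invisible(x)
}

# Integer label matrix (nodes x grid values) of a sweep, for fast tallying.
.sweep_label_matrix <- function(sweep) {
  m <- vapply(sweep$partitions, function(p) unclass(p)[sweep$nodes], integer(length(sweep$nodes)))
  rownames(m) <- sweep$nodes
  m
}

#' Co-membership counts of genes of interest across a sweep
#'
#' For each unordered pair of retained genes of interest, counts at how many
#' grid values the two genes share a community. Genes absent from the network
#' are dropped with a warning (they cannot be placed in any community).
#'
#' @param sweep An `ml_sweep`.
#' @param genes Character vector of genes of interest.
#' @return An object of class `ml_comembership`: list with `genes` (retained,
#'   sorted), `counts` (symmetric integer matrix, diagonal = number of grid
#'   values), `n_grid` and `dropped`.
#' @export
co_membership <- function(sweep, genes) {
  stopifnot(inherits(sweep, "ml_sweep"))
  genes <- sort(unique(.check_gene_ids(genes)))
  retained <- genes[genes %in% sweep$nodes]
  dropped <- setdiff(genes, retained)
  if (length(retained) == 0L)
    stop("none of the genes of interest are present in the network", call. = FALSE)
  if (length(dropped))
    warning(sprintf("%d of %d genes of interest are not in the network and were dropped",
                    length(dropped), length(genes)), call. = FALSE)
  lm <- .sweep_label_matrix(sweep)[retained, , drop = FALSE]
  k <- length(retained)
  counts <- matrix(0L, k, k, dimnames = list(retained, retained))
  for (t in seq_len(ncol(lm))) {
    lab <- lm[, t]
    counts <- counts + outer(lab, lab, "==")
  }
  structure(list(genes = retained, counts = counts,
                 n_grid = length(sweep$grid), dropped = dropped),
            class = "ml_comembership")
}

#' @export
print.ml_comembership <- function(x, ...) {
  off <- x$counts[upper.tri(x$counts)]
  cat(sprintf("<ml_comembership>  %d genes over %d resolutions (%d dropped)\n",
              length(x$genes), x$n_grid, length(x$dropped)))
  cat(sprintf("  pairs fully persistent (count = %d): %d of %d\n",
              x$n_grid, sum(off == x$n_grid), length(off)))
  invisible(x)
}

# Connected components of a logical adjacency matrix, by frontier expansion.
.adj_components <- function(A) {
  k <- nrow(A)
  comp <- integer(k)
  cur <- 0L
  for (s in seq_len(k)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    comp[s] <- cur
    frontier <- s
    while (length(frontier)) {
      nb <- which(colSums(A[frontier, , drop = FALSE]) > 0 & comp == 0L)
      comp[nb] <- cur
      frontier <- nb
    }
  }
  comp
}

#' Extract persistence modules at a co-membership threshold
#'
#' Builds the graph whose edges are gene pairs co-clustered at >= `n` grid
#' values and returns its connected components of size >= 2 (a module is a
#' *group*; singletons are not modules), sorted by decreasing size and then by
#' lexicographically smallest member. Because thresholded edge sets are nested
#' in `n`, modules at `n + 1` always refine modules at `n`.
#'
#' @param comembership An `ml_comembership` from [co_membership()].
#' @param n Persistence threshold in `1..n_grid`; default `n_grid` (full
#'   persistence over the entire resolution range).
#' @param anchors Optional known causal genes used to flag anchored modules.
#' @return A list of `ml_module` objects (class `ml_modules`), each with
#'   `genes`, `threshold`, `anchored` and `anchors`.
#' @export
extract_modules <- function(comembership, n = comembership$n_grid, anchors = NULL) {
  stopifnot(inherits(comembership, "ml_comembership"))
  if (!is.numeric(n) || length(n) != 1L || n < 1L || n > comembership$n_grid)
    stop(sprintf("threshold n must be in 1..%d", comembership$n_grid), call. = FALSE)
  A <- comembership$counts >= n
  diag(A) <- FALSE
  comp <- .adj_components(A)
  groups <- split(comembership$genes, comp)
  groups <- groups[lengths(groups) >= 2L]
  mods <- lapply(groups, function(g) {
    g <- sort(g)
    structure(list(genes = g, threshold = as.integer(n),
                   anchored = any(g %in% anchors),
                   anchors = sort(intersect(g, anchors))),
              class = "ml_module")
  })
  ord <- order(-lengths(lapply(mods, `[[`, "genes")),
               vapply(mods, function(m) m$genes[[1L]], character(1L)))
  structure(unname(mods[ord]), class = "ml_modules")
}

#' @export
print.ml_module <- function(x, ...) {
  cat(sprintf("<ml_module>  %d genes at threshold n = %d%s\n",
              length(x$genes), x$threshold,
              if (x$anchored) sprintf(" (anchored: %s)", paste(x$anchors, collapse = ", "))
              else ""))
  cat(" ", paste(x$genes, collapse = " "), "\n")
  invisible(x)
}

#' @export
print.ml_modules <- function(x, ...) {
  cat(sprintf("<ml_modules>  %d modules\n", length(x)))
  for (m in x)
    cat(sprintf("  [%3d genes]%s %s\n", length(m$genes),
                if (m$anchored) "*" else " ",
                paste(utils::head(m$genes, 8L), collapse = " ")))
  invisible(x)
}

#' Largest module containing any anchor gene
#'
#' @param modules An `ml_modules` list.
#' @param anchor_genes Character vector (e.g. known causal genes).
#' @return The largest module intersecting `anchor_genes` (ties broken by
#'   lexicographically smallest member), or `NULL` if no module is anchored.
#' @export
largest_module_with <- function(modules, anchor_genes) {
  hits <- Filter(function(m) any(m$genes %in% anchor_genes), modules)
  if (length(hits) == 0L) return(NULL)
  sizes <- vapply(hits, function(m) length(m$genes), integer(1L))
  firsts <- vapply(hits, function(m) m$genes[[1L]], character(1L))
  hits[[order(-sizes, firsts)[1L]]]
}

#' Persistent core of a fully persistent module
#'
#' For a module whose genes co-cluster at every grid value, returns the
#' intersection over the grid of the full community (all network nodes, not
#' only genes of interest) containing the module. This is the set of nodes
#' that accompany the module over the entire resolution range; it is always a
#' superset of the module's genes.
#'
#' @param sweep The `ml_sweep` the module was derived from.
#' @param module An `ml_module` with `threshold == length(grid)`.
#' @return Sorted character vector of core node ids.
#' @export
persistent_core <- function(sweep, module) {
  stopifnot(inherits(sweep, "ml_sweep"), inherits(module, "ml_module"))
  core <- NULL
  for (p in sweep$partitions) {
    lab <- unclass(p)[module$genes]
    if (length(unique(lab)) != 1L)
      stop(paste("module is not fully persistent: its genes are split at some",
                 "resolution; lower the threshold or export per-gamma communities"),
           call. = FALSE)
    comm <- names(p)[unclass(p) == lab[[1L]]]
    core <- if (is.null(core)) comm else intersect(core, comm)
  }
  sort(core)
}
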