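# Gene-set catalogs (disease -> associated genes).

#' Construct a gene-set catalog
#'
#' @param sets Named list of character vectors (set name -> genes). Names must
#'   be unique and sets nonempty; duplicate genes within a set are removed.
#' @param descriptions Optional character vector of per-set descriptions.
#' @return An object of class `ml_catalog`.
#' @export
ml_catalog <- function(sets, descriptions = NULL) {
  if (!is.list(sets) || length(sets) == 0L)
    stop("`sets` must be a non-empty named list", call. = FALSE)
  nms <- names(sets)
  if (is.null(nms) || any(!nzchar(nms)) || anyDuplicated(nms))
    stop("set names must be present and unique", call. = FALSE)
  if (any(lengths(sets) == 0L))
    stop("sets must be nonempty", call. = FALSE)
  sets <- lapply(sets, function(g) sort(unique(.check_gene_ids(g))))
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  stopifnot(length(descriptions) == length(sets))
  structure(list(sets = sets, descriptions = stats::setNames(as.character(descriptions), nms)),
            class = "ml_catalog")
}

#' @export
print.ml_catalog <- function(x, ...) {
  sz <- lengths(x$sets)
  cat(sprintf("<ml_catalog>  %d sets, sizes %d..%d (mean %.2f genes/set)\n",
              length(x$sets), min(sz), max(sz), mean(sz)))
  invisible(x)
}

#' Filter a catalog for co-membership validation
#'
#' Applies, in order: (1) drop sets with a single gene; (2) drop sets whose
#' size exceeds `Q3 + iqr_mult * IQR` of the remaining size distribution
#' (linear-interpolation quantiles), guarding against very large umbrella
#' sets that would dominate the statistic; (3) intersect every set with the
#' network's nodes, since genes outside the network cannot be assigned to a
#' community; (4) drop sets reduced below 2 genes. Counts removed at each step
#' are reported.
#'
#' @param catalog An [ml_catalog].
#' @param network_nodes Character vector: the multilayer network's node
#'   universe.
#' @param iqr_mult IQR multiplier for the size cutoff (default 1.5).
#' @return A list with `catalog` (the filtered [ml_catalog]) and `report`
#'   (step-by-step counts, the size cutoff, and the mean retained set size).
#' @export
preprocess_catalog <- function(catalog, network_nodes, iqr_mult = 1.5) {
  stopifnot(inherits(catalog, "ml_catalog"))
  network_nodes <- unique(as.character(network_nodes))
  sets <- catalog$sets
  n_input <- length(sets)
  sz <- lengths(sets)
  sets1 <- sets[sz >= 2L]
  n_singleton <- n_input - length(sets1)
  if (length(sets1) == 0L) stop("no sets left after removing singletons", call. = FALSE)
  sz1 <- lengths(sets1)
  qs <- stats::quantile(sz1, c(0.25, 0.75), type = 7, names = FALSE)
  cutoff <- qs[2L] + iqr_mult * (qs[2L] - qs[1L])
  sets2 <- sets1[sz1 <= cutoff]
  n_large <- length(sets1) - length(sets2)
  inter <- lapply(sets2, intersect, y = network_nodes)
  off_network <- setdiff(unique(unlist(sets2, use.names = FALSE)), network_nodes)
  sets3 <- inter[lengths(inter) >= 2L]
  n_reduced <- length(sets2) - length(sets3)
  if (length(sets3) == 0L)
    stop("no sets left after filtering against the network", call. = FALSE)
  out <- ml_catalog(sets3, catalog$descriptions[names(sets3)])
  list(catalog = out,
       report = list(n_input = n_input,
                     n_dropped_singleton = n_singleton,
                     q1 = qs[1L], q3 = qs[2L], size_cutoff = cutoff,
                     n_dropped_large = n_large,
                     n_genes_off_network = length(off_network),
                     n_dropped_reduced = n_reduced,
                     n_retained = length(sets3),
                     mean_set_size = mean(lengths(sets3))))
}
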