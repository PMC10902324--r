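# Seeded generators with the statistical structure the analysis assumes:
# a planted-partition (stochastic block model) multilayer network with one
# shared ground-truth partition and per-layer noise/coverage, a severity
# cohort whose severe-private genes may be enriched in one planted community,
# and a gene-set catalog with a tunable fraction of community-coherent sets.

#' Simulate a planted-partition multilayer network
#'
#' Each layer is an independent-edge stochastic block model over the same
#' ground-truth partition: intra-community pairs are connected with
#' probability `p_in`, inter-community pairs with `p_out < p_in`. Per-layer
#' node coverage (Bernoulli inclusion, forcing at least 2 nodes per community
#' per layer) emulates layers with very different node sets; nodes outside a
#' layer are isolated there. Defaults: three communities of 30 nodes across
#' three layers at full coverage.
#'
#' @param sizes Integer vector of community sizes (default `c(30, 30, 30)`).
#' @param n_layers Number of layers (default 3).
#' @param p_in,p_out Intra-/inter-community edge probabilities (`p_in` 0.3 and
#'   `p_out` 0.01 by default; `p_in > p_out` required for identifiability).
#' @param coverage Per-layer node inclusion probability in `(0, 1]`; scalar or
#'   length `n_layers` (default 1).
#' @param seed Integer seed; identical seeds give identical networks.
#' @return A list with `network` (an [ml_network]) and `truth` (class
#'   `ml_truth`: the planted `ml_partition` plus all generator parameters).
#' @export
simulate_multilayer <- function(sizes = c(30L, 30L, 30L), n_layers = 3L,
                                p_in = 0.3, p_out = 0.01,
                                coverage = 1, seed = 1L) {
  stopifnot(length(sizes) >= 1L, all(sizes >= 2L), n_layers >= 1L)
  if (!(p_in > p_out && p_out >= 0 && p_in <= 1))
    stop("unidentifiable planted structure: need p_in > p_out >= 0", call. = FALSE)
  coverage <- rep(coverage, length.out = n_layers)
  if (any(coverage <= 0 | coverage > 1))
    stop("coverage must lie in (0, 1]", call. = FALSE)
  N <- sum(sizes)
  ids <- sprintf("G%04d", seq_len(N))
  block <- rep(seq_along(sizes), sizes)
  pair_i <- rep(seq_len(N - 1L), times = (N - 1L):1L)
  pair_j <- sequence((N - 1L):1L, from = 2:N)
  p_edge <- ifelse(block[pair_i] == block[pair_j], p_in, p_out)
  layers <- .with_seed(seed, {
    lapply(seq_len(n_layers), function(l) {
      present <- stats::runif(N) <= coverage[l]
      for (b in seq_along(sizes)) {      # force >= 2 nodes per community
        members <- which(block == b)
        need <- 2L - sum(present[members])
        if (need > 0L) present[members[!present[members]][seq_len(need)]] <- TRUE
      }
      keep <- present[pair_i] & present[pair_j] &
        stats::runif(length(pair_i)) <= p_edge
      ml_layer(data.frame(from = ids[pair_i[keep]], to = ids[pair_j[keep]],
                          stringsAsFactors = FALSE),
               nodes = ids[present], name = sprintf("L%d", l))
    })
  })
  truth <- structure(list(
    partition = as_partition(stats::setNames(block, ids)),
    params = list(sizes = as.integer(sizes), n_layers = as.integer(n_layers),
                  p_in = p_in, p_out = p_out, coverage = coverage,
                  seed = as.integer(seed))
  ), class = "ml_truth")
  list(network = ml_network(layers), truth = truth)
}

#' @export
print.ml_truth <- function(x, ...) {
  p <- x$params
  cat(sprintf("<ml_truth>  %d communities (%s nodes), %d layers, p_in %g / p_out %g, seed %d\n",
              length(p$sizes), paste(p$sizes, collapse = "+"), p$n_layers,
              p$p_in, p$p_out, p$seed))
  invisible(x)
}

#' Simulate a severity cohort over a planted network
#'
#' Every patient receives `k_background` genes drawn uniformly from the node
#' universe (split between the compound-heterozygous and CNV variant
#' classes). When `signal_community` is set, each severe patient additionally
#' receives `k_signal` compound-het genes from that planted community,
#' excluding the `n_causal` held-out causal genes, so the severe-private union
#' is enriched in the signal community. With `signal_community = NULL` the
#' cohort is a calibration null: severity labels carry no gene signal and the
#' causal genes are a uniform draw. Defaults mirror a 20-patient cohort with 8
#' severe and 12 not-severe (2 intermediate + 10 mild) patients.
#'
#' @param truth An `ml_truth` from [simulate_multilayer()].
#' @param n_severe,n_not Class sizes (defaults 8 and 12).
#' @param signal_community 1-based index of the planted community carrying the
#'   severe signal, or `NULL` for a null cohort.
#' @param k_signal Signal genes per severe patient (default 5).
#' @param k_background Background genes per patient (default 10).
#' @param n_causal Number of held-out causal genes (default 5).
#' @param seed Integer seed.
#' @return A list with `cohort` (an [ml_cohort]) and `causal` (character
#'   vector of causal genes).
#' @export
simulate_cohort <- function(truth, n_severe = 8L, n_not = 12L,
                            signal_community = 1L, k_signal = 5L,
                            k_background = 10L, n_causal = 5L, seed = 1L) {
  stopifnot(inherits(truth, "ml_truth"))
  if (n_severe < 1L || n_not < 1L)
    stop("both class sizes must be >= 1", call. = FALSE)
  universe <- names(truth$partition)
  comms <- partition_communities(truth$partition)
  if (!is.null(signal_community)) {
    if (signal_community < 1L || signal_community > length(comms))
      stop("signal_community out of range", call. = FALSE)
    comm <- comms[[signal_community]]
    if (k_signal + n_causal > length(comm))
      stop("k_signal + n_causal exceeds the signal community size", call. = FALSE)
  }
  np <- n_severe + n_not
  .with_seed(seed, {
    causal <- if (is.null(signal_community)) sort(sample(universe, n_causal))
              else sort(sample(comm, n_causal))
    pool <- if (is.null(signal_community)) NULL else setdiff(comm, causal)
    ch <- vector("list", np)
    cn <- vector("list", np)
    for (i in seq_len(np)) {
      bg <- if (k_background > 0L) sample(universe, k_background) else character(0)
      is_ch <- stats::runif(length(bg)) <= 0.7
      genes_ch <- bg[is_ch]
      genes_cn <- bg[!is_ch]
      if (i <= n_severe && !is.null(signal_community) && k_signal > 0L)
        genes_ch <- c(genes_ch, sample(pool, k_signal))
      ch[[i]] <- genes_ch
      cn[[i]] <- genes_cn
    }
    treatment <- stats::runif(np) <= 13 / 20
    cohort <- ml_cohort(
      id = sprintf("P%02d", seq_len(np)),
      severity = rep(c("severe", "not_severe"), c(n_severe, n_not)),
      compound_het = ch, cnv = cn,
      fine_label = c(rep("severe", n_severe),
                     rep("intermediate", min(2L, n_not)),
                     rep("mild", max(0L, n_not - 2L))),
      treatment = treatment)
    list(cohort = cohort, causal = causal)
  })
}

#' Simulate a gene-set catalog over a planted network
#'
#' Emulates a disease-to-genes catalog: a `coherent_fraction` of the sets draw
#' all their genes from a single random planted community (community-coherent
#' sets, the signal the co-membership validation should detect); the rest draw
#' uniformly from the whole universe (the same mechanism as the balanced
#' randomization null). Set sizes are uniform over `size_range`.
#'
#' @param truth An `ml_truth`.
#' @param n_sets Number of sets (default 40).
#' @param size_range Inclusive `(min, max)` set size; `min >= 2`.
#' @param coherent_fraction Fraction of community-coherent sets in `[0, 1]`.
#' @param seed Integer seed.
#' @return An [ml_catalog] with sets named `D0001`, `D0002`, ...
#' @export
simulate_catalog <- function(truth, n_sets = 40L, size_range = c(2L, 10L),
                             coherent_fraction = 0.5, seed = 1L) {
  stopifnot(inherits(truth, "ml_truth"), n_sets >= 1L)
  if (coherent_fraction < 0 || coherent_fraction > 1)
    stop("coherent_fraction must lie in [0, 1]", call. = FALSE)
  if (size_range[1L] < 2L || size_range[2L] < size_range[1L])
    stop("size_range must satisfy 2 <= min <= max", call. = FALSE)
  universe <- names(truth$partition)
  comms <- partition_communities(truth$partition)
  if (size_range[1L] > max(lengths(comms)))
    stop("size_range infeasible for the planted community sizes", call. = FALSE)
  n_coh <- round(coherent_fraction * n_sets)
  sets <- .with_seed(seed, {
    lapply(seq_len(n_sets), function(s) {
      size <- sample(size_range[1L]:size_range[2L], 1L)
      if (s <= n_coh) {
        elig <- which(lengths(comms) >= size)
        if (length(elig) == 0L)
          stop(sprintf("size_range infeasible for the planted community sizes (set size %d)",
                       size), call. = FALSE)
        comm <- comms[[if (length(elig) == 1L) elig else sample(elig, 1L)]]
        sample(comm, size)
      } else sample(universe, size)
    })
  })
  names(sets) <- sprintf("D%04d", seq_len(n_sets))
  ml_catalog(sets)
}

#' Adjusted Rand index between two partitions
#'
#' Pair-counting agreement corrected for chance: 1 iff the partitions are
#' identical up to relabeling, approximately 0 for independent partitions.
#'
#' @param p1,p2 Partitions (coercible via [as_partition()]) over the same node
#'   set.
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(p1, p2) {
  p1 <- as_partition(p1)
  p2 <- as_partition(p2)
  if (!identical(names(p1), names(p2)))
    stop("partitions are defined on different node sets", call. = FALSE)
  n <- length(p1)
  tab <- table(unclass(p1), unclass(p2))
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  denom <- (si + sj) / 2 - expected
  if (denom == 0) return(1)   # both trivial partitions (and hence identical)
  (sij - expected) / denom
}
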