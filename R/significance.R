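# Randomization-based significance procedures and exact tests.
#
# Two permutation nulls mirror the study design: (i) "balanced"
# randomizations replace each gene set by a size-matched uniform draw from the
# network's node universe, destroying biological association while preserving
# the set-size distribution; (ii) severity-label shuffling permutes patient
# labels (class sizes preserved) and rebuilds the group gene sets, while the
# sweep partitions - which do not depend on labels - are reused unchanged.
# Permutation p-values use the add-one estimator (1 + #{null >= obs}) / (1 + R).

.pairs2 <- function(k) k * (k - 1) / 2

#' Co-membership statistic of a gene set under one partition
#'
#' Number of unordered pairs of the set's genes (restricted to the partition
#' domain) that share a community label. Ranges from 0 (all separated) to
#' `choose(k, 2)` (all together).
#'
#' @param partition An `ml_partition` (or named label vector).
#' @param genes Character vector; at least 2 genes must lie in the partition
#'   domain.
#' @return Integer pair count.
#' @export
set_comembership_stat <- function(partition, genes) {
  p <- as_partition(partition)
  genes <- unique(as.character(genes))
  lab <- unclass(p)[genes[genes %in% names(p)]]
  if (length(lab) < 2L)
    stop("fewer than 2 genes of the set are in the partition domain", call. = FALSE)
  sum(.pairs2(tabulate(lab + 1L)))
}

# Fast path: stat from an integer label vector (0-based labels).
.stat_from_labels <- function(lab) sum(.pairs2(tabulate(lab + 1L)))

#' Catalog co-membership validation against balanced randomizations
#'
#' Tests, at every resolution of a sweep, whether the catalog's gene sets are
#' found in the same multilayer communities more often than size-matched
#' random gene sets. For each grid value the observed per-set co-membership
#' pair counts are compared against a null built from `R` balanced
#' randomizations (each set replaced by a uniform draw of the same size from
#' the node universe, without replacement within a set) with a one-sided
#' rank-sum test (observed greater than the pooled null). An add-one empirical
#' p-value per set-size stratum is reported as well, comparing the stratum's
#' observed mean statistic with the per-randomization stratum means.
#'
#' Sets with fewer than 2 genes in the network are dropped with a warning.
#'
#' @param sweep An `ml_sweep`.
#' @param catalog An [ml_catalog], normally preprocessed with
#'   [preprocess_catalog()] against `sweep$nodes`.
#' @param R Number of balanced randomizations (default 1000).
#' @param seed Integer seed driving all resampling.
#' @return An object of class `ml_catalog_validation`: list with `per_gamma`
#'   (data frame: gamma, rank-sum p, observed and null mean statistics),
#'   `stratum` (data frame: gamma, set size, number of sets, empirical p),
#'   `n_sets`, `R` and `seed`.
#' @export
catalog_validation <- function(sweep, catalog, R = 1000L, seed = 1L) {
  stopifnot(inherits(sweep, "ml_sweep"), inherits(catalog, "ml_catalog"))
  if (R < 1L) stop("R must be >= 1", call. = FALSE)
  lm <- .sweep_label_matrix(sweep)
  nodes <- sweep$nodes
  keep <- vapply(catalog$sets, function(g) sum(g %in% nodes) >= 2L, logical(1L))
  if (!any(keep)) stop("no catalog set has >= 2 genes in the network", call. = FALSE)
  if (any(!keep))
    warning(sprintf("%d catalog sets with < 2 genes in the network were dropped",
                    sum(!keep)), call. = FALSE)
  sets <- lapply(catalog$sets[keep], function(g) match(g[g %in% nodes], nodes))
  sizes <- lengths(sets)
  S <- length(sets)
  N <- length(nodes)
  ngrid <- length(sweep$grid)
  per_gamma <- vector("list", ngrid)
  strata <- vector("list", ngrid)
  .with_seed(seed, {
    for (t in seq_len(ngrid)) {
      lab <- lm[, t]
      obs <- vapply(sets, function(ix) .stat_from_labels(lab[ix]), numeric(1L))
      null <- matrix(0, nrow = R, ncol = S)
      for (r in seq_len(R))
        null[r, ] <- vapply(sizes, function(s) .stat_from_labels(lab[sample.int(N, s)]),
                            numeric(1L))
      p <- rank_sum_test(obs, as.vector(null), alternative = "greater")
      per_gamma[[t]] <- data.frame(gamma = sweep$grid[[t]], p_rank_sum = p,
                                   obs_mean = mean(obs), null_mean = mean(null))
      us <- sort(unique(sizes))
      strata[[t]] <- do.call(rbind, lapply(us, function(s) {
        sel <- sizes == s
        om <- mean(obs[sel])
        nm <- rowMeans(null[, sel, drop = FALSE])
        data.frame(gamma = sweep$grid[[t]], size = s, n_sets = sum(sel),
                   p_empirical = (1 + sum(nm >= om)) / (1 + R))
      }))
    }
  })
  structure(list(per_gamma = do.call(rbind, per_gamma),
                 stratum = do.call(rbind, strata),
                 n_sets = S, R = as.integer(R), seed = as.integer(seed)),
            class = "ml_catalog_validation")
}

#' @export
print.ml_catalog_validation <- function(x, ...) {
  cat(sprintf("<ml_catalog_validation>  %d sets, %d randomizations\n", x$n_sets, x$R))
  print(transform(x$per_gamma, p_rank_sum = signif(p_rank_sum, 3)), row.names = FALSE)
  invisible(x)
}

# Size of the largest anchored component of the thresholded co-membership
# graph over `genes` (node-index free fast path used inside shuffles).
.largest_anchored_size <- function(lm, genes, anchors, n) {
  genes <- genes[genes %in% rownames(lm)]
  k <- length(genes)
  if (k < 2L) return(0L)
  sub <- lm[genes, , drop = FALSE]
  C <- matrix(0L, k, k)
  for (t in seq_len(ncol(sub))) {
    lab <- sub[, t]
    C <- C + outer(lab, lab, "==")
  }
  A <- C >= n
  diag(A) <- FALSE
  comp <- .adj_components(A)
  anchored <- comp[genes %in% anchors]
  best <- 0L
  for (cc in unique(anchored)) {
    sz <- sum(comp == cc)
    if (sz >= 2L && sz > best) best <- sz
  }
  best
}

#' Severity-label-shuffling null for module sizes
#'
#' Null distribution of the largest causal-anchored module size per severity
#' group under random reassignment of the severity labels (class sizes
#' preserved). The sweep partitions do not depend on the labels and are reused
#' unchanged across shuffles; only the group-private gene sets, the genes of
#' interest, the co-membership tallies and the modules are rebuilt per
#' shuffle. The observed statistics (true labels) are included.
#'
#' @param sweep An `ml_sweep`.
#' @param cohort An [ml_cohort] with both classes nonempty.
#' @param causal Known causal genes (module anchors).
#' @param n Persistence threshold (default: full grid length).
#' @param R Number of label shuffles (default 1000).
#' @param seed Integer seed.
#' @return An object of class `ml_shuffle_null`: list with `null_severe` and
#'   `null_not_severe` (integer vectors of length `R`; 0 when no anchored
#'   module exists), `observed_severe`, `observed_not_severe`, `n`, `R`,
#'   `seed`.
#' @export
label_shuffle_null <- function(sweep, cohort, causal, n = length(sweep$grid),
                               R = 1000L, seed = 1L) {
  stopifnot(inherits(sweep, "ml_sweep"), inherits(cohort, "ml_cohort"))
  if (R < 1L) stop("R must be >= 1", call. = FALSE)
  sev <- cohort$severity == "severe"
  if (!any(sev) || all(sev))
    stop("cohort must contain both severe and not-severe patients", call. = FALSE)
  causal <- sort(unique(.check_gene_ids(causal, "causal")))
  lm <- .sweep_label_matrix(sweep)
  gene_lists <- .patient_genes(cohort)
  np <- length(gene_lists)
  n_sev <- sum(sev)
  size_for <- function(mask) {
    gp <- .group_private(gene_lists, mask)
    c(.largest_anchored_size(lm, unique(c(causal, gp$severe_private)), causal, n),
      .largest_anchored_size(lm, unique(c(causal, gp$not_severe_private)), causal, n))
  }
  obs <- size_for(sev)
  null <- matrix(0L, nrow = R, ncol = 2L)
  .with_seed(seed, {
    for (r in seq_len(R)) {
      mask <- logical(np)
      mask[sample.int(np, n_sev)] <- TRUE
      null[r, ] <- size_for(mask)
    }
  })
  structure(list(null_severe = null[, 1L], null_not_severe = null[, 2L],
                 observed_severe = obs[[1L]], observed_not_severe = obs[[2L]],
                 n = as.integer(n), R = as.integer(R), seed = as.integer(seed)),
            class = "ml_shuffle_null")
}

#' @export
print.ml_shuffle_null <- function(x, ...) {
  cat(sprintf("<ml_shuffle_null>  %d shuffles at threshold n = %d\n", x$R, x$n))
  cat(sprintf("  severe:     observed %d, null max %d, null mean %.2f\n",
              x$observed_severe, max(x$null_severe), mean(x$null_severe)))
  cat(sprintf("  not severe: observed %d, null max %d, null mean %.2f\n",
              x$observed_not_severe, max(x$null_not_severe), mean(x$null_not_severe)))
  invisible(x)
}

#' Minimum significant module size
#'
#' For each candidate size `k` from 2 up to the observed module size, the
#' add-one permutation p-value `p(k) = (1 + #{null >= k}) / (1 + R)` gives the
#' probability of a label-shuffled cohort producing an anchored module of at
#' least `k` genes. P-values are Benjamini-Hochberg adjusted across the
#' evaluated sizes; the minimum significant size is the smallest `k` whose
#' adjusted p-value is at or below `alpha`.
#'
#' @param null_sizes Integer vector of null module sizes (one per shuffle).
#' @param observed An `ml_module` or the observed module size (integer >= 2).
#' @param alpha Significance level (default 0.05).
#' @return A list of class `ml_min_size`: `k_min` (integer or `NA` when no
#'   size is significant), `table` (data frame with `k`, `p`, `p_adjusted`)
#'   and `alpha`.
#' @export
min_significant_module_size <- function(null_sizes, observed, alpha = 0.05) {
  if (length(null_sizes) == 0L) stop("empty null distribution", call. = FALSE)
  size <- if (inherits(observed, "ml_module")) length(observed$genes)
          else as.integer(observed)
  if (is.na(size) || size < 2L)
    stop("observed module must contain at least 2 genes", call. = FALSE)
  R <- length(null_sizes)
  ks <- 2:size
  p <- vapply(ks, function(k) (1 + sum(null_sizes >= k)) / (1 + R), numeric(1L))
  padj <- bh_adjust(p)
  sig <- ks[padj <= alpha]
  structure(list(k_min = if (length(sig)) min(sig) else NA_integer_,
                 table = data.frame(k = ks, p = p, p_adjusted = padj),
                 alpha = alpha),
            class = "ml_min_size")
}

#' @export
print.ml_min_size <- function(x, ...) {
  cat(sprintf("<ml_min_size>  minimum significant module size: %s (alpha = %g)\n",
              ifelse(is.na(x$k_min), "none", x$k_min), x$alpha))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Module-size significance of a cohort (observed + label-shuffle null)
#'
#' Convenience wrapper running [build_group_gene_sets()], [co_membership()],
#' [extract_modules()], [label_shuffle_null()] and
#' [min_significant_module_size()] for both severity groups.
#'
#' @inheritParams label_shuffle_null
#' @param alpha Significance level.
#' @return List of class `ml_module_significance` with, per group, the
#'   observed largest anchored module, its label-shuffle p-value, and the
#'   minimum significant size table.
#' @export
module_size_significance <- function(sweep, cohort, causal,
                                     n = length(sweep$grid), R = 1000L,
                                     alpha = 0.05, seed = 1L) {
  null <- label_shuffle_null(sweep, cohort, causal, n = n, R = R, seed = seed)
  gs <- build_group_gene_sets(cohort, causal)
  group <- function(interest, nullv, obs_size) {
    mods <- tryCatch(extract_modules(suppressWarnings(co_membership(sweep, interest)),
                                     n = n, anchors = causal),
                     error = function(e) structure(list(), class = "ml_modules"))
    m <- largest_module_with(mods, causal)
    pv <- (1 + sum(nullv >= obs_size)) / (1 + length(nullv))
    list(module = m, observed_size = obs_size, p = pv,
         min_size = if (obs_size >= 2L)
           min_significant_module_size(nullv, obs_size, alpha) else NULL)
  }
  structure(list(
    severe = group(gs$severe_interest, null$null_severe, null$observed_severe),
    not_severe = group(gs$not_severe_interest, null$null_not_severe,
                       null$observed_not_severe),
    null = null, alpha = alpha
  ), class = "ml_module_significance")
}

#' @export
print.ml_module_significance <- function(x, ...) {
  cat("<ml_module_significance>\n")
  for (g in c("severe", "not_severe")) {
    gg <- x[[g]]
    cat(sprintf("  %-10s observed anchored module size %d, p = %.4g, k_min = %s\n",
                g, gg$observed_size, gg$p,
                if (is.null(gg$min_size) || is.na(gg$min_size$k_min)) "none"
                else gg$min_size$k_min))
  }
  invisible(x)
}

#' Two-tailed Fisher exact test on a 2x2 table
#'
#' Exact two-sided p-value: the sum of hypergeometric probabilities, over all
#' tables with the observed margins, that do not exceed the observed table's
#' probability (relative tolerance 1e-7 in the comparison). A table with a
#' zero margin carries no information; its p-value is defined as 1, with a
#' warning, so that scans over sparse clinical variables complete.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return The two-tailed p-value.
#' @examples
#' # severity (severe/not-severe) x pharmacological treatment (yes/no)
#' fisher_exact_2x2(matrix(c(4, 4, 9, 3), 2, byrow = TRUE))
#' @export
fisher_exact_2x2 <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L)))
    stop("`table` must be 2x2", call. = FALSE)
  if (any(is.na(tab)) || any(tab < 0) || any(tab != round(tab)))
    stop("`table` must hold non-negative integer counts", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("zero margin in 2x2 table; p-value defined as 1", call. = FALSE)
    return(1)
  }
  stats::fisher.test(tab)$p.value
}

#' Severity association scan over binary clinical variables
#'
#' For each variable, patients with a missing value are excluded (with a
#' message), a severity x variable 2x2 table is formed, a two-tailed Fisher
#' exact p-value computed, and p-values are Benjamini-Hochberg adjusted across
#' the scanned variables.
#'
#' @param cohort An [ml_cohort].
#' @param variables Character vector of variable names: columns of
#'   `cohort$clinical` and/or `"treatment"`.
#' @return A data frame of class `ml_assoc`: variable, the four cell counts
#'   (severe/not-severe x TRUE/FALSE), patients used, `p`, `p_adjusted`.
#' @export
clinical_association_scan <- function(cohort, variables) {
  stopifnot(inherits(cohort, "ml_cohort"))
  if (length(variables) == 0L) stop("no variables to scan", call. = FALSE)
  sev <- cohort$severity == "severe"
  rows <- lapply(variables, function(v) {
    val <- if (v == "treatment") cohort$treatment
           else if (!is.null(cohort$clinical) && v %in% names(cohort$clinical))
             cohort$clinical[[v]]
           else stop(sprintf("variable '%s' not found in cohort", v), call. = FALSE)
    ok <- !is.na(val)
    if (any(!ok))
      message(sprintf("variable '%s': %d patients without a value excluded",
                      v, sum(!ok)))
    tab <- matrix(c(sum(sev[ok] & val[ok]), sum(sev[ok] & !val[ok]),
                    sum(!sev[ok] & val[ok]), sum(!sev[ok] & !val[ok])),
                  2L, 2L, byrow = TRUE)
    data.frame(variable = v,
               severe_yes = tab[1L, 1L], severe_no = tab[1L, 2L],
               not_severe_yes = tab[2L, 1L], not_severe_no = tab[2L, 2L],
               n_used = sum(ok), p = fisher_exact_2x2(tab))
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- bh_adjust(out$p)
  class(out) <- c("ml_assoc", "data.frame")
  out
}

#' Wilcoxon rank-sum test
#'
#' Two-sample rank-sum p-value: exact enumeration when the combined sample
#' size is at most 20 and there are no ties, otherwise the normal
#' approximation with tie and continuity corrections. `alternative` refers to
#' the first sample: `"greater"` tests whether `x` tends to exceed `y`.
#'
#' @param x,y Nonempty numeric vectors.
#' @param alternative `"two_sided"`, `"greater"` or `"less"`.
#' @return The p-value.
#' @export
rank_sum_test <- function(x, y, alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be nonempty", call. = FALSE)
  exact <- (length(x) + length(y) <= 20L) && !anyDuplicated(c(x, y))
  stats::wilcox.test(x, y,
                     alternative = switch(alternative, two_sided = "two.sided",
                                          greater = "greater", less = "less"),
                     exact = exact, correct = TRUE)$p.value
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' order-preserving and never below the raw p-value.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0L) return(numeric(0))
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvals, method = "BH")
}
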