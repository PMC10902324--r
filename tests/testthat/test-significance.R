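# Catalog preprocessing, permutation procedures and exact tests.

test_that("catalog filtering applies size, IQR and network rules in order", {
  sizes <- c(1, 2, 2, 3, 3, 3, 4, 30)
  genes <- sprintf("g%03d", 1:60)
  sets <- lapply(seq_along(sizes), function(i)
    genes[seq_len(sizes[i]) + c(0, cumsum(sizes))[i]])
  names(sets) <- sprintf("S%d", seq_along(sizes))
  sets[["S1"]] <- sets[["S1"]][1L]   # the singleton
  cat0 <- ml_catalog(sets)
  res <- preprocess_catalog(cat0, network_nodes = genes)
  expect_equal(res$report$n_dropped_singleton, 1L)
  expect_equal(res$report$q1, 2.5)          # linear-interpolation quantiles
  expect_equal(res$report$q3, 3.5)
  expect_equal(res$report$size_cutoff, 5.0)
  expect_equal(res$report$n_dropped_large, 1L)  # the 30-gene set
  expect_equal(res$report$n_retained, 6L)
  expect_equal(res$report$n_genes_off_network, 0L)

  # a 2-gene set with one gene off the network dies at the last step
  cat1 <- ml_catalog(list(A = c("a", "b"), B = c("a", "b", "c"), C = c("a", "x")))
  res1 <- preprocess_catalog(cat1, network_nodes = c("a", "b", "c"))
  expect_equal(res1$report$n_dropped_reduced, 1L)
  expect_false("C" %in% names(res1$catalog$sets))
  expect_error(preprocess_catalog(ml_catalog(list(A = "a")), "a"), "singleton")
})

test_that("the co-membership pair statistic counts same-community pairs", {
  p <- as_partition(c(a = 0, b = 0, c = 1, d = 2, e = 2, f = 2))
  expect_equal(set_comembership_stat(p, c("a", "b", "c")), 1L)
  expect_equal(set_comembership_stat(p, c("d", "e", "f")), choose(3, 2))
  expect_equal(set_comembership_stat(p, c("a", "c", "d")), 0L)
  expect_error(set_comembership_stat(p, c("a", "zz")), "fewer than 2")
})

test_that("catalog validation reduces to identity in the degenerate universe", {
  nodes <- c("a", "b", "c", "d")
  sw <- make_sweep(list(stats::setNames(c(0, 0, 1, 1), nodes)))
  cat0 <- ml_catalog(list(ALL = nodes))
  cv <- catalog_validation(sw, cat0, R = 1L, seed = 1L)
  expect_equal(cv$per_gamma$obs_mean, cv$per_gamma$null_mean)
  expect_error(catalog_validation(sw, cat0, R = 0L), "R must be")
})

test_that("coherent sets score far above the balanced null, null sets do not", {
  nodes <- sprintf("g%02d", 1:30)
  truth <- stats::setNames(rep(0:2, each = 10L), nodes)
  sw <- make_sweep(rep(list(truth), 3L))
  coherent <- ml_catalog(list(A = nodes[1:5], B = nodes[11:15], C = nodes[21:26]))
  cv <- catalog_validation(sw, coherent, R = 100L, seed = 2L)
  expect_true(all(cv$per_gamma$p_rank_sum < 0.01))
  expect_true(all(cv$stratum$p_empirical <= 1 / 50))
  # determinism
  cv2 <- catalog_validation(sw, coherent, R = 100L, seed = 2L)
  expect_identical(cv$per_gamma, cv2$per_gamma)
})

test_that("label shuffling is invariant when all patients share one gene list", {
  nodes <- sprintf("g%02d", 1:20)
  truth <- stats::setNames(rep(0:1, each = 10L), nodes)
  sw <- make_sweep(rep(list(truth), 4L))
  coh <- ml_cohort(id = sprintf("p%d", 1:6),
                   severity = rep(c("severe", "not_severe"), each = 3L),
                   compound_het = rep(list(nodes[1:5]), 6L),
                   cnv = rep(list(character(0)), 6L))
  null <- label_shuffle_null(sw, coh, causal = "g01", n = 4L, R = 25L, seed = 9L)
  # every shuffle yields empty private sets: the null is constant
  expect_length(unique(null$null_severe), 1L)
  expect_length(unique(null$null_not_severe), 1L)
  null2 <- label_shuffle_null(sw, coh, causal = "g01", n = 4L, R = 25L, seed = 9L)
  expect_identical(null$null_severe, null2$null_severe)
})

test_that("planted severe-private signal beats the shuffled null", {
  sim <- simulate_multilayer(seed = 31L)
  grid <- resolution_grid(n = 4L, gamma_max = 2)   # identifiable regime
  sw <- sweep_resolutions(sim$network, grid, seed = 31L)
  coh <- simulate_cohort(sim$truth, signal_community = 1L, seed = 32L)
  null <- label_shuffle_null(sw, coh$cohort, coh$causal, n = 4L, R = 50L,
                             seed = 33L)
  expect_gt(null$observed_severe, max(null$null_severe))
})

test_that("minimum significant size follows the add-one estimator and BH step-up", {
  null <- c(rep(2L, 400L), rep(3L, 400L), rep(5L, 200L))   # R = 1000, all <= 5
  res <- min_significant_module_size(null, observed = 15L, alpha = 0.05)
  expect_equal(res$table$p[res$table$k >= 6], rep(1 / 1001, 10L))
  expect_equal(res$k_min, 6L)
  expect_true(all(diff(res$table$p) <= 0))        # p non-increasing in k
  expect_true(all(res$table$p >= 1 / 1001 & res$table$p <= 1))

  res2 <- min_significant_module_size(c(2L, 2L, 3L, 4L), observed = 2L)
  expect_equal(res2$table$p, 1)
  expect_true(is.na(res2$k_min))

  res3 <- min_significant_module_size(c(2L, 2L, 3L), observed = 3L)
  expect_equal(res3$table$p[res3$table$k == 3], 0.5)   # (1 + 1) / 4

  expect_error(min_significant_module_size(integer(0), 5L), "empty null")
  expect_error(min_significant_module_size(c(1L, 2L), 1L), "at least 2")
})

test_that("fisher exact p matches closed forms and enumeration", {
  expect_equal(fisher_exact_2x2(matrix(c(1, 0, 0, 1), 2)), 1)
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2)), 2 / 252,
               tolerance = 1e-12)
  expect_warning(p0 <- fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
                 "zero margin")
  expect_equal(p0, 1)
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
  set.seed(5)
  for (rep in 1:30) {
    tab <- matrix(stats::rpois(4, 4), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_2x2(tab), fisher_enum_oracle(tab),
                 tolerance = 1e-12)
  }
})

test_that("clinical association scan builds per-variable tables with BH adjustment", {
  coh <- ml_cohort(id = sprintf("p%02d", 1:8),
                   severity = rep(c("severe", "not_severe"), each = 4L),
                   treatment = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
                   clinical = data.frame(flat = rep(TRUE, 8L)))
  expect_warning(res <- clinical_association_scan(coh, c("treatment", "flat")),
                 "zero margin")
  expect_equal(res$p[res$variable == "treatment"], 2 / 70, tolerance = 1e-12)
  expect_equal(res$p[res$variable == "flat"], 1)
  expect_equal(res$p_adjusted, bh_adjust(res$p))
  # adjusted equals raw when a single variable is scanned
  res1 <- clinical_association_scan(coh, "treatment")
  expect_equal(res1$p_adjusted, res1$p)
  expect_error(clinical_association_scan(coh, character(0)), "no variables")
  expect_error(clinical_association_scan(coh, "nope"), "not found")
})

test_that("rank-sum p-values match exact enumeration and flip under swapping", {
  expect_equal(rank_sum_test(c(4, 5, 6), c(1, 2, 3), "greater"), 1 / 20)
  x <- c(0.3, 1.7, 2.2, 5.1)
  y <- c(0.9, 2.9, 3.3)
  for (alt in c("greater", "less", "two_sided"))
    expect_equal(rank_sum_test(x, y, alt), ranksum_enum_oracle(x, y, alt))
  expect_equal(rank_sum_test(x, y, "greater"), rank_sum_test(y, x, "less"))
  expect_equal(rank_sum_test(c(1, 2, 3), c(1, 2, 3), "two_sided"), 1)
  expect_error(rank_sum_test(numeric(0), 1), "nonempty")
})

test_that("BH adjustment reproduces hand-computed values and is order-preserving", {
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(1, 4)), rep(1, 4))
  p <- c(0.04, 0.001, 0.3, 0.012)
  perm <- c(3L, 1L, 4L, 2L)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})
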