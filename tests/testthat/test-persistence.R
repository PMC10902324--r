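# Resolution sweep, co-membership tallying, persistence modules, cores and
# group gene sets.

test_that("the default grid covers (0, 4] with 8 evenly spaced values", {
  g <- resolution_grid()
  expect_equal(unclass(g), seq(0.5, 4, by = 0.5))
  expect_error(resolution_grid(values = c(1, 1)), "strictly increasing")
  expect_error(resolution_grid(values = c(-1, 2)), "positive")
})

test_that("a sweep yields one seeded partition per grid value, reproducibly", {
  sim <- simulate_multilayer(sizes = c(8L, 8L), n_layers = 2L, p_in = 0.8,
                             p_out = 0.05, seed = 3L)
  grid <- resolution_grid(n = 4L, gamma_max = 2)
  sw <- sweep_resolutions(sim$network, grid, seed = 10L)
  expect_length(sw$partitions, 4L)
  expect_length(sw$Q, 4L)
  expect_equal(sw$seeds, 10:13)
  sw2 <- sweep_resolutions(sim$network, grid, seed = 10L)
  expect_identical(lapply(sw$partitions, unclass), lapply(sw2$partitions, unclass))
  # the partition at one grid value is the single-gamma run with its derived seed
  expect_identical(unclass(sw$partitions[[2L]]),
                   unclass(louvain_multilayer(sim$network, grid[[2L]], seed = 11L)))
})

test_that("co-membership counts are symmetric, bounded and account for dropped genes", {
  nodes <- c("a", "b", "c", "d", "e")
  base <- stats::setNames(c(0, 0, 1, 1, 2), nodes)
  alt <- stats::setNames(c(0, 1, 1, 1, 2), nodes)
  sw <- make_sweep(list(base, base, alt, alt, base, base, base, base))
  expect_warning(cm <- co_membership(sw, c(nodes, "zz")), "dropped")
  expect_setequal(cm$dropped, "zz")
  expect_length(cm$genes, 5L)   # retained + dropped = supplied
  expect_equal(cm$counts["a", "b"], 6L)
  expect_equal(cm$counts["c", "d"], 8L)
  expect_equal(cm$counts["a", "e"], 0L)
  expect_true(all(cm$counts == t(cm$counts)))
  expect_true(all(cm$counts >= 0 & cm$counts <= cm$n_grid))
  expect_error(co_membership(sw, "nope"), "none of the genes")

  # identical partitions across the grid force counts into {0, |grid|}
  sw_id <- make_sweep(rep(list(base), 8L))
  cm_id <- co_membership(sw_id, nodes)
  off <- cm_id$counts[upper.tri(cm_id$counts)]
  expect_true(all(off %in% c(0L, 8L)))
})

test_that("modules are thresholded components of size >= 2, sorted and nested", {
  genes <- c("a", "b", "c", "d", "e")
  counts <- matrix(0L, 5, 5, dimnames = list(genes, genes))
  counts["a", "b"] <- counts["b", "a"] <- 8L
  counts["b", "c"] <- counts["c", "b"] <- 8L
  counts["d", "e"] <- counts["e", "d"] <- 3L
  diag(counts) <- 8L
  cm <- structure(list(genes = genes, counts = counts, n_grid = 8L,
                       dropped = character(0)), class = "ml_comembership")
  m8 <- extract_modules(cm, n = 8L)
  expect_length(m8, 1L)
  expect_equal(m8[[1L]]$genes, c("a", "b", "c"))
  m3 <- extract_modules(cm, n = 3L, anchors = "d")
  expect_length(m3, 2L)
  expect_equal(m3[[1L]]$genes, c("a", "b", "c"))   # larger first
  expect_equal(m3[[2L]]$genes, c("d", "e"))
  expect_false(m3[[1L]]$anchored)
  expect_true(m3[[2L]]$anchored)
  expect_error(extract_modules(cm, n = 9L), "1..8")
})

test_that("modules at threshold n+1 always refine modules at n", {
  for (case in 1:40) {
    nodes <- sprintf("g%02d", 1:12)
    parts <- lapply(1:4, function(i) rand_partition(nodes, sample(2:5, 1L),
                                                    seed = case * 10 + i))
    cm <- co_membership(make_sweep(parts), nodes)
    prev <- NULL
    for (n in 4:2) {
      mods <- extract_modules(cm, n = n)
      if (!is.null(prev)) {
        for (m in prev) {
          containing <- Filter(function(M) all(m$genes %in% M$genes), mods)
          expect_gte(length(containing), 1L)
        }
      }
      prev <- mods
    }
  }
})

test_that("largest anchored module selection follows size then lexicographic order", {
  mk <- function(genes) structure(list(genes = sort(genes), threshold = 8L,
                                       anchored = TRUE, anchors = character(0)),
                                  class = "ml_module")
  mods <- structure(list(mk(c("a", "b", "c")), mk(c("d", "e"))),
                    class = "ml_modules")
  expect_equal(largest_module_with(mods, "d")$genes, c("d", "e"))
  expect_null(largest_module_with(mods, "zz"))
  big <- mk(sprintf("m%02d", 1:15))
  small <- mk(c("d", "e"))
  expect_equal(largest_module_with(structure(list(small, big), class = "ml_modules"),
                                   c("d", "m01"))$genes, big$genes)
})

test_that("the persistent core is the cross-resolution community intersection", {
  # 8 identical partitions: core = the full community containing the module
  nodes <- sprintf("g%02d", 1:9)
  base <- stats::setNames(rep(0:2, each = 3L), nodes)
  sw <- make_sweep(rep(list(base), 8L))
  mod <- extract_modules(co_membership(sw, c("g01", "g02")), n = 8L)[[1L]]
  expect_setequal(persistent_core(sw, mod), c("g01", "g02", "g03"))

  # communities overlapping in exactly 5 nodes across the grid
  p1 <- stats::setNames(c(rep(0L, 7L), 1L, 1L), nodes)   # g01..g07 | g08 g09
  p2 <- stats::setNames(c(rep(0L, 5L), 1L, 1L, 0L, 0L), nodes) # g01..g05,g08,g09
  sw2 <- make_sweep(c(rep(list(p1), 4L), rep(list(p2), 4L)))
  mod2 <- extract_modules(co_membership(sw2, c("g01", "g02")), n = 8L)[[1L]]
  core <- persistent_core(sw2, mod2)
  expect_setequal(core, sprintf("g%02d", 1:5))
  expect_true(all(mod2$genes %in% core))   # always a superset of the module

  # a non-persistent module is refused
  mod_bad <- structure(list(genes = c("g01", "g08"), threshold = 8L,
                            anchored = FALSE, anchors = character(0)),
                       class = "ml_module")
  expect_error(persistent_core(sw2, mod_bad), "not fully persistent")
})

test_that("group gene sets split into unions, private sets and linked genes", {
  coh <- ml_cohort(id = c("p1", "p2", "p3"),
                   severity = c("severe", "not_severe", "not_severe"),
                   compound_het = list(c("a", "b"), c("b"), c("d")),
                   cnv = list(c("c"), character(0), character(0)))
  gs <- build_group_gene_sets(coh, causal = "z")
  expect_setequal(gs$severe_private, c("a", "c"))
  expect_setequal(gs$not_severe_private, "d")
  expect_setequal(gs$linked, c("a", "b", "c", "d", "z"))
  expect_setequal(gs$severe_interest, c("a", "c", "z"))
  expect_equal(gs$counts$severe_private[gs$counts$class == "combined"], 2L)

  # identical lists in both groups: both private sets empty
  coh2 <- ml_cohort(id = c("p1", "p2"), severity = c("severe", "not_severe"),
                    compound_het = list("a", "a"), cnv = list("b", "b"))
  gs2 <- build_group_gene_sets(coh2, causal = "z")
  expect_length(gs2$severe_private, 0L)
  expect_length(gs2$not_severe_private, 0L)

  coh3 <- ml_cohort(id = "p1", severity = "severe",
                    compound_het = list("a"), cnv = list(character(0)))
  expect_error(build_group_gene_sets(coh3, "z"), "both severe and not-severe")
})

test_that("cohort construction validates labels and consistency", {
  expect_error(ml_cohort(id = c("p1", "p1"), severity = c("severe", "severe")),
               "duplicate")
  expect_error(ml_cohort(id = "p1", severity = "Severe"), "severe, not_severe")
  expect_error(ml_cohort(id = "p1", severity = "severe", fine_label = "mild"),
               "inconsistent")
  coh <- ml_cohort(id = c("p1", "p2"), severity = c("severe", "not_severe"),
                   fine_label = c("severe", "intermediate"))
  expect_s3_class(coh, "ml_cohort")
})
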