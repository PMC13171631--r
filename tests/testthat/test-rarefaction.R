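test_that("the logarithmic grid follows the per-decade rule", {
  expect_equal(log_grid(35), c(10, 20, 30, 35))
  expect_equal(log_grid(10), 10)
  expect_equal(log_grid(1050),
               c(seq(10, 100, 10), seq(200, 1000, 100), 1050))
  expect_equal(log_grid(100), seq(10, 100, 10))
  expect_equal(log_grid(5), 5)
  expect_error(log_grid(0), "n_max")
})

test_that("exhaustive subset averaging equals the hypergeometric expectation", {
  # three samples holding clusters {A}, {A}, {B}: mean richness at N = 2
  # over all subsets is 5/3
  tab <- seq_table(c("cA", "cA", "cB"), sample_id = c("s1", "s2", "s3"))
  cv <- rarefy_samples(tab, "m1", grid = 2, exhaustive = TRUE)
  expect_equal(curve_means(cv), 5 / 3)
  # general small design: exhaustive mean equals analytic expectation at all N
  sets <- list(c("a", "b"), c("b"), c("a", "c"), c("c", "d"), c("b"))
  tab2 <- seq_table(unlist(sets),
                    sample_id = rep(sprintf("s%d", 1:5), lengths(sets)),
                    contig_id = sprintf("ct%d", seq_along(unlist(sets))))
  for (N in 1:5) {
    cvN <- rarefy_samples(tab2, "m1", grid = N, exhaustive = TRUE)
    expect_equal(curve_means(cvN), expected_richness_hypergeom(sets, N))
  }
})

test_that("permutation curves are nondecreasing and exact at full depth", {
  w <- synthetic_world(n_species = 120, n_samples_per_habitat = c(a = 25, b = 15),
                       n_markers = 2, seed = 19,
                       occupancy_law = list(law = "lognormal",
                                            meanlog = log(0.1), sdlog = 1))
  cen <- simulate_census(w)
  cv <- rarefy_samples(cen, "marker01", n_perm = 5, seed = 11)
  for (p in seq_len(nrow(cv$clusters[[1]]))) {
    per_perm <- vapply(cv$clusters, function(m) m[p, "total"], numeric(1))
    expect_false(is.unsorted(per_perm))
  }
  # last grid point is the full design: all permutations see everything
  final <- cv$clusters[[length(cv$grid)]][, "total"]
  meta <- cen[cen$marker_gene == "marker01" & cen$sample_id != "", ]
  expect_true(all(final == length(unique(meta$cluster_id))))
  expect_equal(stats::sd(final), 0)
})

test_that("stratified counts sum to the total at every grid point", {
  w <- synthetic_world(n_species = 150, n_samples_per_habitat = c(a = 20, b = 10),
                       n_markers = 1, seed = 23)
  cv <- rarefy_samples(simulate_census(w), "marker01", n_perm = 4, seed = 5)
  for (gi in seq_along(cv$grid)) {
    m <- cv$clusters[[gi]]
    expect_equal(rowSums(m[, c("PROGENOMES", "GTDB", "SPIRE_MAG",
                               "UNBINNED_NONSINGLETON", "UNBINNED_ALL"),
                           drop = FALSE]),
                 m[, "total"])
  }
})

test_that("identical samples give a flat curve at the shared richness", {
  tab <- seq_table(rep(c("c1", "c2", "c3"), 4),
                   sample_id = rep(sprintf("s%d", 1:4), each = 3),
                   contig_id = sprintf("ct%d", 1:12))
  cv <- rarefy_samples(tab, "m1", grid = 1:4, n_perm = 3, seed = 1)
  expect_true(all(curve_means(cv) == 3))
})

test_that("cross-marker summaries take medians and propagate zero variance", {
  grid <- log_grid(300)
  curves <- lapply(c(10, 20, 90), function(k) {
    simulate_discovery_curve(k, 0.3, grid)
  })
  sm <- summarize_across_markers(curves)
  expect_equal(sm$median[, "total"],
               curve_means(curves[[2]])) # median of scaled curves = middle one
  expect_true(all(sm$cv == 0)) # single noise-free permutation each
  mismatched <- simulate_discovery_curve(10, 0.3, log_grid(200))
  expect_error(summarize_across_markers(list(curves[[1]], mismatched)),
               "grid")
})

test_that("habitat accumulation increments are order-dependent, sum-invariant", {
  # habitats with disjoint cluster sets of sizes 5 and 3
  tabA <- seq_table(sprintf("a%d", 1:5), sample_id = "sA",
                    contig_id = sprintf("ca%d", 1:5), habitat = "A")
  tabB <- seq_table(sprintf("b%d", 1:3), sample_id = "sB",
                    contig_id = sprintf("cb%d", 1:3), habitat = "B")
  tab <- rbind(tabA, tabB)
  tab$seq_id <- sprintf("q%03d", seq_len(nrow(tab)))
  fw <- incremental_habitat_accumulation(tab, c("A", "B"), "m1", seed = 1)
  expect_equal(unname(fw$increments), c(5, 3))
  bw <- incremental_habitat_accumulation(tab, c("B", "A"), "m1", seed = 1)
  expect_equal(unname(bw$increments), c(3, 5))
  expect_equal(sum(fw$increments), sum(bw$increments))
  # nested habitats: B's clusters are a subset of A's
  tabB2 <- seq_table(sprintf("a%d", 1:2), sample_id = "sB2",
                     contig_id = sprintf("cn%d", 1:2), habitat = "B")
  tab2 <- rbind(tabA, tabB2)
  tab2$seq_id <- sprintf("q%03d", seq_len(nrow(tab2)))
  nested <- incremental_habitat_accumulation(tab2, c("A", "B"), "m1", seed = 2)
  expect_equal(unname(nested$increments), c(5, 0))
  expect_error(incremental_habitat_accumulation(tab, c("A", "B", "Z"), "m1"),
               "unknown habitat")
  expect_error(incremental_habitat_accumulation(tab, c("A"), "m1"),
               "does not cover")
})

test_that("overlapping habitat increments conserve total richness", {
  w <- synthetic_world(n_species = 100,
                       n_samples_per_habitat = c(a = 12, b = 9, c = 6),
                       n_markers = 1, seed = 29, cross_habitat = 0.4)
  cen <- simulate_census(w)
  orders <- list(c("a", "b", "c"), c("c", "a", "b"), c("b", "c", "a"))
  totals <- vapply(orders, function(o) {
    acc <- incremental_habitat_accumulation(cen, o, "marker01", seed = 7)
    expect_equal(sum(acc$increments), acc$total)
    acc$total
  }, numeric(1))
  expect_true(all(totals == totals[1]))
})
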