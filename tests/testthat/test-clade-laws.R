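test_that("Yule-Simon pmf matches closed forms and normalizes", {
  expect_equal(yule_simon_pmf(1, 1), 0.5)
  expect_equal(yule_simon_pmf(2, 1), 1 / 6)
  expect_equal(yule_simon_pmf(1, 2), 2 / 3) # rho/(rho+1) at size 1
  # normalization over a truncated support with negligible tail
  for (rho in c(0.75, 1.5, 3)) {
    expect_equal(sum(yule_simon_pmf(1:1e6, rho)), 1, tolerance = 1e-4)
  }
  expect_error(yule_simon_pmf(0, 1), "size")
  expect_error(yule_simon_pmf(1, 0), "rho")
})

test_that("the Yule-Simon sampler reproduces the pmf", {
  x <- ryule_simon(2e5, 1.5, seed = 17)
  for (k in 1:6) {
    p <- yule_simon_pmf(k, 1.5)
    se <- sqrt(p * (1 - p) / length(x))
    expect_lt(abs(mean(x == k) - p), 4 * se)
  }
})

test_that("MLE of rho equals a dense grid-search oracle", {
  fixtures <- list(
    clade_size_distribution(ryule_simon(3000, 1.2, seed = 4)),
    clade_size_distribution(ryule_simon(3000, 0.6, seed = 5)),
    simulate_simon_clades(3000, 0.4, seed = 6),
    clade_size_distribution(size = c(1, 2, 3, 7), count = c(40, 12, 5, 1))
  )
  grid <- seq(0.05, 12, by = 1e-3)
  for (d in fixtures) {
    mle <- fit_yule_simon(d)$rho
    ll <- vapply(grid, function(r) {
      sum(d$count * (log(r) + lbeta(d$size, r + 1)))
    }, numeric(1))
    expect_lt(abs(mle - grid[which.max(ll)]), 1e-3)
  }
})

test_that("rho is recovered from large Yule-Simon samples", {
  for (rho in c(0.75, 1.5, 3)) {
    fit <- fit_yule_simon(clade_size_distribution(ryule_simon(1e5, rho,
                                                              seed = 42)))
    expect_lt(abs(fit$rho - rho), 0.05)
    expect_true(is.finite(fit$std_error))
  }
})

test_that("all-singleton samples are flagged degenerate, not fitted", {
  fit <- fit_yule_simon(clade_size_distribution(rep(1, 50)))
  expect_true(fit$degenerate)
  expect_identical(fit$rho, Inf)
})

test_that("Willis fit is exact on log-linear counts and flat on constants", {
  f <- fit_willis(clade_size_distribution(size = c(1, 2, 4, 8),
                                          count = c(8, 4, 2, 1)))
  expect_equal(f$omega, 1)
  expect_equal(f$a, 8)
  expect_equal(f$r_squared, 1)
  flat <- fit_willis(clade_size_distribution(size = c(1, 2, 4),
                                             count = c(7, 7, 7)))
  expect_equal(flat$omega, 0)
  expect_error(fit_willis(clade_size_distribution(size = c(1, 2),
                                                  count = c(3, 1))),
               ">= 3")
})

test_that("tail-binned Willis slope approaches rho + 1 on large samples", {
  for (rho in c(0.5, 1, 2)) {
    omegas <- vapply(1:5, function(s) {
      d <- clade_size_distribution(ryule_simon(1e5, rho, seed = 300 + s))
      fit_willis(d, binning = "log", min_size = 5)$omega
    }, numeric(1))
    expect_lt(abs(mean(omegas) - (rho + 1)), 0.35)
  }
})

test_that("lower rho gives heavier tails (99th-percentile clade size)", {
  q99 <- vapply(c(0.5, 1, 2), function(rho) {
    quantile(ryule_simon(5e4, rho, seed = 9), 0.99)
  }, numeric(1))
  expect_true(all(diff(q99) < 0))
})

test_that("clade sizes from partitions match label counting and conserve units", {
  sim <- simulate_yule_tree(120, seed = 21)
  rt <- compute_red(sim$tree)
  # planted fractions are exact RED cutoffs on an ultrametric tree
  phylum <- cut_at_red(rt, sim$rank_fractions[["phylum"]], rank = "phylum")
  genus <- cut_at_red(rt, sim$rank_fractions[["genus"]], rank = "genus")
  tips <- sizes_from_partitions(phylum)
  expect_equal(total_subunits(tips), 120)
  # oracle: count tips per planted phylum label directly
  oracle <- as.integer(table(table(sim$taxonomy$phylum)))
  expect_equal(tips$count, oracle)
  nested <- sizes_from_partitions(phylum, genus)
  expect_equal(total_subunits(nested), length(genus$clades))
  # direct label-counting oracle for genus-within-phylum
  gpp <- tapply(sim$taxonomy$genus, sim$taxonomy$phylum,
                function(g) length(unique(g)))
  expect_equal(sort(rep(nested$size, nested$count)),
               sort(unname(as.integer(gpp))))
  # degenerate shapes
  one <- cut_at_red(rt, 0)
  expect_equal(sizes_from_partitions(one, genus)$size,
               length(genus$clades))
  expect_error(sizes_from_partitions(genus, phylum), "not nested")
})

test_that("clade sizes from a flat taxonomy table match a group-by oracle", {
  tax <- data.frame(
    entity_id = sprintf("e%d", 1:8),
    genus = c("g1", "g1", "g2", "g2", "g3", "g3", "g4", "g__"),
    species = c("s1", "s2", "s3", "s4", "s5", "s6", "s7", "s8")
  )
  d <- sizes_from_taxonomy_table(tax, "genus", "species")
  expect_equal(d$size, c(1, 2))
  expect_equal(d$count, c(1L, 3L)) # g4 has 1 species; g1-g3 have 2; g__ excluded
  expect_equal(sizes_from_taxonomy_table(
    data.frame(genus = "g1", species = "s1"), "genus", "species"
  )$count, 1L)
  expect_error(sizes_from_taxonomy_table(tax, "family", "genus"), "missing")
})

test_that("stratified fits recover the ordering of innovation probabilities", {
  # two habitats simulated with different preferential-attachment strengths
  dists <- list(
    weak_innovation = lapply(1:3, function(s) {
      simulate_simon_clades(2e4, 0.2, seed = 50 + s)
    }),
    strong_innovation = lapply(1:3, function(s) {
      simulate_simon_clades(2e4, 0.6, seed = 60 + s)
    })
  )
  fits <- stratified_fits(dists)
  rho <- setNames(fits$rho, fits$stratum)
  expect_lt(rho[["weak_innovation"]], rho[["strong_innovation"]])
  expect_lt(abs(rho[["weak_innovation"]] - 1 / (1 - 0.2)), 0.1)
  expect_lt(abs(rho[["strong_innovation"]] - 1 / (1 - 0.6)), 0.15)
  # a single global stratum equals the unstratified fit
  d <- simulate_simon_clades(5000, 0.5, seed = 70)
  expect_equal(stratified_fits(list(global = list(d)))$rho,
               fit_yule_simon(d)$rho)
  expect_warning(stratified_fits(list(
    ok = list(d), tiny = list(clade_size_distribution(1))
  )), "skipped")
})
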