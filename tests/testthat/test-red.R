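test_that("RED takes closed-form values on the balanced unit tree", {
  rt <- compute_red(balanced4())
  expect_equal(rt$red[1:4], rep(1, 4)) # tips
  expect_equal(rt$red[5], 0)           # root
  expect_equal(rt$red[6:7], c(0.5, 0.5)) # root children: 0 + (1/2)(1-0)
})

test_that("RED equals an independent recomputation from the definition", {
  trees <- list(caterpillar6(), balanced4(),
                local({set.seed(2); ape::rtree(12)}))
  for (tr in trees) {
    rt <- compute_red(tr)
    expect_equal(rt$red, red_by_definition(tr), tolerance = 1e-12)
  }
})

test_that("RED is 0 at the root, 1 at tips, monotone on random trees", {
  set.seed(101)
  for (i in 1:60) {
    tr <- ape::rphylo(sample(5:40, 1), birth = 1, death = 0)
    rt <- compute_red(tr)
    n_tip <- length(tr$tip.label)
    expect_equal(rt$red[n_tip + 1L], 0)
    expect_true(all(rt$red[1:n_tip] == 1))
    parent <- integer(n_tip + tr$Nnode)
    parent[tr$edge[, 2]] <- tr$edge[, 1]
    kids <- tr$edge[, 2]
    expect_true(all(rt$red[kids] >= rt$red[parent[kids]] - 1e-12))
  }
})

test_that("RED rejects unrooted trees and negative branch lengths", {
  tr <- ape::rtree(8)
  expect_error(compute_red(ape::unroot(tr)), "rooted")
  tr$edge.length[1] <- -0.1
  expect_error(compute_red(tr), "negative")
  noblen <- ape::read.tree(text = "((A,B),(C,D));")
  expect_error(compute_red(noblen), "branch lengths")
})

test_that("zero-length branches inherit the parent RED", {
  tr <- ape::read.tree(text = "((A:1,B:1):0,(C:1,D:1):1);")
  rt <- compute_red(tr)
  expect_equal(rt$red[6], 0) # zero-length child of the root
})

test_that("cutting at RED always yields a partition, coarsening toward 0", {
  set.seed(55)
  for (i in 1:10) {
    tr <- ape::rphylo(30, birth = 1, death = 0)
    rt <- compute_red(tr)
    prev <- Inf
    for (cutoff in c(1, 0.8, 0.5, 0.2, 0)) {
      part <- cut_at_red(rt, cutoff)
      tips <- sort(unlist(part$clades))
      expect_equal(tips, sort(tr$tip.label)) # disjoint covering
      expect_lte(length(part$clades), prev)  # nonincreasing toward 0
      prev <- length(part$clades)
    }
    expect_equal(length(cut_at_red(rt, 0)$clades), 1)
    expect_equal(length(cut_at_red(rt, 1)$clades), 30)
  }
  expect_error(cut_at_red(compute_red(balanced4()), 1.5), "cutoff")
})

test_that("AMI is 1 for identical partitions up to relabelling, ~0 when independent", {
  set.seed(7)
  for (i in 1:100) {
    x <- sample(1:5, 40, replace = TRUE)
    expect_equal(adjusted_mutual_information(x, x), 1, tolerance = 1e-9)
  }
  x <- sample(1:4, 200, replace = TRUE)
  relabel <- c(9, 7, 5, 3)[x]
  expect_equal(adjusted_mutual_information(x, relabel), 1, tolerance = 1e-9)
  a <- sample(1:10, 1e4, replace = TRUE)
  b <- sample(1:10, 1e4, replace = TRUE)
  expect_lt(abs(adjusted_mutual_information(a, b)), 0.01)
  expect_error(adjusted_mutual_information(1:3, 1:4), "mismatch")
})

test_that("calibration recovers planted clades with AMI 1 and ordered cutoffs", {
  sim <- simulate_yule_tree(400, seed = 13)
  rt <- compute_red(sim$tree)
  cutoffs <- numeric(0)
  for (rk in names(sim$rank_fractions)) {
    labels <- setNames(sim$taxonomy[[rk]], sim$taxonomy$entity_id)
    cal <- calibrate_cutoffs(rt, labels, rank = rk)
    expect_equal(max(cal$ami), 1, tolerance = 1e-9)
    part <- cut_at_red(rt, cal$cutoff, rank = rk)
    expect_equal(length(part$clades), unname(sim$clade_counts[[rk]]))
    expect_equal(adjusted_mutual_information(part$membership[names(labels)],
                                             labels), 1, tolerance = 1e-9)
    cutoffs <- c(cutoffs, cal$cutoff)
  }
  expect_false(is.unsorted(cutoffs, strictly = TRUE))
})

test_that("calibration handles degenerate label sets as specified", {
  sim <- simulate_yule_tree(40, seed = 3)
  rt <- compute_red(sim$tree)
  # all-distinct labels: peak at the all-singleton end of the scan
  distinct <- setNames(sim$tree$tip.label, sim$tree$tip.label)
  cal <- calibrate_cutoffs(rt, distinct, rank = "species")
  expect_equal(length(cut_at_red(rt, cal$cutoff)$clades), 40)
  # a single label is rejected
  same <- setNames(rep("p__X", 40), sim$tree$tip.label)
  expect_error(calibrate_cutoffs(rt, same, rank = "phylum"), "distinct")
})

test_that("averaging RED over rootings matches per-rooting recomputation", {
  sim <- simulate_yule_tree(20, seed = 41)
  tree <- sim$tree
  phyla <- split(sim$taxonomy$entity_id, sim$taxonomy$phylum)
  phyla <- phyla[lengths(phyla) < 20 & lengths(phyla) >= 1]
  expect_gte(length(phyla), 2) # planted tree provides several outgroups
  avg <- average_red_over_rootings(tree, phyla)
  # brute-force oracle: accumulate per-rooting RED tables keyed by tip set
  key_of <- function(tr, nd) {
    tips <- ape::extract.clade(tr, nd)$tip.label
    paste(sort(tips), collapse = "|")
  }
  acc <- list()
  for (og in phyla) {
    rr <- ape::root(tree, outgroup = og, resolve.root = TRUE)
    rred <- compute_red(rr)
    n_tip <- length(rr$tip.label)
    for (nd in (n_tip + 1L):(n_tip + rr$Nnode)) {
      tips <- ape::extract.clade(rr, nd)$tip.label
      if (all(tips %in% og)) next
      k <- paste(sort(tips), collapse = "|")
      acc[[k]] <- c(acc[[k]], rred$red[nd])
    }
  }
  n_tip <- length(tree$tip.label)
  for (nd in (n_tip + 2L):(n_tip + tree$Nnode)) {
    k <- key_of(tree, nd)
    if (!is.null(acc[[k]])) {
      expect_equal(avg$red[nd], mean(acc[[k]]), tolerance = 1e-12)
    }
  }
  expect_error(average_red_over_rootings(tree, list(tree$tip.label)),
               "entire tip set")
})

test_that("clade provenance labelling follows the reference > MAG > unbinned rule", {
  tab <- rbind(
    seq_table("cl1", source = c("PROGENOMES")),
    seq_table("cl2", source = "UNBINNED"),
    seq_table("cl3", source = "SPIRE_MAG"),
    seq_table("cl4", source = "UNBINNED"),
    seq_table("cl5", source = "UNBINNED"),
    seq_table("cl6", source = "UNBINNED")
  )
  tab$seq_id <- sprintf("v%03d", seq_len(nrow(tab)))
  part <- list(rank = "phylum", cutoff = 0.3, tolerance = 0.1,
               clades = list(c("cl1", "cl2"), c("cl3", "cl4"),
                             c("cl5", "cl6")),
               membership = setNames(rep(1:3, each = 2),
                                     sprintf("cl%d", 1:6)))
  class(part) <- "clade_partition"
  lab <- label_clade_sources(part, tab)
  expect_equal(lab$provenance, c("reference", "mag_only", "unbinned_only"))
  part$clades[[1]] <- c("cl1", "missing_tip")
  expect_error(label_clade_sources(part, tab), "without cluster mapping")
})

test_that("clade-count summaries take cross-marker medians and conserve totals", {
  mk_part <- function(n_ref, n_mag, n_unb) {
    n <- n_ref + n_mag + n_unb
    p <- list(rank = "phylum", cutoff = 0.3, tolerance = 0.1,
              clades = as.list(sprintf("t%d", seq_len(n))),
              membership = setNames(seq_len(n), sprintf("t%d", seq_len(n))),
              provenance = rep(c("reference", "mag_only", "unbinned_only"),
                               c(n_ref, n_mag, n_unb)))
    class(p) <- "clade_partition"
    p
  }
  parts <- list(
    mA = list(phylum = mk_part(20, 10, 6)),
    mB = list(phylum = mk_part(14, 6, 4)),
    mC = list(phylum = mk_part(30, 12, 6))
  )
  tab <- count_clades_by_level(parts)
  med <- function(cl) tab$median[tab$provenance == cl]
  expect_equal(med("reference"), 20)
  expect_equal(med("total"), 36) # median of {36, 24, 48}
  # totals = sum over provenance classes for every marker
  for (mk in names(parts)) {
    p <- parts[[mk]]$phylum
    expect_equal(length(p$clades), sum(table(p$provenance)))
  }
  one <- count_clades_by_level(parts["mA"])
  expect_equal(one$sd, rep(0, nrow(one)))
})

test_that("phylum subtree profiles report unbinned-to-genome tip ratios", {
  # hand-built tree: phylum clade holds 3 genome-backed and 3 unbinned tips
  tr <- ape::read.tree(
    text = "(((g1:1,g2:1):1,(g3:1,(u1:0.5,(u2:0.2,u3:0.2):0.3):0.5):1):2,(o1:1,o2:1):3);"
  )
  tab <- rbind(
    seq_table("g1", source = "PROGENOMES"),
    seq_table("g2", source = "GTDB"),
    seq_table("g3", source = "SPIRE_MAG"),
    seq_table("u1", source = "UNBINNED"),
    seq_table("u2", source = "UNBINNED"),
    seq_table("u3", source = "UNBINNED"),
    seq_table("o1", source = "PROGENOMES"),
    seq_table("o2", source = "GTDB")
  )
  tab$seq_id <- sprintf("w%03d", seq_len(nrow(tab)))
  rt <- compute_red(tr)
  labels <- c(g1 = "p__A", g2 = "p__A", g3 = "p__A", o1 = "p__B", o2 = "p__B")
  prof <- profile_phylum_subtrees(rt, labels, tab, n_rep = 1, frac = 1,
                                  seed = 1)
  expect_equal(prof$mean_unbinned_ratio[prof$phylum == "p__A"], 1) # 3/3
  expect_equal(prof$mean_unbinned_ratio[prof$phylum == "p__B"], 0)
  # all-genome trees always profile to ratio zero
  prof2 <- profile_phylum_subtrees(rt, labels, tab, n_rep = 3, frac = 0.8,
                                   seed = 2)
  expect_true(all(prof2$mean_unbinned_ratio[prof2$phylum == "p__B"] == 0))
})
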