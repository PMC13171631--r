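# List of descendant tip labels per node id (tips map to themselves).
descendant_tips <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  out <- vector("list", n_node)
  out[seq_len(n_tip)] <- as.list(tree$tip.label)
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(edges))) {
    p <- edges[i, 1L]
    ch <- edges[i, 2L]
    out[[p]] <- c(out[[p]], out[[ch]])
  }
  out
}

#' Relative evolutionary divergence (RED) of every node
#'
#' RED interpolates between 0 at the root and 1 at the tips:
#' `RED(node) = RED(parent) + (d/u) * (1 - RED(parent))`, where `d` is the
#' branch length to the parent and `u` is the mean branch-length distance
#' from the parent to all tips descending through the node (`u = d +` mean
#' node-to-tip distance). Tips are fixed at 1, the root at 0. Since
#' `d <= u`, RED is nondecreasing along every root-to-tip path. Zero-length
#' branches give `d/u = 0`, i.e. the child inherits the parent's RED;
#' multifurcations are supported natively.
#'
#' @param tree A rooted `phylo` with nonnegative branch lengths.
#' @return Object of class `red_tree`: list with `tree`, `red` (numeric per
#'   node id, tips first), `mean_tip_distance` (per node), `n_rootings`
#'   (1 for a single rooting).
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' compute_red(tr)$red  # root children at 0.5
#' @export
compute_red <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop_census("tree must be rooted")
  if (is.null(tree$edge.length)) stop_census("tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop_census("negative branch lengths")
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  root <- n_tip + 1L
  post <- ape::reorder.phylo(tree, "postorder")
  edges <- post$edge
  lens <- post$edge.length
  tip_count <- c(rep(1, n_tip), rep(0, tree$Nnode))
  tip_dist_sum <- numeric(n_node)
  for (i in seq_len(nrow(edges))) {
    p <- edges[i, 1L]
    ch <- edges[i, 2L]
    tip_count[p] <- tip_count[p] + tip_count[ch]
    tip_dist_sum[p] <- tip_dist_sum[p] + tip_dist_sum[ch] + lens[i] * tip_count[ch]
  }
  mean_tip <- tip_dist_sum / tip_count
  red <- numeric(n_node)
  red[root] <- 0
  for (i in rev(seq_len(nrow(edges)))) { # preorder
    p <- edges[i, 1L]
    ch <- edges[i, 2L]
    if (ch <= n_tip) {
      red[ch] <- 1
    } else {
      d <- lens[i]
      u <- d + mean_tip[ch]
      red[ch] <- if (u > 0) red[p] + (d / u) * (1 - red[p]) else red[p]
    }
  }
  out <- list(tree = tree, red = red, mean_tip_distance = mean_tip,
              n_rootings = rep(1L, n_node))
  class(out) <- "red_tree"
  out
}

#' @export
print.red_tree <- function(x, ...) {
  n_tip <- length(x$tree$tip.label)
  internal <- x$red[-seq_len(n_tip)]
  cat(sprintf(
    "RED-annotated tree: %d tips, %d internal nodes, internal RED %.3f..%.3f\n",
    n_tip, x$tree$Nnode, min(internal), max(internal)
  ))
  invisible(x)
}

# canonical key of a node = sorted descendant tip set
node_keys <- function(tree) {
  vapply(descendant_tips(tree), function(t) paste(sort(t), collapse = "\r"),
         character(1))
}

#' Average RED over alternative rootings
#'
#' Recomputes RED after re-rooting the tree on each supplied outgroup in
#' turn, then averages per node across rootings. Nodes are matched between
#' rootings by their descendant tip set; nodes lying inside the current
#' outgroup (tip set a subset of the outgroup) are ignored for that rooting,
#' and rootings in which a node is dissolved contribute nothing to its
#' average. Nodes never seen in any rooting keep their base-tree RED.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param outgroup_sets List of character vectors of tip labels; each must be
#'   a proper subset of the tips and resolvable as an outgroup.
#' @return A `red_tree` on the original topology with averaged RED and a
#'   per-node `n_rootings` count.
#' @export
average_red_over_rootings <- function(tree, outgroup_sets) {
  stopifnot(inherits(tree, "phylo"), length(outgroup_sets) >= 1)
  n_tip <- length(tree$tip.label)
  for (og in outgroup_sets) {
    if (length(setdiff(tree$tip.label, og)) == 0L) {
      stop_census("outgroup equals the entire tip set")
    }
    if (length(setdiff(og, tree$tip.label)) > 0L) {
      stop_census("outgroup contains unknown tips")
    }
  }
  base_keys <- node_keys(tree)
  acc <- stats::setNames(numeric(length(base_keys)), base_keys)
  nrt <- stats::setNames(integer(length(base_keys)), base_keys)
  for (og in outgroup_sets) {
    rerooted <- ape::root(tree, outgroup = og, resolve.root = TRUE)
    rt <- compute_red(rerooted)
    keys <- node_keys(rerooted)
    tips_by_node <- descendant_tips(rerooted)
    for (node in seq_along(keys)) {
      if (node <= length(rerooted$tip.label)) next
      if (all(tips_by_node[[node]] %in% og)) next # inside current outgroup
      k <- keys[node]
      if (k %in% base_keys) {
        acc[k] <- acc[k] + rt$red[node]
        nrt[k] <- nrt[k] + 1L
      }
    }
  }
  base <- compute_red(tree)
  red <- base$red
  internal <- (n_tip + 1L):(n_tip + tree$Nnode)
  seen <- nrt[base_keys[internal]] > 0
  red[internal][seen] <- (acc[base_keys[internal]] /
                            pmax(nrt[base_keys[internal]], 1L))[seen]
  red[n_tip + 1L] <- 0 # root of the reference topology stays at 0
  out <- list(tree = tree, red = red,
              mean_tip_distance = base$mean_tip_distance,
              n_rootings = unname(nrt[base_keys]))
  class(out) <- "red_tree"
  out
}

#' Cut a RED-annotated tree into rank-level clades
#'
#' Clade roots are the maximal (first-crossing) nodes with
#' `RED(node) >= cutoff` and `RED(parent) < cutoff` along each root-to-tip
#' path; because tips sit at RED 1, every tip falls under exactly one clade
#' root (tips not under any internal crossing become singleton clades). The
#' resulting clades always partition the tip set. The `tolerance` (default
#' 0.1) is metadata describing the calibration scan window around the cutoff;
#' it does not alter the cut itself.
#'
#' @param red_tree A `red_tree` from [compute_red()] or
#'   [average_red_over_rootings()].
#' @param cutoff RED cutoff in `[0, 1]`.
#' @param tolerance Scan-window half-width recorded with the partition.
#' @param rank Optional rank name recorded with the partition.
#' @return Object of class `clade_partition`: list with `rank`, `cutoff`,
#'   `tolerance`, `clades` (list of tip-label vectors), `roots` (node ids),
#'   `membership` (named integer vector tip -> clade index).
#' @export
cut_at_red <- function(red_tree, cutoff, tolerance = 0.1, rank = NA_character_) {
  stopifnot(inherits(red_tree, "red_tree"))
  if (cutoff < 0 || cutoff > 1) stop_census("cutoff must be in [0, 1]")
  tree <- red_tree$tree
  red <- red_tree$red
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  parent <- integer(n_tip + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  parent[root] <- root
  parent_red <- red[parent]
  parent_red[root] <- -Inf
  is_clade_root <- red >= cutoff & parent_red < cutoff
  roots <- which(is_clade_root)
  tips_below <- descendant_tips(tree)
  clades <- lapply(roots, function(nd) tips_below[[nd]])
  membership <- integer(n_tip)
  names(membership) <- tree$tip.label
  for (i in seq_along(clades)) {
    membership[clades[[i]]] <- i
  }
  if (any(membership == 0L)) stop_census("internal error: uncovered tips")
  out <- list(rank = rank, cutoff = cutoff, tolerance = tolerance,
              clades = clades, roots = roots, membership = membership)
  class(out) <- "clade_partition"
  out
}

#' @export
print.clade_partition <- function(x, ...) {
  cat(sprintf(
    "Clade partition (%s, cutoff %.3f): %d clades over %d tips\n",
    x$rank, x$cutoff, length(x$clades), length(x$membership)
  ))
  if (!is.null(x$provenance)) {
    print(table(x$provenance))
  }
  invisible(x)
}

#' Adjusted mutual information between two labellings
#'
#' Chance-corrected agreement between two partitions of the same elements:
#' `AMI = (MI - E[MI]) / (mean(H(a), H(b)) - E[MI])`, with the expected
#' mutual information taken under the hypergeometric model of random
#' labellings with fixed cluster sizes, and arithmetic-mean normalization.
#' 1 for identical partitions up to relabelling; about 0 for independent
#' partitions. The expectation is aggregated over unique cluster-size pairs,
#' so partitions with many equal-sized (e.g. singleton) clusters stay cheap.
#'
#' @param part_a,part_b Vectors of cluster labels over the same elements.
#' @return A single numeric score (<= 1).
#' @export
adjusted_mutual_information <- function(part_a, part_b) {
  if (length(part_a) != length(part_b)) stop_census("labelling size mismatch")
  n <- length(part_a)
  if (n == 0L) stop_census("empty labellings")
  a <- as.integer(factor(part_a))
  b <- as.integer(factor(part_b))
  tab <- table(a, b)
  ai <- rowSums(tab)
  bj <- colSums(tab)
  p <- tab / n
  nz <- p > 0
  mi <- sum(p[nz] * base::log(p[nz] / (outer(ai, bj) / n^2)[nz]))
  h <- function(sizes) {
    q <- sizes / n
    -sum(q * base::log(q))
  }
  ha <- h(ai)
  hb <- h(bj)
  # expected MI over unique size pairs
  ua <- table(ai)
  ub <- table(bj)
  emi <- 0
  for (ia in seq_along(ua)) {
    sa <- as.numeric(names(ua)[ia])
    for (ib in seq_along(ub)) {
      sb <- as.numeric(names(ub)[ib])
      lo <- max(1, sa + sb - n)
      hi <- min(sa, sb)
      if (hi < lo) next
      nij <- lo:hi
      logp <- lchoose(sb, nij) + lchoose(n - sb, sa - nij) - lchoose(n, sa)
      term <- sum((nij / n) * base::log(n * nij / (sa * sb)) * exp(logp))
      emi <- emi + as.numeric(ua[ia]) * as.numeric(ub[ib]) * term
    }
  }
  denom <- (ha + hb) / 2 - emi
  if (abs(denom) < 1e-12 * max(1, ha + hb)) {
    # degenerate normalization (e.g. both all-singletons or both trivial):
    # agreement is perfect iff MI attains its expectation-corrected maximum
    return(if (abs(mi - emi) < 1e-12 * max(1, abs(mi))) 1 else 0)
  }
  (mi - emi) / denom
}

#' Calibrate a RED cutoff against reference taxonomy labels
#'
#' Scans a grid of RED cutoffs, cuts the tree at each, restricts the
#' resulting partition to the labelled tips and scores it against the
#' reference labels at the focal rank by adjusted mutual information. The
#' selected cutoff attains the maximum AMI (midpoint of the maximal plateau
#' when several grid values tie), reported together with its `+/- tolerance`
#' window.
#'
#' @param red_tree A `red_tree`.
#' @param labels Named character vector, tip label -> taxon name at the focal
#'   rank (a subset of tips may be labelled; only those are scored), or a
#'   taxonomy data frame with columns `entity_id` and `rank`.
#' @param rank Rank name (used to extract the column when `labels` is a data
#'   frame, and recorded in the result).
#' @param grid_step Cutoff grid step (default 0.01).
#' @param tolerance Window half-width around the selected cutoff (default 0.1).
#' @return Object of class `calibration_result`: list with `rank`, `grid`,
#'   `ami`, `cutoff`, `window`, `n_labelled`.
#' @export
calibrate_cutoffs <- function(red_tree, labels, rank = NA_character_,
                              grid_step = 0.01, tolerance = 0.1) {
  stopifnot(inherits(red_tree, "red_tree"))
  if (is.data.frame(labels)) {
    if (!rank %in% names(labels)) stop_census("rank column '%s' missing", rank)
    labels <- stats::setNames(as.character(labels[[rank]]), labels$entity_id)
  }
  labels <- labels[!is.na(labels) & labels != ""]
  labels <- labels[names(labels) %in% red_tree$tree$tip.label]
  if (length(labels) == 0L) stop_census("no labelled tips on the tree")
  if (length(unique(labels)) < 2L) {
    stop_census("need >= 2 distinct labels at rank '%s'", rank)
  }
  grid <- seq(0, 1, by = grid_step)
  ami <- vapply(grid, function(cutoff) {
    part <- cut_at_red(red_tree, cutoff, tolerance = tolerance, rank = rank)
    adjusted_mutual_information(part$membership[names(labels)], labels)
  }, numeric(1))
  best <- max(ami)
  idx <- which(ami >= best - 1e-12)
  # middle of the maximal contiguous plateau containing the first maximum
  runs <- split(idx, cumsum(c(1, diff(idx) != 1)))
  run <- runs[[which.max(lengths(runs))]]
  sel <- grid[run[ceiling(length(run) / 2)]]
  out <- list(rank = rank, grid = grid, ami = ami, cutoff = sel,
              window = c(max(0, sel - tolerance), min(1, sel + tolerance)),
              n_labelled = length(labels))
  class(out) <- "calibration_result"
  out
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "RED calibration (%s): cutoff %.2f (window %.2f..%.2f), peak AMI %.4f over %d labelled tips\n",
    x$rank, x$cutoff, x$window[1L], x$window[2L], max(x$ami), x$n_labelled
  ))
  invisible(x)
}

#' Label clades by data provenance
#'
#' Classifies each clade of a partition from the data sources of its member
#' clusters (tips of the gene tree are cluster ids): `reference` if any
#' member sequence comes from an isolate reference or reference catalogue,
#' `mag_only` if none do but at least one study MAG is present, else
#' `unbinned_only`.
#'
#' @param partition A `clade_partition` whose tips are cluster ids.
#' @param table Sequence table providing per-cluster source labels.
#' @return The partition with an added `provenance` character vector (one
#'   class per clade).
#' @export
label_clade_sources <- function(partition, table) {
  stopifnot(inherits(partition, "clade_partition"))
  validate_sequence_table(table)
  src_by_cluster <- split(table$source, table$cluster_id)
  partition$provenance <- vapply(partition$clades, function(tips) {
    srcs <- src_by_cluster[tips]
    if (any(vapply(srcs, is.null, logical(1)))) {
      stop_census("tip(s) without cluster mapping: %s",
                  paste(utils::head(tips[vapply(srcs, is.null, logical(1))], 3),
                        collapse = ", "))
    }
    srcs <- unlist(srcs, use.names = FALSE)
    if (any(srcs %in% c("PROGENOMES", "GTDB"))) {
      "reference"
    } else if (any(srcs == "SPIRE_MAG")) {
      "mag_only"
    } else {
      "unbinned_only"
    }
  }, character(1))
  partition
}

#' Cross-marker clade-count table
#'
#' Summarizes clade counts per rank and provenance class across marker genes
#' as median and standard deviation (reported as 0 for a single marker).
#'
#' @param partitions Nested list: marker -> rank -> provenance-labelled
#'   `clade_partition` (see [label_clade_sources()]).
#' @return Data frame with columns `rank`, `provenance`, `median`, `sd`,
#'   `n_markers`; provenance includes `total`.
#' @export
count_clades_by_level <- function(partitions) {
  stopifnot(length(partitions) >= 1)
  classes <- c("reference", "mag_only", "unbinned_only", "total")
  rows <- list()
  ranks <- names(partitions[[1L]])
  for (rk in ranks) {
    counts <- sapply(partitions, function(per_marker) {
      part <- per_marker[[rk]]
      prov <- part$provenance %||% rep("total", length(part$clades))
      vapply(classes, function(cl) {
        if (cl == "total") length(part$clades) else sum(prov == cl)
      }, numeric(1))
    })
    counts <- matrix(counts, nrow = length(classes),
                     dimnames = list(classes, names(partitions)))
    for (cl in classes) {
      v <- counts[cl, ]
      rows[[length(rows) + 1L]] <- data.frame(
        rank = rk, provenance = cl,
        median = stats::median(v),
        sd = if (length(v) > 1) stats::sd(v) else 0,
        n_markers = length(v)
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Profile phylum subtrees for unbinned-to-genome tip ratios
#'
#' For each labelled phylum, repeatedly (`n_rep` times) takes a random subset
#' of `frac` of its genome-backed tips, finds their most recent common
#' ancestor, and profiles the subtree below it for the ratio of tips backed
#' only by unbinned sequences to genome-backed tips; repetitions damp the
#' effect of misplaced genomes. Values are averaged over repetitions.
#'
#' @param red_tree A `red_tree` (only the topology is used).
#' @param labels Named character vector, tip -> phylum, for genome-backed
#'   tips (or taxonomy data frame with `entity_id` and `phylum` columns).
#' @param table Sequence table: tips are cluster ids; a tip is genome-backed
#'   if its cluster contains any `PROGENOMES`, `GTDB` or `SPIRE_MAG`
#'   sequence.
#' @param n_rep Repetitions per phylum (default 5).
#' @param frac Fraction of genome-backed tips used for the MRCA (default 0.8).
#' @param seed Optional integer seed.
#' @return Data frame: `phylum`, `n_genome_tips`, `mean_subtree_tips`,
#'   `mean_unbinned_ratio`.
#' @export
profile_phylum_subtrees <- function(red_tree, labels, table, n_rep = 5,
                                    frac = 0.8, seed = NULL) {
  stopifnot(inherits(red_tree, "red_tree"))
  if (is.data.frame(labels)) {
    labels <- stats::setNames(as.character(labels$phylum), labels$entity_id)
  }
  validate_sequence_table(table)
  tree <- red_tree$tree
  cats <- cluster_source_categories(table)
  tip_cat <- cats[tree$tip.label]
  if (anyNA(tip_cat)) stop_census("tip(s) without cluster mapping")
  genome_backed <- tip_cat %in% c("PROGENOMES", "GTDB", "SPIRE_MAG")
  names(genome_backed) <- tree$tip.label
  labels <- labels[!is.na(labels) & labels != ""]
  labels <- labels[names(labels) %in% tree$tip.label[genome_backed[tree$tip.label]]]
  tips_below <- descendant_tips(tree)
  phyla <- unique(labels)
  local_seed(seed, {
    rows <- lapply(phyla, function(ph) {
      tips <- names(labels)[labels == ph]
      if (length(tips) < 2L) {
        stop_census("phylum '%s' has < 2 genome-backed labelled tips", ph)
      }
      ratios <- numeric(n_rep)
      sizes <- numeric(n_rep)
      for (r in seq_len(n_rep)) {
        k <- max(2L, ceiling(frac * length(tips)))
        sub <- if (k >= length(tips)) tips else sample(tips, k)
        mrca <- ape::getMRCA(tree, sub)
        st <- tips_below[[mrca]]
        gb <- sum(genome_backed[st])
        ub <- sum(!genome_backed[st])
        ratios[r] <- if (gb > 0) ub / gb else Inf
        sizes[r] <- length(st)
      }
      data.frame(phylum = ph, n_genome_tips = length(tips),
                 mean_subtree_tips = mean(sizes),
                 mean_unbinned_ratio = mean(ratios))
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
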