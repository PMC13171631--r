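# Small in-code fixtures shared across test files.

# Minimal sequence table builder; defaults give one UNBINNED metagenomic
# record per row with distinct contigs.
seq_table <- function(cluster_id, source = "UNBINNED",
                      sample_id = NULL, contig_id = NULL,
                      habitat = "habA", marker = "m1",
                      species_id = NULL, genome_id = NULL) {
  n <- length(cluster_id)
  source <- rep_len(source, n)
  if (is.null(sample_id)) sample_id <- sprintf("s%03d", seq_len(n))
  sample_id <- rep_len(sample_id, n)
  sample_id[source %in% c("PROGENOMES", "GTDB")] <- ""
  if (is.null(contig_id)) {
    contig_id <- ifelse(source == "UNBINNED", sprintf("ctg%03d", seq_len(n)), "")
  }
  habitat <- ifelse(sample_id == "", "", rep_len(habitat, n))
  out <- data.frame(
    seq_id = sprintf("q%04d", seq_len(n)),
    marker_gene = rep_len(marker, n),
    cluster_id = cluster_id,
    source = source,
    sample_id = sample_id,
    contig_id = rep_len(contig_id, n),
    habitat = habitat,
    stringsAsFactors = FALSE
  )
  if (!is.null(species_id)) out$species_id <- rep_len(species_id, n)
  if (!is.null(genome_id)) out$genome_id <- rep_len(genome_id, n)
  out
}

# Balanced depth-2 tree with unit branches: root children sit at RED 0.5.
balanced4 <- function() {
  ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
}

# 6-tip caterpillar with mixed branch lengths for hand-checked RED values.
caterpillar6 <- function() {
  ape::read.tree(
    text = "(t1:3,(t2:2.5,(t3:2,(t4:1.5,(t5:1,t6:0.5):0.5):0.75):0.25):1);"
  )
}

# Independent RED recomputation straight from the definition, using ape's
# pairwise distance matrix (no shared code with compute_red's recursion).
red_by_definition <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  dmat <- ape::dist.nodes(tree)
  parent <- integer(n_node)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  edge_len <- numeric(n_node)
  edge_len[tree$edge[, 2L]] <- tree$edge.length
  tips_below <- lapply(seq_len(n_node), function(nd) {
    if (nd <= n_tip) return(nd)
    which(vapply(seq_len(n_tip), function(tp) {
      cur <- tp
      repeat {
        if (cur == nd) return(TRUE)
        if (cur == n_tip + 1L) return(FALSE)
        cur <- parent[cur]
      }
    }, logical(1)))
  })
  red <- rep(NA_real_, n_node)
  red[n_tip + 1L] <- 0
  # repeatedly relax until all nodes have a value (order-free)
  while (anyNA(red)) {
    for (nd in seq_len(n_node)) {
      if (!is.na(red[nd]) || is.na(red[parent[nd]])) next
      if (nd <= n_tip) {
        red[nd] <- 1
      } else {
        d <- edge_len[nd]
        u <- d + mean(dmat[nd, tips_below[[nd]]])
        red[nd] <- red[parent[nd]] + (d / u) * (1 - red[parent[nd]])
      }
    }
  }
  red
}

# Analytic sample-based rarefaction expectation: for each cluster present in
# m_j of n samples, P(discovered in a random N-subset) follows the
# hypergeometric complement.
expected_richness_hypergeom <- function(sample_sets, N) {
  n <- length(sample_sets)
  clusters <- unique(unlist(sample_sets))
  sum(vapply(clusters, function(cl) {
    m <- sum(vapply(sample_sets, function(s) cl %in% s, logical(1)))
    1 - choose(n - m, N) / choose(n, N)
  }, numeric(1)))
}
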