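#' Synthetic world parameters
#'
#' Bundles and validates the parameters of the synthetic marker-gene census
#' generator: a fixed species pool with a long-tailed occupancy law, habitat
#' structure, per-species data-source tiers (isolate reference, reference
#' catalogue, study MAG, unbinned), several marker genes, sequence dropout and
#' a controllable cluster-to-species split rate (the ground-truth inverse of
#' the conversion factor).
#'
#' Defaults emulate a down-scaled cross-habitat survey: a species pool of
#' 2,000, lognormal occupancy with a heavy singleton fraction, three habitats
#' of unequal sampling depth, source-tier probabilities that put the large
#' majority of species beyond all genome catalogues, and a cluster split rate
#' slightly above 1 (marker-gene clustering near one cluster per species).
#'
#' @param n_species Number of species in the pool (>= 1).
#' @param occupancy_law List with element `law` in `"lognormal"`,
#'   `"log_series"` or `"uniform"` plus law parameters: `meanlog`/`sdlog`
#'   (lognormal occupancy probability, capped at 1), `theta` (logarithmic
#'   distribution of the number of occupied samples), or `p` (fixed occupancy
#'   probability; `p = 1` means always present).
#' @param n_samples_per_habitat Named integer vector, habitat -> sample count.
#' @param source_probs Named probabilities (summing to 1) that a species is
#'   tiered as `PROGENOMES`, `GTDB`, `SPIRE_MAG` or `UNBINNED`.
#' @param n_markers Number of marker genes.
#' @param marker_dropout Probability that a present species' gene is missed in
#'   a sample (per marker).
#' @param cluster_split_rate Expected gene clusters per species (> 0); the
#'   ground-truth conversion factor is `1 / cluster_split_rate`.
#' @param cross_habitat Relative occupancy weight of samples outside a
#'   species' home habitat (0..1).
#' @param mag_bin_prob Probability that a metagenomic sequence of a
#'   genome-tiered species is binned into a MAG (labelled `SPIRE_MAG`) rather
#'   than left unbinned.
#' @param seed Integer seed recorded in outputs.
#' @return Object of class `synthetic_world`.
#' @export
synthetic_world <- function(n_species = 2000,
                            occupancy_law = list(law = "lognormal",
                                                 meanlog = log(0.03),
                                                 sdlog = 1.5),
                            n_samples_per_habitat = c(human_gut = 150,
                                                      soil = 100,
                                                      freshwater = 80),
                            source_probs = c(PROGENOMES = 0.03,
                                             GTDB = 0.035,
                                             SPIRE_MAG = 0.115,
                                             UNBINNED = 0.82),
                            n_markers = 10,
                            marker_dropout = 0.05,
                            cluster_split_rate = 1.1,
                            cross_habitat = 0.1,
                            mag_bin_prob = 0.5,
                            seed = 1L) {
  if (n_species < 1) stop_census("n_species must be >= 1")
  if (length(n_samples_per_habitat) == 0L ||
      is.null(names(n_samples_per_habitat)) ||
      any(names(n_samples_per_habitat) == "")) {
    stop_census("n_samples_per_habitat must be a named vector with >= 1 habitat")
  }
  src <- c("PROGENOMES", "GTDB", "SPIRE_MAG", "UNBINNED")
  if (!setequal(names(source_probs), src)) {
    stop_census("source_probs must name exactly: %s", paste(src, collapse = ", "))
  }
  source_probs <- source_probs[src]
  if (any(source_probs < 0) || any(source_probs > 1) ||
      abs(sum(source_probs) - 1) > 1e-8) {
    stop_census("source_probs must be probabilities summing to 1")
  }
  if (marker_dropout < 0 || marker_dropout > 1) {
    stop_census("marker_dropout must be in [0, 1]")
  }
  if (cluster_split_rate <= 0) stop_census("cluster_split_rate must be > 0")
  if (!occupancy_law$law %in% c("lognormal", "log_series", "uniform")) {
    stop_census("unknown occupancy law '%s'", occupancy_law$law)
  }
  out <- list(
    n_species = as.integer(n_species),
    occupancy_law = occupancy_law,
    n_samples_per_habitat = n_samples_per_habitat,
    source_probs = source_probs,
    n_markers = as.integer(n_markers),
    marker_dropout = marker_dropout,
    cluster_split_rate = cluster_split_rate,
    cross_habitat = cross_habitat,
    mag_bin_prob = mag_bin_prob,
    seed = as.integer(seed)
  )
  class(out) <- "synthetic_world"
  out
}

#' Simulate a Simon preferential-attachment process
#'
#' At each of `n_steps` steps a new species arrives: with probability
#' `p_innovation` it founds a new clade of size 1; otherwise it joins an
#' existing clade chosen with probability proportional to the clade's current
#' size (rich-get-richer). The first step always founds a clade. For
#' `p_innovation < 1` the stationary clade-size law is Yule-Simon with
#' `rho = 1 / (1 - p_innovation)`.
#'
#' @param n_steps Number of species added (>= 1).
#' @param p_innovation Innovation probability in `[0, 1]`; `p = 0` grows a
#'   single seeded clade.
#' @param seed Optional integer seed.
#' @return A [clade_size_distribution()] whose subunits sum to `n_steps`.
#' @export
simulate_simon_clades <- function(n_steps, p_innovation, seed = NULL) {
  if (n_steps < 1) stop_census("n_steps must be >= 1 (empty distribution)")
  if (p_innovation < 0 || p_innovation > 1) {
    stop_census("p_innovation must be in [0, 1]")
  }
  n_steps <- as.integer(n_steps)
  local_seed(seed, {
    innovate <- stats::runif(n_steps) < p_innovation
    innovate[1L] <- TRUE
    # size-proportional choice == clade of a uniformly chosen earlier arrival
    pick <- 1L + as.integer(floor(stats::runif(n_steps) * (seq_len(n_steps) - 1L)))
    clade <- integer(n_steps)
    n_clades <- 0L
    for (t in seq_len(n_steps)) {
      if (innovate[t]) {
        n_clades <- n_clades + 1L
        clade[t] <- n_clades
      } else {
        clade[t] <- clade[pick[t]]
      }
    }
    d <- clade_size_distribution(tabulate(clade, nbins = n_clades))
    attr(d, "p_innovation") <- p_innovation
    attr(d, "seed") <- seed
    d
  })
}

#' Simulate a pure-birth tree with planted rank labels
#'
#' Grows a Yule (pure-birth, exponential waiting time) tree with `n_tips`
#' tips, then plants taxonomic ranks by cutting the true tree at fixed
#' fractions of total depth: for each rank, the clade roots are the first
#' nodes (or tip edges) crossing `fraction * depth` on each root-to-tip path,
#' and every tip below one root shares that root's label. Labels are therefore
#' internally consistent by construction, and independent of any RED
#' computation (planting uses true node depths only).
#'
#' @param n_tips Number of tips (>= 2).
#' @param seed Optional integer seed.
#' @param birth Birth rate of the pure-birth process.
#' @param rank_fractions Named increasing depth fractions in (0, 1) for the
#'   planted ranks.
#' @return List with elements `tree` (ultrametric `phylo`), `taxonomy` (data
#'   frame: `entity_id`, one column per rank, `taxonomy` GTDB-style string),
#'   `rank_fractions`, `clade_counts` (planted clades per rank), `seed`.
#' @export
simulate_yule_tree <- function(n_tips, seed = NULL, birth = 1,
                               rank_fractions = c(phylum = 0.20, class = 0.35,
                                                  order = 0.50, family = 0.65,
                                                  genus = 0.80)) {
  if (n_tips < 2) stop_census("n_tips must be >= 2")
  if (is.unsorted(rank_fractions, strictly = TRUE) ||
      any(rank_fractions <= 0) || any(rank_fractions >= 1)) {
    stop_census("rank_fractions must be strictly increasing within (0, 1)")
  }
  local_seed(seed, {
    tree <- ape::rphylo(n_tips, birth = birth, death = 0)
    depth <- ape::node.depth.edgelength(tree)
    total_depth <- max(depth[seq_len(n_tips)])
    tips_below <- descendant_tips(tree)
    parent <- integer(n_tips + tree$Nnode)
    parent[tree$edge[, 2L]] <- tree$edge[, 1L]
    root <- n_tips + 1L
    parent[root] <- root # root depth is 0 < threshold, so root never qualifies
    prefix <- c(phylum = "p__", class = "c__", order = "o__", family = "f__",
                genus = "g__")
    tax <- data.frame(entity_id = tree$tip.label, stringsAsFactors = FALSE)
    clade_counts <- integer(length(rank_fractions))
    names(clade_counts) <- names(rank_fractions)
    for (rk in names(rank_fractions)) {
      thr <- rank_fractions[[rk]] * total_depth
      roots <- which(depth >= thr & depth[parent] < thr)
      clade_counts[[rk]] <- length(roots)
      pf <- if (rk %in% names(prefix)) prefix[[rk]] else paste0(substr(rk, 1, 1), "__")
      lab <- rep(NA_character_, n_tips)
      for (i in seq_along(roots)) {
        lab[match(tips_below[[roots[i]]], tree$tip.label)] <-
          sprintf("%s%s%03d", pf, toupper(substr(rk, 1, 1)), i)
      }
      tax[[rk]] <- lab
    }
    rank_cols <- names(rank_fractions)
    tax$taxonomy <- apply(tax[, rank_cols, drop = FALSE], 1L,
                          function(r) paste(r, collapse = ";"))
    list(tree = tree, taxonomy = tax, rank_fractions = rank_fractions,
         clade_counts = clade_counts, seed = seed)
  })
}

# logarithmic-series sampler on 1..kmax (pmf proportional to theta^k / k)
rlogseries_trunc <- function(n, theta, kmax) {
  k <- seq_len(kmax)
  w <- exp(k * base::log(theta) - base::log(k))
  sample(k, n, replace = TRUE, prob = w)
}

#' Simulate a marker-gene cluster census
#'
#' Generates the sequence-level table every downstream stage consumes. Species
#' occurrence per sample follows the world's occupancy law with habitat
#' affinity; each present species contributes one sequence per marker per
#' sample unless dropped out; the species-to-cluster mapping is fixed per
#' marker with an expected `cluster_split_rate` clusters per species; source
#' tiers add genome-derived records (no sample) for reference-tiered species.
#' Deterministic under the world's seed.
#'
#' @param world A [synthetic_world()].
#' @return A sequence table (data frame with columns `seq_id`, `marker_gene`,
#'   `cluster_id`, `source`, `sample_id`, `contig_id`, `habitat`, plus the
#'   ground-truth column `species_id`), with a `truth` attribute carrying the
#'   per-species tiers, home habitats, the presence table and cluster maps.
#' @export
simulate_census <- function(world) {
  stopifnot(inherits(world, "synthetic_world"))
  local_seed(world$seed, {
    habs <- names(world$n_samples_per_habitat)
    n_sp <- world$n_species
    sp_id <- sprintf("sp%05d", seq_len(n_sp))
    tier <- sample(names(world$source_probs), n_sp, replace = TRUE,
                   prob = world$source_probs)
    home <- sample(habs, n_sp, replace = TRUE)
    samples <- unlist(lapply(habs, function(h) {
      sprintf("%s_s%04d", h, seq_len(world$n_samples_per_habitat[[h]]))
    }), use.names = FALSE)
    sample_hab <- rep(habs, times = world$n_samples_per_habitat)
    n_samp <- length(samples)

    law <- world$occupancy_law
    pres_sp <- integer(0)
    pres_samp <- integer(0)
    if (law$law == "log_series") {
      k_occ <- rlogseries_trunc(n_sp, law$theta %||% 0.95, n_samp)
      for (i in seq_len(n_sp)) {
        w <- ifelse(sample_hab == home[i], 1, world$cross_habitat)
        occ <- sample.int(n_samp, k_occ[i], prob = w)
        pres_sp <- c(pres_sp, rep.int(i, length(occ)))
        pres_samp <- c(pres_samp, occ)
      }
    } else {
      p <- switch(law$law,
        lognormal = pmin(stats::rlnorm(n_sp, law$meanlog %||% log(0.03),
                                       law$sdlog %||% 1.5), 1),
        uniform = rep(law$p %||% 1, n_sp)
      )
      # species x sample presence, habitat-weighted
      pm <- outer(p, rep(1, n_samp)) *
        (1 * (outer(home, sample_hab, "==")) +
           world$cross_habitat * (1 - outer(home, sample_hab, "==")))
      hit <- which(matrix(stats::runif(n_sp * n_samp), n_sp, n_samp) < pm,
                   arr.ind = TRUE)
      pres_sp <- hit[, 1L]
      pres_samp <- hit[, 2L]
    }
    o <- order(pres_sp, pres_samp)
    pres_sp <- pres_sp[o]
    pres_samp <- pres_samp[o]

    markers <- sprintf("marker%02d", seq_len(world$n_markers))
    # fixed species -> cluster map per marker
    n_clust <- matrix(1L + stats::rpois(n_sp * world$n_markers,
                                        world$cluster_split_rate - 1),
                      n_sp, world$n_markers)

    # metagenomic sequences: presence x marker, thinned by dropout
    n_pres <- length(pres_sp)
    rows <- vector("list", world$n_markers + 1L)
    for (m in seq_len(world$n_markers)) {
      keep <- if (world$marker_dropout > 0) {
        stats::runif(n_pres) >= world$marker_dropout
      } else rep(TRUE, n_pres)
      spi <- pres_sp[keep]
      smi <- pres_samp[keep]
      cl <- 1L + as.integer(floor(stats::runif(length(spi)) * n_clust[spi, m]))
      src <- ifelse(tier[spi] == "UNBINNED", "UNBINNED",
                    ifelse(stats::runif(length(spi)) < world$mag_bin_prob,
                           "SPIRE_MAG", "UNBINNED"))
      rows[[m]] <- data.frame(
        marker_gene = markers[m],
        cluster_id = sprintf("%s_%s_c%d", markers[m], sp_id[spi], cl),
        source = src,
        sample_id = samples[smi],
        contig_id = ifelse(src == "UNBINNED",
                           sprintf("%s_ctg_%s", samples[smi], sp_id[spi]), ""),
        habitat = sample_hab[smi],
        species_id = sp_id[spi],
        genome_id = "",
        stringsAsFactors = FALSE
      )
    }
    # genome-derived records for reference-tiered species; enough genomes to
    # realize every cluster of the species (round-robin assignment), so the
    # ground-truth conversion factor equals 1 / cluster_split_rate
    ref <- which(tier %in% c("PROGENOMES", "GTDB"))
    if (length(ref) > 0) {
      n_gen <- apply(n_clust[ref, , drop = FALSE], 1L, max) +
        stats::rpois(length(ref), 1)
      gsp <- rep.int(ref, n_gen * world$n_markers)
      gen_idx <- sequence(n_gen)
      gen_of <- sprintf("gen_%s_%d", sp_id[rep.int(ref, n_gen)], gen_idx)
      ggen <- rep.int(gen_of, world$n_markers)
      gm <- rep(seq_len(world$n_markers), each = sum(n_gen))
      cl <- 1L + (rep.int(gen_idx, world$n_markers) - 1L) %%
        n_clust[cbind(gsp, gm)]
      rows[[world$n_markers + 1L]] <- data.frame(
        marker_gene = markers[gm],
        cluster_id = sprintf("%s_%s_c%d", markers[gm], sp_id[gsp], cl),
        source = tier[gsp],
        sample_id = "",
        contig_id = "",
        habitat = "",
        species_id = sp_id[gsp],
        genome_id = ggen,
        stringsAsFactors = FALSE
      )
    }
    tab <- do.call(rbind, rows)
    tab <- cbind(seq_id = sprintf("seq%07d", seq_len(nrow(tab))), tab,
                 stringsAsFactors = FALSE)
    rownames(tab) <- NULL
    attr(tab, "truth") <- list(
      species_id = sp_id, tier = tier, home_habitat = home,
      presence = data.frame(species_id = sp_id[pres_sp],
                            sample_id = samples[pres_samp],
                            stringsAsFactors = FALSE),
      n_clusters = n_clust, markers = markers, samples = samples,
      sample_habitat = sample_hab, world = world
    )
    tab
  })
}

#' Simulate a species-discovery curve with known power law
#'
#' Builds a cumulative discovery curve whose marginal gains between
#' consecutive grid points follow `k * N^-gamma` evaluated at the geometric
#' midpoint of each interval, with multiplicative lognormal noise.
#' `noise_sd = 0` gives the exact law, so [fit_discovery_law()] recovers
#' `gamma` to machine precision.
#'
#' @param k Proportionality constant (> 0).
#' @param gamma Saturation coefficient.
#' @param grid Strictly increasing vector of sample counts.
#' @param noise_sd Standard deviation of the lognormal noise on marginals.
#' @param seed Optional integer seed.
#' @return A `rarefaction_curve` (single permutation, stratum `total`).
#' @export
simulate_discovery_curve <- function(k, gamma, grid, noise_sd = 0,
                                     seed = NULL) {
  if (k <= 0) stop_census("k must be > 0")
  if (length(grid) < 2 || is.unsorted(grid, strictly = TRUE)) {
    stop_census("grid must be strictly increasing with >= 2 points")
  }
  local_seed(seed, {
    mid <- sqrt(grid[-length(grid)] * grid[-1L])
    dN <- diff(grid)
    noise <- if (noise_sd > 0) {
      exp(stats::rnorm(length(mid), 0, noise_sd))
    } else rep(1, length(mid))
    marg <- k * mid^(-gamma) * noise
    if (any(marg <= 0)) stop_census("curve would decrease; rejected")
    cumulative <- cumsum(c(k * grid[1L]^(1 - gamma), marg * dN))
    new_rarefaction_curve(
      grid = grid,
      clusters = lapply(cumulative, function(v) {
        matrix(v, 1, 1, dimnames = list(NULL, "total"))
      }),
      conversion_factor = 1,
      marker = "synthetic", habitat = "global", seed = seed
    )
  })
}
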