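#' Logarithmic rarefaction grid
#'
#' Per decade `d >= 1`, multiples of `10^d` from `10^d` to `10^(d+1)`
#' (10, 20, ..., 100; 200, 300, ..., 1,000; ...), capped at and always
#' including `n_max`.
#'
#' @param n_max Largest sample (or sequence) count (>= 1).
#' @return Increasing integer vector.
#' @examples
#' log_grid(35)  # 10 20 30 35
#' @export
log_grid <- function(n_max) {
  if (n_max < 1) stop_census("n_max must be >= 1")
  n_max <- as.integer(n_max)
  g <- integer(0)
  d <- 1
  while (10^d <= n_max) {
    g <- c(g, as.integer(seq(10^d, 10^(d + 1), by = 10^d)))
    d <- d + 1
  }
  g <- unique(g[g <= n_max])
  if (length(g) == 0L || g[length(g)] != n_max) g <- c(g, n_max)
  g
}

new_rarefaction_curve <- function(grid, clusters, conversion_factor = 1,
                                  marker = NA_character_, habitat = "global",
                                  seed = NULL) {
  species <- lapply(clusters, function(m) m * conversion_factor)
  out <- list(grid = grid, clusters = clusters, species = species,
              conversion_factor = conversion_factor, marker = marker,
              habitat = habitat, seed = seed)
  class(out) <- "rarefaction_curve"
  out
}

#' Permutation-mean species (or cluster) counts of a rarefaction curve
#'
#' @param curve A `rarefaction_curve`.
#' @param stratum Stratum column name (default `"total"`).
#' @param what `"species"` (conversion-scaled) or `"clusters"`.
#' @return Numeric vector over the curve's grid.
#' @export
curve_means <- function(curve, stratum = "total", what = c("species", "clusters")) {
  what <- match.arg(what)
  vapply(curve[[what]], function(m) {
    if (!stratum %in% colnames(m)) stop_census("unknown stratum '%s'", stratum)
    mean(m[, stratum])
  }, numeric(1))
}

#' @export
print.rarefaction_curve <- function(x, ...) {
  tot <- curve_means(x, "total")
  cat(sprintf(
    "Rarefaction curve (marker %s, habitat %s): %d grid points, N = %g..%g, mean richness %.1f..%.1f\n",
    x$marker, x$habitat, length(x$grid), min(x$grid), max(x$grid),
    tot[1L], tot[length(tot)]
  ))
  invisible(x)
}

#' Sample-based rarefaction of a marker-gene cluster census
#'
#' Builds a species-discovery curve by subsampling metagenomic samples
#' without replacement along a logarithmic grid. Permutations are nested:
#' each permutation is one random ordering of all samples, truncated at each
#' grid point, so every permutation curve is nondecreasing by construction.
#' Discovered clusters are attributed hierarchically by
#' [assign_source_category()] evaluated on each cluster's full provenance
#' (including genome-derived members not tied to any sample), and converted
#' to species via the marker's conversion factor.
#'
#' @param table Sequence table.
#' @param marker Marker gene to rarefy.
#' @param habitat Optional habitat filter (character vector); `NULL` uses all
#'   samples ("global").
#' @param n_perm Number of random permutations per grid step (default 5).
#' @param seed Optional integer seed.
#' @param grid Optional custom grid (default [log_grid()] of the sample count).
#' @param conversion A `conversion_fit` (or bare factor) for cluster-to-species
#'   scaling; default 1 (curve in cluster units).
#' @param exhaustive If `TRUE`, enumerate all subsets at each grid point
#'   instead of drawing permutations (small designs only).
#' @return A `rarefaction_curve`; each grid point holds a matrix
#'   (permutations x strata) of discovered cluster counts, strata being the
#'   five provenance categories plus `total`.
#' @export
rarefy_samples <- function(table, marker, habitat = NULL, n_perm = 5,
                           seed = NULL, grid = NULL, conversion = 1,
                           exhaustive = FALSE) {
  validate_sequence_table(table)
  if (!marker %in% table$marker_gene) {
    stop_census("marker '%s' absent from table", marker)
  }
  mk <- table[table$marker_gene == marker, , drop = FALSE]
  meta <- mk[mk$sample_id != "", , drop = FALSE]
  if (!is.null(habitat)) meta <- meta[meta$habitat %in% habitat, , drop = FALSE]
  samples <- sort(unique(meta$sample_id))
  n <- length(samples)
  if (n < 1) stop_census("no samples left after filtering")
  if (is.null(grid)) grid <- log_grid(n)
  grid <- sort(unique(pmin(grid, n)))
  cat_map <- cluster_source_categories(mk)
  sample_clusters <- lapply(
    split(meta$cluster_id, factor(meta$sample_id, levels = samples)),
    unique
  )
  strata <- c(CATEGORY_LEVELS, "total")
  count_subset <- function(cl_ids) {
    cl <- unique(cl_ids)
    tab <- table(factor(cat_map[cl], levels = CATEGORY_LEVELS))
    c(as.integer(tab), length(cl))
  }
  factor_value <- if (inherits(conversion, "conversion_fit")) {
    conversion$factor
  } else as.numeric(conversion)
  clusters <- local_seed(seed, {
    if (exhaustive) {
      lapply(grid, function(N) {
        subsets <- utils::combn(n, N, simplify = FALSE)
        m <- t(vapply(subsets, function(idx) {
          count_subset(unlist(sample_clusters[idx], use.names = FALSE))
        }, numeric(length(strata))))
        colnames(m) <- strata
        m
      })
    } else {
      perms <- replicate(n_perm, sample.int(n), simplify = FALSE)
      lapply(grid, function(N) {
        m <- t(vapply(perms, function(p) {
          count_subset(unlist(sample_clusters[p[seq_len(N)]], use.names = FALSE))
        }, numeric(length(strata))))
        colnames(m) <- strata
        m
      })
    }
  })
  new_rarefaction_curve(grid, clusters, conversion_factor = factor_value,
                        marker = marker,
                        habitat = if (is.null(habitat)) "global"
                                  else paste(habitat, collapse = "+"),
                        seed = seed)
}

#' Cross-marker summary of rarefaction curves
#'
#' Summarizes a set of per-marker curves on a common grid: the median across
#' markers of the permutation-mean species count at each grid point (per
#' stratum), and the per-marker coefficient of variation (s.d. divided by
#' mean, over permutations) of the total species count at each grid point.
#'
#' @param curves List of `rarefaction_curve` objects with identical grids.
#' @return List with `grid`, `median` (matrix grid x strata), `cv` (matrix
#'   grid x markers), `markers`.
#' @export
summarize_across_markers <- function(curves) {
  stopifnot(length(curves) >= 1)
  grid <- curves[[1L]]$grid
  for (cv in curves) {
    if (!identical(cv$grid, grid)) stop_census("curves have mismatching grids")
  }
  strata <- colnames(curves[[1L]]$species[[1L]])
  med <- sapply(strata, function(st) {
    per_marker <- vapply(curves, curve_means, numeric(length(grid)),
                         stratum = st)
    apply(matrix(per_marker, nrow = length(grid)), 1L, stats::median)
  })
  med <- matrix(med, nrow = length(grid), dimnames = list(NULL, strata))
  cvm <- vapply(curves, function(cv) {
    vapply(cv$species, function(m) {
      tot <- m[, "total"]
      mu <- mean(tot)
      if (mu == 0 || length(tot) < 2) 0 else stats::sd(tot) / mu
    }, numeric(1))
  }, numeric(length(grid)))
  cvm <- matrix(cvm, nrow = length(grid),
                dimnames = list(NULL, vapply(curves, function(cv) cv$marker,
                                             character(1))))
  list(grid = grid, median = med, cv = cvm,
       markers = colnames(cvm))
}

#' Incremental habitat-stratified accumulation
#'
#' Appends samples habitat block by habitat block in a given order (discovery
#' order randomized within each block) and tracks cumulative discovered
#' clusters; the per-habitat increment is the number of clusters first
#' discovered within that habitat's block. Increments depend on the order,
#' but always sum to the total richness.
#'
#' @param table Sequence table.
#' @param habitat_order Character vector covering every habitat present.
#' @param marker Marker gene.
#' @param seed Optional integer seed.
#' @return List with `per_sample` (data frame: `sample_id`, `habitat`,
#'   `n_new`, `cumulative`), `increments` (named vector per habitat),
#'   `total`.
#' @export
incremental_habitat_accumulation <- function(table, habitat_order, marker,
                                             seed = NULL) {
  validate_sequence_table(table)
  meta <- table[table$marker_gene == marker & table$sample_id != "", ,
                drop = FALSE]
  if (nrow(meta) == 0L) stop_census("marker '%s' has no metagenomic records", marker)
  present <- unique(meta$habitat)
  if (length(setdiff(present, habitat_order)) > 0) {
    stop_census("habitat_order does not cover habitat(s): %s",
                paste(setdiff(present, habitat_order), collapse = ", "))
  }
  if (length(setdiff(habitat_order, present)) > 0) {
    stop_census("unknown habitat(s) in order: %s",
                paste(setdiff(habitat_order, present), collapse = ", "))
  }
  sample_hab <- tapply(meta$habitat, meta$sample_id, function(h) h[1L])
  local_seed(seed, {
    ordered_samples <- unlist(lapply(habitat_order, function(h) {
      s <- names(sample_hab)[sample_hab == h]
      if (length(s) > 1) sample(s) else s
    }), use.names = FALSE)
    sample_clusters <- lapply(
      split(meta$cluster_id, meta$sample_id), unique
    )
    seen <- character(0)
    n_new <- integer(length(ordered_samples))
    for (i in seq_along(ordered_samples)) {
      cl <- sample_clusters[[ordered_samples[i]]]
      new <- setdiff(cl, seen)
      n_new[i] <- length(new)
      seen <- c(seen, new)
    }
    habs <- unname(sample_hab[ordered_samples])
    per_sample <- data.frame(
      sample_id = ordered_samples, habitat = habs,
      n_new = n_new, cumulative = cumsum(n_new),
      stringsAsFactors = FALSE
    )
    increments <- vapply(habitat_order, function(h) {
      sum(n_new[habs == h])
    }, numeric(1))
    list(per_sample = per_sample, increments = increments,
         total = length(seen))
  })
}
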