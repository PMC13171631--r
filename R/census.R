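SOURCE_LEVELS <- c("PROGENOMES", "GTDB", "SPIRE_MAG", "UNBINNED")
CATEGORY_LEVELS <- c("PROGENOMES", "GTDB", "SPIRE_MAG",
                     "UNBINNED_NONSINGLETON", "UNBINNED_ALL")

validate_sequence_table <- function(table, require_species = FALSE) {
  need <- c("seq_id", "marker_gene", "cluster_id", "source", "sample_id",
            "contig_id", "habitat")
  miss <- setdiff(need, names(table))
  if (length(miss) > 0) {
    stop_census("sequence table is missing column(s): %s",
                paste(miss, collapse = ", "))
  }
  bad <- !table$source %in% SOURCE_LEVELS
  if (any(bad)) {
    stop_census("unknown source value(s) at row(s) %s",
                paste(utils::head(which(bad), 5), collapse = ", "))
  }
  if (require_species && !"species_id" %in% names(table)) {
    stop_census("sequence table lacks a species_id column")
  }
  invisible(table)
}

#' Hierarchical provenance category of a cluster
#'
#' Assigns a marker-gene cluster to one of five hierarchically ordered data
#' provenance categories from the sources of its member sequences: isolate
#' reference (`PROGENOMES`) if any member is from proGenomes-type isolate
#' genomes, irrespective of other members; else reference catalogue (`GTDB`);
#' else study MAG (`SPIRE_MAG`); else unbinned, split into non-singletons
#' (`UNBINNED_NONSINGLETON`, at least two sequences from different contigs)
#' and the remainder (`UNBINNED_ALL`, unconfirmed singletons). The
#' assignment only depends on the set of members, not their order.
#'
#' @param cluster Data frame of the cluster's member sequence records (needs
#'   columns `source` and `contig_id`).
#' @return A single category string (one of the five levels).
#' @seealso [cluster_source_categories()] for the vectorized per-cluster map.
#' @export
assign_source_category <- function(cluster) {
  if (NROW(cluster) == 0L) stop_census("empty cluster")
  src <- cluster$source
  if (any(src == "PROGENOMES")) {
    return("PROGENOMES")
  }
  if (any(src == "GTDB")) {
    return("GTDB")
  }
  if (any(src == "SPIRE_MAG")) {
    return("SPIRE_MAG")
  }
  contigs <- unique(cluster$contig_id[cluster$contig_id != ""])
  if (length(contigs) >= 2L) "UNBINNED_NONSINGLETON" else "UNBINNED_ALL"
}

#' Provenance category per cluster, vectorized
#'
#' @param table Sequence table (possibly restricted to one marker gene).
#' @return Named character vector, cluster_id -> category.
#' @export
cluster_source_categories <- function(table) {
  validate_sequence_table(table)
  cl <- factor(table$cluster_id)
  has <- function(source) {
    tapply(table$source == source, cl, any)
  }
  n_contigs <- tapply(
    ifelse(table$contig_id == "", NA_character_,
           table$contig_id),
    cl, function(x) length(unique(x[!is.na(x)]))
  )
  out <- ifelse(has("PROGENOMES"), "PROGENOMES",
         ifelse(has("GTDB"), "GTDB",
         ifelse(has("SPIRE_MAG"), "SPIRE_MAG",
         ifelse(n_contigs >= 2L, "UNBINNED_NONSINGLETON", "UNBINNED_ALL"))))
  stats::setNames(as.character(out), levels(cl))
}

# zero-intercept least-squares slope (number_of_species ~ number_of_clusters)
origin_slope <- function(x, y) {
  sxx <- sum(as.numeric(x)^2)
  if (sxx == 0) stop_census("all cluster counts zero; cannot fit slope")
  slope <- sum(as.numeric(x) * as.numeric(y)) / sxx
  resid <- y - slope * x
  se <- if (length(x) > 1) {
    sqrt(sum(resid^2) / (length(x) - 1) / sxx)
  } else NA_real_
  list(slope = slope, std_error = se)
}

#' Estimate a gene-cluster-to-species conversion factor
#'
#' Downsamples the marker's genome-derived sequences along a logarithmic grid
#' (`n_iter` iterations per grid size), recording at each draw the number of
#' discovered gene clusters and the number of species they represent, then
#' fits the zero-intercept regression `species ~ clusters` (slope
#' `sum(xy)/sum(x^2)`, forced through the origin). The slope is the number of
#' newly discovered species per newly discovered marker-gene cluster.
#'
#' @param table Sequence table.
#' @param species_labels Named character vector, `seq_id` -> species, for
#'   every genome-derived sequence of the marker (defaults to the table's own
#'   `species_id` column when present).
#' @param marker Marker gene name.
#' @param n_iter Downsampling iterations per grid step (default 10).
#' @param seed Optional integer seed.
#' @param sources Which data sources count as genome-derived for this fit;
#'   fit each source individually to mirror per-catalogue factors.
#' @param unit Downsampling unit: `"sequence"` (default) draws individual
#'   gene sequences; `"genome"` draws whole genomes (a `genome_id` column is
#'   required) so that all sequences of a genome are co-sampled.
#' @param grid Optional custom grid of subsample sizes.
#' @return Object of class `conversion_fit` with elements `marker_gene`,
#'   `factor`, `std_error`, `n_points`.
#' @export
estimate_conversion_factor <- function(table, species_labels = NULL, marker,
                                       n_iter = 10, seed = NULL,
                                       sources = c("PROGENOMES", "GTDB",
                                                   "SPIRE_MAG"),
                                       unit = c("sequence", "genome"),
                                       grid = NULL) {
  validate_sequence_table(table)
  unit <- match.arg(unit)
  rows <- table[table$marker_gene == marker & table$source %in% sources, ,
                drop = FALSE]
  if (nrow(rows) == 0L) stop_census("marker '%s' absent from table", marker)
  if (is.null(species_labels)) {
    if (!"species_id" %in% names(rows)) {
      stop_census("no species labels: supply species_labels or a species_id column")
    }
    sp <- rows$species_id
  } else {
    sp <- unname(species_labels[rows$seq_id])
  }
  if (anyNA(sp) || any(sp == "")) {
    stop_census("every genome-derived sequence of marker '%s' needs a species label",
                marker)
  }
  if (unit == "genome") {
    if (!"genome_id" %in% names(rows) || any(rows$genome_id == "")) {
      stop_census("unit = 'genome' requires a nonempty genome_id column")
    }
    units <- split(seq_len(nrow(rows)), rows$genome_id)
  } else {
    units <- as.list(seq_len(nrow(rows)))
  }
  n_units <- length(units)
  if (is.null(grid)) grid <- log_grid(n_units)
  grid <- grid[grid <= n_units]
  pts_x <- numeric(0)
  pts_y <- numeric(0)
  local_seed(seed, {
    for (N in grid) {
      for (it in seq_len(n_iter)) {
        idx <- unlist(units[sample.int(n_units, N)], use.names = FALSE)
        pts_x <- c(pts_x, length(unique(rows$cluster_id[idx])))
        pts_y <- c(pts_y, length(unique(sp[idx])))
      }
    }
  })
  if (length(unique(pts_x[pts_x > 0])) < 3) {
    stop_census("fewer than 3 distinct grid points with nonzero cluster counts")
  }
  fit <- origin_slope(pts_x, pts_y)
  out <- list(marker_gene = marker, factor = fit$slope,
              std_error = fit$std_error, n_points = length(pts_x))
  class(out) <- "conversion_fit"
  out
}

#' @export
print.conversion_fit <- function(x, ...) {
  cat(sprintf(
    "Conversion fit (%s): %.4f species per gene cluster (s.e. %.2e, %d points)\n",
    x$marker_gene, x$factor, x$std_error, x$n_points
  ))
  invisible(x)
}

#' Convert cluster counts to species estimates
#'
#' Per-marker species estimate = discovered clusters times the marker's
#' conversion factor; the cross-marker summary is the median and standard
#' deviation.
#'
#' @param cluster_counts Named numeric vector, marker -> cluster count.
#' @param fits Named list of `conversion_fit` objects (or bare factors),
#'   marker -> fit; must cover the same marker set.
#' @return List with `per_marker` (named estimates), `median`, `sd`.
#' @export
estimate_species_counts <- function(cluster_counts, fits) {
  if (length(cluster_counts) == 0L) stop_census("empty marker set")
  markers <- names(cluster_counts)
  if (!setequal(markers, names(fits))) {
    stop_census("cluster_counts and fits must cover the same markers")
  }
  fac <- vapply(fits[markers], function(f) {
    if (inherits(f, "conversion_fit")) f$factor else as.numeric(f)
  }, numeric(1))
  est <- cluster_counts * fac
  list(per_marker = est,
       median = stats::median(est),
       sd = if (length(est) > 1) stats::sd(est) else 0)
}

#' Filter marker genes by cross-marker consistency
#'
#' Drops markers flagged as redundant (shared between domain marker sets and
#' prone to cross-mapping), then drops markers whose species estimate deviates
#' from the median (computed over the non-redundant markers) by more than
#' `max_dev` (default 20%).
#'
#' @param estimates Named numeric vector, marker -> species estimate.
#' @param redundant Character vector of marker names to drop a priori.
#' @param max_dev Maximum allowed relative deviation from the median.
#' @return Character vector of retained marker names.
#' @export
filter_marker_genes <- function(estimates, redundant = character(),
                                max_dev = 0.2) {
  if (length(estimates) < 3) stop_census("need >= 3 markers")
  keep <- setdiff(names(estimates), redundant)
  if (length(keep) == 0L) stop_census("all markers dropped as redundant")
  med <- stats::median(estimates[keep])
  ok <- keep[abs(estimates[keep] - med) / med <= max_dev]
  if (length(ok) == 0L) stop_census("all markers dropped by the %g%% deviation filter",
                                    100 * max_dev)
  ok
}
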