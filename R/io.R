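#' Read and write marker-gene sequence tables
#'
#' Tab-separated with header; schema: `seq_id`, `marker_gene`, `cluster_id`,
#' `source`, `sample_id`, `contig_id`, `habitat` (empty string for
#' inapplicable fields; genome-derived records carry no sample). Unknown
#' source or habitat values and duplicate sequence ids are rejected with the
#' offending line numbers. Extra columns (e.g. ground-truth `species_id`)
#' are preserved on read and optionally written.
#'
#' @param path File path.
#' @param habitats Optional declared habitat list; metagenomic records with
#'   habitats outside it are rejected.
#' @return A validated sequence table (data frame).
#' @export
read_sequences_tsv <- function(path, habitats = NULL) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "",
                           na.strings = NULL)
  validate_sequence_table(tab)
  dup <- duplicated(tab$seq_id)
  if (any(dup)) {
    stop_census("duplicate seq_id '%s' at line %d",
                tab$seq_id[which(dup)[1L]], which(dup)[1L] + 1L)
  }
  bad_contig <- tab$source == "UNBINNED" & tab$contig_id == ""
  if (any(bad_contig)) {
    stop_census("UNBINNED record(s) without contig_id at line(s) %s",
                paste(utils::head(which(bad_contig) + 1L, 5), collapse = ", "))
  }
  meta <- tab$sample_id != ""
  if (!is.null(habitats)) {
    bad <- meta & !tab$habitat %in% habitats
    if (any(bad)) {
      stop_census("undeclared habitat value(s) at line(s) %s",
                  paste(utils::head(which(bad) + 1L, 5), collapse = ", "))
    }
  }
  tab
}

#' @rdname read_sequences_tsv
#' @param table Sequence table to write.
#' @param include_truth Also write generator ground-truth columns
#'   (`species_id`, `genome_id`) when present.
#' @export
write_sequences_tsv <- function(table, path, include_truth = FALSE) {
  validate_sequence_table(table)
  cols <- c("seq_id", "marker_gene", "cluster_id", "source", "sample_id",
            "contig_id", "habitat")
  if (include_truth) {
    cols <- c(cols, intersect(c("species_id", "genome_id"), names(table)))
  }
  utils::write.table(table[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a taxonomy table
#'
#' Tab-separated with columns `entity_id` and `taxonomy`, the latter a
#' GTDB-style rank string (`d__...;p__...;c__...;o__...;f__...;g__...;s__...`).
#' Missing trailing ranks are tolerated. Returns one column per rank plus
#' the original string.
#'
#' @param path File path.
#' @return Data frame with columns `entity_id`, `domain`, `phylum`, `class`,
#'   `order`, `family`, `genus`, `species`, `taxonomy`.
#' @export
read_taxonomy_tsv <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "",
                           na.strings = NULL)
  for (col in c("entity_id", "taxonomy")) {
    if (!col %in% names(tab)) stop_census("taxonomy table lacks column '%s'", col)
  }
  cbind(tab["entity_id"], parse_gtdb_taxonomy(tab$taxonomy),
        taxonomy = tab$taxonomy, stringsAsFactors = FALSE)
}

#' Parse GTDB-style taxonomy strings
#'
#' @param x Character vector of `;`-separated rank strings with one-letter
#'   prefixes (`d__`, `p__`, ...). Unrecognized or missing ranks yield `NA`.
#' @return Data frame with one column per canonical rank.
#' @export
parse_gtdb_taxonomy <- function(x) {
  ranks <- c(d = "domain", p = "phylum", c = "class", o = "order",
             f = "family", g = "genus", s = "species")
  out <- matrix(NA_character_, nrow = length(x), ncol = length(ranks),
                dimnames = list(NULL, unname(ranks)))
  parts <- strsplit(x, ";", fixed = TRUE)
  for (i in seq_along(parts)) {
    for (p in parts[[i]]) {
      p <- trimws(p)
      if (nchar(p) < 3 || substr(p, 2, 3) != "__") next
      key <- substr(p, 1, 1)
      if (key %in% names(ranks) && nchar(p) > 3) {
        out[i, ranks[[key]]] <- p
      }
    }
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Read a newick tree
#'
#' Standard newick via \pkg{ape}; multifurcations, quoted labels and internal
#' node labels are supported. Trees without branch lengths are rejected when
#' `require_lengths = TRUE` (RED mode needs them).
#'
#' @param path File path (or a newick string via `text`).
#' @param text Optional newick string instead of a file.
#' @param require_lengths Reject trees without branch lengths (default TRUE).
#' @return An ape `phylo`.
#' @export
read_newick_tree <- function(path = NULL, text = NULL, require_lengths = TRUE) {
  tree <- if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
  if (is.null(tree)) stop_census("could not parse newick input")
  if (require_lengths && is.null(tree$edge.length)) {
    stop_census("tree has no branch lengths (required for RED)")
  }
  tree
}

default_pipeline_config <- function() {
  list(
    seed = 1L,
    outdir = "cladecensus_run",
    world = list(
      n_species = 300,
      n_samples_per_habitat = c(human_gut = 40, soil = 30, freshwater = 20),
      n_markers = 3,
      occupancy_law = list(law = "lognormal", meanlog = log(0.08), sdlog = 1.2),
      cluster_split_rate = 1.1
    ),
    n_perm = 5,
    conversion_n_iter = 10,
    tree = list(n_tips = 150),
    red = list(grid_step = 0.01, tolerance = 0.1),
    habitat_order = NULL,
    fit_mode = "marginal"
  )
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]])) {
      base[[k]] <- merge_config(base[[k]], override[[k]])
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' Pipeline configuration
#'
#' Builds a full pipeline configuration by merging user overrides (an R list
#' or a YAML file path) into the defaults: a small three-habitat synthetic
#' world, five rarefaction permutations, ten conversion iterations, a
#' 150-tip calibration tree and a 0.01 RED grid.
#'
#' @param config Named list of overrides, or path to a YAML file, or `NULL`.
#' @return Config list with a `config_hash` fingerprint.
#' @export
pipeline_config <- function(config = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_pipeline_config(), config %||% list())
  if (!is.null(cfg$world$n_samples_per_habitat)) {
    cfg$world$n_samples_per_habitat <- unlist(cfg$world$n_samples_per_habitat)
  }
  cfg$world$seed <- cfg$seed
  # hash the scientific configuration only (output location excluded)
  cfg$config_hash <- content_hash(paste(deparse(
    cfg[setdiff(names(cfg), c("config_hash", "outdir"))]
  ), collapse = ""))
  cfg
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full synthetic-census pipeline
#'
#' Orchestrates every stage on a synthetic world with known ground truth:
#' census generation, per-marker conversion-factor estimation, global and
#' habitat-stratified rarefaction, discovery-law fits, RED computation and
#' calibration on a planted-rank tree per marker, clade cutting with
#' provenance labelling and clade-count summaries, and Willis / Yule-Simon
#' fits of the resulting clade-size distributions. All stages derive their
#' seeds from the single config seed, so a rerun with the same config is
#' byte-identical. Writes all result tables as TSV plus a JSON manifest
#' (config hash, seed, per-file fingerprints) into `config$outdir`.
#'
#' @param config See [pipeline_config()].
#' @return Invisibly, a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- pipeline_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  world <- do.call(synthetic_world, cfg$world)
  habitats <- names(world$n_samples_per_habitat)
  if (!is.null(cfg$habitat_order) &&
      !setequal(cfg$habitat_order, habitats)) {
    stop_census("stage habitat_order: order must cover exactly the world's habitats")
  }
  files <- character(0)
  stage <- function(name, code) {
    message(sprintf("[cladecensus] stage %s", name))
    tryCatch(code, error = function(e) {
      stop_census("stage %s failed: %s", name, conditionMessage(e))
    })
  }

  census <- stage("census", simulate_census(world))
  files["sequences"] <- write_tsv(
    census[, c("seq_id", "marker_gene", "cluster_id", "source", "sample_id",
               "contig_id", "habitat")],
    file.path(cfg$outdir, "sequences.tsv")
  )
  markers <- attr(census, "truth")$markers

  fits <- stage("conversion", {
    out <- lapply(seq_along(markers), function(i) {
      estimate_conversion_factor(census, marker = markers[i],
                                 n_iter = cfg$conversion_n_iter,
                                 seed = cfg$seed * 1000L + i)
    })
    names(out) <- markers
    out
  })
  files["conversion_fits"] <- write_tsv(
    data.frame(
      marker_gene = markers,
      factor = vapply(fits, `[[`, numeric(1), "factor"),
      std_error = vapply(fits, `[[`, numeric(1), "std_error"),
      n_points = vapply(fits, `[[`, integer(1), "n_points")
    ),
    file.path(cfg$outdir, "conversion_fits.tsv")
  )

  curves <- stage("rarefaction", {
    out <- list()
    for (i in seq_along(markers)) {
      for (hab in c(list(NULL), as.list(habitats))) {
        cv <- rarefy_samples(census, markers[i], habitat = hab,
                             n_perm = cfg$n_perm,
                             seed = cfg$seed * 2000L + i,
                             conversion = fits[[markers[i]]])
        out[[length(out) + 1L]] <- cv
      }
    }
    out
  })
  files["curves"] <- write_tsv(
    do.call(rbind, lapply(curves, function(cv) {
      do.call(rbind, lapply(seq_along(cv$grid), function(gi) {
        m <- cv$clusters[[gi]]
        data.frame(
          marker_gene = cv$marker, habitat = cv$habitat, N = cv$grid[gi],
          permutation = rep(seq_len(nrow(m)), ncol(m)),
          stratum = rep(colnames(m), each = nrow(m)),
          clusters = as.vector(m),
          species = as.vector(m) * cv$conversion_factor
        )
      }))
    })),
    file.path(cfg$outdir, "curves.tsv")
  )

  disc <- stage("discovery_fit", {
    lapply(curves, function(cv) {
      tryCatch(fit_discovery_law(cv, mode = cfg$fit_mode),
               error = function(e) NULL)
    })
  })
  disc <- disc[!vapply(disc, is.null, logical(1))]
  files["discovery_fits"] <- write_tsv(
    do.call(rbind, lapply(disc, function(f) {
      data.frame(
        habitat = f$habitat, stratum = f$stratum, marker_gene = f$marker_gene,
        k = f$k, gamma = f$gamma, alpha = f$alpha, r2 = f$r_squared,
        class = classify_saturation(f)
      )
    })),
    file.path(cfg$outdir, "discovery_fits.tsv")
  )

  red_out <- stage("red", {
    per_marker <- list()
    for (i in seq_along(markers)) {
      clusters_i <- sort(unique(census$cluster_id[census$marker_gene == markers[i]]))
      n_tips <- min(cfg$tree$n_tips, length(clusters_i))
      sim <- simulate_yule_tree(n_tips, seed = cfg$seed * 3000L + i)
      sim$tree$tip.label <- clusters_i[seq_len(n_tips)]
      sim$taxonomy$entity_id <- sim$tree$tip.label
      rt <- compute_red(sim$tree)
      ranks <- names(sim$rank_fractions)
      calib <- lapply(ranks, function(rk) {
        calibrate_cutoffs(rt, stats::setNames(sim$taxonomy[[rk]],
                                              sim$taxonomy$entity_id),
                          rank = rk, grid_step = cfg$red$grid_step,
                          tolerance = cfg$red$tolerance)
      })
      names(calib) <- ranks
      parts <- lapply(calib, function(cl) {
        label_clade_sources(cut_at_red(rt, cl$cutoff,
                                       tolerance = cfg$red$tolerance,
                                       rank = cl$rank), census)
      })
      per_marker[[markers[i]]] <- list(sim = sim, red = rt, calib = calib,
                                       parts = parts)
    }
    per_marker
  })
  files["red_values"] <- write_tsv(
    do.call(rbind, lapply(names(red_out), function(mk) {
      rt <- red_out[[mk]]$red
      n_tip <- length(rt$tree$tip.label)
      data.frame(marker_gene = mk,
                 node = seq_along(rt$red),
                 is_tip = seq_along(rt$red) <= n_tip,
                 red = rt$red,
                 n_rootings = rt$n_rootings)
    })),
    file.path(cfg$outdir, "red_values.tsv")
  )
  files["calibration"] <- write_tsv(
    do.call(rbind, lapply(names(red_out), function(mk) {
      do.call(rbind, lapply(red_out[[mk]]$calib, function(cl) {
        data.frame(marker_gene = mk, rank = cl$rank, cutoff = cl$grid,
                   ami = cl$ami, selected = cl$grid == cl$cutoff)
      }))
    })),
    file.path(cfg$outdir, "calibration.tsv")
  )
  files["partitions"] <- write_tsv(
    do.call(rbind, lapply(names(red_out), function(mk) {
      do.call(rbind, lapply(red_out[[mk]]$parts, function(part) {
        data.frame(marker_gene = mk, rank = part$rank, cutoff = part$cutoff,
                   clade_id = rep(seq_along(part$clades),
                                  lengths(part$clades)),
                   tip = unlist(part$clades, use.names = FALSE),
                   provenance = rep(part$provenance, lengths(part$clades)))
      }))
    })),
    file.path(cfg$outdir, "partitions.tsv")
  )
  clade_counts <- count_clades_by_level(
    lapply(red_out, function(x) x$parts)
  )
  files["clade_counts"] <- write_tsv(
    clade_counts, file.path(cfg$outdir, "clade_counts.tsv")
  )

  laws <- stage("clade_laws", {
    rows <- list()
    for (mk in names(red_out)) {
      parts <- red_out[[mk]]$parts
      pairs <- list(
        c("phylum", "genus"),
        c("family", "genus"),
        c("genus", NA)
      )
      for (pr in pairs) {
        dist <- tryCatch({
          if (is.na(pr[2L])) {
            sizes_from_partitions(parts[[pr[1L]]])
          } else {
            sizes_from_partitions(parts[[pr[1L]]], parts[[pr[2L]]])
          }
        }, error = function(e) NULL)
        if (is.null(dist) || total_clades(dist) < 2) next
        ys <- fit_yule_simon(dist)
        wl <- tryCatch(fit_willis(dist), error = function(e) NULL)
        rows[[length(rows) + 1L]] <- data.frame(
          marker_gene = mk, stratum = "global", parent_rank = pr[1L],
          child_unit = if (is.na(pr[2L])) "species-tip" else pr[2L],
          omega = if (is.null(wl)) NA_real_ else wl$omega,
          a = if (is.null(wl)) NA_real_ else wl$a,
          r2 = if (is.null(wl)) NA_real_ else wl$r_squared,
          rho = ys$rho, se = ys$std_error, n_clades = ys$n_clades
        )
      }
    }
    do.call(rbind, rows)
  })
  files["law_fits"] <- write_tsv(laws, file.path(cfg$outdir, "law_fits.tsv"))

  manifest <- list(
    package = "cladecensus",
    version = as.character(utils::packageVersion("cladecensus")),
    seed = cfg$seed,
    config_hash = cfg$config_hash,
    files = lapply(files, function(f) {
      list(path = basename(f),
           hash = content_hash(readBin(f, "raw", file.info(f)$size)))
    })
  )
  manifest_path <- file.path(cfg$outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(config = cfg, census = census, conversion = fits,
                 curves = curves, discovery = disc, red = red_out,
                 clade_counts = clade_counts, laws = laws,
                 manifest = manifest, files = c(files, manifest = manifest_path)))
}
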