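#' Clade-size distributions
#'
#' A clade-size distribution records, for each observed clade size `S` (number
#' of subunits a clade contains: species-level tips, or subclades at the next
#' rank down), the number of clades `C` of that size. It is the common currency
#' between tree partitions, flat taxonomies, the Simon preferential-attachment
#' generator and the Willis / Yule-Simon fitting routines.
#'
#' @param sizes Integer vector of raw clade sizes (one entry per clade), or
#'   `NULL` if `size`/`count` are given directly.
#' @param size,count Parallel vectors giving the distribution in tabulated
#'   form (`count[i]` clades of size `size[i]`). Ignored when `sizes` is given.
#' @param parent_rank,child_unit,stratum Optional metadata: the rank of the
#'   counted clades, the unit they are counted in (`"species-tip"` or
#'   `"subclade"`), and the stratum (habitat, phylum, or `"global"`).
#'
#' @return An object of class `clade_size_dist`: a data frame with columns
#'   `size` and `count` (sorted by size, zero counts dropped) and metadata
#'   attributes.
#' @examples
#' d <- clade_size_distribution(c(1, 1, 1, 2, 2, 5))
#' total_clades(d)    # 6
#' total_subunits(d)  # 12
#' @export
clade_size_distribution <- function(sizes = NULL, size = NULL, count = NULL,
                                    parent_rank = NA_character_,
                                    child_unit = NA_character_,
                                    stratum = "global") {
  if (!is.null(sizes)) {
    if (length(sizes) == 0L) {
      stop_census("empty clade-size distribution: no clades supplied")
    }
    if (any(sizes < 1)) stop_census("clade sizes must be >= 1")
    tab <- table(sizes)
    size <- as.numeric(names(tab)) # numeric: heavy tails overflow int range
    count <- as.integer(tab)
    o <- order(size)
    size <- size[o]
    count <- count[o]
  } else {
    if (is.null(size) || is.null(count) || length(size) != length(count)) {
      stop_census("supply either `sizes` or parallel `size`/`count` vectors")
    }
    keep <- count > 0
    size <- as.numeric(size[keep])
    count <- as.integer(count[keep])
    if (length(size) == 0L) {
      stop_census("empty clade-size distribution: no clades supplied")
    }
    if (any(size < 1)) stop_census("clade sizes must be >= 1")
    if (anyDuplicated(size)) stop_census("duplicated sizes in distribution")
    o <- order(size)
    size <- size[o]
    count <- count[o]
  }
  out <- data.frame(size = size, count = count)
  attr(out, "parent_rank") <- parent_rank
  attr(out, "child_unit") <- child_unit
  attr(out, "stratum") <- stratum
  class(out) <- c("clade_size_dist", "data.frame")
  out
}

#' @rdname clade_size_distribution
#' @param x A `clade_size_dist` object.
#' @export
total_clades <- function(x) sum(x$count)

#' @rdname clade_size_distribution
#' @export
total_subunits <- function(x) sum(as.numeric(x$size) * x$count)

#' @export
print.clade_size_dist <- function(x, ...) {
  cat(sprintf(
    "Clade-size distribution: %d clades, %g subunits, sizes %g..%g\n",
    total_clades(x), total_subunits(x), min(x$size), max(x$size)
  ))
  if (!is.na(attr(x, "parent_rank"))) {
    cat(sprintf(
      "  rank: %s; unit: %s; stratum: %s\n",
      attr(x, "parent_rank"), attr(x, "child_unit"), attr(x, "stratum")
    ))
  }
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("  ... %d more sizes\n", nrow(x) - 10L))
  invisible(x)
}
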