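#' Yule-Simon probability mass function
#'
#' Stationary clade-size law of a preferential-attachment (rich-get-richer)
#' process: `f(S) = rho * B(S, rho + 1)`, with `B` the beta function. Computed
#' in log space via `lbeta` for numerical stability. Low `rho` means heavier
#' tails (stronger preferential attachment, more dominance by few large
#' clades); for large sizes the pmf approximates a power law with exponent
#' `rho + 1`.
#'
#' @param size Integer vector of clade sizes (>= 1).
#' @param rho Shape parameter (> 0).
#' @param log If `TRUE`, return log-probabilities.
#' @return Numeric vector of (log-)probabilities.
#' @examples
#' yule_simon_pmf(1, 1)  # 0.5
#' yule_simon_pmf(2, 1)  # 1/6
#' @export
yule_simon_pmf <- function(size, rho, log = FALSE) {
  if (any(size < 1) || any(size != floor(size))) {
    stop_census("`size` must be integer >= 1")
  }
  if (length(rho) != 1L || !is.finite(rho) || rho <= 0) {
    stop_census("`rho` must be a single positive number")
  }
  lp <- base::log(rho) + lbeta(size, rho + 1)
  if (log) lp else exp(lp)
}

#' Sample from the Yule-Simon distribution
#'
#' Uses the exact mixture representation: draw `u ~ Beta(rho, 1)` and then
#' `K ~ 1 + Geometric(u)`, which has marginal pmf `rho * B(k, rho + 1)`.
#'
#' @param n Number of draws.
#' @param rho Shape parameter (> 0).
#' @param seed Optional integer seed.
#' @return Integer vector of clade sizes.
#' @export
ryule_simon <- function(n, rho, seed = NULL) {
  if (rho <= 0) stop_census("`rho` must be positive")
  local_seed(seed, {
    u <- stats::rbeta(n, rho, 1)
    k <- stats::rgeom(n, prob = u) + 1L
    # astronomically small u can overflow rgeom; fall back to inverse cdf tail
    bad <- is.na(k)
    if (any(bad)) k[bad] <- .Machine$integer.max
    k
  })
}

#' Maximum-likelihood fit of the Yule-Simon distribution
#'
#' Maximizes `sum(count * log(rho * B(size, rho + 1)))` over `rho > 0` by
#' bracketed one-dimensional optimization in `log(rho)`. The standard error is
#' taken from the observed information (numerical second derivative at the
#' optimum). A sample in which every clade is a singleton pushes the MLE to
#' the `rho -> Inf` boundary and is reported as degenerate rather than fitted.
#'
#' @param dist A [clade_size_distribution()].
#' @param interval Search interval for `rho` (default `[1e-4, 1e4]`).
#' @return Object of class `yule_simon_fit` with elements `rho`,
#'   `log_likelihood`, `std_error`, `n_clades`, `degenerate`.
#' @export
fit_yule_simon <- function(dist, interval = c(1e-4, 1e4)) {
  stopifnot(inherits(dist, "clade_size_dist"))
  s <- dist$size
  cnt <- dist$count
  n_clades <- sum(cnt)
  if (n_clades < 2) stop_census("need at least 2 clades to fit")
  out <- list(
    rho = NA_real_, log_likelihood = NA_real_, std_error = NA_real_,
    n_clades = n_clades, degenerate = FALSE
  )
  class(out) <- "yule_simon_fit"
  if (all(s == 1L)) {
    out$rho <- Inf
    out$degenerate <- TRUE
    return(out)
  }
  ll <- function(rho) sum(cnt * (base::log(rho) + lbeta(s, rho + 1)))
  opt <- stats::optimize(
    function(lr) -ll(exp(lr)),
    interval = base::log(interval), tol = 1e-10
  )
  rho <- exp(opt$minimum)
  out$rho <- rho
  out$log_likelihood <- -opt$objective
  h <- max(1e-5, rho * 1e-4)
  d2 <- (ll(rho + h) - 2 * ll(rho) + ll(rho - h)) / h^2
  if (is.finite(d2) && d2 < 0) out$std_error <- sqrt(-1 / d2)
  out
}

#' @export
print.yule_simon_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("Yule-Simon fit: degenerate (all clades singletons, rho -> Inf)\n")
  } else {
    cat(sprintf(
      "Yule-Simon fit: rho = %.4f (s.e. %.4f), logLik = %.2f, n = %d clades\n",
      x$rho, x$std_error, x$log_likelihood, x$n_clades
    ))
  }
  invisible(x)
}

#' Willis power-law fit of a clade-size distribution
#'
#' Fits `C = a * S^-omega` by ordinary least squares of `log(C)` on `log(S)`
#' over the observed sizes (sizes with zero count are absent from the
#' distribution and hence excluded). `omega` is the negative slope in the
#' log-log plot; positive `omega` means large clades are exponentially rarer
#' than small ones.
#'
#' The default fits raw (unbinned) frequencies. For heavy-tailed samples the
#' scattered count-one tail flattens the raw log-log slope; the
#' `binning = "log"` option aggregates sizes into geometric bins (counts
#' divided by bin width, placed at the bin's geometric mean), which tracks
#' the tail exponent much more faithfully and is the mode to use when
#' comparing `omega` with the Yule-Simon asymptotics (`omega ~ rho + 1`).
#'
#' @param dist A [clade_size_distribution()].
#' @param binning `"none"` (default: raw log-log OLS) or `"log"`
#'   (geometric binning with base `bin_ratio`).
#' @param bin_ratio Geometric bin width for `binning = "log"` (default 2).
#' @param min_size Truncation flag: drop sizes below this value before
#'   fitting (default 1 = no truncation). Tail (asymptotic) comparisons use
#'   a head trim, since the Yule-Simon pmf only approaches its power-law
#'   asymptote for larger sizes.
#' @return Object of class `willis_fit` with elements `a`, `omega`,
#'   `r_squared`, `n_sizes`, `binning`.
#' @examples
#' d <- clade_size_distribution(size = c(1, 2, 4, 8), count = c(8, 4, 2, 1))
#' fit_willis(d)  # omega = 1, a = 8
#' @export
fit_willis <- function(dist, binning = c("none", "log"), bin_ratio = 2,
                       min_size = 1) {
  stopifnot(inherits(dist, "clade_size_dist"))
  binning <- match.arg(binning)
  if (min_size > 1) {
    keep <- dist$size >= min_size
    if (sum(keep) < 3) stop_census("fewer than 3 sizes above min_size")
    dist <- clade_size_distribution(size = dist$size[keep],
                                    count = dist$count[keep])
  }
  if (binning == "log") {
    bin <- floor(base::log(dist$size) / base::log(bin_ratio))
    lo <- bin_ratio^unique(sort(bin))
    width <- pmax(ceiling(bin_ratio^(unique(sort(bin)) + 1)) - ceiling(lo), 1)
    cnt <- as.numeric(tapply(dist$count, bin, sum))
    ctr <- as.numeric(tapply(rep(dist$size, dist$count), rep(bin, dist$count),
                             function(s) exp(mean(base::log(s)))))
    df <- data.frame(size = ctr, count = cnt / width)
  } else {
    df <- data.frame(size = as.numeric(dist$size), count = as.numeric(dist$count))
  }
  if (nrow(df) < 3) stop_census("need >= 3 distinct sizes for a Willis fit")
  fit <- stats::lm(log(count) ~ log(size), data = df)
  r2 <- suppressWarnings(summary(fit)$r.squared)
  out <- list(
    a = exp(unname(coef(fit)[1L])),
    omega = -unname(coef(fit)[2L]),
    r_squared = r2,
    n_sizes = nrow(df),
    binning = binning
  )
  class(out) <- "willis_fit"
  out
}

#' @export
print.willis_fit <- function(x, ...) {
  cat(sprintf(
    "Willis fit: omega = %.4f, a = %.4f, R^2 = %.4f over %d sizes\n",
    x$omega, x$a, x$r_squared, x$n_sizes
  ))
  invisible(x)
}

#' Clade sizes from nested partitions
#'
#' Counts, for each clade of the `parent` partition, how many child units it
#' contains: nested clades of a finer `child` partition, or species-level tips
#' when `child` is `NULL`.
#'
#' @param parent A `clade_partition` (see [cut_at_red()]).
#' @param child Optional finer `clade_partition`; must refine `parent` (every
#'   child clade nested inside one parent clade).
#' @return A [clade_size_distribution()].
#' @export
sizes_from_partitions <- function(parent, child = NULL) {
  stopifnot(inherits(parent, "clade_partition"))
  if (is.null(child)) {
    return(clade_size_distribution(
      lengths(parent$clades),
      parent_rank = parent$rank %||% NA_character_,
      child_unit = "species-tip"
    ))
  }
  stopifnot(inherits(child, "clade_partition"))
  parent_of_tip <- parent$membership
  counts <- integer(length(parent$clades))
  for (tips in child$clades) {
    pid <- unique(parent_of_tip[tips])
    if (anyNA(pid)) stop_census("child partition contains tips absent from parent")
    if (length(pid) != 1L) {
      stop_census("partitions are not nested: a child clade spans %d parent clades",
                  length(pid))
    }
    counts[pid] <- counts[pid] + 1L
  }
  clade_size_distribution(
    counts,
    parent_rank = parent$rank %||% NA_character_,
    child_unit = "subclade"
  )
}

#' Clade sizes from a flat taxonomy table
#'
#' Counts distinct `child_rank` names per `parent_rank` name in a flat
#' taxonomy table (one row per entity, one column per rank). Empty strings,
#' `NA`s and bare GTDB-style rank prefixes (`"p__"` etc.) are treated as
#' unlabelled placeholders and excluded.
#'
#' @param taxonomy Data frame with columns named after ranks.
#' @param parent_rank,child_rank Column names.
#' @return A [clade_size_distribution()].
#' @export
sizes_from_taxonomy_table <- function(taxonomy, parent_rank, child_rank) {
  for (rk in c(parent_rank, child_rank)) {
    if (!rk %in% names(taxonomy)) stop_census("rank column '%s' missing", rk)
  }
  p <- as.character(taxonomy[[parent_rank]])
  ch <- as.character(taxonomy[[child_rank]])
  unlabelled <- function(x) is.na(x) | x == "" | grepl("^[a-z]__$", x)
  keep <- !unlabelled(p) & !unlabelled(ch)
  if (!any(keep)) stop_census("no labelled (%s, %s) pairs", parent_rank, child_rank)
  sizes <- tapply(ch[keep], p[keep], function(v) length(unique(v)))
  clade_size_distribution(
    as.integer(sizes),
    parent_rank = parent_rank, child_unit = child_rank
  )
}

#' Stratified Yule-Simon fits
#'
#' Refits the Yule-Simon shape parameter within strata (habitats or phyla).
#' Each stratum holds one clade-size distribution per marker gene; `rho` is
#' fitted per marker and summarized as the median across markers. Strata with
#' fewer than `min_clades` clades (or only degenerate fits) are skipped with a
#' warning.
#'
#' @param dists_by_stratum Named list: stratum -> list of
#'   [clade_size_distribution()] objects (one per marker gene).
#' @param min_clades Minimum clades per distribution (default 2).
#' @return Data frame with columns `stratum`, `rho`, `n_markers`.
#' @export
stratified_fits <- function(dists_by_stratum, min_clades = 2) {
  stopifnot(is.list(dists_by_stratum), length(dists_by_stratum) > 0)
  rows <- lapply(names(dists_by_stratum), function(st) {
    dists <- dists_by_stratum[[st]]
    if (inherits(dists, "clade_size_dist")) dists <- list(dists)
    rhos <- vapply(dists, function(d) {
      if (total_clades(d) < min_clades) {
        return(NA_real_)
      }
      f <- fit_yule_simon(d)
      if (f$degenerate) NA_real_ else f$rho
    }, numeric(1))
    rhos <- rhos[is.finite(rhos)]
    if (length(rhos) == 0L) {
      warning(sprintf("stratum '%s' skipped: <%d clades or degenerate fits",
                      st, min_clades), call. = FALSE)
      return(NULL)
    }
    data.frame(stratum = st, rho = stats::median(rhos), n_markers = length(rhos))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop_census("no stratum could be fitted")
  rownames(out) <- NULL
  out
}
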