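#' Fit the species-discovery power law
#'
#' Fits `S = k * N^-gamma`, where `S` is the number of newly discovered
#' species per `N` samples added to the survey. Marginal gains are computed
#' between consecutive grid points of the permutation-mean cumulative curve,
#' placed at the geometric midpoint of each interval (unbiased on a log grid),
#' and `gamma`/`k` are estimated by least squares of `log(dS/dN)` on
#' `log(N)`. The species discovery coefficient is `alpha = 1 - gamma`.
#'
#' Zero marginal gains are excluded from the log-log regression; if more than
#' half of the intervals are zero (or all of them), the curve is treated as
#' empirically saturated and a saturated sentinel (`alpha = 0`,
#' `saturated = TRUE`) is returned instead of a regression fit.
#'
#' An alternative `mode = "cumulative"` fits `log(C)` on `log(N)` directly
#' (Heaps-style integrated form, slope `1 - gamma`) for cross-checking.
#'
#' @param curve A `rarefaction_curve`.
#' @param stratum Stratum to fit (default `"total"`).
#' @param mode `"marginal"` (default) or `"cumulative"`.
#' @return Object of class `discovery_fit` with elements `k`, `gamma`,
#'   `alpha`, `r_squared`, `n_points`, `stratum`, `habitat`, `marker_gene`,
#'   `saturated`, `mode`.
#' @export
fit_discovery_law <- function(curve, stratum = "total",
                              mode = c("marginal", "cumulative")) {
  stopifnot(inherits(curve, "rarefaction_curve"))
  mode <- match.arg(mode)
  y <- curve_means(curve, stratum)
  N <- as.numeric(curve$grid)
  out <- list(k = NA_real_, gamma = NA_real_, alpha = NA_real_,
              r_squared = NA_real_, n_points = 0L, stratum = stratum,
              habitat = curve$habitat, marker_gene = curve$marker,
              saturated = FALSE, mode = mode)
  class(out) <- "discovery_fit"
  if (mode == "cumulative") {
    if (any(y <= 0)) stop_census("cumulative mode needs positive counts")
    fit <- stats::lm(log(y) ~ log(N))
    slope <- unname(coef(fit)[2L])
    out$gamma <- 1 - slope
    out$alpha <- slope
    out$k <- exp(unname(coef(fit)[1L])) * slope
    out$r_squared <- suppressWarnings(summary(fit)$r.squared)
    out$n_points <- length(N)
    return(out)
  }
  dS <- diff(y)
  dN <- diff(N)
  if (any(dS < -1e-9)) stop_census("curve is not nondecreasing")
  mid <- sqrt(N[-length(N)] * N[-1L])
  pos <- dS > 0
  if (!any(pos) || mean(!pos) > 0.5) {
    out$saturated <- TRUE
    out$gamma <- 1
    out$alpha <- 0
    return(out)
  }
  if (sum(pos) < 4) {
    stop_census("need >= 4 grid intervals with positive marginal gains (have %d)",
                sum(pos))
  }
  lx <- log(mid[pos])
  ly <- log(dS[pos] / dN[pos])
  fit <- stats::lm(ly ~ lx)
  out$gamma <- -unname(coef(fit)[2L])
  out$k <- exp(unname(coef(fit)[1L]))
  out$alpha <- alpha_from_gamma(out$gamma)
  out$r_squared <- suppressWarnings(summary(fit)$r.squared)
  out$n_points <- sum(pos)
  out
}

#' @export
print.discovery_fit <- function(x, ...) {
  if (x$saturated) {
    cat(sprintf("Discovery fit (%s, %s): saturated (alpha <= 0)\n",
                x$marker_gene, x$habitat))
  } else {
    cat(sprintf(
      "Discovery fit (%s, %s, %s): k = %.4g, gamma = %.4f, alpha = %.4f, R^2 = %.4f (%d points)\n",
      x$marker_gene, x$habitat, x$stratum, x$k, x$gamma, x$alpha,
      x$r_squared, x$n_points
    ))
  }
  invisible(x)
}

#' Species discovery coefficient from the saturation coefficient
#'
#' `alpha = 1 - gamma`; `alpha` scales on `(-Inf, 1]`.
#'
#' @param gamma Saturation coefficient(s).
#' @return `1 - gamma`.
#' @export
alpha_from_gamma <- function(gamma) 1 - gamma

#' Classify a discovery coefficient
#'
#' `alpha <= 0`: discovery is saturated (adding samples of the same kind is
#' not expected to add species, analogous to a closed pangenome);
#' `0 < alpha < threshold`: open (discovery continues but slows down);
#' `alpha >= threshold` (default 0.8): virtually no slowdown in discovery.
#'
#' @param alpha Discovery coefficient(s) (or a `discovery_fit`).
#' @param threshold Near-unsaturated threshold (default 0.8).
#' @return Character vector in `saturated`, `open`, `near_unsaturated`.
#' @export
classify_saturation <- function(alpha, threshold = 0.8) {
  if (inherits(alpha, "discovery_fit")) {
    if (alpha$saturated) return("saturated")
    alpha <- alpha$alpha
  }
  if (any(alpha > 1 + 1e-9)) stop_census("alpha must be <= 1")
  ifelse(alpha <= 0, "saturated",
         ifelse(alpha < threshold, "open", "near_unsaturated"))
}
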