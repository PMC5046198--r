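#' Inputs for the relative scan likelihoods
#'
#' Bundles the per-zone and total counts of the two Bernoulli series. The
#' genomic application has a shared masked support, so `n1 = n2 = n_Z` and
#' `N1 = N2 = N`, but the likelihoods are implemented generally with
#' per-series trial counts.
#'
#' @param x1,x2 in-zone success counts.
#' @param n1,n2 in-zone trial counts (`0 < n_i < N_i`).
#' @param X1,X2 total success counts.
#' @param N1,N2 total trial counts.
#' @return A list of class `rel_inputs`.
#' @export
rel_inputs <- function(x1, n1, X1, N1, x2, n2, X2, N2) {
  v <- lapply(list(x1 = x1, n1 = n1, X1 = X1, N1 = N1, x2 = x2, n2 = n2,
                   X2 = X2, N2 = N2), as.numeric)
  with(v, {
    if (any(n1 <= 0) || any(n1 >= N1) || any(n2 <= 0) || any(n2 >= N2))
      stop("in-zone trial counts must satisfy 0 < n_i < N_i")
    if (any(x1 < 0) || any(x1 > pmin(n1, X1)) ||
        any(x2 < 0) || any(x2 > pmin(n2, X2)))
      stop("success counts must satisfy 0 <= x_i <= min(n_i, X_i)")
    if (any(X1 - x1 > N1 - n1) || any(X2 - x2 > N2 - n2))
      stop("out-zone successes cannot exceed out-zone trials")
  })
  structure(v, class = "rel_inputs")
}

# Unconstrained per-series log-likelihood at the closed-form MLEs
# p_hat = x/n, q_hat = (X - x)/(N - n); vectorized.
.loglik1_series <- function(x, n, X, N) {
  p <- x / n
  q <- (X - x) / (N - n)
  .xlogy(x, p) + .xlogy(n - x, 1 - p) + .xlogy(X - x, q) +
    .xlogy((N - n) - (X - x), 1 - q)
}

#' Unconstrained (alternative) log-likelihood for a zone
#'
#' The two series are independent, so the joint likelihood is the product
#' of two Bernoulli scan likelihoods and its supremum is attained at the
#' closed-form estimates `p_i = x_i / n_i`, `q_i = (X_i - x_i) /
#' (N_i - n_i)` for each series separately (no one-sided branching: the
#' alternative is unconstrained).
#'
#' @param inputs a [rel_inputs()].
#' @return The log-likelihood supremum under the alternative.
#' @export
loglik_h1 <- function(inputs) {
  stopifnot(inherits(inputs, "rel_inputs"))
  with(inputs, .loglik1_series(x1, n1, X1, N1) +
         .loglik1_series(x2, n2, X2, N2))
}

#' Constrained (null) fit: shared in-zone rate multiplier
#'
#' Maximizes the null log-likelihood in which both series share one in-zone
#' multiplier `k` (`p_i = k * q_i`). No closed form exists, so the fit is
#' numerical: for fixed `k` the conditional maximizer of each `q_i` is the
#' feasible root of a quadratic, and the resulting profile over `log k` is
#' maximized by a coarse grid plus golden-section refinement (bracket
#' `k` in `[1e-9, 1e9]`, refined beyond 1e-13 in `log k`). Fits that end on
#' the `k` bracket edge (for example zones with no in-zone successes, where
#' the maximizer degenerates to `k -> 0`) are flagged as boundary fits.
#'
#' @param inputs a [rel_inputs()] (fields may be vectors of equal length
#'   for batch fitting; totals must be scalars).
#' @return A list with `k`, `q1`, `q2` (constrained estimates), `ll0` (the
#'   maximized null log-likelihood) and logical `boundary`; each vectorized
#'   along the zones.
#' @export
fit_h0 <- function(inputs) {
  stopifnot(inherits(inputs, "rel_inputs"))
  if (length(inputs$X1) != 1L || length(inputs$X2) != 1L ||
      length(inputs$N1) != 1L || length(inputs$N2) != 1L)
    stop("totals X_i, N_i must be scalars")
  m <- max(length(inputs$x1), length(inputs$x2))
  fit <- .h0_fit_cpp(rep_len(inputs$x1, m), rep_len(inputs$n1, m),
                     rep_len(inputs$x2, m), rep_len(inputs$n2, m),
                     inputs$X1, inputs$N1, inputs$X2, inputs$N2)
  fit$boundary <- fit$boundary == 1L
  fit
}

#' Relative scan statistic for one zone (or a batch)
#'
#' Wilks statistic `lambda = 2 * (l1 - l0)` comparing the unconstrained
#' alternative ([loglik_h1()], 4 free parameters) against the shared-`k`
#' null ([fit_h0()], 3 free parameters); under the null `lambda` is
#' asymptotically chi-squared with 1 degree of freedom. Nestedness
#' guarantees `lambda >= 0`; sub-tolerance negative values arising from the
#' numerical null fit are clamped to zero.
#'
#' @param inputs a [rel_inputs()].
#' @return A list with `lambda`, `p_raw` (upper-tail chi-squared 1 df) and
#'   the fitted values of both models (`ll1`, `ll0`, `k`, `q1`, `q2`,
#'   `boundary`).
#' @export
lambda_rel <- function(inputs) {
  ll1 <- loglik_h1(inputs)
  fit <- fit_h0(inputs)
  lam <- 2 * (ll1 - fit$ll0)
  bad <- lam < -1e-6 * (1 + abs(ll1))
  if (any(bad))
    warning(sum(bad), " zone(s) with non-convergent null fit ",
            "(lambda < 0 beyond tolerance)")
  lam <- pmax(lam, 0)
  list(lambda = lam, p_raw = pchisq(lam, df = 1, lower.tail = FALSE),
       ll1 = ll1, ll0 = fit$ll0, k = fit$k, q1 = fit$q1, q2 = fit$q2,
       boundary = fit$boundary, converged = !bad)
}

#' Classify a relative cluster by its dominant series
#'
#' Compares the unconstrained in/out rate ratios `p_i / q_i`: the zone is a
#' relative cluster for the first series when `ratio1 > ratio2`, for the
#' second otherwise. Exact ties are labelled for the first series by
#' convention and flagged. The reported effect size is the natural log of
#' the ratio of ratios (positive means first series); when one ratio is
#' degenerate (a `q_hat` of zero) the label comes from one-sided dominance
#' and the log ratio is an infinite sentinel.
#'
#' @param ratio1,ratio2 per-series in/out rate ratios (vectorized).
#' @param labels length-2 character vector of series names.
#' @return A list with `label` (factor), `log_ratio` and logical `tie`.
#' @export
classify_relative <- function(ratio1, ratio2,
                              labels = c("series1", "series2")) {
  r1 <- as.numeric(ratio1); r2 <- as.numeric(ratio2)
  # 0/0 ratios (a series with no events at all) carry no signal: neutral 1
  r1[is.nan(r1)] <- 1
  r2[is.nan(r2)] <- 1
  lab <- ifelse(r1 >= r2, labels[1], labels[2])
  log_ratio <- suppressWarnings(log(r1) - log(r2))
  log_ratio[r1 > r2 & (is.nan(log_ratio))] <- Inf
  log_ratio[r1 < r2 & (is.nan(log_ratio))] <- -Inf
  log_ratio[r1 == r2] <- 0
  list(label = factor(lab, levels = labels), log_ratio = log_ratio,
       tie = r1 == r2)
}

#' Relative scan over a zone family
#'
#' Computes the relative scan statistic for every candidate zone of a
#' two-series `zone_set` and ranks zones by decreasing `lambda` (ties:
#' shorter length, chromosome order, leftmost). The scan statistic `S` is
#' the first row's `lambda`.
#'
#' @param zones a two-series `zone_set` from [enumerate_zones()].
#' @param totals optional list with `X1`, `X2`, `N` overriding the
#'   `zone_set` attributes.
#' @return A data.frame of class `rel_scan`: zone columns plus `lambda`,
#'   per-series unconstrained estimates (`p1`, `q1`, `p2`, `q2`), ratios,
#'   `log_ratio` (natural log of the ratio of ratios), `label`, constrained
#'   estimates (`k_hat`, `q1_null`, `q2_null`), `boundary`, `p_raw`.
#' @export
scan_rel <- function(zones, totals = NULL) {
  if (is.null(totals)) totals <- attr(zones, "totals")
  if (!"x2" %in% names(zones))
    stop("relative scan needs a two-series zone_set")
  if (nrow(zones) == 0L) stop("zone family is empty")
  labs <- attr(zones, "labels")
  if (is.null(labs) || length(labs) != 2L) labs <- c("series1", "series2")
  labs <- make.unique(labs)  # identical dataset labels must stay distinct
  z <- as.data.frame(zones)
  N <- totals$N
  ok <- z$n > 0 & z$n < N
  if (!all(ok)) {
    warning(sum(!ok), " zone(s) with degenerate trial counts excluded")
    z <- z[ok, , drop = FALSE]
    if (nrow(z) == 0L) stop("no scannable zones left")
  }
  inp <- rel_inputs(x1 = z$x1, n1 = z$n, X1 = totals$X1, N1 = N,
                    x2 = z$x2, n2 = z$n, X2 = totals$X2, N2 = N)
  lr <- lambda_rel(inp)
  z$lambda <- lr$lambda
  z$p1 <- z$x1 / z$n
  z$q1 <- (totals$X1 - z$x1) / (N - z$n)
  z$p2 <- z$x2 / z$n
  z$q2 <- (totals$X2 - z$x2) / (N - z$n)
  z$ratio1 <- z$p1 / z$q1
  z$ratio2 <- z$p2 / z$q2
  cls <- classify_relative(z$ratio1, z$ratio2, labels = labs)
  z$log_ratio <- cls$log_ratio
  z$label <- as.character(cls$label)
  z$k_hat <- lr$k
  z$q1_null <- lr$q1
  z$q2_null <- lr$q2
  z$boundary <- lr$boundary
  z$converged <- lr$converged
  z$p_raw <- lr$p_raw
  if (!all(z$converged)) {
    warning(sum(!z$converged), " non-convergent zone(s) excluded from ",
            "ranking")
    z <- z[z$converged, , drop = FALSE]
  }
  ord <- attr(zones, "chrom_order")
  ci <- if (is.null(ord)) xtfrm(z$chrom) else match(z$chrom, ord)
  z <- z[order(-z$lambda, z$length, ci, z$start), , drop = FALSE]
  rownames(z) <- NULL
  structure(z, class = c("rel_scan", "data.frame"), totals = totals,
            labels = labs)
}
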