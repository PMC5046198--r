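# All likelihood work is in log space with the 0*log(0) = 0 convention,
# which keeps closed forms exact at boundary counts (x = 0 or x = n).
.xlogy <- function(a, p) ifelse(a > 0, a * log(p), 0)

# Null log-likelihood of a constant success probability X/N over G.
.loglik0_uni <- function(X, N) .xlogy(X, X / N) + .xlogy(N - X, 1 - X / N)

#' Bernoulli scan log-likelihood-ratio statistic for one zone
#'
#' Twice the log of the likelihood ratio comparing an elevated in-zone
#' success probability against a constant probability over the whole
#' support. The alternative is one-sided: when the in-zone rate `x_Z / n_Z`
#' does not exceed the out-zone rate `(X - x_Z) / (N - n_Z)` the ratio is 1
#' and `lambda = 0`. Vectorized over `x_Z`, `n_Z`.
#'
#' @param x_Z in-zone success count(s).
#' @param n_Z in-zone trial count(s), `0 < n_Z < N`.
#' @param X total success count on the support.
#' @param N total trial count on the support.
#' @return `lambda = 2 * (l1 - l0) >= 0`, vectorized.
#' @examples
#' loglr_uni(5, 10, 5, 100)   # about 25.84
#' loglr_uni(1, 50, 10, 100)  # 0: in-rate below out-rate
#' @export
loglr_uni <- function(x_Z, n_Z, X, N) {
  x_Z <- as.numeric(x_Z); n_Z <- as.numeric(n_Z)
  X <- as.numeric(X); N <- as.numeric(N)
  if (any(n_Z <= 0) || any(n_Z >= N))
    stop("n_Z must satisfy 0 < n_Z < N")
  if (X > N || any(x_Z > n_Z) || any(x_Z > X) || any(x_Z < 0))
    stop("counts must satisfy 0 <= x_Z <= min(n_Z, X) and X <= N")
  if (any(X - x_Z > N - n_Z))
    stop("out-zone successes cannot exceed out-zone trials")
  if (X == 0) return(numeric(length(x_Z)))
  p_in <- x_Z / n_Z
  q_out <- (X - x_Z) / (N - n_Z)
  l1 <- .xlogy(x_Z, p_in) + .xlogy(n_Z - x_Z, 1 - p_in) +
    .xlogy(X - x_Z, q_out) + .xlogy((N - n_Z) - (X - x_Z), 1 - q_out)
  lam <- 2 * (l1 - .loglik0_uni(X, N))
  lam[p_in <= q_out] <- 0
  pmax(lam, 0)
}

#' Univariate Bernoulli scan over a zone family
#'
#' Computes the scan statistic for every candidate zone and ranks zones by
#' decreasing `lambda`; ties are broken by shorter genomic length, then by
#' chromosome order and leftmost start. The scan maximum `S` is the first
#' row's statistic. Raw p-values use the upper tail of the chi-squared
#' distribution with 1 df applied to `lambda` (conservative, because the
#' one-sided truncation puts mass at zero); a Monte Carlo alternative based
#' on the null distribution of the scan maximum is available through
#' [pvalue_uni()] with [mc_null_max_lambda()].
#'
#' @param zones a `zone_set` from [enumerate_zones()] (single-series).
#' @param X,N totals; defaults taken from the `zone_set` attributes.
#' @return A data.frame of class `uni_scan`: zone columns plus `lambda`,
#'   `S` (the likelihood ratio `exp(lambda / 2)`), `p_in`, `q_out`,
#'   `rate_ratio`, `p_raw`. Sorted; attribute `totals` carries `X`, `N`.
#' @export
scan_uni <- function(zones, X = NULL, N = NULL) {
  tot <- attr(zones, "totals")
  if (is.null(X)) X <- tot$X1
  if (is.null(N)) N <- tot$N
  if (nrow(zones) == 0L) stop("zone family is empty")
  z <- as.data.frame(zones)
  ok <- z$n > 0 & z$n < N
  if (!all(ok)) {
    warning(sum(!ok), " zone(s) with degenerate trial counts excluded")
    z <- z[ok, , drop = FALSE]
    if (nrow(z) == 0L) stop("no scannable zones left")
  }
  z$lambda <- loglr_uni(z$x1, z$n, X, N)
  z$S <- exp(z$lambda / 2)
  z$p_in <- z$x1 / z$n
  z$q_out <- (X - z$x1) / (N - z$n)
  z$rate_ratio <- z$p_in / z$q_out
  z$p_raw <- pvalue_uni(z$lambda)
  ord <- attr(zones, "chrom_order")
  ci <- if (is.null(ord)) xtfrm(z$chrom) else match(z$chrom, ord)
  z <- z[order(-z$lambda, z$length, ci, z$start), , drop = FALSE]
  rownames(z) <- NULL
  structure(z, class = c("uni_scan", "data.frame"),
            totals = list(X = X, N = N),
            labels = attr(zones, "labels"))
}

#' P-value for a scan log-likelihood-ratio statistic
#'
#' Default: upper-tail probability of the chi-squared distribution with one
#' degree of freedom at `lambda` (Wilks). For the scan maximum, a
#' Kulldorff-style Monte Carlo p-value can be computed instead by supplying
#' replicate null maxima from [mc_null_max_lambda()]: the p-value is
#' `(r + 1) / (B + 1)` where `r` is the number of null maxima at or above
#' the observed value.
#'
#' @param lambda observed statistic(s), `>= 0`.
#' @param method `"chisq"` (default) or `"montecarlo"`.
#' @param null_max numeric vector of null-replicate scan maxima (required
#'   for `"montecarlo"`).
#' @return P-value(s) in `[0, 1]`.
#' @export
pvalue_uni <- function(lambda, method = c("chisq", "montecarlo"),
                       null_max = NULL) {
  method <- match.arg(method)
  if (any(lambda < 0)) stop("lambda must be non-negative")
  if (method == "chisq")
    return(pchisq(lambda, df = 1, lower.tail = FALSE))
  if (is.null(null_max) || !length(null_max))
    stop("montecarlo method needs 'null_max' replicates")
  vapply(lambda, function(l)
    (sum(null_max >= l) + 1) / (length(null_max) + 1), numeric(1))
}

#' Null distribution of the univariate scan maximum by Monte Carlo
#'
#' Simulates `B` datasets of `X` events placed uniformly on the mappable
#' support, re-enumerates zones with the same filters, and returns each
#' replicate's maximal `lambda`.
#'
#' @inheritParams enumerate_zones
#' @param X number of events per replicate.
#' @param B number of replicates.
#' @param seed integer seed for reproducibility.
#' @return Numeric vector of length `B`.
#' @export
mc_null_max_lambda <- function(support, blind = NULL, X, L_max = 2.5e7,
                               EC_min = 3, B = 99, seed = NULL) {
  scen <- simulation_scenario(support, blind = blind, n_events = X)
  seeds <- .spawn_seeds(seed, B)
  vapply(seq_len(B), function(b) {
    d <- simulate_is(scen, seed = seeds[b])[[1]]
    z <- enumerate_zones(d, support, blind, L_max = L_max,
                         EC_min = EC_min)
    if (nrow(z) == 0L) return(0)
    max(loglr_uni(z$x1, z$n, attr(z, "totals")$X1, attr(z, "totals")$N))
  }, numeric(1))
}
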