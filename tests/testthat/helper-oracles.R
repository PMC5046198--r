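# Independent oracles used by the unit and acceptance tests. These
# re-derive the likelihood formulas from scratch and deliberately share no
# code with the package implementation.

# a * log(p) with the 0 * log(0) = 0 convention; a may be scalar or vector.
xlogy_o <- function(a, p) {
  p <- pmax(p, 1e-300)
  out <- a * log(p)
  out[a == 0] <- 0
  out
}

# Univariate scan statistic, direct evaluation (vectorized over x, n).
loglr_oracle <- function(x, n, X, N) {
  p_in <- x / n
  q_out <- (X - x) / (N - n)
  l1 <- xlogy_o(x, p_in) + xlogy_o(n - x, 1 - p_in) +
    xlogy_o(X - x, q_out) + xlogy_o((N - n) - (X - x), 1 - q_out)
  l0 <- xlogy_o(X, X / N) + xlogy_o(N - X, 1 - X / N)
  lam <- 2 * (l1 - l0)
  lam[p_in <= q_out] <- 0
  pmax(lam, 0)
}

# Constrained null log-likelihood at (k, q1, q2), vectorized over the
# parameters; infeasible points get -Inf.
ll0_oracle <- function(k, q1, q2, x1, n1, X1, N1, x2, n2, X2, N2) {
  v <- xlogy_o(x1, k * q1) + xlogy_o(n1 - x1, 1 - k * q1) +
    xlogy_o(X1 - x1, q1) + xlogy_o(N1 - n1 - X1 + x1, 1 - q1) +
    xlogy_o(x2, k * q2) + xlogy_o(n2 - x2, 1 - k * q2) +
    xlogy_o(X2 - x2, q2) + xlogy_o(N2 - n2 - X2 + x2, 1 - q2)
  v[k * q1 >= 1 | k * q2 >= 1] <- -Inf
  v
}

# Refining grid search for the constrained null maximum: 21 points per
# dimension in log space, zooming on a window of +/- 2 grid steps around
# the incumbent until the step is below 5e-7 (comfortably past the 1e-6
# refinement target).
grid_fit_h0 <- function(x1, n1, X1, N1, x2, n2, X2, N2) {
  lo <- c(log(1e-6), log(1e-8), log(1e-8))
  hi <- c(log(1e6), log(1 - 1e-8), log(1 - 1e-8))
  repeat {
    gk <- seq(lo[1], hi[1], length.out = 21)
    g1 <- seq(lo[2], hi[2], length.out = 21)
    g2 <- seq(lo[3], hi[3], length.out = 21)
    gr <- expand.grid(k = gk, q1 = g1, q2 = g2)
    v <- ll0_oracle(exp(gr$k), exp(gr$q1), exp(gr$q2),
                    x1, n1, X1, N1, x2, n2, X2, N2)
    i <- which.max(v)
    b <- c(gr$k[i], gr$q1[i], gr$q2[i])
    st <- c(gk[2] - gk[1], g1[2] - g1[1], g2[2] - g2[1])
    if (all(st < 5e-7))
      return(list(ll0 = v[i], k = exp(b[1]), q1 = exp(b[2]),
                  q2 = exp(b[3])))
    lo <- b - 2 * st
    hi <- b + 2 * st
  }
}

# Random small univariate scan instance on one chromosome: length L,
# a handful of strand-specific blind intervals, and X events sampled
# uniformly (without replacement) from the enumerated mappable trials.
rand_scan_instance <- function(L = sample(300:2500, 1),
                               n_blind = sample(0:5, 1),
                               X = sample(5:40, 1)) {
  blind_df <- NULL
  if (n_blind > 0) {
    s <- sample.int(L, n_blind)
    w <- sample.int(max(2, L %/% 10), n_blind, replace = TRUE)
    blind_df <- data.frame(chrom = "chrA", start = s,
                           end = pmin(L, s + w - 1),
                           strand = sample(c("+", "-", "*"), n_blind,
                                           replace = TRUE))
  }
  mask_p <- logical(L)
  mask_m <- logical(L)
  if (!is.null(blind_df)) {
    for (i in seq_len(n_blind)) {
      idx <- blind_df$start[i]:blind_df$end[i]
      if (blind_df$strand[i] %in% c("+", "*")) mask_p[idx] <- TRUE
      if (blind_df$strand[i] %in% c("-", "*")) mask_m[idx] <- TRUE
    }
  }
  trials <- rbind(data.frame(pos = which(!mask_p), strand = "+"),
                  data.frame(pos = which(!mask_m), strand = "-"))
  X <- min(X, nrow(trials))
  pick <- trials[sample.int(nrow(trials), X), , drop = FALSE]
  list(L = L, blind_df = blind_df,
       events = data.frame(chrom = "chrA", position = pick$pos,
                           strand = pick$strand),
       trial_per_bp = (!mask_p) + (!mask_m))
}

# Exhaustive scan over ALL intervals [a, b] of the chromosome holding at
# least EC_min events and at least two distinct event positions (the
# candidate family is delimited by pairs of distinct positions); bp-level
# prefix sums, nothing shared with the package's interval arithmetic.
# Returns the maximal statistic and the event-delimited cores of every
# maximizing interval.
brute_scan_uni <- function(inst, EC_min = 2) {
  L <- inst$L
  ev <- tabulate(inst$events$position, nbins = L)
  cumx <- c(0, cumsum(ev))  # 1-shifted prefix sums
  cumn <- c(0, cumsum(inst$trial_per_bp))
  cump <- c(0, cumsum(ev > 0))
  N <- cumn[L + 1]
  X <- sum(ev)
  a <- rep.int(seq_len(L), rev(seq_len(L)))
  b <- sequence(rev(seq_len(L)), from = seq_len(L))
  x <- cumx[b + 1] - cumx[a]
  n <- cumn[b + 1] - cumn[a]
  npos <- cump[b + 1] - cump[a]
  keep <- x >= EC_min & npos >= 2 & n >= 1 & n < N
  a <- a[keep]; b <- b[keep]; x <- x[keep]; n <- n[keep]
  lam <- loglr_oracle(x, n, X, N)
  mx <- max(lam)
  top <- which(lam >= mx - 1e-9 * max(1, abs(mx)))
  pos <- sort(unique(inst$events$position))
  cores <- unique(data.frame(
    start = vapply(a[top], function(ai) min(pos[pos >= ai]), numeric(1)),
    end = vapply(b[top], function(bi) max(pos[pos <= bi]), numeric(1))))
  list(max_lambda = mx, cores = cores, X = X, N = N)
}

# Package-side view of the same instance.
pkg_instance <- function(inst) {
  support <- genome_support(c(chrA = inst$L))
  blind <- blind_regions(inst$blind_df, support)
  dataset <- is_dataset(inst$events, support, blind)
  list(support = support, blind = blind, dataset = dataset)
}

# Interval Jaccard index on the bp scale (vectorized).
jaccard_iv <- function(s1, e1, s2, e2) {
  inter <- pmax(0, pmin(e1, e2) - pmax(s1, s2) + 1)
  inter / ((e1 - s1 + 1) + (e2 - s2 + 1) - inter)
}
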