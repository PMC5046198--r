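#' Upper bound on the number of candidate zones
#'
#' With `X1 + X2` pooled events, every candidate zone is delimited by an
#' ordered pair of distinct event positions, so the zone family can hold at
#' most `(X1 + X2) * (X1 + X2 - 1) / 2` elements. The bound is attained when
#' all events lie on one chromosome at distinct positions and no filter is
#' applied.
#'
#' @param X1,X2 per-series total event counts (use `X2 = 0` in univariate
#'   mode).
#' @return The pair-count bound (double).
#' @export
zone_upper_bound <- function(X1, X2 = 0) {
  if (any(X1 < 0) || any(X2 < 0))
    stop("event counts must be non-negative")
  x <- as.numeric(X1) + as.numeric(X2)
  x * (x - 1) / 2
}

#' Enumerate candidate zones delimited by events
#'
#' Builds the zone family: per chromosome, every interval whose endpoints
#' are an ordered pair of distinct (pooled, in two-series mode) event
#' positions. For a fixed event content the likelihood ratio can only
#' decrease as failures are added to a zone, so restricting the scan to
#' event-delimited intervals loses no maximizer. Zones whose genomic length
#' (`end - start`, simple coordinate difference) exceeds `L_max`, or whose
#' pooled event count is below `EC_min`, are filtered out; zones of exactly
#' `L_max` length or exactly `EC_min` events are kept. Each zone carries its
#' effective trial count `n` (both strands, blind bases subtracted) and
#' per-series event counts.
#'
#' @param datasets an [is_dataset()] or a list of one or two of them.
#' @param support a [genome_support()].
#' @param blind a [blind_regions()] mask or `NULL`.
#' @param L_max maximum zone length in bp (default 2.5e7).
#' @param EC_min minimum pooled event count per zone (default 3).
#' @return A data.frame of class `zone_set` with columns `chrom`, `start`,
#'   `end`, `length`, `n`, `x1` (and `x2` in two-series mode) and
#'   attributes `totals` (list with `X1`, `X2`, `N`), `labels`, `L_max`,
#'   `EC_min`.
#' @export
enumerate_zones <- function(datasets, support, blind = NULL,
                            L_max = 2.5e7, EC_min = 3) {
  .check_support(support)
  blind <- .check_blind(blind, support)
  if (inherits(datasets, "is_dataset")) datasets <- list(datasets)
  if (!length(datasets) %in% 1:2 ||
      !all(vapply(datasets, inherits, logical(1), "is_dataset")))
    stop("datasets must be one or two 'is_dataset' objects")
  if (L_max <= 0) stop("L_max must be positive")
  if (EC_min < 1) stop("EC_min must be >= 1")
  two <- length(datasets) == 2L
  N <- effective_genome_size(support, blind)
  X <- vapply(datasets, function(d) nrow(d$events), numeric(1))

  res <- vector("list", length(support$chrom))
  names(res) <- names(support$chrom)
  for (ch in names(support$chrom)) {
    evpos <- lapply(datasets, function(d)
      d$events$position[d$events$chrom == ch])
    pooled <- sort(unique(unlist(evpos)))
    m <- length(pooled)
    if (m < 2L) next
    # per-series event count at each pooled position (strands can double up)
    cnt <- lapply(evpos, function(p) {
      tb <- table(factor(p, levels = pooled))
      as.numeric(tb)
    })
    cum <- lapply(cnt, function(v) c(0, cumsum(v)))  # 1-shifted prefix sums
    # pairs (i < j) with pooled[j] - pooled[i] <= L_max
    hi <- findInterval(pooled + L_max, pooled)
    npair <- hi - seq_len(m)
    keep_i <- which(npair > 0)
    if (!length(keep_i)) next
    i_vec <- rep.int(keep_i, npair[keep_i])
    j_vec <- sequence(npair[keep_i], from = keep_i + 1L)
    xs <- lapply(seq_along(datasets), function(d)
      cum[[d]][j_vec + 1L] - cum[[d]][i_vec])
    pool_x <- Reduce(`+`, xs)
    sel <- pool_x >= EC_min
    if (!any(sel)) next
    i_vec <- i_vec[sel]; j_vec <- j_vec[sel]
    xs <- lapply(xs, `[`, sel)
    starts <- pooled[i_vec]; ends <- pooled[j_vec]
    n <- effective_interval_size(support, blind, rep(ch, length(starts)),
                                 starts, ends)
    df <- data.frame(chrom = ch, start = starts, end = ends,
                     length = ends - starts, n = n, x1 = xs[[1]])
    if (two) df$x2 <- xs[[2]]
    res[[ch]] <- df
  }
  out <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), length = numeric(), n = numeric(),
                      x1 = numeric())
    if (two) out$x2 <- numeric()
  }
  if (nrow(out)) {
    degenerate <- out$n <= 0
    if (any(degenerate)) {
      warning(sum(degenerate),
              " zone(s) with zero effective size dropped (fully blind ",
              "span containing events is contradictory input)")
      out <- out[!degenerate, , drop = FALSE]
    }
  }
  rownames(out) <- NULL
  structure(out, class = c("zone_set", "data.frame"),
            totals = list(X1 = X[1], X2 = if (two) X[2] else 0, N = N),
            labels = vapply(datasets, `[[`, character(1), "label"),
            L_max = L_max, EC_min = EC_min,
            chrom_order = names(support$chrom))
}
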