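#' Holm-Bonferroni step-down adjustment
#'
#' Standard step-down Holm adjustment over the zone family (delegates to
#' [stats::p.adjust()]): sort ascending, take the running maximum of
#' `(m - j + 1) * p_(j)`, cap at 1, and map back to input order. Controls
#' the family-wise error rate at the nominal level under arbitrary
#' dependence between zone tests.
#'
#' @param p_values numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
holm_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  p.adjust(p_values, method = "holm")
}

# Do two interval sets overlap? Vectorized over the first set.
.overlaps_any <- function(chrom, start, end, ref) {
  if (is.null(ref) || nrow(ref) == 0L) return(rep(FALSE, length(chrom)))
  out <- logical(length(chrom))
  for (i in seq_len(nrow(ref))) {
    out <- out | (chrom == ref$chrom[i] & start <= ref$end[i] &
                    end >= ref$start[i])
  }
  out
}

#' Sequential cluster detection with family-wise error control
#'
#' The full detection loop: enumerate candidate zones, scan (univariate
#' with one dataset, relative with two), Holm-adjust the raw p-values over
#' the current family, and test the maximizer. If its adjusted p-value is
#' below `alpha` the zone is accepted and removed from the support (its
#' interval becomes blind on both strands, events inside are dropped, and
#' zones overlapping any accepted zone are excluded), totals are
#' recomputed, and the scan restarts on the residual support. The loop
#' stops when the maximizer is no longer significant, no zones remain, or
#' `max_rounds` is reached. Accepted zones are pairwise disjoint by
#' construction.
#'
#' By default one zone (the maximizer) is accepted per round. With
#' `accept = "batch"` all Holm-significant zones of a round are accepted
#' greedily in rank order, skipping zones that overlap an already accepted
#' one; this reproduces in fewer rounds what the one-per-round loop would
#' eventually deliver, at the cost of a less strictly sequential error
#' control argument.
#'
#' @param datasets an [is_dataset()] or list of one or two.
#' @param support a [genome_support()].
#' @param blind a [blind_regions()] mask or `NULL`.
#' @param L_max,EC_min zone filters, see [enumerate_zones()].
#' @param alpha family-wise significance level in (0, 1), default 0.01.
#' @param accept `"one-per-round"` (default) or `"batch"`.
#' @param max_rounds optional cap on the number of detection rounds.
#' @return A list of class `detection_report`: `accepted` (data.frame of
#'   accepted zones with round index, statistics and adjusted p-values),
#'   `rounds` (per-round bookkeeping: family size, residual totals,
#'   top statistic), `stopped` (reason), and the run parameters.
#' @export
detect_sequential <- function(datasets, support, blind = NULL,
                              L_max = 2.5e7, EC_min = 3, alpha = 0.01,
                              accept = c("one-per-round", "batch"),
                              max_rounds = Inf) {
  .check_support(support)
  accept <- match.arg(accept)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  if (inherits(datasets, "is_dataset")) datasets <- list(datasets)
  two <- length(datasets) == 2L
  blind <- .check_blind(blind, support)

  cur_data <- datasets
  cur_blind <- blind
  accepted <- NULL       # chrom/start/end of accepted zones
  accepted_full <- NULL  # full result rows of accepted zones
  rounds <- NULL
  stopped <- NULL
  round <- 0L
  while (round < max_rounds) {
    round <- round + 1L
    zones <- enumerate_zones(cur_data, support, cur_blind, L_max = L_max,
                             EC_min = EC_min)
    if (nrow(zones) && !is.null(accepted)) {
      keep <- !.overlaps_any(zones$chrom, zones$start, zones$end,
                             accepted)
      at <- attributes(zones)
      zones <- zones[keep, , drop = FALSE]
      attr(zones, "totals") <- at$totals
      attr(zones, "labels") <- at$labels
      attr(zones, "chrom_order") <- at$chrom_order
    }
    tot <- attr(zones, "totals")
    if (nrow(zones) == 0L) {
      stopped <- "no_zones"
      rounds <- rbind(rounds, data.frame(
        round = round, m = 0, N = tot$N, X1 = tot$X1, X2 = tot$X2,
        top_lambda = NA_real_, top_p_adj = NA_real_, n_accepted = 0))
      break
    }
    res <- if (two) scan_rel(zones) else scan_uni(zones)
    res$p_adj <- holm_adjust(res$p_raw)
    m <- nrow(res)
    sig <- res$p_adj < alpha
    take <- integer(0)
    if (sig[1]) {
      if (accept == "one-per-round") {
        take <- 1L
      } else {
        cand <- which(sig)
        picked <- accepted
        for (i in cand) {
          if (!.overlaps_any(res$chrom[i], res$start[i], res$end[i],
                             picked)) {
            take <- c(take, i)
            picked <- rbind(picked,
                            data.frame(chrom = res$chrom[i],
                                       start = res$start[i],
                                       end = res$end[i]))
          }
        }
      }
    }
    rounds <- rbind(rounds, data.frame(
      round = round, m = m, N = tot$N, X1 = tot$X1, X2 = tot$X2,
      top_lambda = res$lambda[1], top_p_adj = res$p_adj[1],
      n_accepted = length(take)))
    if (!length(take)) {
      stopped <- "not_significant"
      break
    }
    acc <- as.data.frame(res)[take, , drop = FALSE]
    acc$round <- round
    accepted <- rbind(accepted,
                      acc[, c("chrom", "start", "end"), drop = FALSE])
    accepted_full <- rbind(accepted_full, acc)
    # remove accepted intervals from the support (blind on both strands)
    # and drop the events they contain
    extra <- data.frame(chrom = acc$chrom, start = acc$start,
                        end = acc$end, strand = "*")
    cur_blind <- blind_regions(rbind(cur_blind$regions[,
                     c("chrom", "start", "end", "strand")], extra),
                     support)
    cur_data <- lapply(cur_data, function(d) {
      drop <- .overlaps_any(d$events$chrom, d$events$position,
                            d$events$position, acc)
      d$events <- d$events[!drop, , drop = FALSE]
      d
    })
  }
  if (is.null(stopped)) stopped <- "max_rounds"
  full <- if (is.null(accepted_full)) data.frame() else accepted_full
  rownames(full) <- NULL
  structure(list(accepted = full, rounds = rounds, stopped = stopped,
                 alpha = alpha, L_max = L_max, EC_min = EC_min,
                 accept = accept, mode = if (two) "rel" else "uni",
                 labels = vapply(datasets, `[[`, character(1), "label")),
            class = "detection_report")
}

#' @export
print.detection_report <- function(x, ...) {
  cat("detection_report (", x$mode, " mode, alpha = ", x$alpha, "): ",
      nrow(x$accepted), " accepted zone(s) in ",
      if (is.null(x$rounds)) 0 else nrow(x$rounds),
      " round(s); stopped: ", x$stopped, "\n", sep = "")
  if (nrow(x$accepted)) {
    cols <- intersect(c("round", "chrom", "start", "end", "lambda", "x1",
                        "x2", "label", "p_adj"), names(x$accepted))
    print(utils::head(x$accepted[, cols], 10))
  }
  invisible(x)
}
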