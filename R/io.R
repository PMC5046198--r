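#' Read chromosome sizes
#'
#' Two-column tab-separated file (no header): chromosome name, length in
#' bp. Chromosome names are taken verbatim and their file order defines
#' the chromosome order used everywhere downstream.
#'
#' @param path file path.
#' @return A [genome_support()].
#' @export
read_chrom_sizes <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("chrom-sizes file needs two columns: name, length")
  genome_support(stats::setNames(as.numeric(df[[2]]),
                                 as.character(df[[1]])))
}

#' Read an integration-site coordinate table
#'
#' Three-column tab-separated file with header `chr  position  strand`
#' (1-based positions, strand `+` or `-`). Duplicate rows are collapsed
#' with a warning; a strand value outside `{+, -}` or an unknown
#' chromosome is an error naming the offending line.
#'
#' @param path file path.
#' @param support a [genome_support()].
#' @param blind optional [blind_regions()]; events on masked trials are an
#'   error unless `on_blind = "drop"`.
#' @param label dataset name; defaults to the file name.
#' @inheritParams is_dataset
#' @return An [is_dataset()].
#' @export
read_is_table <- function(path, support, blind = NULL, label = NULL,
                          on_blind = c("error", "drop")) {
  if (is.null(label))
    label <- tools::file_path_sans_ext(basename(path))
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                   colClasses = c("character", "numeric", "character"))
  names(df) <- c("chrom", "position", "strand")[seq_len(ncol(df))]
  if (ncol(df) < 3)
    stop("IS table needs three columns: chr, position, strand")
  bad <- which(!(df$strand %in% c("+", "-")))
  if (length(bad))
    stop("invalid strand value '", df$strand[bad[1]], "' at line ",
         bad[1] + 1L, " of ", path)
  bad <- which(!(df$chrom %in% names(support$chrom)))
  if (length(bad))
    stop("unknown chromosome '", df$chrom[bad[1]], "' at line ",
         bad[1] + 1L, " of ", path, "; valid: ",
         paste(names(support$chrom), collapse = ", "))
  is_dataset(df, support, blind = blind, label = label,
             on_blind = on_blind)
}

#' Write an integration-site coordinate table
#'
#' @param dataset an [is_dataset()].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_is_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "is_dataset"))
  df <- dataset$events
  names(df) <- c("chr", "position", "strand")
  write.table(format(df, scientific = FALSE, trim = TRUE), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a blind-region mask from a BED file
#'
#' BED uses 0-based half-open coordinates; they are converted to the
#' package's 1-based inclusive convention at this boundary only. Strand
#' `"."` (BED3/unstranded records) expands to both strands; overlapping
#' intervals are merged per (chromosome, strand); intervals past a
#' chromosome end are an error.
#'
#' @param path BED file path (BED3 or BED6).
#' @param support a [genome_support()].
#' @return A [blind_regions()].
#' @export
read_blind_bed <- function(path, support) {
  gr <- rtracklayer::import(path, format = "bed")
  if (!length(gr)) return(blind_regions(NULL, support))
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),  # already 1-based
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)))
  blind_regions(df, support)
}

# p-values below double precision print as "<2e-16"
.fmt_p <- function(p) ifelse(p < 2e-16, "<2e-16", signif(p, 4))

#' Write a ranked cluster table
#'
#' Tab-separated, one row per zone, ranked as scanned. Univariate columns:
#' `S` (the statistic `lambda`), `chr`, `start`, `end`, `IS_count`,
#' `rate_ratio`, `raw_p`, `adj_p`. Relative columns: `S`, `chr`, `start`,
#' `end`, per-series IS counts, `log_ratio` (natural log of the ratio of
#' in/out rate ratios, positive for the first series), `type` (dominant
#' series label), `raw_p`, `adj_p`. Statistics are printed at 4
#' significant digits; p-values below representable precision print as
#' `<2e-16`.
#'
#' @param results a `uni_scan` or `rel_scan` data.frame (a `p_adj` column
#'   is added with [holm_adjust()] if missing).
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_cluster_table <- function(results, path) {
  if (!nrow(results)) {
    mode <- if (inherits(results, "rel_scan")) "rel" else "uni"
  } else {
    mode <- if ("x2" %in% names(results)) "rel" else "uni"
  }
  res <- as.data.frame(results)
  if (nrow(res) && !"p_adj" %in% names(res))
    res$p_adj <- holm_adjust(res$p_raw)
  labs <- attr(results, "labels")
  if (is.null(labs)) labs <- c("series1", "series2")
  if (mode == "uni") {
    out <- data.frame(S = numeric(), chr = character(), start = numeric(),
                      end = numeric(), IS_count = numeric(),
                      rate_ratio = numeric(), raw_p = character(),
                      adj_p = character())
    if (nrow(res))
      out <- data.frame(S = signif(res$lambda, 4), chr = res$chrom,
                        start = res$start, end = res$end,
                        IS_count = res$x1,
                        rate_ratio = signif(res$rate_ratio, 4),
                        raw_p = .fmt_p(res$p_raw),
                        adj_p = .fmt_p(res$p_adj))
  } else {
    cnt <- paste0("IS_", make.names(labs))
    out <- data.frame(S = numeric(), chr = character(), start = numeric(),
                      end = numeric(), c1 = numeric(), c2 = numeric(),
                      log_ratio = numeric(), type = character(),
                      raw_p = character(), adj_p = character())
    names(out)[5:6] <- cnt
    if (nrow(res)) {
      out <- data.frame(S = signif(res$lambda, 4), chr = res$chrom,
                        start = res$start, end = res$end,
                        c1 = res$x1, c2 = res$x2,
                        log_ratio = signif(res$log_ratio, 4),
                        type = res$label,
                        raw_p = .fmt_p(res$p_raw),
                        adj_p = .fmt_p(res$p_adj))
      names(out)[5:6] <- cnt
    }
  }
  write.table(format(out, scientific = FALSE, trim = TRUE), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a cluster table written by [write_cluster_table()]
#'
#' @param path file path.
#' @return A data.frame with the documented columns (p-value columns are
#'   character because of the `<2e-16` convention).
#' @export
read_cluster_table <- function(path) {
  read.delim(path, header = TRUE, stringsAsFactors = FALSE,
             colClasses = "character") |>
    (\(df) {
      for (cl in intersect(c("S", "start", "end", "IS_count",
                             "rate_ratio", "log_ratio"), names(df)))
        df[[cl]] <- as.numeric(df[[cl]])
      for (cl in grep("^IS_", names(df), value = TRUE))
        df[[cl]] <- as.numeric(df[[cl]])
      df
    })()
}

#' Write a detection report (TSV + JSON metadata sidecar)
#'
#' One row per accepted zone with its round index; the sidecar records run
#' parameters, per-round family sizes and residual totals, and the
#' stopping reason, at full numeric precision.
#'
#' @param report a `detection_report` from [detect_sequential()].
#' @param path output TSV path; the sidecar is written next to it with a
#'   `.json` extension.
#' @return The TSV path, invisibly.
#' @export
write_detection_report <- function(report, path) {
  stopifnot(inherits(report, "detection_report"))
  acc <- report$accepted
  cols <- intersect(c("round", "chrom", "start", "end", "lambda", "x1",
                      "x2", "rate_ratio", "log_ratio", "label", "p_raw",
                      "p_adj"), names(acc))
  out <- if (nrow(acc)) acc[, cols, drop = FALSE] else
    data.frame(round = numeric(), chrom = character(), start = numeric(),
               end = numeric(), lambda = numeric())
  if (nrow(out)) {
    out$lambda <- signif(out$lambda, 4)
    if ("log_ratio" %in% names(out))
      out$log_ratio <- signif(out$log_ratio, 4)
    if ("rate_ratio" %in% names(out))
      out$rate_ratio <- signif(out$rate_ratio, 4)
    for (cl in intersect(c("p_raw", "p_adj"), names(out)))
      out[[cl]] <- .fmt_p(out[[cl]])
  }
  write.table(format(out, scientific = FALSE, trim = TRUE), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(mode = report$mode, alpha = report$alpha,
               L_max = report$L_max, EC_min = report$EC_min,
               accept = report$accept, labels = report$labels,
               stopped = report$stopped, rounds = report$rounds,
               accepted = if (nrow(acc)) acc else NULL)
  jsonlite::write_json(meta, paste0(tools::file_path_sans_ext(path),
                                    ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
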