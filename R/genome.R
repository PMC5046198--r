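#' Genomic support for a two-stranded Bernoulli trial set
#'
#' The study area is a set of chromosomes, each contributing one Bernoulli
#' trial per base pair per strand, so a chromosome of length `L` holds `2 * L`
#' theoretical trials. Chromosome order is kept as given and used for all
#' downstream ordering and tie-breaking.
#'
#' @param chrom_sizes named numeric vector of chromosome lengths in bp
#'   (names are chromosome identifiers, lengths positive integers).
#' @return An object of class `genome_support`.
#' @examples
#' g <- genome_support(c(chr1 = 1000, chr2 = 500))
#' effective_genome_size(g)  # 3000
#' @export
genome_support <- function(chrom_sizes) {
  if (length(chrom_sizes) == 0L)
    stop("chrom_sizes must contain at least one chromosome")
  nm <- names(chrom_sizes)
  if (is.null(nm) || any(!nzchar(nm)) || anyDuplicated(nm))
    stop("chrom_sizes must have unique non-empty names")
  len <- as.numeric(chrom_sizes)
  if (any(!is.finite(len)) || any(len < 1) || any(len != floor(len)))
    stop("chromosome lengths must be positive integers")
  structure(list(chrom = stats::setNames(len, nm)), class = "genome_support")
}

#' @export
print.genome_support <- function(x, ...) {
  cat("genome_support:", length(x$chrom), "chromosome(s),",
      format(sum(x$chrom), big.mark = ","), "bp,",
      format(2 * sum(x$chrom), big.mark = ","), "theoretical trials\n")
  invisible(x)
}

.check_support <- function(support) {
  if (!inherits(support, "genome_support"))
    stop("expected a 'genome_support' object")
  support
}

#' Strand-aware blind-region (mappability) mask
#'
#' Blind regions are genomic stretches that the assay cannot observe
#' (restriction-site or mappability constraints); their base pairs are
#' excluded from the Bernoulli trial set. Intervals are strand-specific,
#' stored 1-based inclusive, and merged per (chromosome, strand) on
#' construction. Strand `"*"` (or `"."`) expands to both strands.
#'
#' @param regions data.frame with columns `chrom`, `start`, `end`, `strand`
#'   (1-based inclusive coordinates; strand in `"+"`, `"-"`, `"*"` or `"."`),
#'   or `NULL` for an empty mask.
#' @param support a [genome_support()]; intervals must lie within bounds.
#' @return An object of class `blind_regions`.
#' @examples
#' g <- genome_support(c(chr1 = 1000))
#' b <- blind_regions(data.frame(chrom = "chr1", start = 1, end = 100,
#'                               strand = "+"), g)
#' effective_genome_size(g, b)  # 1900
#' @export
blind_regions <- function(regions = NULL, support) {
  .check_support(support)
  if (is.null(regions) || nrow(regions) == 0L) {
    df <- data.frame(chrom = character(), start = numeric(),
                     end = numeric(), strand = character())
    return(structure(list(regions = df, index = list()),
                     class = "blind_regions"))
  }
  need <- c("chrom", "start", "end", "strand")
  if (!all(need %in% names(regions)))
    stop("regions must have columns: ", paste(need, collapse = ", "))
  chrom <- as.character(regions$chrom)
  start <- as.numeric(regions$start)
  end <- as.numeric(regions$end)
  strand <- as.character(regions$strand)
  strand[strand == "."] <- "*"
  if (!all(strand %in% c("+", "-", "*")))
    stop("strand must be one of '+', '-', '*', '.'")
  bad <- !(chrom %in% names(support$chrom))
  if (any(bad))
    stop("unknown chromosome(s) in mask: ",
         paste(unique(chrom[bad]), collapse = ", "),
         "; valid: ", paste(names(support$chrom), collapse = ", "))
  if (any(start < 1) || any(end < start))
    stop("blind intervals must satisfy 1 <= start <= end")
  if (any(end > support$chrom[chrom]))
    stop("blind interval(s) exceed chromosome bounds")
  # expand "*" to both strands, then merge per (chrom, strand)
  both <- strand == "*"
  chrom <- c(chrom, chrom[both]); start <- c(start, start[both])
  end <- c(end, end[both])
  strand <- c(ifelse(both, "+", strand), rep("-", sum(both)))
  out <- data.frame(chrom = character(), start = numeric(),
                    end = numeric(), strand = character())
  idx <- list()
  for (ch in names(support$chrom)) {
    for (st in c("+", "-")) {
      sel <- chrom == ch & strand == st
      if (!any(sel)) next
      ir <- IRanges::reduce(IRanges::IRanges(start = start[sel],
                                             end = end[sel]))
      s <- as.numeric(IRanges::start(ir))
      e <- as.numeric(IRanges::end(ir))
      out <- rbind(out, data.frame(chrom = ch, start = s, end = e,
                                   strand = st))
      idx[[ch]][[st]] <- list(start = s, end = e,
                              cum = cumsum(e - s + 1))
    }
  }
  structure(list(regions = out, index = idx), class = "blind_regions")
}

#' @export
print.blind_regions <- function(x, ...) {
  cat("blind_regions:", nrow(x$regions), "merged strand-specific",
      "interval(s),", format(sum(x$regions$end - x$regions$start + 1),
                             big.mark = ","), "masked trials\n")
  invisible(x)
}

.check_blind <- function(blind, support) {
  if (is.null(blind)) return(blind_regions(NULL, support))
  if (!inherits(blind, "blind_regions"))
    stop("expected a 'blind_regions' object or NULL")
  blind
}

# Masked bases of one strand's merged interval list within [a, b],
# vectorized over a, b. cov(x) = masked bases in [1, x].
.strand_overlap <- function(stridx, a, b) {
  if (is.null(stridx)) return(numeric(length(a)))
  cov <- function(x) {
    i <- findInterval(x, stridx$start)
    out <- numeric(length(x))
    pos <- i > 0
    out[pos] <- stridx$cum[i[pos]] -
      pmax(0, stridx$end[i[pos]] - x[pos])
    out
  }
  cov(b) - cov(a - 1)
}

# Total masked trials (both strands) overlapping [start, end] on chrom;
# vectorized over equal-length chrom/start/end.
.blind_overlap <- function(blind, chrom, start, end) {
  out <- numeric(length(chrom))
  if (length(blind$index) == 0L) return(out)
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    ix <- blind$index[[ch]]
    if (is.null(ix)) next
    out[sel] <- .strand_overlap(ix[["+"]], start[sel], end[sel]) +
      .strand_overlap(ix[["-"]], start[sel], end[sel])
  }
  out
}

#' Effective genome size (total Bernoulli trial count)
#'
#' Number of observable Bernoulli trials on the whole support: twice the
#' summed chromosome lengths minus the masked bases, counting both strands
#' separately. Returned as a double because genomic trial counts exceed the
#' 32-bit integer range.
#'
#' @param support a [genome_support()].
#' @param blind a [blind_regions()] mask, or `NULL` for none.
#' @return Trial count `N` (double, integral-valued).
#' @export
effective_genome_size <- function(support, blind = NULL) {
  .check_support(support)
  blind <- .check_blind(blind, support)
  n <- 2 * sum(support$chrom) -
    sum(blind$regions$end - blind$regions$start + 1)
  if (n <= 0) stop("mask removes the entire support")
  n
}

#' Effective interval size (zone trial count)
#'
#' Observable trials within `[start, end]` on one chromosome: the
#' theoretical size `2 * (end - start + 1)` minus masked bases overlapping
#' the interval on either strand. Vectorized over `chrom`, `start`, `end`.
#'
#' @inheritParams effective_genome_size
#' @param chrom chromosome name(s).
#' @param start,end 1-based inclusive interval bounds, `start <= end`.
#' @return Trial count(s) `n_Z` (double, `>= 0`).
#' @export
effective_interval_size <- function(support, blind = NULL, chrom, start,
                                    end) {
  .check_support(support)
  blind <- .check_blind(blind, support)
  chrom <- as.character(chrom)
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(!(chrom %in% names(support$chrom))))
    stop("unknown chromosome in interval query")
  if (any(start > end)) stop("start must be <= end")
  if (any(start < 1) || any(end > support$chrom[chrom]))
    stop("interval outside chromosome bounds")
  2 * (end - start + 1) - .blind_overlap(blind, chrom, start, end)
}

#' Event dataset (integration-site coordinates)
#'
#' A set of point events, one Bernoulli success per (chromosome, position,
#' strand). Events must be unique per coordinate triple and must not fall
#' into a blind region on their own strand (by default an error; with
#' `on_blind = "drop"` offending events are removed with a warning).
#'
#' @param events data.frame with columns `chrom`, `position` (1-based bp),
#'   `strand` (`"+"` or `"-"`).
#' @param support a [genome_support()].
#' @param blind optional [blind_regions()] used to validate events.
#' @param label dataset name used in outputs.
#' @param on_blind `"error"` (default) or `"drop"` for events in blind
#'   regions.
#' @return An object of class `is_dataset`.
#' @export
is_dataset <- function(events, support, blind = NULL, label = "series1",
                       on_blind = c("error", "drop")) {
  .check_support(support)
  on_blind <- match.arg(on_blind)
  need <- c("chrom", "position", "strand")
  if (!all(need %in% names(events)))
    stop("events must have columns: ", paste(need, collapse = ", "))
  df <- data.frame(chrom = as.character(events$chrom),
                   position = as.numeric(events$position),
                   strand = as.character(events$strand))
  if (nrow(df)) {
    if (!all(df$strand %in% c("+", "-")))
      stop("event strand must be '+' or '-'")
    bad <- !(df$chrom %in% names(support$chrom))
    if (any(bad))
      stop("unknown chromosome(s) in events: ",
           paste(unique(df$chrom[bad]), collapse = ", "),
           "; valid: ", paste(names(support$chrom), collapse = ", "))
    if (any(df$position < 1) || any(df$position != floor(df$position)))
      stop("positions must be positive integers")
    if (any(df$position > support$chrom[df$chrom]))
      stop("event position(s) exceed chromosome length")
    dup <- duplicated(df)
    if (any(dup)) {
      warning(sum(dup), " duplicated event(s) collapsed")
      df <- df[!dup, , drop = FALSE]
    }
    if (!is.null(blind)) {
      blind <- .check_blind(blind, support)
      inb <- vapply(seq_len(nrow(df)), function(i) {
        ix <- blind$index[[df$chrom[i]]][[df$strand[i]]]
        .strand_overlap(ix, df$position[i], df$position[i]) > 0
      }, logical(1))
      if (any(inb)) {
        if (on_blind == "error")
          stop(sum(inb), " event(s) fall inside blind regions on their ",
               "own strand; use on_blind = 'drop' to discard them")
        warning(sum(inb), " event(s) inside blind regions dropped")
        df <- df[!inb, , drop = FALSE]
      }
    }
    o <- order(match(df$chrom, names(support$chrom)), df$position,
               df$strand)
    df <- df[o, , drop = FALSE]
    rownames(df) <- NULL
  }
  structure(list(events = df, label = label), class = "is_dataset")
}

#' @export
print.is_dataset <- function(x, ...) {
  cat("is_dataset '", x$label, "': ", nrow(x$events), " event(s) on ",
      length(unique(x$events$chrom)), " chromosome(s)\n", sep = "")
  invisible(x)
}

#' Count events of a dataset within an interval
#'
#' Events with matching chromosome and `start <= position <= end`, both
#' strands pooled.
#'
#' @param dataset an [is_dataset()].
#' @param chrom chromosome name.
#' @param start,end 1-based inclusive interval bounds.
#' @return Integer count.
#' @export
count_events <- function(dataset, chrom, start, end) {
  if (!inherits(dataset, "is_dataset")) stop("expected an 'is_dataset'")
  ev <- dataset$events
  sum(ev$chrom == chrom & ev$position >= start & ev$position <= end)
}
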