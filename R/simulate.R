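# Derive B reproducible child seeds (< 2^31) from one seed (or none).
.spawn_seeds <- function(seed, B) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed))
  }
  sample.int(.Machine$integer.max - 1L, B)
}

#' Define a simulation scenario
#'
#' Describes a generative model with the statistical structure the scans
#' assume: Bernoulli events scattered on the mappable (non-blind) trials of
#' a two-stranded support, with a piecewise-constant event rate. Sampling
#' is conditional on the per-series totals (exactly `n_events[i]` distinct
#' events per series), matching the scans' conditioning on observed totals.
#' Planted intervals multiply the base rate by per-series factors: equal
#' multipliers (`r1 = r2 = k`) encode the relative-scan null of shared rate
#' variation; unequal multipliers plant a relative cluster.
#'
#' @param support a [genome_support()].
#' @param blind a [blind_regions()] mask or `NULL`.
#' @param n_events numeric vector of length 1 (one series) or 2: total
#'   events per series.
#' @param plants `NULL`, or a data.frame with columns `chrom`, `start`,
#'   `end`, `r1` (and optionally `r2`, defaulting to `r1`): disjoint
#'   in-support intervals and their positive rate multipliers.
#' @param labels series names.
#' @return A list of class `sim_scenario`.
#' @export
simulation_scenario <- function(support, blind = NULL, n_events,
                                plants = NULL,
                                labels = paste0("series",
                                                seq_along(n_events))) {
  .check_support(support)
  blind <- .check_blind(blind, support)
  if (!length(n_events) %in% 1:2 || any(n_events < 1))
    stop("n_events must be one or two positive counts")
  if (!is.null(plants)) {
    need <- c("chrom", "start", "end", "r1")
    if (!all(need %in% names(plants)))
      stop("plants needs columns: ", paste(need, collapse = ", "))
    if (!"r2" %in% names(plants)) plants$r2 <- plants$r1
    if (any(plants$r1 <= 0) || any(plants$r2 <= 0))
      stop("rate multipliers must be positive")
    if (any(!(plants$chrom %in% names(support$chrom))) ||
        any(plants$start < 1) ||
        any(plants$end > support$chrom[as.character(plants$chrom)]))
      stop("planted intervals must lie within the support")
    o <- order(match(plants$chrom, names(support$chrom)), plants$start)
    plants <- plants[o, , drop = FALSE]
    same <- duplicated(plants$chrom)
    if (any(same & plants$start <= c(-Inf, plants$end[-nrow(plants)])))
      stop("planted intervals must be mutually disjoint")
  }
  structure(list(support = support, blind = blind,
                 n_events = as.numeric(n_events), plants = plants,
                 labels = labels),
            class = "sim_scenario")
}

# Piecewise-constant segment table over the mappable support:
# one row per (chrom, strand, interval) with per-series multipliers.
.sim_segments <- function(scenario) {
  support <- scenario$support
  blind <- scenario$blind
  plants <- scenario$plants
  segs <- NULL
  offset <- 0
  for (ch in names(support$chrom)) {
    len <- support$chrom[[ch]]
    for (st in c("+", "-")) {
      ix <- blind$index[[ch]][[st]]
      mappable <- if (is.null(ix)) {
        IRanges::IRanges(start = 1, end = len)
      } else {
        IRanges::setdiff(IRanges::IRanges(start = 1, end = len),
                         IRanges::IRanges(start = ix$start, end = ix$end))
      }
      if (!length(mappable)) next
      # split at plant boundaries so each segment has a constant rate
      pl <- if (is.null(plants)) NULL else
        plants[plants$chrom == ch, , drop = FALSE]
      if (!is.null(pl) && nrow(pl)) {
        cuts <- IRanges::disjoin(c(mappable,
                                   IRanges::IRanges(start = pl$start,
                                                    end = pl$end)))
        # disjoin pieces fall entirely inside or outside the mappable set
        mappable <- cuts[IRanges::overlapsAny(cuts, mappable,
                                              type = "within")]
      }
      s <- IRanges::start(mappable); e <- IRanges::end(mappable)
      r1 <- rep(1, length(s)); r2 <- rep(1, length(s))
      if (!is.null(pl) && nrow(pl)) {
        for (i in seq_len(nrow(pl))) {
          inside <- s >= pl$start[i] & e <= pl$end[i]
          r1[inside] <- pl$r1[i]
          r2[inside] <- pl$r2[i]
        }
      }
      segs <- rbind(segs, data.frame(
        chrom = ch, strand = st, start = s, end = e, width = e - s + 1,
        r1 = r1, r2 = r2, offset = offset + cumsum(c(0,
          utils::head(e - s + 1, -1)))))
      offset <- offset + sum(e - s + 1)
    }
  }
  if (is.null(segs)) stop("no mappable trials in scenario")
  segs
}

#' Simulate event datasets from a scenario
#'
#' Draws exactly the requested number of distinct events per series:
#' repeated weighted draws of a segment (probability proportional to
#' segment width times its rate multiplier) and a uniform position within
#' it, with duplicate (chromosome, position, strand) triples redrawn until
#' the requested count of distinct events is reached. With the genomic
#' trial counts the scans target, duplicates are rare and the scheme is an
#' accurate stand-in for successive weighted sampling without replacement.
#' A fixed seed gives bit-identical output.
#'
#' @param scenario a [simulation_scenario()].
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return A list of one or two [is_dataset()] objects.
#' @export
simulate_is <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed))
  }
  segs <- .sim_segments(scenario)
  n_mappable <- sum(segs$width)
  lapply(seq_along(scenario$n_events), function(d) {
    X <- scenario$n_events[d]
    if (X > n_mappable)
      stop("requested ", X, " events but only ", n_mappable,
           " mappable trials")
    w <- segs$width * segs[[paste0("r", d)]]
    chosen_key <- numeric(0)
    chosen_seg <- integer(0)
    chosen_pos <- numeric(0)
    while (length(chosen_key) < X) {
      m <- X - length(chosen_key)
      si <- sample.int(nrow(segs), m, replace = TRUE, prob = w)
      pos <- segs$start[si] + floor(runif(m) * segs$width[si])
      key <- segs$offset[si] + (pos - segs$start[si])
      keep <- !duplicated(c(chosen_key, key))[length(chosen_key) +
                                                seq_len(m)]
      chosen_key <- c(chosen_key, key[keep])
      chosen_seg <- c(chosen_seg, si[keep])
      chosen_pos <- c(chosen_pos, pos[keep])
    }
    is_dataset(data.frame(chrom = segs$chrom[chosen_seg],
                          position = chosen_pos,
                          strand = segs$strand[chosen_seg]),
               scenario$support, blind = scenario$blind,
               label = scenario$labels[d])
  })
}

#' Expected in-plant event fraction under a scenario
#'
#' Closed-form expectation of the fraction of a series' events falling in
#' the planted intervals under the weighted-sampling scheme (first-draw
#' probability; exact in the large-`N` limit).
#'
#' @param scenario a [simulation_scenario()].
#' @param series 1 or 2.
#' @return Expected fraction in `[0, 1]`.
#' @export
expected_plant_fraction <- function(scenario, series = 1) {
  segs <- .sim_segments(scenario)
  r <- segs[[paste0("r", series)]]
  sum(segs$width[r != 1] * r[r != 1]) / sum(segs$width * r)
}

#' Write a deterministic suite of synthetic fixtures
#'
#' Generates a small set of scenario files exercising every pipeline mode:
#' a chromosome-sizes table, a strand-mixed blind-region BED, a uniform
#' null series, a shared-cluster pair (relative-scan null), a planted
#' relative-cluster pair, and a series with two disjoint planted clusters.
#' All files are plain text and reproducible from the seed.
#'
#' @param out_dir output directory (created if missing).
#' @param seed integer seed.
#' @return Named character vector of written paths, invisibly.
#' @export
make_fixture_suite <- function(out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  support <- genome_support(c(sim1 = 200000, sim2 = 100000))
  mask <- data.frame(chrom = c("sim1", "sim1", "sim2"),
                     start = c(20001, 120001, 50001),
                     end = c(22000, 121000, 53000),
                     strand = c("+", "*", "-"))
  blind <- blind_regions(mask, support)
  paths <- c(chrom_sizes = file.path(out_dir, "chrom_sizes.tsv"),
             blind = file.path(out_dir, "blind.bed"),
             null = file.path(out_dir, "null_series.tsv"),
             shared1 = file.path(out_dir, "shared_cluster_1.tsv"),
             shared2 = file.path(out_dir, "shared_cluster_2.tsv"),
             rel1 = file.path(out_dir, "relative_cluster_1.tsv"),
             rel2 = file.path(out_dir, "relative_cluster_2.tsv"),
             two = file.path(out_dir, "two_clusters.tsv"),
             meta = file.path(out_dir, "scenarios.json"))
  write.table(data.frame(names(support$chrom), support$chrom),
              paths["chrom_sizes"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  bed <- data.frame(chrom = mask$chrom, start = mask$start - 1,
                    end = mask$end, name = "blind", score = 0,
                    strand = ifelse(mask$strand == "*", ".", mask$strand))
  write.table(bed, paths["blind"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  seeds <- .spawn_seeds(seed, 4)

  null_sc <- simulation_scenario(support, blind, n_events = 300,
                                 labels = "null_series")
  write_is_table(simulate_is(null_sc, seed = seeds[1])[[1]],
                 paths["null"])
  shared_sc <- simulation_scenario(support, blind, n_events = c(300, 300),
    plants = data.frame(chrom = "sim1", start = 60001, end = 64000,
                        r1 = 8, r2 = 8),
    labels = c("shared_cluster_1", "shared_cluster_2"))
  sh <- simulate_is(shared_sc, seed = seeds[2])
  write_is_table(sh[[1]], paths["shared1"])
  write_is_table(sh[[2]], paths["shared2"])
  rel_sc <- simulation_scenario(support, blind, n_events = c(300, 300),
    plants = data.frame(chrom = "sim1", start = 100001, end = 103000,
                        r1 = 25, r2 = 1),
    labels = c("relative_cluster_1", "relative_cluster_2"))
  rl <- simulate_is(rel_sc, seed = seeds[3])
  write_is_table(rl[[1]], paths["rel1"])
  write_is_table(rl[[2]], paths["rel2"])
  two_sc <- simulation_scenario(support, blind, n_events = 400,
    plants = data.frame(chrom = c("sim1", "sim2"),
                        start = c(30001, 70001), end = c(33000, 73000),
                        r1 = 30, r2 = 30),
    labels = "two_clusters")
  write_is_table(simulate_is(two_sc, seed = seeds[4])[[1]], paths["two"])
  jsonlite::write_json(list(
    seed = seed, child_seeds = seeds,
    support = as.list(support$chrom),
    scenarios = list(
      null = list(n_events = 300),
      shared_cluster = list(n_events = c(300, 300), plant = "sim1:60001-64000",
                            k = 8),
      relative_cluster = list(n_events = c(300, 300),
                              plant = "sim1:100001-103000", r1 = 25,
                              r2 = 1),
      two_clusters = list(n_events = 400,
                          plants = c("sim1:30001-33000",
                                     "sim2:70001-73000"), k = 30))),
    paths["meta"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
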