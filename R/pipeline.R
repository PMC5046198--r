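#' Assemble a pipeline run configuration
#'
#' Defaults match the analysis settings the method was designed around:
#' zones longer than 2.5e7 bp or holding fewer than 3 pooled events are
#' filtered, and detection uses a family-wise significance level of 0.01.
#' An `L_max` above half the support triggers a warning (such clusters are
#' rarely informative) but is allowed.
#'
#' @param mode `"scan"` (univariate), `"relscan"` (two series) or
#'   `"simulate"`.
#' @param chrom_sizes path to a chromosome-sizes TSV.
#' @param is1,is2 paths to IS coordinate tables (`is2` only for
#'   `relscan`).
#' @param blind optional path to a blind-region BED mask.
#' @param scenario for `simulate`: path to a YAML scenario file with keys
#'   `n_events` (one or two counts) and optionally `plants` (list of
#'   `chrom`, `start`, `end`, `r1`, `r2`) and `labels`.
#' @param lmax,ecmin,alpha scan parameters.
#' @param pvalue_mode `"chisq"` (default) or `"montecarlo"` (univariate
#'   scan maximum only; `mc_replicates` controls the replicate count).
#' @param sequential_mode `"one-per-round"` or `"batch"`.
#' @param mc_replicates Monte Carlo replicates for
#'   `pvalue_mode = "montecarlo"`.
#' @param seed integer seed for any randomness (simulation, Monte Carlo).
#' @param out output directory.
#' @return A list of class `run_config`.
#' @export
run_config <- function(mode = c("scan", "relscan", "simulate"),
                       chrom_sizes, is1 = NULL, is2 = NULL, blind = NULL,
                       scenario = NULL, lmax = 2.5e7, ecmin = 3,
                       alpha = 0.01,
                       pvalue_mode = c("chisq", "montecarlo"),
                       sequential_mode = c("one-per-round", "batch"),
                       mc_replicates = 999, seed = NULL, out = ".") {
  mode <- match.arg(mode)
  pvalue_mode <- match.arg(pvalue_mode)
  sequential_mode <- match.arg(sequential_mode)
  if (mode == "scan" && is.null(is1)) stop("scan mode needs --is1")
  if (mode == "relscan" && (is.null(is1) || is.null(is2)))
    stop("relscan mode needs --is1 and --is2")
  if (mode == "simulate" && is.null(scenario))
    stop("simulate mode needs --scenario")
  structure(list(mode = mode, chrom_sizes = chrom_sizes, is1 = is1,
                 is2 = is2, blind = blind, scenario = scenario,
                 lmax = lmax, ecmin = ecmin, alpha = alpha,
                 pvalue_mode = pvalue_mode,
                 sequential_mode = sequential_mode,
                 mc_replicates = mc_replicates,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 out = out),
            class = "run_config")
}

.log_step <- function(...) message("[relscan] ", ...)

#' Run the scan pipeline from a configuration
#'
#' Executes the full workflow for the configured mode: load inputs,
#' compute effective sizes and totals, enumerate and filter zones, scan,
#' adjust, sequentially detect, and write the output files (ranked cluster
#' table, detection report TSV + JSON metadata, BED of accepted zones).
#' Per-step counts (effective genome size, totals, zone-family sizes) are
#' logged via [message()]. Re-running with an identical configuration and
#' seed reproduces identical outputs.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the main in-memory results (`report`,
#'   `scan`, and for simulate the datasets).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  support <- read_chrom_sizes(config$chrom_sizes)
  blind <- if (is.null(config$blind)) blind_regions(NULL, support) else
    read_blind_bed(config$blind, support)

  if (config$mode == "simulate") {
    sc <- yaml::read_yaml(config$scenario)
    plants <- if (!is.null(sc$plants))
      do.call(rbind, lapply(sc$plants, as.data.frame))
    scen <- simulation_scenario(support, blind,
                                n_events = unlist(sc$n_events),
                                plants = plants,
                                labels = if (!is.null(sc$labels))
                                  unlist(sc$labels) else
                                  paste0("series",
                                         seq_along(unlist(sc$n_events))))
    ds <- simulate_is(scen, seed = config$seed)
    paths <- vapply(ds, function(d) {
      p <- file.path(config$out, paste0(d$label, ".tsv"))
      write_is_table(d, p)
      p
    }, character(1))
    .log_step("simulated ", length(ds), " dataset(s): ",
              paste(basename(paths), collapse = ", "))
    return(invisible(list(datasets = ds, paths = paths)))
  }

  N <- effective_genome_size(support, blind)
  d1 <- read_is_table(config$is1, support, blind)
  datasets <- list(d1)
  if (config$mode == "relscan")
    datasets <- c(datasets, list(read_is_table(config$is2, support,
                                               blind)))
  X <- vapply(datasets, function(d) nrow(d$events), numeric(1))
  .log_step("effective genome size N = ", format(N, big.mark = ","),
            "; totals X = ", paste(X, collapse = ", "))
  ub <- zone_upper_bound(X[1], if (length(X) > 1) X[2] else 0)
  zones <- enumerate_zones(datasets, support, blind, L_max = config$lmax,
                           EC_min = config$ecmin)
  if (config$lmax > sum(support$chrom) / 2)
    warning("L_max exceeds half of the support; very long zones are ",
            "rarely informative")
  .log_step("|Z| = ", nrow(zones), " zone(s) after filters (upper bound ",
            format(ub, big.mark = ","), ")")
  if (nrow(zones) == 0L) {
    .log_step("no candidate zones; writing empty outputs")
    empty <- structure(data.frame(), class =
      c(if (config$mode == "relscan") "rel_scan" else "uni_scan",
        "data.frame"))
    write_cluster_table(empty, file.path(config$out, "clusters.tsv"))
    return(invisible(list(report = NULL, scan = NULL)))
  }
  scan <- if (config$mode == "relscan") scan_rel(zones) else
    scan_uni(zones)
  scan$p_adj <- holm_adjust(scan$p_raw)
  if (config$mode == "scan" && config$pvalue_mode == "montecarlo") {
    .log_step("Monte Carlo null maxima: ", config$mc_replicates,
              " replicate(s)")
    null_max <- mc_null_max_lambda(support, blind, X[1],
                                   L_max = config$lmax,
                                   EC_min = config$ecmin,
                                   B = config$mc_replicates,
                                   seed = config$seed)
    attr(scan, "mc_p_max") <- pvalue_uni(scan$lambda[1],
                                         method = "montecarlo",
                                         null_max = null_max)
    .log_step("Monte Carlo p-value of the scan maximum: ",
              signif(attr(scan, "mc_p_max"), 4))
  }
  write_cluster_table(scan, file.path(config$out, "clusters.tsv"))
  report <- detect_sequential(datasets, support, blind,
                              L_max = config$lmax, EC_min = config$ecmin,
                              alpha = config$alpha,
                              accept = config$sequential_mode)
  .log_step("sequential detection: ", nrow(report$accepted),
            " accepted zone(s), stopped: ", report$stopped)
  write_detection_report(report, file.path(config$out, "detections.tsv"))
  if (nrow(report$accepted)) {
    bed <- data.frame(chrom = report$accepted$chrom,
                      start = report$accepted$start - 1,
                      end = report$accepted$end,
                      name = paste0("cluster_", report$accepted$round),
                      score = round(pmin(report$accepted$lambda, 1000)),
                      strand = ".")
    write.table(format(bed, scientific = FALSE, trim = TRUE),
                file.path(config$out, "detections.bed"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(list(report = report, scan = scan))
}

#' Command-line entry point
#'
#' Thin wrapper over [run_config()] and [run_pipeline()]. The first
#' argument is the subcommand (`scan`, `relscan` or `simulate`), followed
#' by flags. An executable script using this function is installed under
#' `system.file("scripts", "relscan", package = "relscan")`.
#'
#' @param args character vector of command-line arguments (subcommand
#'   first), e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return Exit status, invisibly (0 on success).
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args) || args[1] %in% c("-h", "--help")) {
    cat("usage: relscan <scan|relscan|simulate> [options]\n",
        "run 'relscan <subcommand> --help' for options\n")
    return(invisible(0L))
  }
  mode <- args[1]
  if (!mode %in% c("scan", "relscan", "simulate"))
    stop("unknown subcommand '", mode,
         "'; expected scan, relscan or simulate")
  opts <- list(
    optparse::make_option("--is1", type = "character", default = NULL,
                          help = "first IS table (chr, position, strand)"),
    optparse::make_option("--is2", type = "character", default = NULL,
                          help = "second IS table (relscan mode)"),
    optparse::make_option("--blind", type = "character", default = NULL,
                          help = "blind-region BED mask"),
    optparse::make_option("--chrom-sizes", type = "character",
                          dest = "chrom_sizes",
                          help = "chromosome sizes TSV (required)"),
    optparse::make_option("--scenario", type = "character",
                          default = NULL,
                          help = "YAML scenario file (simulate mode)"),
    optparse::make_option("--lmax", type = "double", default = 2.5e7,
                          help = "maximum zone length in bp [%default]"),
    optparse::make_option("--ecmin", type = "integer", default = 3L,
                          help = "minimum pooled events per zone [%default]"),
    optparse::make_option("--alpha", type = "double", default = 0.01,
                          help = "family-wise significance level [%default]"),
    optparse::make_option("--pvalue-mode", type = "character",
                          default = "chisq", dest = "pvalue_mode",
                          help = "chisq or montecarlo [%default]"),
    optparse::make_option("--sequential-mode", type = "character",
                          default = "one-per-round",
                          dest = "sequential_mode",
                          help = "one-per-round or batch [%default]"),
    optparse::make_option("--mc-replicates", type = "integer",
                          default = 999L, dest = "mc_replicates",
                          help = "Monte Carlo replicates [%default]"),
    optparse::make_option("--seed", type = "integer", default = NULL,
                          help = "seed for simulation / Monte Carlo"),
    optparse::make_option("--out", type = "character", default = ".",
                          help = "output directory [%default]"))
  parser <- optparse::OptionParser(
    usage = paste0("relscan ", mode, " [options]"), option_list = opts)
  o <- optparse::parse_args(parser, args = args[-1])
  if (is.null(o$chrom_sizes)) stop("--chrom-sizes is required")
  cfg <- run_config(mode = mode, chrom_sizes = o$chrom_sizes,
                    is1 = o$is1, is2 = o$is2, blind = o$blind,
                    scenario = o$scenario, lmax = o$lmax,
                    ecmin = o$ecmin, alpha = o$alpha,
                    pvalue_mode = o$pvalue_mode,
                    sequential_mode = o$sequential_mode,
                    mc_replicates = o$mc_replicates, seed = o$seed,
                    out = o$out)
  run_pipeline(cfg)
  invisible(0L)
}
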