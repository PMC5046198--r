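test_that("effective genome size subtracts strand-specific blind bases", {
  g1 <- genome_support(c(chr1 = 1000))
  expect_identical(effective_genome_size(g1), 2000)

  b <- blind_regions(data.frame(chrom = "chr1", start = c(1, 901),
                                end = c(100, 1000),
                                strand = c("+", "-")), g1)
  expect_identical(effective_genome_size(g1, b), 1800)

  g2 <- genome_support(c(chr1 = 500, chr2 = 300))
  b2 <- blind_regions(data.frame(chrom = "chr1", start = 1, end = 50,
                                 strand = "+"), g2)
  expect_identical(effective_genome_size(g2, b2), 1550)

  # "*" strand masks both strands; overlaps merge on load
  b3 <- blind_regions(data.frame(chrom = "chr1", start = c(1, 26),
                                 end = c(50, 60), strand = "*"), g2)
  expect_identical(effective_genome_size(g2, b3), 1600 - 120)
  expect_identical(nrow(b3$regions), 2L)
})

test_that("effective interval size handles masks and degenerate spans", {
  g <- genome_support(c(chr1 = 1000))
  b <- blind_regions(data.frame(chrom = "chr1",
                                start = c(101, 151),
                                end = c(110, 155),
                                strand = c("+", "-")), g)
  expect_identical(effective_interval_size(g, b, "chr1", 101, 200), 185)
  expect_identical(effective_interval_size(g, NULL, "chr1", 500, 500), 2)
  bfull <- blind_regions(data.frame(chrom = "chr1", start = 301,
                                    end = 400, strand = "*"), g)
  expect_identical(effective_interval_size(g, bfull, "chr1", 301, 400), 0)
  # partial overlap only counts masked bases inside the query
  expect_identical(effective_interval_size(g, b, "chr1", 105, 200), 181)
})

test_that("interval and mask bounds are validated", {
  g <- genome_support(c(chr1 = 1000))
  expect_error(blind_regions(data.frame(chrom = "chr1", start = 900,
                                        end = 1100, strand = "+"), g),
               "exceed")
  expect_error(blind_regions(data.frame(chrom = "chrX", start = 1,
                                        end = 10, strand = "+"), g),
               "unknown")
  expect_error(effective_interval_size(g, NULL, "chr1", 900, 1100),
               "outside")
  expect_error(effective_interval_size(g, NULL, "chr1", 200, 100), "<=")
  expect_error(genome_support(c(chr1 = 0)), "positive")
})

test_that("count_events is boundary-inclusive and pools strands", {
  g <- genome_support(c(chr1 = 1000, chr2 = 500))
  d <- is_dataset(data.frame(chrom = "chr1", position = c(100, 200, 300),
                             strand = c("+", "-", "+")), g)
  expect_identical(count_events(d, "chr1", 100, 200), 2L)
  expect_identical(count_events(d, "chr1", 100, 300), 3L)
  expect_identical(count_events(d, "chr2", 1, 500), 0L)
})

test_that("interval sizes and counts are additive over partitions", {
  set.seed(7)
  g <- genome_support(c(chrA = 5000, chrB = 2000))
  s <- sample.int(4900, 8)
  b <- blind_regions(data.frame(chrom = "chrA", start = s,
                                end = s + sample.int(80, 8),
                                strand = sample(c("+", "-", "*"), 8,
                                                replace = TRUE)), g)
  d <- is_dataset(data.frame(chrom = "chrA",
                             position = sample.int(5000, 50),
                             strand = sample(c("+", "-"), 50,
                                             replace = TRUE)),
                  g, on_blind = "error")
  cuts <- sort(sample(2:4999, 6))
  starts <- c(1, cuts)
  ends <- c(cuts - 1, 5000)
  sizes <- effective_interval_size(g, b, rep("chrA", 7), starts, ends)
  chrA_total <- 2 * 5000 - sum(with(b$regions, end - start + 1))
  expect_equal(sum(sizes), chrA_total)
  counts <- vapply(seq_along(starts), function(i)
    count_events(d, "chrA", starts[i], ends[i]), integer(1))
  expect_identical(sum(counts), 50L)
  # nested intervals: size is monotone in length
  expect_true(all(diff(effective_interval_size(
    g, b, rep("chrA", 10), rep(1, 10), seq(500, 5000, 500))) >= 0))
})

test_that("events in blind regions are rejected or dropped on request", {
  g <- genome_support(c(chr1 = 1000))
  b <- blind_regions(data.frame(chrom = "chr1", start = 100, end = 200,
                                strand = "+"), g)
  ev <- data.frame(chrom = "chr1", position = c(150, 150, 500),
                   strand = c("+", "-", "+"))
  expect_error(is_dataset(ev, g, b), "blind")
  expect_warning(d <- is_dataset(ev, g, b, on_blind = "drop"), "dropped")
  # the minus-strand event at 150 survives: mask is strand-specific
  expect_identical(nrow(d$events), 2L)
  expect_warning(
    is_dataset(rbind(ev[3, ], ev[3, ]), g),
    "duplicated")
})
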