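test_that("zones are all event-delimited pairs, subject to the filters", {
  g <- genome_support(c(chr1 = 100000))
  d <- is_dataset(data.frame(chrom = "chr1", position = c(100, 200, 300),
                             strand = "+"), g)
  z <- enumerate_zones(d, g, NULL, L_max = 1e4, EC_min = 2)
  expect_identical(nrow(z), 3L)
  expect_setequal(paste(z$start, z$end),
                  c("100 200", "200 300", "100 300"))
  # only the full span holds 3 events
  z3 <- enumerate_zones(d, g, NULL, L_max = 1e4, EC_min = 3)
  expect_identical(nrow(z3), 1L)
  expect_identical(c(z3$start, z3$end), c(100, 300))
  # length filter: simple coordinate difference, boundary kept
  zl <- enumerate_zones(d, g, NULL, L_max = 150, EC_min = 2)
  expect_setequal(paste(zl$start, zl$end), c("100 200", "200 300"))
  zb <- enumerate_zones(d, g, NULL, L_max = 100, EC_min = 2)
  expect_identical(nrow(zb), 2L)  # zones of exactly L_max are kept
})

test_that("zone effective sizes and counts match the genome model", {
  g <- genome_support(c(chr1 = 100000))
  b <- blind_regions(data.frame(chrom = "chr1", start = 150, end = 250,
                                strand = "+"), g)
  d <- is_dataset(data.frame(chrom = "chr1", position = c(100, 300, 500),
                             strand = c("+", "-", "+")), g, b)
  z <- enumerate_zones(d, g, b, L_max = 1e4, EC_min = 2)
  for (i in seq_len(nrow(z))) {
    expect_identical(z$n[i], effective_interval_size(g, b, z$chrom[i],
                                                     z$start[i],
                                                     z$end[i]))
    expect_identical(z$x1[i], as.numeric(count_events(d, z$chrom[i],
                                                      z$start[i],
                                                      z$end[i])))
    expect_true(z$n[i] >= z$x1[i])
  }
})

test_that("zone count respects the pooled-pair upper bound", {
  expect_identical(zone_upper_bound(3, 0), 3)
  expect_identical(zone_upper_bound(2, 2), 6)
  expect_identical(zone_upper_bound(0, 0), 0)

  set.seed(11)
  g <- genome_support(c(chr1 = 50000))
  d1 <- is_dataset(data.frame(chrom = "chr1",
                              position = sample.int(50000, 15),
                              strand = "+"), g, label = "a")
  d2 <- is_dataset(data.frame(chrom = "chr1",
                              position = sample.int(50000, 10),
                              strand = "-"), g, label = "b")
  z <- enumerate_zones(list(d1, d2), g, NULL, L_max = 50000, EC_min = 1)
  expect_lte(nrow(z), zone_upper_bound(15, 10))
  # all events on one chromosome, distinct positions: bound attained
  if (length(unique(c(d1$events$position, d2$events$position))) == 25)
    expect_identical(nrow(z), as.integer(zone_upper_bound(15, 10)))
  # two-series zones are delimited by the pooled event set
  expect_true(all(z$start %in% c(d1$events$position, d2$events$position)))
  expect_true(all((z$x1 + z$x2) >= 1))
})

test_that("length and count filters commute", {
  set.seed(3)
  g <- genome_support(c(chr1 = 20000))
  d <- is_dataset(data.frame(chrom = "chr1",
                             position = sample.int(20000, 30),
                             strand = sample(c("+", "-"), 30, TRUE)), g)
  zf <- enumerate_zones(d, g, NULL, L_max = 3000, EC_min = 4)
  zu <- enumerate_zones(d, g, NULL, L_max = .Machine$double.xmax,
                        EC_min = 1)
  manual <- zu[zu$length <= 3000 & zu$x1 >= 4, ]
  expect_identical(nrow(zf), nrow(manual))
  expect_setequal(paste(zf$start, zf$end), paste(manual$start, manual$end))
})

test_that("zones never span chromosomes and empty input gives no zones", {
  g <- genome_support(c(chr1 = 1000, chr2 = 1000))
  d <- is_dataset(data.frame(chrom = c("chr1", "chr1", "chr2", "chr2"),
                             position = c(10, 20, 30, 40),
                             strand = "+"), g)
  z <- enumerate_zones(d, g, NULL, L_max = 1000, EC_min = 2)
  expect_identical(nrow(z), 2L)
  expect_true(all(z$chrom == c("chr1", "chr2")))
  empty <- is_dataset(data.frame(chrom = character(),
                                 position = numeric(),
                                 strand = character()), g)
  expect_identical(nrow(enumerate_zones(empty, g, NULL)), 0L)
})

test_that("scan on event-delimited zones equals the exhaustive scan", {
  set.seed(101)
  for (r in 1:5) {
    inst <- rand_scan_instance(L = sample(300:900, 1))
    if (length(unique(inst$events$position)) < 2) next
    pk <- pkg_instance(inst)
    z <- enumerate_zones(pk$dataset, pk$support, pk$blind,
                         L_max = inst$L, EC_min = 2)
    res <- scan_uni(z)
    bf <- brute_scan_uni(inst, EC_min = 2)
    expect_equal(attr(res, "totals")$N, bf$N)
    expect_equal(res$lambda[1], bf$max_lambda,
                 tolerance = 1e-9)
  }
})
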