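test_that("holm adjustment reproduces the step-down computation", {
  # by-hand step-down: m=3 -> (3*.001, max(.003, 2*.02), max(.04, 1*.04))
  expect_equal(holm_adjust(c(0.001, 0.02, 0.04)), c(0.003, 0.04, 0.04))
  expect_identical(holm_adjust(numeric(0)), numeric(0))
  expect_identical(holm_adjust(c(1, 1, 1)), c(1, 1, 1))
  expect_identical(holm_adjust(0.03), 0.03)
  # order-preservation and elementwise dominance over raw p
  set.seed(9)
  p <- runif(50)
  adj <- holm_adjust(p)
  expect_true(all(adj >= p))
  expect_equal(adj[which.min(p)], min(1, 50 * min(p)))
  expect_error(holm_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("a single strong planted cluster is detected in one round", {
  set.seed(71)
  g <- genome_support(c(chr1 = 50000))
  scen <- simulation_scenario(
    g, NULL, n_events = 150,
    plants = data.frame(chrom = "chr1", start = 20001, end = 22000,
                        r1 = 50))
  d <- simulate_is(scen, seed = 3)[[1]]
  rep <- detect_sequential(d, g, NULL, L_max = 2.5e7, EC_min = 3,
                           alpha = 0.01)
  expect_identical(rep$stopped, "not_significant")
  expect_identical(nrow(rep$accepted), 1L)
  expect_gt(jaccard_iv(rep$accepted$start[1], rep$accepted$end[1],
                       20001, 22000), 0.5)
  expect_lt(rep$accepted$p_adj[1], 0.01)
  # round-2 residual totals reflect the removal
  expect_identical(nrow(rep$rounds), 2L)
  expect_equal(rep$rounds$X1[2],
               rep$rounds$X1[1] - rep$accepted$x1[1])
  n_rm <- effective_interval_size(g, NULL, "chr1",
                                  rep$accepted$start[1],
                                  rep$accepted$end[1])
  expect_equal(rep$rounds$N[2], rep$rounds$N[1] - n_rm)
})

test_that("two disjoint planted clusters are found in successive rounds", {
  set.seed(73)
  g <- genome_support(c(chr1 = 50000))
  scen <- simulation_scenario(
    g, NULL, n_events = 150,
    plants = data.frame(chrom = "chr1", start = c(10001, 35001),
                        end = c(12000, 37000), r1 = 40))
  d <- simulate_is(scen, seed = 5)[[1]]
  rep <- detect_sequential(d, g, NULL, alpha = 0.01)
  expect_gte(nrow(rep$accepted), 2L)
  acc <- rep$accepted[order(rep$accepted$start), ]
  # pairwise disjoint by construction
  if (nrow(acc) > 1)
    expect_true(all(acc$start[-1] > acc$end[-nrow(acc)]))
  expect_true(any(jaccard_iv(acc$start, acc$end, 10001, 12000) > 0.4))
  expect_true(any(jaccard_iv(acc$start, acc$end, 35001, 37000) > 0.4))
  expect_true(all(diff(rep$accepted$round) > 0))
})

test_that("identical inputs to the relative scan yield no detections", {
  set.seed(77)
  g <- genome_support(c(chr1 = 50000))
  scen <- simulation_scenario(g, NULL, n_events = 100)
  d <- simulate_is(scen, seed = 11)[[1]]
  d2 <- d; d2$label <- "copy"
  rep <- detect_sequential(list(d, d2), g, NULL, alpha = 0.01)
  expect_identical(nrow(rep$accepted), 0L)
  expect_identical(rep$stopped, "not_significant")
  expect_equal(rep$rounds$top_lambda[1], 0, tolerance = 1e-6)
})

test_that("batch acceptance keeps accepted zones disjoint", {
  set.seed(79)
  g <- genome_support(c(chr1 = 50000))
  scen <- simulation_scenario(
    g, NULL, n_events = 150,
    plants = data.frame(chrom = "chr1", start = c(10001, 35001),
                        end = c(12000, 37000), r1 = 40))
  d <- simulate_is(scen, seed = 13)[[1]]
  rep <- detect_sequential(d, g, NULL, alpha = 0.01, accept = "batch")
  acc <- rep$accepted[order(rep$accepted$start), ]
  expect_gte(nrow(acc), 2L)
  expect_true(all(acc$start[-1] > acc$end[-nrow(acc)]))
})

test_that("max_rounds caps the loop", {
  set.seed(83)
  g <- genome_support(c(chr1 = 50000))
  scen <- simulation_scenario(
    g, NULL, n_events = 150,
    plants = data.frame(chrom = "chr1", start = c(10001, 35001),
                        end = c(12000, 37000), r1 = 40))
  d <- simulate_is(scen, seed = 17)[[1]]
  rep <- detect_sequential(d, g, NULL, alpha = 0.01, max_rounds = 1)
  expect_identical(nrow(rep$accepted), 1L)
  expect_identical(rep$stopped, "max_rounds")
})
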