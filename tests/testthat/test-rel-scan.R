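test_that("unconstrained likelihood matches closed forms and decomposes", {
  inp <- rel_inputs(5, 10, 5, 100, 5, 10, 5, 100)
  expect_equal(loglik_h1(inp), 2 * 10 * log(0.5), tolerance = 1e-12)
  # all-zero zone with empty series
  g0 <- rel_inputs(0, 10, 0, 100, 0, 10, 0, 100)
  expect_identical(loglik_h1(g0), 0)
  # independence: the joint supremum is the sum of per-series suprema
  set.seed(21)
  for (r in 1:50) {
    N1 <- sample(200:2000, 1); N2 <- sample(200:2000, 1)
    X1 <- sample(1:40, 1); X2 <- sample(1:40, 1)
    n1 <- sample(1:(N1 - 1), 1); n2 <- sample(1:(N2 - 1), 1)
    x1 <- sample(max(0, X1 - (N1 - n1)):min(n1, X1), 1)
    x2 <- sample(max(0, X2 - (N2 - n2)):min(n2, X2), 1)
    per_series <- function(x, n, X, N) {
      p <- x / n; q <- (X - x) / (N - n)
      xlogy_o(x, p) + xlogy_o(n - x, 1 - p) + xlogy_o(X - x, q) +
        xlogy_o((N - n) - (X - x), 1 - q)
    }
    expect_equal(loglik_h1(rel_inputs(x1, n1, X1, N1, x2, n2, X2, N2)),
                 per_series(x1, n1, X1, N1) + per_series(x2, n2, X2, N2),
                 tolerance = 1e-12)
  }
  expect_error(rel_inputs(5, 0, 5, 100, 1, 10, 5, 100), "trial")
  expect_error(rel_inputs(11, 10, 20, 100, 1, 10, 5, 100), "success")
})

test_that("identical series saturate the shared-multiplier null", {
  inp <- rel_inputs(5, 100, 20, 1000, 5, 100, 20, 1000)
  f <- fit_h0(inp)
  expect_equal(f$ll0, loglik_h1(inp), tolerance = 1e-10)
  expect_equal(f$k, (5 / 100) / (15 / 900), tolerance = 1e-6)
  expect_equal(f$q1, 15 / 900, tolerance = 1e-6)
  lr <- lambda_rel(inp)
  expect_equal(lr$lambda, 0, tolerance = 1e-8)
  expect_equal(lr$p_raw, 1, tolerance = 1e-8)
})

test_that("constrained fit matches the refining grid-search oracle", {
  set.seed(31)
  for (r in 1:10) {
    N1 <- sample(500:3000, 1); N2 <- sample(500:3000, 1)
    X1 <- sample(5:60, 1); X2 <- sample(5:60, 1)
    n1 <- sample(20:300, 1); n2 <- sample(20:300, 1)
    x1 <- sample(1:min(n1 %/% 2, X1), 1)
    x2 <- sample(1:min(n2 %/% 2, X2), 1)
    o <- grid_fit_h0(x1, n1, X1, N1, x2, n2, X2, N2)
    f <- fit_h0(rel_inputs(x1, n1, X1, N1, x2, n2, X2, N2))
    expect_lt(abs(f$ll0 - o$ll0) / abs(o$ll0), 1e-4)
    expect_gte(2 * (loglik_h1(rel_inputs(x1, n1, X1, N1,
                                         x2, n2, X2, N2)) - f$ll0),
               -1e-8)
  }
})

test_that("empty-zone and empty-series boundaries are handled", {
  # no in-zone successes at all: k collapses to the lower boundary
  inp <- rel_inputs(0, 100, 20, 1000, 0, 100, 10, 1000)
  f <- fit_h0(inp)
  expect_true(f$boundary)
  expect_lt(f$k, 1e-6)
  expect_gte(lambda_rel(inp)$lambda, 0)
  # an entirely empty second series carries no information: the shared
  # multiplier can absorb series 1 completely, so lambda is 0
  inp2 <- rel_inputs(8, 100, 20, 1000, 0, 100, 0, 1000)
  expect_equal(lambda_rel(inp2)$lambda, 0, tolerance = 1e-6)
})

test_that("lambda is nonnegative and invariant under series exchange", {
  set.seed(41)
  for (r in 1:40) {
    N <- sample(1000:5000, 1)
    X1 <- sample(2:80, 1); X2 <- sample(2:80, 1)
    n <- sample(10:(N %/% 3), 1)
    x1 <- sample(0:min(n, X1), 1); x2 <- sample(0:min(n, X2), 1)
    a <- lambda_rel(rel_inputs(x1, n, X1, N, x2, n, X2, N))
    b <- lambda_rel(rel_inputs(x2, n, X2, N, x1, n, X1, N))
    expect_gte(a$lambda, 0)
    expect_equal(a$lambda, b$lambda, tolerance = 1e-9)
  }
})

test_that("classification compares in/out rate ratios with sign symmetry", {
  cl <- classify_relative(5, 1)
  expect_identical(as.character(cl$label), "series1")
  expect_equal(cl$log_ratio, log(5))
  cl2 <- classify_relative(1, 5)
  expect_identical(as.character(cl2$label), "series2")
  expect_equal(cl2$log_ratio, -log(5))
  tie <- classify_relative(2, 2)
  expect_identical(as.character(tie$label), "series1")
  expect_identical(tie$log_ratio, 0)
  expect_true(tie$tie)
  inf <- classify_relative(Inf, 3)
  expect_identical(as.character(inf$label), "series1")
  expect_identical(inf$log_ratio, Inf)
})

test_that("scan_rel ranks by lambda and labels the dominant series", {
  set.seed(51)
  g <- genome_support(c(chr1 = 100000))
  scen <- simulation_scenario(
    g, NULL, n_events = c(120, 120),
    plants = data.frame(chrom = "chr1", start = 40001, end = 42000,
                        r1 = 40, r2 = 1),
    labels = c("proc1", "proc2"))
  ds <- simulate_is(scen, seed = 7)
  z <- enumerate_zones(ds, g, NULL, L_max = 1e5, EC_min = 3)
  res <- scan_rel(z)
  expect_true(all(diff(res$lambda) <= 0))
  expect_true(all(res$lambda >= 0))
  top <- res[1, ]
  expect_identical(top$label, "proc1")
  expect_gt(jaccard_iv(top$start, top$end, 40001, 42000), 0.3)
  # swapping the datasets flips labels, negates log-ratios, keeps lambda
  z_sw <- enumerate_zones(rev(ds), g, NULL, L_max = 1e5, EC_min = 3)
  res_sw <- scan_rel(z_sw)
  key <- paste(res$start, res$end)
  key_sw <- paste(res_sw$start, res_sw$end)
  expect_setequal(key, key_sw)
  m <- match(key, key_sw)
  expect_equal(res_sw$lambda[m], res$lambda, tolerance = 1e-9)
  finite <- is.finite(res$log_ratio)
  expect_identical(res_sw$log_ratio[m][finite], -res$log_ratio[finite])
  # the winning process keeps its name: the label follows the dataset
  strict <- res$log_ratio != 0
  expect_identical(res_sw$label[m][strict], res$label[strict])
})
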