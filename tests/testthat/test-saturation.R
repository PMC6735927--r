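test_that("noiseless curves are recovered essentially exactly", {
  x <- seq(0.1, 5, length.out = 60)
  y <- 0.4 * x / (0.8 + x)
  fit <- fit_saturation(x, y)
  expect_equal(fit$a, 0.4, tolerance = 1e-6)
  expect_equal(fit$b, 0.8, tolerance = 1e-6)
  expect_lt(fit$sse, 1e-10)
  expect_true(fit$converged)
})

test_that("degenerate all-zero divergence yields a = 0 with unidentified b", {
  fit <- fit_saturation(seq(0.1, 2, length.out = 10), rep(0, 10))
  expect_equal(fit$a, 0)
  expect_equal(fit$sse, 0)
  expect_false(fit$b_identified)
})

test_that("fit is invariant under permutation of the points", {
  set.seed(3)
  d <- sim_curve_points(200, 0.5, 1.0, 0.05)
  f1 <- fit_saturation(d)
  idx <- sample.int(nrow(d))
  f2 <- fit_saturation(d[idx, ])
  expect_equal(f1$a, f2$a, tolerance = 1e-9)
  expect_equal(f1$b, f2$b, tolerance = 1e-9)
})

test_that("the fitted curve passes through the origin and is monotone", {
  set.seed(4)
  fit <- fit_saturation(sim_curve_points(100, 0.3, 0.6, 0.05))
  expect_equal(predict(fit, 0), 0)
  grid <- predict(fit, seq(0, 10, by = 0.1))
  expect_true(all(diff(grid) >= 0))
})

test_that("optimizer agrees with minpack.lm nonlinear least squares", {
  skip_if_not_installed("minpack.lm")
  set.seed(11)
  for (rep in 1:5) {
    d <- sim_curve_points(150, runif(1, 0.2, 0.8), runif(1, 0.3, 1.5), 0.05)
    fit <- fit_saturation(d)
    nls_fit <- minpack.lm::nlsLM(
      value ~ a * ks / (b + ks), data = d,
      start = list(a = mean(d$value), b = 1),
      lower = c(0, 1e-6), upper = c(1, 100))
    cf <- coef(nls_fit)
    expect_equal(fit$a, unname(cf["a"]), tolerance = 1e-4)
    expect_equal(fit$b, unname(cf["b"]), tolerance = 1e-3)
  }
})

test_that("optimizer matches exhaustive grid-search oracles", {
  set.seed(19)
  for (rep in 1:5) {
    n <- sample(50:200, 1)
    d <- sim_curve_points(n, runif(1, 0.2, 0.9), runif(1, 0.2, 1.5), 0.05)
    # fit over the same bounded box the grid enumerates
    fit <- fit_saturation(d, b_range = c(1e-3, 3))
    # the optimizer attains (at least) the dense 2-D grid minimum
    grid2d <- grid_fit_oracle(d$ks, d$value,
                              a_grid = seq(0, 1, by = 1e-3),
                              b_grid = seq(1e-3, 3, by = 1e-3))
    expect_lte(fit$sse, grid2d$sse + 1e-12)
    # parameters agree with the profiled exhaustive enumeration over b
    oracle <- grid_fit_profiled(d$ks, d$value, seq(1e-3, 3, by = 1e-3))
    expect_lte(abs(fit$a - oracle$a), 1e-3 + 1e-9)
    expect_lte(abs(fit$b - oracle$b), 1e-3 + 1e-9)
  }
})

test_that("identical partitions give F near 0 and p near 1", {
  set.seed(5)
  d <- sim_curve_points(300, 0.4, 0.8, 0.08)
  mc <- compare_partitions(list(one = d, two = d))
  expect_lt(mc$f_stat, 1e-6)
  expect_gt(mc$p_value, 0.999)
  # identical data give identical fits
  expect_equal(mc$fits$one$a, mc$fits$two$a)
  expect_equal(mc$fits$one$b, mc$fits$two$b)
})

test_that("F-test degrees of freedom follow the nested-model accounting", {
  set.seed(6)
  parts <- list(p1 = sim_curve_points(40, 0.3, 0.5, 0.05),
                p2 = sim_curve_points(60, 0.5, 0.5, 0.05))
  mc <- compare_partitions(parts)
  expect_equal(mc$df_num, 2L)
  expect_equal(mc$df_den, 100L - 4L)
  expect_gte(mc$combined$sse, mc$sse_separate)
})

test_that("nesting SSE inequality holds across random comparisons", {
  set.seed(8)
  for (rep in 1:20) {
    parts <- list(
      g1 = sim_curve_points(sample(20:80, 1), runif(1, 0.1, 0.9),
                            runif(1, 0.2, 2), runif(1, 0.01, 0.15)),
      g2 = sim_curve_points(sample(20:80, 1), runif(1, 0.1, 0.9),
                            runif(1, 0.2, 2), runif(1, 0.01, 0.15)))
    mc <- compare_partitions(parts)
    expect_gte(mc$combined$sse, mc$sse_separate - 1e-9)
    expect_gte(mc$p_value, 0); expect_lte(mc$p_value, 1)
  }
})

test_that("clearly different asymptotes are detected; shared curves are not", {
  set.seed(9)
  diff_parts <- list(lo = sim_curve_points(300, 0.2, 0.6, 0.1),
                     hi = sim_curve_points(300, 0.4, 0.6, 0.1))
  expect_lt(compare_partitions(diff_parts)$p_value, 1e-4)
  same <- list(a = sim_curve_points(300, 0.3, 0.6, 0.1),
               b = sim_curve_points(300, 0.3, 0.6, 0.1))
  expect_gt(compare_partitions(same)$p_value, 1e-4)
})

test_that("bootstrap band contains the point estimate and narrows with noise", {
  set.seed(10)
  d <- sim_curve_points(150, 0.4, 0.8, 0.1)
  fit <- fit_saturation(d)
  band <- confidence_band(fit, n_boot = 200, seed = 99)
  expect_true(all(band$lower <= band$fit + 1e-12))
  expect_true(all(band$upper >= band$fit - 1e-12))
  quiet <- fit_saturation(sim_curve_points(150, 0.4, 0.8, 0.005))
  band_q <- confidence_band(quiet, n_boot = 200, seed = 99)
  expect_lt(mean(band_q$upper - band_q$lower),
            mean(band$upper - band$lower))
  expect_error(confidence_band(fit, n_boot = 10, seed = 1), "bootstrap")
})

test_that("the figure-suite driver partitions, fits, and compares correctly", {
  d <- generate_dataset(e2e_config(seed = 41))
  res <- assemble_records(d)
  suite <- run_figure_suite(res$records, measures = c("sd", "ed"),
                            scheme = "mode")
  expect_equal(nrow(suite$comparisons), 2L)
  for (ms in c("sd", "ed")) {
    f <- suite$fits[suite$fits$measure == ms, ]
    expect_lt(f$a[f$partition == "block"], f$a[f$partition == "tandem"])
  }
  within <- run_figure_suite(res$records, measures = "ed",
                             scheme = "mode_x_ppi")
  expect_setequal(within$comparisons$comparison,
                  c("within_tandem", "within_block"))
  # a single adequate partition still yields its fit, comparison skipped
  lone <- res$records[res$records$mode == "tandem", ]
  lone_res <- run_figure_suite(lone, measures = "ed", scheme = "mode")
  expect_equal(lone_res$fits$partition, "tandem")
  expect_null(lone_res$comparisons)
  expect_match(lone_res$skipped, "block")
})
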