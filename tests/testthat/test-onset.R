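step_data <- function(mid = 5, lo = 1, hi = 9, n_per = 5) {
  x <- rep(seq(lo, hi, by = 0.5), each = n_per)
  data.frame(stage = x, expression = as.integer(x > mid))
}

test_that("perfectly separated data give a capped slope with the right midpoint", {
  cv <- fit_onset_curve(step_data(5))
  expect_true(cv$flagged)
  expect_equal(abs(cv$b), 50)
  expect_gt(cv$midpoint, 4.5)
  expect_lt(cv$midpoint, 5.5)
})

test_that("uninformative designs return flagged flat curves, tiny data error", {
  d <- data.frame(stage = rep(c(2, 4, 6, 8), each = 2),
                  expression = rep(c(0, 1), 4))
  cv <- fit_onset_curve(d)
  expect_equal(cv$b, 0, tolerance = 1e-6)
  expect_equal(stats::plogis(cv$a), 0.5, tolerance = 1e-6)
  # one outcome class only
  cv1 <- fit_onset_curve(data.frame(stage = 1:6, expression = rep(1L, 6)))
  expect_true(cv1$flagged)
  expect_gt(stats::plogis(cv1$a), 0.99)
  # all observations at a single stage with mixed outcomes
  cv2 <- fit_onset_curve(data.frame(stage = rep(3, 6),
                                    expression = c(0, 1, 0, 1, 1, 0)))
  expect_true(cv2$flagged)
  expect_equal(cv2$b, 0)
  expect_error(fit_onset_curve(data.frame(stage = 1:3,
                                          expression = c(0, 1, 0))),
               "at least 4")
})

test_that("logistic fits recover a known midpoint", {
  hits <- 0L
  for (k in 1:50) {
    d <- sim_onset(data.frame(gene = "g", a = -10, b = 2),
                   stages = seq(1, 9, by = 0.5), n_per_stage = 12,
                   seed = 400 + k)  # n = 204
    cv <- fit_onset_curve(d)
    if (is.finite(cv$midpoint) && abs(cv$midpoint - 5) <= 0.3)
      hits <- hits + 1L
  }
  expect_gte(hits, 45L)
})

test_that("analytic AUC matches its closed-form special cases", {
  expect_equal(curve_auc(c(0, 0), 0, 10), 5)
  expect_equal(curve_auc(c(0, 1), -40, 40), 40, tolerance = 1e-10)
  expect_error(curve_auc(c(0, 1), 3, 3), "lo")
})

test_that("analytic AUC matches adaptive quadrature on random curves", {
  set.seed(10)
  for (k in 1:100) {
    a <- stats::runif(1, -30, 30)
    b <- stats::runif(1, -10, 10)
    lo <- stats::runif(1, -10, 5)
    hi <- lo + stats::runif(1, 0.5, 15)
    num <- stats::integrate(function(x) stats::plogis(a + b * x), lo, hi,
                            rel.tol = 1e-12)$value
    expect_equal(curve_auc(c(a, b), lo, hi), num, tolerance = 1e-8)
  }
})

test_that("delta is zero on identical data, symmetric, and tracks midpoint shifts", {
  d <- step_data(4)
  expect_equal(delta_obs(d, d), 0)
  d2 <- step_data(6)
  expect_equal(delta_obs(d, d2), delta_obs(d2, d))
  # both curves saturate inside the pooled range: delta ~ midpoint shift
  expect_equal(delta_obs(d, d2), 2, tolerance = 0.3)
})

test_that("the mixed bootstrap is reproducible and degenerate-safe", {
  genes <- data.frame(gene = c("A", "B"), a = c(-10, -12), b = 2)
  d <- sim_onset(genes, stages = 1:9, n_per_stage = 4, seed = 20)
  dA <- d[d$gene == "A", ]; dB <- d[d$gene == "B", ]
  t1 <- delta_onset_test(dA, dB, n_boot = 200, seed = 99)
  t2 <- delta_onset_test(dA, dB, n_boot = 200, seed = 99)
  expect_identical(t1$p_value, t2$p_value)
  expect_identical(t1$null_quantiles, t2$null_quantiles)
  t3 <- delta_onset_test(dA, dB, n_boot = 200, seed = 100)
  expect_false(identical(t1$null_quantiles, t3$null_quantiles))
  expect_gt(t1$p_value, 0)
  expect_lte(t1$p_value, 1)
  # identical inputs: delta_obs 0, p exactly 1
  t4 <- delta_onset_test(dA, dA, n_boot = 150, seed = 1)
  expect_equal(t4$delta_obs, 0)
  expect_equal(t4$p_value, 1)
  expect_error(delta_onset_test(dA[1:3, ], dB, n_boot = 200), "at least 4")
  expect_error(delta_onset_test(dA, dB, n_boot = 50), "n_boot")
})

test_that("p-values fall as the true onset separation grows", {
  mean_p <- vapply(c(0, 1.5, 3), function(sep) {
    ps <- vapply(1:6, function(k) {
      genes <- data.frame(gene = c("A", "B"), a = c(-10, -10 - 2 * sep), b = 2)
      set.seed(3000 + 100 * sep + k)
      d <- sim_onset(genes, stages = stats::runif(50, 1, 12), n_per_stage = 1,
                     seed = 600 + 100 * sep + k)
      delta_onset_test(d[d$gene == "A", ], d[d$gene == "B", ],
                       n_boot = 200, seed = 700 + k)$p_value
    }, numeric(1))
    mean(ps)
  }, numeric(1))
  expect_gt(mean_p[1], mean_p[3])
  expect_true(all(diff(mean_p) <= 0.15))  # monotone in expectation, noisy
})

test_that("pairwise reports carry one starred row per requested pair", {
  genes <- data.frame(gene = c("Antp", "sal", "Notch"),
                      a = c(-6, -10, -14), b = 2)
  d <- sim_onset(genes, stages = 1:9, n_per_stage = 6, seed = 30)
  rep <- pairwise_onset_report(d, list(c("Antp", "sal"), c("sal", "Notch")),
                               n_boot = 200, seed = 31)
  expect_equal(nrow(rep), 2L)
  expect_true(all(rep$stars %in% c("***", "**", "*", "ns")))
  # identical genes compare as ns
  d2 <- rbind(d, transform(d[d$gene == "sal", ], gene = "sal2"))
  rep2 <- pairwise_onset_report(d2, list(c("sal", "sal2")),
                                n_boot = 200, seed = 32)
  expect_equal(rep2$stars, "ns")
  expect_error(pairwise_onset_report(d, list(c("sal", "Dll")), n_boot = 200),
               "Dll")
})

test_that("star thresholds follow the reporting convention", {
  stars <- eyespots:::onset_stars
  expect_equal(stars(c(5e-5, 5e-3, 0.04, 0.05, 0.3)),
               c("***", "**", "*", "ns", "ns"))
})
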