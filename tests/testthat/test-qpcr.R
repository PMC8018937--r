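perfect_series <- data.frame(dilution_factor = c(1, 0.5, 0.25, 0.125),
                             cq = c(20, 21, 22, 23))

test_that("a perfect 2-fold series gives slope -3.3219 and efficiency 1", {
  cv <- fit_standard_curve(perfect_series)
  expect_equal(cv$slope, -1 / log10(2), tolerance = 1e-9)
  expect_equal(cv$slope, -3.321928, tolerance = 1e-6)
  expect_equal(cv$efficiency, 1, tolerance = 1e-9)
  expect_equal(cv$r_squared, 1, tolerance = 1e-12)
  expect_equal(unname(coef(cv)), c(cv$intercept, cv$slope))
  expect_equal(predict(cv, 0.5), 21, tolerance = 1e-9)
})

test_that("degenerate dilution series are rejected or flagged", {
  expect_error(fit_standard_curve(data.frame(
    dilution_factor = c(1, 1, 0.5), cq = c(20, 20, 21))), ">= 3 distinct")
  expect_error(fit_standard_curve(data.frame(
    dilution_factor = c(1, -0.5, 0.25), cq = c(20, 21, 22))), "> 0")
  expect_warning(cv <- fit_standard_curve(data.frame(
    dilution_factor = c(1, 0.5, 0.25), cq = c(20, 20, 20))), "zero")
  expect_identical(cv$flag, "zero_slope")
  expect_error(interpolate_quantity(20, cv), "zero-slope")
  expect_warning(cv <- fit_standard_curve(data.frame(
    dilution_factor = c(1, 0.5, 0.25), cq = c(20, 19, 18))), "positive")
  expect_identical(cv$flag, "positive_slope")
})

test_that("interpolation inverts the curve", {
  cv <- fit_standard_curve(perfect_series)
  expect_equal(interpolate_quantity(cv$intercept, cv), 1, tolerance = 1e-9)
  # one log10 step: 3.32 cycles later means tenfold less template
  expect_equal(interpolate_quantity(cv$intercept - cv$slope, cv), 0.1,
               tolerance = 1e-9)
  expect_equal(interpolate_quantity(cv$intercept + cv$slope, cv), 10,
               tolerance = 1e-9)
  # round trip: the fitted points recover their dilution factors
  expect_equal(interpolate_quantity(perfect_series$cq, cv),
               perfect_series$dilution_factor, tolerance = 1e-9)
})

test_that("noisy dilution series recover the slope on average", {
  slopes <- vapply(1:50, function(s) {
    sim <- simulate_qpcr(data.frame(sample_id = "s1", target = "t",
                                    quantity = 1),
                         sigma = 0.1, seed = s)
    fit_standard_curve(sim$dilution_table)$slope
  }, 0)
  expect_lt(abs(mean(slopes) - (-3.321928)), 0.15)
})

test_that("reference normalization divides by the geometric mean", {
  df <- data.frame(sample_id = "s1", target = c("4R", "GAPDH", "HPRT1"),
                   quantity = c(10, 2, 8))
  out <- normalize_to_references(df)
  expect_equal(out$normalized_quantity[out$target == "4R"], 2.5)  # geomean 4
  # refs equal to target normalize to 1
  df$quantity <- c(4, 4, 4)
  out <- normalize_to_references(df)
  expect_equal(out$normalized_quantity, c(1, 1, 1))
  # per-sample global scaling cancels
  df <- data.frame(sample_id = rep(c("s1", "s2"), each = 3),
                   target = rep(c("4R", "GAPDH", "HPRT1"), 2),
                   quantity = c(10, 2, 8, 70, 14, 56))  # s2 = 7 * s1
  out <- normalize_to_references(df)
  expect_equal(out$normalized_quantity[1:3], out$normalized_quantity[4:6])
  expect_error(normalize_to_references(
    data.frame(sample_id = "s1", target = "4R", quantity = 1)),
    "missing reference target 'GAPDH'")
})

test_that("ratios are percentages with a zero-denominator guard", {
  expect_equal(qpcr_ratio(0.2, 1)$ratio_percent, 20)
  expect_equal(qpcr_ratio(3, 3)$ratio_percent, 100)
  r <- qpcr_ratio(1, 0)
  expect_false(r$defined)
  expect_true(is.na(r$ratio_percent))
})

qpcr_truth <- function(ratio = 0.2) {
  do.call(rbind, lapply(c("s1", "s2", "s3"), function(s)
    data.frame(sample_id = s, target = c("4R", "3R", "GAPDH", "HPRT1"),
               quantity = c(ratio, 1, 0.5, 0.7))))
}

test_that("the noise-free pipeline inverts the forward model exactly", {
  sim <- simulate_qpcr(qpcr_truth(0.2), sigma = 0)
  res <- qpcr_quantify(sim$cq_table, sim$dilution_table)
  # interpolated quantities equal the generating truth
  merged <- merge(res$quantities, qpcr_truth(0.2),
                  by = c("sample_id", "target"))
  expect_lt(max(abs(merged$quantity.x - merged$quantity.y)), 1e-9)
  expect_equal(res$ratios$ratio_percent, rep(20, 3), tolerance = 1e-9)
  expect_equal(res$summary$mean, 20, tolerance = 1e-9)
  expect_equal(res$summary$n, 3L)
  # triplicate dispersion is carried and zero without noise
  expect_equal(res$quantities$n_replicates, rep(3, nrow(res$quantities)))
  expect_lt(max(res$quantities$cq_sd), 1e-12)
  expect_equal(res$curves[["4R"]]$efficiency, 1, tolerance = 1e-9)
})

test_that("noisy Cq data recover the generating ratio on average", {
  ratios <- vapply(1:50, function(s) {
    sim <- simulate_qpcr(qpcr_truth(0.2), sigma = 0.05, seed = s)
    qpcr_quantify(sim$cq_table, sim$dilution_table)$summary$mean
  }, 0)
  expect_lt(abs(mean(ratios) - 20), 2)
})

test_that("missing targets and hot wells are handled", {
  sim <- simulate_qpcr(qpcr_truth(0.2), sigma = 0)
  cq <- sim$cq_table[sim$cq_table$target != "HPRT1", ]
  expect_error(qpcr_quantify(cq, sim$dilution_table), "HPRT1")
  # wells above the Cq cutoff are excluded and reported
  cq <- sim$cq_table
  cq$cq[1] <- 39.5
  res <- qpcr_quantify(cq, sim$dilution_table)
  expect_equal(nrow(res$excluded_wells), 1L)
})

test_that("simulate_qpcr validates its arguments", {
  q <- qpcr_truth(0.2)
  expect_error(simulate_qpcr(q, sigma = -1), "sigma")
  expect_error(simulate_qpcr(q, slope = 2), "slope")
  q$quantity[1] <- 0
  expect_error(simulate_qpcr(q), "> 0")
})
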