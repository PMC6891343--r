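test_that("calibration recovers exact lines and matches the normal equations", {
  r <- exact_records(M_w = 1:5 * 100, L_A = c(10, 12, 9, 14, 11), K = 0.4)
  m <- suppressWarnings(fit_calibration(r))
  expect_equal(m$C1, 0.4, tolerance = 1e-12)
  expect_equal(m$C0, 0, tolerance = 1e-10)
  expect_equal(m$adj_R2, 1, tolerance = 1e-10)
  expect_equal(m$pearson_r, 1, tolerance = 1e-10)

  r2 <- exact_records(M_w = 1:5 * 100, L_A = c(10, 12, 9, 14, 11),
                      K = 0.47, C0 = 2)
  m2 <- suppressWarnings(fit_calibration(r2))
  expect_equal(m2$C1, 0.47, tolerance = 1e-10)
  expect_equal(m2$C0, 2, tolerance = 1e-8)

  # hand-evaluated normal equations on a fixed small fit
  x <- c(1, 2, 3, 4); y <- c(1.1, 1.9, 3.2, 3.8)
  n <- 4
  slope <- (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
  icept <- mean(y) - slope * mean(x)
  ssr <- sum((y - icept - slope * x)^2)
  r2_hand <- 1 - ssr / sum((y - mean(y))^2)
  m3 <- fit_calibration(data.frame(water_mass_mg = x, leaf_area_cm2 = 1, tau = y))
  expect_equal(m3$C1, slope, tolerance = 1e-12)
  expect_equal(m3$C0, icept, tolerance = 1e-12)
  expect_equal(m3$R2, r2_hand, tolerance = 1e-12)
  expect_equal(m3$adj_R2, 1 - (1 - r2_hand) * 3 / 2, tolerance = 1e-12)

  expect_error(fit_calibration(r[1:2, ]), class = "leafthz_insufficient_data")
  expect_error(
    fit_calibration(data.frame(water_mass_mg = c(5, 5, 5),
                               leaf_area_cm2 = 1, tau = 1:3)),
    class = "leafthz_degenerate_design")
})

test_that("zero-intercept slope is sum(xy)/sum(x^2)", {
  expect_equal(fit_zero_intercept(exact_records(1:6 * 50, 7, K = 0.5)), 0.5)
  expect_equal(
    fit_zero_intercept(data.frame(water_mass_mg = 100, leaf_area_cm2 = 1,
                                  tau = 39)), 0.39)
  expect_equal(
    fit_zero_intercept(data.frame(water_mass_mg = c(1, 2), leaf_area_cm2 = 1,
                                  tau = c(1, 1))), 3 / 5)
  # equals the full fit's slope when the generating intercept is zero
  set.seed(71)
  r <- exact_records(runif(30, 50, 500), runif(30, 5, 40), K = 0.45)
  r$tau <- r$tau * (1 + rnorm(30, 0, 0.02))
  m <- fit_calibration(r)
  expect_lt(abs(fit_zero_intercept(r) - m$C1), m$se_C1)
})

test_that("adjusted R^2 applies the n, p correction", {
  expect_equal(adjusted_r2(1, 8), 1)
  expect_equal(adjusted_r2(0.9, 10), 1 - 0.1 * 9 / 8)
  expect_equal(adjusted_r2(0, 10), -0.125)
  expect_error(adjusted_r2(0.5, 2), class = "leafthz_domain_error")
  expect_error(adjusted_r2(1.2, 10), class = "leafthz_domain_error")
})

test_that("pearson test matches the direct sample-correlation formula", {
  expect_equal(pearson_test(1:6, 2 * (1:6) + 1)$r, 1)
  expect_equal(pearson_test(1:6, -(1:6))$r, -1)
  expect_equal(pearson_test(c(1, 2, 3), c(1, 3, 2))$r, 0.5)

  set.seed(72)
  for (i in 1:50) {
    n <- sample(5:12, 1)
    x <- rnorm(n); y <- rnorm(n)
    got <- pearson_test(x, y)
    r_hand <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    t_hand <- r_hand * sqrt((n - 2) / (1 - r_hand^2))
    expect_equal(got$r, r_hand, tolerance = 1e-12)
    expect_equal(got$p, 2 * pt(-abs(t_hand), n - 2), tolerance = 1e-12)
  }
  expect_error(pearson_test(1:2, 2:3), class = "leafthz_insufficient_data")
  expect_error(pearson_test(c(1, 1, 1), 1:3), class = "leafthz_degenerate_design")
})

test_that("water-mass prediction inverts the calibration with propagated error", {
  r <- exact_records(M_w = 1:6 * 50, L_A = c(8, 11, 9, 13, 10, 12), K = 0.5)
  m <- suppressWarnings(fit_calibration(r))
  pr <- predict_water_mass(5, 10, m)
  expect_equal(pr$M_w_hat, 100, tolerance = 1e-8)
  expect_lt(pr$se, 1e-6)
  expect_equal(unname(pr$interval[, "low"]), pr$M_w_hat, tolerance = 1e-5)
  expect_equal(predict_water_mass(1e-300, 10, m)$M_w_hat, 0, tolerance = 1e-6)

  # inversion of a V. vinifera-scale measurement
  r_vv <- exact_records(M_w = seq(400, 1600, length.out = 8),
                        L_A = seq(50, 120, length.out = 8), K = 0.39)
  m_vv <- suppressWarnings(fit_calibration(r_vv))
  expect_equal(predict_water_mass(4.754, 85.35, m_vv)$M_w_hat,
               4.754 * 85.35 / 0.39, tolerance = 1e-6)
  expect_equal(predict_water_mass(4.754, 85.35, m_vv)$M_w_hat, 1040.4,
               tolerance = 1e-3)

  # prediction o forward model is the identity on water mass
  set.seed(73)
  fmp <- forward_model_params(m$C1, m$C0)
  M <- runif(20, 10, 500); L <- runif(20, 4, 40)
  pr_rt <- predict_water_mass(forward_tau(M, L, fmp), L, m)
  expect_equal(pr_rt$M_w_hat, M, tolerance = 1e-8)

  r_pos <- exact_records(M_w = 1:6 * 50, L_A = c(8, 11, 9, 13, 10, 12),
                         K = 0.5, C0 = 5)
  m_pos <- suppressWarnings(fit_calibration(r_pos))
  expect_warning(predict_water_mass(0.01, 0.1, m_pos),
                 class = "leafthz_negative_prediction")
  bad <- structure(c(unclass(m), list()), class = "calibration_model")
  bad$C1 <- -0.1
  expect_error(predict_water_mass(5, 10, bad),
               class = "leafthz_non_invertible_calibration")
})

test_that("prediction intervals widen with noise and use the t quantile", {
  set.seed(74)
  r <- exact_records(runif(12, 50, 500), runif(12, 5, 40), K = 0.45)
  r$tau <- r$tau * (1 + rnorm(12, 0, 0.05))
  m <- fit_calibration(r)
  p95 <- predict_water_mass(4.5, 20, m, confidence = 0.95)
  p50 <- predict_water_mass(4.5, 20, m, confidence = 0.50)
  expect_gt(p95$se, 0)
  expect_equal(p95$se, p50$se)
  expect_gt(diff(p95$interval[1, ]), diff(p50$interval[1, ]))
  expect_equal(unname(diff(p95$interval[1, ])),
               2 * qt(0.975, m$n - 2) * p95$se)
})

test_that("tukey letters mirror explicit pairwise Tukey-Kramer tests", {
  # identical groups share a letter
  expect_equal(unname(tukey_letters(list(x = c(1, 2, 3, 2), y = c(2, 1, 3, 2)))),
               c("a", "a"))
  # overwhelming separation: disjoint letters, highest mean gets "a"
  set.seed(75)
  sep <- tukey_letters(list(lo = rnorm(5, 0, 0.01), hi = rnorm(5, 1000, 0.01)))
  expect_equal(sep[["hi"]], "a")
  expect_equal(sep[["lo"]], "b")
  # graded means where only the extreme pair differs
  g3 <- list(a = c(0.8, 1.1, 0.9, 1.2, 1.0), b = c(1.9, 2.3, 2.0, 2.4, 2.1),
             c = c(3.0, 3.4, 3.1, 3.5, 3.2) + 0.4)
  g3 <- lapply(g3, function(v) v * 2)
  p_ac <- tukey_kramer_p(g3, 1, 3)
  p_ab <- tukey_kramer_p(g3, 1, 2)
  let3 <- tukey_letters(g3)
  # shared letter iff pairwise p > alpha, for every pair
  share <- function(l, i, j) length(intersect(strsplit(l[[i]], "")[[1]],
                                              strsplit(l[[j]], "")[[1]])) > 0
  expect_equal(share(let3, "a", "c"), p_ac > 0.05)
  expect_equal(share(let3, "a", "b"), p_ab > 0.05)

  # property: agreement with the explicit studentized-range p on random data
  set.seed(76)
  for (rep in 1:20) {
    k <- sample(3:5, 1)
    gs <- setNames(lapply(seq_len(k), function(i)
      rnorm(sample(4:9, 1), mean = sample(0:3, 1))), letters[10 + seq_len(k)])
    lets <- tukey_letters(gs)
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      expect_equal(share(lets, names(gs)[i], names(gs)[j]),
                   tukey_kramer_p(gs, i, j) > 0.05,
                   info = sprintf("rep %d pair %d-%d", rep, i, j))
    }
  }
  expect_error(tukey_letters(list(a = 1, b = c(1, 2))),
               class = "leafthz_insufficient_data")
})

test_that("correlation table reproduces the composite-product structure", {
  # constant leaf area: tau-vs-Mw and tauLA-vs-Mw are the same regression
  r <- exact_records(M_w = seq(50, 400, length.out = 10), L_A = 12, K = 0.45)
  set.seed(77)
  r$tau <- r$tau * (1 + rnorm(10, 0, 0.05))
  ct <- correlation_table(r)
  expect_equal(ct$adj_R2[ct$relation == "tau_vs_Mw"],
               ct$adj_R2[ct$relation == "tauLA_vs_Mw"], tolerance = 1e-12)

  # noiseless forward-model data with varying area: composite row exact
  r2 <- exact_records(M_w = seq(50, 400, length.out = 10),
                      L_A = seq(5, 40, length.out = 10), K = 0.45)
  ct2 <- suppressWarnings(correlation_table(r2))
  expect_equal(ct2$adj_R2[ct2$relation == "tauLA_vs_Mw"], 1, tolerance = 1e-10)
  expect_true(ct2$significant[ct2$relation == "tauLA_vs_Mw"])

  # null data: the significance star appears at roughly the alpha rate
  set.seed(78)
  stars <- vapply(1:200, function(i) {
    d <- data.frame(species_code = "NU", water_mass_mg = rnorm(15, 100, 20),
                    leaf_area_cm2 = rnorm(15, 10, 1), tau = rnorm(15, 5, 0.5))
    ct <- correlation_table(d)
    ct$significant[ct$relation == "tau_vs_Mw"]
  }, logical(1))
  expect_lt(mean(stars), 0.12)
})
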