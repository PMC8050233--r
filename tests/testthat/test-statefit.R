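# Unbinned-ML mixtures, BIC selection, distance conversion, occupancy
# tables, and condition comparison.

test_that("efficiency/distance conversion matches the Förster relation", {
  cal <- forster_calibration(56)
  expect_equal(efficiency_to_distance(0.5, cal), 56)
  expect_equal(distance_to_efficiency(56, cal), 0.5)
  expect_equal(distance_to_efficiency(80, forster_calibration(80)), 0.5)
  expect_equal(efficiency_to_distance(0.138, cal), 76.0, tolerance = 0.1 / 76)

  e <- seq(0.01, 0.99, by = 0.01)
  back <- distance_to_efficiency(efficiency_to_distance(e, cal), cal)
  expect_equal(back, e, tolerance = 1e-9)

  expect_equal(efficiency_to_distance(1.5, cal),
               efficiency_to_distance(0.999, cal))  # clamped
  expect_error(efficiency_to_distance(1.5, cal, clamp = FALSE),
               "outside \\(0, 1\\)")
  expect_error(distance_to_efficiency(-3, cal))
})

test_that("single-component fits recover mean and width", {
  s <- sample_mixture(list(means = 0.5, sigmas = 0.05, weights = 1), 1e4,
                      seed = 101)
  f <- fit_gmm(s$e, 1, seed = 1)
  expect_lt(abs(f$means - 0.5), 0.002)
  expect_lt(abs(f$sigmas - 0.05), 0.002)
  expect_equal(f$weights, 1)
  expect_equal(f$bic, 2 * log(1e4) - 2 * f$log_likelihood)
})

test_that("a symmetric two-component mixture is recovered with equal weights", {
  mix <- list(means = c(0.3, 0.7), sigmas = c(0.05, 0.05), weights = c(0.5, 0.5))
  s <- sample_mixture(mix, 2e4, seed = 7)
  f <- fit_gmm(s$e, 2, seed = 2)
  expect_lt(max(abs(f$weights - 0.5)), 0.02)
  expect_lt(max(abs(f$means - c(0.3, 0.7))), 0.01)
})

test_that("fit refuses undersized samples", {
  expect_error(fit_gmm(rnorm(30, 0.5, 0.05), 5), "at least 10\\*k")
})

test_that("the EM agrees with an independent mixture implementation", {
  suppressMessages(library(mclust))
  mix <- list(means = c(0.25, 0.65), sigmas = c(0.04, 0.06),
              weights = c(0.4, 0.6))
  s <- sample_mixture(mix, 3000, seed = 9)
  f <- fit_gmm(s$e, 2, seed = 3, sigma_floor = 1e-4)
  ref <- mclust::Mclust(s$e, G = 2, modelNames = "V", verbose = FALSE)
  expect_lt(abs(f$log_likelihood - ref$loglik), 0.05)
  expect_lt(max(abs(sort(f$means) - sort(as.numeric(ref$parameters$mean)))),
            0.005)
  expect_lt(max(abs(sort(f$weights) - sort(ref$parameters$pro))), 0.01)
})

test_that("native five-state weights are recovered within two points", {
  mix <- por_native_mixture()
  s <- sample_mixture(mix, 1e5, seed = 11)
  f <- fit_gmm(s$e, 5, seed = 4)
  expect_lt(max(abs(f$weights - mix$weights)), 0.02)
  expect_lt(max(abs(f$means - mix$means)), 0.01)
})

test_that("BIC selects one state for single-Gaussian data", {
  s <- sample_mixture(list(means = 0.5, sigmas = 0.05, weights = 1), 5000,
                      seed = 12)
  sc <- scan_k(s$e, 1, 4, seed = 5)
  expect_equal(sc$selected_k, 1)
})

test_that("BIC under-selects at tiny n and its formula holds", {
  mix <- por_native_mixture()
  s <- sample_mixture(mix, 50, seed = 13)
  sc <- scan_k(s$e, 1, 5, seed = 6)
  expect_lt(sc$selected_k, 5)          # penalty dominates at n = 50
  ok <- !is.na(sc$scan$bic)
  expect_equal(sc$scan$bic[ok],
               (3 * sc$scan$k[ok] - 1) * log(50) - 2 * sc$scan$log_likelihood[ok])
})

test_that("BIC selection sharpens towards five states as n grows", {
  mix <- por_native_mixture()
  sel <- purrr::map_int(c(1e3, 1e4), function(n) {
    s <- sample_mixture(mix, n, seed = 14)
    scan_k(s$e, 3, 6, seed = 7, n_restarts = 6)$selected_k
  })
  expect_true(sel[1] <= sel[2])
  expect_equal(sel[2], 5L)
})

test_that("selected-model likelihood dominates smaller-k refits", {
  mix <- por_native_mixture()
  s <- sample_mixture(mix, 5000, seed = 15)
  sc <- scan_k(s$e, 1, 6, seed = 8)
  ll <- sc$scan$log_likelihood
  k_sel <- sc$selected_k
  expect_true(all(ll[sc$scan$k < k_sel] <= ll[sc$scan$k == k_sel]))
})

test_that("mixture fits recover parameters for well-separated components", {
  mix <- list(means = c(0.2, 0.45, 0.75), sigmas = c(0.05, 0.05, 0.05),
              weights = c(0.3, 0.3, 0.4))
  s <- sample_mixture(mix, 1e4, seed = 16)
  f <- fit_gmm(s$e, 3, seed = 9)
  expect_lt(max(abs(f$means - mix$means)), 0.01)
  expect_lt(max(abs(f$sigmas - mix$sigmas)), 0.01)
  expect_lt(max(abs(f$weights - mix$weights)), 0.02)
})

test_that("occupancy tables order states by decreasing distance", {
  mix <- por_native_mixture()
  s <- sample_mixture(mix, 2e4, seed = 17)
  f <- fit_gmm(s$e, 5, seed = 10)
  tab <- occupancy_table(f)
  expect_equal(tab$state, paste0("S", 1:5))
  expect_true(all(diff(tab$distance_A) < 0))
  expect_equal(sum(tab$occupancy_pct), 100, tolerance = 0.1)
  expect_equal(tab$distance_A, c(76, 64, 57, 48, 44), tolerance = 0.02)

  single <- fit_gmm(rnorm(500, 0.5, 0.05), 1, seed = 11)
  t1 <- occupancy_table(single)
  expect_equal(t1$occupancy_pct, 100)

  tied <- single
  tied$k <- 2L
  tied$means <- c(0.5, 0.5); tied$sigmas <- c(0.05, 0.05)
  tied$weights <- c(0.5, 0.5)
  expect_warning(occupancy_table(tied), "merged")
})

test_that("identical conditions give zero occupancy shifts with covering CIs", {
  mix <- por_native_mixture()
  s <- sample_mixture(mix, 8000, seed = 18)
  eff <- tibble::tibble(trace_id = rep(sprintf("t%03d", 1:80), each = 100),
                        e = s$e)
  f <- fit_gmm(s$e, 5, seed = 12)
  shift <- compare_conditions(f, f, eff, eff, n_bootstrap = 100, seed = 13)
  expect_equal(shift$delta, rep(0, 5))
  expect_true(all(shift$ci_lo <= 0 & shift$ci_hi >= 0))
})

test_that("a constructed rifampicin-like shift is detected in S1", {
  native <- por_native_mixture()
  rif <- por_rifampicin_mixture()
  sa <- sample_mixture(native, 3e4, seed = 19)
  sb <- sample_mixture(rif, 3e4, seed = 20)
  eff_a <- tibble::tibble(trace_id = rep(sprintf("a%03d", 1:150), each = 200),
                          e = sa$e)
  eff_b <- tibble::tibble(trace_id = rep(sprintf("b%03d", 1:150), each = 200),
                          e = sb$e)
  fa <- fit_gmm(sa$e, 5, seed = 14)
  fb <- fit_gmm(sb$e, 5, seed = 15)
  shift <- compare_conditions(fa, fb, eff_a, eff_b, n_bootstrap = 60, seed = 16)
  d_s1 <- shift$delta[shift$state == "S1"]
  expect_lt(abs(d_s1 - (33 - 17 / 0.99)), 2)
  expect_true(shift$ci_lo[1] > 0)      # the S1 gain is resolved from zero
  expect_lt(abs(sum(shift$delta)), 1e-6)

  f3 <- fit_gmm(sample_mixture(native, 2000, seed = 1)$e, 3, seed = 2)
  expect_error(compare_conditions(fa, f3, eff_a, eff_b), "different k")
})

test_that("bootstrap CIs mostly cover zero when B is a resample of A", {
  mix <- list(means = c(0.3, 0.7), sigmas = c(0.05, 0.05), weights = c(0.4, 0.6))
  covered <- 0L
  n_rep <- 10L
  for (r in seq_len(n_rep)) {
    sa <- sample_mixture(mix, 4000, seed = 400 + r)
    ids <- rep(sprintf("t%02d", 1:40), each = 100)
    eff_a <- tibble::tibble(trace_id = ids, e = sa$e)
    resampled <- withr::with_seed(500 + r, sample(unique(ids), 40, replace = TRUE))
    eff_b <- purrr::map_dfr(seq_along(resampled), function(i) {
      rows <- eff_a[eff_a$trace_id == resampled[i], ]
      rows$trace_id <- sprintf("b%02d", i)
      rows
    })
    fa <- fit_gmm(eff_a$e, 2, seed = 600 + r)
    fb <- fit_gmm(eff_b$e, 2, seed = 700 + r)
    shift <- compare_conditions(fa, fb, eff_a, eff_b, n_bootstrap = 80,
                                seed = 800 + r)
    if (shift$ci_lo[1] <= 0 && shift$ci_hi[1] >= 0) covered <- covered + 1L
  }
  expect_gte(covered, ceiling(0.8 * n_rep))
})

test_that("tidy and glance expose the fitted mixture", {
  s <- sample_mixture(list(means = c(0.3, 0.7), sigmas = c(0.05, 0.05),
                           weights = c(0.5, 0.5)), 2000, seed = 21)
  f <- fit_gmm(s$e, 2, seed = 17)
  td <- tidy(f)
  expect_equal(td$component, c("S1", "S2"))
  expect_equal(sum(td$weight), 1, tolerance = 1e-9)
  gl <- glance(f)
  expect_equal(gl$k, 2)
  expect_true(gl$converged)
})
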