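# Synthetic-data generator: state paths, trace rendering, binning,
# mixture and dose-response sampling.

test_that("state paths follow the per-frame switching model", {
  m0 <- two_state_model(p = 0)
  path0 <- simulate_state_sequence(m0, 500, seed = 7)
  expect_length(path0, 500)
  expect_equal(length(unique(path0)), 1)     # no transitions possible

  m <- two_state_model(p = 0.95)
  path <- simulate_state_sequence(m, 1e5, seed = 11)
  occ <- mean(path == 1)
  expect_lt(abs(occ - 0.5), 0.01)            # symmetric stationary distribution
  switch_freq <- mean(diff(path) != 0)
  expect_lt(abs(switch_freq - 0.95), 0.01)

  # K > 2: landing state uniform over the others
  m3 <- sim_state_model(c(0.2, 0.5, 0.8), transition_probability = 1)
  p3 <- simulate_state_sequence(m3, 3e4, seed = 3)
  expect_true(all(diff(p3) != 0))
  tab <- table(factor(p3, levels = 1:3)) / length(p3)
  expect_true(all(abs(tab - 1 / 3) < 0.02))

  expect_error(sim_state_model(numeric(0)), "at least one state")
  expect_error(sim_state_model(c(0, 0.5)), "strictly inside")
})

test_that("switch frequency converges to p_trans within 3 SE for long chains", {
  for (p in c(0.2, 0.5, 0.95)) {
    path <- simulate_state_sequence(two_state_model(p = p), 1e4, seed = 41)
    se <- sqrt(p * (1 - p) / (1e4 - 1))
    expect_lt(abs(mean(diff(path) != 0) - p), 3 * se + 1e-12)
  }
})

test_that("rendered traces with identity photophysics reproduce state E exactly", {
  m <- two_state_model(p = 0.95)
  phys <- photophysics_config(noise_fraction = 0)
  path <- simulate_state_sequence(m, 200, seed = 5)
  tr <- render_alex_trace(path, m, phys, seed = 5)
  e_app <- tr$I_DA / (tr$I_DD + tr$I_DA)
  expect_equal(e_app, tr$E_true, tolerance = 1e-12)
  s_app <- (tr$I_DD + tr$I_DA) / (tr$I_DD + tr$I_DA + tr$I_AA)
  expect_equal(s_app, rep(0.5, 200), tolerance = 1e-12)
})

test_that("donor leakage appears as I_DA = alpha * I_DD on donor-only traces", {
  m <- sim_state_model(0.5)  # E irrelevant without an acceptor
  phys <- photophysics_config(noise_fraction = 0, alpha = 0.05)
  tr <- render_alex_trace(rep(1L, 50), m, phys, seed = 2, species = "donor_only")
  expect_equal(tr$I_DA, 0.05 * tr$I_DD, tolerance = 1e-12)
  expect_equal(tr$I_AA, rep(0, 50))
})

test_that("acceptor bleach times are geometric with the configured rate", {
  m <- two_state_model()
  phys <- photophysics_config(acceptor_bleach_rate = 0.005)
  bleach <- purrr::map_int(1:400, function(i) {
    tr <- render_alex_trace(rep(1L, 3000), m, phys, seed = 1000 + i)
    b <- trace_meta(tr)$acceptor_bleach_frame
    if (is.na(b)) -1L else b
  })
  bleach <- bleach[bleach >= 0]
  expect_gt(length(bleach), 380)             # nearly all bleach within 3000 frames
  expected <- (1 - 0.005) / 0.005            # geometric mean frames survived
  se <- sqrt((1 - 0.005) / 0.005^2) / sqrt(length(bleach))
  expect_lt(abs(mean(bleach) - expected), 3 * se)
})

test_that("bleached channels drop and metadata records the bleach frame", {
  m <- two_state_model()
  phys <- photophysics_config(noise_fraction = 0, acceptor_bleach_rate = 0.02)
  tr <- render_alex_trace(rep(2L, 400), m, phys, seed = 31)
  b <- trace_meta(tr)$acceptor_bleach_frame
  expect_false(is.na(b))
  post <- tr[tr$frame >= b, ]
  expect_true(all(abs(post$I_AA) < 1e-9))    # noise 0: exactly dark
  expect_true(all(abs(post$I_DA) < 1e-9))
  expect_true(all(post$I_DD > 0))            # donor recovers to zero-FRET level
  pre <- tr[tr$frame < b, ]
  expect_true(all(pre$I_AA > 0))
})

test_that("binning averages full bins, drops the remainder, scales the period", {
  tr <- manual_trace(I_DD = rep(c(0, 1), 10), I_DA = rep(2, 20),
                     I_AA = rep(3, 20))
  tr <- alexfret:::set_trace_meta(tr, tibble::tibble(trace_id = "tr1",
                                                     frame_period = 0.2))
  b1 <- bin_intensities(tr, 1)
  expect_equal(b1$I_DD, tr$I_DD)
  b2 <- bin_intensities(tr, 2)
  expect_equal(b2$I_DD, rep(0.5, 10))        # alternating 0/1 pairs
  expect_equal(b2$I_DA, rep(2, 10))
  expect_equal(trace_meta(b2)$frame_period, 0.4)
  b3 <- bin_intensities(tr, 3)
  expect_equal(nrow(b3), 6)                  # trailing partial bin dropped
  expect_error(bin_intensities(tr, 21), "exceeds trace length")
})

test_that("binning commutes with averaging for noise-free traces", {
  m <- two_state_model()
  phys <- photophysics_config(noise_fraction = 0)
  tr <- render_alex_trace(simulate_state_sequence(m, 120, seed = 9), m, phys,
                          seed = 9)
  b4 <- bin_intensities(bin_intensities(tr, 2), 2)
  b4b <- bin_intensities(tr, 4)
  expect_equal(b4$I_DA, b4b$I_DA, tolerance = 1e-12)
  expect_equal(mean(b4$I_DD), mean(tr$I_DD[1:120]), tolerance = 1e-12)
})

test_that("expected transitions per bin is p times the bin size", {
  expect_equal(expected_transitions_per_bin(0.95, 1), 0.95)
  expect_equal(expected_transitions_per_bin(0.95, 100), 95)
  expect_equal(expected_transitions_per_bin(0, 50), 0)
})

test_that("control simulation yields the configured sets of 200-frame traces", {
  cfg <- control_config(n_traces = 3, trace_length_after_binning = 200)
  traces <- simulate_control_traces(cfg, seed = 2)
  expect_setequal(unique(traces$bin_size), c(1, 5, 10, 20, 50, 100))
  lens <- dplyr::count(traces, .data$trace_id)
  expect_true(all(lens$n == 200))
  expect_equal(nrow(lens), 18)

  # noise off, bin 1: apparent efficiencies sit exactly on the state values
  cfg0 <- control_config(bin_sizes = 1L, n_traces = 2, noise_fraction = 0)
  t0 <- simulate_control_traces(cfg0, seed = 3)
  e <- t0$I_DA / (t0$I_DD + t0$I_DA)
  expect_true(all(abs(e - 0.3) < 1e-9 | abs(e - 0.7) < 1e-9))
})

test_that("coarse binning shrinks the per-trace efficiency variance", {
  cfg <- control_config(bin_sizes = c(1L, 100L), n_traces = 4,
                        trace_length_after_binning = 150)
  traces <- simulate_control_traces(cfg, seed = 4)
  ev <- traces %>%
    dplyr::mutate(e = I_DA / (I_DD + I_DA)) %>%
    dplyr::group_by(bin_size, trace_id) %>%
    dplyr::summarise(v = var(e), .groups = "drop") %>%
    dplyr::group_by(bin_size) %>%
    dplyr::summarise(v = mean(v), .groups = "drop")
  expect_lt(ev$v[ev$bin_size == 100], 0.05 * ev$v[ev$bin_size == 1])
})

test_that("mixture sampling reproduces weights and component moments", {
  mix <- por_native_mixture()
  s <- sample_mixture(mix, 1e5, seed = 21)
  freq <- as.numeric(table(factor(s$component, levels = 1:5))) / 1e5
  expect_true(all(abs(freq - mix$weights) < 0.01))
  for (j in c(1, 4)) {
    xj <- s$e[s$component == j]
    expect_lt(abs(mean(xj) - mix$means[j]), 0.001)
    expect_lt(abs(sd(xj) - mix$sigmas[j]), 0.001)
  }

  one <- sample_mixture(list(means = 0.5, sigmas = 0.05, weights = 1),
                        1e5, seed = 8)
  expect_lt(abs(mean(one$e) - 0.5), 0.001)

  degen <- sample_mixture(list(means = mix$means, sigmas = rep(0, 5),
                               weights = mix$weights), 2000, seed = 5)
  expect_setequal(unique(degen$e), mix$means)
})

test_that("dose-response simulation matches the Hill curve", {
  cfg <- dose_response_config(A = 100, B = 14, ic50 = 10, hill_n = 1,
                              concentrations = c(0.01, 1, 10, 100, 1000),
                              noise_sd = 0, replicates = 2)
  tab <- simulate_dose_response(cfg, seed = 1)
  expect_equal(nrow(tab), 10)
  at_ic50 <- tab$response_pct[tab$concentration_uM == 10]
  expect_equal(at_ic50, rep((100 + 14) / 2, 2), tolerance = 1e-12)  # midpoint
  near_zero <- tab$response_pct[tab$concentration_uM == 0.01]
  expect_equal(near_zero, rep(100, 2), tolerance = 1e-2)            # x -> 0 limit

  # noisy table agrees with direct formula evaluation in expectation
  cfgn <- dose_response_config(A = 100, B = 14, ic50 = 10, hill_n = 1,
                               concentrations = 10^seq(0, 3, length.out = 8),
                               noise_sd = 5, replicates = 50)
  tn <- simulate_dose_response(cfgn, seed = 2)
  agg <- tapply(tn$response_pct, tn$concentration_uM, mean)
  f <- hill_response(as.numeric(names(agg)), 100, 14, 10, 1)
  expect_true(all(abs(agg - f) < 5 / sqrt(50) * 4))
})
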