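# Conformational-state inference: unbinned-likelihood Gaussian mixtures,
# BIC model selection, distance conversion, condition comparison.

#' Förster calibration
#'
#' @param r0 Förster radius in Å; 56 Å for the Cy3/Cy5 pair used throughout.
#' @return An object of class `forster_calibration`.
#' @export
forster_calibration <- function(r0 = 56) {
  assert_pos(r0, "r0")
  structure(list(r0 = r0), class = "forster_calibration")
}

#' Convert FRET efficiency to inter-dye distance
#'
#' `r = R0 * (1/E - 1)^(1/6)`. Efficiencies are clamped to
#' \[0.001, 0.999\] before inversion unless `clamp = FALSE`, in which case
#' values outside (0, 1) raise an error.
#'
#' @param e FRET efficiencies.
#' @param cal A [forster_calibration()].
#' @param clamp Clamp efficiencies into the invertible range.
#' @return Distances in Å.
#' @export
efficiency_to_distance <- function(e, cal = forster_calibration(), clamp = TRUE) {
  stopifnot(inherits(cal, "forster_calibration"))
  if (clamp) {
    e <- pmin(pmax(e, 0.001), 0.999)
  } else if (any(e <= 0 | e >= 1)) {
    abort("efficiency outside (0, 1); enable `clamp` or fix the input")
  }
  cal$r0 * (1 / e - 1)^(1 / 6)
}

#' Convert inter-dye distance to FRET efficiency
#'
#' `E = 1 / (1 + (r/R0)^6)`; exact inverse of [efficiency_to_distance()].
#'
#' @param r Distances in Å (> 0).
#' @param cal A [forster_calibration()].
#' @return FRET efficiencies.
#' @export
distance_to_efficiency <- function(r, cal = forster_calibration()) {
  stopifnot(inherits(cal, "forster_calibration"))
  assert_pos(r, "r")
  1 / (1 + (r / cal$r0)^6)
}

# k-means++-style initialisation: spread centres, then one hard assignment
kmeanspp_init <- function(x, k) {
  n <- length(x)
  centers <- numeric(k)
  centers[1] <- x[sample.int(n, 1)]
  if (k > 1) {
    d2 <- (x - centers[1])^2
    for (j in 2:k) {
      p <- d2 / sum(d2)
      centers[j] <- x[sample.int(n, 1, prob = p)]
      d2 <- pmin(d2, (x - centers[j])^2)
    }
  }
  assign <- max.col(-abs(outer(x, centers, "-")), ties.method = "first")
  mu <- numeric(k); sg <- numeric(k); w <- numeric(k)
  overall_sd <- max(sd(x), 1e-3)
  for (j in seq_len(k)) {
    xj <- x[assign == j]
    mu[j] <- if (length(xj) > 0) mean(xj) else centers[j]
    sg[j] <- if (length(xj) > 1) max(sd(xj), 0.25 * overall_sd / k) else overall_sd / k
    w[j] <- max(length(xj) / n, 1 / (10 * k))
  }
  list(mu = mu, sigma = sg, w = w / sum(w))
}

#' Fit a Gaussian mixture by unbinned maximum likelihood
#'
#' EM on the individual efficiency values (the likelihood is the product of
#' per-observation mixture densities, never a binned histogram fit). Each of
#' `n_restarts` k-means++-style initialisations is run through a short EM;
#' the best is polished to convergence (per-observation log-likelihood change
#' below `tol` or `max_iter` iterations). Components are returned sorted by
#' increasing mean efficiency, i.e. decreasing implied inter-dye distance.
#'
#' @param e Numeric vector of FRET efficiencies, or a data frame with an `e`
#'   column (e.g. from [sample_mixture()]).
#' @param k Number of components; requires at least `10 * k` observations.
#' @param seed Integer seed for initialisation.
#' @param n_restarts Number of random restarts (default 10).
#' @param max_iter,tol EM convergence controls.
#' @param sigma_floor Lower bound on component widths (efficiency units),
#'   preventing spike collapse on duplicated values.
#' @return An object of class `gmm_fit` with elements `k`, `means`, `sigmas`,
#'   `weights`, `log_likelihood`, `bic`, `n_data`, `converged`, `data`.
#' @export
fit_gmm <- function(e, k, seed = 1, n_restarts = 10, max_iter = 2000,
                    tol = 1e-8, sigma_floor = 0.01) {
  if (is.data.frame(e)) e <- e$e
  e <- as.numeric(e[is.finite(e)])
  k <- assert_count(k, "k")
  n <- length(e)
  if (n < 10 * k) {
    abort(sprintf("need at least 10*k = %d observations, got %d", 10 * k, n))
  }
  n_restarts <- assert_count(n_restarts, "n_restarts")

  runs <- with_seed(seed, {
    purrr::map(seq_len(n_restarts), function(r) {
      init <- kmeanspp_init(e, k)
      fit <- em_gmm_cpp(e, init$mu, init$sigma, init$w,
                        max_iter = 100L, tol = 1e-6, sigma_floor = sigma_floor)
      fit$degenerate <- any(fit$w < 1e-4)
      fit
    })
  })
  ok <- purrr::keep(runs, ~ !.x$degenerate && is.finite(.x$loglik))
  if (length(ok) == 0) {
    abort(sprintf("all %d restarts collapsed to a degenerate component (k = %d)",
                  n_restarts, k))
  }
  best <- ok[[which.max(purrr::map_dbl(ok, "loglik"))]]
  fit <- em_gmm_cpp(e, best$mu, best$sigma, best$w,
                    max_iter = as.integer(max_iter), tol = tol,
                    sigma_floor = sigma_floor)
  if (any(fit$w < 1e-4)) {
    abort(sprintf("degenerate component after polishing (k = %d)", k))
  }
  ord <- order(fit$mu)
  structure(
    list(k = k, means = fit$mu[ord], sigmas = fit$sigma[ord],
         weights = fit$w[ord] / sum(fit$w),
         log_likelihood = fit$loglik,
         bic = bic_gmm(fit$loglik, k, n),
         n_data = n, converged = fit$converged, iterations = fit$iterations,
         sigma_floor = sigma_floor, data = e),
    class = "gmm_fit"
  )
}

# BIC with p = 3k - 1 free parameters (k means, k sigmas, k - 1 weights)
bic_gmm <- function(loglik, k, n) (3 * k - 1) * log(n) - 2 * loglik

#' @export
print.gmm_fit <- function(x, ...) {
  cat(sprintf("Unbinned-ML Gaussian mixture: k = %d, n = %d, logL = %.2f, BIC = %.2f\n",
              x$k, x$n_data, x$log_likelihood, x$bic))
  print(tidy(x))
  invisible(x)
}

#' Scan mixture sizes and select by BIC
#'
#' Fits `k = k_min..k_max` with [fit_gmm()] and computes
#' `BIC = (3k - 1) ln(N) - 2 ln(L)`; the selected model is the strict BIC
#' minimiser. A k whose fit fails is recorded as missing and excluded from
#' selection.
#'
#' @inheritParams fit_gmm
#' @param k_min,k_max Scan range (`k_max >= k_min >= 1`).
#' @return An object of class `bic_scan` with the scan table (`k`,
#'   `log_likelihood`, `bic`), `selected_k`, and the fitted models.
#' @export
scan_k <- function(e, k_min = 1, k_max = 8, seed = 1, n_restarts = 10,
                   sigma_floor = 0.01) {
  k_min <- assert_count(k_min, "k_min")
  k_max <- assert_count(k_max, "k_max")
  if (k_max < k_min) abort("`k_max` must be >= `k_min`")
  if (is.data.frame(e)) e <- e$e
  fits <- purrr::map(k_min:k_max, function(k) {
    tryCatch(fit_gmm(e, k, seed = seed + k, n_restarts = n_restarts,
                     sigma_floor = sigma_floor),
             error = function(err) NULL)
  })
  names(fits) <- paste0("k", k_min:k_max)
  scan <- tibble(
    k = k_min:k_max,
    log_likelihood = purrr::map_dbl(fits, ~ if (is.null(.x)) NA_real_ else .x$log_likelihood),
    bic = purrr::map_dbl(fits, ~ if (is.null(.x)) NA_real_ else .x$bic)
  )
  if (all(is.na(scan$bic))) abort("every k in the scan failed to fit")
  selected <- scan$k[which.min(scan$bic)]
  structure(
    list(scan = scan, selected_k = selected,
         best_fit = fits[[paste0("k", selected)]], fits = fits),
    class = "bic_scan"
  )
}

#' @export
print.bic_scan <- function(x, ...) {
  cat(sprintf("BIC scan over k = %d..%d; selected k = %d\n",
              min(x$scan$k), max(x$scan$k), x$selected_k))
  print(x$scan)
  invisible(x)
}

#' Conformational-state table from a fitted mixture
#'
#' Labels the components S1..Sk by decreasing inter-dye distance (S1 is the
#' most extended, lowest-efficiency state), converts mean efficiencies to
#' distances, and reports occupancies in percent.
#'
#' @param model A [fit_gmm()] result.
#' @param cal A [forster_calibration()].
#' @return A tibble `state, mean_E, sigma, distance_A, occupancy_pct` of
#'   class `state_table`.
#' @export
occupancy_table <- function(model, cal = forster_calibration()) {
  stopifnot(inherits(model, "gmm_fit"))
  if (any(diff(model$means) < 1e-9)) {
    warn("two components share a mean efficiency; distance ordering is tied and labels were merged arbitrarily")
  }
  out <- tibble(
    state = paste0("S", seq_len(model$k)),
    mean_E = model$means,
    sigma = model$sigmas,
    distance_A = efficiency_to_distance(model$means, cal),
    occupancy_pct = 100 * model$weights
  )
  class(out) <- c("state_table", class(out))
  out
}

#' Write a state table as TSV
#'
#' @param table A [occupancy_table()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_state_table <- function(table, path) {
  readr::write_tsv(as_tibble(table), path)
  invisible(path)
}

# weights-only EM with fixed means/sigmas; dens may be precomputed
refit_weights <- function(e, means, sigmas, w0 = NULL, dens = NULL,
                          max_iter = 500, tol = 1e-10) {
  k <- length(means)
  if (is.null(dens)) dens <- outer_dens(e, means, sigmas)
  if (is.null(w0)) w0 <- rep(1 / k, k)
  w <- w0
  ll_old <- -Inf
  for (i in seq_len(max_iter)) {
    num <- sweep(dens, 2, w, "*")
    tot <- rowSums(num)
    ll <- sum(log(tot))
    w <- colSums(num / tot) / nrow(dens)
    if (abs(ll - ll_old) < tol * abs(ll)) break
    ll_old <- ll
  }
  w
}

outer_dens <- function(e, means, sigmas) {
  vapply(seq_along(means),
         function(j) dnorm(e, means[j], sigmas[j]),
         numeric(length(e)))
}

#' Compare state occupancies between two conditions
#'
#' Quantifies the equilibrium shift induced by a ligand: states are matched
#' across conditions by nearest mean efficiency, and per-state occupancy
#' deltas get percentile bootstrap confidence intervals obtained by
#' resampling whole traces (never individual frames) within each condition
#' and refitting the mixture weights with means and sigmas held fixed at the
#' reference (condition A) values.
#'
#' @param fit_a,fit_b [fit_gmm()] results for the two conditions; must share
#'   `k`.
#' @param e_a,e_b Data frames with columns `trace_id` and `e`: the
#'   frame-wise efficiencies each condition was fitted on.
#' @param n_bootstrap Bootstrap replicates.
#' @param seed Integer seed.
#' @param conf Confidence level.
#' @return A tibble of class `occupancy_shift`:
#'   `state, mean_E, occupancy_a, occupancy_b, delta, ci_lo, ci_hi`.
#' @export
compare_conditions <- function(fit_a, fit_b, e_a, e_b, n_bootstrap = 200,
                               seed = 1, conf = 0.95) {
  stopifnot(inherits(fit_a, "gmm_fit"), inherits(fit_b, "gmm_fit"))
  if (fit_a$k != fit_b$k) abort("conditions were fitted with different k")
  for (nm in c("trace_id", "e")) {
    if (!nm %in% names(e_a) || !nm %in% names(e_b)) {
      abort("`e_a` and `e_b` need columns `trace_id` and `e`")
    }
  }
  k <- fit_a$k
  # nearest-mean matching: both fits are sorted by mean, verify the sorted
  # pairing is the nearest-mean pairing
  nearest <- vapply(fit_a$means, function(m) which.min(abs(fit_b$means - m)),
                    integer(1))
  if (!identical(nearest, seq_len(k))) {
    warn("state matching by nearest mean is not one-to-one; using distance-rank matching")
  }

  boot_weights <- function(eff, seed_off) {
    ids <- unique(eff$trace_id)
    by_trace <- split(seq_len(nrow(eff)), eff$trace_id)
    dens <- outer_dens(eff$e, fit_a$means, fit_a$sigmas)
    with_seed(seed + seed_off, {
      vapply(seq_len(n_bootstrap), function(b) {
        take <- sample(ids, length(ids), replace = TRUE)
        idx <- unlist(by_trace[take], use.names = FALSE)
        refit_weights(NULL, fit_a$means, fit_a$sigmas, dens = dens[idx, , drop = FALSE])
      }, numeric(k))
    })
  }
  wa <- boot_weights(e_a, 0L)
  wb <- boot_weights(e_b, 1L)
  deltas <- 100 * (wb - wa)
  alpha <- (1 - conf) / 2
  ci <- apply(deltas, 1, stats::quantile, probs = c(alpha, 1 - alpha))

  out <- tibble(
    state = paste0("S", seq_len(k)),
    mean_E = fit_a$means,
    occupancy_a = 100 * fit_a$weights,
    occupancy_b = 100 * fit_b$weights,
    delta = 100 * (fit_b$weights - fit_a$weights),
    ci_lo = ci[1, ],
    ci_hi = ci[2, ]
  )
  class(out) <- c("occupancy_shift", class(out))
  out
}
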