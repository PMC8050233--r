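# Trace idealisation by Gaussian-emission HMMs, dynamic-fraction summaries,
# and the donor/acceptor cross-correlation control.

# density floor keeps forward-backward finite for outliers
emission_dens <- function(x, mu, sg) {
  pmax(dnorm(x, mu, sg), 1e-300)
}

# one Baum-Welch run for a K-state Gaussian-emission HMM (scaled
# forward-backward); returns NULL on numerical failure
baum_welch <- function(x, mu, sg, A, pi0, max_iter = 200, tol = 1e-6,
                       sigma_floor = 1e-4) {
  n <- length(x)
  K <- length(mu)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    B <- vapply(seq_len(K), function(j) emission_dens(x, mu[j], sg[j]),
                numeric(n))
    fwd <- matrix(0, n, K)
    scl <- numeric(n)
    a <- pi0 * B[1, ]
    scl[1] <- sum(a)
    fwd[1, ] <- a / scl[1]
    for (t in 2:n) {
      a <- (fwd[t - 1, ] %*% A) * B[t, ]
      scl[t] <- sum(a)
      if (scl[t] <= 0 || !is.finite(scl[t])) return(NULL)
      fwd[t, ] <- a / scl[t]
    }
    ll <- sum(log(scl))
    bwd <- matrix(0, n, K)
    bwd[n, ] <- 1
    for (t in (n - 1):1) {
      b <- A %*% (B[t + 1, ] * bwd[t + 1, ])
      bwd[t, ] <- b / scl[t + 1]
    }
    g <- fwd * bwd
    g <- g / rowSums(g)
    # transition expectations
    xi_sum <- matrix(0, K, K)
    for (t in 1:(n - 1)) {
      xi <- (fwd[t, ] %o% (B[t + 1, ] * bwd[t + 1, ])) * A / scl[t + 1]
      xi_sum <- xi_sum + xi
    }
    pi0 <- g[1, ]
    A <- xi_sum / pmax(rowSums(xi_sum), 1e-300)
    A <- A / rowSums(A)
    nk <- colSums(g)
    mu <- colSums(g * x) / nk
    sg <- pmax(sqrt(colSums(g * (outer(x, mu, "-"))^2) / nk), sigma_floor)
    if (abs(ll - ll_old) < tol * (abs(ll) + 1)) break
    ll_old <- ll
  }
  list(mu = mu, sigma = sg, A = A, pi = pi0, loglik = ll, iterations = iter,
       converged = iter < max_iter)
}

viterbi_path <- function(x, mu, sg, A, pi0) {
  n <- length(x)
  K <- length(mu)
  lB <- vapply(seq_len(K), function(j) log(emission_dens(x, mu[j], sg[j])),
               numeric(n))
  lA <- log(pmax(A, 1e-300))
  v <- log(pmax(pi0, 1e-300)) + lB[1, ]
  back <- matrix(0L, n, K)
  for (t in 2:n) {
    m <- outer(v, rep(1, K)) + lA
    back[t, ] <- max.col(t(m), ties.method = "first")
    v <- m[cbind(back[t, ], seq_len(K))] + lB[t, ]
  }
  path <- integer(n)
  path[n] <- which.max(v)
  for (t in (n - 1):1) path[t] <- back[t + 1, path[t + 1]]
  path
}

# free parameters of a K-state Gaussian HMM: (K-1) initial + K(K-1)
# transition + 2K emission
hmm_n_params <- function(K) K * K + 2 * K - 1

#' Idealise a single trace with a Gaussian-emission HMM
#'
#' Fits hidden Markov models with 1..`max_states` states to one trace's
#' frame-wise efficiencies by EM (Baum-Welch), selects the state count by
#' per-trace BIC, and decodes the most likely state path by Viterbi.
#'
#' @param e Numeric vector of efficiencies for one trace (>= 10 frames), or
#'   a data frame with an `E` (or `e`) column.
#' @param max_states Largest state count tried.
#' @param seed Integer seed for the EM restarts.
#' @param n_restarts Restarts per state count.
#' @param sigma_floor Emission-width floor in efficiency units.
#' @return An object of class `hmm_path`: per-frame `states`, fitted
#'   `means`/`sigmas`/`transition_matrix`, `k`, `transitions` (number of
#'   state changes along the path), `dwells`, `bic_table`, `log_likelihood`,
#'   `converged`.
#' @export
fit_trace_hmm <- function(e, max_states = 2, seed = 1, n_restarts = 3,
                          sigma_floor = 1e-4) {
  if (is.data.frame(e)) e <- if ("E" %in% names(e)) e$E else e$e
  e <- as.numeric(e[is.finite(e)])
  if (length(e) < 10) abort("at least 10 frames are required")
  max_states <- assert_count(max_states, "max_states")
  n <- length(e)

  fit_k <- function(K) {
    if (K == 1) {
      mu <- mean(e)
      sg <- max(sd(e), sigma_floor)
      return(list(mu = mu, sigma = sg, A = matrix(1, 1, 1), pi = 1,
                  loglik = sum(log(emission_dens(e, mu, sg))),
                  converged = TRUE))
    }
    runs <- with_seed(seed + K, {
      purrr::map(seq_len(n_restarts), function(r) {
        q <- stats::quantile(e, probs = (seq_len(K) - 0.5) / K, names = FALSE)
        mu0 <- q + rnorm(K, 0, max(sd(e), sigma_floor) / 4 * (r - 1))
        sg0 <- rep(max(sd(e) / K, sigma_floor), K)
        A0 <- matrix(0.1 / (K - 1), K, K)
        diag(A0) <- 0.9
        baum_welch(e, mu0, sg0, A0, rep(1 / K, K),
                   sigma_floor = sigma_floor)
      })
    })
    runs <- purrr::compact(runs)
    if (length(runs) == 0) return(NULL)
    runs[[which.max(purrr::map_dbl(runs, "loglik"))]]
  }

  fits <- purrr::map(seq_len(max_states), fit_k)
  bic <- purrr::map_dbl(seq_along(fits), function(K) {
    if (is.null(fits[[K]])) return(NA_real_)
    hmm_n_params(K) * log(n) - 2 * fits[[K]]$loglik
  })
  if (all(is.na(bic))) abort("HMM fitting failed for every state count")
  k_sel <- which.min(bic)
  best <- fits[[k_sel]]
  path <- if (k_sel == 1) rep(1L, n) else {
    viterbi_path(e, best$mu, best$sigma, best$A, best$pi)
  }
  # relabel states by increasing mean efficiency
  ord <- order(best$mu)
  relabel <- match(seq_len(k_sel), ord)
  path <- relabel[path]
  r <- rle(path)
  structure(
    list(states = as.integer(path), k = k_sel,
         means = best$mu[ord], sigmas = best$sigma[ord],
         transition_matrix = best$A[ord, ord, drop = FALSE],
         log_likelihood = best$loglik,
         bic_table = tibble(k = seq_len(max_states), bic = bic),
         transitions = sum(diff(path) != 0),
         dwells = tibble(state = r$values, length = r$lengths),
         converged = isTRUE(best$converged), n_frames = n),
    class = "hmm_path"
  )
}

#' @export
print.hmm_path <- function(x, ...) {
  cat(sprintf("HMM idealisation: %d state(s), %d transition(s) over %d frames\n",
              x$k, x$transitions, x$n_frames))
  invisible(x)
}

#' Idealise every trace of a condition
#'
#' Runs [fit_trace_hmm()] per trace on frame-wise efficiencies.
#'
#' @param eff A tibble with columns `trace_id` and `E` (e.g. from
#'   [apply_corrections()]); invalid frames are dropped.
#' @inheritParams fit_trace_hmm
#' @return A tibble `trace_id, k, transitions, converged` with the list of
#'   `hmm_path` objects in the `"paths"` attribute.
#' @export
idealize_traces <- function(eff, max_states = 2, seed = 1, n_restarts = 3) {
  if (!all(c("trace_id", "E") %in% names(eff))) {
    abort("`eff` needs columns `trace_id` and `E`")
  }
  if ("valid" %in% names(eff)) eff <- eff[eff$valid, ]
  groups <- split(eff$E, factor(eff$trace_id, levels = unique(eff$trace_id)))
  paths <- purrr::imap(groups, function(e, id) {
    tryCatch(fit_trace_hmm(e, max_states = max_states,
                           seed = seed + match(id, names(groups)),
                           n_restarts = n_restarts),
             error = function(err) NULL)
  })
  out <- purrr::imap_dfr(paths, function(p, id) {
    if (is.null(p)) {
      tibble(trace_id = id, k = NA_integer_, transitions = NA_integer_,
             converged = FALSE)
    } else {
      tibble(trace_id = id, k = p$k, transitions = p$transitions,
             converged = p$converged)
    }
  })
  attr(out, "paths") <- paths
  out
}

# Wilson score interval for a binomial proportion
wilson_ci <- function(x, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, centre - half), min(1, centre + half))
}

#' Fraction of traces showing dynamic transitions
#'
#' A trace is dynamic when its idealised path contains at least one state
#' transition. Reports the dynamic fraction with a Wilson score confidence
#' interval.
#'
#' @param idealized Output of [idealize_traces()] (or any tibble with a
#'   `transitions` column; non-converged traces are excluded).
#' @param conf Confidence level.
#' @return A one-row tibble `n_traces, n_dynamic, fraction_dynamic, ci_lo,
#'   ci_hi`.
#' @export
fraction_dynamic <- function(idealized, conf = 0.95) {
  if (!"transitions" %in% names(idealized)) {
    abort("`idealized` needs a `transitions` column")
  }
  tr <- idealized$transitions[!is.na(idealized$transitions)]
  if (length(tr) == 0) abort("no successfully idealised traces")
  n <- length(tr)
  nd <- sum(tr >= 1)
  ci <- wilson_ci(nd, n, conf)
  tibble(n_traces = n, n_dynamic = nd, fraction_dynamic = nd / n,
         ci_lo = ci[1], ci_hi = ci[2])
}

#' Donor/acceptor Pearson cross-correlation per trace
#'
#' Sample Pearson correlation between the two donor-excitation channels
#' `I_DD` and `I_DA` over the analysed frames of each trace — the only
#' FRET-anti-correlated channel pair. Traces with fewer than 3 frames or zero
#' variance in either channel yield an undefined correlation: `NA` with a
#' warning, or an error when no trace has a defined value.
#'
#' @param traces A trace tibble (bin first with [bin_intensities()] to probe
#'   coarser time resolutions).
#' @return A tibble `trace_id, rho, n_frames` (plus `bin_size` when present
#'   in the input).
#' @export
pearson_cross_correlation <- function(traces) {
  assert_traces(traces)
  out <- purrr::map_dfr(split_traces(traces), function(tr) {
    ok <- nrow(tr) >= 3 && sd(tr$I_DD) > 0 && sd(tr$I_DA) > 0
    tibble(trace_id = tr$trace_id[1],
           rho = if (ok) cor(tr$I_DD, tr$I_DA) else NA_real_,
           n_frames = nrow(tr),
           bin_size = if ("bin_size" %in% names(tr)) tr$bin_size[1] else NA_integer_)
  })
  if (all(is.na(out$rho))) {
    abort("undefined correlation: every trace has < 3 frames or zero channel variance")
  }
  if (any(is.na(out$rho))) {
    warn(sprintf("%d trace(s) with undefined correlation (NA)", sum(is.na(out$rho))))
  }
  if (all(is.na(out$bin_size))) out$bin_size <- NULL
  out
}

#' Run the binning/cross-correlation control experiment
#'
#' Simulates the fast two-state control, bins at every configured bin size,
#' computes the per-trace donor/acceptor Pearson correlation, and aggregates
#' per bin size. At bin size 1 the fast anti-correlated switching gives
#' strongly negative correlations; as more and more transitions are averaged
#' into each bin the correlation collapses towards zero — the signature of
#' dynamics faster than the sampling period.
#'
#' @param config A [control_config()].
#' @param seed Integer seed.
#' @return A tibble of class `crosscorr_summary`:
#'   `bin_size, n_traces, mean_rho, sd_rho`, with the per-trace correlations
#'   in the `"per_trace"` attribute.
#' @export
control_experiment <- function(config = control_config(), seed = 1) {
  traces <- simulate_control_traces(config, seed)
  per_trace <- pearson_cross_correlation(traces)
  out <- per_trace %>%
    filter(!is.na(.data$rho)) %>%
    group_by(.data$bin_size) %>%
    summarise(n_traces = dplyr::n(), mean_rho = mean(.data$rho),
              sd_rho = sd(.data$rho), .groups = "drop") %>%
    arrange(.data$bin_size)
  attr(out, "per_trace") <- per_trace
  class(out) <- c("crosscorr_summary", class(out))
  out
}
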