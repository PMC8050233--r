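# broom-style tidiers for fitted objects.

#' Tidy a fitted Gaussian mixture
#'
#' @param x A [fit_gmm()] result.
#' @param ... Unused.
#' @return A tibble with one row per component: `component` (S1..Sk by
#'   decreasing implied distance), `mean`, `sigma`, `weight`.
#' @export
tidy.gmm_fit <- function(x, ...) {
  tibble(component = paste0("S", seq_len(x$k)),
         mean = x$means, sigma = x$sigmas, weight = x$weights)
}

#' Glance at a fitted Gaussian mixture
#'
#' @param x A [fit_gmm()] result.
#' @param ... Unused.
#' @return A one-row tibble `k, log_likelihood, bic, n, converged,
#'   iterations`.
#' @export
glance.gmm_fit <- function(x, ...) {
  tibble(k = x$k, log_likelihood = x$log_likelihood, bic = x$bic,
         n = x$n_data, converged = x$converged, iterations = x$iterations)
}

#' Tidy a BIC scan
#'
#' @param x A [scan_k()] result.
#' @param ... Unused.
#' @return The scan table with a `selected` flag.
#' @export
tidy.bic_scan <- function(x, ...) {
  mutate(x$scan, selected = .data$k == x$selected_k)
}

#' Glance at a BIC scan
#'
#' @param x A [scan_k()] result.
#' @param ... Unused.
#' @return A one-row tibble `selected_k, k_min, k_max, n`.
#' @export
glance.bic_scan <- function(x, ...) {
  tibble(selected_k = x$selected_k, k_min = min(x$scan$k),
         k_max = max(x$scan$k), n = x$best_fit$n_data)
}

#' Tidy a Hill dose-response fit
#'
#' @param x A [fit_hill()] result.
#' @param ... Unused.
#' @return A tibble `term, estimate, std.error`.
#' @export
tidy.hill_fit <- function(x, ...) {
  est <- c(A = x$A, B = x$B, ic50 = x$ic50, n = x$hill_n)
  se <- rep(NA_real_, 4)
  if (!is.null(x$vcov)) se <- sqrt(diag(x$vcov))[c("A", "B", "ic50", "n")]
  tibble(term = names(est), estimate = unname(est), std.error = unname(se))
}

#' Glance at a Hill dose-response fit
#'
#' @param x A [fit_hill()] result.
#' @param ... Unused.
#' @return A one-row tibble `ic50, hill_n, identifiable, ic50_in_window,
#'   n_at_bound, n_obs, fit_window`.
#' @export
glance.hill_fit <- function(x, ...) {
  tibble(ic50 = x$ic50, hill_n = x$hill_n, identifiable = x$identifiable,
         ic50_in_window = x$ic50_in_window, n_at_bound = x$n_at_bound,
         n_obs = x$n_obs, fit_window = x$fit_window)
}

#' Tidy an HMM idealisation
#'
#' @param x A [fit_trace_hmm()] result.
#' @param ... Unused.
#' @return A tibble with one row per fitted state: `state, mean, sigma,
#'   self_transition`.
#' @export
tidy.hmm_path <- function(x, ...) {
  tibble(state = seq_len(x$k), mean = x$means, sigma = x$sigmas,
         self_transition = diag(x$transition_matrix))
}
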