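# ALEX correction factors: estimation and application.

#' ALEX correction factors
#'
#' The four factors converting apparent to absolute FRET efficiency and
#' stoichiometry: `alpha` (donor emission leaking into the acceptor channel),
#' `delta` (direct acceptor excitation by the donor laser), `gamma`
#' (acceptor/donor detection and quantum-yield ratio) and `beta` (excitation
#' normalisation between the two lasers).
#'
#' @param alpha,delta Crosstalk fractions (>= 0).
#' @param gamma,beta Multiplicative factors (> 0).
#' @return An object of class `correction_factors`.
#' @export
correction_factors <- function(alpha = 0, delta = 0, gamma = 1, beta = 1) {
  assert_pos(alpha, "alpha", strict = FALSE)
  assert_pos(delta, "delta", strict = FALSE)
  assert_pos(gamma, "gamma")
  assert_pos(beta, "beta")
  structure(list(alpha = alpha, delta = delta, gamma = gamma, beta = beta),
            class = "correction_factors")
}

#' @export
print.correction_factors <- function(x, ...) {
  cat(sprintf("ALEX correction factors: alpha=%.4f delta=%.4f gamma=%.4f beta=%.4f\n",
              x$alpha, x$delta, x$gamma, x$beta))
  invisible(x)
}

#' Apparent FRET efficiency and stoichiometry
#'
#' Per-frame uncorrected quantities:
#' `E_app = I_DA / (I_DD + I_DA)` and
#' `S_app = (I_DD + I_DA) / (I_DD + I_DA + I_AA)`.
#' Frames with a zero denominator are flagged invalid and excluded from all
#' downstream summaries.
#'
#' @param traces A trace tibble.
#' @return A tibble `trace_id, frame, E_app, S_app, valid`.
#' @export
apparent_es <- function(traces) {
  assert_traces(traces)
  den_e <- traces$I_DD + traces$I_DA
  den_s <- den_e + traces$I_AA
  e <- ifelse(den_e != 0, traces$I_DA / den_e, NA_real_)
  s <- ifelse(den_s != 0, den_e / den_s, NA_real_)
  tibble(trace_id = traces$trace_id, frame = traces$frame,
         E_app = e, S_app = s, valid = is.finite(e) & is.finite(s))
}

#' Split traces into calibration species by apparent stoichiometry
#'
#' Reproducible replacement for selecting donor-only and acceptor-only
#' molecules by eye: traces whose mean apparent stoichiometry exceeds
#' `s_high` are donor-only, those below `s_low` acceptor-only, the rest
#' dual-labelled.
#'
#' @param traces A trace tibble.
#' @param s_high,s_low Gating thresholds on mean `S_app`.
#' @return A list of trace tibbles `donor_only`, `acceptor_only`, `dual`.
#' @export
split_by_stoichiometry <- function(traces, s_high = 0.9, s_low = 0.1) {
  assert_traces(traces)
  app <- apparent_es(traces)
  ms <- app %>%
    filter(.data$valid) %>%
    group_by(.data$trace_id) %>%
    summarise(mean_s = mean(.data$S_app), .groups = "drop")
  pick <- function(ids) {
    out <- traces[traces$trace_id %in% ids, ]
    meta <- trace_meta(traces)
    if (!is.null(meta)) out <- set_trace_meta(out, meta[meta$trace_id %in% ids, ])
    out
  }
  list(donor_only = pick(ms$trace_id[ms$mean_s > s_high]),
       acceptor_only = pick(ms$trace_id[ms$mean_s < s_low]),
       dual = pick(ms$trace_id[ms$mean_s >= s_low & ms$mean_s <= s_high]))
}

#' Estimate leakage and direct-excitation factors
#'
#' From single-fluorophore calibration populations:
#' `alpha = <E_app> / (1 - <E_app>)` over pooled donor-only frames and
#' `delta = <S_app> / (1 - <S_app>)` over pooled acceptor-only frames.
#' The pooled apparent quantities are formed from the pooled channel means
#' (`<E_app> = <I_DA> / (<I_DD> + <I_DA>)` and likewise for `<S_app>`), which
#' is identical on noise-free data and removes the ratio-noise bias that a
#' frame-wise mean of `E_app`/`S_app` carries at realistic intensity noise.
#'
#' @param donor_only_traces,acceptor_only_traces Trace tibbles holding at
#'   least one trace each (e.g. from [split_by_stoichiometry()]).
#' @return A [correction_factors()] with `gamma = beta = 1`.
#' @export
estimate_alpha_delta <- function(donor_only_traces, acceptor_only_traces) {
  assert_traces(donor_only_traces)
  assert_traces(acceptor_only_traces)
  if (nrow(donor_only_traces) == 0 || nrow(acceptor_only_traces) == 0) {
    abort("both calibration populations must contain at least one trace")
  }
  mean_e <- mean(donor_only_traces$I_DA) /
    (mean(donor_only_traces$I_DD) + mean(donor_only_traces$I_DA))
  den_s <- mean(acceptor_only_traces$I_DD) + mean(acceptor_only_traces$I_DA) +
    mean(acceptor_only_traces$I_AA)
  mean_s <- (mean(acceptor_only_traces$I_DD) +
               mean(acceptor_only_traces$I_DA)) / den_s
  if (!is.finite(mean_e) || mean_e >= 1 || !is.finite(mean_s) || mean_s >= 1) {
    abort("degenerate calibration population: mean apparent quantity >= 1")
  }
  correction_factors(alpha = max(mean_e / (1 - mean_e), 0),
                     delta = max(mean_s / (1 - mean_s), 0))
}

#' Estimate detection and excitation factors from FRET populations
#'
#' After leakage/direct-excitation correction, the inverse apparent
#' stoichiometry of dual-labelled populations is linear in apparent
#' efficiency: `1/S = a + b * E`. A weighted least-squares fit over
#' population centroids yields `beta = a + b - 1` and
#' `gamma = (a - 1) / (a + b - 1)`.
#'
#' Populations can be supplied directly as centroids, or derived internally
#' by a two-component mixture fit on alpha/delta-corrected efficiencies of
#' dual-labelled traces.
#'
#' @param populations Data frame with columns `e`, `s` (one centroid per
#'   population) and optionally `n` (weights), or `NULL` to derive centroids
#'   from `traces`.
#' @param traces Dual-labelled trace tibble (used when `populations` is
#'   `NULL`).
#' @param factors [correction_factors()] carrying the alpha/delta step
#'   (gamma/beta ignored).
#' @param k Number of mixture components used to form centroids.
#' @param seed Integer seed for the internal mixture fit.
#' @return A [correction_factors()] combining the supplied alpha/delta with
#'   the estimated gamma/beta.
#' @export
estimate_beta_gamma <- function(populations = NULL, traces = NULL,
                                factors = correction_factors(), k = 2,
                                seed = 1) {
  if (is.null(populations)) {
    if (is.null(traces)) abort("supply either `populations` or `traces`")
    ad <- correction_factors(alpha = factors$alpha, delta = factors$delta)
    eff <- apply_corrections(traces, ad)
    eff <- eff[eff$valid, ]
    fit <- fit_gmm(eff$E, k = k, seed = seed, n_restarts = 5)
    dens <- sweep(outer_dens(eff$E, fit$means, fit$sigmas), 2, fit$weights, "*")
    comp <- max.col(dens, ties.method = "first")
    populations <- tibble(e = as.numeric(tapply(eff$E, comp, mean)),
                          s = as.numeric(tapply(eff$S, comp, mean)),
                          n = as.numeric(table(comp)))
  }
  if (!all(c("e", "s") %in% names(populations))) {
    abort("`populations` needs columns `e` and `s`")
  }
  if (nrow(populations) < 2) {
    abort("underdetermined: at least two FRET populations are required")
  }
  if (max(populations$e) - min(populations$e) < 0.05) {
    abort("underdetermined: population efficiencies differ by < 0.05")
  }
  w <- if ("n" %in% names(populations)) populations$n else rep(1, nrow(populations))
  fit <- stats::lm(I(1 / s) ~ e, data = populations, weights = w)
  a <- coef(fit)[[1]]
  b <- coef(fit)[[2]]
  beta <- a + b - 1
  if (!is.finite(beta) || beta <= 0) abort("degenerate fit: beta <= 0")
  gamma <- (a - 1) / beta
  if (!is.finite(gamma) || gamma <= 0) abort("degenerate fit: gamma <= 0")
  correction_factors(alpha = factors$alpha, delta = factors$delta,
                     gamma = gamma, beta = beta)
}

#' Apply ALEX corrections to a trace
#'
#' Converts raw intensities to absolute FRET efficiency and stoichiometry:
#' \deqn{F_{DA} = I_{DA} - \alpha I_{DD} - \delta I_{AA}}
#' \deqn{E = F_{DA} / (\gamma I_{DD} + F_{DA})}
#' \deqn{S = (\gamma I_{DD} + F_{DA}) / (\gamma I_{DD} + F_{DA} + I_{AA}/\beta)}
#' Values are stored unclamped; clamping happens only at distance
#' conversion. Frames with non-finite results are flagged invalid.
#'
#' @param traces A trace tibble.
#' @param factors A [correction_factors()].
#' @return A tibble `trace_id, frame, E, S, valid`.
#' @export
apply_corrections <- function(traces, factors) {
  assert_traces(traces)
  stopifnot(inherits(factors, "correction_factors"))
  f_da <- traces$I_DA - factors$alpha * traces$I_DD - factors$delta * traces$I_AA
  den_e <- factors$gamma * traces$I_DD + f_da
  den_s <- den_e + traces$I_AA / factors$beta
  e <- ifelse(den_e != 0, f_da / den_e, NA_real_)
  s <- ifelse(den_s != 0, den_e / den_s, NA_real_)
  tibble(trace_id = traces$trace_id, frame = traces$frame,
         E = e, S = s, valid = is.finite(e) & is.finite(s))
}

#' Write correction factors as JSON
#'
#' @param factors A [correction_factors()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_correction_factors <- function(factors, path) {
  stopifnot(inherits(factors, "correction_factors"))
  jsonlite::write_json(unclass(factors), path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  invisible(path)
}

#' Read correction factors from JSON
#'
#' @param path Path to a JSON file written by [write_correction_factors()].
#' @return A [correction_factors()].
#' @export
read_correction_factors <- function(path) {
  x <- jsonlite::fromJSON(path)
  correction_factors(alpha = x$alpha, delta = x$delta,
                     gamma = x$gamma, beta = x$beta)
}
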