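# Activity normalisation, bounded Hill dose-response fits, and the
# ANOVA + Tukey HSD significance procedure.

#' Hill dose-response curve
#'
#' `f(x) = A + (B - A) / (1 + (ic50/x)^n)`: `A` is the response without
#' ligand, `B` the response at saturating ligand, `ic50` the half-effect
#' concentration and `n` the Hill coefficient.
#'
#' @param x Concentrations (> 0).
#' @param A,B Baseline and plateau responses.
#' @param ic50 Half-effect concentration (> 0).
#' @param n Hill coefficient (>= 0).
#' @return Response values.
#' @export
hill_response <- function(x, A, B, ic50, n) {
  A + (B - A) / (1 + (ic50 / x)^n)
}

#' Normalise an activity measurement to its control
#'
#' Expresses a sample as percent of control with error propagation:
#' `R = 100 * m_s / m_c` and
#' `sd_R = R * sqrt((sd_s/m_s)^2 + (sd_c/m_c)^2)`.
#'
#' @param sample_mean,sample_sd Sample mean and SD.
#' @param control_mean,control_sd Control mean and SD (`control_mean != 0`).
#' @param n_sample,n_control Optional replicate counts carried through.
#' @return A tibble `mean_pct, sd_pct, n_sample, n_control`.
#' @export
normalize_to_control <- function(sample_mean, sample_sd,
                                 control_mean, control_sd,
                                 n_sample = NA_integer_, n_control = NA_integer_) {
  if (any(control_mean == 0)) abort("control mean must be non-zero")
  r <- 100 * sample_mean / control_mean
  sd_r <- abs(r) * sqrt((sample_sd / sample_mean)^2 +
                          (control_sd / control_mean)^2)
  # a zero sample mean propagates only the control term
  sd_r <- ifelse(sample_mean == 0,
                 100 * sample_sd / abs(control_mean), sd_r)
  tibble(mean_pct = r, sd_pct = sd_r,
         n_sample = n_sample, n_control = n_control)
}

#' Fit a bounded Hill dose-response curve
#'
#' Bounded nonlinear least squares of [hill_response()] on replicate
#' responses, with an optional fit window (`max_concentration`) supporting
#' ligands whose effect inverts at high concentration, where the curve is
#' fitted on the low-concentration branch only. The Hill coefficient can be
#' box-bounded (e.g. to \[0, 5\]). Tables whose response does not change
#' across the window are flagged unidentifiable rather than fitted, and a
#' fitted IC50 falling outside the tested concentration range — a weakly
#' identified ridge solution where plateau and IC50 trade off — is flagged
#' via `ic50_in_window` so downstream summaries can exclude it.
#'
#' @param table A tibble with columns `concentration_uM` and `response_pct`
#'   (one row per replicate measurement), e.g. from
#'   [simulate_dose_response()].
#' @param n_bounds Length-2 bounds on the Hill coefficient (default
#'   unbounded below infinity, `c(0, Inf)`).
#' @param max_concentration Upper edge of the fit window in uM.
#' @param start Optional named list overriding the self-starting values.
#' @return An object of class `hill_fit` with `A`, `B`, `ic50`, `hill_n`,
#'   `vcov`, `identifiable`, `fit_window`, `n_bounds`, `n_obs`, `model`.
#' @export
fit_hill <- function(table, n_bounds = c(0, Inf), max_concentration = Inf,
                     start = NULL) {
  for (nm in c("concentration_uM", "response_pct")) {
    if (!nm %in% names(table)) abort(sprintf("`table` needs column `%s`", nm))
  }
  if (length(n_bounds) != 2 || n_bounds[1] < 0 || n_bounds[2] <= n_bounds[1]) {
    abort("`n_bounds` must be an increasing pair with lower bound >= 0")
  }
  dat <- table[is.finite(table$response_pct) &
                 table$concentration_uM <= max_concentration, ]
  if (length(unique(dat$concentration_uM)) < 4) {
    abort("at least 4 distinct concentrations are required inside the fit window")
  }
  if (any(dat$concentration_uM <= 0)) abort("concentrations must be > 0")

  conc_means <- tapply(dat$response_pct, dat$concentration_uM, mean)
  conc_levels <- as.numeric(names(conc_means))
  resid_noise <- sd(unlist(tapply(dat$response_pct, dat$concentration_uM,
                                  function(v) v - mean(v))))
  if (is.na(resid_noise)) resid_noise <- 0
  flat <- diff(range(conc_means)) <= max(2 * resid_noise, 1e-10)
  if (flat) {
    fit <- list(A = mean(dat$response_pct), B = mean(dat$response_pct),
                ic50 = NA_real_, hill_n = NA_real_, vcov = NULL,
                identifiable = FALSE, ic50_in_window = FALSE,
                n_at_bound = FALSE, fit_window = max_concentration,
                n_bounds = n_bounds, n_obs = nrow(dat), model = NULL,
                data = dat)
    class(fit) <- "hill_fit"
    return(fit)
  }

  o <- order(conc_levels)
  s <- list(A = unname(conc_means[o][1]),
            B = unname(conc_means[o][length(o)]),
            ic50 = exp(mean(log(range(conc_levels)))),
            n = min(max(1, n_bounds[1] + 1e-3), n_bounds[2]))
  if (!is.null(start)) s[names(start)] <- start

  m <- tryCatch(
    minpack.lm::nlsLM(
      response_pct ~ hill_response(concentration_uM, A, B, ic50, n),
      data = dat, start = s,
      lower = c(A = -Inf, B = -Inf, ic50 = 1e-9, n = n_bounds[1]),
      upper = c(A = Inf, B = Inf, ic50 = Inf, n = n_bounds[2]),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) abort(sprintf(
      "Hill fit did not converge: %s (residual range %.3g..%.3g)",
      conditionMessage(e), min(dat$response_pct), max(dat$response_pct)))
  )
  cf <- coef(m)
  sigma_resid <- sd(resid(m))
  # an IC50 outside the tested concentration range is not measured by the
  # experiment; such fits are flagged so summaries can exclude them
  in_window <- cf[["ic50"]] >= min(conc_levels) && cf[["ic50"]] <= max(conc_levels)
  fit <- list(A = cf[["A"]], B = cf[["B"]], ic50 = cf[["ic50"]],
              hill_n = cf[["n"]],
              vcov = tryCatch(stats::vcov(m), error = function(e) NULL),
              identifiable = abs(cf[["B"]] - cf[["A"]]) > 2 * sigma_resid &&
                in_window,
              ic50_in_window = in_window,
              n_at_bound = cf[["n"]] <= n_bounds[1] + 1e-6 ||
                cf[["n"]] >= n_bounds[2] - 1e-6,
              fit_window = max_concentration, n_bounds = n_bounds,
              n_obs = nrow(dat), model = m, data = dat)
  class(fit) <- "hill_fit"
  fit
}

#' @export
print.hill_fit <- function(x, ...) {
  if (!x$identifiable && is.na(x$ic50)) {
    cat("Hill fit: response flat across the window; IC50 unidentifiable\n")
  } else {
    cat(sprintf("Hill fit: A=%.2f B=%.2f IC50=%.3g uM n=%.3g%s\n",
                x$A, x$B, x$ic50, x$hill_n,
                if (x$identifiable) "" else "  [IC50 weakly identified]"))
  }
  invisible(x)
}

#' One-way ANOVA with Tukey HSD follow-up
#'
#' The significance procedure for comparative activity data: a one-way ANOVA
#' decides whether any group differs (confidence level 0.05); when it does,
#' Tukey's HSD (Tukey-Kramer under unequal group sizes) provides
#' multiplicity-adjusted pairwise p values, starred at
#' 0.05 / 0.01 / 0.005.
#'
#' @param data A data frame.
#' @param response,group Column names (strings) of the response values and
#'   group labels.
#' @param control Optional control-group label; when given, the pairwise
#'   table is restricted to comparisons against it.
#' @return An object of class `significance_table` with `anova` (one-row
#'   tibble: F, df, p) and `pairs` (tibble with adjusted p and stars; empty
#'   when the ANOVA is not significant).
#' @export
anova_tukey <- function(data, response = "response_pct", group = "group",
                        control = NULL) {
  for (nm in c(response, group)) {
    if (!nm %in% names(data)) abort(sprintf("`data` needs column `%s`", nm))
  }
  y <- data[[response]]
  gr <- factor(data[[group]])
  if (nlevels(gr) < 2) abort("at least two groups are required")
  sizes <- table(gr)
  if (any(sizes < 2)) {
    abort(sprintf("every group needs n >= 2 (offending: %s)",
                  paste(names(sizes)[sizes < 2], collapse = ", ")))
  }
  fit <- aov(y ~ gr)
  an <- summary(fit)[[1]]
  f <- an[["F value"]][1]
  p <- an[["Pr(>F)"]][1]
  anova_tbl <- tibble(F = f, df_between = an[["Df"]][1],
                      df_within = an[["Df"]][2], p = p)

  stars_of <- function(p) dplyr::case_when(
    p < 0.005 ~ "***", p < 0.01 ~ "**", p < 0.05 ~ "*", TRUE ~ ""
  )
  pairs <- tibble(comparison = character(), diff = numeric(),
                  lwr = numeric(), upr = numeric(), p_adj = numeric(),
                  stars = character())
  if (is.finite(p) && p < 0.05) {
    tk <- TukeyHSD(fit)$gr
    pairs <- tibble(comparison = rownames(tk), diff = tk[, "diff"],
                    lwr = tk[, "lwr"], upr = tk[, "upr"],
                    p_adj = tk[, "p adj"]) %>%
      mutate(stars = stars_of(.data$p_adj))
    if (!is.null(control)) {
      keep <- startsWith(pairs$comparison, paste0(control, "-")) |
        endsWith(pairs$comparison, paste0("-", control))
      pairs <- pairs[keep, ]
    }
  }
  out <- list(anova = anova_tbl, pairs = pairs, control = control)
  class(out) <- "significance_table"
  out
}

#' @export
print.significance_table <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F = %.3f, p = %.4g\n", x$anova$F, x$anova$p))
  if (nrow(x$pairs) > 0) print(x$pairs) else cat("no pairwise follow-up (ANOVA not significant)\n")
  invisible(x)
}

#' Write a significance table as TSV with star annotations
#'
#' @param x An [anova_tukey()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_significance_table <- function(x, path) {
  stopifnot(inherits(x, "significance_table"))
  readr::write_tsv(x$pairs, path)
  invisible(path)
}
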