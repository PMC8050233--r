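# Trace table io, photobleach detection, and rule-based quality control.

#' Read a trace table from TSV
#'
#' Reads three-channel ALEX traces from the tab-separated schema
#' `trace_id, frame, I_DD, I_DA, I_AA` (header required, one row per frame).
#' An optional JSON sidecar (`<path>.json` by default) restores per-trace
#' metadata written by [write_trace_table()].
#'
#' @param path Path to the TSV file.
#' @param sidecar Path to the metadata sidecar; defaults to `<path>.json`
#'   when that file exists.
#' @return A trace tibble (see [render_alex_trace()] for the layout).
#' @export
read_trace_table <- function(path, sidecar = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  traces <- readr::read_tsv(path, show_col_types = FALSE,
                            col_types = readr::cols(.default = readr::col_guess()))
  missing <- setdiff(trace_cols, names(traces))
  if (length(missing) > 0) {
    abort(sprintf("%s: missing column(s): %s", path,
                  paste(missing, collapse = ", ")))
  }
  for (cl in c("frame", "I_DD", "I_DA", "I_AA")) {
    if (!is.numeric(traces[[cl]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(traces[[cl]]))))[1]
      abort(sprintf("%s: non-numeric value in column %s at data row %d",
                    path, cl, if (is.na(bad)) 1L else bad))
    }
  }
  if (any(traces$frame < 0 | traces$frame != round(traces$frame))) {
    bad <- which(traces$frame < 0 | traces$frame != round(traces$frame))[1]
    abort(sprintf("%s: invalid frame index at data row %d", path, bad))
  }
  dup <- duplicated(traces[, c("trace_id", "frame")])
  if (any(dup)) {
    abort(sprintf("%s: duplicated (trace_id, frame) at data row %d",
                  path, which(dup)[1]))
  }
  traces <- as_tibble(traces)
  traces$frame <- as.integer(traces$frame)
  if (is.null(sidecar)) {
    cand <- paste0(path, ".json")
    if (file.exists(cand)) sidecar <- cand
  }
  if (!is.null(sidecar) && file.exists(sidecar)) {
    meta <- as_tibble(jsonlite::fromJSON(sidecar))
    traces <- set_trace_meta(traces, meta)
  }
  traces
}

#' Write a trace table to TSV
#'
#' Writes the five schema columns to TSV and, when metadata is attached,
#' a JSON sidecar holding frame period, condition and bleach annotations so
#' that a write/read round trip is lossless.
#'
#' @param traces A trace tibble.
#' @param path Output TSV path.
#' @param sidecar Output path for the metadata sidecar (default
#'   `<path>.json`); only written when metadata exists.
#' @return `path`, invisibly.
#' @export
write_trace_table <- function(traces, path, sidecar = paste0(path, ".json")) {
  assert_traces(traces)
  readr::write_tsv(traces[, trace_cols], path)
  meta <- trace_meta(traces)
  if (!is.null(meta)) {
    jsonlite::write_json(meta, sidecar, dataframe = "columns", digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}

# centred rolling mean with truncated windows at the edges
roll_mean <- function(x, w = 5L) {
  n <- length(x)
  h <- w %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# best mean-difference split of x: split after index t maximises
# mean(x[1:t]) - mean(x[(t+1):n]); splits leaving a segment shorter than
# min_seg are excluded (a one-frame fluctuation is not a bleach step)
best_split <- function(x, min_seg = 1L) {
  n <- length(x)
  if (n < 2 * min_seg || n < 2) {
    return(list(t = NA_integer_, drop = -Inf, pre_mean = mean(x)))
  }
  cs <- cumsum(x)
  t <- seq_len(n - 1)
  pre <- cs[t] / t
  post <- (cs[n] - cs[t]) / (n - t)
  drop <- pre - post
  drop[t < min_seg | t > n - min_seg] <- -Inf
  i <- which.max(drop)
  list(t = i, drop = drop[i], pre_mean = pre[i], post_mean = post[i])
}

# single-channel step detection: change point on the rolling mean, refined on
# the raw signal, with a scale-invariant validity guard
detect_channel_step <- function(x, window = 5L) {
  s <- roll_mean(x, window)
  bs <- best_split(s, min_seg = window)
  if (!is.finite(bs$drop) || is.na(bs$t)) return(NULL)
  # refine the split on the raw channel near the smoothed change point
  lo <- max(window, bs$t - window)
  hi <- min(length(x) - window, bs$t + window)
  if (hi < lo) return(NULL)
  cand <- purrr::map(lo:hi, function(t) {
    pre <- mean(x[1:t]); post <- mean(x[(t + 1):length(x)])
    list(t = t, drop = pre - post, pre_mean = pre, post_mean = post)
  })
  best <- cand[[which.max(purrr::map_dbl(cand, "drop"))]]
  # a real bleach step must drop by >= 50% of the pre-step mean, and the
  # pre-step mean must stand clear of the residual noise
  resid_sd <- sd(c(x[1:best$t] - best$pre_mean,
                   x[(best$t + 1):length(x)] - best$post_mean))
  if (is.na(resid_sd)) resid_sd <- 0
  if (best$pre_mean <= 0 || best$drop < 0.5 * best$pre_mean ||
      best$pre_mean < resid_sd) {
    return(NULL)
  }
  best
}

# count additional >=50%-of-prebleach-mean drops on either side of a step
count_steps <- function(x, step, window = 5L) {
  thr <- 0.5 * step$pre_mean
  n_extra <- 0L
  segments <- list(x[1:step$t], x[(step$t + 1):length(x)])
  for (seg in segments) {
    if (length(seg) < 2 * window) next
    bs <- best_split(roll_mean(seg, window), min_seg = window)
    if (is.finite(bs$drop) && bs$drop >= thr) n_extra <- n_extra + 1L
  }
  1L + n_extra
}

#' Detect photobleaching change points
#'
#' Locates the acceptor bleach as the change point maximising the drop in
#' mean `I_AA`, and the donor bleach likewise on the total donor-excitation
#' signal `I_DD + I_DA`. Change points are found on a rolling mean (window 5)
#' and refined on the raw channel. A trace is single-step when no channel
#' shows a second drop of at least 50% of the pre-bleach mean. "No bleach
#' detected" (`NA` frames) is a valid result.
#'
#' @param traces A trace tibble (one or several traces).
#' @param window Rolling-mean window in frames.
#' @return A tibble with one row per trace: `trace_id`,
#'   `acceptor_bleach_frame`, `donor_bleach_frame` (0-based first dark frame,
#'   `NA` when none), `single_step`, `n_steps`.
#' @export
detect_bleach <- function(traces, window = 5L) {
  assert_traces(traces)
  purrr::map_dfr(split_traces(traces), function(tr) {
    acc <- detect_channel_step(tr$I_AA, window)
    don <- detect_channel_step(tr$I_DD + tr$I_DA, window)
    acc_steps <- if (is.null(acc)) 0L else count_steps(tr$I_AA, acc, window)
    don_steps <- if (is.null(don)) 0L else {
      count_steps(tr$I_DD + tr$I_DA, don, window)
    }
    tibble(
      trace_id = tr$trace_id[1],
      acceptor_bleach_frame = if (is.null(acc)) NA_integer_ else tr$frame[acc$t + 1L],
      donor_bleach_frame = if (is.null(don)) NA_integer_ else tr$frame[don$t + 1L],
      # one bleach step per dye is the single-molecule signature; a second
      # drop within the same channel indicates an aggregate
      single_step = acc_steps <= 1L && don_steps <= 1L,
      n_steps = acc_steps + don_steps
    )
  })
}

#' Quality-control criteria for smFRET traces
#'
#' Deterministic acceptance rules standing in for learned trace
#' classification: a stoichiometry window selecting single-donor
#' single-acceptor molecules, a minimum usable pre-bleach length, an optional
#' single-step bleach requirement, and a donor/acceptor anti-correlation
#' threshold.
#'
#' @param stoichiometry_window Numeric `(low, high)` inside (0, 1); the mean
#'   apparent stoichiometry over the pre-bleach region must fall inside it.
#' @param min_prebleach_frames Minimum pre-bleach frames (>= 5).
#' @param require_single_bleach_step Reject traces with multi-step bleaching
#'   (aggregates / multiple fluorophores).
#' @param min_anticorrelation Maximum allowed Pearson correlation between
#'   `I_DD` and `I_DA` over the pre-bleach region (<= 0 enforces
#'   anti-correlation; `NA` disables the rule, e.g. for static samples).
#' @return An object of class `qc_criteria`.
#' @export
qc_criteria <- function(stoichiometry_window = c(0.3, 0.7),
                        min_prebleach_frames = 10L,
                        require_single_bleach_step = TRUE,
                        min_anticorrelation = 0) {
  w <- stoichiometry_window
  if (length(w) != 2 || !(0 < w[1] && w[1] < w[2] && w[2] < 1)) {
    abort("`stoichiometry_window` must satisfy 0 < low < high < 1")
  }
  min_prebleach_frames <- assert_count(min_prebleach_frames,
                                       "min_prebleach_frames", min = 5)
  if (!is.na(min_anticorrelation) && min_anticorrelation > 0) {
    abort("`min_anticorrelation` must be <= 0 (or NA to disable)")
  }
  structure(
    list(stoichiometry_window = as.numeric(w),
         min_prebleach_frames = min_prebleach_frames,
         require_single_bleach_step = isTRUE(require_single_bleach_step),
         min_anticorrelation = min_anticorrelation),
    class = "qc_criteria"
  )
}

#' Filter traces by quality-control rules
#'
#' Applies [qc_criteria()] to each trace. The usable region of a trace is the
#' pre-bleach region: frames strictly before the first detected bleach
#' (donor or acceptor); traces with no detected bleach use all frames.
#' Acceptance requires, in order: enough pre-bleach frames, single-step
#' bleaching (when required), mean apparent stoichiometry inside the window,
#' and Pearson(I_DD, I_DA) at or below the anti-correlation threshold.
#' Accepted traces are returned truncated to their pre-bleach region.
#'
#' @param traces A trace tibble.
#' @param criteria A [qc_criteria()].
#' @return An object of class `qc_result`: a list with `traces` (accepted,
#'   truncated to the pre-bleach region), `report` (per-trace tibble with
#'   accept flag and reason code), and `counts` (per-reason tally).
#' @export
qc_filter <- function(traces, criteria = qc_criteria()) {
  assert_traces(traces)
  stopifnot(inherits(criteria, "qc_criteria"))
  bleach <- detect_bleach(traces)
  per_trace <- split_traces(traces)

  rows <- purrr::map(names(per_trace), function(id) {
    tr <- per_trace[[id]]
    b <- bleach[bleach$trace_id == id, ]
    first_bleach <- suppressWarnings(
      min(b$acceptor_bleach_frame, b$donor_bleach_frame, na.rm = TRUE))
    pre <- if (is.finite(first_bleach)) tr[tr$frame < first_bleach, ] else tr

    app <- apparent_es(pre)
    mean_s <- mean(app$S_app[app$valid])
    rho <- if (nrow(pre) >= 3 && sd(pre$I_DD) > 0 && sd(pre$I_DA) > 0) {
      cor(pre$I_DD, pre$I_DA)
    } else NA_real_

    reason <- NA_character_
    if (nrow(pre) < criteria$min_prebleach_frames) {
      reason <- "prebleach_length"
    } else if (criteria$require_single_bleach_step && !b$single_step) {
      reason <- "multistep"
    } else if (!is.finite(mean_s) ||
               mean_s < criteria$stoichiometry_window[1] ||
               mean_s > criteria$stoichiometry_window[2]) {
      reason <- "stoichiometry"
    } else if (!is.na(criteria$min_anticorrelation) &&
               (is.na(rho) || rho > criteria$min_anticorrelation)) {
      reason <- "anticorrelation"
    }
    list(report = tibble(trace_id = id, accepted = is.na(reason),
                         reason = ifelse(is.na(reason), "accepted", reason),
                         prebleach_frames = nrow(pre),
                         mean_stoichiometry = mean_s, rho = rho),
         pre = if (is.na(reason)) pre else NULL)
  })

  report <- bind_rows(purrr::map(rows, "report"))
  accepted <- bind_rows(purrr::compact(purrr::map(rows, "pre")))
  meta <- trace_meta(traces)
  if (!is.null(meta) && nrow(accepted) > 0) {
    meta <- meta[meta$trace_id %in% unique(accepted$trace_id), ]
    accepted <- set_trace_meta(accepted, meta)
  }
  counts <- report %>%
    group_by(reason) %>%
    summarise(n = dplyr::n(), .groups = "drop")
  structure(
    list(traces = accepted, report = report, counts = counts,
         n_total = nrow(report), n_accepted = sum(report$accepted),
         criteria = criteria, bleach = bleach),
    class = "qc_result"
  )
}

#' @export
print.qc_result <- function(x, ...) {
  cat(sprintf("smFRET QC: %d/%d traces accepted\n", x$n_accepted, x$n_total))
  print(x$counts)
  invisible(x)
}

#' Write a QC report as JSON
#'
#' @param qc A [qc_filter()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(qc, path) {
  stopifnot(inherits(qc, "qc_result"))
  jsonlite::write_json(
    list(n_total = qc$n_total, n_accepted = qc$n_accepted,
         counts = qc$counts, per_trace = qc$report),
    path, dataframe = "columns", auto_unbox = TRUE, digits = 10, na = "null",
    pretty = TRUE)
  invisible(path)
}
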