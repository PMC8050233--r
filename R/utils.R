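# Internal helpers shared across modules.

# Run `code` under an explicit seed without touching the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must be in [0, 1].", name))
  }
  invisible(x)
}

assert_pos <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && all(is.finite(x)) && (if (strict) all(x > 0) else all(x >= 0))
  if (!ok) abort(sprintf("`%s` must be %s.", name, if (strict) "> 0" else ">= 0"))
  invisible(x)
}

assert_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < min || x != round(x)) {
    abort(sprintf("`%s` must be an integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

# Columns every trace table must carry.
trace_cols <- c("trace_id", "frame", "I_DD", "I_DA", "I_AA")

assert_traces <- function(traces) {
  if (!is.data.frame(traces)) abort("`traces` must be a data frame.")
  missing <- setdiff(trace_cols, names(traces))
  if (length(missing) > 0) {
    abort(sprintf("trace table is missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  invisible(traces)
}

# Per-trace metadata attached to a trace tibble (frame_period, condition,
# bleach annotations). Returns an empty template when absent.
#' Per-trace metadata of a trace table
#'
#' Trace tables generated by [render_alex_trace()] and friends carry a
#' per-trace metadata tibble (frame period, condition, true bleach frames,
#' ground-truth labels) in the `"meta"` attribute. This accessor retrieves it.
#'
#' @param traces A trace tibble.
#' @return A tibble with one row per trace, or `NULL` when no metadata is
#'   attached.
#' @export
trace_meta <- function(traces) {
  attr(traces, "meta", exact = TRUE)
}

set_trace_meta <- function(traces, meta) {
  attr(traces, "meta") <- meta
  traces
}

frame_period_of <- function(traces, default = 0.2) {
  meta <- trace_meta(traces)
  if (!is.null(meta) && "frame_period" %in% names(meta)) {
    fp <- unique(meta$frame_period)
    if (length(fp) == 1 && is.finite(fp)) return(fp)
  }
  fp <- attr(traces, "frame_period", exact = TRUE)
  if (!is.null(fp)) return(fp)
  default
}

# split a trace table into a named list of per-trace tibbles, preserving order
split_traces <- function(traces) {
  split(traces, factor(traces$trace_id, levels = unique(traces$trace_id)))
}
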