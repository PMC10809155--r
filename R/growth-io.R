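# Reading, validating and normalising replicated growth-signal time series.
#
# CSV dialect: comma separated, header row, UTF-8, '.' decimals.
# Curve file columns:     time_h, signal, replicate, condition_id
# Condition file columns: condition_id, glucose_g_l, caproate_g_l, organism
# (extra condition columns are passed through into each curve's `meta`).

#' Construct and validate a growth curve
#'
#' A `growth_curve` holds one replicate's raw instrument signal over time
#' (backscatter or total-absorption equivalent, arbitrary units) together
#' with its condition metadata. Invariants enforced: strictly increasing
#' times starting at >= 0, at least 5 points, strictly positive signals,
#' and no signal below `detection_floor * max(signal)` (defaults to 1e-6;
#' values that low indicate an instrument fault and are rejected rather
#' than clipped).
#'
#' @param times Numeric vector of time points (h).
#' @param signals Numeric vector of raw signals, same length.
#' @param replicate_id,condition_id Text labels.
#' @param meta Named list of condition attributes (substrate g/L, caproate
#'   g/L, organism, ...).
#' @param detection_floor Fraction of the maximum signal below which a
#'   signal is considered unmeasurable.
#' @return Object of class `growth_curve`.
#' @export
growth_curve <- function(times, signals, replicate_id = "r1",
                         condition_id = "c1", meta = list(),
                         detection_floor = 1e-6) {
  times <- as.numeric(times)
  signals <- as.numeric(signals)
  if (length(times) != length(signals)) {
    ck_abort(sprintf("replicate %s: times and signals differ in length",
                     replicate_id), "validation")
  }
  if (length(times) < 5L) {
    ck_abort(sprintf("replicate %s: need >= 5 time points, got %d",
                     replicate_id, length(times)), "validation")
  }
  if (any(!is.finite(times)) || times[1] < 0 || any(diff(times) <= 0)) {
    ck_abort(sprintf(
      "replicate %s: times must be finite, start >= 0 and be strictly increasing",
      replicate_id), "validation")
  }
  if (any(!is.finite(signals)) || any(signals <= 0)) {
    ck_abort(sprintf("replicate %s: all signals must be > 0", replicate_id),
             "validation")
  }
  if (any(signals < detection_floor * max(signals))) {
    ck_abort(sprintf("replicate %s: signals below the detection floor (%g of max)",
                     replicate_id, detection_floor), "validation")
  }
  structure(
    list(replicate_id = as.character(replicate_id),
         condition_id = as.character(condition_id),
         times = times, signals = signals, meta = meta),
    class = "growth_curve"
  )
}

#' Read replicated growth curves and their condition table from CSV
#'
#' @param path CSV with columns `time_h`, `signal`, `replicate`,
#'   `condition_id`.
#' @param condition_path CSV keyed by `condition_id`; all remaining columns
#'   become each curve's `meta`.
#' @param time_unit Unit of the time column in the file; converted to
#'   hours on load.
#' @param detection_floor Passed to [growth_curve()].
#' @return List of `growth_curve` objects, one per (condition, replicate),
#'   rows sorted by time. An empty file yields an empty list with a warning.
#' @export
read_curves <- function(path, condition_path, time_unit = c("h", "min", "s"),
                        detection_floor = 1e-6) {
  time_unit <- match.arg(time_unit)
  curves <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  conditions <- readr::read_csv(condition_path, show_col_types = FALSE,
                                progress = FALSE)
  need <- c("time_h", "signal", "replicate", "condition_id")
  miss <- setdiff(need, names(curves))
  if (length(miss)) {
    ck_abort(paste0("curve file is missing column(s): ",
                    paste(miss, collapse = ", ")), "schema")
  }
  if (!"condition_id" %in% names(conditions)) {
    ck_abort("condition table is missing column: condition_id", "schema")
  }
  if (nrow(curves) == 0L) {
    ck_warn("curve file contains no rows; returning an empty collection", "io")
    return(list())
  }
  unmatched <- setdiff(unique(curves$condition_id), conditions$condition_id)
  if (length(unmatched)) {
    ck_abort(paste0("condition id(s) not in the condition table: ",
                    paste(unmatched, collapse = ", ")), "validation")
  }
  div <- c(h = 1, min = 60, s = 3600)[[time_unit]]
  curves$time_h <- curves$time_h / div

  meta_of <- function(cid) {
    row <- conditions[conditions$condition_id == cid, , drop = FALSE]
    as.list(row[1, setdiff(names(row), "condition_id"), drop = FALSE])
  }
  out <- list()
  for (cid in unique(curves$condition_id)) {
    sub_c <- curves[curves$condition_id == cid, , drop = FALSE]
    meta <- meta_of(cid)
    for (rep in unique(sub_c$replicate)) {
      sub <- sub_c[sub_c$replicate == rep, , drop = FALSE]
      sub <- sub[order(sub$time_h), , drop = FALSE]
      if (anyDuplicated(sub$time_h)) {
        ck_abort(sprintf(
          "replicate %s in condition %s has duplicated time points", rep, cid),
          "validation")
      }
      out[[length(out) + 1L]] <- growth_curve(
        sub$time_h, sub$signal, replicate_id = rep, condition_id = cid,
        meta = meta, detection_floor = detection_floor)
    }
  }
  out
}

#' Write growth curves back to the curve-file CSV dialect
#'
#' Inverse of [read_curves()] for the curve file; `read_curves()` on the
#' output reproduces times and signals exactly.
#'
#' @param curves List of `growth_curve` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_curves <- function(curves, path) {
  rows <- dplyr::bind_rows(lapply(curves, function(cu) {
    tibble::tibble(time_h = cu$times, signal = cu$signals,
                   replicate = cu$replicate_id, condition_id = cu$condition_id)
  }))
  readr::write_csv(rows, path)
  invisible(path)
}

#' Normalise a growth curve to its initial signal
#'
#' Log mode (default): `y_i = ln(signal_i / signal_1)`, so `y` starts at 0
#' and the Gompertz `mu_m` is a specific growth rate in 1/h. Linear mode:
#' `y_i = signal_i / signal_1` (starts at 1), retained for instruments
#' whose signal is already proportional to biomass and for comparison
#' with OD-ratio conventions.
#'
#' @param curve A `growth_curve`.
#' @param mode `"log"` or `"linear"`.
#' @return Object of class `normalized_curve`: `times`, `y`, `mode`, plus
#'   the source ids and meta.
#' @export
normalize <- function(curve, mode = c("log", "linear")) {
  mode <- match.arg(mode)
  s0 <- curve$signals[1]
  if (!is.finite(s0) || s0 == 0) {
    ck_abort("first signal is zero; cannot normalise", "validation")
  }
  y <- if (mode == "log") log(curve$signals / s0) else curve$signals / s0
  structure(
    list(times = curve$times, y = y, mode = mode,
         replicate_id = curve$replicate_id, condition_id = curve$condition_id,
         meta = curve$meta),
    class = "normalized_curve"
  )
}

#' Construct a normalised curve directly
#'
#' Mostly for model-generated data: wraps already-normalised `(times, y)`
#' values in the container [fit_gompertz()] expects, bypassing the raw
#' signal representation.
#'
#' @param times Time points (h).
#' @param y Normalised growth signal.
#' @param mode `"log"` or `"linear"` (what `y` means; see [normalize()]).
#' @param replicate_id,condition_id Labels.
#' @return A `normalized_curve`.
#' @export
normalized_curve <- function(times, y, mode = c("log", "linear"),
                             replicate_id = "r1", condition_id = "c1") {
  mode <- match.arg(mode)
  if (length(times) != length(y)) {
    ck_abort("`times` and `y` must have the same length", "validation")
  }
  structure(
    list(times = as.numeric(times), y = as.numeric(y), mode = mode,
         replicate_id = replicate_id, condition_id = condition_id,
         meta = list()),
    class = "normalized_curve"
  )
}

#' @export
print.growth_curve <- function(x, ...) {
  cat(sprintf("<growth_curve> %s / %s: %d points over %.3g h\n",
              x$condition_id, x$replicate_id, length(x$times), max(x$times)))
  invisible(x)
}
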