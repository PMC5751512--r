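# Uniform-grid time-series bookkeeping shared by every stage. All records are
# plain tibbles (one row per sample, one column per channel) with protocol
# metadata carried in attributes, so they pipe through dplyr naturally and the
# package functions re-attach what they need.

check_uniform_time <- function(t, tol = 1e-6) {
  if (length(t) < 2) abort("time grid needs at least 2 samples")
  if (any(!is.finite(t))) abort("non-finite values in the time grid")
  dt <- diff(t)
  if (dt[1] <= 0) abort("time must be strictly increasing")
  if (any(abs(dt - dt[1]) > tol)) {
    abort("non-uniform sampling: time steps vary by more than the tolerance")
  }
  dt[1]
}

window_idx <- function(t, window) {
  if (length(window) != 2 || !all(is.finite(window)) || window[2] <= window[1]) {
    abort("window must be c(start, end) in seconds with end > start")
  }
  which(t >= window[1] & t < window[2])
}

#' Construct a measurement record
#'
#' A measurement record is a tibble of synchronized 1 Hz channels -- the
#' calorimetric signal `y1_mV`, the thermostat temperature `y2_C`, the
#' thermostat power `W2_mW`, optionally the known dissipated power `W1_mW`
#' (calibration runs only) and the room temperature `Troom_C` -- plus protocol
#' metadata (phase markers, programmed setpoints) carried as attributes.
#'
#' @param data Data frame with a `t` column (seconds, uniform step) and any of
#'   the channel columns above.
#' @param phases Optional tibble with columns `label`, `start`, `end` (seconds,
#'   half-open intervals) marking protocol phases; must be disjoint, ordered
#'   and within the time span.
#' @param tcal Programmed thermostat setpoint(s) in deg C.
#' @param delta Logical; `TRUE` once baselines have been subtracted (delta
#'   form). Channels keep their column names; [write_record()] suffixes them
#'   with `_delta` on disk.
#' @param truth Optional list of generating parameters (synthetic runs carry
#'   their ground truth here for recovery tests).
#' @param sensor Optional sensor label.
#' @param seed Optional integer seed the record was generated under.
#' @return A `measurement_record` tibble.
#' @export
new_measurement_record <- function(data, phases = NULL, tcal = NULL,
                                   delta = FALSE, truth = NULL, sensor = NULL,
                                   seed = NULL) {
  if (!is.data.frame(data) || !"t" %in% names(data)) {
    abort("`data` must be a data frame with a `t` column")
  }
  check_uniform_time(data$t)
  chan <- setdiff(names(data), "t")
  bad <- chan[vapply(chan, function(ch) any(!is.finite(data[[ch]])), logical(1))]
  if (length(bad)) abort(paste0("non-finite samples in channel(s): ",
                                paste(bad, collapse = ", ")))
  out <- tibble::as_tibble(data)
  class(out) <- c("measurement_record", class(out))
  attr(out, "phases") <- phases
  attr(out, "tcal") <- tcal
  attr(out, "delta") <- isTRUE(delta)
  attr(out, "truth") <- truth
  attr(out, "sensor") <- sensor
  attr(out, "seed") <- seed
  validate_phases(out)
  out
}

validate_phases <- function(rec) {
  ph <- attr(rec, "phases")
  if (is.null(ph)) return(invisible(rec))
  if (!all(c("label", "start", "end") %in% names(ph))) {
    abort("phases need columns label, start, end")
  }
  if (any(ph$end <= ph$start)) abort("phase intervals must have end > start")
  tspan <- range(rec$t)
  if (any(ph$start < tspan[1] - 1e-9) || any(ph$end > tspan[2] + 1 + 1e-9)) {
    abort("phase intervals fall outside the record's time span")
  }
  if (nrow(ph) > 1) {
    o <- order(ph$start)
    if (any(ph$start[o][-1] < ph$end[o][-nrow(ph)] - 1e-9)) {
      abort("phase intervals must be disjoint and ordered")
    }
  }
  invisible(rec)
}

#' @export
print.measurement_record <- function(x, ...) {
  dt <- diff(x$t[1:2])
  cat(sprintf("<measurement_record> %d samples, dt = %g s%s%s\n",
              nrow(x), dt,
              if (isTRUE(attr(x, "delta"))) ", delta form" else "",
              if (!is.null(attr(x, "sensor"))) paste0(", sensor ", attr(x, "sensor")) else ""))
  ph <- attr(x, "phases")
  if (!is.null(ph)) {
    cat("phases: ", paste(sprintf("%s[%g,%g)", ph$label, ph$start, ph$end),
                          collapse = " "), "\n", sep = "")
  }
  NextMethod()
}

#' @rdname new_measurement_record
#' @param rec A measurement record.
#' @export
record_phases <- function(rec) attr(rec, "phases")

#' @rdname new_measurement_record
#' @export
is_delta <- function(rec) isTRUE(attr(rec, "delta"))

#' @rdname new_measurement_record
#' @param label Phase label to look up.
#' @export
phase_window <- function(rec, label) {
  ph <- record_phases(rec)
  if (is.null(ph) || !label %in% ph$label) {
    abort(paste0("record has no phase labelled '", label, "'"))
  }
  row <- ph[ph$label == label, ][1, ]
  c(row$start, row$end)
}

# Re-attach record metadata after a tibble operation stripped it.
restore_record <- function(data, template, delta = attr(template, "delta")) {
  new_measurement_record(data,
    phases = attr(template, "phases"), tcal = attr(template, "tcal"),
    delta = delta, truth = attr(template, "truth"),
    sensor = attr(template, "sensor"), seed = attr(template, "seed"))
}
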