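#' Load a packaged measurement fixture
#'
#' The package embeds the published study tables as plain-CSV fixtures:
#' `"table1"` — glucose levels and recorded channel voltages of 15
#' participants (the measurement schema); `"table2"` — the same
#' measurements with the device estimate and the fuzzy-logic error half
#' width (`fl_glucose`, `fl_error`, mg/dL); `"table3"` — per-participant
#' means and standard deviations from the reference device, the test
#' device, and the fuzzy model (`*_sd` columns, mg/dL).
#'
#' @param name one of `"table1"`, `"table2"`, `"table3"`.
#' @return data.frame with 15 rows.
#' @examples
#' load_fixture("table1")
#' @export
load_fixture <- function(name = c("table1", "table2", "table3")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"), package = "glucofuzz",
                      mustWork = TRUE)
  if (name == "table1") read_measurements(path)
  else utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Run the full measurement-analysis pipeline
#'
#' Per record: estimate glucose from the channel voltages through the
#' calibration model (or take the device's own estimate in pass-through
#' mode), classify the (reference, estimate) pair on the Clarke Error
#' Grid, compute the continuous severity, predict the relative error
#' tolerance with the fuzzy system, and attach the resulting glucose
#' interval `estimate +/- estimate * error / 100` (relative-error
#' convention, recorded in the summary). Deterministic given its inputs.
#'
#' @param records data.frame in the measurement schema (see
#'   [read_measurements()]), or a fixture name accepted by
#'   [load_fixture()]. For pass-through mode a `device_glucose` column
#'   suffices alongside `reference_glucose`.
#' @param passthrough if `TRUE`, use the `device_glucose` column as the
#'   estimate instead of calibrating.
#' @param model a fitted `calibration_model`; if `NULL` and
#'   `passthrough = FALSE`, one is fit on the fly from `records`.
#' @param channels,target passed to [cal_fit()] when fitting on the fly.
#' @param fuzzy a [fuzzy_system()]; default [default_fuzzy_system()].
#' @param axis_max CEG estimate-axis maximum, mg/dL.
#' @return object of class `glucofuzz_result`: list with `rows` (the
#'   input plus `estimated_glucose`, `zone`, `severity`,
#'   `predicted_error_percent`, `glucose_lo`, `glucose_hi`),
#'   `zone_report` (a [ceg_zone_report()]), and `summary` (run
#'   metadata: mode, error convention, clamped-input count).
#' @examples
#' res <- run_analysis(load_fixture("table2"), passthrough = TRUE)
#' res$zone_report
#' @export
run_analysis <- function(records, passthrough = FALSE, model = NULL,
                         channels = "finger",
                         target = "reference_glucose",
                         fuzzy = default_fuzzy_system(),
                         axis_max = 600) {
  if (is.character(records) && length(records) == 1) {
    records <- load_fixture(records)
  }
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop_invalid("records", "needs a non-empty measurement table")
  }
  need <- c("reference_glucose", "v_finger",
            if (passthrough) "device_glucose")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    stop(sprintf("input format error: missing column(s) %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }

  if (passthrough) {
    estimate <- records$device_glucose
    mode <- "passthrough"
  } else {
    if (is.null(model)) {
      model <- cal_fit(records, channels = channels, target = target)
    }
    estimate <- as.numeric(cal_predict(model,
                                       v_finger = records$v_finger,
                                       v_tear = records$v_tear))
    mode <- paste0("calibrated[", paste(model$channels, collapse = "+"), "]")
  }

  zone <- ceg_classify(records$reference_glucose, estimate)
  severity <- ceg_severity(records$reference_glucose, estimate,
                           axis_max = axis_max)
  n_clamped <- 0L
  err <- vapply(seq_len(nrow(records)), function(i) {
    curve <- fz_infer(fuzzy, records$v_finger[i], severity[i])
    if (curve$clamped) n_clamped <<- n_clamped + 1L
    fz_defuzzify(curve)
  }, numeric(1))

  half <- estimate * err / 100
  rows <- cbind(records,
                data.frame(estimated_glucose = estimate, zone = zone,
                           severity = severity,
                           predicted_error_percent = err,
                           glucose_lo = estimate - half,
                           glucose_hi = estimate + half,
                           stringsAsFactors = FALSE))
  structure(list(
    rows = rows,
    zone_report = ceg_zone_report(records$reference_glucose, estimate),
    summary = list(n = nrow(rows), mode = mode,
                   error_convention = "relative",
                   axis_max = axis_max,
                   clamped_fuzzy_inputs = n_clamped,
                   model = if (!passthrough) unclass(model))),
    class = "glucofuzz_result")
}

#' @export
print.glucofuzz_result <- function(x, ...) {
  cat(sprintf("glucofuzz analysis: %d records, mode %s\n",
              x$summary$n, x$summary$mode))
  print(x$zone_report)
  cat(sprintf("mean predicted error: %.1f %%\n",
              mean(x$rows$predicted_error_percent)))
  invisible(x)
}

#' Write an analysis result
#'
#' Writes the augmented row table as CSV (numbers at full precision)
#' and, for JSON, the zone report plus run summary. The displayed
#' glucose interval is rounded to whole mg/dL in the `interval` column,
#' matching the conventional `estimate +/- half-width` presentation.
#'
#' @param result a `glucofuzz_result` from [run_analysis()].
#' @param path output file path.
#' @param format `"csv"` (row table) or `"json"` (report + summary).
#' @return `path`, invisibly.
#' @export
write_result <- function(result, path, format = c("csv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(result, "glucofuzz_result"))
  if (format == "csv") {
    rows <- result$rows
    rows$interval <- sprintf("%d ± %d", round(rows$estimated_glucose),
                             round(rows$estimated_glucose *
                                     rows$predicted_error_percent / 100))
    utils::write.csv(rows, path, row.names = FALSE)
  } else {
    jsonlite::write_json(
      list(summary = result$summary,
           zone_report = list(n = attr(result$zone_report, "n"),
                              zones = as.data.frame(result$zone_report))),
      path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

#' Per-group fingertip voltage ranges
#'
#' Minimum and maximum recorded finger voltage for the diabetic and
#' healthy groups — the group-separation summary used to argue the
#' channels discriminate the two populations.
#'
#' @param records data.frame with `v_finger` and a logical or
#'   `Pos`/`Neg` `diabetic` column.
#' @return data.frame with columns `group`, `n`, `v_min`, `v_max`; a
#'   group absent from the data gets `n = 0` and `NA` bounds with a
#'   warning.
#' @examples
#' summarize_group_ranges(load_fixture("table1"))
#' @export
summarize_group_ranges <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    stop_invalid("records", "needs a non-empty measurement table")
  }
  if (!all(c("v_finger", "diabetic") %in% names(records))) {
    stop_invalid("records", "needs v_finger and diabetic columns")
  }
  diab <- if (is.logical(records$diabetic)) records$diabetic
          else .parse_flag(records$diabetic, "Pos", "Neg", "diabetic")
  out <- do.call(rbind, lapply(c(FALSE, TRUE), function(flag) {
    v <- records$v_finger[diab == flag]
    grp <- if (flag) "diabetic" else "healthy"
    if (length(v) == 0) {
      warning(sprintf("group %s absent from the records", grp), call. = FALSE)
      data.frame(group = grp, n = 0L, v_min = NA_real_, v_max = NA_real_)
    } else {
      data.frame(group = grp, n = length(v), v_min = min(v), v_max = max(v))
    }
  }))
  rownames(out) <- NULL
  out
}
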