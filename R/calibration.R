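#' Fit an affine voltage-to-glucose calibration
#'
#' Ordinary least squares fit of glucose (mg/dL) on one or both sensor
#' channels (fingertip and/or tear voltage). The photodetector output is
#' proportional to received light, so an affine map per channel is the
#' minimal calibration consistent with the acquisition chain; when both
#' channels are selected a single joint fit
#' `glucose ~ 1 + v_finger + v_tear` fuses them.
#'
#' @param records data.frame of measurement records (see
#'   [read_measurements()] for the schema). Must contain the selected
#'   voltage columns and the target column.
#' @param channels character subset of `c("finger", "tear")`.
#' @param target `"reference_glucose"` (calibrate against the reference
#'   meter, the default) or `"device_glucose"` (reproduce the device's
#'   own displayed estimates).
#' @return object of class `calibration_model`: intercept (mg/dL),
#'   one coefficient per channel (mg/dL per volt), the channel set and
#'   target, and a residual summary (`mae`, `max_abs`, mg/dL).
#' @examples
#' rec <- data.frame(reference_glucose = 40 + 38 * c(1, 2, 3, 4),
#'                   v_finger = c(1, 2, 3, 4))
#' cal_fit(rec, channels = "finger")
#' @export
cal_fit <- function(records, channels = "finger",
                    target = c("reference_glucose", "device_glucose")) {
  target <- match.arg(target)
  channels <- match.arg(channels, c("finger", "tear"), several.ok = TRUE)
  vcols <- paste0("v_", channels)
  missing_cols <- setdiff(c(vcols, target), names(records))
  if (length(missing_cols)) {
    stop_invalid("records", paste("missing column(s):",
                                  paste(missing_cols, collapse = ", ")))
  }
  n <- nrow(records)
  if (n < length(channels) + 2) {
    stop(sprintf("degenerate fit: %d record(s) cannot identify %d channel(s) + intercept",
                 n, length(channels)), call. = FALSE)
  }
  X <- cbind(1, as.matrix(records[, vcols, drop = FALSE]))
  if (qr(X)$rank < ncol(X)) {
    stop("degenerate fit: design matrix is rank deficient (constant or collinear voltages)",
         call. = FALSE)
  }
  y <- records[[target]]
  fit <- stats::lm.fit(X, y)
  coefs <- fit$coefficients
  res <- fit$residuals
  structure(list(intercept = unname(coefs[1]),
                 coefficients = stats::setNames(unname(coefs[-1]), vcols),
                 channels = channels, target = target, n = n,
                 residuals = list(mae = mean(abs(res)),
                                  max_abs = max(abs(res)))),
            class = "calibration_model")
}

#' Predict glucose from sensor voltages
#'
#' Affine evaluation of a fitted calibration. Predictions are clipped
#' below at 1 mg/dL; if clipping occurred the result carries attribute
#' `clipped = TRUE` and a warning is emitted.
#'
#' @param model a `calibration_model` from [cal_fit()].
#' @param v_finger,v_tear numeric vectors of channel voltages, volts;
#'   only the model's channels are required.
#' @return numeric vector of estimated glucose, mg/dL.
#' @export
cal_predict <- function(model, v_finger = NULL, v_tear = NULL) {
  stopifnot(inherits(model, "calibration_model"))
  inputs <- list(v_finger = v_finger, v_tear = v_tear)
  vcols <- names(model$coefficients)
  for (col in vcols) {
    if (is.null(inputs[[col]])) {
      stop_invalid(col, "required by this calibration model")
    }
  }
  n <- max(vapply(inputs[vcols], length, integer(1)))
  est <- rep(model$intercept, n)
  for (col in vcols) {
    est <- est + model$coefficients[[col]] * rep_len(inputs[[col]], n)
  }
  if (any(est < 1)) {
    warning("prediction(s) below 1 mg/dL clipped", call. = FALSE)
    est <- pmax(est, 1)
    attr(est, "clipped") <- TRUE
  }
  est
}

#' @export
print.calibration_model <- function(x, ...) {
  terms <- paste(sprintf("%.4g * %s", x$coefficients,
                         names(x$coefficients)), collapse = " + ")
  cat(sprintf("Affine calibration (%s, n = %d):\n  glucose = %.4g + %s\n",
              x$target, x$n, x$intercept, terms))
  cat(sprintf("  residuals: MAE %.3g mg/dL, max |r| %.3g mg/dL\n",
              x$residuals$mae, x$residuals$max_abs))
  invisible(x)
}

#' Serialize / restore a calibration model as JSON
#'
#' @param model a `calibration_model`.
#' @param path file path.
#' @return `write_calibration()` returns `path` invisibly;
#'   `read_calibration()` returns the restored model.
#' @export
write_calibration <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  payload <- unclass(model)
  payload$coefficients <- as.list(payload$coefficients)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(intercept = lst$intercept,
                 coefficients = unlist(lst$coefficients),
                 channels = lst$channels, target = lst$target, n = lst$n,
                 residuals = as.list(lst$residuals)),
            class = "calibration_model")
}

# ---- Table-1-schema CSV I/O --------------------------------------------

.schema_cols <- c("reference_glucose", "v_finger", "v_tear", "age",
                  "device_glucose", "gender", "diabetic", "fasting")

#' Read / write measurement tables
#'
#' CSV I/O for the fixed measurement schema: `reference_glucose`
#' (mg/dL), `v_finger`, `v_tear` (volts), `age` (years),
#' `device_glucose` (mg/dL, may be empty), `gender` (`M`/`F`),
#' `diabetic` (`Pos`/`Neg`), `fasting` (`Yes`/`No`). The reader returns
#' `diabetic` and `fasting` as logicals and accepts `TRUE`/`FALSE`
#' spellings too; the writer emits the `Pos`/`Neg` and `Yes`/`No`
#' tokens. Extra columns (e.g. participant ids from the simulator) pass
#' through untouched.
#'
#' @param path CSV file path.
#' @param records data.frame carrying at least the schema columns.
#' @return `read_measurements()`: data.frame with the schema columns
#'   (plus any extras); `write_measurements()`: `path`, invisibly.
#' @export
read_measurements <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.schema_cols, names(df))
  if (length(missing_cols)) {
    stop(sprintf("input format error: missing column(s) %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df$diabetic <- .parse_flag(df$diabetic, yes = "Pos", no = "Neg", "diabetic")
  df$fasting <- .parse_flag(df$fasting, yes = "Yes", no = "No", "fasting")
  check_glucose(df$reference_glucose, "reference_glucose")
  if (any(df$v_finger < 0, na.rm = TRUE) || any(df$v_tear < 0, na.rm = TRUE)) {
    stop_invalid("v_finger/v_tear", "voltages must be >= 0")
  }
  df
}

#' @rdname read_measurements
#' @export
write_measurements <- function(records, path) {
  missing_cols <- setdiff(.schema_cols, names(records))
  if (length(missing_cols)) {
    stop_invalid("records", paste("missing column(s):",
                                  paste(missing_cols, collapse = ", ")))
  }
  out <- records
  if (is.logical(out$diabetic)) {
    out$diabetic <- ifelse(out$diabetic, "Pos", "Neg")
  }
  if (is.logical(out$fasting)) {
    out$fasting <- ifelse(out$fasting, "Yes", "No")
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

.parse_flag <- function(x, yes, no, field) {
  if (is.logical(x)) return(x)
  x <- trimws(as.character(x))
  out <- rep(NA, length(x))
  out[x %in% c(yes, "TRUE", "True", "true")] <- TRUE
  out[x %in% c(no, "FALSE", "False", "false")] <- FALSE
  if (anyNA(out)) {
    stop_invalid(field, sprintf("expected %s/%s values", yes, no))
  }
  out
}
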