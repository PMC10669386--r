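#' Triangular membership degree
#'
#' Evaluates the piecewise-linear hat function with feet `a`, `c` and
#' peak `b`. Degenerate shoulders (`a == b` or `b == c`) evaluate as
#' one-sided ramps with membership 1 at `b`; membership is 0 outside
#' `[a, c]`. Total on the reals.
#'
#' @param mf numeric triple `c(a, b, c)` with `a <= b <= c`, in the
#'   linguistic variable's units.
#' @param x numeric vector of crisp values.
#' @return membership degrees in `[0, 1]`, same length as `x`.
#' @examples
#' fz_membership(c(0, 50, 100), c(25, 50, 125))  # 0.5, 1, 0
#' @export
fz_membership <- function(mf, x) {
  a <- mf[[1]]; b <- mf[[2]]; c <- mf[[3]]
  if (!(a <= b && b <= c)) stop_invalid("mf", "requires a <= b <= c")
  up <- if (a == b) as.numeric(x >= b) else (x - a) / (b - a)
  dn <- if (b == c) as.numeric(x <= b) else (c - x) / (c - b)
  clamp(pmin(up, dn), 0, 1)
}

#' Linguistic variable with triangular membership functions
#'
#' @param name variable name.
#' @param domain closed interval `c(lo, hi)` in the variable's units.
#' @param mfs named list of `c(a, b, c)` triples, in label order. Labels
#'   must be unique, supports must lie within the domain, and every
#'   point of the domain must have positive membership in at least one
#'   label (coverage).
#' @return object of class `fuzzy_variable`.
#' @export
fuzzy_variable <- function(name, domain, mfs) {
  if (length(domain) != 2 || domain[1] >= domain[2]) {
    stop_invalid("domain", "must be c(lo, hi) with lo < hi")
  }
  if (is.null(names(mfs)) || anyDuplicated(names(mfs))) {
    stop_invalid("mfs", "labels must be unique and named")
  }
  for (lab in names(mfs)) {
    mf <- mfs[[lab]]
    if (length(mf) != 3 || !(mf[1] <= mf[2] && mf[2] <= mf[3])) {
      stop_invalid("mfs", sprintf("label %s is not a valid a <= b <= c triple", lab))
    }
    if (mf[1] < domain[1] - 1e-12 || mf[3] > domain[2] + 1e-12) {
      stop_invalid("mfs", sprintf("support of %s lies outside the domain", lab))
    }
  }
  grid <- seq(domain[1], domain[2], length.out = 501)
  cover <- Reduce(`+`, lapply(mfs, fz_membership, x = grid))
  if (any(cover <= 0)) {
    stop_invalid("mfs", sprintf("domain of %s not fully covered by the MFs", name))
  }
  structure(list(name = name, domain = as.numeric(domain),
                 mfs = lapply(mfs, as.numeric)),
            class = "fuzzy_variable")
}

# evenly spaced triangular partition with touching feet and shoulders
# at the domain ends
.fz_partition <- function(name, domain, labels) {
  peaks <- seq(domain[1], domain[2], length.out = length(labels))
  mfs <- lapply(seq_along(labels), function(i) {
    a <- if (i == 1) peaks[1] else peaks[i - 1]
    c <- if (i == length(labels)) peaks[length(labels)] else peaks[i + 1]
    c(a, peaks[i], c)
  })
  names(mfs) <- labels
  fuzzy_variable(name, domain, mfs)
}

#' Two-input Mamdani fuzzy system
#'
#' Assembles the voltage + CEG-position -> predicted-error-% system:
#' canonical Mamdani operators (AND = min, implication = min clip,
#' aggregation = max, defuzzification = sampled centroid). The rule
#' base must cover every (voltage label, CEG label) combination exactly
#' once; violations raise a configuration error here, not at inference
#' time.
#'
#' @param voltage [fuzzy_variable()] for the sensor voltage input, volts.
#' @param ceg [fuzzy_variable()] for the CEG zone-position input,
#'   dimensionless in `[0, 1]`.
#' @param error [fuzzy_variable()] for the predicted error output, `%`
#'   in `[0, 100]`.
#' @param rules data.frame with character columns `voltage`, `ceg`,
#'   `error` naming antecedent and consequent labels.
#' @param resolution number of evaluation points used to sample the
#'   aggregated output curve for centroid defuzzification.
#' @return object of class `fuzzy_system`.
#' @seealso [default_fuzzy_system()] for the packaged default.
#' @export
fuzzy_system <- function(voltage, ceg, error, rules, resolution = 1001) {
  stopifnot(inherits(voltage, "fuzzy_variable"),
            inherits(ceg, "fuzzy_variable"),
            inherits(error, "fuzzy_variable"))
  need <- c("voltage", "ceg", "error")
  if (!is.data.frame(rules) || !all(need %in% names(rules))) {
    stop_invalid("rules", "must be a data.frame with columns voltage, ceg, error")
  }
  for (col in need) {
    var <- list(voltage = voltage, ceg = ceg, error = error)[[col]]
    bad <- setdiff(rules[[col]], names(var$mfs))
    if (length(bad)) {
      stop_invalid("rules", sprintf("unknown %s label(s): %s",
                                    col, paste(bad, collapse = ", ")))
    }
  }
  combo <- paste(rules$voltage, rules$ceg)
  full <- as.vector(outer(names(voltage$mfs), names(ceg$mfs), paste))
  if (anyDuplicated(combo) || !setequal(combo, full)) {
    stop_invalid("rules",
      "rule base must cover every (voltage, ceg) label pair exactly once")
  }
  check_scalar(resolution, "resolution", lower = 10)
  structure(list(voltage = voltage, ceg = ceg, error = error,
                 rules = rules[, need], resolution = as.integer(resolution)),
            class = "fuzzy_system")
}

#' Default fuzzy system for the glucose error predictor
#'
#' Voltage domain `[1, 4.5]` V spanned by four evenly spaced triangles
#' LoGl, MiGl, MoGl, HiGl (low/mild/moderate/high glucose) with touching
#' feet and shoulders at the domain ends; CEG position `[0, 1]` and
#' error output `[0, 100]` % each spanned by five triangles labeled
#' A-E. The 4 x 5 rule grid maps every voltage label with CEG label Z to
#' error label Z, so the predicted error tracks the CEG zone position at
#' any voltage.
#'
#' @param resolution centroid sampling resolution (default 1001 points).
#' @return a [fuzzy_system()].
#' @examples
#' sys <- default_fuzzy_system()
#' fz_predict_error(sys, voltage = 1.55, severity = 0.05)
#' @export
default_fuzzy_system <- function(resolution = 1001) {
  voltage <- .fz_partition("voltage", c(1, 4.5),
                           c("LoGl", "MiGl", "MoGl", "HiGl"))
  ceg <- .fz_partition("ceg_position", c(0, 1), c("A", "B", "C", "D", "E"))
  error <- .fz_partition("error_percent", c(0, 100), c("A", "B", "C", "D", "E"))
  rules <- expand.grid(voltage = names(voltage$mfs), ceg = names(ceg$mfs),
                       stringsAsFactors = FALSE)
  rules$error <- rules$ceg
  fuzzy_system(voltage, ceg, error, rules, resolution = resolution)
}

#' Fuzzify a crisp value
#'
#' Returns the membership degree of `x` in each label of the variable.
#' Values outside the domain are clamped to its ends; the result then
#' carries attribute `clamped = TRUE` so callers can log it.
#'
#' @param var a [fuzzy_variable()].
#' @param x single crisp value.
#' @return named numeric vector of degrees in `[0, 1]`, one per label.
#' @export
fz_fuzzify <- function(var, x) {
  check_scalar(x, var$name)
  xc <- clamp(x, var$domain[1], var$domain[2])
  out <- vapply(var$mfs, fz_membership, numeric(1), x = xc)
  if (xc != x) attr(out, "clamped") <- TRUE
  out
}

#' Run Mamdani inference
#'
#' For each rule, the activation is the minimum of its antecedent
#' degrees; the consequent MF is clipped at the activation; the
#' aggregate is the pointwise maximum over rules, sampled at the
#' system's resolution over the output domain.
#'
#' @param sys a [fuzzy_system()].
#' @param voltage crisp sensor voltage, volts.
#' @param ceg_position crisp CEG zone position in `[0, 1]`.
#' @return object of class `fuzzy_curve`: list with numeric vectors `x`
#'   (output-domain samples) and `mu` (aggregated membership), plus a
#'   `clamped` flag recording whether an input was out of domain.
#' @export
fz_infer <- function(sys, voltage, ceg_position) {
  dv <- fz_fuzzify(sys$voltage, voltage)
  dc <- fz_fuzzify(sys$ceg, ceg_position)
  x <- seq(sys$error$domain[1], sys$error$domain[2],
           length.out = sys$resolution)
  mu <- numeric(length(x))
  for (i in seq_len(nrow(sys$rules))) {
    act <- min(dv[[sys$rules$voltage[i]]], dc[[sys$rules$ceg[i]]])
    if (act > 0) {
      clipped <- pmin(fz_membership(sys$error$mfs[[sys$rules$error[i]]], x), act)
      mu <- pmax(mu, clipped)
    }
  }
  structure(list(x = x, mu = mu,
                 clamped = isTRUE(attr(dv, "clamped")) ||
                           isTRUE(attr(dc, "clamped"))),
            class = "fuzzy_curve")
}

#' Centroid defuzzification
#'
#' Crisp output as the centre of gravity of the sampled aggregated
#' curve, `sum(x * mu) / sum(mu)`.
#'
#' @param curve a `fuzzy_curve` from [fz_infer()], or any list with
#'   numeric `x` and `mu` of equal length.
#' @return single crisp value within the output domain hull.
#' @export
fz_defuzzify <- function(curve) {
  mu <- curve$mu
  if (length(mu) != length(curve$x)) stop_invalid("curve", "x/mu length mismatch")
  if (all(mu <= 0)) {
    stop("no rule fired: aggregated output curve is identically zero",
         call. = FALSE)
  }
  sum(curve$x * mu) / sum(mu)
}

#' Predict the glucose error tolerance
#'
#' Full fuzzification -> inference -> centroid chain mapping a sensor
#' voltage and a CEG severity to a predicted relative glucose error in
#' percent. Deterministic; vectorized over paired inputs.
#'
#' @param sys a [fuzzy_system()].
#' @param voltage numeric vector of sensor voltages, volts.
#' @param severity numeric vector of CEG severities in `[0, 1]` (see
#'   [ceg_severity()]).
#' @return numeric vector of predicted errors in `[0, 100]` %.
#' @export
fz_predict_error <- function(sys, voltage, severity) {
  n <- max(length(voltage), length(severity))
  voltage <- rep_len(voltage, n)
  severity <- rep_len(severity, n)
  vapply(seq_len(n), function(i) {
    fz_defuzzify(fz_infer(sys, voltage[i], severity[i]))
  }, numeric(1))
}

#' @export
print.fuzzy_system <- function(x, ...) {
  cat("Mamdani fuzzy system (min/min/max, sampled centroid)\n")
  for (v in x[c("voltage", "ceg", "error")]) {
    cat(sprintf("  %s: [%g, %g] with MFs %s\n", v$name,
                v$domain[1], v$domain[2],
                paste(names(v$mfs), collapse = ", ")))
  }
  cat(sprintf("  %d rules, centroid resolution %d\n",
              nrow(x$rules), x$resolution))
  invisible(x)
}

# ---- configuration round-trip ------------------------------------------

.fz_var_to_list <- function(var) {
  list(name = var$name, domain = var$domain, mfs = var$mfs)
}

.fz_var_from_list <- function(lst) {
  fuzzy_variable(lst$name, as.numeric(lst$domain),
                 lapply(lst$mfs, as.numeric))
}

#' Serialize / restore a fuzzy system configuration
#'
#' A system round-trips losslessly through a plain list and through
#' JSON or YAML files: variables as labeled `(a, b, c)` triples, rules
#' as label triples, plus the centroid resolution. Numeric values are
#' written at full double precision so a reload is bit-exact.
#'
#' @param sys a [fuzzy_system()].
#' @param path file path; the extension (`.json`, `.yml`/`.yaml`)
#'   selects the format unless `format` is given.
#' @param format `"json"` or `"yaml"`; default inferred from `path`.
#' @return `write_fuzzy_system()` returns `path` invisibly;
#'   `read_fuzzy_system()` returns the restored [fuzzy_system()].
#' @export
write_fuzzy_system <- function(sys, path, format = NULL) {
  stopifnot(inherits(sys, "fuzzy_system"))
  format <- format %||% (if (grepl("\\.ya?ml$", path)) "yaml" else "json")
  payload <- list(
    variables = lapply(sys[c("voltage", "ceg", "error")], .fz_var_to_list),
    rules = sys$rules,
    resolution = sys$resolution)
  if (format == "yaml") {
    yaml::write_yaml(payload, path, precision = 17)
  } else {
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  }
  invisible(path)
}

#' @rdname write_fuzzy_system
#' @export
read_fuzzy_system <- function(path, format = NULL) {
  format <- format %||% (if (grepl("\\.ya?ml$", path)) "yaml" else "json")
  lst <- if (format == "yaml") yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  rules <- as.data.frame(lst$rules, stringsAsFactors = FALSE)
  fuzzy_system(.fz_var_from_list(lst$variables$voltage),
               .fz_var_from_list(lst$variables$ceg),
               .fz_var_from_list(lst$variables$error),
               rules, resolution = as.numeric(lst$resolution))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
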