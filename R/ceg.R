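#' Clarke Error Grid zone classification
#'
#' Classifies paired glucose readings (reference vs estimate, both mg/dL)
#' into Clarke Error Grid (CEG) zones A-E. Zone A contains clinically
#' accurate estimates (within 20% of the reference, or both readings in
#' the hypoglycaemic band below 70 mg/dL); zone B deviations are benign;
#' zones C, D and E carry increasing clinical risk. The classifier uses
#' the standard Clarke (1987) inequality set, evaluated in the fixed
#' order A, E, C, D with B as the fall-through, so exact boundary points
#' resolve deterministically to the first matching zone.
#'
#' @param reference numeric vector of reference glucose values, mg/dL.
#' @param estimate numeric vector of estimated glucose values, mg/dL.
#'   Recycled against `reference` if one of them has length 1.
#' @return character vector of zone labels, each one of `"A".."E"`.
#' @examples
#' ceg_classify(100, 100)       # identity line -> "A"
#' ceg_classify(110, 116)       # within 20%    -> "A"
#' ceg_classify(60, 200)        # hypo read high -> "E"
#' @export
ceg_classify <- function(reference, estimate) {
  check_glucose(reference, "reference")
  check_glucose(estimate, "estimate")
  if (length(reference) != length(estimate)) {
    if (length(reference) == 1) reference <- rep(reference, length(estimate))
    else if (length(estimate) == 1) estimate <- rep(estimate, length(reference))
    else stop_invalid("estimate", "length mismatch with `reference`")
  }
  .ceg_classify_raw(reference, estimate)
}

# Inequality set evaluated in order A, E, C, D, else B; vectorized,
# no sanity-bound checks (callers validate).
.ceg_classify_raw <- function(ref, est) {
  zone_a <- (est <= 70 & ref <= 70) | (est >= 0.8 * ref & est <= 1.2 * ref)
  zone_e <- (ref >= 180 & est <= 70) | (ref <= 70 & est >= 180)
  zone_c <- (ref >= 70 & ref <= 290 & est >= ref + 110) |
    (ref >= 130 & ref <= 180 & est <= 1.4 * ref - 182)
  zone_d <- (ref >= 240 & est >= 70 & est <= 180) |
    (ref <= 70 & est >= 70 & est <= 180)
  out <- rep("B", length(ref))
  out[zone_d] <- "D"
  out[zone_c] <- "C"
  out[zone_e] <- "E"
  out[zone_a] <- "A"
  out
}

#' Partition of the estimate axis into CEG zone intervals
#'
#' For a fixed reference glucose, partitions the estimate axis
#' `(0, axis_max]` into contiguous labeled intervals whose interior
#' points classify to the interval's zone. Used by the continuous
#' severity score and as a brute-force cross-check of the classifier.
#'
#' @param reference single reference glucose value, mg/dL.
#' @param axis_max upper end of the estimate axis, mg/dL (default 600,
#'   the conventional CEG plotting range).
#' @return data.frame with columns `lower`, `upper`, `zone`; intervals
#'   are ordered, non-overlapping and cover `(0, axis_max]`.
#' @examples
#' ceg_zone_intervals(100)
#' @export
ceg_zone_intervals <- function(reference, axis_max = 600) {
  check_scalar(reference, "reference", lower = 0, strict = TRUE)
  check_scalar(axis_max, "axis_max", lower = 0, strict = TRUE)
  # All zone boundaries on the estimate axis are among these cuts.
  cuts <- c(70, 180, 0.8 * reference, 1.2 * reference,
            reference + 110, 1.4 * reference - 182)
  cuts <- sort(unique(cuts[cuts > 0 & cuts < axis_max]))
  breaks <- c(0, cuts, axis_max)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  labels <- .ceg_classify_raw(rep(reference, length(mids)), mids)
  # merge adjacent runs with equal labels
  keep <- c(TRUE, labels[-1] != labels[-length(labels)])
  lower <- breaks[-length(breaks)][keep]
  upper <- c(lower[-1], axis_max)
  data.frame(lower = lower, upper = upper, zone = labels[keep],
             stringsAsFactors = FALSE)
}

#' Continuous CEG severity (normalized zone position)
#'
#' Maps a glucose pair to a dimensionless score in `[0, 1]` encoding how
#' far the estimate lies from clinical accuracy: 0 on the identity line
#' inside zone A, approaching 1 deep inside zone E. The score is
#' `(z + d) / 5`, where `z` is the zone's ordinal index (A=0 .. E=4) and
#' `d` in `[0, 1)` is the fractional depth of the estimate within its
#' zone's interval on the estimate axis, measured away from the identity
#' line. It is piecewise linear and non-decreasing along any vertical
#' ray moving away from the identity line. This is the second input of
#' the fuzzy error predictor.
#'
#' @inheritParams ceg_classify
#' @param axis_max upper end of the estimate axis used to close the
#'   outermost intervals, mg/dL.
#' @return numeric vector of severities in `[0, 1]`.
#' @examples
#' ceg_severity(100, 100)  # 0
#' ceg_severity(110, 116)  # inside zone A, < 0.2
#' @export
ceg_severity <- function(reference, estimate, axis_max = 600) {
  zones <- ceg_classify(reference, estimate)
  n <- max(length(reference), length(estimate))
  ref <- rep_len(reference, n)
  est <- rep_len(estimate, n)
  vapply(seq_len(n), function(i) {
    .ceg_severity_one(ref[i], est[i], zones[i], axis_max)
  }, numeric(1))
}

.ceg_severity_one <- function(ref, est, zone, axis_max) {
  z <- match(zone, c("A", "B", "C", "D", "E")) - 1L
  iv <- ceg_zone_intervals(ref, axis_max = max(axis_max, est))
  # pick the interval containing est whose label agrees with classify();
  # boundary points may sit on the closed edge of either neighbour
  cand <- which(iv$lower <= est & est <= iv$upper & iv$zone == zone)
  if (length(cand) == 0) cand <- which(iv$lower < est & est <= iv$upper)
  lo <- iv$lower[cand[1]]
  hi <- iv$upper[cand[1]]
  d <- if (lo <= ref && ref <= hi) {
    # zone A interval straddles the identity line: depth from the line
    span <- if (est >= ref) hi - ref else ref - lo
    if (span <= 0) 0 else abs(est - ref) / span
  } else if (lo >= ref) {
    (est - lo) / (hi - lo)   # above the identity line
  } else {
    (hi - est) / (hi - lo)   # below the identity line
  }
  clamp((z + clamp(d, 0, 1)) / 5, 0, 1)
}

#' Zone occupancy report
#'
#' Tabulates CEG zone counts and percentages for a set of glucose pairs,
#' the summary conventionally reported for glucose-meter accuracy
#' (e.g. "97.5% of measurements fell into zone A").
#'
#' @inheritParams ceg_classify
#' @return object of class `ceg_report`: a data.frame with columns
#'   `zone`, `count`, `percent` (one row per zone A-E, percentages
#'   summing to 100) and attribute `n`, the number of pairs.
#' @examples
#' ceg_zone_report(c(100, 60), c(100, 200))
#' @export
ceg_zone_report <- function(reference, estimate) {
  if (length(reference) == 0 || length(estimate) == 0) {
    stop_invalid("reference", "needs at least one pair")
  }
  zones <- ceg_classify(reference, estimate)
  counts <- table(factor(zones, levels = c("A", "B", "C", "D", "E")))
  n <- sum(counts)
  out <- data.frame(zone = names(counts),
                    count = as.integer(counts),
                    percent = 100 * as.integer(counts) / n,
                    stringsAsFactors = FALSE)
  attr(out, "n") <- n
  class(out) <- c("ceg_report", "data.frame")
  out
}

#' @export
print.ceg_report <- function(x, ...) {
  cat(sprintf("Clarke Error Grid report (n = %d pairs)\n", attr(x, "n")))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Write a zone report to CSV or JSON
#'
#' @param report a `ceg_report` from [ceg_zone_report()].
#' @param path output file path.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
ceg_write_report <- function(report, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  } else {
    jsonlite::write_json(
      list(n = attr(report, "n"), zones = as.data.frame(report)),
      path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
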