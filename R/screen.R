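# Plate-screen detection statistics: mass-spectrometry detection calls
# against a negative-control null, and per-enzyme promiscuity summaries.

#' Mass-spectrometry detection threshold from negative controls
#'
#' Computes the detection threshold as `mean(control) + 3 * sd(control)`
#' (sample standard deviation, n-1 denominator): a product is called
#' detectable when its ion-count peak area lies three standard deviations
#' above the negative-control average. Setting `literal_3sd = TRUE` gives
#' the alternative reading `3 * sd(control)` without the mean.
#'
#' @param control_areas Numeric vector of negative-control peak areas
#'   (>= 2 replicates).
#' @param n_sd Number of standard deviations above the control mean.
#' @param literal_3sd Use `n_sd * sd` without adding the control mean.
#' @return Single numeric threshold.
#' @examples
#' ms_detection_threshold(c(8, 10, 12))  # 10 + 3 * 2 = 16
#' @export
ms_detection_threshold <- function(control_areas, n_sd = 3,
                                   literal_3sd = FALSE) {
  stopifnot(is.numeric(control_areas), all(control_areas >= 0))
  if (length(control_areas) < 2L)
    stop("need at least 2 negative-control replicates")
  s <- sd(control_areas)
  if (literal_3sd) n_sd * s else mean(control_areas) + n_sd * s
}

#' Detection call for one plate measurement
#'
#' Precedence: a present UV yield means the product is `quantified`
#' regardless of the MS channel; otherwise the product is `detectable` iff
#' its MS peak area strictly exceeds the threshold; otherwise
#' `not_detected`.
#'
#' @param ms_area Ion-count peak area (>= 0).
#' @param uv_yield UV-quantified yield in percent, or `NA` when below UV
#'   detection.
#' @param threshold Threshold from [ms_detection_threshold()].
#' @return One of `"quantified"`, `"detectable"`, `"not_detected"`.
#' @export
call_detection <- function(ms_area, uv_yield = NA_real_, threshold) {
  stopifnot(is.numeric(ms_area), ms_area >= 0, is.numeric(threshold))
  if (!is.na(uv_yield)) {
    stopifnot(uv_yield >= 0, uv_yield <= 100)
    return("quantified")
  }
  if (ms_area > threshold) "detectable" else "not_detected"
}

#' Detection calls for a tidy plate table
#'
#' Applies [ms_detection_threshold()] per substrate over the control rows
#' and [call_detection()] to every non-control measurement. Control
#' statistics are pooled per substrate (each substrate gets its own
#' background null).
#'
#' @param plate `data.frame` with columns `enzyme`, `substrate`,
#'   `ms_area`, `is_control`, and optionally `uv_yield` (NA = below UV
#'   detection).
#' @param n_sd,literal_3sd Passed to [ms_detection_threshold()].
#' @return `data.frame` with `enzyme`, `substrate`, `call` and
#'   `threshold`.
#' @export
call_plate <- function(plate, n_sd = 3, literal_3sd = FALSE) {
  need <- c("enzyme", "substrate", "ms_area", "is_control")
  missing_cols <- setdiff(need, names(plate))
  if (length(missing_cols) > 0L)
    stop("plate table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (is.null(plate$uv_yield)) plate$uv_yield <- NA_real_
  thresholds <- vapply(split(plate, plate$substrate), function(s) {
    ctrl <- s$ms_area[s$is_control]
    if (length(ctrl) < 2L)
      stop("substrate '", s$substrate[1],
           "': need >= 2 negative-control replicates")
    ms_detection_threshold(ctrl, n_sd = n_sd, literal_3sd = literal_3sd)
  }, numeric(1))
  samples <- plate[!plate$is_control, , drop = FALSE]
  data.frame(
    enzyme = samples$enzyme,
    substrate = samples$substrate,
    call = mapply(call_detection, samples$ms_area, samples$uv_yield,
                  thresholds[samples$substrate]),
    threshold = unname(thresholds[samples$substrate]),
    stringsAsFactors = FALSE)
}

#' Fraction of a substrate panel accepted by an enzyme
#'
#' Substrate promiscuity summary: the percentage of the panel with a
#' `quantified` or `detectable` call. Each substrate may appear at most
#' once per enzyme.
#'
#' @param calls `data.frame` of one enzyme's calls with columns
#'   `substrate` and `call`.
#' @param n_substrates Panel size (>= number of called substrates).
#' @return Percentage in \[0, 100\].
#' @export
promiscuity_fraction <- function(calls, n_substrates) {
  stopifnot(is.data.frame(calls), n_substrates >= 1)
  if (anyDuplicated(calls$substrate))
    stop("duplicated substrate(s): ",
         paste(unique(calls$substrate[duplicated(calls$substrate)]),
               collapse = ", "))
  if (nrow(calls) > n_substrates)
    stop("more calls than substrates in the panel")
  accepted <- sum(calls$call %in% c("quantified", "detectable"))
  100 * accepted / n_substrates
}

#' Per-enzyme promiscuity summary for a plate
#'
#' @param calls Output of [call_plate()].
#' @param n_substrates Panel size; defaults to the number of distinct
#'   substrates in `calls`.
#' @return `data.frame` with `enzyme`, `n_accepted`,
#'   `promiscuity_percent`, sorted by descending promiscuity then enzyme
#'   id.
#' @export
promiscuity_summary <- function(calls, n_substrates = NULL) {
  if (is.null(n_substrates)) n_substrates <- length(unique(calls$substrate))
  out <- do.call(rbind, lapply(split(calls, calls$enzyme), function(s) {
    data.frame(enzyme = s$enzyme[1],
               n_accepted = sum(s$call %in% c("quantified", "detectable")),
               promiscuity_percent = promiscuity_fraction(s, n_substrates),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$promiscuity_percent, out$enzyme), , drop = FALSE]
  rownames(out) <- NULL
  out
}
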