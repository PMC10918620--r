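#' Group delta observations into per-sample series
#'
#' Splits a delta table by sample label and attaches to each series its
#' reference delta. Labels present in `reference` get the literature value;
#' labels without one fall back to the mean-substitution policy: the series'
#' own arithmetic mean delta is used as the reference, which by construction
#' makes the mean deviation exactly zero (such rows still carry useful spread
#' information, and report a trivial zero-mean test).
#'
#' @param deltas an `ssb_deltas` data frame (see [ssb_deltas()]), or any data
#'   frame with columns `label`, `delta_permil`, `prop_se`.
#' @param reference optional reference table from [read_reference_table()] or
#'   [reference_table()]; a data frame with columns `label` and `delta_true`.
#' @return A named list of `ssb_series` objects, one per label in order of
#'   first appearance. Each series is a list with elements `label`, `deltas`
#'   (the observation rows), `reference_delta`, `reference_source`
#'   (`"literature"` or `"sample_mean"`).
#' @export
sample_series <- function(deltas, reference = NULL) {
  stopifnot(is.data.frame(deltas))
  needed <- c("label", "delta_permil", "prop_se")
  if (!all(needed %in% names(deltas)))
    stop("delta table must have columns: ", paste(needed, collapse = ", "))
  labels <- unique(deltas$label)
  ref_map <- NULL
  if (!is.null(reference)) {
    stopifnot(is.data.frame(reference),
              all(c("label", "delta_true") %in% names(reference)))
    ref_map <- stats::setNames(reference$delta_true, reference$label)
  }
  out <- lapply(labels, function(lab) {
    d <- deltas[deltas$label == lab, , drop = FALSE]
    if (!is.null(ref_map) && lab %in% names(ref_map) &&
        is.finite(ref_map[[lab]])) {
      ref <- unname(ref_map[[lab]])
      src <- "literature"
    } else {
      ref <- mean(d$delta_permil)
      src <- "sample_mean"
    }
    structure(
      list(label = lab, deltas = d,
           reference_delta = ref, reference_source = src),
      class = "ssb_series"
    )
  })
  names(out) <- labels
  out
}

#' Construct a single sample series directly
#'
#' Convenience constructor for building an `ssb_series` in code (simulation,
#' tests) without going through a delta table. When `reference_delta` is
#' `NULL` the mean-substitution policy applies.
#'
#' @param label sample label.
#' @param delta_permil numeric vector of measured deltas (per mil).
#' @param prop_se numeric vector of propagated standard errors (per mil);
#'   recycled if length 1.
#' @param reference_delta accepted delta value (per mil) or `NULL`.
#' @param seq_index optional acquisition indices (default `0:(n-1)`).
#' @return An `ssb_series` object.
#' @export
ssb_series <- function(label, delta_permil, prop_se = 0,
                       reference_delta = NULL, seq_index = NULL) {
  n <- length(delta_permil)
  if (n == 0L) stop("a series needs at least one delta observation")
  if (is.null(seq_index)) seq_index <- seq_len(n) - 1L
  d <- data.frame(label = label, seq_index = as.integer(seq_index),
                  delta_permil = as.numeric(delta_permil),
                  prop_se = rep_len(as.numeric(prop_se), n),
                  stringsAsFactors = FALSE)
  if (any(d$prop_se < 0, na.rm = TRUE))
    stop("prop_se must be non-negative")
  structure(
    list(label = label, deltas = d,
         reference_delta = if (is.null(reference_delta)) mean(d$delta_permil)
                           else reference_delta,
         reference_source = if (is.null(reference_delta)) "sample_mean"
                            else "literature"),
    class = "ssb_series"
  )
}

#' Deviations of measured deltas from the reference value
#'
#' For a series of measured deltas and its reference value, the deviation of
#' the i-th measurement is \eqn{\Delta_i = \delta_i - \delta^{true}}. The
#' spread of these deviations is the reproducibility term of the uncertainty
#' budget; its standard deviation uses the n-1 denominator.
#'
#' @param series an `ssb_series` (one element of [sample_series()] output).
#' @return A list of class `ssb_deviations`: `label`, `deviations` (numeric
#'   vector), `prop_se` (matching propagated standard errors), `delta_avg`
#'   (mean measured delta), `deviation_avg`, `sd` (sample SD of the
#'   deviations, `NA` for a single observation), `n`, `reference_delta`,
#'   `reference_source`.
#' @export
deviations <- function(series) {
  stopifnot(inherits(series, "ssb_series"))
  d <- series$deltas
  if (nrow(d) == 0L) stop("series '", series$label, "' has no observations")
  dev <- d$delta_permil - series$reference_delta
  structure(
    list(
      label = series$label,
      deviations = dev,
      prop_se = d$prop_se,
      delta_avg = mean(d$delta_permil),
      deviation_avg = mean(dev),
      sd = if (length(dev) > 1L) stats::sd(dev) else NA_real_,
      n = length(dev),
      reference_delta = series$reference_delta,
      reference_source = series$reference_source
    ),
    class = "ssb_deviations"
  )
}
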