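#' Construct a standard-sample bracketing measurement run
#'
#' An `ssb_run` is an ordered table of acquisitions, one row per measured
#' isotope ratio. Each acquisition records which solution was in the plasma
#' (the bracketing standard or a sample), the mean isotope ratio over the
#' integration cycles, the standard error of that mean, and the cycle count.
#' Row order is acquisition order; `seq_index` makes the ordering explicit
#' and survives subsetting.
#'
#' @param label character vector of sample/standard identifiers.
#' @param role character vector, `"standard"` or `"sample"` (case is
#'   normalized).
#' @param mean_ratio numeric vector of dimensionless isotope ratios
#'   (e.g. 82/78); strictly positive.
#' @param std_error numeric vector of standard errors of `mean_ratio`;
#'   non-negative.
#' @param n_cycles integer vector of integration cycles per acquisition
#'   (default 1).
#' @param seq_index integer vector of acquisition positions; defaults to
#'   `0:(n-1)` in input order. Must be strictly increasing.
#'
#' @return A data frame of class `ssb_run` with columns `label`, `role`,
#'   `seq_index`, `mean_ratio`, `std_error`, `n_cycles`.
#' @seealso [pair_brackets()], [ssb_deltas()], [read_run_table()]
#' @export
#' @examples
#' ssb_run(
#'   label      = c("STD", "SELM-1", "STD"),
#'   role       = c("standard", "sample", "standard"),
#'   mean_ratio = c(0.3670, 0.3675, 0.3672),
#'   std_error  = c(2e-5, 3e-5, 2e-5)
#' )
ssb_run <- function(label, role, mean_ratio, std_error,
                    n_cycles = 1L, seq_index = NULL) {
  n <- length(mean_ratio)
  if (n == 0L) stop("an SSB run must contain at least one acquisition")
  if (is.null(seq_index)) seq_index <- seq_len(n) - 1L
  n_cycles <- rep_len(as.integer(n_cycles), n)
  run <- data.frame(
    label      = as.character(label),
    role       = normalize_role(role),
    seq_index  = as.integer(seq_index),
    mean_ratio = as.numeric(mean_ratio),
    std_error  = as.numeric(std_error),
    n_cycles   = n_cycles,
    stringsAsFactors = FALSE
  )
  validate_ssb_run(run)
}

#' Coerce a data frame to an `ssb_run`
#'
#' @param x a data frame with columns `label`, `role`, `mean_ratio`,
#'   `std_error`, and optionally `n_cycles` and `seq_index`.
#' @return A validated `ssb_run`.
#' @export
as_ssb_run <- function(x) {
  stopifnot(is.data.frame(x))
  needed <- c("label", "role", "mean_ratio", "std_error")
  missing <- setdiff(needed, names(x))
  if (length(missing))
    stop("missing run column(s): ", paste(missing, collapse = ", "))
  ssb_run(
    label      = x$label,
    role       = x$role,
    mean_ratio = x$mean_ratio,
    std_error  = x$std_error,
    n_cycles   = if ("n_cycles" %in% names(x)) x$n_cycles else 1L,
    seq_index  = if ("seq_index" %in% names(x)) x$seq_index else NULL
  )
}

normalize_role <- function(role) {
  r <- tolower(trimws(as.character(role)))
  bad <- !(r %in% c("standard", "sample"))
  if (any(bad))
    stop("invalid role value(s): ", paste(unique(role[bad]), collapse = ", "),
         " (expected 'standard' or 'sample')")
  r
}

validate_ssb_run <- function(run) {
  if (any(!is.finite(run$mean_ratio)) || any(run$mean_ratio <= 0))
    stop("mean_ratio must be finite and strictly positive")
  if (any(!is.finite(run$std_error)) || any(run$std_error < 0))
    stop("std_error must be finite and non-negative")
  if (any(run$n_cycles < 1L))
    stop("n_cycles must be >= 1")
  if (anyNA(run$seq_index) || any(diff(run$seq_index) <= 0L))
    stop("seq_index must be unique and strictly increasing in row order")
  class(run) <- c("ssb_run", "data.frame")
  run
}

#' @export
print.ssb_run <- function(x, ...) {
  cat(sprintf("SSB measurement run: %d acquisitions (%d standard, %d sample)\n",
              nrow(x), sum(x$role == "standard"), sum(x$role == "sample")))
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}
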