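#' Shapiro-Wilk normality check of pooled deviations
#'
#' Thin wrapper around [stats::shapiro.test()] that returns a bare p-value
#' and an explicit not-applicable marker (`NA`) outside the test's validity
#' range (3 <= n <= 5000) or for a degenerate (zero-variance) set, instead
#' of erroring or silently defaulting.
#'
#' @param x numeric vector of deviations (per mil).
#' @return p-value in `[0, 1]`, or `NA_real_` when the test does not apply.
#' @export
test_normality <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3L || n > 5000L) return(NA_real_)
  if (max(x) - min(x) == 0) return(NA_real_)
  stats::shapiro.test(x)$p.value
}

#' One-sample t-test that deviations are centred on zero
#'
#' Two-sided one-sample Student t-test of mean zero. For a series whose
#' reference value was substituted by its own mean, the t statistic is zero
#' by construction and the p-value is 1. Degenerate inputs (n < 2 or zero
#' variance) return the `NA` not-applicable marker.
#'
#' @param x numeric vector of deviations (per mil).
#' @return Two-sided p-value in `[0, 1]`, or `NA_real_` when not applicable.
#' @export
test_zero_mean <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2L || max(x) - min(x) == 0) return(NA_real_)
  stats::t.test(x, mu = 0, alternative = "two.sided")$p.value
}

#' Expanded uncertainty at a given coverage level
#'
#' Half-width of the central coverage interval of a zero-mean normal with
#' the given standard deviation: `U = qnorm((1 + coverage)/2) * sd`. At the
#' default 95% coverage this is the 0.975 normal quantile (1.959964...)
#' times the standard deviation — the bound within which a newly measured
#' delta is expected to fall, relative to the expected value, with 95%
#' confidence.
#'
#' @param sd standard deviation (per mil), non-negative; vectorized.
#' @param coverage coverage probability in (0, 1); default 0.95.
#' @return Expanded uncertainty in the units of `sd`.
#' @export
#' @examples
#' expanded_uncertainty(0.0701)  # ~0.14 per mil
expanded_uncertainty <- function(sd, coverage = 0.95) {
  if (!is.numeric(coverage) || length(coverage) != 1L ||
      !is.finite(coverage) || coverage <= 0 || coverage >= 1)
    stop("coverage must be a single number strictly between 0 and 1")
  if (any(sd < 0, na.rm = TRUE)) stop("sd must be non-negative")
  stats::qnorm((1 + coverage) / 2) * sd
}

#' Monte Carlo standard deviation of deviations under measurement noise
#'
#' The reproducibility standard deviation of the deviations ignores the
#' precision with which each individual delta was measured. This routine
#' propagates that per-delta precision by simulation: in every run each
#' deviation is disturbed by independent zero-mean normal noise with
#' standard deviation equal to that observation's own propagated standard
#' error, the sample SD of the disturbed set is recomputed (per series and
#' pooled over all series), and the reported value is the arithmetic mean of
#' the per-run SDs over all runs.
#'
#' Noise is drawn observation-major within each run from a single seeded
#' generator, so results are reproducible from `(data, runs, seed)` and
#' independent of the chunking used internally. If every propagated standard
#' error is zero the disturbed sets equal the original set in every run and
#' the result equals the plain SD exactly, at any run count.
#'
#' @param series_list list of `ssb_series` objects ([sample_series()]).
#' @param runs number of Monte Carlo runs (default `1e6`).
#' @param seed optional integer seed; when supplied, `set.seed(seed)` is
#'   called so repeated calls are bit-identical.
#' @param chunk_size runs simulated per internal block (memory/speed
#'   trade-off; does not affect the result).
#' @return A list of class `ssb_mc`: `per_series` (named numeric vector of
#'   mean per-run SDs; `NA` for single-observation series), `pooled`
#'   (same, over the concatenated deviations), `runs`, `seed`.
#' @export
monte_carlo_sd <- function(series_list, runs = 1e6, seed = NULL,
                           chunk_size = 2000L) {
  if (inherits(series_list, "ssb_series")) series_list <- list(series_list)
  stopifnot(length(series_list) >= 1L, runs >= 1)
  runs <- as.numeric(runs)

  devs <- lapply(series_list, deviations)
  dev <- unlist(lapply(devs, `[[`, "deviations"), use.names = FALSE)
  se  <- unlist(lapply(devs, `[[`, "prop_se"), use.names = FALSE)
  grp <- rep(seq_along(devs), vapply(devs, `[[`, 0L, "n"))
  labels <- vapply(devs, `[[`, "", "label")
  n <- length(dev)

  if (anyNA(se)) {
    bad <- which(is.na(se))[1L]
    obs <- do.call(rbind, lapply(series_list, `[[`, "deltas"))
    stop(sprintf("missing propagated standard error for observation '%s' (seq_index %s)",
                 obs$label[bad], obs$seq_index[bad]))
  }

  base_per <- vapply(devs, `[[`, 0, "sd")
  base_pool <- if (n > 1L) stats::sd(dev) else NA_real_

  # exact algebraic shortcut: zero noise leaves every run identical
  if (all(se == 0)) {
    return(structure(list(per_series = stats::setNames(base_per, labels),
                          pooled = base_pool, runs = runs, seed = seed),
                     class = "ssb_mc"))
  }

  if (!is.null(seed)) set.seed(seed)
  rows <- split(seq_len(n), grp)
  n_per <- vapply(devs, `[[`, 0L, "n")
  # per-run SDs are stored, then averaged in one pass, so the result is
  # exactly independent of the internal chunking
  sd_pool <- numeric(runs)
  sd_per <- lapply(seq_along(devs), function(g) numeric(runs))
  done <- 0
  col_sd <- function(X) {
    m <- ncol(X)
    k <- nrow(X)
    if (k < 2L) return(rep(NA_real_, m))
    cm <- .colMeans(X, k, m)
    sqrt(.colSums((X - rep(cm, each = k))^2, k, m) / (k - 1))
  }
  while (done < runs) {
    m <- as.integer(min(chunk_size, runs - done))
    slice <- seq.int(done + 1L, done + m)
    X <- dev + matrix(stats::rnorm(n * m), n, m) * se
    sd_pool[slice] <- col_sd(X)
    for (g in seq_along(rows)) {
      if (n_per[g] > 1L)
        sd_per[[g]][slice] <- col_sd(X[rows[[g]], , drop = FALSE])
    }
    done <- done + m
  }
  per <- vapply(seq_along(devs), function(g)
    if (n_per[g] > 1L) sum(sd_per[[g]]) / runs else NA_real_, 0)
  structure(list(per_series = stats::setNames(per, labels),
                 pooled = if (n > 1L) sum(sd_pool) / runs else NA_real_,
                 runs = runs, seed = seed),
            class = "ssb_mc")
}

#' Build the per-sample and joint uncertainty report
#'
#' Assembles, for every sample series and for all series pooled ("jointly"),
#' the deviation statistics, validation tests, and the two tiers of expanded
#' uncertainty: the classical reproducibility-based `U` and the Monte
#' Carlo `U` that additionally carries each delta's own propagated standard
#' error. Each row is flagged by which uncertainty component dominates:
#' when `sd_delta_mc / sd_delta` exceeds `ratio_threshold` the per-delta
#' measurement precision (not reproducibility) drives the final uncertainty.
#'
#' @param x an `ssb_deltas` table, or a list of `ssb_series`.
#' @param reference optional reference table (ignored when `x` is already a
#'   series list).
#' @param runs Monte Carlo runs (default `1e6`).
#' @param seed optional integer seed for the Monte Carlo draws.
#' @param coverage coverage probability for the expanded uncertainties.
#' @param ratio_threshold dominance flag threshold on `sd_delta_mc/sd_delta`
#'   (default 1.5).
#' @param chunk_size passed to [monte_carlo_sd()].
#' @return An object of class `ssb_report`: a list with `table` (one row per
#'   sample plus a final `"jointly"` row; columns `label`,
#'   `reference_delta`, `reference_source`, `n`, `delta_avg`,
#'   `deviation_avg`, `sd_delta`, `sd_delta_mc`, `u`, `u_mc`, `shapiro_p`,
#'   `ttest_p`, `dominance`), plus `runs`, `seed`, `coverage`,
#'   `ratio_threshold`. The joint row pools the concatenated deviations of
#'   all samples; its `n` is the sum of the per-sample `n`.
#' @export
build_report <- function(x, reference = NULL, runs = 1e6, seed = NULL,
                         coverage = 0.95, ratio_threshold = 1.5,
                         chunk_size = 2000L) {
  series_list <- if (is.data.frame(x)) sample_series(x, reference) else x
  stopifnot(is.list(series_list), length(series_list) >= 1L)
  labels <- vapply(series_list, `[[`, "", "label")
  if (anyDuplicated(labels))
    stop("duplicate sample label(s): ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))

  devs <- lapply(series_list, deviations)
  mc <- monte_carlo_sd(series_list, runs = runs, seed = seed,
                       chunk_size = chunk_size)

  pooled_dev <- unlist(lapply(devs, `[[`, "deviations"), use.names = FALSE)
  row_of <- function(lab, ref, src, dv, sd_mc) {
    data.frame(
      label = lab,
      reference_delta = ref,
      reference_source = src,
      n = length(dv$dev),
      delta_avg = dv$delta_avg,
      deviation_avg = mean(dv$dev),
      sd_delta = dv$sd,
      sd_delta_mc = sd_mc,
      u = expanded_uncertainty(dv$sd, coverage),
      u_mc = expanded_uncertainty(sd_mc, coverage),
      shapiro_p = test_normality(dv$dev),
      ttest_p = test_zero_mean(dv$dev),
      stringsAsFactors = FALSE
    )
  }
  per_rows <- lapply(seq_along(devs), function(i) {
    d <- devs[[i]]
    row_of(d$label, d$reference_delta, d$reference_source,
           list(dev = d$deviations, delta_avg = d$delta_avg, sd = d$sd),
           mc$per_series[[i]])
  })
  joint <- row_of("jointly", NA_real_, NA_character_,
                  list(dev = pooled_dev, delta_avg = NA_real_,
                       sd = if (length(pooled_dev) > 1L) stats::sd(pooled_dev)
                            else NA_real_),
                  mc$pooled)
  tab <- do.call(rbind, c(per_rows, list(joint)))
  ratio <- tab$sd_delta_mc / tab$sd_delta
  tab$dominance <- ifelse(is.finite(ratio) & ratio >= ratio_threshold |
                            (!is.na(ratio) & is.infinite(ratio)),
                          "measurement-precision-dominated",
                          "reproducibility-dominated")
  rownames(tab) <- NULL
  structure(list(table = tab, runs = mc$runs, seed = seed,
                 coverage = coverage, ratio_threshold = ratio_threshold),
            class = "ssb_report")
}

#' @export
print.ssb_report <- function(x, ...) {
  cat(sprintf(
    "SSB uncertainty report (%d samples; MC runs = %s, seed = %s, coverage = %g%%)\n\n",
    nrow(x$table) - 1L, format(x$runs, big.mark = ","),
    if (is.null(x$seed)) "none" else x$seed, 100 * x$coverage))
  t <- x$table
  disp <- data.frame(
    label = t$label,
    delta_true = ifelse(is.na(t$reference_delta) |
                          t$reference_source %in% "sample_mean", "n.d.",
                        sprintf("%.2f", t$reference_delta)),
    delta_avg = ifelse(is.na(t$delta_avg), "", sprintf("%.2f", t$delta_avg)),
    dev_avg = sprintf("%.2f", t$deviation_avg),
    sd = sprintf("%.2f", t$sd_delta),
    sd_mc = sprintf("%.2f", t$sd_delta_mc),
    u = sprintf("%.2f", t$u),
    u_mc = sprintf("%.2f", t$u_mc),
    shapiro_p = ifelse(is.na(t$shapiro_p), "n/a", sprintf("%.4f", t$shapiro_p)),
    ttest_p = ifelse(is.na(t$ttest_p), "n/a", sprintf("%.4f", t$ttest_p)),
    n = t$n,
    stringsAsFactors = FALSE
  )
  print(disp, row.names = FALSE)
  invisible(x)
}
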