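#' Pair a run into standard-sample-standard triplets
#'
#' Walks the acquisition sequence and assigns to every sample acquisition its
#' nearest preceding and following standard acquisitions. One standard
#' acquisition may close one bracket and open the next (the usual alternating
#' SSB scheme), so adjacent samples share a bracketing standard. Two
#' consecutive standards with no sample between them are permitted: the later
#' one simply starts the next bracket. Two consecutive samples with no
#' standard between them are rejected — the bracketing scheme is strictly
#' standard-sample-standard.
#'
#' @param run an [ssb_run()].
#' @return A data frame of class `ssb_brackets`, one row per sample
#'   acquisition, with the sample `label` and `seq_index`, the row indices
#'   `i_b1`, `i_s`, `i_b2` into `run`, and the six values entering the delta:
#'   `mu_b1`, `mu_s`, `mu_b2`, `se_b1`, `se_s`, `se_b2`.
#' @export
#' @examples
#' run <- ssb_run(c("STD", "A", "STD", "B", "STD"),
#'                c("standard", "sample", "standard", "sample", "standard"),
#'                c(0.3670, 0.3675, 0.3672, 0.3668, 0.3671),
#'                rep(2e-5, 5))
#' pair_brackets(run)  # two triplets sharing the middle standard
pair_brackets <- function(run) {
  if (!inherits(run, "ssb_run")) run <- as_ssb_run(run)
  is_std <- run$role == "standard"
  i_smp <- which(!is_std)
  if (length(i_smp) == 0L)
    stop("run contains no sample acquisitions")
  i_std <- which(is_std)

  first_smp <- i_smp[1L]
  last_smp <- i_smp[length(i_smp)]
  if (first_smp < min(i_std))
    stop(sprintf("unbracketed sample at seq_index %d: no standard precedes it",
                 run$seq_index[first_smp]))
  if (last_smp > max(i_std))
    stop(sprintf("unbracketed sample at seq_index %d: no standard follows it",
                 run$seq_index[last_smp]))
  if (length(i_smp) > 1L) {
    gap_has_std <- vapply(seq_len(length(i_smp) - 1L), function(k) {
      any(i_std > i_smp[k] & i_std < i_smp[k + 1L])
    }, logical(1L))
    if (any(!gap_has_std)) {
      k <- which(!gap_has_std)[1L]
      stop(sprintf(
        "consecutive samples at seq_index %d and %d share no bracketing standard",
        run$seq_index[i_smp[k]], run$seq_index[i_smp[k + 1L]]))
    }
  }

  # nearest standard on each side; findInterval gives the last std before s
  pos_b1 <- i_std[findInterval(i_smp, i_std)]
  pos_b2 <- i_std[findInterval(i_smp, i_std) + 1L]

  br <- data.frame(
    label     = run$label[i_smp],
    seq_index = run$seq_index[i_smp],
    i_b1 = pos_b1, i_s = i_smp, i_b2 = pos_b2,
    mu_b1 = run$mean_ratio[pos_b1],
    mu_s  = run$mean_ratio[i_smp],
    mu_b2 = run$mean_ratio[pos_b2],
    se_b1 = run$std_error[pos_b1],
    se_s  = run$std_error[i_smp],
    se_b2 = run$std_error[pos_b2],
    stringsAsFactors = FALSE
  )
  class(br) <- c("ssb_brackets", "data.frame")
  br
}

#' Bracketing delta value in per mil
#'
#' The sample's isotope ratio relative to the arithmetic mean of the two
#' bracketing standard ratios, expressed as a deviation in parts per
#' thousand:
#' \deqn{\delta = \left(\frac{\mu_s}{(\mu_{b1}+\mu_{b2})/2} - 1\right)
#'   \times 1000\ \text{‰}}
#' Because the instrumental mass-bias factor multiplies all three ratios, it
#' cancels exactly: `compute_delta` is invariant under scaling all three
#' ratios by any positive constant.
#'
#' @param mu_s,mu_b1,mu_b2 numeric vectors of the sample and bracketing
#'   standard mean ratios; strictly positive.
#' @return Numeric vector of delta values in per mil.
#' @export
#' @examples
#' compute_delta(0.3675, 0.3670, 0.3672)
#' compute_delta(1.0010, 1, 1)  # exactly 1 per mil
compute_delta <- function(mu_s, mu_b1, mu_b2) {
  if (any(c(mu_s, mu_b1, mu_b2) <= 0, na.rm = TRUE))
    stop("all isotope ratios must be strictly positive")
  (mu_s / ((mu_b1 + mu_b2) / 2) - 1) * 1000
}

#' Propagated standard error of a bracketing delta
#'
#' First-order (Taylor / differentiation) propagation of the three
#' acquisition standard errors into a standard error for the delta. With
#' \eqn{B = (\mu_{b1}+\mu_{b2})/2},
#' \deqn{SD_\delta = \frac{1000}{B}\sqrt{\sigma_s^2 +
#'   \frac{\mu_s^2}{4B^2}\left(\sigma_{b1}^2 + \sigma_{b2}^2\right)}}
#' in per mil. The expression is symmetric in the two brackets and scales
#' linearly when all three standard errors are scaled by a common factor.
#' First-order propagation is accurate here because acquisition standard
#' errors are tiny relative to the ratios (relative SE well below 1e-2).
#'
#' @param mu_s,mu_b1,mu_b2 mean isotope ratios (strictly positive).
#' @param se_s,se_b1,se_b2 their standard errors (non-negative).
#' @return Numeric vector: the propagated standard error of the delta, in
#'   per mil. Zero exactly when all three standard errors are zero.
#' @export
propagate_se <- function(mu_s, mu_b1, mu_b2, se_s, se_b1, se_b2) {
  if (any(c(mu_s, mu_b1, mu_b2) <= 0, na.rm = TRUE))
    stop("all isotope ratios must be strictly positive")
  if (any(c(se_s, se_b1, se_b2) < 0, na.rm = TRUE))
    stop("standard errors must be non-negative")
  B <- (mu_b1 + mu_b2) / 2
  1000 / B * sqrt(se_s^2 + mu_s^2 / (4 * B^2) * (se_b1^2 + se_b2^2))
}

#' Delta table for a measurement run
#'
#' Runs the full bracketing computation: pairs the run into triplets, then
#' computes each sample delta and its propagated standard error.
#'
#' @param x an [ssb_run()] or the `ssb_brackets` output of
#'   [pair_brackets()].
#' @return A data frame of class `ssb_deltas` with columns `label`,
#'   `seq_index` (of the sample acquisition), `delta_permil`, `prop_se`.
#' @export
#' @examples
#' run <- ssb_run(c("STD", "A", "STD"), c("standard", "sample", "standard"),
#'                c(0.3670, 0.3675, 0.3672), c(2e-5, 3e-5, 2e-5))
#' ssb_deltas(run)
ssb_deltas <- function(x) {
  br <- if (inherits(x, "ssb_brackets")) x else pair_brackets(x)
  out <- data.frame(
    label        = br$label,
    seq_index    = br$seq_index,
    delta_permil = compute_delta(br$mu_s, br$mu_b1, br$mu_b2),
    prop_se      = propagate_se(br$mu_s, br$mu_b1, br$mu_b2,
                                br$se_s, br$se_b1, br$se_b2),
    stringsAsFactors = FALSE
  )
  class(out) <- c("ssb_deltas", "data.frame")
  out
}
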