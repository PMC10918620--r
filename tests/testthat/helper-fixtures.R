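# Fixture builders shared across test files. Everything is generated in
# code; no data files.

# minimal alternating run: standards at even positions, samples at odd
make_run <- function(ratios, roles = NULL, ses = NULL, labels = NULL) {
  n <- length(ratios)
  if (is.null(roles))
    roles <- ifelse(seq_len(n) %% 2L == 1L, "standard", "sample")
  if (is.null(ses)) ses <- rep(2e-5, n)
  if (is.null(labels))
    labels <- ifelse(roles == "standard", "STD", "SMP")
  ssb_run(labels, roles, ratios, ses)
}

# random admissible bracketing triplet: ratios of realistic magnitude with
# small relative standard errors (first-order propagation regime)
random_triplet <- function() {
  mu <- stats::runif(3, 0.1, 2)
  rsd <- stats::runif(3, 1e-5, 1e-3)
  list(mu_s = mu[1], mu_b1 = mu[2], mu_b2 = mu[3],
       se_s = mu[1] * rsd[1], se_b1 = mu[2] * rsd[2], se_b2 = mu[3] * rsd[3])
}

# brute-force sampling oracle for the propagated standard error: draw the
# three ratios from their normals, evaluate the delta formula on each draw,
# return the empirical SD (independent of the closed-form derivative path)
mc_se_oracle <- function(tr, draws = 1e6) {
  s <- stats::rnorm(draws, tr$mu_s, tr$se_s)
  b1 <- stats::rnorm(draws, tr$mu_b1, tr$se_b1)
  b2 <- stats::rnorm(draws, tr$mu_b2, tr$se_b2)
  stats::sd((s / ((b1 + b2) / 2) - 1) * 1000)
}

# central-finite-difference gradient of the delta formula combined in
# quadrature with the three standard errors
fd_se_oracle <- function(tr, h_rel = 1e-6) {
  f <- function(s, b1, b2) (s / ((b1 + b2) / 2) - 1) * 1000
  g <- function(which) {
    h <- h_rel * tr[[which]]
    up <- tr; up[[which]] <- tr[[which]] + h
    dn <- tr; dn[[which]] <- tr[[which]] - h
    (f(up$mu_s, up$mu_b1, up$mu_b2) - f(dn$mu_s, dn$mu_b1, dn$mu_b2)) / (2 * h)
  }
  sqrt((g("mu_s") * tr$se_s)^2 + (g("mu_b1") * tr$se_b1)^2 +
         (g("mu_b2") * tr$se_b2)^2)
}

# per-sample observation counts of a typical multi-sample reference campaign
# (eight materials, 185 deltas in total)
campaign_counts <- function() {
  c("NIST-3149" = 54L, "ASW" = 15L, "NASS-4" = 7L, "SELM-1" = 53L,
    "BC210a" = 13L, "SGR-1" = 25L, "SCo-1" = 9L, "MAG-1" = 9L)
}

# synthetic multi-sample series list with given per-sample counts
make_campaign <- function(counts = campaign_counts(), sd = 0.07,
                          prop_se = 0.08, seed = 1) {
  set.seed(seed)
  lapply(names(counts), function(lab) {
    ssb_series(lab, stats::rnorm(counts[[lab]], 0, sd), prop_se,
               reference_delta = 0)
  })
}
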