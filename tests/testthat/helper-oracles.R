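# Independent oracles and small fixture builders used across the suite.

# Mann-Whitney U by direct pair counting (independent of the rank formula)
brute_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) {
    u <- u + (xi > yj) + 0.5 * (xi == yj)
  }
  u
}

# exact two-tailed Mann-Whitney P by full enumeration of label assignments,
# using the pair-counting U
brute_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  idx <- utils::combn(n, length(x))
  u_obs <- brute_u(x, y)
  u_all <- apply(idx, 2, function(ii) brute_u(pooled[ii], pooled[-ii]))
  min(1, 2 * min(mean(u_all <= u_obs + 1e-9), mean(u_all >= u_obs - 1e-9)))
}

# a spectrum containing Gaussian peaks on an optional linear ramp
gaussian_spectrum <- function(mz = seq(1000, 3000, by = 1), centers = 2000,
                              heights = 100, sigmas = 1, ramp = c(0, 0),
                              noise_sd = 0, seed = NULL,
                              sample_id = "fixture") {
  if (!is.null(seed)) set.seed(seed)
  y <- ramp[1] + ramp[2] * (mz - mz[1])
  for (i in seq_along(centers)) {
    y <- y + heights[i] * exp(-(mz - centers[i])^2 / (2 * sigmas[i]^2))
  }
  if (noise_sd > 0) y <- y + rnorm(length(mz), 0, noise_sd)
  spectrum(mz, y, sample_id = sample_id)
}

# a small peak matrix with planted class effects and null columns:
# effect columns follow the discovery-cohort group means with the
# AUC-calibrated log-normal spread, null columns share one mean in both
# classes
planted_matrix <- function(n_case = 100, n_control = 100, n_null = 12,
                           seed = 1) {
  set.seed(seed)
  eff <- data.frame(
    mz = c(1895.3, 1944.0, 2020.9, 2080.7, 2104.5,
           2656.8, 3154.9, 3238.5, 3875.9, 4042.8),
    mean_case = c(2664.8, 858.5, 3328.8, 295.8, 132.8,
                  565.6, 145.8, 1015.9, 349.7, 271.5),
    mean_control = c(374.7, 3103.8, 320.5, 1187.9, 544.7,
                     704.3, 1566.3, 451.2, 557.3, 940.5),
    auc = c(0.838, 0.906, 0.746, 0.896, 0.906,
            0.673, 0.980, 0.623, 0.733, 0.859))
  labels <- rep(c("case", "control"), c(n_case, n_control))
  n <- n_case + n_control
  draw <- function(mu, sdlog) rlnorm(length(mu), log(mu) - sdlog^2 / 2, sdlog)
  X_eff <- sapply(seq_len(nrow(eff)), function(j) {
    # log-sd such that the two-class AUC matches the planted value
    sdlog <- abs(log(eff$mean_case[j] / eff$mean_control[j])) /
      (sqrt(2) * qnorm(eff$auc[j]))
    draw(ifelse(labels == "case", eff$mean_case[j], eff$mean_control[j]),
         sdlog)
  })
  null_mz <- seq(5000, by = 100, length.out = n_null)
  X_null <- sapply(seq_len(n_null), function(j)
    draw(rep(800, n), sqrt(log1p(0.8^2))))
  X <- cbind(X_eff, X_null)
  mzs <- c(eff$mz, null_mz)
  colnames(X) <- sprintf("%.1f", mzs)
  peaks <- data.frame(mz_ref = mzs, n_present = n, presence_frac = 1,
                      effect = rep(c(TRUE, FALSE), c(nrow(eff), n_null)))
  pepdiag:::new_peak_matrix(X, sprintf("s%03d", seq_len(n)), labels, peaks,
                            cohort_id = "planted")
}
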