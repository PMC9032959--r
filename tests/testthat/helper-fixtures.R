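# shared fixtures: small, fast study configurations built in code

quiet_cfg <- function(...) {
  defaults <- list(n_participants = 1L, n_voxels = 60L, n_runs = 4L,
                   n_timepoints = 60L, noise_sd = 0.3, seed = 42L)
  over <- list(...)
  do.call(study_config, utils::modifyList(defaults, over))
}

noiseless_cfg <- function(...) quiet_cfg(noise_sd = 0, ...)

# baseline/block drive pair under the default spread model
default_drives <- function(cfg = quiet_cfg()) {
  S <- build_spread(cfg$spread_lambda)
  list(baseline = peripheral_drives(S, "baseline"),
       block = peripheral_drives(S, "block", cfg$blocked_finger,
                                 cfg$block_fraction))
}

# noiseless cluster-mean activity table for a session
noiseless_activity <- function(cfg, session = "baseline",
                               drives = default_drives(cfg)[[session]]) {
  tm <- generate_tuning_map(cfg)
  pat <- generate_session_patterns(tm, session, cfg, drives)
  cluster_activity(pat$mean_patterns, true_cluster_map(tm))
}

# random 5-unit model with spectral radius < 1
random_stable_model <- function() {
  repeat {
    L <- matrix(stats::runif(25, -0.2, 0.2), 5, 5)
    if (max(Mod(eigen(L, only.values = TRUE)$values)) < 0.95) break
  }
  cortical_model(W = matrix(stats::rnorm(25), 5, 5),
                 b = stats::rnorm(1),
                 alpha = stats::runif(5, 0.5, 1.5), L = L)
}

# direct (loop-based) cross-nobis oracle: run-pair sum evaluated literally
crossnobis_direct <- function(runs, i, j) {
  V <- ncol(runs[[1]])
  pairs <- utils::combn(length(runs), 2)
  acc <- 0
  for (p in seq_len(ncol(pairs))) {
    A <- runs[[pairs[1, p]]]; B <- runs[[pairs[2, p]]]
    acc <- acc + sum((A[i, ] - A[j, ]) * (B[i, ] - B[j, ])) / V
  }
  acc / ncol(pairs)
}
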