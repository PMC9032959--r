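test_that("tuning maps are topographic, deterministic and degenerate correctly", {
  cfg <- quiet_cfg()
  tm1 <- generate_tuning_map(cfg)
  tm2 <- generate_tuning_map(cfg)
  expect_identical(tm1, tm2)

  # each voxel's maximal weight sits on its true cluster's finger
  mx <- apply(tm1$tuning_weights, 1, which.max)
  expect_equal(cluster_labels()[mx], as.character(tm1$true_cluster_label))
  expect_equal(unname(apply(tm1$tuning_weights, 1, max)),
               rep(1, cfg$n_voxels))
  # preferred fingers are ordered along the axis (positions are sorted)
  expect_false(is.unsorted(as.integer(tm1$true_cluster_label)))

  # zero tuning width: indicator tuning
  tm0 <- generate_tuning_map(quiet_cfg(tuning_width = 0))
  expect_true(all(tm0$tuning_weights %in% c(0, 1)))
  expect_equal(unname(rowSums(tm0$tuning_weights)), rep(1, cfg$n_voxels))

  # neighbouring fingers' tuning columns correlate more than non-neighbours
  W <- tm1$tuning_weights
  cc <- cor(W)
  neigh <- mean(cc[cbind(1:4, 2:5)])
  nonneigh <- mean(cc[abs(outer(1:5, 1:5, "-")) >= 2])
  expect_gt(neigh, nonneigh)

  expect_error(study_config(n_voxels = 0), "configuration error")
})

test_that("session patterns follow the generator equations", {
  cfg <- noiseless_cfg()
  drv <- default_drives(cfg)
  tm <- generate_tuning_map(cfg)

  pat <- generate_session_patterns(tm, "baseline", cfg, drv$baseline)
  # zero noise: every run equals the noiseless mean
  for (b in pat$betas) expect_equal(b, pat$mean_patterns)
  # the mean pattern is exactly tuning %*% drive
  expect_equal(pat$mean_patterns,
               t(tm$tuning_weights %*% as.matrix(drv$baseline)),
               ignore_attr = TRUE)

  # block session: D2-stimulation activity over C2 voxels strictly lower
  blk <- generate_session_patterns(tm, "block", cfg, drv$block)
  c2 <- tm$true_cluster_label == "C2"
  expect_lt(mean(blk$mean_patterns["D2", c2]),
            mean(pat$mean_patterns["D2", c2]))
  # gains: blocked cluster scaled by gain_blocked, others by gain_global
  raw <- t(tm$tuning_weights %*% as.matrix(drv$block))
  expect_equal(blk$mean_patterns[, c2], cfg$gain_blocked * raw[, c2])
  expect_equal(blk$mean_patterns[, !c2], cfg$gain_global * raw[, !c2])

  expect_error(generate_session_patterns(tm, "baseline", cfg,
                                         as.matrix(drv$baseline)[, 1:3]),
               "shape error")
})

test_that("winner-takes-all on noiseless baseline patterns recovers truth", {
  cfg <- noiseless_cfg()
  tm <- generate_tuning_map(cfg)
  pat <- generate_session_patterns(tm, "baseline", cfg,
                                   default_drives(cfg)$baseline)
  winner <- apply(pat$mean_patterns, 2, which.max)
  expect_equal(cluster_labels()[winner],
               as.character(tm$true_cluster_label))
})

test_that("pattern correlations decay with finger distance", {
  cfg <- noiseless_cfg()
  tm <- generate_tuning_map(cfg)
  P <- generate_session_patterns(tm, "baseline", cfg,
                                 default_drives(cfg)$baseline)$mean_patterns
  cc <- cor(t(P))
  expect_gt(cc["D2", "D3"], cc["D2", "D5"])
  expect_gt(cc["D1", "D2"], cc["D1", "D4"])
})

test_that("residual noise matches the configured covariance", {
  cfg <- quiet_cfg(n_voxels = 8L, n_timepoints = 20000L, noise_sd = 1,
                   n_runs = 1L)
  tm <- generate_tuning_map(cfg)
  pat <- generate_session_patterns(tm, "baseline", cfg,
                                   default_drives(cfg)$baseline)
  S <- cov(pat$residuals[[1]])
  expect_lt(max(abs(S - diag(8))), 0.06)
  expect_lt(max(abs(colMeans(pat$residuals[[1]]))), 0.05)

  # a non-identity covariance is respected too
  R <- 0.5 ^ abs(outer(1:8, 1:8, "-"))
  cfgR <- quiet_cfg(n_voxels = 8L, n_timepoints = 20000L, noise_sd = 1,
                    n_runs = 1L, residual_cov = R)
  patR <- generate_session_patterns(generate_tuning_map(cfgR), "baseline",
                                    cfgR, default_drives(cfgR)$baseline)
  expect_lt(max(abs(cov(patR$residuals[[1]]) - R)), 0.08)
})

test_that("traveling-wave runs have the configured structure", {
  cfg <- noiseless_cfg()
  tm <- generate_tuning_map(cfg)
  fw <- generate_wave_run(tm, cfg, "forward")
  # run length = n_cycles * cycle / tr
  expect_equal(nrow(fw), cfg$n_cycles * 5 * cfg$on_seconds /
                           cfg$tr_seconds)
  # forward and backward schedules are finger-order reversals
  bw <- generate_wave_run(tm, cfg, "backward")
  sf <- attr(fw, "schedule"); sb <- attr(bw, "schedule")
  expect_equal(sb$finger[1:5], rev(sf$finger[1:5]))
  expect_equal(sb$onset, sf$onset)

  # a voxel tuned only to D1 carries the HRF-convolved D1 boxcar
  cfg1 <- noiseless_cfg(tuning_width = 0, n_voxels = 40L)
  tm1 <- generate_tuning_map(cfg1)
  v <- which(tm1$true_cluster_label == "C1")[1]
  run <- generate_wave_run(tm1, cfg1, "forward")
  n_time <- nrow(run)
  times <- (seq_len(n_time) - 1) * cfg1$tr_seconds
  box <- as.numeric(times %% (5 * cfg1$on_seconds) < cfg1$on_seconds)
  ref <- somatomap:::convolve_hrf_circular(
    box, double_gamma_hrf(cfg1$tr_seconds))
  expect_equal(cor(run[, v], ref), 1, tolerance = 1e-12)
})

test_that("psychophysics trials follow the generating Weibull curve", {
  tt <- generate_psychophys_trials(1.5, 2, n_per_width = 10L, seed = 7)
  expect_identical(tt, generate_psychophys_trials(1.5, 2,
                                                  n_per_width = 10L,
                                                  seed = 7))
  expect_true(all(tt$correct %in% 0:1))
  expect_setequal(unique(tt$grating_width_mm), c(0.5, 1, 1.5, 2.5, 3.5))

  # forced certainty: a threshold far below every width pins the success
  # probability at 1, so all trials come out correct
  sure <- generate_psychophys_trials(1e-6, 1, n_per_width = 50L, seed = 1)
  expect_true(all(sure$correct == 1))

  # large n: empirical accuracy within 3 binomial SE of the curve
  big <- generate_psychophys_trials(1.5, 2, n_per_width = 10000L, seed = 3)
  gen <- attr(big, "generating")
  acc <- tapply(big$correct, big$grating_width_mm, mean)
  p <- weibull_psy(as.numeric(names(acc)), gen$scale, gen$slope)
  se <- sqrt(p * (1 - p) / 10000)
  expect_true(all(abs(acc - p) <= 3 * se))

  expect_error(generate_psychophys_trials(-1, 2), "domain error")
})

test_that("the whole synthetic study is bit-identical under one seed", {
  cfg <- quiet_cfg(n_voxels = 40L, n_timepoints = 30L)
  s1 <- run_pipeline(cfg)
  s2 <- run_pipeline(cfg)
  expect_identical(s1$participants[[1]]$sessions$baseline$patterns$betas,
                   s2$participants[[1]]$sessions$baseline$patterns$betas)
  expect_identical(s1$gains$gain_global, s2$gains$gain_global)
  expect_identical(s1$participants[[1]]$rdm_change$pct_change_all,
                   s2$participants[[1]]$rdm_change$pct_change_all)
})
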