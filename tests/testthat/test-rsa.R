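test_that("noise whitener inverts the regularized covariance", {
  set.seed(21)
  # white residuals: whitener close to identity
  R <- matrix(rnorm(4000 * 6), 4000, 6)
  wh <- noise_whitener(R)
  expect_lt(max(abs(wh$transform - diag(6))), 0.1)
  expect_equal(t(wh$transform) %*% wh$transform, solve(wh$sigma),
               tolerance = 1e-8)

  # 2-voxel toy with known covariance: hand 2x2 matrix algebra
  S2 <- matrix(c(2, 0.8, 0.8, 1), 2, 2)
  X <- MASS::mvrnorm(5000, c(0, 0), S2)
  wh2 <- noise_whitener(X, shrinkage = 0.1)
  Semp <- crossprod(scale(X, scale = FALSE)) / (nrow(X) - 1)
  Sreg <- 0.9 * Semp + 0.1 * diag(diag(Semp))
  expect_equal(t(wh2$transform) %*% wh2$transform, solve(Sreg),
               tolerance = 1e-8)

  # whitened residuals have near-identity sample covariance
  Xw <- X %*% wh2$transform
  expect_lt(max(abs(cov(Xw) - diag(2))), 0.15)
})

test_that("cross-nobis distances match hand and brute-force oracles", {
  # identical patterns in all runs: exactly zero
  runs <- replicate(3, matrix(rnorm(10), 2, 5,
                              dimnames = list(c("D1", "D2"), NULL)),
                    simplify = FALSE)
  runs <- lapply(runs, function(x) { x[2, ] <- x[1, ]; x })
  r0 <- crossnobis_rdm(runs, include_rest = FALSE)
  expect_equal(unname(r0["D1", "D2"]), 0)

  # 2 runs, 2 voxels, identity whitener, difference (1,0) in both runs
  a <- matrix(c(1, 0, 0, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("D1", "D2"), NULL))
  r1 <- crossnobis_rdm(list(a, a), include_rest = FALSE)
  expect_equal(unname(r1["D1", "D2"]), 0.5)

  # brute-force run-pair summation on random toys, to 1e-12
  set.seed(31)
  for (i in 1:20) {
    n_runs <- sample(2:3, 1); nv <- sample(2:4, 1)
    runs <- replicate(n_runs,
                      matrix(rnorm(5 * nv), 5, nv,
                             dimnames = list(finger_labels(), NULL)),
                      simplify = FALSE)
    rr <- crossnobis_rdm(runs, include_rest = FALSE)
    for (j in 1:4) for (k in (j + 1):5)
      expect_equal(unname(rr[j, k]), crossnobis_direct(runs, j, k),
                   tolerance = 1e-12)
  }

  # scaling all patterns by s scales distances by s^2
  runs <- replicate(4, matrix(rnorm(15), 5, 3,
                              dimnames = list(finger_labels(), NULL)),
                    simplify = FALSE)
  r_1 <- crossnobis_rdm(runs, include_rest = TRUE)
  r_s <- crossnobis_rdm(lapply(runs, `*`, 3), include_rest = TRUE)
  expect_equal(unclass(r_s), 9 * unclass(r_1), ignore_attr = TRUE)

  expect_error(crossnobis_rdm(runs[1]), "cross-validation impossible")
})

test_that("cross-nobis is unbiased under equal condition means", {
  set.seed(41)
  d <- replicate(400, {
    mu <- rnorm(20)
    runs <- replicate(4, rbind(D1 = mu + rnorm(20), D2 = mu + rnorm(20)),
                      simplify = FALSE)
    crossnobis_rdm(runs, include_rest = FALSE)["D1", "D2"]
  })
  expect_lt(abs(mean(d)), 3 * sd(d) / sqrt(length(d)))
})

test_that("MDS reproduces planar geometry and Procrustes is rigid", {
  set.seed(51)
  pts <- matrix(rnorm(12), 6, 2,
                dimnames = list(c(finger_labels(), "rest"), NULL))
  D2 <- as.matrix(dist(pts))^2          # rdm on the squared-distance scale
  r <- new_rdm(D2, "euclidean")
  g <- mds_group(list(r, r))
  expect_equal(as.matrix(dist(g$mean_points)), as.matrix(dist(pts)),
               tolerance = 1e-8, ignore_attr = TRUE)

  # two configurations differing by a pure rotation align with ~0 disparity
  th <- 0.7
  Rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  pts2 <- pts %*% Rot
  r2 <- new_rdm(as.matrix(dist(pts2))^2, "euclidean")
  g2 <- mds_group(list(r, r2))
  expect_lt(g2$disparity[2], 1e-8)
  # alignment preserves each participant's inter-point distances exactly
  expect_equal(as.matrix(dist(g2$points[[2]])), as.matrix(dist(pts2)),
               tolerance = 1e-8, ignore_attr = TRUE)

  bad <- matrix(1:36, 6, 6)
  expect_error(new_rdm(bad), "validation error")
})

test_that("session-change summaries have the stated arithmetic", {
  set.seed(61)
  pts <- matrix(rnorm(12), 6, 2,
                dimnames = list(c(finger_labels(), "rest"), NULL))
  base <- new_rdm(as.matrix(dist(pts))^2, "euclidean")
  # identical sessions: zero change everywhere, perfect rank correlation
  ch0 <- rdm_session_change(base, base)
  expect_equal(ch0$pct_change_all, 0)
  expect_equal(ch0$pct_change_nonblocked, 0)
  expect_equal(ch0$spearman_canonical, 1)
  expect_lte(ch0$perm_p, 1 / 60)  # at the resolution of 120 relabelings

  # uniform shrink by 0.71: -29% everywhere, structure preserved
  blk <- new_rdm(0.71 * unclass(base), "euclidean")
  ch <- rdm_session_change(base, blk)
  expect_equal(ch$pct_change_all, -29)
  expect_equal(ch$pct_change_nonblocked, -29)
  expect_equal(ch$pct_change_neighbors, -29)
  expect_equal(ch$spearman_canonical, 1)

  expect_error(rdm_session_change(base,
                                  new_rdm(unclass(base)[1:5, 1:5])),
               "validation error")
})
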