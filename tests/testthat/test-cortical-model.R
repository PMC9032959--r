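test_that("settlement matches the closed-form fixed point", {
  # L = 0, unit gains: one step to W p + b
  m0 <- cortical_model(W = diag(5), b = 0.5, L = matrix(0, 5, 5))
  p <- c(1, 0, 0, 0, 0)
  r0 <- settle(m0, p)
  expect_equal(unname(r0$activity[, 1]), p + 0.5)
  expect_equal(r0$iterations, 1L)

  # 2-unit coupled toy embedded in the 5-unit model: hand-solved 2x2 system
  L2 <- matrix(0, 5, 5); L2[1, 2] <- L2[2, 1] <- 0.5
  m2 <- cortical_model(W = diag(5), b = 0, L = L2)
  expect_equal(unname(fixed_point(m2, p)[, 1]), c(4 / 3, 2 / 3, 0, 0, 0),
               tolerance = 1e-12)

  # oracle equivalence on random stable models
  set.seed(71)
  for (i in 1:30) {
    m <- random_stable_model()
    pr <- matrix(runif(5), 5, 1)
    s <- settle(m, pr, tol = 1e-10, max_iter = 10000)
    expect_equal(s$activity, fixed_point(m, pr), tolerance = 1e-7)
  }

  # linearity: with b = 0, scaling p scales the response
  mb <- cortical_model(W = matrix(rnorm(25), 5, 5), b = 0)
  expect_equal(fixed_point(mb, 3 * p), 3 * fixed_point(mb, p))

  # non-convergence carries the last state
  mslow <- cortical_model(W = diag(5), b = 0,
                          L = diag(0.99, 5))
  err <- tryCatch(settle(mslow, p, tol = 1e-12, max_iter = 3),
                  error = identity)
  expect_match(conditionMessage(err), "non-convergence")
  expect_length(attr(err, "last_state"), 5)

  # spectral radius >= 1 rejected at construction
  expect_error(cortical_model(W = diag(5), L = diag(1.1, 5)),
               "divergence error")
})

test_that("gain placement scales only the feedforward term", {
  set.seed(72)
  W <- matrix(rnorm(25), 5, 5)
  p <- runif(5)
  m <- cortical_model(W, b = 0, alpha = c(2, 1, 1, 1, 1),
                      L = lateral_kernel())
  m1 <- cortical_model(W, b = 0, L = lateral_kernel())
  # (I - L) c = diag(alpha) W p: doubling alpha_1 doubles row 1 of the
  # feedforward drive, not the lateral contribution
  lhs <- (diag(5) - lateral_kernel()) %*% fixed_point(m, p)
  rhs <- c(2, 1, 1, 1, 1) * as.numeric(W %*% p)
  expect_equal(as.numeric(lhs), rhs, tolerance = 1e-10)

  # the config switch moves the gain onto the whole right-hand side
  ms <- cortical_model(W, b = 0.3, alpha = c(2, 1, 1, 1, 1),
                       L = lateral_kernel(), gain_scales_lateral = TRUE)
  cs <- fixed_point(ms, p)
  resid <- cs - c(2, 1, 1, 1, 1) *
    (as.numeric(W %*% p) + 0.3 + lateral_kernel() %*% cs)
  expect_lt(max(abs(resid)), 1e-10)
})

test_that("baseline fitting recovers generating weights and targets", {
  set.seed(73)
  drives <- peripheral_drives(build_spread())
  W_true <- matrix(rnorm(25, sd = 0.5), 5, 5)
  gen <- cortical_model(W_true, b = 0, L = lateral_kernel())
  target <- fixed_point(gen, drives)  # cluster x condition

  fit <- fit_cortical_model(t(target), drives)
  expect_equal(unname(fit$W), unname(W_true), tolerance = 1e-8)
  # settled responses reproduce the training targets elementwise
  expect_lt(max(abs(fit$fitted - target)), 1e-8)
  expect_lt(max(abs(predict(fit, tol = 1e-12, max_iter = 10000) - target)),
            1e-6)

  # closed-form regression equals iterative refinement
  fit_it <- fit_cortical_model(t(target), drives, method = "iterative")
  expect_equal(fit_it$W, fit$W, tolerance = 1e-6)

  # rank-deficient drives are rejected
  bad <- unclass(drives); bad[, 2] <- bad[, 1]
  expect_error(fit_cortical_model(t(target), bad), "identifiability error")
})

test_that("the fitted baseline model settles quickly on real drives", {
  cfg <- noiseless_cfg()
  act <- noiseless_activity(cfg)
  drives <- default_drives(cfg)$baseline
  m <- fit_cortical_model(act, drives)
  resp <- settle(m, drives, tol = 1e-3)
  expect_true(all(resp$iterations <= 6))
  expect_lt(max(abs(resp$activity - fixed_point(m, drives))), 10 * 1e-3)
})

test_that("static block prediction collapses the blocked representation", {
  cfg <- noiseless_cfg()
  act <- noiseless_activity(cfg)
  drv <- default_drives(cfg)
  m <- fit_cortical_model(act, drv$baseline)

  # fraction 1: identical to baseline responses
  same <- predict_static_block(m, drv$baseline)
  expect_equal(same$response$activity, fixed_point(m, drv$baseline),
               tolerance = 1e-5)

  pred <- predict_static_block(m, drv$block)
  base_resp <- settle(m, drv$baseline)
  # D2-stimulation response of unit 2 drops under the block
  expect_lt(pred$response$activity["C2", "D2"],
            base_resp$activity["C2", "D2"])
  # D2's distance-from-rest shrinks more (proportionally) than any
  # non-blocked finger's
  rdm_b <- model_rdm(base_resp, include_rest = TRUE)
  rel <- unclass(pred$rdm)[finger_labels(), "rest"] /
    unclass(rdm_b)[finger_labels(), "rest"]
  expect_lt(rel["D2"], min(rel[c("D1", "D3", "D4", "D5")]))

  expect_error(predict_static_block(
    cortical_model(diag(5), alpha = rep(0.9, 5)), drv$block),
    "baseline gains")
})

test_that("two-parameter gain fit recovers generating gains", {
  cfg <- noiseless_cfg()
  act <- noiseless_activity(cfg)
  drv <- default_drives(cfg)
  m <- fit_cortical_model(act, drv$baseline)

  # no change to explain: gains (1, 1)
  gf0 <- fit_gains(m, drv$baseline, t(fixed_point(m, drv$baseline)))
  expect_equal(gf0$gain_global, 1, tolerance = 1e-6)
  expect_equal(gf0$gain_blocked, 1, tolerance = 1e-6)

  # targets generated with the homeostatic gain configuration
  mt <- m; mt$alpha <- c(0.75, 1.25, 0.75, 0.75, 0.75)
  target <- fixed_point(mt, drv$block)
  gf <- fit_gains(m, drv$block, t(target))
  expect_equal(gf$gain_global, 0.75, tolerance = 1e-3)
  expect_equal(gf$gain_blocked, 1.25, tolerance = 1e-3)
  # the optimum beats every coarse-grid cell
  expect_lte(gf$sse, min(gf$grid))
})

test_that("model RDMs are Euclidean metrics over responses", {
  A <- cbind(a = c(1, 0, 0, 0, 0), b = c(0, 1, 0, 0, 0))
  r <- model_rdm(A)
  expect_equal(unname(r["a", "b"]), sqrt(2))
  expect_equal(unname(diag(r)), rep(0, 2))
  expect_equal(unclass(r), t(unclass(r)), ignore_attr = TRUE)
  # coincident responses: all-zero distances
  expect_true(all(model_rdm(cbind(A[, 1], A[, 1])) == 0))
  # rest appears as the zero response
  rr <- model_rdm(A, include_rest = TRUE)
  expect_equal(unname(rr["a", "rest"]), 1)
})

test_that("homeostatic gains reproduce shrink-without-reshape; static fails", {
  cfg <- noiseless_cfg()
  act <- noiseless_activity(cfg)
  drv <- default_drives(cfg)
  m <- fit_cortical_model(act, drv$baseline)
  rdm_base <- model_rdm(settle(m, drv$baseline), include_rest = TRUE)

  mh <- m; mh$alpha <- c(0.75, 1.25, 0.75, 0.75, 0.75)
  rdm_homeo <- model_rdm(settle(mh, drv$block), include_rest = TRUE)
  ch <- rdm_session_change(rdm_base, rdm_homeo)
  expect_lt(ch$pct_change_all, 0)          # representation shrinks
  expect_lte(ch$perm_p, 0.05)              # but keeps its shape
  # D2's rest distance does not collapse disproportionately: relative to
  # the other fingers, D2 stands higher under homeostatic gains than under
  # the static model, which singles D2 out for collapse
  rel <- unclass(rdm_homeo)[finger_labels(), "rest"] /
    unclass(rdm_base)[finger_labels(), "rest"]
  rel_static <- unclass(predict_static_block(m, drv$block)$rdm)[
    finger_labels(), "rest"] / unclass(rdm_base)[finger_labels(), "rest"]
  expect_gt(rel["D2"] / mean(rel[-2]),
            rel_static["D2"] / mean(rel_static[-2]))
  # the static model barely moves the non-blocked fingers at all
  expect_lt(max(abs(1 - rel_static[-2])), max(abs(1 - rel[-2])) + 0.2)
  expect_equal(unname(which.min(rel_static)), 2L)
})
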