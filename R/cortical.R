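#' Distance-dependent lateral connection matrix
#'
#' Lateral connectivity between the five cortical finger clusters depends on
#' inter-cluster distance alone, so every cluster carries the same
#' connection profile, shifted spatially. The default profile implements
#' short-range excitation and long-range inhibition, a canonical choice in
#' cortical map modelling; the self-connection is zero (recurrence within a
#' cluster is absorbed into the feedforward weight).
#'
#' @param weights numeric vector \code{k(0) .. k(4)}: connection strength at
#'   inter-cluster distances 0 to 4.
#' @return a 5 x 5 matrix \code{L} with \code{L[i, j] = weights[|i - j| + 1]}.
#' @export
#' @examples
#' L <- lateral_kernel()
#' L[1, 2]  # nearest-neighbour excitation
lateral_kernel <- function(weights = c(0, 0.15, -0.05, -0.10, -0.10)) {
  stopifnot(length(weights) == 5)
  d <- abs(outer(1:5, 1:5, "-"))
  L <- matrix(weights[d + 1], 5, 5,
              dimnames = list(cluster_labels(), cluster_labels()))
  L
}

spectral_radius <- function(L) max(Mod(eigen(L, only.values = TRUE)$values))

#' Construct a five-unit recurrent cortical model
#'
#' The model describes the settled activity of five cortical finger clusters
#' under pooled peripheral input. At each time step the activity of cluster
#' \eqn{i} is
#' \deqn{c_i(t) = \alpha_i w_i^T p + b + l_i^T c(t-1)}
#' where \eqn{\alpha_i} is a per-cluster gain, \eqn{w_i} the feedforward
#' weights from the five fingers, \eqn{p} the vector of pooled peripheral
#' drives, \eqn{b} a scalar offset and \eqn{l_i} the lateral connection
#' profile. The gain scales only the feedforward term; lateral input and
#' offset are unscaled. A baseline model has all gains equal to 1.
#'
#' @param W 5 x 5 feedforward weight matrix (row \eqn{i} = cluster \eqn{i}'s
#'   connection strengths from the five fingers).
#' @param b scalar offset.
#' @param alpha 5-vector of per-cluster gains.
#' @param L 5 x 5 lateral connection matrix; must have spectral radius < 1
#'   for the dynamics to settle.
#' @param gain_scales_lateral if \code{TRUE}, the gain multiplies the whole
#'   right-hand side (including lateral input and offset) instead of the
#'   feedforward term only. Off by default: the update equation above is
#'   followed literally.
#' @return an object of class \code{"cortical_model"}.
#' @seealso [settle()], [fixed_point()], [fit_cortical_model()],
#'   [fit_gains()]
#' @export
cortical_model <- function(W, b = 0, alpha = rep(1, 5),
                           L = lateral_kernel(),
                           gain_scales_lateral = FALSE) {
  W <- as.matrix(W)
  stopifnot(all(dim(W) == c(5, 5)), length(alpha) == 5,
            length(b) == 1, all(dim(L) == c(5, 5)))
  rho <- spectral_radius(if (gain_scales_lateral) diag(alpha) %*% L else L)
  if (rho >= 1)
    stop("divergence error: lateral matrix has spectral radius ",
         signif(rho, 4), " >= 1; the dynamics would not settle")
  dimnames(W) <- list(cluster = cluster_labels(), finger = finger_labels())
  m <- list(W = W, b = b, alpha = as.numeric(alpha), L = L,
            gain_scales_lateral = gain_scales_lateral,
            spectral_radius = rho)
  class(m) <- "cortical_model"
  m
}

## effective per-step drive and recurrence for one condition
.model_terms <- function(model, p) {
  p <- as.numeric(p)
  stopifnot(length(p) == 5)
  ff <- model$alpha * as.numeric(model$W %*% p)
  if (model$gain_scales_lateral) {
    list(drive = model$alpha * (as.numeric(model$W %*% p) + model$b),
         A = diag(model$alpha) %*% model$L)
  } else {
    list(drive = ff + model$b, A = model$L)
  }
}

.as_drive_matrix <- function(drives) {
  if (is.matrix(drives)) {
    D <- matrix(as.numeric(drives), nrow(drives), ncol(drives))
    stopifnot(nrow(D) == 5)
  } else {
    D <- matrix(as.numeric(drives), 5, 1)
  }
  if (is.null(colnames(drives)) || is.null(dim(drives)))
    colnames(D) <- paste0("cond", seq_len(ncol(D)))
  else colnames(D) <- colnames(drives)
  rownames(D) <- finger_labels()
  D
}

#' Settle the recurrent dynamics under peripheral input
#'
#' Iterates the cortical update equation from \code{c(0) = 0} until the
#' maximum absolute change between successive states drops below \code{tol},
#' for every stimulation condition in \code{drives}. With the default fitted
#' lateral kernel the dynamics typically settle within six time steps.
#'
#' @param model a [cortical_model()].
#' @param drives a 5-vector (one condition) or a finger x condition matrix
#'   such as [peripheral_drives()].
#' @param tol convergence tolerance on the max-norm change.
#' @param max_iter iteration cap; exceeding it raises a non-convergence
#'   error carrying the last state in \code{attr(cnd, "last_state")}.
#' @return an object of class \code{"cortical_response"}: list with
#'   \code{activity} (cluster x condition matrix of settled states),
#'   \code{iterations} (per condition), \code{converged} (logical).
#' @export
settle <- function(model, drives, tol = 1e-6, max_iter = 100L) {
  stopifnot(inherits(model, "cortical_model"), tol > 0)
  D <- .as_drive_matrix(drives)
  act <- matrix(NA_real_, 5, ncol(D),
                dimnames = list(cluster = cluster_labels(),
                                condition = colnames(D)))
  iters <- integer(ncol(D)); conv <- logical(ncol(D))
  for (j in seq_len(ncol(D))) {
    tm <- .model_terms(model, D[, j])
    c_prev <- rep(0, 5)
    ok <- FALSE
    for (it in seq_len(max_iter)) {
      c_new <- tm$drive + as.numeric(tm$A %*% c_prev)
      if (max(abs(c_new - c_prev)) < tol) { ok <- TRUE; c_prev <- c_new; break }
      c_prev <- c_new
    }
    if (!ok) {
      cnd <- simpleError(paste0("non-convergence: settlement did not reach tol ",
                                tol, " within ", max_iter, " iterations"))
      attr(cnd, "last_state") <- c_prev
      stop(cnd)
    }
    ## the state had settled at the previous step: the detecting update
    ## changed it by less than tol (so L = 0 settles in one step)
    act[, j] <- c_prev; iters[j] <- it - 1L; conv[j] <- ok
  }
  structure(list(activity = act, iterations = iters, converged = conv,
                 tol = tol),
            class = "cortical_response")
}

#' Closed-form fixed point of the cortical dynamics
#'
#' At convergence the update equation rearranges to the linear system
#' \eqn{(I - L) c = \mathrm{diag}(\alpha) W p + b\,1}, solved directly. This
#' is the analytic oracle for [settle()].
#'
#' @inheritParams settle
#' @return cluster x condition matrix of fixed-point activities.
#' @export
fixed_point <- function(model, drives) {
  stopifnot(inherits(model, "cortical_model"))
  D <- .as_drive_matrix(drives)
  out <- matrix(NA_real_, 5, ncol(D),
                dimnames = list(cluster = cluster_labels(),
                                condition = colnames(D)))
  for (j in seq_len(ncol(D))) {
    tm <- .model_terms(model, D[, j])
    out[, j] <- solve(diag(5) - tm$A, tm$drive)
  }
  out
}

#' Fit the baseline cortical model to observed cluster activity
#'
#' Feedforward weights and offset are fitted so that the settled model
#' responses reproduce the observed baseline activity of the five clusters
#' under the five single-finger stimulation conditions, with all gains fixed
#' at 1. The weights are first estimated by multiple regression of the
#' target activities on the drives (ignoring lateral input), then refined so
#' that the settled activity after the lateral updates matches the targets:
#' either in closed form, by regressing the \eqn{(I - L)}-transformed targets
#' on the drives, or by damped iterative adjustment of the weights based on
#' the settled activity (both converge to the same solution; the closed form
#' is the analytic oracle for the iteration).
#'
#' The offset \code{b} is not identifiable jointly with \code{W} from the
#' settled activities (any offset can be absorbed into the weights), mirroring
#' the fact that models differing only in the assumed rest state cannot be
#' distinguished; it is therefore fixed by argument, default 0.
#'
#' @param target observed baseline activity: a finger x cluster
#'   \code{activity_table} from [cluster_activity()], or a cluster x
#'   condition matrix (set \code{target_layout = "cluster_by_condition"}).
#' @param drives baseline [peripheral_drives()] (finger x condition); must
#'   be full rank.
#' @param L lateral connection matrix.
#' @param b fixed scalar offset.
#' @param method \code{"closed_form"} or \code{"iterative"} refinement.
#' @param target_layout orientation of \code{target}.
#' @param tol,max_iter iterative-refinement controls.
#' @return a fitted [cortical_model()] with components \code{fitted}
#'   (settled responses) and \code{target} attached.
#' @export
fit_cortical_model <- function(target, drives,
                               L = lateral_kernel(), b = 0,
                               method = c("closed_form", "iterative"),
                               target_layout = c("finger_by_cluster",
                                                 "cluster_by_condition"),
                               tol = 1e-10, max_iter = 500L) {
  method <- match.arg(method)
  target_layout <- match.arg(target_layout)
  Ct <- as.matrix(target)
  if (target_layout == "finger_by_cluster") Ct <- t(Ct)  # -> cluster x cond
  stopifnot(all(dim(Ct) == c(5, 5)))
  P <- .as_drive_matrix(drives)
  if (qr(P)$rank < 5)
    stop("identifiability error: drive matrix is rank-deficient")
  ones <- matrix(1, 5, ncol(P))
  ## stage 1: multiple regression of targets on drives, no lateral term
  W0 <- t(solve(t(P) %*% P, t(P) %*% t(Ct - b * ones)))
  if (method == "closed_form") {
    ## at the fixed point (I - L) C = W P + b 11', so W solves a regression
    ## of the transformed targets on the drives
    M <- (diag(5) - L) %*% Ct - b * ones
    W <- t(solve(t(P) %*% P, t(P) %*% t(M)))
  } else {
    ## damped update driven by the settled-activity error
    W <- W0
    Pinv <- solve(P)
    eta <- 0.5
    for (it in seq_len(max_iter)) {
      Cm <- fixed_point(cortical_model(W, b = b, L = L), P)
      E <- Ct - Cm
      if (max(abs(E)) < tol) break
      W <- W + eta * ((diag(5) - L) %*% E) %*% Pinv
    }
  }
  m <- cortical_model(W, b = b, alpha = rep(1, 5), L = L)
  m$fitted <- fixed_point(m, P)
  dimnames(m$fitted) <- dimnames(Ct) <- list(cluster = cluster_labels(),
                                             condition = colnames(P))
  m$target <- Ct
  m$drives <- P
  m$method <- method
  m
}

#' Predict block-session responses without cortical change (static model)
#'
#' Settles the baseline-fitted model on the blocked peripheral drives with
#' every cortical parameter unchanged — the hypothesis that the cortex does
#' not react to input loss — and returns the predicted responses together
#' with their Euclidean representational dissimilarity matrix.
#'
#' @param model a baseline-fitted [cortical_model()] (all gains 1).
#' @param blocked_drives [peripheral_drives()] for the block session.
#' @param include_rest include rest (the zero response) as a sixth condition
#'   in the RDM.
#' @param ... passed to [settle()].
#' @return list with \code{response} (a \code{cortical_response}) and
#'   \code{rdm} (an [rdm] object, Euclidean estimator).
#' @export
predict_static_block <- function(model, blocked_drives, include_rest = TRUE,
                                 ...) {
  stopifnot(inherits(model, "cortical_model"))
  if (max(abs(model$alpha - 1)) > 1e-12)
    stop("static-block prediction requires baseline gains (all 1)")
  resp <- settle(model, blocked_drives, ...)
  list(response = resp,
       rdm = model_rdm(resp, include_rest = include_rest))
}

#' Fit homeostatic gain changes to block-session activity
#'
#' Tests whether homeostatic gain changes can account for the observed
#' block-session activity: the gain vector is constrained to two free
#' parameters — one shared gain for all non-blocked clusters and one gain
#' for the blocked finger's cluster (which replaces, not multiplies, the
#' shared gain) — and fitted by least squares between the settled responses
#' under the blocked drives and the target activity. The optimiser is a
#' coarse grid search over \code{grid} x \code{grid} followed by Nelder-Mead
#' refinement from the best cell.
#'
#' @param model a baseline-fitted [cortical_model()].
#' @param blocked_drives block-session [peripheral_drives()].
#' @param target observed block-session activity (same layouts as
#'   [fit_cortical_model()]).
#' @param blocked_finger which finger's cluster receives its own gain.
#' @param grid numeric vector of candidate gain values for the coarse grid.
#' @param target_layout orientation of \code{target}.
#' @return an object of class \code{"gain_fit"}: list with
#'   \code{gain_global}, \code{gain_blocked}, \code{sse}, the refitted
#'   \code{model}, and the evaluated \code{grid} (a matrix of SSE values).
#' @export
fit_gains <- function(model, blocked_drives, target,
                      blocked_finger = "D2",
                      grid = seq(0.25, 2, by = 0.05),
                      target_layout = c("finger_by_cluster",
                                        "cluster_by_condition")) {
  stopifnot(inherits(model, "cortical_model"))
  target_layout <- match.arg(target_layout)
  Ct <- as.matrix(target)
  if (target_layout == "finger_by_cluster") Ct <- t(Ct)
  stopifnot(all(dim(Ct) == c(5, 5)))
  P <- .as_drive_matrix(blocked_drives)
  bi <- match(blocked_finger, finger_labels())
  if (is.na(bi)) stop("domain error: unknown finger label '",
                      blocked_finger, "'")
  sse <- function(g) {
    alpha <- rep(g[1], 5); alpha[bi] <- g[2]
    m <- model; m$alpha <- alpha
    resp <- tryCatch(settle(m, P, tol = 1e-9, max_iter = 1000L),
                     error = function(e) {
                       warning("candidate gains (", signif(g[1], 3), ", ",
                               signif(g[2], 3),
                               ") discarded: settlement did not converge")
                       NULL
                     })
    if (is.null(resp)) return(Inf)
    sum((resp$activity - Ct)^2)
  }
  G <- outer(grid, grid, Vectorize(function(a, b) sse(c(a, b))))
  dimnames(G) <- list(gain_global = grid, gain_blocked = grid)
  best <- arrayInd(which.min(G), dim(G))
  start <- c(grid[best[1]], grid[best[2]])
  opt <- stats::optim(start, sse, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  m <- model; m$alpha <- rep(opt$par[1], 5); m$alpha[bi] <- opt$par[2]
  out <- list(gain_global = opt$par[1], gain_blocked = opt$par[2],
              sse = opt$value, model = m, grid = G,
              blocked_finger = blocked_finger)
  class(out) <- "gain_fit"
  out
}

#' @export
print.gain_fit <- function(x, digits = 4, ...) {
  cat("Homeostatic gain fit (blocked finger:", x$blocked_finger, ")\n")
  cat("  shared gain  :", signif(x$gain_global, digits), "\n")
  cat("  blocked gain :", signif(x$gain_blocked, digits), "\n")
  cat("  residual SSE :", format(x$sse, digits = digits), "\n")
  invisible(x)
}

#' Euclidean RDM of modelled cortical responses
#'
#' Pairwise Euclidean distances between the settled five-unit response
#' vectors of each stimulation condition, optionally including rest as the
#' all-zero response.
#'
#' @param responses a \code{cortical_response} from [settle()] or a cluster
#'   x condition activity matrix.
#' @param include_rest add rest (zero response) as an extra condition.
#' @return an [rdm] object with estimator \code{"euclidean"}.
#' @export
model_rdm <- function(responses, include_rest = FALSE) {
  A <- if (inherits(responses, "cortical_response")) responses$activity
       else as.matrix(responses)
  if (ncol(A) < 2) stop("model_rdm needs at least 2 conditions")
  if (include_rest) A <- cbind(A, rest = 0)
  D <- as.matrix(stats::dist(t(A)))
  new_rdm(D, estimator = "euclidean")
}

#' @export
print.cortical_model <- function(x, digits = 3, ...) {
  cat("Five-unit recurrent cortical model\n")
  cat("  gains alpha :", paste(signif(x$alpha, digits), collapse = " "), "\n")
  cat("  offset b    :", signif(x$b, digits), "\n")
  cat("  lateral spectral radius:", signif(x$spectral_radius, digits), "\n")
  cat("  feedforward weights W (cluster x finger):\n")
  print(round(x$W, digits))
  if (!is.null(x$fitted))
    cat("  fitted to baseline activity (", x$method, " refinement)\n",
        sep = "")
  invisible(x)
}

#' @export
summary.cortical_model <- function(object, ...) {
  out <- list(model = object)
  if (!is.null(object$fitted)) {
    r <- object$target - object$fitted
    out$train_rmse <- sqrt(mean(r^2))
    out$residuals <- r
  }
  class(out) <- "summary.cortical_model"
  out
}

#' @export
print.summary.cortical_model <- function(x, ...) {
  print(x$model)
  if (!is.null(x$train_rmse))
    cat("  training RMSE:", format(x$train_rmse, digits = 4), "\n")
  invisible(x)
}

#' @export
coef.cortical_model <- function(object, ...) {
  list(W = object$W, b = object$b, alpha = object$alpha, L = object$L)
}

#' Settled responses for new peripheral drives
#'
#' @param object a [cortical_model()].
#' @param drives finger x condition drive matrix; defaults to the training
#'   drives when the model was fitted.
#' @param ... passed to [settle()].
#' @return cluster x condition matrix of settled activities.
#' @export
predict.cortical_model <- function(object, drives = NULL, ...) {
  if (is.null(drives)) drives <- object$drives
  if (is.null(drives)) stop("drives must be supplied for an unfitted model")
  settle(object, drives, ...)$activity
}

#' Simulate noisy activity tables from a cortical model
#'
#' Draws \code{nsim} cluster x condition activity matrices: the settled
#' responses plus i.i.d. Gaussian observation noise.
#'
#' @param object a [cortical_model()].
#' @param nsim number of simulated tables.
#' @param seed integer seed.
#' @param drives finger x condition drive matrix (defaults to the training
#'   drives).
#' @param noise_sd observation noise standard deviation.
#' @param ... ignored.
#' @return list of \code{nsim} cluster x condition matrices.
#' @export
simulate.cortical_model <- function(object, nsim = 1, seed = NULL,
                                    drives = NULL, noise_sd = 0.1, ...) {
  if (is.null(drives)) drives <- object$drives
  if (is.null(drives)) stop("drives must be supplied for an unfitted model")
  mu <- fixed_point(object, drives)
  draw <- function() mu + matrix(stats::rnorm(length(mu), sd = noise_sd),
                                 nrow(mu), ncol(mu))
  if (!is.null(seed)) with_seed(seed, replicate(nsim, draw(),
                                                simplify = FALSE))
  else replicate(nsim, draw(), simplify = FALSE)
}

#' @export
residuals.cortical_model <- function(object, ...) {
  if (is.null(object$fitted)) stop("model was not fitted to data")
  object$target - object$fitted
}

#' @export
print.cortical_response <- function(x, digits = 3, ...) {
  cat("Settled cortical response (",
      paste(range(x$iterations), collapse = "-"), " iterations, tol ",
      x$tol, ")\n", sep = "")
  print(round(x$activity, digits))
  invisible(x)
}
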