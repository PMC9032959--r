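#' Double-gamma hemodynamic response function
#'
#' The canonical BOLD impulse response modelled as a difference of two gamma
#' densities: a positive response peaking about 6 s after the event and a
#' late undershoot peaking about 16 s, weighted 1/6 of the peak. With unit
#' dispersions the kernel is
#' \deqn{h(t) = \Gamma(t; 6, 1) - \Gamma(t; 16, 1)/6}
#' sampled at the acquisition interval; \code{h(0) = 0} because both gamma
#' densities vanish at zero for shape > 1.
#'
#' @param tr sampling interval in seconds.
#' @param length kernel duration in seconds.
#' @param peak_delay,undershoot_delay gamma shape parameters (seconds, with
#'   unit dispersion).
#' @param dispersion,u_dispersion gamma scale parameters.
#' @param ratio undershoot amplitude relative to the peak.
#' @return numeric vector of \code{floor(length/tr) + 1} samples at
#'   \code{t = 0, tr, 2 tr, ...}.
#' @export
#' @examples
#' h <- double_gamma_hrf(tr = 2, length = 32)
#' h[1]  # 0
double_gamma_hrf <- function(tr, length = 32,
                             peak_delay = 6, undershoot_delay = 16,
                             dispersion = 1, u_dispersion = 1,
                             ratio = 1 / 6) {
  stopifnot(tr > 0, length > 0)
  t <- seq(0, length, by = tr)
  stats::dgamma(t, shape = peak_delay / dispersion, scale = dispersion) -
    ratio * stats::dgamma(t, shape = undershoot_delay / u_dispersion,
                          scale = u_dispersion)
}

## linear convolution of a stimulus time course with a kernel, truncated to
## the stimulus length
convolve_hrf <- function(x, kernel) {
  n <- length(x)
  y <- stats::convolve(c(x, numeric(length(kernel))),
                       rev(kernel), type = "open")
  y[seq_len(n)]
}

## circular convolution for periodic (traveling-wave) designs
convolve_hrf_circular <- function(x, kernel) {
  n <- length(x)
  k <- numeric(n)
  idx <- seq_along(kernel)
  ## fold the kernel into one period
  for (i in idx) k[((i - 1) %% n) + 1] <- k[((i - 1) %% n) + 1] + kernel[i]
  Re(stats::fft(stats::fft(x) * stats::fft(k), inverse = TRUE)) / n
}

#' Design matrix for the finger-stimulation GLM
#'
#' One HRF-convolved boxcar regressor per finger, its temporal derivative
#' (first difference of the convolved regressor, capturing latency shifts),
#' and an intercept: 11 columns in total. Rest is the implicit baseline and
#' gets no regressor.
#'
#' @param schedule a data frame with columns \code{finger}, \code{onset},
#'   \code{duration} (seconds), e.g. \code{attr(run, "schedule")} of a
#'   [generate_wave_run()] output or [block_schedule()].
#' @param n_time number of volumes.
#' @param tr sampling interval in seconds.
#' @param hrf HRF kernel; defaults to [double_gamma_hrf()] at this
#'   \code{tr}.
#' @return a \code{n_time} x 11 matrix of class \code{"design_matrix"} with
#'   labelled columns (\code{D1..D5}, \code{D1_deriv..}, \code{intercept}).
#' @export
design_matrix <- function(schedule, n_time, tr,
                          hrf = double_gamma_hrf(tr)) {
  fingers <- finger_labels()
  X <- matrix(0, n_time, 2 * length(fingers) + 1)
  colnames(X) <- c(fingers, paste0(fingers, "_deriv"), "intercept")
  times <- (seq_len(n_time) - 1) * tr
  for (f in seq_along(fingers)) {
    box <- numeric(n_time)
    ev <- schedule[schedule$finger == fingers[f], , drop = FALSE]
    for (i in seq_len(nrow(ev)))
      box[times >= ev$onset[i] & times < ev$onset[i] + ev$duration[i]] <- 1
    conv <- convolve_hrf(box, hrf)
    X[, f] <- conv
    X[, length(fingers) + f] <- c(0, diff(conv)) / tr
  }
  X[, "intercept"] <- 1
  class(X) <- c("design_matrix", "matrix", "array")
  X
}

#' Ordinary least-squares GLM fit
#'
#' Fits the design to every voxel's time course by OLS in one pass:
#' \code{betas = (X'X)^{-1} X'Y}, \code{residuals = Y - X betas}. Residuals
#' are orthogonal to the design columns by construction.
#'
#' @param run a time x voxel data matrix (e.g. a [generate_wave_run()]
#'   output).
#' @param design a [design_matrix()] (or any full-rank time x regressor
#'   matrix).
#' @return an object of class \code{"glm_fit"}: list with \code{betas}
#'   (regressor x voxel), \code{residuals} (time x voxel), \code{dof}
#'   (time points minus design rank).
#' @export
fit_glm <- function(run, design) {
  Y <- as.matrix(run)
  X <- unclass(as.matrix(design))
  if (nrow(Y) != nrow(X))
    stop("shape error: data has ", nrow(Y), " time points, design has ",
         nrow(X))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("singularity error: design is rank-deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  B <- qr.coef(qx, Y)
  R <- Y - X %*% B
  rownames(B) <- colnames(X)
  colnames(B) <- colnames(Y)
  structure(list(betas = B, residuals = R, dof = nrow(X) - qx$rank),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat("GLM fit:", ncol(x$betas), "voxels,", nrow(x$betas),
      "regressors, residual dof", x$dof, "\n")
  invisible(x)
}

## the 11 contrast weight vectors over the 5 finger-boxcar betas
contrast_weights <- function() {
  fingers <- finger_labels()
  Wts <- matrix(0, 11, 5, dimnames = list(NULL, fingers))
  nm <- character(11)
  for (f in 1:5) {                       # finger vs rest
    Wts[f, f] <- 1
    nm[f] <- paste0(fingers[f], "_vs_rest")
  }
  for (f in 1:5) {                       # finger vs other fingers
    Wts[5 + f, ] <- -1 / 4
    Wts[5 + f, f] <- 1
    nm[5 + f] <- paste0(fingers[f], "_vs_others")
  }
  Wts[11, ] <- 1 / 5                     # all fingers vs rest
  nm[11] <- "all_vs_rest"
  rownames(Wts) <- nm
  Wts
}

#' Contrast maps with fixed-effects run averaging
#'
#' Computes the 11 standard contrasts from each run's finger-boxcar betas —
#' each finger versus rest (rest is the implicit baseline, so the contrast
#' is the boxcar beta itself), each finger versus the mean of the other
#' four, and all fingers versus rest — and averages them across runs with a
#' fixed-effects model (unweighted voxel-wise mean). Temporal-derivative and
#' intercept betas do not enter any contrast.
#'
#' @param fits a \code{glm_fit} or list of them (one per run). Each must
#'   carry the five finger betas in rows \code{D1..D5}; alternatively a
#'   condition x voxel beta matrix per run is accepted.
#' @return an object of class \code{"contrast_set"}: list with
#'   \code{per_run} (list of 11 x voxel matrices) and \code{average}
#'   (11 x voxel fixed-effects mean).
#' @export
compute_contrasts <- function(fits) {
  if (inherits(fits, "glm_fit") || is.matrix(fits)) fits <- list(fits)
  if (length(fits) < 1) stop("need at least one run")
  get_betas <- function(f) {
    B <- if (inherits(f, "glm_fit")) f$betas else as.matrix(f)
    if (!all(finger_labels() %in% rownames(B)))
      B <- B[seq_len(5), , drop = FALSE]
    else B <- B[finger_labels(), , drop = FALSE]
    B
  }
  nv <- vapply(fits, function(f) ncol(get_betas(f)), 1L)
  if (length(unique(nv)) != 1)
    stop("shape error: voxel counts differ across runs (",
         paste(unique(nv), collapse = ", "), ")")
  Wts <- contrast_weights()
  per_run <- lapply(fits, function(f) Wts %*% get_betas(f))
  avg <- Reduce("+", per_run) / length(per_run)
  structure(list(per_run = per_run, average = avg,
                 averaging = "fixed_effects_unweighted_mean"),
            class = "contrast_set")
}

#' @export
print.contrast_set <- function(x, ...) {
  cat("Contrast set: 11 contrasts,", length(x$per_run), "runs,",
      ncol(x$average), "voxels (fixed-effects unweighted mean)\n")
  invisible(x)
}

#' Finger-versus-rest contrast maps
#'
#' @param contrasts a [compute_contrasts()] result.
#' @return 5 x voxel matrix of run-averaged finger-vs-rest contrasts, rows
#'   \code{D1..D5}.
#' @export
finger_vs_rest <- function(contrasts) {
  stopifnot(inherits(contrasts, "contrast_set"))
  m <- contrasts$average[paste0(finger_labels(), "_vs_rest"), ,
                         drop = FALSE]
  rownames(m) <- finger_labels()
  m
}
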