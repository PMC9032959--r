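#' Generate a topographic finger tuning map
#'
#' Places voxels along a 1-D cortical axis and assigns each a nonnegative
#' tuning weight for every finger that decays as a Gaussian in the distance
#' between the voxel's position and the finger's preferred position, at
#' scale \code{tuning_width}. Finger centres are evenly spaced along the
#' axis (D1 to D5), so preferred-finger territory is ordered
#' topographically; neighbouring fingers' tuning profiles overlap, which is
#' what makes "remapping" artifacts possible in winner-takes-all analyses.
#' Each voxel's weights are normalised so its maximum is 1, attained at its
#' true cluster's finger. A \code{tuning_width} of 0 degenerates to
#' non-overlapping indicator tuning.
#'
#' @param config a [study_config()].
#' @param participant_seed integer seed for voxel placement (use
#'   [child_seed()] to derive it from the master seed).
#' @return an object of class \code{"tuning_map"}: list with
#'   \code{voxel_positions} (sorted), \code{tuning_weights} (voxel x 5
#'   matrix), \code{true_cluster_label} (factor \code{C1..C5}),
#'   \code{finger_centers}.
#' @export
generate_tuning_map <- function(config, participant_seed = config$seed) {
  stopifnot(inherits(config, "study_config"))
  if (config$n_voxels < 1)
    stop("configuration error: non-positive voxel count")
  L <- config$cortical_axis_length
  centers <- L * (seq_len(5) - 0.5) / 5
  pos <- with_seed(participant_seed,
                   sort(stats::runif(config$n_voxels, 0, L)))
  d <- outer(pos, centers, "-")
  tw <- config$tuning_width
  W <- if (tw == 0) {
    nearest <- apply(abs(d), 1, which.min)
    m <- matrix(0, config$n_voxels, 5)
    m[cbind(seq_len(config$n_voxels), nearest)] <- 1
    m
  } else {
    exp(-d^2 / (2 * tw^2))
  }
  W <- W / apply(W, 1, max)
  colnames(W) <- finger_labels()
  lab <- factor(cluster_labels()[apply(W, 1, which.max)],
                levels = cluster_labels())
  structure(list(voxel_positions = pos, tuning_weights = W,
                 true_cluster_label = lab, finger_centers = centers,
                 seed = participant_seed),
            class = "tuning_map")
}

#' @export
print.tuning_map <- function(x, ...) {
  cat("Tuning map:", length(x$voxel_positions), "voxels; cluster sizes:",
      paste(table(x$true_cluster_label), collapse = " "), "\n")
  invisible(x)
}

## per-voxel multiplicative gain for a session
session_gains <- function(tuning, session, config) {
  g <- rep(1, length(tuning$voxel_positions))
  if (session == "block") {
    g[] <- config$gain_global
    blocked_cluster <- sub("D", "C", config$blocked_finger)
    g[tuning$true_cluster_label == blocked_cluster] <- config$gain_blocked
  }
  g
}

## draw n rows of voxel noise with the configured covariance, scaled by sd
draw_noise <- function(n, config) {
  V <- config$n_voxels
  if (identical(config$residual_cov, "identity")) {
    matrix(stats::rnorm(n * V, sd = config$noise_sd), n, V)
  } else {
    config$noise_sd *
      MASS::mvrnorm(n, mu = rep(0, V), Sigma = config$residual_cov)
  }
}

#' Generate per-run finger activity patterns for one session
#'
#' The noiseless mean pattern of stimulation condition \code{j} is the
#' tuning map applied to that condition's pooled peripheral drive,
#' \code{tuning_weights \%*\% drive_j}, scaled by a per-voxel session gain:
#' 1 everywhere at baseline; in the block session \code{gain_global} for all
#' voxels except the blocked finger's cluster, which gets
#' \code{gain_blocked} instead (gains scale the feedforward drive, mirroring
#' the cortical model). Per-run betas add Gaussian noise with the configured
#' voxel covariance; residual time series with the same covariance are
#' emitted for prewhitening.
#'
#' @param tuning a [generate_tuning_map()] result.
#' @param session \code{"baseline"} or \code{"block"}.
#' @param config a [study_config()].
#' @param drives finger x condition [peripheral_drives()] matching the
#'   session.
#' @param participant participant index entering the seed arithmetic.
#' @return an object of class \code{"voxel_pattern_set"}: list with
#'   \code{session}, \code{betas} (per run, condition x voxel),
#'   \code{residuals} (per run, time x voxel), \code{mean_patterns}
#'   (noiseless condition x voxel), \code{ground_truth}.
#' @export
generate_session_patterns <- function(tuning, session = c("baseline",
                                                          "block"),
                                      config, drives,
                                      participant = 1L) {
  session <- match.arg(session)
  stopifnot(inherits(tuning, "tuning_map"), inherits(config, "study_config"))
  D <- as.matrix(drives)
  if (!all(dim(D) == c(5, 5)))
    stop("shape error: drives must contain one 5-vector per condition")
  g <- session_gains(tuning, session, config)
  mean_pat <- t(g * (tuning$tuning_weights %*% D))  # condition x voxel
  rownames(mean_pat) <- finger_labels()
  stage <- if (session == "baseline") 2L else 3L
  betas <- residuals <- vector("list", config$n_runs)
  for (r in seq_len(config$n_runs)) {
    betas[[r]] <- with_seed(
      child_seed(config$seed, participant, stage, r),
      mean_pat + draw_noise(5, config))
    rownames(betas[[r]]) <- finger_labels()
    residuals[[r]] <- with_seed(
      child_seed(config$seed, participant, stage + 10L, r),
      draw_noise(config$n_timepoints, config))
  }
  structure(list(session = session, betas = betas, residuals = residuals,
                 mean_patterns = mean_pat, ground_truth = tuning),
            class = "voxel_pattern_set")
}

#' @export
print.voxel_pattern_set <- function(x, ...) {
  cat("Voxel pattern set (", x$session, "): ", length(x$betas),
      " runs, 5 conditions, ", ncol(x$betas[[1]]), " voxels\n", sep = "")
  invisible(x)
}

## traveling-wave event schedule (onsets/durations in seconds)
wave_schedule <- function(config, direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  cycle <- 5 * config$on_seconds
  order <- if (direction == "forward") 1:5 else 5:1
  sched <- do.call(rbind, lapply(seq_len(config$n_cycles), function(cy) {
    data.frame(finger = finger_labels()[order],
               onset = (cy - 1) * cycle +
                 (seq_len(5) - 1) * config$on_seconds,
               duration = config$on_seconds)
  }))
  rownames(sched) <- NULL
  sched
}

#' Generate a traveling-wave localizer BOLD run
#'
#' Simulates the phase-encoded finger-mapping run: the five fingers are
#' stimulated consecutively for \code{on_seconds} each (so each finger sees
#' an 8-s "on" period followed by a 32-s "off" period per 40-s cycle with
#' the defaults), for \code{n_cycles} cycles; backward runs reverse the
#' finger order. Each finger's boxcar is convolved with the double-gamma HRF
#' (circularly, since the design is periodic), mixed into voxels through the
#' tuning weights, and Gaussian noise is added.
#'
#' @param tuning a [generate_tuning_map()] result.
#' @param config a [study_config()].
#' @param direction \code{"forward"} or \code{"backward"}.
#' @param participant,run indices entering the seed arithmetic.
#' @param noise_sd noise level, defaulting to the configured value.
#' @return a time x voxel matrix of class \code{"bold_run"} with attributes
#'   \code{schedule} (finger/onset/duration data frame), \code{direction},
#'   \code{tr}. Run length is \code{n_cycles * 5 * on_seconds / tr} samples.
#' @export
generate_wave_run <- function(tuning, config,
                              direction = c("forward", "backward"),
                              participant = 1L, run = 1L,
                              noise_sd = config$noise_sd) {
  direction <- match.arg(direction)
  stopifnot(inherits(tuning, "tuning_map"))
  cycle <- 5 * config$on_seconds
  if (cycle %% config$tr_seconds != 0)
    stop("configuration error: cycle length must be divisible by tr")
  n_time <- as.integer(config$n_cycles * cycle / config$tr_seconds)
  sched <- wave_schedule(config, direction)
  times <- (seq_len(n_time) - 1) * config$tr_seconds
  hrf <- double_gamma_hrf(config$tr_seconds)
  neural <- matrix(0, n_time, 5, dimnames = list(NULL, finger_labels()))
  for (f in finger_labels()) {
    box <- numeric(n_time)
    ev <- sched[sched$finger == f, , drop = FALSE]
    for (i in seq_len(nrow(ev)))
      box[times >= ev$onset[i] & times < ev$onset[i] + ev$duration[i]] <- 1
    neural[, f] <- convolve_hrf_circular(box, hrf)
  }
  stage <- if (direction == "forward") 20L else 21L
  Y <- neural %*% t(tuning$tuning_weights)
  if (noise_sd > 0)
    Y <- Y + with_seed(child_seed(config$seed, participant, stage, run),
                       matrix(stats::rnorm(length(Y), sd = noise_sd),
                              nrow(Y), ncol(Y)))
  structure(Y, schedule = sched, direction = direction,
            tr = config$tr_seconds,
            class = c("bold_run", "matrix", "array"))
}

#' Generate 2AFC psychophysics trials from a Weibull observer
#'
#' Draws Bernoulli correctness at each grating width from the Weibull
#' psychometric function (see [weibull_psy()]) of a simulated observer with
#' a known 82\%-accuracy threshold and shape. Used to validate psychometric
#' fitting with ground truth.
#'
#' @param threshold grating width (mm) at which the generating curve passes
#'   \code{level} accuracy; must be positive.
#' @param slope Weibull shape parameter (steepness) of the generating curve.
#' @param widths grating widths (mm) tested; default the five-level set
#'   0.5, 1.0, 1.5, 2.5, 3.5.
#' @param n_per_width trials per width.
#' @param seed integer seed.
#' @param finger finger label recorded on the trials.
#' @param gamma,lambda guess and lapse rate of the generating curve.
#' @param level accuracy level defining \code{threshold} (default 0.82).
#' @return a data frame of class \code{"trial_table"} with columns
#'   \code{finger}, \code{grating_width_mm}, \code{trial_index},
#'   \code{correct}; generating parameters in attributes.
#' @export
generate_psychophys_trials <- function(threshold, slope,
                                       widths = c(0.5, 1, 1.5, 2.5, 3.5),
                                       n_per_width = 20L, seed = 1L,
                                       finger = "D2",
                                       gamma = 0.05, lambda = 0,
                                       level = 0.82) {
  if (threshold <= 0) stop("domain error: threshold must be positive")
  if (length(widths) < 1) stop("widths must be nonempty")
  if (n_per_width < 1) stop("n_per_width must be >= 1")
  scale <- weibull_scale_from_threshold(threshold, slope, gamma, lambda,
                                        level)
  p <- weibull_psy(widths, scale, slope, gamma, lambda)
  tab <- with_seed(seed, {
    do.call(rbind, lapply(seq_along(widths), function(i) {
      data.frame(finger = finger, grating_width_mm = widths[i],
                 trial_index = seq_len(n_per_width),
                 correct = stats::rbinom(n_per_width, 1, p[i]))
    }))
  })
  tab <- tab[order(tab$grating_width_mm, tab$trial_index), ]
  rownames(tab) <- NULL
  attr(tab, "generating") <- list(threshold = threshold, slope = slope,
                                  scale = scale, gamma = gamma,
                                  lambda = lambda, level = level)
  class(tab) <- c("trial_table", "data.frame")
  tab
}
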