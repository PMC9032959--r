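#' Study configuration
#'
#' Collects every knob of the synthetic study in one validated object:
#' the size of the simulated hand area, the topographic overlap scale,
#' noise structure, the nerve-block parameters (which finger, what residual
#' drive fraction) and the homeostatic gain constants used when generating
#' block-session activity.
#'
#' @param n_participants number of simulated participants.
#' @param n_voxels number of voxels in the hand area.
#' @param cortical_axis_length length of the 1-D cortical axis (arbitrary
#'   units) along which voxels and finger centres are placed.
#' @param tuning_width Gaussian tuning width (same units as the axis)
#'   controlling how much neighbouring-finger representations overlap.
#' @param n_runs runs per session and task.
#' @param n_timepoints residual time points emitted per run.
#' @param noise_sd standard deviation of the additive beta noise.
#' @param residual_cov voxel-by-voxel residual covariance matrix, or the
#'   string \code{"identity"}.
#' @param blocked_finger finger receiving the nerve block (\code{"D1"} ..
#'   \code{"D5"}).
#' @param block_fraction residual afferent drive of the blocked finger as a
#'   fraction of baseline (0.2 means 20\% residual activation).
#' @param gain_global multiplicative gain applied to all cortical clusters in
#'   the block session.
#' @param gain_blocked gain applied to the blocked finger's cluster instead of
#'   \code{gain_global}.
#' @param spread_lambda length scale of the peripheral mechanical spread
#'   kernel (finger-index units); see [build_spread()].
#' @param tr_seconds sampling interval of simulated BOLD runs.
#' @param n_cycles traveling-wave cycles per localizer run.
#' @param on_seconds,off_seconds per-finger stimulation on/off durations in
#'   the traveling-wave design.
#' @param seed master seed; all child seeds are derived from it by fixed
#'   arithmetic (see [child_seed()]).
#' @return an object of class \code{"study_config"} (a validated list).
#' @export
#' @examples
#' cfg <- study_config(n_voxels = 50, seed = 1)
#' cfg$block_fraction
study_config <- function(n_participants = 1L,
                         n_voxels = 200L,
                         cortical_axis_length = 10,
                         tuning_width = 1,
                         n_runs = 4L,
                         n_timepoints = 100L,
                         noise_sd = 0.5,
                         residual_cov = "identity",
                         blocked_finger = "D2",
                         block_fraction = 0.2,
                         gain_global = 0.75,
                         gain_blocked = 1.25,
                         spread_lambda = -1 / log(0.3),
                         tr_seconds = 2,
                         n_cycles = 5L,
                         on_seconds = 8,
                         off_seconds = 32,
                         seed = 1L) {
  counts <- c(n_participants = n_participants, n_voxels = n_voxels,
              n_runs = n_runs, n_timepoints = n_timepoints,
              n_cycles = n_cycles)
  if (any(counts < 1))
    stop("configuration error: all counts must be >= 1 (",
         paste(names(counts)[counts < 1], collapse = ", "), ")")
  if (block_fraction < 0 || block_fraction > 1)
    stop("configuration error: block_fraction must lie in [0, 1]")
  if (tuning_width < 0)
    stop("configuration error: tuning_width must be >= 0")
  if (noise_sd < 0)
    stop("configuration error: noise_sd must be >= 0")
  if (gain_global <= 0 || gain_blocked <= 0)
    stop("configuration error: gains must be > 0")
  if (tr_seconds <= 0)
    stop("configuration error: tr_seconds must be > 0")
  blocked_finger <- match.arg(blocked_finger, finger_labels())
  if (is.character(residual_cov)) {
    residual_cov <- match.arg(residual_cov, "identity")
  } else {
    residual_cov <- as.matrix(residual_cov)
    if (nrow(residual_cov) != n_voxels || ncol(residual_cov) != n_voxels)
      stop("configuration error: residual_cov must be n_voxels x n_voxels")
    if (max(abs(residual_cov - t(residual_cov))) > 1e-8)
      stop("configuration error: residual_cov must be symmetric")
    if (min(eigen(residual_cov, symmetric = TRUE,
                  only.values = TRUE)$values) <= 0)
      stop("configuration error: residual_cov must be positive definite")
  }
  cfg <- list(
    n_participants = as.integer(n_participants),
    n_voxels = as.integer(n_voxels),
    cortical_axis_length = cortical_axis_length,
    tuning_width = tuning_width,
    n_runs = as.integer(n_runs),
    n_timepoints = as.integer(n_timepoints),
    noise_sd = noise_sd,
    residual_cov = residual_cov,
    blocked_finger = blocked_finger,
    block_fraction = block_fraction,
    gain_global = gain_global,
    gain_blocked = gain_blocked,
    spread_lambda = spread_lambda,
    tr_seconds = tr_seconds,
    n_cycles = as.integer(n_cycles),
    on_seconds = on_seconds,
    off_seconds = off_seconds,
    seed = as.integer(seed)
  )
  class(cfg) <- "study_config"
  cfg
}

#' @export
print.study_config <- function(x, ...) {
  cat("Study configuration\n")
  cat("  participants:", x$n_participants,
      " voxels:", x$n_voxels,
      " runs/session:", x$n_runs, "\n")
  cat("  tuning width:", x$tuning_width,
      " noise sd:", x$noise_sd, "\n")
  cat("  block:", x$blocked_finger,
      sprintf("(%.0f%% residual drive)", 100 * x$block_fraction),
      " gains:", x$gain_global, "/", x$gain_blocked, "\n")
  cat("  master seed:", x$seed, "\n")
  invisible(x)
}

#' Finger condition labels
#'
#' @return character vector \code{c("D1", ..., "D5")} (thumb to little
#'   finger).
#' @export
finger_labels <- function() paste0("D", 1:5)

#' Cluster labels
#'
#' @return character vector \code{c("C1", ..., "C5")}.
#' @export
cluster_labels <- function() paste0("C", 1:5)

#' Derive a child seed from the master seed
#'
#' Every random stage of the pipeline draws its seed deterministically from
#' the master seed so that a whole study regenerates bit-identically. The
#' arithmetic is fixed: distinct primes multiply the participant index and a
#' stage identifier, the run index adds, and the result is folded into the
#' 32-bit signed integer range.
#'
#' @param seed master integer seed.
#' @param participant participant index (1-based), 0 for group-level stages.
#' @param stage integer stage identifier (each calling stage uses its own
#'   constant).
#' @param run run index, 0 when not run-specific.
#' @return a non-negative integer below \code{2^31}.
#' @export
child_seed <- function(seed, participant = 0L, stage = 0L, run = 0L) {
  ## magnitudes stay below 2^53, so double arithmetic is exact
  v <- (as.numeric(seed) * 48271 + participant * 7919 +
        stage * 104729 + run * 131) %% 2147483647
  as.integer(v)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Read / write a study configuration
#'
#' Configurations round-trip losslessly through YAML or JSON (chosen by file
#' extension). A matrix-valued \code{residual_cov} is stored as a nested list
#' of rows.
#'
#' @param config a \code{study_config} object.
#' @param path file path ending in \code{.yaml}, \code{.yml} or \code{.json}.
#' @return \code{read_study_config} returns a \code{study_config};
#'   \code{write_study_config} returns \code{path} invisibly.
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  x <- unclass(config)
  if (is.matrix(x$residual_cov))
    x$residual_cov <- apply(x$residual_cov, 1, as.numeric, simplify = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(x, path, precision = 15)
  } else if (ext == "json") {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else stop("unsupported config extension: ", ext)
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
       else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
       else stop("unsupported config extension: ", ext)
  if (is.list(x$residual_cov))
    x$residual_cov <- do.call(rbind, lapply(x$residual_cov, as.numeric))
  do.call(study_config, x)
}
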