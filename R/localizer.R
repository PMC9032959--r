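#' Lag-shifted reference models for traveling-wave mapping
#'
#' Builds the phase-encoded localizer reference set: an HRF-convolved boxcar
#' modelling one finger's stimulation (8 s on, 32 s off per 40-s cycle with
#' the defaults), repeated over all cycles, and cyclically shifted by one
#' sampling interval at a time across the full cycle. With a 40-s cycle
#' sampled every 2 s this yields 20 reference models; consecutive groups of
#' \code{n_lags / n_fingers} lags (4 with the defaults) are assigned to each
#' finger, since a response beginning k samples later belongs to the finger
#' stimulated k samples later in the cycle.
#'
#' @param tr sampling interval, seconds.
#' @param on,off per-finger on/off durations, seconds (\code{on + off} is
#'   the cycle length and must equal \code{n_fingers * on}).
#' @param n_fingers number of fingers in the cycle.
#' @param n_cycles cycles per run.
#' @return an object of class \code{"reference_models"}: list with
#'   \code{models} (time x lag matrix, lag m = base shifted by m samples),
#'   \code{lag_finger} (finger index owning each lag), \code{cycle_samples},
#'   \code{tr}.
#' @export
build_reference_models <- function(tr = 2, on = 8, off = 32,
                                   n_fingers = 5, n_cycles = 5) {
  cycle <- on + off
  if (cycle %% tr != 0)
    stop("configuration error: cycle length not divisible by tr")
  if (abs(cycle - n_fingers * on) > 1e-9)
    stop("configuration error: off period must equal (n_fingers - 1) * on")
  n_lags <- as.integer(cycle / tr)
  if (n_lags %% n_fingers != 0)
    stop("configuration error: lags not divisible among fingers")
  n_time <- as.integer(n_cycles * cycle / tr)
  box <- rep(0, n_time)
  t_sec <- (seq_len(n_time) - 1) * tr
  box[(t_sec %% cycle) < on] <- 1
  base <- convolve_hrf_circular(box, double_gamma_hrf(tr))
  shift <- function(x, m) if (m == 0) x else c(utils::tail(x, m),
                                               utils::head(x, -m))
  M <- vapply(0:(n_lags - 1), function(m) shift(base, m), numeric(n_time))
  colnames(M) <- paste0("lag", 0:(n_lags - 1))
  lag_finger <- rep(seq_len(n_fingers), each = n_lags / n_fingers)
  structure(list(models = M, lag_finger = lag_finger,
                 n_lags = n_lags, cycle_samples = n_lags, tr = tr,
                 on = on, off = off, n_fingers = n_fingers,
                 n_cycles = n_cycles),
            class = "reference_models")
}

#' @export
print.reference_models <- function(x, ...) {
  cat("Reference model set:", x$n_lags, "lag-shifted models (",
      x$n_lags / x$n_fingers, "lags per finger ),",
      nrow(x$models), "samples\n")
  invisible(x)
}

## finger owning each lag for a given run direction: backward runs present
## the fingers in reverse order, so lag group g maps to finger n-g+1
lag_finger_map <- function(refs, direction) {
  if (direction == "forward") refs$lag_finger
  else refs$n_fingers + 1L - refs$lag_finger
}

#' Voxel-wise lag correlation and finger assignment
#'
#' Correlates every reference model with every voxel's BOLD time course,
#' standardises the r values with Fisher's r-to-z transformation (r clipped
#' to \eqn{\pm(1 - 10^{-6})} so z stays finite), aggregates z over each
#' finger's lags (mean by default, maximum optionally), and averages across
#' the forward and backward runs (backward lags are remapped to fingers by
#' the reversed stimulation order). Each voxel's winning finger is the
#' argmax of its five aggregated z values, ties broken toward the lowest
#' finger index; a one-sided p value per finger is obtained from a
#' t statistic on the correlation implied by the aggregated z, with
#' effective degrees of freedom = time points − 2. Voxels with a constant
#' time course have undefined correlations and are flagged and excluded
#' (all-NA row).
#'
#' @param runs a [generate_wave_run()] output or list of them (mixing
#'   forward and backward runs).
#' @param refs a [build_reference_models()] set.
#' @param aggregate \code{"mean"} or \code{"max"} over a finger's lags.
#' @return an object of class \code{"finger_correlation_map"}: list with
#'   \code{z} (voxel x finger aggregated z), \code{winner} (integer finger
#'   index per voxel, NA for excluded voxels), \code{p} (voxel x finger),
#'   \code{excluded} (logical), \code{n_time}.
#' @export
correlate_voxels <- function(runs, refs, aggregate = c("mean", "max")) {
  aggregate <- match.arg(aggregate)
  stopifnot(inherits(refs, "reference_models"))
  if (inherits(runs, "bold_run")) runs <- list(runs)
  nv <- ncol(runs[[1]])
  n_time <- nrow(refs$models)
  zsum <- matrix(0, nv, refs$n_fingers,
                 dimnames = list(NULL, finger_labels()[seq_len(refs$n_fingers)]))
  excluded <- rep(FALSE, nv)
  for (run in runs) {
    Y <- as.matrix(run)
    if (nrow(Y) != n_time)
      stop("shape error: run length ", nrow(Y),
           " does not match reference models (", n_time, ")")
    const <- apply(Y, 2, stats::sd) == 0
    excluded <- excluded | const
    r <- suppressWarnings(stats::cor(Y, refs$models))  # voxel x lag
    r <- pmin(pmax(r, -(1 - 1e-6)), 1 - 1e-6)
    z <- atanh(r)
    fmap <- lag_finger_map(refs, attr(run, "direction") %||% "forward")
    zf <- vapply(seq_len(refs$n_fingers), function(f) {
      zl <- z[, fmap == f, drop = FALSE]
      if (aggregate == "mean") rowMeans(zl) else apply(zl, 1, max)
    }, numeric(nv))
    zsum <- zsum + zf
  }
  zbar <- zsum / length(runs)
  zbar[excluded, ] <- NA_real_
  winner <- apply(zbar, 1, function(v) if (anyNA(v)) NA_integer_
                  else which.max(v))
  ## p from a t statistic on the correlation implied by the aggregated z
  dof <- n_time - 2
  rbar <- tanh(zbar)
  tstat <- rbar * sqrt(dof / pmax(1 - rbar^2, 1e-12))
  p <- stats::pt(tstat, df = dof, lower.tail = FALSE)
  structure(list(z = zbar, winner = winner, p = p, excluded = excluded,
                 n_time = n_time, aggregate = aggregate),
            class = "finger_correlation_map")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.finger_correlation_map <- function(x, ...) {
  cat("Finger correlation map:", nrow(x$z), "voxels; winners:",
      paste(table(factor(x$winner, 1:5)), collapse = " "),
      "; excluded:", sum(x$excluded), "\n")
  invisible(x)
}

#' FDR-thresholded winner-takes-all cluster definition
#'
#' Defines the finger-selective clusters C1-C5: for each finger, a
#' Benjamini-Hochberg false-discovery-rate threshold at level \code{q} is
#' applied to the p values of the voxels whose winning finger it is (within
#' the hand-area mask); surviving voxels are labelled with that finger's
#' cluster. Clusters are disjoint by construction (each voxel has one
#' winner), lie within the mask, and need not be contiguous.
#'
#' @param map a [correlate_voxels()] result.
#' @param hand_mask logical or integer vector selecting hand-area voxels.
#' @param q FDR level in (0, 1); the study uses q < 0.01.
#' @return an object of class \code{"cluster_map"}: list with \code{label}
#'   (factor \code{C1..C5} or NA per voxel), \code{mask} (logical),
#'   \code{sizes} (named voxel counts).
#' @export
define_clusters <- function(map, hand_mask = NULL, q = 0.01) {
  stopifnot(inherits(map, "finger_correlation_map"))
  nv <- nrow(map$z)
  if (is.null(hand_mask)) hand_mask <- rep(TRUE, nv)
  if (is.numeric(hand_mask) && !is.logical(hand_mask)) {
    m <- rep(FALSE, nv); m[hand_mask] <- TRUE; hand_mask <- m
  }
  if (!any(hand_mask)) stop("configuration error: empty hand mask")
  if (q <= 0 || q >= 1) stop("q must lie in (0, 1)")
  label <- factor(rep(NA_character_, nv), levels = cluster_labels())
  for (f in 1:5) {
    cand <- which(hand_mask & !map$excluded &
                    !is.na(map$winner) & map$winner == f)
    if (!length(cand)) next
    pf <- map$p[cbind(cand, f)]
    keep <- stats::p.adjust(pf, method = "BH") <= q
    label[cand[keep]] <- cluster_labels()[f]
  }
  structure(list(label = label, mask = hand_mask,
                 sizes = table(label, useNA = "no"), q = q),
            class = "cluster_map")
}

#' @export
print.cluster_map <- function(x, ...) {
  cat("Cluster map (FDR q <=", x$q, "):",
      sum(!is.na(x$label)), "of", sum(x$mask), "masked voxels assigned\n")
  print(x$sizes)
  invisible(x)
}

#' Cluster membership as a logical index
#'
#' @param clusters a [define_clusters()] result (or any \code{cluster_map}).
#' @param cluster cluster label, e.g. \code{"C2"}.
#' @return logical vector over voxels.
#' @export
cluster_voxels <- function(clusters, cluster) {
  stopifnot(inherits(clusters, "cluster_map"))
  !is.na(clusters$label) & clusters$label == cluster
}

#' Cluster map from a tuning map's ground truth
#'
#' Wraps the generator's true voxel labels in a \code{cluster_map} so
#' downstream analyses can run against ground truth.
#'
#' @param tuning a [generate_tuning_map()] result.
#' @return a \code{cluster_map} labelling every voxel with its true cluster.
#' @export
true_cluster_map <- function(tuning) {
  stopifnot(inherits(tuning, "tuning_map"))
  structure(list(label = tuning$true_cluster_label,
                 mask = rep(TRUE, length(tuning$true_cluster_label)),
                 sizes = table(tuning$true_cluster_label), q = NA_real_),
            class = "cluster_map")
}
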