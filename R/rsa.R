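#' Representational dissimilarity matrix (RDM)
#'
#' Symmetric dissimilarity structure over a set of conditions (the five
#' fingers, optionally plus rest). Cross-nobis entries are unbiased and may
#' legitimately fall below zero when two patterns do not differ; the class
#' therefore does not force non-negativity.
#'
#' @param mat symmetric numeric matrix with zero diagonal, dimnames =
#'   condition labels.
#' @param estimator \code{"crossnobis"} or \code{"euclidean"}.
#' @return the matrix with class \code{"rdm"} and an \code{"estimator"}
#'   attribute.
#' @name rdm
#' @export
new_rdm <- function(mat, estimator = c("crossnobis", "euclidean")) {
  estimator <- match.arg(estimator)
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat) || max(abs(mat - t(mat))) > 1e-8)
    stop("validation error: RDM must be a symmetric square matrix")
  mat <- (mat + t(mat)) / 2
  diag(mat) <- 0
  attr(mat, "estimator") <- estimator
  class(mat) <- c("rdm", "matrix", "array")
  mat
}

#' @export
print.rdm <- function(x, digits = 3, ...) {
  cat("RDM (", attr(x, "estimator"), ", ", nrow(x), " conditions)\n",
      sep = "")
  print(round(unclass(x), digits))
  invisible(x)
}

## lower-triangle vector of condition-pair dissimilarities
rdm_vec <- function(x) x[lower.tri(x)]

#' Noise whitener from GLM residuals
#'
#' Estimates the voxel-by-voxel noise covariance from the GLM residual time
#' series (pooled across runs), shrinks it toward its diagonal and returns
#' the inverse symmetric square root as a whitening transform, so that
#' \code{t(Wm) \%*\% Wm} equals the inverse of the regularised covariance.
#' Multivariate distances computed on whitened patterns are Mahalanobis
#' distances with respect to the noise.
#'
#' Shrinkage intensity defaults to an analytic estimate in the
#' Ledoit-Wolf/Schafer-Strimmer style: the ratio of the summed sampling
#' variances of the off-diagonal covariances to their summed squares,
#' clipped to \code{[0, 1]}.
#'
#' @param residuals a time x voxel matrix or a list of them (one per run).
#' @param shrinkage \code{NULL} for the analytic intensity, or a fixed value
#'   in \code{[0, 1]}.
#' @param reg_floor smallest admissible eigenvalue of the shrunk covariance,
#'   relative to the mean eigenvalue; below it a ridge is added with a
#'   warning.
#' @return an object of class \code{"noise_whitener"}: list with
#'   \code{transform} (voxel x voxel), \code{sigma} (the shrunk covariance),
#'   \code{shrinkage}, \code{dof}.
#' @export
noise_whitener <- function(residuals, shrinkage = NULL, reg_floor = 1e-8) {
  if (is.matrix(residuals)) residuals <- list(residuals)
  V <- ncol(residuals[[1]])
  n_tot <- sum(vapply(residuals, nrow, 1L))
  if (n_tot <= 1) stop("need more than one residual time point")
  ## pooled covariance across runs (each run centred separately)
  S <- matrix(0, V, V)
  for (R in residuals) {
    Rc <- scale(R, center = TRUE, scale = FALSE)
    S <- S + crossprod(Rc)
  }
  dof <- n_tot - length(residuals)
  S <- S / dof
  if (is.null(shrinkage)) {
    ## analytic intensity: var of off-diagonal entries over their energy
    Xc <- do.call(rbind, lapply(residuals, scale, center = TRUE,
                                scale = FALSE))
    n <- nrow(Xc)
    ## sampling variance of each covariance entry
    W2 <- crossprod(Xc^2) / n - (crossprod(Xc) / n)^2
    varS <- W2 * n / ((n - 1)^2)
    off <- !diag(TRUE, V)
    num <- sum(varS[off])
    den <- sum((S[off])^2)
    shrinkage <- if (den <= 0) 1 else max(0, min(1, num / den))
  }
  Sig <- (1 - shrinkage) * S + shrinkage * diag(diag(S), V)
  e <- eigen(Sig, symmetric = TRUE)
  floor_val <- reg_floor * mean(e$values)
  if (min(e$values) < floor_val) {
    warning("shrunk covariance near-singular; regularization floor applied")
    e$values <- pmax(e$values, floor_val)
    Sig <- e$vectors %*% (e$values * t(e$vectors))
    e <- eigen(Sig, symmetric = TRUE)
  }
  Wm <- e$vectors %*% (t(e$vectors) / sqrt(e$values))
  out <- list(transform = Wm, sigma = Sig, shrinkage = shrinkage, dof = dof)
  class(out) <- "noise_whitener"
  out
}

#' @export
print.noise_whitener <- function(x, ...) {
  cat("Noise whitener:", ncol(x$transform), "voxels, shrinkage",
      signif(x$shrinkage, 3), ", residual dof", x$dof, "\n")
  invisible(x)
}

#' Cross-validated Mahalanobis (cross-nobis) RDM
#'
#' For each condition pair, the squared Mahalanobis distance is estimated by
#' cross-validating the pattern difference across independent imaging runs:
#' \deqn{d_{jk} = \mathrm{mean}_{(A,B)} \; \delta_{jk}^{(A)\top}
#'   \delta_{jk}^{(B)} / V}
#' over all unordered run pairs \eqn{(A, B)}, where \eqn{\delta_{jk}} is the
#' whitened pattern difference of conditions \eqn{j, k} in one run and
#' \eqn{V} the voxel count (normalisation makes values comparable across
#' regions of different size). Because the two factors carry independent
#' noise the estimator is unbiased: its expectation is zero — and single
#' estimates can go below zero — when the true patterns do not differ.
#' Rest can be included as an extra condition with uniform activity 0 in
#' every run. No mean-centering is applied anywhere, so distances from rest
#' are meaningful.
#'
#' @param patterns a \code{voxel_pattern_set} from
#'   [generate_session_patterns()], or a list of run-wise condition x voxel
#'   beta matrices.
#' @param whitener a [noise_whitener()]; \code{NULL} for the identity
#'   (plain cross-validated Euclidean inner products).
#' @param include_rest include rest as an all-zero pattern.
#' @param voxels optional integer/logical index restricting the analysis to
#'   a voxel subset (e.g. one cluster); whitening uses the matching
#'   submatrix rows/columns of the transform only when \code{whitener} was
#'   built on the same subset, so pass a whitener built from the subset's
#'   residuals.
#' @return an [rdm] object with estimator \code{"crossnobis"}.
#' @export
crossnobis_rdm <- function(patterns, whitener = NULL, include_rest = TRUE,
                           voxels = NULL) {
  runs <- if (inherits(patterns, "voxel_pattern_set")) patterns$betas
          else patterns
  if (length(runs) < 2)
    stop("cross-validation impossible: need at least 2 runs")
  runs <- lapply(runs, as.matrix)
  if (!is.null(voxels)) runs <- lapply(runs, function(m) m[, voxels,
                                                           drop = FALSE])
  V <- ncol(runs[[1]])
  labs <- rownames(runs[[1]])
  if (is.null(labs)) labs <- finger_labels()[seq_len(nrow(runs[[1]]))]
  if (include_rest) {
    runs <- lapply(runs, function(m) rbind(m, rest = 0))
    labs <- c(labs, "rest")
  }
  if (!is.null(whitener)) {
    Wm <- whitener$transform
    if (ncol(Wm) != V)
      stop("shape error: whitener built for ", ncol(Wm),
           " voxels, patterns have ", V)
    runs <- lapply(runs, function(m) m %*% Wm)
  }
  K <- length(labs)
  pairs <- utils::combn(length(runs), 2)
  D <- matrix(0, K, K, dimnames = list(labs, labs))
  for (j in seq_len(K - 1)) for (k in (j + 1):K) {
    acc <- 0
    for (p in seq_len(ncol(pairs))) {
      dA <- runs[[pairs[1, p]]][j, ] - runs[[pairs[1, p]]][k, ]
      dB <- runs[[pairs[2, p]]][j, ] - runs[[pairs[2, p]]][k, ]
      acc <- acc + sum(dA * dB) / V
    }
    D[j, k] <- D[k, j] <- acc / ncol(pairs)
  }
  new_rdm(D, estimator = "crossnobis")
}

## scaling-free Procrustes: rotate/reflect + translate B onto A
procrustes_align <- function(A, B) {
  stopifnot(all(dim(A) == dim(B)))
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  sv <- svd(t(B0) %*% A0)
  R <- sv$u %*% t(sv$v)
  aligned <- B0 %*% R
  aligned <- sweep(aligned, 2, ca, "+")
  list(aligned = aligned, rotation = R,
       disparity = sum((aligned - A)^2))
}

#' MDS projection with Procrustes group averaging
#'
#' Projects each participant's RDM into two dimensions by classical
#' (metric) multidimensional scaling, rigidly aligns all configurations to
#' the first participant's by scaling-free Procrustes (rotation/reflection
#' plus translation only, so each participant's inter-point distances are
#' preserved exactly), averages the aligned configurations, and finally
#' rotates the common space so the two axes carry the maximal between-finger
#' variance (principal axes of the group-mean finger points, rest excluded).
#' RDM entries are treated as squared distances (the cross-nobis scale), so
#' MDS runs on their square roots after clipping negatives to zero.
#'
#' @param rdms list of [rdm] objects, one per participant, sharing the same
#'   condition list.
#' @return an object of class \code{"group_configuration"}: list with
#'   \code{points} (list of aligned condition x 2 matrices),
#'   \code{mean_points}, \code{disparity} (per participant, alignment sum of
#'   squares against the reference).
#' @export
mds_group <- function(rdms) {
  if (inherits(rdms, "rdm")) rdms <- list(rdms)
  labs <- rownames(rdms[[1]])
  for (r in rdms) {
    if (!inherits(r, "rdm")) stop("validation error: inputs must be RDMs")
    if (!identical(rownames(r), labs))
      stop("validation error: RDMs must share the condition list")
  }
  embed <- function(r) {
    d <- sqrt(pmax(unclass(r), 0))
    x <- stats::cmdscale(stats::as.dist(d), k = 2)
    rownames(x) <- labs
    x
  }
  pts <- lapply(rdms, embed)
  ref <- pts[[1]]
  disparity <- numeric(length(pts))
  for (i in seq_along(pts)) {
    al <- procrustes_align(ref, pts[[i]])
    pts[[i]] <- al$aligned
    disparity[i] <- al$disparity
  }
  mp <- Reduce("+", pts) / length(pts)
  ## rotate the common space to the principal axes of the finger points
  fing <- mp[rownames(mp) != "rest", , drop = FALSE]
  pc <- eigen(stats::cov(fing), symmetric = TRUE)$vectors
  pts <- lapply(pts, function(x) {
    y <- x %*% pc; dimnames(y) <- list(labs, c("dim1", "dim2")); y
  })
  mp <- mp %*% pc
  dimnames(mp) <- list(labs, c("dim1", "dim2"))
  structure(list(points = pts, mean_points = mp, disparity = disparity),
            class = "group_configuration")
}

#' @export
print.group_configuration <- function(x, digits = 3, ...) {
  cat("Group MDS configuration (", length(x$points), " participants)\n",
      sep = "")
  print(round(x$mean_points, digits))
  invisible(x)
}

#' @export
plot.group_configuration <- function(x, ...) {
  mp <- x$mean_points
  graphics::plot(mp, type = "n", xlab = "dim 1", ylab = "dim 2",
                 main = "Group representational configuration", ...)
  for (p in x$points) graphics::points(p, col = "grey70", pch = 16,
                                       cex = 0.6)
  graphics::text(mp, labels = rownames(mp), font = 2)
  invisible(x)
}

#' Session change of the representational structure
#'
#' Summarises how the finger RDM changes from the baseline to the block
#' session: percent change of mean interfinger dissimilarity (over all
#' finger pairs; over pairs among the non-blocked fingers; for the blocked
#' finger against its neighbours vs. non-neighbours), per-finger
#' distance-from-rest changes when rest is present, and the Spearman rank
#' correlation of the block RDM with a canonical finger RDM together with a
#' finger-label-permutation p value (all 5! relabelings are enumerated, so
#' the p value is exact and bounded below by 1/120).
#'
#' @param baseline,block [rdm] objects with matched condition lists.
#' @param canonical canonical finger [rdm] (defaults to \code{baseline}).
#' @param blocked_finger finger label whose input was blocked.
#' @return an object of class \code{"rdm_change"}: list with
#'   \code{pct_change_all}, \code{pct_change_nonblocked},
#'   \code{pct_change_neighbors}, \code{pct_change_nonneighbors},
#'   \code{rest_change} (per finger, when rest present),
#'   \code{spearman_canonical}, \code{perm_p}, and the session means.
#' @export
rdm_session_change <- function(baseline, block, canonical = baseline,
                               blocked_finger = "D2") {
  if (!identical(rownames(baseline), rownames(block)) ||
      !identical(rownames(baseline), rownames(canonical)))
    stop("validation error: RDMs must share matched condition lists")
  labs <- rownames(baseline)
  fingers <- intersect(finger_labels(), labs)
  bi <- match(blocked_finger, fingers)
  pair_mean <- function(r, keep) {
    m <- unclass(r)[keep, keep, drop = FALSE]
    mean(m[lower.tri(m)])
  }
  pct <- function(b0, b1) 100 * (b1 - b0) / b0
  nonblocked <- setdiff(fingers, blocked_finger)
  neigh_idx <- which(abs(seq_along(fingers) - bi) == 1)
  nonneigh_idx <- which(abs(seq_along(fingers) - bi) > 1)
  mean_to <- function(r, set) mean(unclass(r)[blocked_finger, set])
  out <- list(
    mean_baseline = pair_mean(baseline, fingers),
    mean_block = pair_mean(block, fingers),
    pct_change_all = pct(pair_mean(baseline, fingers),
                         pair_mean(block, fingers)),
    pct_change_nonblocked = pct(pair_mean(baseline, nonblocked),
                                pair_mean(block, nonblocked)),
    pct_change_neighbors = pct(mean_to(baseline, fingers[neigh_idx]),
                               mean_to(block, fingers[neigh_idx])),
    pct_change_nonneighbors = pct(mean_to(baseline, fingers[nonneigh_idx]),
                                  mean_to(block, fingers[nonneigh_idx]))
  )
  if ("rest" %in% labs) {
    out$rest_change <- unclass(block)[fingers, "rest"] -
      unclass(baseline)[fingers, "rest"]
  }
  ## rank correlation with the canonical structure, exact permutation null
  sub <- function(r, ord = fingers) unclass(r)[ord, ord]
  v_can <- rdm_vec(sub(canonical))
  v_blk <- rdm_vec(sub(block))
  obs <- stats::cor(v_blk, v_can, method = "spearman")
  perms <- permutations_of(length(fingers))
  stat <- apply(perms, 1, function(p) {
    stats::cor(rdm_vec(sub(block, fingers[p])), v_can, method = "spearman")
  })
  out$spearman_canonical <- obs
  out$perm_p <- mean(stat >= obs - 1e-12)
  out$n_perm <- nrow(perms)
  class(out) <- "rdm_change"
  out
}

#' @export
print.rdm_change <- function(x, digits = 3, ...) {
  cat("Representational change, baseline -> block\n")
  cat(sprintf("  mean interfinger dissimilarity: %.4g -> %.4g (%+.1f%%)\n",
              x$mean_baseline, x$mean_block, x$pct_change_all))
  cat(sprintf("  non-blocked pairs: %+.1f%%; blocked vs neighbors: %+.1f%%; vs non-neighbors: %+.1f%%\n",
              x$pct_change_nonblocked, x$pct_change_neighbors,
              x$pct_change_nonneighbors))
  cat(sprintf("  Spearman with canonical RDM: %.3f (permutation p = %.4g, %d relabelings)\n",
              x$spearman_canonical, x$perm_p, x$n_perm))
  invisible(x)
}

## all permutations of 1..n, one per row
permutations_of <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- permutations_of(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}
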