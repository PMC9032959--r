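#' Mean finger activity per cluster
#'
#' The univariate activity table: entry (finger f, cluster c) is the mean of
#' finger f's finger-versus-rest contrast over cluster c's voxels. An empty
#' cluster yields NA (flagged missing, never silently zero).
#'
#' @param contrasts a [compute_contrasts()] result, or a 5 x voxel matrix of
#'   run-averaged finger-vs-rest contrasts (rows \code{D1..D5}).
#' @param clusters a \code{cluster_map}.
#' @return a 5 x 5 matrix of class \code{"activity_table"} (fingers x
#'   clusters).
#' @export
cluster_activity <- function(contrasts, clusters) {
  A <- if (inherits(contrasts, "contrast_set")) finger_vs_rest(contrasts)
       else as.matrix(contrasts)
  stopifnot(inherits(clusters, "cluster_map"), nrow(A) == 5)
  if (!any(!is.na(clusters$label)))
    stop("clusters are empty")
  out <- matrix(NA_real_, 5, 5,
                dimnames = list(finger = finger_labels(),
                                cluster = cluster_labels()))
  for (cl in cluster_labels()) {
    vox <- cluster_voxels(clusters, cl)
    if (!any(vox)) next  # empty cluster stays NA
    out[, cl] <- rowMeans(A[, vox, drop = FALSE])
  }
  class(out) <- c("activity_table", "matrix", "array")
  out
}

#' @export
print.activity_table <- function(x, digits = 3, ...) {
  cat("Activity table (finger x cluster means)\n")
  print(round(unclass(x), digits))
  invisible(x)
}

#' Per-cluster finger selectivity
#'
#' For each retained cluster, the activity of its target finger minus the
#' mean activity of the nontarget fingers. To keep the measure independent
#' of the blocked finger, that finger's activity and its cluster are
#' excluded by default, leaving three nontarget fingers per retained
#' cluster.
#'
#' @param table an [cluster_activity()] table (fingers x clusters).
#' @param exclude_finger finger dropped from the nontarget set (NULL for
#'   none).
#' @param exclude_cluster cluster dropped from the output (NULL for none).
#' @return named numeric vector of selectivities, one per retained cluster.
#' @export
cluster_selectivity <- function(table, exclude_finger = "D2",
                                exclude_cluster = "C2") {
  stopifnot(inherits(table, "activity_table") ||
              all(dim(as.matrix(table)) == c(5, 5)))
  table <- as.matrix(table)
  if (!is.null(exclude_finger) && !exclude_finger %in% finger_labels())
    stop("invalid finger label: ", exclude_finger)
  if (!is.null(exclude_cluster) && !exclude_cluster %in% cluster_labels())
    stop("invalid cluster label: ", exclude_cluster)
  keep <- setdiff(cluster_labels(), exclude_cluster)
  out <- numeric(0)
  for (cl in keep) {
    target <- sub("C", "D", cl)
    if (!is.null(exclude_finger) && identical(target, exclude_finger))
      stop("definition error: excluded finger ", exclude_finger,
           " is the target of retained cluster ", cl)
    nontarget <- setdiff(finger_labels(), c(target, exclude_finger))
    out[cl] <- table[target, cl] - mean(table[nontarget, cl])
  }
  out
}

#' Winner-takes-all finger assignment with finger subsets
#'
#' Assigns every voxel to the finger (within \code{finger_subset}) evoking
#' its strongest contrast, or marks it non-active when the maximum does not
#' exceed zero (thresholding can be disabled to emulate the unthresholded
#' variant in which negative activity is also assigned). Repeating the
#' analysis with D2 removed from the subset emulates the classical
#' deafferentation analysis in which the deprived finger cannot be probed —
#' and, because finger tuning overlaps, mechanically reassigns part of the
#' deprived cluster to the neighbouring fingers even without any cortical
#' change.
#'
#' Counts are reported for the voxels of \code{target_cluster}: per finger,
#' plus the grouped counts used in the deprived-cluster comparison (the
#' blocked finger when included; its neighbours; its non-neighbours; and
#' non-active voxels, so the groups partition the cluster).
#'
#' @param contrasts a [compute_contrasts()] result or 5 x voxel
#'   finger-vs-rest matrix.
#' @param clusters a \code{cluster_map}.
#' @param finger_subset nonempty subset of \code{D1..D5} to assign among.
#' @param target_cluster cluster whose composition is counted.
#' @param threshold_positive require the maximal contrast to exceed 0.
#' @return an object of class \code{"winner_map"}: list with
#'   \code{assignment} (factor over voxels, levels the subset, NA =
#'   non-active), \code{counts} (per finger within the target cluster),
#'   \code{groups} (blocked / neighbors / non_neighbors / nonactive counts),
#'   \code{subset}, \code{target_cluster}.
#' @export
winner_map_counts <- function(contrasts, clusters,
                              finger_subset = finger_labels(),
                              target_cluster = "C2",
                              threshold_positive = TRUE) {
  A <- if (inherits(contrasts, "contrast_set")) finger_vs_rest(contrasts)
       else as.matrix(contrasts)
  stopifnot(inherits(clusters, "cluster_map"))
  if (length(finger_subset) == 0)
    stop("configuration error: empty finger subset")
  if (!all(finger_subset %in% finger_labels()))
    stop("configuration error: unknown fingers in subset")
  finger_subset <- finger_labels()[finger_labels() %in% finger_subset]
  As <- A[finger_subset, , drop = FALSE]
  ## which.max over rows breaks ties toward the lowest finger index
  win_idx <- apply(As, 2, which.max)
  win <- finger_subset[win_idx]
  if (threshold_positive) {
    mx <- apply(As, 2, max)
    win[mx <= 0] <- NA
  }
  assignment <- factor(win, levels = finger_subset)
  target_finger <- sub("C", "D", target_cluster)
  vox <- cluster_voxels(clusters, target_cluster)
  counts <- table(assignment[vox], useNA = "no")
  ti <- match(target_finger, finger_labels())
  neigh <- finger_labels()[abs(seq_len(5) - ti) == 1]
  nonneigh <- finger_labels()[abs(seq_len(5) - ti) > 1]
  cnt <- function(set) sum(counts[intersect(set, names(counts))])
  groups <- c(
    blocked = if (target_finger %in% finger_subset) cnt(target_finger)
              else NA_integer_,
    neighbors = cnt(neigh),
    non_neighbors = cnt(nonneigh),
    nonactive = sum(vox) - sum(counts)
  )
  structure(list(assignment = assignment, counts = counts, groups = groups,
                 subset = finger_subset, target_cluster = target_cluster,
                 threshold_positive = threshold_positive,
                 cluster_size = sum(vox)),
            class = "winner_map")
}

#' @export
print.winner_map <- function(x, ...) {
  cat("Winner-takes-all map over {", paste(x$subset, collapse = ", "),
      "}", if (!x$threshold_positive) " (unthresholded)", "\n", sep = "")
  cat("  ", x$target_cluster, " composition (", x$cluster_size,
      " voxels):\n", sep = "")
  print(x$counts)
  cat("  groups: blocked =", x$groups["blocked"],
      ", neighbors =", x$groups["neighbors"],
      ", non-neighbors =", x$groups["non_neighbors"],
      ", non-active =", x$groups["nonactive"], "\n")
  invisible(x)
}
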