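make_clusters <- function(labels) {
  structure(list(label = factor(labels, levels = cluster_labels()),
                 mask = rep(TRUE, length(labels)),
                 sizes = table(factor(labels, levels = cluster_labels())),
                 q = NA_real_),
            class = "cluster_map")
}

test_that("cluster activity tables are voxel means per cluster", {
  A <- matrix(7, 5, 6, dimnames = list(finger_labels(), NULL))
  cl <- make_clusters(rep(c("C1", "C2", "C3"), each = 2))
  tab <- cluster_activity(A, cl)
  expect_equal(unname(tab[, "C1"]), rep(7, 5))
  # empty clusters are flagged missing, not zero
  expect_true(all(is.na(tab[, "C4"])))

  A2 <- A; A2["D3", 3:4] <- c(1, 3)
  expect_equal(unname(cluster_activity(A2, cl)["D3", "C2"]), 2)

  # permutation invariance under voxel reordering
  set.seed(1)
  A3 <- matrix(rnorm(30), 5, 6, dimnames = list(finger_labels(), NULL))
  perm <- sample(6)
  cl_p <- make_clusters(rep(c("C1", "C2", "C3"), each = 2)[perm])
  expect_equal(cluster_activity(A3[, perm], cl_p),
               cluster_activity(A3, cl))
})

test_that("selectivity subtracts nontarget means with exclusions", {
  tab <- matrix(1, 5, 5, dimnames = list(finger_labels(),
                                         cluster_labels()))
  class(tab) <- c("activity_table", "matrix", "array")
  # uniform table: zero selectivity, excluded cluster absent
  s <- cluster_selectivity(tab)
  expect_equal(unname(s), rep(0, 4))
  expect_named(s, c("C1", "C3", "C4", "C5"))

  # hand arithmetic: target 2.0, nontargets (1.0, 0.5, 0.0) after exclusion
  tab2 <- tab
  tab2[, "C3"] <- c(1.0, 9, 2.0, 0.5, 0.0)  # D2 = 9 must be ignored
  expect_equal(unname(cluster_selectivity(tab2)["C3"]), 2.0 - 0.5)

  # excluding a retained cluster's target finger is a definition error
  expect_error(cluster_selectivity(tab, exclude_finger = "D2",
                                   exclude_cluster = "C3"),
               "definition error")
})

test_that("winner-takes-all assignment, thresholding and partition", {
  A <- cbind(c(1, 0, 0, 0, 0), c(-1, -2, -3, -4, -5), c(0, 2, 1, 0, 0))
  rownames(A) <- finger_labels()
  cl <- make_clusters(c("C2", "C2", "C2"))
  wm <- winner_map_counts(A, cl)
  expect_equal(as.character(wm$assignment),
               c("D1", NA, "D2"))
  # counts + non-active partition the cluster
  expect_equal(sum(wm$counts) + wm$groups[["nonactive"]],
               wm$cluster_size)

  # unthresholded variant assigns every voxel
  wmu <- winner_map_counts(A, cl, threshold_positive = FALSE)
  expect_false(anyNA(wmu$assignment))
  expect_equal(as.character(wmu$assignment[2]), "D1")

  # ties break toward the lowest finger index
  At <- matrix(1, 5, 1, dimnames = list(finger_labels(), NULL))
  expect_equal(as.character(winner_map_counts(At, make_clusters("C2"))$
                              assignment), "D1")

  expect_error(winner_map_counts(A, cl, finger_subset = character(0)),
               "configuration error")
})

test_that("subset monotonicity: removing a finger never lowers other counts", {
  cfg <- quiet_cfg(n_voxels = 100L)
  tm <- generate_tuning_map(cfg)
  pat <- generate_session_patterns(tm, "baseline", cfg,
                                   default_drives(cfg)$baseline)
  contr <- compute_contrasts(pat$betas)
  cl <- true_cluster_map(tm)
  full <- winner_map_counts(contr, cl)
  for (drop in finger_labels()) {
    sub <- winner_map_counts(contr, cl,
                             finger_subset = setdiff(finger_labels(), drop))
    keep <- intersect(names(full$counts), names(sub$counts))
    expect_true(all(sub$counts[keep] >= full$counts[keep]))
  }
})

test_that("excluding the blocked finger manufactures 'remapping' at baseline", {
  # the methodological artifact: with overlapping tuning and NO block,
  # a 4-finger winner map already shows neighbours invading C2
  cfg <- quiet_cfg(n_voxels = 150L, seed = 9L)
  tm <- generate_tuning_map(cfg)
  pat <- generate_session_patterns(tm, "baseline", cfg,
                                   default_drives(cfg)$baseline)
  contr <- compute_contrasts(pat$betas)
  cl <- true_cluster_map(tm)
  full <- winner_map_counts(contr, cl)
  excl <- winner_map_counts(contr, cl,
                            finger_subset = setdiff(finger_labels(), "D2"))
  n13_full <- sum(full$counts[c("D1", "D3")])
  n13_excl <- sum(excl$counts[c("D1", "D3")])
  expect_gt(n13_excl, n13_full)
})

test_that("a global gain below one lowers selectivity in every cluster", {
  cfg <- noiseless_cfg(n_voxels = 100L)
  tm <- generate_tuning_map(cfg)
  drv <- default_drives(cfg)
  cl <- true_cluster_map(tm)
  base <- cluster_activity(compute_contrasts(
    generate_session_patterns(tm, "baseline", cfg, drv$baseline)$betas), cl)
  blk <- cluster_activity(compute_contrasts(
    generate_session_patterns(tm, "block", cfg, drv$block)$betas), cl)
  sel_b <- cluster_selectivity(base)
  sel_k <- cluster_selectivity(blk)
  expect_true(all(sel_k < sel_b))
})
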