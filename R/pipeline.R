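## run one pipeline stage, rethrowing errors tagged with the stage name
run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

mat_long <- function(m, value = "value") {
  df <- as.data.frame(as.table(m), stringsAsFactors = FALSE)
  names(df) <- c(names(dimnames(m)) %||% c("row", "col"), value)[1:3]
  df
}

rdm_long <- function(r) {
  labs <- rownames(r)
  idx <- which(lower.tri(r), arr.ind = TRUE)
  data.frame(condition_i = labs[idx[, 2]], condition_j = labs[idx[, 1]],
             distance = unclass(r)[idx])
}

#' Run the full synthetic study end-to-end
#'
#' Executes every stage in dependency order for each simulated participant:
#' peripheral drives (with and without the nerve block), tuning map,
#' traveling-wave localizer runs and FDR-thresholded cluster definition,
#' session activity patterns, contrasts, univariate activity / selectivity /
#' winner-takes-all remapping analyses under both finger subsets,
#' cross-nobis RSA with session-change summaries and group MDS, the
#' cortical-model fits (baseline fit, static-block prediction, homeostatic
#' gain fit) on the group-mean activity, and Weibull psychometric fits per
#' session. All randomness derives from the master seed via [child_seed()],
#' so identical configurations regenerate bit-identical outputs.
#'
#' When \code{out_dir} is given, every intermediate table is written as a
#' delimited file under one directory per participant/session, together
#' with a \code{manifest.json} listing each output file with its MD5
#' content hash, the seeds used and the package version, plus a top-level
#' \code{summary.json}.
#'
#' @param config a [study_config()].
#' @param out_dir output directory, or \code{NULL} to skip writing.
#' @param q FDR level for cluster definition.
#' @param psych_thresholds generating 82\%-thresholds (mm) for the baseline
#'   and block psychophysics of the blocked finger.
#' @param psych_slope generating Weibull shape.
#' @param verbose print stage progress.
#' @return an object of class \code{"somatomap_study"}: a list with
#'   per-participant results, group-level summaries and the config.
#' @export
run_pipeline <- function(config = study_config(), out_dir = NULL,
                         q = 0.01,
                         psych_thresholds = c(baseline = 1.5, block = 12),
                         psych_slope = 2, verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  say <- function(...) if (verbose) message(...)

  say("simulate: peripheral drives")
  spread <- run_stage("peripheral", build_spread(config$spread_lambda))
  drives_base <- peripheral_drives(spread, "baseline")
  drives_block <- run_stage("peripheral",
    peripheral_drives(spread, "block", config$blocked_finger,
                      config$block_fraction))

  refs <- run_stage("localize",
    build_reference_models(tr = config$tr_seconds, on = config$on_seconds,
                           off = config$off_seconds, n_fingers = 5,
                           n_cycles = config$n_cycles))

  participants <- vector("list", config$n_participants)
  for (p in seq_len(config$n_participants)) {
    say("participant ", p)
    tuning <- run_stage("simulate",
      generate_tuning_map(config, child_seed(config$seed, p, 1L)))

    ## localizer: one forward + one backward wave run
    waves <- run_stage("simulate", list(
      generate_wave_run(tuning, config, "forward", p, 1L),
      generate_wave_run(tuning, config, "backward", p, 2L)))
    cmap <- run_stage("localize", correlate_voxels(waves, refs))
    clusters <- run_stage("localize", define_clusters(cmap, q = q))

    sessions <- list()
    for (sess in c("baseline", "block")) {
      drv <- if (sess == "baseline") drives_base else drives_block
      pat <- run_stage("simulate",
        generate_session_patterns(tuning, sess, config, drv, p))
      contr <- run_stage("glm", compute_contrasts(pat$betas))
      act <- run_stage("map", cluster_activity(contr, clusters))
      sel <- run_stage("map",
        cluster_selectivity(act, config$blocked_finger,
                            sub("D", "C", config$blocked_finger)))
      wm5 <- run_stage("map", winner_map_counts(contr, clusters))
      wm4 <- run_stage("map",
        winner_map_counts(contr, clusters,
                          setdiff(finger_labels(), config$blocked_finger)))
      wh <- run_stage("rsa", noise_whitener(pat$residuals))
      rdm <- run_stage("rsa", crossnobis_rdm(pat, wh, include_rest = TRUE))
      sessions[[sess]] <- list(patterns = pat, contrasts = contr,
                               activity = act, selectivity = sel,
                               winner_full = wm5, winner_excl = wm4,
                               rdm = rdm)
    }
    change <- run_stage("rsa",
      rdm_session_change(sessions$baseline$rdm, sessions$block$rdm,
                         blocked_finger = config$blocked_finger))
    participants[[p]] <- list(tuning = tuning, clusters = clusters,
                              sessions = sessions, rdm_change = change)
  }

  say("group: MDS, cortical model, psychophysics")
  mds <- run_stage("rsa",
    mds_group(lapply(participants,
                     function(pp) pp$sessions$baseline$rdm)))

  mean_table <- function(sess) {
    tabs <- lapply(participants, function(pp) pp$sessions[[sess]]$activity)
    Reduce("+", tabs) / length(tabs)
  }
  act_base <- mean_table("baseline")
  act_block <- mean_table("block")
  model <- run_stage("model", fit_cortical_model(act_base, drives_base))
  static <- run_stage("model", predict_static_block(model, drives_block))
  gains <- run_stage("model",
    fit_gains(model, drives_block, act_block,
              blocked_finger = config$blocked_finger))

  psych <- list()
  for (sess in c("baseline", "block")) {
    trials <- run_stage("psychophys",
      generate_psychophys_trials(psych_thresholds[[sess]], psych_slope,
                                 seed = child_seed(config$seed, 0L,
                                                   30L + (sess == "block")),
                                 finger = config$blocked_finger))
    psych[[sess]] <- list(trials = trials,
                          fit = run_stage("psychophys",
                                          fit_weibull(trials)))
  }

  study <- structure(
    list(config = config, spread = spread,
         drives = list(baseline = drives_base, block = drives_block),
         reference_models = refs, participants = participants,
         mds = mds, model = model, static_block = static, gains = gains,
         psychophys = psych,
         counts = list(n_reference_models = refs$n_lags,
                       n_contrasts = nrow(contrast_weights()),
                       n_clusters = length(cluster_labels()))),
    class = "somatomap_study")
  if (!is.null(out_dir)) write_study(study, out_dir)
  study
}

#' Write a study's tables and manifest to disk
#'
#' @param study a [run_pipeline()] result.
#' @param out_dir output directory (created if missing).
#' @return \code{out_dir}, invisibly.
#' @export
write_study <- function(study, out_dir) {
  stopifnot(inherits(study, "somatomap_study"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  add <- function(path) files <<- c(files, path)
  cfg <- study$config
  add(write_study_config(cfg, file.path(out_dir, "config.json")))
  add(write_tsv(mat_long(unclass(study$drives$baseline), "drive"),
                file.path(out_dir, "drives_baseline.tsv")))
  add(write_tsv(mat_long(unclass(study$drives$block), "drive"),
                file.path(out_dir, "drives_block.tsv")))
  for (p in seq_along(study$participants)) {
    pp <- study$participants[[p]]
    pdir <- file.path(out_dir, sprintf("participant%02d", p))
    dir.create(pdir, showWarnings = FALSE)
    add(write_tsv(data.frame(voxel = seq_along(pp$tuning$voxel_positions),
                             position = pp$tuning$voxel_positions,
                             true_cluster = pp$tuning$true_cluster_label,
                             cluster = as.character(pp$clusters$label)),
                  file.path(pdir, "voxels.tsv")))
    for (sess in names(pp$sessions)) {
      ss <- pp$sessions[[sess]]
      sdir <- file.path(pdir, sess)
      dir.create(sdir, showWarnings = FALSE)
      betas <- do.call(rbind, lapply(seq_along(ss$patterns$betas),
        function(r) {
          df <- mat_long(ss$patterns$betas[[r]], "beta")
          names(df)[1:2] <- c("condition", "voxel")
          df$voxel <- as.integer(factor(df$voxel,
                                        levels = unique(df$voxel)))
          cbind(run = r, df)
        }))
      add(write_tsv(betas, file.path(sdir, "betas.tsv")))
      add(write_tsv(mat_long(unclass(ss$activity), "activity"),
                    file.path(sdir, "activity.tsv")))
      add(write_tsv(data.frame(cluster = names(ss$selectivity),
                               selectivity = as.numeric(ss$selectivity)),
                    file.path(sdir, "selectivity.tsv")))
      wcounts <- rbind(
        data.frame(subset = "five_finger",
                   group = names(ss$winner_full$groups),
                   count = as.integer(ss$winner_full$groups)),
        data.frame(subset = "exclude_blocked",
                   group = names(ss$winner_excl$groups),
                   count = as.integer(ss$winner_excl$groups)))
      add(write_tsv(wcounts, file.path(sdir, "winner_counts.tsv")))
      add(write_tsv(rdm_long(ss$rdm), file.path(sdir, "rdm.tsv")))
    }
  }
  ch <- study$participants[[1]]$rdm_change
  group <- data.frame(
    measure = c("pct_change_all", "pct_change_nonblocked",
                "spearman_canonical", "gain_global", "gain_blocked",
                "psych_threshold_baseline", "psych_threshold_block"),
    value = c(mean(vapply(study$participants,
                          function(pp) pp$rdm_change$pct_change_all, 0)),
              mean(vapply(study$participants,
                          function(pp) pp$rdm_change$pct_change_nonblocked,
                          0)),
              mean(vapply(study$participants,
                          function(pp) pp$rdm_change$spearman_canonical,
                          0)),
              study$gains$gain_global, study$gains$gain_blocked,
              study$psychophys$baseline$fit$threshold,
              study$psychophys$block$fit$threshold))
  add(write_tsv(group, file.path(out_dir, "summary.tsv")))
  add(write_tsv(mat_long(study$model$W, "weight"),
                file.path(out_dir, "model_weights.tsv")))
  rel <- sub(paste0("^", gsub("([][{}()+*^$\\\\.|?])", "\\\\\\1", out_dir),
                    "/?"), "", files)
  manifest <- list(
    package = "somatomap",
    version = as.character(utils::packageVersion("somatomap")),
    master_seed = cfg$seed,
    counts = study$counts,
    files = lapply(seq_along(files), function(i)
      list(path = rel[i], md5 = unname(tools::md5sum(files[i]))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.somatomap_study <- function(x, ...) {
  cat("Synthetic nerve-block study:", x$config$n_participants,
      "participant(s),", x$config$n_voxels, "voxels, seed",
      x$config$seed, "\n")
  cat("  reference models:", x$counts$n_reference_models,
      " contrasts:", x$counts$n_contrasts, "\n")
  cat(sprintf("  mean interfinger dissimilarity change: %+.1f%%\n",
              mean(vapply(x$participants,
                          function(pp) pp$rdm_change$pct_change_all, 0))))
  cat(sprintf("  recovered gains: shared %.3f, blocked %.3f\n",
              x$gains$gain_global, x$gains$gain_blocked))
  cat(sprintf("  tactile threshold: %.2f mm (baseline) -> %.2f mm (block%s)\n",
              x$psychophys$baseline$fit$threshold,
              x$psychophys$block$fit$threshold,
              if (x$psychophys$block$fit$extrapolated)
                ", extrapolated" else ""))
  invisible(x)
}
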