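# End-to-end orchestration: simulate -> preprocess -> ERP scores -> TF scores
# -> RSA -> statistics, with a machine-readable summary.

#' Pipeline configuration
#'
#' Bundles every stage's parameters; each stochastic stage receives a
#' deterministic child seed derived from `seed`, so reruns with the same
#' config are identical at the table level.
#'
#' @param design [design_spec()].
#' @param effects [effect_spec()].
#' @param noise [noise_spec()].
#' @param seed master integer seed.
#' @param rules artifact-rejection rules to apply.
#' @param filter list(lo, hi, order) or NULL to skip filtering.
#' @param erp_window,baseline_window ERP epoch view and baseline (ms).
#' @param measures named list of [measure_spec()].
#' @param bank [wavelet_bank()].
#' @param tf_measures named list of band-power definitions
#'   (list(band, window, roi)).
#' @param weld_window welding-baseline window (ms).
#' @param rsa list(time_window, n_perm, alpha_cluster, shrinkage).
#' @param reliability list(n_splits) for split-half reliability.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(design = design_spec(),
                            effects = default_effects(),
                            noise = default_noise(),
                            seed = 1,
                            rules = c("step", "range", "flatline", "drift"),
                            filter = list(lo = 0.1, hi = 35, order = 2),
                            erp_window = c(-200, 1000),
                            baseline_window = c(-200, 0),
                            measures = default_erp_measures(),
                            bank = wavelet_bank(),
                            tf_measures = list(
                              theta = list(band = c(4, 7),
                                           window = c(150, 450), roi = "FCz"),
                              delta = list(band = c(1, 3),
                                           window = c(200, 500), roi = "CPz")),
                            weld_window = c(-500, -300),
                            rsa = list(time_window = c(-200, 1000),
                                       n_perm = 1000, alpha_cluster = 0.05,
                                       shrinkage = "lw"),
                            reliability = list(n_splits = 20)) {
  structure(list(design = design, effects = effects, noise = noise,
                 seed = seed, rules = rules, filter = filter,
                 erp_window = erp_window, baseline_window = baseline_window,
                 measures = measures, bank = bank, tf_measures = tf_measures,
                 weld_window = weld_window, rsa = rsa,
                 reliability = reliability),
            class = "pipeline_config")
}

#' Run the full pipeline on a simulated cohort
#'
#' Per participant: simulate, reject artifacts (on the raw epochs, whose
#' thresholds refer to raw voltages), band-pass filter, re-reference to the
#' averaged mastoids, baseline-subtract the ERP view and score the ERP
#' measures, Morlet-transform and weld the band-power measures, and compute
#' the RDM-regression coding series (full design and split by reward time).
#' Then: mixed models and contrasts per measure, rating ANOVA, split-half
#' reliabilities, magnitude-effect correlations with a family-wise FDR, and
#' cluster-based permutation tests on the coding series.
#'
#' @param cfg [pipeline_config()].
#' @param out_dir optional directory for CSV tables and `summary.json`.
#' @param progress print per-participant progress.
#' @return list of class `pipeline_result` (also serialized as JSON when
#'   `out_dir` is given).
#' @export
run_pipeline <- function(cfg, out_dir = NULL, progress = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  np <- cfg$design$n_participants
  tf_channels <- unique(unlist(lapply(cfg$tf_measures, `[[`, "roi")))
  scores_all <- list()
  ratings_all <- list()
  coding_full <- list()
  coding_split <- list()
  retained <- numeric(np)
  for (i in seq_len(np)) {
    sim <- simulate_participant(cfg$design, cfg$effects, cfg$noise,
                                seed = child_seed(cfg$seed, i),
                                participant_id = sprintf("P%02d", i))
    rej <- reject_artifacts(sim$epochs, rules = cfg$rules)
    retained[i] <- attr(rej$report, "retained_fraction")
    e <- rej$epochs
    if (!is.null(cfg$filter))
      e <- filter_bandpass(e, cfg$filter$lo, cfg$filter$hi, cfg$filter$order)
    if (all(c("M1", "M2") %in% e$channels$name))
      e <- rereference_mastoids(e)
    erp_e <- baseline_subtract(subset_epochs(e, time_window = cfg$erp_window),
                               cfg$baseline_window)
    for (m in cfg$measures)
      scores_all[[paste(i, m$name)]] <- score_single_trial(erp_e, m)
    if (length(cfg$tf_measures)) {
      tf_crop <- c(cfg$weld_window[1] - 100,
                   max(vapply(cfg$tf_measures,
                              function(tm) tm$window[2], 0)) + 100)
      tf <- morlet_transform(e, cfg$bank, channels = tf_channels,
                             crop = tf_crop)
      tf <- weld_baseline(tf, cfg$weld_window)
      for (nm in names(cfg$tf_measures)) {
        tm <- cfg$tf_measures[[nm]]
        scores_all[[paste(i, nm)]] <-
          score_band_power(tf, tm$band, tm$window, tm$roi, name = nm)
      }
      rm(tf)
    }
    nr <- neural_rdm(erp_e, shrinkage = cfg$rsa$shrinkage,
                     time_window = cfg$rsa$time_window)
    coding_full[[i]] <- rdm_regression(nr, model_rdms())
    coding_split[[i]] <- rsa_by_time_condition(
      erp_e, shrinkage = cfg$rsa$shrinkage,
      time_window = cfg$rsa$time_window)
    ratings_all[[i]] <- sim$ratings
    if (progress) message("participant ", i, "/", np, " done")
  }
  scores <- do.call(rbind, scores_all)
  ratings <- do.call(rbind, ratings_all)

  fits <- list(); contrasts <- list(); reliab <- list()
  for (nm in unique(scores$measure)) {
    sc <- scores[scores$measure == nm, ]
    fits[[nm]] <- fit_mixed(sc)
    contrasts[[nm]] <- list(
      simple_magnitude = emm_contrasts(fits[[nm]], "simple_magnitude"),
      ben_mag_within_time = emm_contrasts(fits[[nm]], "ben_mag_within_time"))
    reliab[[nm]] <- split_half_reliability(
      sc, n_splits = cfg$reliability$n_splits,
      seed = child_seed(cfg$seed, 7001))
  }
  anova_ratings <- rm_anova(ratings)

  cor_measures <- intersect(c("rewp", "p3", "delta"), unique(scores$measure))
  cors <- list()
  for (nm in cor_measures)
    cors[[nm]] <- magnitude_effect_correlations(scores[scores$measure == nm, ])
  rating_scores <- data.frame(participant = ratings$participant,
                              beneficiary = ratings$beneficiary,
                              magnitude = ratings$magnitude,
                              time = ratings$time, value = ratings$rating,
                              stringsAsFactors = FALSE)
  cors[["rating"]] <- magnitude_effect_correlations(rating_scores)
  # one FDR family across the measures' immediate+delayed correlation ps
  praw <- unlist(lapply(cors, function(x) c(x$p_immediate, x$p_delayed)))
  padj <- fdr_adjust(praw)
  k <- 0
  for (nm in names(cors)) {
    cors[[nm]]$p_immediate_fdr <- padj[k + 1]
    cors[[nm]]$p_delayed_fdr <- padj[k + 2]
    k <- k + 2
  }

  times_rsa <- coding_full[[1]]$times
  clusters <- list()
  for (pred in c("beneficiary", "magnitude", "time"))
    clusters[[pred]] <- cluster_permutation(
      stack_coding(coding_full, pred), times_rsa,
      n_perm = cfg$rsa$n_perm, alpha_cluster = cfg$rsa$alpha_cluster,
      seed = child_seed(cfg$seed, 8001))
  clusters_split <- list()
  for (lv in c("immediate", "delayed")) {
    series <- lapply(coding_split, `[[`, lv)
    for (pred in c("beneficiary", "magnitude"))
      clusters_split[[paste(lv, pred, sep = ".")]] <- cluster_permutation(
        stack_coding(series, pred), times_rsa,
        n_perm = cfg$rsa$n_perm, alpha_cluster = cfg$rsa$alpha_cluster,
        seed = child_seed(cfg$seed, 8002))
  }

  res <- structure(list(
    scores = scores, ratings = ratings, retained_fraction = mean(retained),
    fits = fits, contrasts = contrasts, reliability = reliab,
    anova_ratings = anova_ratings, correlations = cors,
    clusters = clusters, clusters_split = clusters_split,
    coding_times = times_rsa, seed = cfg$seed,
    config_version = "1.0"), class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(res, out_dir)
  res
}

cluster_table <- function(cl) {
  if (!nrow(cl$clusters)) return(cl$clusters)
  cbind(cluster_id = seq_len(nrow(cl$clusters)), cl$clusters)
}

#' Serialize a pipeline result (CSV tables + summary JSON)
#' @param res pipeline_result.
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_result <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(res$scores, file.path(out_dir, "scores.csv"),
                   row.names = FALSE)
  utils::write.csv(res$ratings, file.path(out_dir, "ratings.csv"),
                   row.names = FALSE)
  for (nm in names(res$fits))
    utils::write.csv(res$fits[[nm]]$fixed,
                     file.path(out_dir, paste0("fixed_", nm, ".csv")),
                     row.names = FALSE)
  allcl <- c(res$clusters, res$clusters_split)
  cl_rows <- do.call(rbind, lapply(names(allcl), function(nm) {
    tb <- cluster_table(allcl[[nm]])
    if (!nrow(tb)) return(NULL)
    cbind(series = nm, tb)
  }))
  if (!is.null(cl_rows))
    utils::write.csv(cl_rows, file.path(out_dir, "clusters.csv"),
                     row.names = FALSE)
  summary <- pipeline_summary(res)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' Machine-readable summary of a pipeline result
#' @param res pipeline_result.
#' @return nested list (JSON-ready).
#' @export
pipeline_summary <- function(res) {
  list(
    schema_version = "1.0",
    seed = res$seed,
    retained_fraction = res$retained_fraction,
    fixed_effects = lapply(res$fits, function(f)
      stats::setNames(as.list(f$fixed$estimate), f$fixed$term)),
    reliability = res$reliability,
    anova_ratings = stats::setNames(
      lapply(seq_len(nrow(res$anova_ratings)), function(i)
        list(F = res$anova_ratings$F[i], p = res$anova_ratings$p[i],
             pes = res$anova_ratings$pes[i])),
      res$anova_ratings$term),
    correlations = lapply(res$correlations, function(x)
      list(r_immediate = x$r_immediate, r_delayed = x$r_delayed,
           z = x$z, p_comparison = x$p_comparison)),
    clusters = lapply(c(res$clusters, res$clusters_split), function(cl)
      lapply(seq_len(nrow(cl$clusters)), function(i) as.list(cl$clusters[i, ])))
  )
}

#' Plot grand-averaged waveforms for a channel (best-effort base graphics)
#' @param ga result of [grand_average()].
#' @param channel channel name.
#' @param file optional PNG path.
#' @export
plot_grand_average <- function(ga, channel, file = NULL) {
  ci <- match(channel, ga$channels$name)
  if (is.na(ci)) stop("channel not present: ", channel)
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 600)
    on.exit(grDevices::dev.off())
  }
  y <- t(ga$mean[, ci, ])
  graphics::matplot(ga$times, y, type = "l", lty = 1,
                    xlab = "time (ms)", ylab = "amplitude (uV)",
                    main = paste("Grand average at", channel))
  graphics::legend("topright", legend = paste(ga$cells$beneficiary,
                                              ga$cells$magnitude,
                                              ga$cells$time, sep = "."),
                   col = seq_len(8), lty = 1, cex = 0.7)
  invisible(ga)
}
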