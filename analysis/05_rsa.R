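#!/usr/bin/env Rscript
# Time-resolved RSA: Mahalanobis neural RDMs over the scalp channels,
# z-scored model-RDM regression per participant, cluster-based permutation
# inference for the full design and split by reward time.

suppressPackageStartupMessages(library(prosorew))

clean_dir <- file.path("scratch", "clean")
participants <- sort(list.dirs(clean_dir, recursive = FALSE))
stopifnot(length(participants) > 0)

coding_full <- list()
coding_split <- list()
for (p in participants) {
  e <- read_epochs(p, "internal")
  erp <- baseline_subtract(subset_epochs(e, time_window = c(-200, 1000)),
                           c(-200, 0))
  nr <- neural_rdm(erp)             # pooled-residual covariance, LW shrinkage
  coding_full[[p]] <- rdm_regression(nr, model_rdms())
  coding_split[[p]] <- rsa_by_time_condition(erp)
  cat(".")
}
cat("\n")

times <- coding_full[[1]]$times
rows <- list()
run_cluster <- function(series_list, predictor, label, seed) {
  cl <- cluster_permutation(stack_coding(series_list, predictor), times,
                            n_perm = 1000, seed = seed)
  tab <- cl$clusters
  if (nrow(tab)) rows[[label]] <<- cbind(series = label,
                                         cluster_id = seq_len(nrow(tab)), tab)
  sig <- tab[tab$p < 0.05, , drop = FALSE]
  if (nrow(sig))
    cat(sprintf("%s: cluster %g-%g ms, p = %.3f\n", label,
                sig$t_start_ms[1], sig$t_end_ms[1], sig$p[1]))
  else cat(sprintf("%s: no significant cluster\n", label))
}

for (pred in c("beneficiary", "magnitude", "time"))
  run_cluster(coding_full, pred, paste0("full.", pred), seed = 31)
for (lv in c("immediate", "delayed")) {
  series <- lapply(coding_split, `[[`, lv)
  for (pred in c("beneficiary", "magnitude"))
    run_cluster(series, pred, paste(lv, pred, sep = "."), seed = 32)
}

write.csv(do.call(rbind, rows), file.path("results", "rsa_clusters.csv"),
          row.names = FALSE)
cat("Cluster table written to results/rsa_clusters.csv\n")
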