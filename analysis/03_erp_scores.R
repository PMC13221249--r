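#!/usr/bin/env Rscript
# Single-trial RewP and P3 mean amplitudes on baseline-subtracted ERP epochs,
# split-half reliabilities, and the grand-average waveform figure.

suppressPackageStartupMessages(library(prosorew))

clean_dir <- file.path("scratch", "clean")
participants <- sort(list.dirs(clean_dir, recursive = FALSE))
stopifnot(length(participants) > 0)

measures <- default_erp_measures()
scores <- list()
erp_sets <- list()
for (p in participants) {
  e <- read_epochs(p, "internal")
  erp <- baseline_subtract(subset_epochs(e, time_window = c(-200, 1000)),
                           c(-200, 0))
  erp_sets[[p]] <- erp
  for (m in measures)
    scores[[paste(p, m$name)]] <- score_single_trial(erp, m)
}
scores <- do.call(rbind, scores)
write.csv(scores, file.path("results", "erp_scores.csv"), row.names = FALSE)

for (nm in names(measures)) {
  r <- split_half_reliability(scores[scores$measure == nm, ],
                              n_splits = 50, seed = 7)
  cat(sprintf("%s split-half reliability (Spearman-Brown): r = %.3f\n", nm, r))
}

ga <- grand_average(erp_sets)
plot_grand_average(ga, "FCz", file = file.path("results", "grand_average_FCz.png"))
plot_grand_average(ga, "Pz", file = file.path("results", "grand_average_Pz.png"))
cat("Grand-average figures written to results/\n")
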