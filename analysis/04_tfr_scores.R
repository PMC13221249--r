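#!/usr/bin/env Rscript
# Morlet decomposition at the scoring channels, welding-baseline
# normalization, and single-trial theta/delta power scores.

suppressPackageStartupMessages(library(prosorew))

clean_dir <- file.path("scratch", "clean")
participants <- sort(list.dirs(clean_dir, recursive = FALSE))
stopifnot(length(participants) > 0)

bank <- wavelet_bank()        # 1-30 Hz, 30 log steps, cycles 3-10
bands <- list(
  theta = list(band = c(4, 7), window = c(150, 450), roi = "FCz"),
  delta = list(band = c(1, 3), window = c(200, 500), roi = "CPz"))

scores <- list()
for (p in participants) {
  e <- read_epochs(p, "internal")
  tf <- morlet_transform(e, bank, channels = c("FCz", "CPz"),
                         crop = c(-600, 1000))
  tf <- weld_baseline(tf, c(-500, -300))
  for (nm in names(bands)) {
    b <- bands[[nm]]
    scores[[paste(p, nm)]] <- score_band_power(tf, b$band, b$window, b$roi,
                                               name = nm)
  }
  cat(".")
}
cat("\n")
scores <- do.call(rbind, scores)
write.csv(scores, file.path("results", "tf_scores.csv"), row.names = FALSE)
for (nm in names(bands))
  cat(sprintf("%s welded-z grand mean: %.3f\n", nm,
              mean(scores$value[scores$measure == nm])))
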