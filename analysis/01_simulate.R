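#!/usr/bin/env Rscript
# Simulate the study cohort and persist it for the downstream analysis steps.
# Epoch containers are bulky and go under scratch/ (regenerable); the rating
# table and the ground-truth coefficients go under results/.

suppressPackageStartupMessages(library(prosorew))

seed <- 20260101
cohort_dir <- file.path("scratch", "cohort")
dir.create(cohort_dir, showWarnings = FALSE, recursive = TRUE)
dir.create("results", showWarnings = FALSE)

# 16 participants at 16 trials/cell keeps the whole workflow interactive;
# scripts/acceptance.R runs the full 40 x 40 cohort
design <- design_spec(n_participants = 16, n_trials_per_cell = 16,
                      sampling_rate = 250, epoch_window = c(-1500, 2000),
                      layout = standard_layout())
effects <- default_effects()
noise <- default_noise()

cat(sprintf("Simulating %d participants x %d trials at %g Hz...\n",
            design$n_participants, design$n_trials_per_cell * 8,
            design$sampling_rate))

ratings <- list()
truth <- list()
for (i in seq_len(design$n_participants)) {
  bundle <- simulate_participant(design, effects, noise,
                                 seed = child_seed(seed, i),
                                 participant_id = sprintf("P%02d", i))
  write_epochs(bundle$epochs, file.path(cohort_dir, sprintf("P%02d", i)))
  ratings[[i]] <- bundle$ratings
  truth[[i]] <- data.frame(participant = sprintf("P%02d", i),
                           family = rep(names(bundle$truth$coefficients),
                                        each = 8),
                           term = rep(colnames(design_matrix_terms()),
                                      times = length(bundle$truth$coefficients)),
                           coefficient = unlist(bundle$truth$coefficients))
  cat(".")
}
cat("\n")

write.csv(do.call(rbind, ratings), file.path("results", "ratings.csv"),
          row.names = FALSE)
write.csv(do.call(rbind, truth),
          file.path("results", "ground_truth_coefficients.csv"),
          row.names = FALSE)
cat("Cohort written to", cohort_dir, "\n")
cat("Population RewP magnitude coefficient (ground truth):",
    effects$components$rewp$beta[3], "uV\n")
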