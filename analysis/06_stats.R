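#!/usr/bin/env Rscript
# The factorial statistical layer on the scored cohort: coded mixed-effects
# models per measure, EMM simple magnitude effects and interaction contrasts
# with FDR, the rating ANOVA, and the self-other magnitude-effect
# correlations with a dependent-correlation comparison.

suppressPackageStartupMessages(library(prosorew))

erp <- read.csv(file.path("results", "erp_scores.csv"))
tf <- read.csv(file.path("results", "tf_scores.csv"))
ratings <- read.csv(file.path("results", "ratings.csv"))
scores <- rbind(erp, tf)

for (nm in unique(scores$measure)) {
  fit <- fit_mixed(scores[scores$measure == nm, ])
  cat("\n==", nm, "==\n")
  print(fit)
  write.csv(fit$fixed, file.path("results", paste0("fixed_", nm, ".csv")),
            row.names = FALSE)
  con <- rbind(emm_contrasts(fit, "simple_magnitude"),
               emm_contrasts(fit, "ben_mag_within_time"))
  write.csv(con, file.path("results", paste0("contrasts_", nm, ".csv")),
            row.names = FALSE)
}

cat("\n== liking ratings: repeated-measures ANOVA ==\n")
av <- rm_anova(ratings)
print(av, digits = 3)
write.csv(av, file.path("results", "anova_ratings.csv"), row.names = FALSE)

cat("\n== self-other magnitude-effect correlations ==\n")
cors <- list()
for (nm in c("rewp", "p3", "delta"))
  cors[[nm]] <- magnitude_effect_correlations(scores[scores$measure == nm, ])
cors[["rating"]] <- magnitude_effect_correlations(
  data.frame(participant = ratings$participant,
             beneficiary = ratings$beneficiary,
             magnitude = ratings$magnitude, time = ratings$time,
             value = ratings$rating))
praw <- unlist(lapply(cors, function(x) c(x$p_immediate, x$p_delayed)))
padj <- fdr_adjust(praw)
tab <- data.frame(measure = names(cors),
                  r_immediate = sapply(cors, `[[`, "r_immediate"),
                  r_delayed = sapply(cors, `[[`, "r_delayed"),
                  p_immediate_fdr = padj[seq(1, 8, by = 2)],
                  p_delayed_fdr = padj[seq(2, 8, by = 2)],
                  z_comparison = sapply(cors, `[[`, "z"),
                  p_comparison = sapply(cors, `[[`, "p_comparison"))
print(tab, digits = 3, row.names = FALSE)
write.csv(tab, file.path("results", "correlations.csv"), row.names = FALSE)
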