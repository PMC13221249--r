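# direct score simulator (no EEG): participant-level coefficients around
# population terms, trial-level Gaussian noise
simulate_scores <- function(np, trials_per_cell, beta, sd_between = 0,
                            sd_trial = 0, seed = 1) {
  set.seed(seed)
  ct <- cell_table()
  do.call(rbind, lapply(seq_len(np), function(p) {
    bp <- beta + rnorm(8) * sd_between
    mu <- terms_to_cells(bp)
    cond <- ct[rep(seq_len(8), each = trials_per_cell), ]
    data.frame(participant = sprintf("P%03d", p), cond,
               value = mu[cond$cell] + rnorm(nrow(cond)) * sd_trial,
               stringsAsFactors = FALSE)
  }))
}

test_that("balanced noiseless data returns the injected coefficients exactly", {
  beta <- c(0, 0, 2, 0, 0, 0, 0, 0)       # magnitude effect 2.0
  sc <- simulate_scores(np = 4, trials_per_cell = 4, beta = beta)
  fit <- fit_mixed(sc)
  est <- stats::setNames(fit$fixed$estimate, fit$fixed$term)
  expect_equal(unname(est["mag"]), 2, tolerance = 1e-9)
  expect_equal(unname(est["ben:mag:tim"]), 0, tolerance = 1e-9)
  expect_true(length(fit$trail) > 0)      # degenerate fit was simplified
})

test_that("a noisy n = 40 cohort recovers the three-way coefficient within 3 SE", {
  beta <- c(5, -2.5, 2.5, -0.6, -1.2, 0, 0, 1.6)
  sc <- simulate_scores(np = 40, trials_per_cell = 10, beta = beta,
                        sd_between = c(1.5), sd_trial = 4, seed = 7)
  fit <- fit_mixed(sc)
  row <- fit$fixed[fit$fixed$term == "ben:mag:tim", ]
  expect_lt(abs(row$estimate - 1.6), 3 * row$se)
  row_mag <- fit$fixed[fit$fixed$term == "mag", ]
  expect_lt(abs(row_mag$estimate - 2.5), 3 * row_mag$se)
  expect_equal(row$t, row$estimate / row$se)
})

test_that("fixed effects match the brute-force cell-means contrasts under balance", {
  sc <- simulate_scores(np = 12, trials_per_cell = 6,
                        beta = c(3, -1, 2, -0.5, 0.8, 0, 0, 1.2),
                        sd_between = 0.5, sd_trial = 2, seed = 8)
  fit <- fit_mixed(sc)
  # oracle: grand cell means -> term coefficients via the coding inverse
  cm <- tapply(sc$value, sc$cell, mean)
  beta_oracle <- cells_to_terms(unname(cm[as.character(1:8)]))
  est <- stats::setNames(fit$fixed$estimate, fit$fixed$term)
  expect_equal(unname(est[names(beta_oracle)]), unname(beta_oracle),
               tolerance = 1e-6)
})

test_that("label permutation drives all effect estimates toward zero", {
  sc <- simulate_scores(np = 10, trials_per_cell = 8,
                        beta = c(4, -2, 2, -1, 1, 0, 0, 1),
                        sd_between = 1, sd_trial = 3, seed = 9)
  set.seed(10)
  perm <- unlist(tapply(seq_len(nrow(sc)), sc$participant,
                        sample, simplify = FALSE))
  cols <- c("beneficiary", "magnitude", "time", "ben", "mag", "tim", "cell")
  sc[cols] <- sc[perm, cols]
  fit <- fit_mixed(sc)
  eff <- fit$fixed[fit$fixed$term != "(Intercept)", ]
  expect_true(all(abs(eff$t) < 4))
})

test_that("simple magnitude effects collapse to the main effect without interactions", {
  V <- diag(1e-4, 8)
  dimnames(V) <- list(prosorew:::.fixed_terms, prosorew:::.fixed_terms)
  fake <- structure(list(
    fixed = data.frame(term = prosorew:::.fixed_terms,
                       estimate = c(1, 0, 2, 0, 0, 0, 0, 0),
                       se = rep(0.01, 8), t = 0, p = 1),
    vcov = V), class = "mixed_fit")
  con <- emm_contrasts(fake, "simple_magnitude")
  expect_equal(con$estimate, rep(2, 4))
})

test_that("contrast sign bookkeeping matches the hand linear combination", {
  V <- diag(0.04, 8)
  dimnames(V) <- list(prosorew:::.fixed_terms, prosorew:::.fixed_terms)
  fake <- structure(list(
    fixed = data.frame(term = prosorew:::.fixed_terms,
                       estimate = c(0, 0, 2, 0, 0, 0, 0, 1),
                       se = rep(0.2, 8), t = 0, p = 1),
    vcov = V), class = "mixed_fit")
  con <- emm_contrasts(fake, "simple_magnitude")
  # effect(b, t) = b_mag + b*t*b_3way with b, t in {-0.5, +0.5}
  hand <- c(2 + 0.25, 2 - 0.25, 2 - 0.25, 2 + 0.25)
  lab <- c("magnitude effect | beneficiary=self, time=immediate",
           "magnitude effect | beneficiary=self, time=delayed",
           "magnitude effect | beneficiary=other, time=immediate",
           "magnitude effect | beneficiary=other, time=delayed")
  expect_equal(stats::setNames(con$estimate, con$contrast)[lab],
               stats::setNames(hand, lab))
  # SE propagation over all four weighted terms (mag, ben:mag, mag:tim, 3way):
  # var = 0.04 * (1 + 0.5^2 + 0.5^2 + 0.25^2)
  expect_equal(con$se, rep(sqrt(0.04 * (1 + 0.25 + 0.25 + 0.0625)), 4),
               tolerance = 1e-10)
  con2 <- emm_contrasts(fake, "ben_mag_within_time")
  expect_equal(con2$estimate, c(-0.5, 0.5))
})

test_that("EMM contrasts agree with the emmeans package on a real fit", {
  sc <- simulate_scores(np = 12, trials_per_cell = 6,
                        beta = c(4, -2, 2.5, -0.5, -1, 0, 0, 1.5),
                        sd_between = 1, sd_trial = 3, seed = 11)
  fit <- fit_mixed(sc)
  con <- emm_contrasts(fit, "simple_magnitude")
  em <- emmeans::emmeans(fit$fit, ~ mag | ben + tim,
                         at = list(ben = c(-0.5, 0.5), mag = c(-0.5, 0.5),
                                   tim = c(-0.5, 0.5)),
                         lmer.df = "asymptotic")
  emc <- as.data.frame(emmeans::contrast(em, method = "revpairwise"))
  # align by (ben, tim) combination
  emc$label <- paste0("magnitude effect | beneficiary=",
                      ifelse(emc$ben < 0, "self", "other"), ", time=",
                      ifelse(emc$tim < 0, "immediate", "delayed"))
  m <- match(con$contrast, emc$label)
  expect_equal(con$estimate, emc$estimate[m], tolerance = 1e-6)
  expect_equal(con$se, emc$SE[m], tolerance = 1e-6)
})

test_that("BH adjustment matches the textbook example and p.adjust ordering", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(fdr_adjust(p), rep(0.04, 4))
  set.seed(18)
  q <- runif(50)
  expect_true(all(fdr_adjust(q) >= q))     # adjusted p >= raw p
})

test_that("rm_anova reproduces the paired-t equivalence and aov cross-check", {
  set.seed(12)
  np <- 15
  ct <- cell_table()
  ratings <- do.call(rbind, lapply(seq_len(np), function(p)
    data.frame(participant = sprintf("P%02d", p), ct,
               rating = rnorm(8, 5, 1))))
  res <- rm_anova(ratings)
  expect_equal(res$df1, rep(1, 7))
  expect_equal(res$df2, rep(np - 1, 7))
  # paired-t equivalence for the magnitude main effect
  lg <- tapply(ratings$rating[ratings$mag > 0],
               ratings$participant[ratings$mag > 0], mean)
  sm <- tapply(ratings$rating[ratings$mag < 0],
               ratings$participant[ratings$mag < 0], mean)
  tt <- stats::t.test(lg - sm)
  expect_equal(res$F[res$term == "mag"], unname(tt$statistic^2),
               tolerance = 1e-10)
  expect_equal(res$p[res$term == "mag"], tt$p.value, tolerance = 1e-10)
  # full aov cross-check with participant-crossed error strata
  ratings$P <- factor(ratings$participant)
  ratings$B <- factor(ratings$beneficiary)
  ratings$M <- factor(ratings$magnitude)
  ratings$Ti <- factor(ratings$time)
  av <- summary(stats::aov(rating ~ B * M * Ti +
                             Error(P / (B * M * Ti)), data = ratings))
  f_aov <- vapply(av[2:8], function(s) s[[1]]$`F value`[1], 0)
  expect_equal(sort(res$F), sort(unname(f_aov)), tolerance = 1e-8)
})

test_that("a zero-variance contrast is flagged as degenerate, not an error", {
  ct <- cell_table()
  ratings <- do.call(rbind, lapply(1:6, function(p)
    data.frame(participant = p, ct, rating = 5 + ct$mag)))  # identical effect
  res <- rm_anova(ratings)
  row <- res[res$term == "mag", ]
  expect_true(row$degenerate)
  expect_true(is.infinite(row$F))
  expect_equal(row$pes, 1)
})

test_that("rating ANOVA holds its type-I rate under the null", {
  set.seed(13)
  np <- 12
  ct <- cell_table()
  hits <- 0
  nsim <- 400
  for (s in seq_len(nsim)) {
    ratings <- data.frame(participant = rep(seq_len(np), each = 8),
                          ct[rep(seq_len(8), np), ],
                          rating = rnorm(np * 8, 5, 1))
    res <- rm_anova(ratings)
    hits <- hits + (res$p[res$term == "ben:mag:tim"] < 0.05)
  }
  expect_lt(hits / nsim, 0.05 + 3 * sqrt(0.05 * 0.95 / nsim))
  expect_gt(hits / nsim, 0.05 - 3 * sqrt(0.05 * 0.95 / nsim))
})

cor_scores <- function(eff_mat, seed = NULL) {
  # eff_mat: participants x 4 (self.imm, other.imm, self.del, other.del)
  np <- nrow(eff_mat)
  ct <- cell_table()
  do.call(rbind, lapply(seq_len(np), function(p) {
    cond <- ct
    base <- 5
    key <- paste(cond$beneficiary, cond$time, sep = ".")
    effs <- stats::setNames(eff_mat[p, ],
                            c("self.immediate", "other.immediate",
                              "self.delayed", "other.delayed"))
    data.frame(participant = sprintf("P%03d", p), cond,
               value = base + ifelse(cond$mag > 0, 1, 0) * effs[key],
               stringsAsFactors = FALSE)
  }))
}

test_that("identical self and other effects give r = 1 and comparison z = 0", {
  set.seed(14)
  x <- rnorm(20, 2, 1)
  y <- rnorm(20, 1, 1)
  sc <- cor_scores(cbind(x, x, y, y))
  res <- magnitude_effect_correlations(sc)
  expect_equal(res$r_immediate, 1, tolerance = 1e-10)
  expect_equal(res$r_delayed, 1, tolerance = 1e-10)
  expect_equal(res$z, 0)
})

test_that("independent effects give near-zero correlations", {
  set.seed(15)
  sc <- cor_scores(matrix(rnorm(4 * 200), 200, 4))
  res <- magnitude_effect_correlations(sc)
  expect_lt(abs(res$r_immediate), 0.15)
  expect_lt(abs(res$r_delayed), 0.15)
})

test_that("the sampled correlation is unbiased for a rho = 0.5 population", {
  set.seed(16)
  nsim <- 400
  n <- 40
  rs <- numeric(nsim)
  for (s in seq_len(nsim)) {
    z <- rnorm(n)
    x <- z + rnorm(n)
    y <- z + rnorm(n)                    # corr(x, y) = 0.5
    sc <- cor_scores(cbind(x, y, rnorm(n), rnorm(n)))
    rs[s] <- magnitude_effect_correlations(sc)$r_immediate
  }
  expect_equal(mean(rs), 0.5, tolerance = 0.05)
})

test_that("the ZPF dependent-correlation z is calibrated under an equal-rho null", {
  set.seed(17)
  nsim <- 500
  n <- 40
  hits <- 0
  for (s in seq_len(nsim)) {
    g <- rnorm(n)
    si <- g + rnorm(n); oi <- g + rnorm(n)       # rho = .5
    g2 <- rnorm(n)
    sd_ <- g2 + rnorm(n); od <- g2 + rnorm(n)    # rho = .5 again
    R <- stats::cor(cbind(si, oi, sd_, od))
    z <- prosorew:::zpf_compare(R, n)$z
    hits <- hits + (abs(z) > 1.96)
  }
  rate <- hits / nsim
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / nsim))
})
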