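# Factorial statistical layer: coded mixed-effects models with deterministic
# random-structure simplification, EMM-style interaction contrasts with FDR,
# repeated-measures ANOVA on ratings, and magnitude-effect correlations with
# a dependent-correlation comparison.

.fixed_terms <- c("(Intercept)", "ben", "mag", "tim", "ben:mag", "ben:tim",
                  "mag:tim", "ben:mag:tim")

#' Fit the coded mixed-effects model for a single-trial measure
#'
#' Fixed effects: beneficiary, magnitude, time (coded -0.5/+0.5) and all
#' interactions. Random effects: the maximal declared structure (by-participant
#' intercept plus slopes for the three first-level variables, REML). If the
#' maximal fit is singular or fails to converge, the structure is simplified
#' deterministically: first the random-effect correlations are dropped, then
#' the random slope with the smallest estimated variance, repeatedly, down to
#' a random intercept and finally a fixed-effects-only fit; the trail is
#' recorded.
#'
#' @param scores single_trial_scores (stacked cohort) with columns
#'   participant, ben, mag, tim, value.
#' @param df_method "normal" (p from a standard-normal reference on t) or
#'   "satterthwaite" (requires lmerTest).
#' @return list of class `mixed_fit`: `fixed` (data.frame term, estimate, se,
#'   t, p), `vcov`, `formula`, `trail`, `fit`.
#' @export
fit_mixed <- function(scores, df_method = c("normal", "satterthwaite")) {
  df_method <- match.arg(df_method)
  stopifnot(all(c("participant", "ben", "mag", "tim", "value") %in%
                names(scores)))
  if (length(unique(scores$participant)) < 2)
    stop("need >= 2 participants")
  dat <- data.frame(value = scores$value, ben = scores$ben, mag = scores$mag,
                    tim = scores$tim,
                    participant = factor(scores$participant))
  forms <- c(
    "value ~ ben * mag * tim + (1 + ben + mag + tim | participant)",
    "value ~ ben * mag * tim + (1 + ben + mag + tim || participant)")
  trail <- character(0)
  slopes <- c("ben", "mag", "tim")
  fit <- NULL
  used <- NULL
  try_fit <- function(f) {
    ok <- TRUE
    m <- withCallingHandlers(
      tryCatch(suppressMessages(lme4::lmer(stats::as.formula(f), data = dat, REML = TRUE)),
               error = function(err) NULL),
      warning = function(w) { ok <<- FALSE; invokeRestart("muffleWarning") })
    if (is.null(m) || !ok || lme4::isSingular(m, tol = 1e-4)) return(NULL)
    # degenerate (e.g. zero-residual) fits can break vcov extraction
    V <- suppressWarnings(tryCatch(as.matrix(stats::vcov(m)),
                                   error = function(err) NULL))
    if (is.null(V) || any(!is.finite(V))) NULL else m
  }
  for (f in forms) {
    fit <- try_fit(f)
    if (!is.null(fit)) { used <- f; break }
    trail <- c(trail, paste("dropped:", f))
  }
  while (is.null(fit) && length(slopes)) {
    # drop the slope with the smallest variance in the (refitted) diagonal model
    f_all <- paste0("value ~ ben * mag * tim + (1 + ",
                    paste(slopes, collapse = " + "), " || participant)")
    probe <- suppressWarnings(tryCatch(
      suppressMessages(lme4::lmer(stats::as.formula(f_all), data = dat, REML = TRUE)),
      error = function(err) NULL))
    drop_one <- if (!is.null(probe)) {
      vc <- as.data.frame(lme4::VarCorr(probe))
      vs <- vc[vc$var1 %in% slopes & is.na(vc$var2), c("var1", "vcov")]
      vs$var1[which.min(vs$vcov)]
    } else slopes[length(slopes)]
    slopes <- setdiff(slopes, drop_one)
    trail <- c(trail, paste("dropped random slope:", drop_one))
    f <- if (length(slopes))
      paste0("value ~ ben * mag * tim + (1 + ",
             paste(slopes, collapse = " + "), " || participant)")
    else "value ~ ben * mag * tim + (1 | participant)"
    fit <- try_fit(f)
    if (!is.null(fit)) used <- f
  }
  if (is.null(fit)) {
    f <- "value ~ ben * mag * tim + (1 | participant)"
    fit <- try_fit(f)
    if (!is.null(fit)) used <- f
  }
  if (is.null(fit)) {
    trail <- c(trail, "fell back to fixed-effects-only OLS")
    used <- "value ~ ben * mag * tim"
    fit <- stats::lm(stats::as.formula(used), data = dat)
    # noiseless balanced inputs legitimately produce a perfect fit here
    est <- stats::coef(fit)
    V <- suppressWarnings(stats::vcov(fit))
    se <- sqrt(diag(V))
    se[se == 0] <- NA
  } else {
    if (df_method == "satterthwaite") {
      if (!requireNamespace("lmerTest", quietly = TRUE))
        stop("df_method = \"satterthwaite\" requires the lmerTest package")
      fit2 <- lmerTest::as_lmerModLmerTest(fit)
      sm <- stats::coef(summary(fit2))
      fixed <- data.frame(term = rownames(sm), estimate = sm[, "Estimate"],
                          se = sm[, "Std. Error"], t = sm[, "t value"],
                          p = sm[, "Pr(>|t|)"], stringsAsFactors = FALSE)
      rownames(fixed) <- NULL
      return(structure(list(fixed = fixed, vcov = as.matrix(stats::vcov(fit)),
                            formula = used, trail = trail, fit = fit),
                       class = "mixed_fit"))
    }
    est <- lme4::fixef(fit)
    V <- as.matrix(stats::vcov(fit))
    se <- sqrt(diag(V))
  }
  tval <- est / se
  fixed <- data.frame(term = names(est), estimate = unname(est),
                      se = unname(se), t = unname(tval),
                      p = 2 * stats::pnorm(-abs(unname(tval))),
                      stringsAsFactors = FALSE)
  structure(list(fixed = fixed, vcov = as.matrix(V), formula = used,
                 trail = trail, fit = fit),
            class = "mixed_fit")
}

#' @exportS3Method base::print
print.mixed_fit <- function(x, ...) {
  cat("mixed model:", x$formula, "\n")
  if (length(x$trail)) cat("simplification trail:",
                           paste(x$trail, collapse = "; "), "\n")
  print(x$fixed, digits = 3)
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#' @param p numeric vector of p-values.
#' @return adjusted p-values (same order).
#' @export
fdr_adjust <- function(p) stats::p.adjust(p, method = "BH")

# Contrast rows over the 8 fixed-effect terms. Each returns a named numeric
# vector aligned with .fixed_terms.
contrast_row <- function(weights) {
  v <- stats::setNames(numeric(8), .fixed_terms)
  v[names(weights)] <- weights
  v
}

#' Estimated-marginal-mean style interaction contrasts
#'
#' Contrasts are linear combinations of the fixed effects under the
#' -0.5/+0.5 coding with covariance-propagated SEs; p-values use a
#' standard-normal reference and are BH-FDR adjusted within the family.
#' Families:
#' \describe{
#'   \item{"simple_magnitude"}{the magnitude effect within each
#'     beneficiary x time cell: b_mag + s_b b_bm + s_t b_mt + s_b s_t b_3way.}
#'   \item{"ben_mag_within_time"}{the beneficiary x magnitude interaction
#'     within each time level: b_bm + s_t b_3way.}
#'   \item{"mag_time_within_ben"}{the magnitude x time interaction within
#'     each beneficiary level: b_mt + s_b b_3way.}
#' }
#'
#' @param fit `mixed_fit`.
#' @param family one of the family names above.
#' @return data.frame of class `contrast_result`: contrast, estimate, se, z,
#'   p, p_fdr.
#' @export
emm_contrasts <- function(fit, family = c("simple_magnitude",
                                          "ben_mag_within_time",
                                          "mag_time_within_ben")) {
  family <- match.arg(family)
  est <- stats::setNames(fit$fixed$estimate, fit$fixed$term)
  V <- fit$vcov
  if (!all(.fixed_terms %in% names(est)))
    stop("fit lacks required fixed terms")
  rows <- switch(family,
    simple_magnitude = {
      out <- list()
      for (b in c(-0.5, 0.5)) for (tt in c(-0.5, 0.5)) {
        lab <- paste0("magnitude effect | beneficiary=",
                      ifelse(b < 0, "self", "other"), ", time=",
                      ifelse(tt < 0, "immediate", "delayed"))
        out[[lab]] <- contrast_row(c("mag" = 1, "ben:mag" = b,
                                     "mag:tim" = tt, "ben:mag:tim" = b * tt))
      }
      out
    },
    ben_mag_within_time = {
      out <- list()
      for (tt in c(-0.5, 0.5)) {
        lab <- paste0("beneficiary x magnitude | time=",
                      ifelse(tt < 0, "immediate", "delayed"))
        out[[lab]] <- contrast_row(c("ben:mag" = 1, "ben:mag:tim" = tt))
      }
      out
    },
    mag_time_within_ben = {
      out <- list()
      for (b in c(-0.5, 0.5)) {
        lab <- paste0("magnitude x time | beneficiary=",
                      ifelse(b < 0, "self", "other"))
        out[[lab]] <- contrast_row(c("mag:tim" = 1, "ben:mag:tim" = b))
      }
      out
    })
  L <- do.call(rbind, rows)
  L <- L[, names(est), drop = FALSE]
  estc <- drop(L %*% est)
  sec <- sqrt(diag(L %*% V %*% t(L)))
  z <- estc / sec
  p <- 2 * stats::pnorm(-abs(z))
  out <- data.frame(contrast = names(rows), estimate = estc, se = sec, z = z,
                    p = p, p_fdr = fdr_adjust(p), family = family,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("contrast_result", "data.frame")
  out
}

#' Repeated-measures ANOVA for the 2x2x2 rating design
#'
#' Classical within-subject ANOVA computed from per-participant contrast
#' scores: for each effect, F(1, n-1) equals the squared paired t on the
#' participant-wise contrast, with partial eta squared
#' SS_effect / (SS_effect + SS_error). A degenerate zero-variance contrast is
#' reported with `F = Inf` and flagged.
#'
#' @param ratings data.frame with columns participant, ben, mag, tim, rating
#'   (one row per participant x cell).
#' @return data.frame of class `anova_result`: term, F, df1, df2, p, pes,
#'   degenerate.
#' @export
rm_anova <- function(ratings) {
  need <- c("participant", "ben", "mag", "tim", "rating")
  stopifnot(all(need %in% names(ratings)))
  wide <- tapply(ratings$rating,
                 list(ratings$participant,
                      paste(ratings$ben, ratings$mag, ratings$tim)), mean)
  if (anyNA(wide)) stop("missing cells in the rating table")
  np <- nrow(wide)
  keycodes <- do.call(rbind, lapply(strsplit(colnames(wide), " "), as.numeric))
  terms <- list(ben = keycodes[, 1], mag = keycodes[, 2], tim = keycodes[, 3],
                `ben:mag` = keycodes[, 1] * keycodes[, 2],
                `ben:tim` = keycodes[, 1] * keycodes[, 3],
                `mag:tim` = keycodes[, 2] * keycodes[, 3],
                `ben:mag:tim` = keycodes[, 1] * keycodes[, 2] * keycodes[, 3])
  res <- lapply(names(terms), function(nm) {
    w <- sign(terms[[nm]])
    contrast <- drop(wide %*% w) / (sum(w > 0))  # mean(+cells) - mean(-cells)
    mbar <- mean(contrast); s <- stats::sd(contrast)
    degenerate <- s == 0
    tstat <- if (degenerate) Inf * sign(mbar) else mbar / (s / sqrt(np))
    Fv <- tstat^2
    pes <- if (is.infinite(Fv)) 1 else Fv / (Fv + (np - 1))
    data.frame(term = nm, F = Fv, df1 = 1, df2 = np - 1,
               p = if (is.infinite(Fv)) 0 else
                 stats::pf(Fv, 1, np - 1, lower.tail = FALSE),
               pes = pes, degenerate = degenerate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("anova_result", "data.frame")
  out
}

# ZPF comparison of two dependent, non-overlapping correlations r_jk vs r_hm
# (Raghunathan, Rosenthal & Rubin 1996 / Steiger 1980): Fisher z difference
# scaled by the covariance between the two correlations implied by the full
# correlation matrix of the four variables.
zpf_compare <- function(R, n, jk = c(1, 2), hm = c(3, 4)) {
  j <- jk[1]; k <- jk[2]; h <- hm[1]; m <- hm[2]
  r_jk <- R[j, k]; r_hm <- R[h, m]
  psi <- 0.5 * ((R[j, h] - R[j, k] * R[k, h]) * (R[k, m] - R[k, h] * R[h, m]) +
                (R[j, m] - R[j, h] * R[h, m]) * (R[k, h] - R[j, k] * R[j, h]) +
                (R[j, h] - R[j, m] * R[m, h]) * (R[k, m] - R[j, k] * R[j, m]) +
                (R[j, m] - R[j, k] * R[k, m]) * (R[k, h] - R[k, m] * R[m, h]))
  if (abs(r_jk - r_hm) < 1e-15) return(list(z = 0, p = 1))
  cvz <- psi / ((1 - r_jk^2) * (1 - r_hm^2))
  z1 <- atanh(r_jk); z2 <- atanh(r_hm)
  z <- (z1 - z2) * sqrt((n - 3) / (2 - 2 * cvz))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Correlations of magnitude effects between self and other
#'
#' Per participant and beneficiary x time cell, the magnitude effect is
#' mean(large) - mean(small). Pearson correlations between the self and other
#' effects across participants are computed separately for immediate and
#' delayed rewards, and compared with a dependent (same-sample,
#' non-overlapping variables) z-procedure (ZPF; `method = "fisher"` falls
#' back to the independent-samples Fisher comparison).
#'
#' @param scores single_trial_scores for a cohort.
#' @param method "zpf" or "fisher".
#' @return list of class `correlation_comparison`: `r_immediate`,
#'   `r_delayed`, `p_immediate`, `p_delayed`, `z`, `p_comparison`,
#'   `effects` (per-participant table).
#' @export
magnitude_effect_correlations <- function(scores, method = c("zpf", "fisher")) {
  method <- match.arg(method)
  parts <- unique(scores$participant)
  if (length(parts) < 3) stop("need >= 3 participants")
  key <- paste(scores$beneficiary, scores$time, sep = ".")
  eff <- expand.grid(participant = parts,
                     beneficiary = .factor_levels$beneficiary,
                     time = .factor_levels$time, stringsAsFactors = FALSE)
  eff$effect <- NA_real_
  for (i in seq_len(nrow(eff))) {
    sel <- scores$participant == eff$participant[i] &
      scores$beneficiary == eff$beneficiary[i] & scores$time == eff$time[i]
    lg <- scores$value[sel & scores$magnitude == "large"]
    sm <- scores$value[sel & scores$magnitude == "small"]
    if (!length(lg) || !length(sm))
      stop("participant ", eff$participant[i], " has an empty ",
           eff$beneficiary[i], " x ", eff$time[i], " x magnitude cell")
    eff$effect[i] <- mean(lg) - mean(sm)
  }
  get <- function(b, tt) eff$effect[eff$beneficiary == b & eff$time == tt][
    order(eff$participant[eff$beneficiary == b & eff$time == tt])]
  si <- get("self", "immediate"); oi <- get("other", "immediate")
  sd_ <- get("self", "delayed"); od <- get("other", "delayed")
  n <- length(si)
  ri <- stats::cor(si, oi); rd <- stats::cor(sd_, od)
  pi_ <- stats::cor.test(si, oi)$p.value
  pd <- stats::cor.test(sd_, od)$p.value
  cmp <- if (method == "zpf") {
    R <- stats::cor(cbind(si, oi, sd_, od))
    zpf_compare(R, n)
  } else {
    z <- if (abs(ri - rd) < 1e-15) 0 else
      (atanh(ri) - atanh(rd)) / sqrt(2 / (n - 3))
    list(z = z, p = 2 * stats::pnorm(-abs(z)))
  }
  structure(list(r_immediate = ri, r_delayed = rd, p_immediate = pi_,
                 p_delayed = pd, z = cmp$z, p_comparison = cmp$p,
                 n = n, method = method, effects = eff),
            class = "correlation_comparison")
}
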