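# Single-trial ERP mean-amplitude scoring, grand averages, split-half
# reliability.

#' Measurement specification for a single-trial scalar measure
#'
#' Defaults follow the orthogonal-selection windows used throughout the
#' package: RewP = mean amplitude 260-360 ms at Fz/FCz; P3 = 320-420 ms at
#' CPz/Pz.
#'
#' @param name measure name (e.g. "rewp").
#' @param window (start, end) ms.
#' @param roi character vector of channel names averaged over.
#' @param statistic only "mean" (mean amplitude) is defined.
#' @return list of class `measure_spec`.
#' @export
measure_spec <- function(name, window, roi, statistic = "mean") {
  stopifnot(length(window) == 2, window[1] < window[2], length(roi) >= 1,
            identical(statistic, "mean"))
  structure(list(name = name, window = window, roi = roi,
                 statistic = statistic), class = "measure_spec")
}

#' Default ERP measures (RewP and P3)
#' @return named list of [measure_spec()].
#' @export
default_erp_measures <- function() {
  list(rewp = measure_spec("rewp", c(260, 360), c("Fz", "FCz")),
       p3 = measure_spec("p3", c(320, 420), c("CPz", "Pz")))
}

#' Score a measure on every trial
#'
#' The score is the mean over the ROI channels and all samples at or inside
#' the window endpoints (260-360 ms at 500 Hz spans 51 samples). ERP measures
#' are expected on baseline-subtracted epochs.
#'
#' @param e epochset (baseline-subtracted for ERP use).
#' @param m [measure_spec()].
#' @return data.frame of class `single_trial_scores`: participant, trial,
#'   condition columns, measure, value (uV).
#' @export
score_single_trial <- function(e, m) {
  stopifnot(inherits(m, "measure_spec"))
  ci <- channel_index(e, m$roi)
  si <- time_index(e$times, m$window)
  vals <- apply(e$data[, ci, si, drop = FALSE], 1, mean)
  out <- cbind(participant = e$participant_id,
               trial = seq_len(n_trials(e)),
               e$conditions,
               measure = m$name, value = vals, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("single_trial_scores", "data.frame")
  out
}

#' Grand-averaged waveforms per design cell
#'
#' Averages participant-level cell means (unweighted across participants) and
#' reports the between-participant SEM.
#'
#' @param epochs_list list of epochsets on a common time axis and montage.
#' @return list with `mean` and `sem` arrays (cell x channel x time), `cells`,
#'   `times`, `channels`, `n_participants`.
#' @export
grand_average <- function(epochs_list) {
  e1 <- epochs_list[[1]]
  for (e in epochs_list)
    if (!isTRUE(all.equal(e$times, e1$times)) ||
        !identical(e$channels$name, e1$channels$name))
      stop("mismatched time axes or channel sets across participants")
  ct <- cell_table()
  np <- length(epochs_list)
  d <- dim(e1$data)
  acc <- array(0, dim = c(8, d[2], d[3]))
  acc2 <- acc
  for (e in epochs_list) {
    for (k in seq_len(8)) {
      sel <- which(e$conditions$beneficiary == ct$beneficiary[k] &
                   e$conditions$magnitude == ct$magnitude[k] &
                   e$conditions$time == ct$time[k])
      if (!length(sel))
        stop("participant ", e$participant_id, " has no trials in cell ",
             paste(ct$beneficiary[k], ct$magnitude[k], ct$time[k], sep = "."))
      cm <- apply(e$data[sel, , , drop = FALSE], c(2, 3), mean)
      acc[k, , ] <- acc[k, , ] + cm
      acc2[k, , ] <- acc2[k, , ] + cm^2
    }
  }
  gm <- acc / np
  sem <- if (np > 1) sqrt(pmax(acc2 / np - gm^2, 0) * np / (np - 1) / np)
         else array(0, dim = dim(gm))
  list(mean = gm, sem = sem, cells = ct, times = e1$times,
       channels = e1$channels, n_participants = np)
}

#' Split-half reliability of a single-trial measure
#'
#' For each of `n_splits` random splits (stratified by design cell), trials
#' are divided into halves within participant; per-participant half means are
#' correlated across participants and Spearman-Brown corrected
#' (2r / (1 + r)). The mean over splits is returned. `method = "oddeven"`
#' uses the single deterministic odd/even split instead.
#'
#' @param scores single_trial_scores for a cohort (stacked).
#' @param n_splits number of random splits.
#' @param seed integer seed for the random splits.
#' @param method "random" or "oddeven".
#' @return Spearman-Brown corrected reliability (scalar).
#' @export
split_half_reliability <- function(scores, n_splits = 100, seed = 1,
                                   method = c("random", "oddeven")) {
  method <- match.arg(method)
  set.seed(seed)
  cellkey <- paste(scores$beneficiary, scores$magnitude, scores$time, sep = ".")
  by_p <- split(seq_len(nrow(scores)), scores$participant)
  counts <- table(scores$participant, cellkey)
  if (any(counts < 2))
    stop("every participant needs >= 2 trials per cell for a stratified split")
  one_split <- function(split_id) {
    half <- logical(nrow(scores))
    for (idx in by_p) {
      for (cidx in split(idx, cellkey[idx])) {
        n <- length(cidx)
        pick <- if (method == "oddeven") cidx[seq(1, n, by = 2)]
                else sample(cidx, floor(n / 2))
        half[pick] <- TRUE
      }
    }
    a <- tapply(scores$value[half], scores$participant[half], mean)
    b <- tapply(scores$value[!half], scores$participant[!half], mean)
    b <- b[names(a)]
    r <- stats::cor(a, b)
    2 * r / (1 + r)
  }
  if (method == "oddeven") return(one_split(1))
  mean(vapply(seq_len(n_splits), one_split, 0))
}
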