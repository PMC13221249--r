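# Epoch-level preprocessing: four-rule artifact rejection, baseline
# subtraction, zero-phase Butterworth band-pass, averaged-mastoid re-reference.

#' Default artifact-rejection thresholds
#'
#' Step: sample-to-sample difference > 50 uV. Range: max-min within an epoch
#' > 200 uV. Flatline: some 100-ms interval in which every sample-to-sample
#' absolute difference is < 0.5 uV. Drift: |least-squares slope| over the
#' whole epoch > 100 uV (per epoch length). All comparisons are strict.
#'
#' @return named list of thresholds.
#' @export
default_rejection_thresholds <- function() {
  list(step = 50, range = 200, flatline = 0.5, flat_window_ms = 100, drift = 100)
}

#' Reject artifact-contaminated epochs
#'
#' A trial is dropped iff any enabled rule fires on any channel. Thresholds
#' are strict inequalities (a difference of exactly 50 uV does not fire the
#' step rule; a flat interval whose largest difference is exactly 0.5 uV does
#' not fire the flatline rule).
#'
#' @param e epochset.
#' @param rules subset of `c("step", "range", "flatline", "drift")`.
#' @param thresholds named list as from [default_rejection_thresholds()].
#' @return list with elements `epochs` (the retained epochset) and `report`
#'   (data.frame: trial, keep, rules fired; attribute `retained_fraction`).
#' @export
reject_artifacts <- function(e, rules = c("step", "range", "flatline", "drift"),
                             thresholds = default_rejection_thresholds()) {
  rules <- match.arg(rules, several.ok = TRUE)
  stopifnot(all(unlist(thresholds[c("step", "range", "flatline", "drift")]) > 0))
  nt <- n_trials(e)
  fs <- sampling_rate(e)
  k <- max(2L, round(thresholds$flat_window_ms * fs / 1000) + 1L) # samples per window
  tt <- e$times
  tc <- tt - mean(tt)
  denom <- sum(tc^2)
  span <- max(tt) - min(tt)
  fired <- vector("list", nt)
  for (i in seq_len(nt)) {
    X <- e$data[i, , , drop = TRUE]              # channel x time
    if (is.null(dim(X))) X <- matrix(X, nrow = 1)
    D <- abs(X[, -1, drop = FALSE] - X[, -ncol(X), drop = FALSE])
    f <- character(0)
    if ("step" %in% rules && max(D) > thresholds$step) f <- c(f, "step")
    if ("range" %in% rules &&
        max(apply(X, 1, function(v) max(v) - min(v))) > thresholds$range)
      f <- c(f, "range")
    if ("flatline" %in% rules) {
      # fire if some run of (k-1) consecutive small diffs exists on a channel
      flat <- apply(D < thresholds$flatline, 1, function(v) {
        r <- rle(v); any(r$values & r$lengths >= (k - 1L))
      })
      if (any(flat)) f <- c(f, "flatline")
    }
    if ("drift" %in% rules) {
      slope <- (X %*% tc) / denom * span          # uV over the epoch
      if (max(abs(slope)) > thresholds$drift) f <- c(f, "drift")
    }
    fired[[i]] <- f
  }
  keep <- lengths(fired) == 0L
  report <- data.frame(trial = seq_len(nt), keep = keep,
                       rules = vapply(fired, paste, "", collapse = ","),
                       stringsAsFactors = FALSE)
  attr(report, "retained_fraction") <- mean(keep)
  if (!any(keep))
    warning("all trials rejected; returning an empty epoch set")
  list(epochs = subset_epochs(e, trials = which(keep)), report = report)
}

#' Subtract a prestimulus baseline
#'
#' Per trial and channel, the mean over `window` is subtracted. Applying a
#' baseline twice is an error.
#'
#' @param e epochset with `baseline = NULL`.
#' @param window (start, end) ms, inside the epoch.
#' @return baselined epochset.
#' @export
baseline_subtract <- function(e, window = c(-200, 0)) {
  if (!is.null(e$baseline)) stop("epochs are already baseline-subtracted")
  if (window[1] < min(e$times) - 1e-9 || window[2] > max(e$times) + 1e-9)
    stop("baseline window outside epoch")
  idx <- time_index(e$times, window)
  bl <- apply(e$data[, , idx, drop = FALSE], c(1, 2), mean)
  e$data <- e$data - array(bl, dim = dim(e$data))
  e$baseline <- window
  e
}

# Zero-phase application of an IIR filter to the columns of a (time x series)
# matrix: multiply the FFT by the squared magnitude response |H|^2, which is
# exactly the ideal forward-backward (filtfilt) response, free of start-up
# transients. Reflection padding suppresses circular wrap-around.
filtfilt_mat <- function(b, a, X, pad) {
  nt <- nrow(X)
  pad <- min(pad, nt - 1L)
  idx <- c(seq(pad + 1, 2), seq_len(nt), seq(nt - 1, nt - pad))
  Xp <- X[idx, , drop = FALSE]
  npad <- nrow(Xp)
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  ww <- 2 * pi * (seq_len(npad) - 1) / npad
  E <- exp(-1i * outer(ww, seq_len(n) - 1))
  gain <- Mod((E %*% b) / (E %*% a))^2
  Y <- Re(stats::mvfft(stats::mvfft(Xp) * as.vector(gain),
                       inverse = TRUE)) / npad
  Y[pad + seq_len(nt), , drop = FALSE]
}

#' Zero-phase Butterworth band-pass filter
#'
#' Order-2 Butterworth (12 dB/octave roll-off) applied forward-backward (zero
#' phase): the squared magnitude response is applied in the frequency domain
#' after reflection padding, which equals the ideal filtfilt response without
#' start-up transients. Default band 0.1-35 Hz.
#'
#' @param e epochset.
#' @param lo_hz,hi_hz band edges, 0 < lo < hi < Nyquist.
#' @param order Butterworth order before the forward-backward pass.
#' @return filtered epochset.
#' @export
filter_bandpass <- function(e, lo_hz = 0.1, hi_hz = 35, order = 2) {
  fs <- sampling_rate(e)
  if (!(lo_hz > 0 && lo_hz < hi_hz && hi_hz < fs / 2))
    stop("invalid band: need 0 < lo < hi < Nyquist (", fs / 2, " Hz)")
  bf <- signal::butter(order, c(lo_hz, hi_hz) / (fs / 2), type = "pass")
  d <- dim(e$data)
  X <- matrix(aperm(e$data, c(3, 1, 2)), nrow = d[3])  # time x (trial*channel)
  Y <- filtfilt_mat(bf$b, bf$a, X, pad = round(fs))    # 1 s reflection padding
  e$data <- aperm(array(Y, dim = c(d[3], d[1], d[2])), c(2, 3, 1))
  e
}

#' Re-reference to the averaged mastoids
#'
#' Subtracts the mean of the two mastoid channels from every channel.
#'
#' @param e epochset.
#' @param left,right mastoid channel names.
#' @return re-referenced epochset.
#' @export
rereference_mastoids <- function(e, left = "M1", right = "M2") {
  idx <- channel_index(e, c(left, right))
  ref <- (e$data[, idx[1], , drop = FALSE] + e$data[, idx[2], , drop = FALSE]) / 2
  e$data <- e$data - ref[, rep(1, dim(e$data)[2]), , drop = FALSE]
  e
}
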