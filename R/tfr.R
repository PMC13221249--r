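# Single-trial Morlet wavelet decomposition and welding-baseline
# normalization; band-power scoring.

#' Morlet wavelet bank
#'
#' Frequencies are geometrically (log) spaced between `f_lo` and `f_hi`
#' inclusive; cycles are geometrically spaced between `c_lo` and `c_hi` and
#' paired index-wise with the frequencies. Defaults: 1-30 Hz in 30 steps,
#' cycles 3-10.
#'
#' @param f_lo,f_hi frequency range (Hz).
#' @param n number of wavelets.
#' @param c_lo,c_hi cycle range.
#' @return list of class `wavelet_bank` with `frequencies` and `cycles`.
#' @export
wavelet_bank <- function(f_lo = 1, f_hi = 30, n = 30, c_lo = 3, c_hi = 10) {
  stopifnot(f_lo > 0, f_hi > f_lo, n >= 2, c_lo > 0, c_hi >= c_lo)
  structure(list(frequencies = exp(seq(log(f_lo), log(f_hi), length.out = n)),
                 cycles = exp(seq(log(c_lo), log(c_hi), length.out = n))),
            class = "wavelet_bank")
}

#' Single-trial Morlet power
#'
#' Convolves each trial and channel with complex Morlet wavelets (Gaussian
#' envelope SD `sigma_t = cycles / (2 pi f)`) and returns squared magnitude.
#' Each wavelet is amplitude-normalized so that a unit-amplitude sinusoid at
#' the wavelet's frequency yields peak power 1 regardless of frequency.
#' Epochs are reflection-padded by the wavelet half-support at the lowest
#' frequency before convolution; the padding is discarded afterwards.
#'
#' @param e epochset.
#' @param bank [wavelet_bank()].
#' @param channels optional channel subset (names) to decompose.
#' @param crop optional (start, end) ms window to retain in the output.
#' @return list of class `tfr`: `power` (trial x channel x frequency x time),
#'   `times`, `frequencies`, `channels`, `conditions`, `normalization`.
#' @export
morlet_transform <- function(e, bank = wavelet_bank(), channels = NULL,
                             crop = NULL) {
  stopifnot(inherits(bank, "wavelet_bank"))
  fs <- sampling_rate(e)
  if (!is.null(channels)) e <- subset_epochs(e, channels = channels)
  nt <- length(e$times)
  sigma_lo <- bank$cycles[1] / (2 * pi * bank$frequencies[1])
  half_support <- ceiling(4 * sigma_lo * fs)      # samples
  if (nt <= half_support)
    stop("epoch too short for the lowest frequency (", bank$frequencies[1],
         " Hz): need more than ", half_support, " samples (",
         round(half_support * 1000 / fs), " ms) of data for edge padding")
  pad <- half_support
  npad <- nt + 2 * pad
  idx_pad <- c(seq(pad + 1, 2), seq_len(nt), seq(nt - 1, nt - pad))
  d <- dim(e$data)
  X <- matrix(aperm(e$data, c(3, 1, 2)), nrow = nt)   # time x (trial*channel)
  Xp <- X[idx_pad, , drop = FALSE]
  FX <- stats::mvfft(Xp)
  keep_t <- if (is.null(crop)) seq_along(e$times) else time_index(e$times, crop)
  out_times <- e$times[keep_t]
  power <- array(0, dim = c(d[1], d[2], length(bank$frequencies), length(keep_t)))
  tw <- (seq_len(npad) - 1 - floor(npad / 2)) / fs   # wavelet time axis (s)
  for (k in seq_along(bank$frequencies)) {
    f <- bank$frequencies[k]
    sigma_t <- bank$cycles[k] / (2 * pi * f)
    env <- exp(-tw^2 / (2 * sigma_t^2))
    w <- env * exp(2i * pi * f * tw)
    w <- w / (sum(env) / 2)                # unit peak power for unit sinusoid
    # circular convolution via FFT; wavelet centered, so rotate by half length
    FW <- stats::fft(w)
    conv <- stats::mvfft(FX * FW, inverse = TRUE) / npad
    shift <- floor(npad / 2)
    rows <- ((pad + keep_t - 1 + shift) %% npad) + 1
    P <- Mod(conv[rows, , drop = FALSE])^2
    power[, , k, ] <- aperm(array(P, dim = c(length(keep_t), d[1], d[2])),
                            c(2, 3, 1))
  }
  structure(list(power = power, times = out_times,
                 frequencies = bank$frequencies, channels = e$channels,
                 conditions = e$conditions, participant_id = e$participant_id,
                 normalization = "raw", baseline_window = NULL),
            class = "tfr")
}

#' @exportS3Method base::print
print.tfr <- function(x, ...) {
  d <- dim(x$power)
  cat(sprintf("<tfr> %s: %d trials x %d channels x %d freqs x %d samples [%s]\n",
              x$participant_id, d[1], d[2], d[3], d[4], x$normalization))
  invisible(x)
}

#' Welding-baseline normalization of single-trial power
#'
#' Per channel and frequency, all baseline-window power samples from all
#' trials are pooled into one long baseline; its mean and SD standardize every
#' sample of every trial ((p - mu) / sigma). After normalization the pooled
#' baseline samples have mean 0 and SD 1 exactly. Pooling across trials gives
#' a less biased single-trial normalizer than per-trial z-scoring because the
#' per-trial baseline mean is itself a noisy, skewed quantity for power data.
#'
#' @param t raw `tfr`.
#' @param window baseline (start, end) ms; default -500 to -300.
#' @param method "zscore" (subtract pooled mean, divide pooled SD), "meandiv"
#'   (divide by pooled mean) or "db" (10*log10(p / pooled mean)).
#' @return normalized `tfr`.
#' @export
weld_baseline <- function(t, window = c(-500, -300),
                          method = c("zscore", "meandiv", "db")) {
  method <- match.arg(method)
  if (t$normalization != "raw")
    stop("power is already normalized (", t$normalization, ")")
  bi <- time_index(t$times, window)
  d <- dim(t$power)
  for (ch in seq_len(d[2])) {
    for (fr in seq_len(d[3])) {
      base <- as.vector(t$power[, ch, fr, bi])
      mu <- mean(base)
      sg <- stats::sd(base)
      if (method == "zscore") {
        if (sg == 0) stop("degenerate baseline: pooled SD is zero (channel ",
                          t$channels$name[ch], ", ",
                          round(t$frequencies[fr], 2), " Hz)")
        t$power[, ch, fr, ] <- (t$power[, ch, fr, ] - mu) / sg
      } else if (method == "meandiv") {
        if (mu == 0) stop("degenerate baseline: pooled mean is zero")
        t$power[, ch, fr, ] <- t$power[, ch, fr, ] / mu
      } else {
        if (mu == 0) stop("degenerate baseline: pooled mean is zero")
        t$power[, ch, fr, ] <- 10 * log10(t$power[, ch, fr, ] / mu)
      }
    }
  }
  t$normalization <- switch(method, zscore = "welded-z", meandiv = "welded-ratio",
                            db = "welded-db")
  t$baseline_window <- window
  t
}

#' Single-trial band power scores
#'
#' Mean of normalized power over the ROI channels, the bank frequencies inside
#' the band, and the window samples.
#'
#' @param t welded (normalized) `tfr`.
#' @param band (f_lo, f_hi) Hz.
#' @param window (start, end) ms.
#' @param roi channel names.
#' @param name measure name for the output.
#' @return single_trial_scores data.frame (value in welded-z units).
#' @export
score_band_power <- function(t, band, window, roi, name = "power") {
  if (t$normalization == "raw")
    stop("band power is scored on normalized (welded) power; ",
         "call weld_baseline() first")
  ci <- match(roi, t$channels$name)
  if (anyNA(ci)) stop("channel(s) not present: ",
                      paste(roi[is.na(ci)], collapse = ", "))
  fi <- which(t$frequencies >= band[1] - 1e-9 & t$frequencies <= band[2] + 1e-9)
  if (!length(fi))
    stop("band [", band[1], ", ", band[2], "] Hz contains no bank frequency; ",
         "bank: ", paste(round(t$frequencies, 3), collapse = ", "))
  si <- time_index(t$times, window)
  vals <- apply(t$power[, ci, fi, si, drop = FALSE], 1, mean)
  out <- cbind(participant = t$participant_id,
               trial = seq_len(dim(t$power)[1]),
               t$conditions, measure = name, value = vals,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("single_trial_scores", "data.frame")
  out
}

#' Write/read a TFR in the internal directory container
#'
#' Same layout as the epochs container (meta.json + CSV tables + raw
#' little-endian float32 array), with the normalization state and frequency
#' axis recorded in the metadata.
#'
#' @param t `tfr` object.
#' @param path directory to create/overwrite.
#' @return `path` invisibly (`write_tfr`); a `tfr` (`read_tfr`).
#' @export
write_tfr <- function(t, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(t$power)
  meta <- list(format = "prosorew-tfr",
               version = list(major = .format_version[["major"]],
                              minor = .format_version[["minor"]]),
               participant_id = t$participant_id,
               dims = d,
               t0_ms = t$times[1], dt_ms = mean(diff(t$times)),
               frequencies = t$frequencies,
               normalization = t$normalization,
               baseline_window = if (is.null(t$baseline_window)) NULL
                                 else as.numeric(t$baseline_window))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.csv(t$channels, file.path(path, "channels.csv"),
                   row.names = FALSE)
  utils::write.csv(t$conditions, file.path(path, "conditions.csv"),
                   row.names = FALSE)
  con <- file(file.path(path, "power.bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(t$power), con, size = 4L, endian = "little")
  invisible(path)
}

#' @rdname write_tfr
#' @param path directory written by [write_tfr()].
#' @export
read_tfr <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"))
  if (!identical(meta$format, "prosorew-tfr"))
    stop("not a prosorew TFR container: ", path)
  if (meta$version$major != .format_version[["major"]])
    stop("unsupported container major version ", meta$version$major)
  d <- unlist(meta$dims)
  con <- file(file.path(path, "power.bin"), "rb")
  on.exit(close(con))
  raw <- readBin(con, "numeric", n = prod(d), size = 4L, endian = "little")
  structure(list(
    power = array(raw, dim = d),
    times = meta$t0_ms + meta$dt_ms * (seq_len(d[4]) - 1),
    frequencies = unlist(meta$frequencies),
    channels = utils::read.csv(file.path(path, "channels.csv"),
                               stringsAsFactors = FALSE),
    conditions = utils::read.csv(file.path(path, "conditions.csv"),
                                 stringsAsFactors = FALSE),
    participant_id = meta$participant_id,
    normalization = meta$normalization,
    baseline_window = if (is.null(meta$baseline_window)) NULL
                      else unlist(meta$baseline_window)),
    class = "tfr")
}
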