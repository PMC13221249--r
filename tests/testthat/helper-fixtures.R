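# Shared fixtures: small montages/designs so tests stay fast, a direct TFR
# constructor for normalization tests, a brute-force BH oracle, and a minimal
# EDF+ writer used as an independent fixture generator for the reader.

small_layout <- function() {
  full <- standard_layout()
  keep <- c("Fz", "FCz", "Cz", "CPz", "Pz", "F3", "F4", "C3", "C4",
            "P3", "P4", "Oz", "M1", "M2")
  full[match(keep, full$name), ]
}

quick_design <- function(n_participants = 2, n_trials_per_cell = 4,
                         sampling_rate = 250, epoch_window = c(-1500, 2000),
                         layout = small_layout()) {
  design_spec(n_participants, n_trials_per_cell, sampling_rate,
              epoch_window, layout)
}

quiet_noise <- function() noise_spec(onef_sd = 0, onef_exponent = 1, white_sd = 0)

null_effects <- function() effect_spec(rating_beta = c(5, 0, 0, 0, 0, 0, 0, 0))

# epochset with explicitly given data on the small montage
make_epochs <- function(data, fs = 250, t0 = -200, conditions = NULL,
                        layout = small_layout()) {
  nt <- dim(data)[3]
  times <- t0 + (seq_len(nt) - 1) * 1000 / fs
  if (is.null(conditions)) {
    ct <- cell_table()
    reps <- ceiling(dim(data)[1] / 8)
    conditions <- ct[rep(seq_len(8), reps)[seq_len(dim(data)[1])], ]
    rownames(conditions) <- NULL
  }
  epochset(data, times, layout[seq_len(dim(data)[2]), ], conditions)
}

# tfr object built directly from a power array (trial x channel x freq x time)
make_tfr <- function(power, times, frequencies, channel_names = NULL,
                     conditions = NULL, normalization = "raw") {
  nch <- dim(power)[2]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nch))
  channels <- data.frame(name = channel_names, x = 0, y = 0)
  if (is.null(conditions)) {
    ct <- cell_table()
    reps <- ceiling(dim(power)[1] / 8)
    conditions <- ct[rep(seq_len(8), reps)[seq_len(dim(power)[1])], ]
  }
  structure(list(power = power, times = times, frequencies = frequencies,
                 channels = channels, conditions = conditions,
                 participant_id = "T01", normalization = normalization,
                 baseline_window = NULL),
            class = "tfr")
}

# O(m^2) brute-force Benjamini-Hochberg step-up
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  for (k in seq_len(m)) {
    # step-up: min over j >= k of p_(j) * m / j, capped at 1
    vals <- p[ord[k:m]] * m / (k:m)
    adj[ord[k]] <- min(1, min(vals))
  }
  adj
}

# Minimal EDF+ writer (continuous, 1-s records, int16, one annotation signal).
# Independent of the package reader; used to build reader fixtures.
write_edf_fixture <- function(path, data, fs, events, labels,
                              phys_range = c(-400, 400)) {
  nch <- nrow(data)
  n_samp <- ncol(data)
  n_rec <- ceiling(n_samp / fs)
  pad_to <- n_rec * fs
  if (pad_to > n_samp)
    data <- cbind(data, matrix(0, nch, pad_to - n_samp))
  ns <- nch + 1L
  ann_spr <- 32L                                   # 64 bytes per record
  fixed <- function(s, w) {
    s <- substr(s, 1, w)
    paste0(s, strrep(" ", w - nchar(s)))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(s, w) writeChar(fixed(s, w), con, eos = NULL)
  put("0", 8); put("X X X X", 80); put("Startdate 01-JAN-2000 X X X", 80)
  put("01.01.00", 8); put("00.00.00", 8)
  put(as.character(256 * (1 + ns)), 8); put("EDF+C", 44)
  put(as.character(n_rec), 8); put("1", 8); put(as.character(ns), 4)
  for (i in seq_len(nch)) put(labels[i], 16); put("EDF Annotations", 16)
  for (i in seq_len(ns)) put("", 80)
  for (i in seq_len(nch)) put("uV", 8); put("", 8)
  for (i in seq_len(nch)) put(as.character(phys_range[1]), 8); put("-1", 8)
  for (i in seq_len(nch)) put(as.character(phys_range[2]), 8); put("1", 8)
  for (i in seq_len(nch)) put("-32768", 8); put("-32768", 8)
  for (i in seq_len(nch)) put("32767", 8); put("32767", 8)
  for (i in seq_len(ns)) put("", 80)
  for (i in seq_len(nch)) put(as.character(fs), 8); put(as.character(ann_spr), 8)
  for (i in seq_len(ns)) put("", 32)
  scale <- (phys_range[2] - phys_range[1]) / (32767 - (-32768))
  dig <- round((data - phys_range[1]) / scale) + (-32768)
  dig <- pmin(pmax(dig, -32768), 32767)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (i in seq_len(nch))
      writeBin(as.integer(dig[i, idx]), con, size = 2L, endian = "little")
    raw_tal <- charToRaw(sprintf("+%g\x14\x14", r - 1))
    ev <- events[events$onset >= (r - 1) & events$onset < r, , drop = FALSE]
    for (k in seq_len(nrow(ev)))
      raw_tal <- c(raw_tal, as.raw(0),
                   charToRaw(sprintf("+%g\x150\x14%s\x14",
                                     ev$onset[k], ev$code[k])))
    pad <- ann_spr * 2L - length(raw_tal)
    stopifnot(pad >= 0)
    writeBin(c(raw_tal, raw(pad)), con)
  }
  invisible(path)
}
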