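# Minimal EDF+ reader: continuous recording with an "EDF Annotations" signal
# carrying event codes, epoched on the fly around each mapped event. Only the
# subset of EDF+ needed for feedback-locked epoching is implemented (int16
# little-endian samples, one annotation signal, uniform sampling across EEG
# signals).

read_ascii <- function(con, n) trimws(rawToChar(readBin(con, "raw", n)))

read_epochs_edf <- function(path, event_map, epoch_window, layout = NULL) {
  if (is.null(event_map) || is.null(names(event_map)))
    stop("EDF+ reading requires a named event_map (code -> 'beneficiary.magnitude.time')")
  con <- file(path, "rb")
  on.exit(close(con))
  read_ascii(con, 8)                       # version
  read_ascii(con, 80); read_ascii(con, 80) # patient, recording
  read_ascii(con, 8); read_ascii(con, 8)   # start date, time
  as.integer(read_ascii(con, 8))           # header length
  read_ascii(con, 44)                      # reserved ("EDF+C")
  n_rec <- as.integer(read_ascii(con, 8))
  dur <- as.numeric(read_ascii(con, 8))
  ns <- as.integer(read_ascii(con, 4))
  field <- function(w) vapply(seq_len(ns), function(i) read_ascii(con, w), "")
  labels <- field(16)
  field(80); dims <- field(8)
  phys_min <- as.numeric(field(8)); phys_max <- as.numeric(field(8))
  dig_min <- as.numeric(field(8)); dig_max <- as.numeric(field(8))
  field(80)
  spr <- as.integer(field(8))              # samples per record
  field(32)

  ann_idx <- which(labels == "EDF Annotations")
  sig_idx <- setdiff(seq_len(ns), ann_idx)
  if (!length(sig_idx)) stop("EDF file contains no EEG signals")
  if (length(unique(spr[sig_idx])) != 1)
    stop("non-uniform time axis: EEG signals have differing samples per record")
  fs <- spr[sig_idx[1]] / dur
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  offset <- phys_min - scale * dig_min

  sig <- lapply(sig_idx, function(i) numeric(0))
  names(sig) <- labels[sig_idx]
  chunks <- lapply(sig_idx, function(i) vector("list", n_rec))
  ann_bytes <- list()
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      if (i %in% ann_idx) {
        ann_bytes[[length(ann_bytes) + 1L]] <- readBin(con, "raw", spr[i] * 2L)
      } else {
        x <- readBin(con, "integer", spr[i], size = 2L, endian = "little")
        chunks[[match(i, sig_idx)]][[r]] <- x * scale[i] + offset[i]
      }
    }
  }
  data_cont <- do.call(cbind, lapply(chunks, function(ch) unlist(ch)))
  colnames(data_cont) <- labels[sig_idx]

  ev <- parse_edf_annotations(unlist(ann_bytes))
  ev <- ev[ev$text != "", , drop = FALSE]
  unknown <- setdiff(unique(ev$text), names(event_map))
  if (length(unknown))
    stop("event_map is missing code(s): ", paste(unknown, collapse = ", "))

  dt <- 1000 / fs
  i0 <- round(epoch_window[1] / dt); i1 <- round(epoch_window[2] / dt)
  times <- (i0:i1) * dt
  keep <- logical(nrow(ev))
  epochs <- vector("list", nrow(ev))
  for (k in seq_len(nrow(ev))) {
    s <- round(ev$onset[k] * fs) + 1L
    lo <- s + i0; hi <- s + i1
    if (lo >= 1 && hi <= nrow(data_cont)) {
      keep[k] <- TRUE
      epochs[[k]] <- t(data_cont[lo:hi, , drop = FALSE])
    }
  }
  ev <- ev[keep, , drop = FALSE]; epochs <- epochs[keep]
  if (!length(epochs)) stop("no mapped events with a complete epoch window")
  data <- array(0, dim = c(length(epochs), length(sig_idx), length(times)))
  for (k in seq_along(epochs)) data[k, , ] <- epochs[[k]]

  cells <- strsplit(unname(event_map[ev$text]), ".", fixed = TRUE)
  conditions <- data.frame(
    beneficiary = vapply(cells, `[`, "", 1),
    magnitude = vapply(cells, `[`, "", 2),
    time = vapply(cells, `[`, "", 3),
    stringsAsFactors = FALSE)
  conditions$ben <- ifelse(conditions$beneficiary == "self", -0.5, 0.5)
  conditions$mag <- ifelse(conditions$magnitude == "small", -0.5, 0.5)
  conditions$tim <- ifelse(conditions$time == "immediate", -0.5, 0.5)

  channels <- data.frame(name = labels[sig_idx], x = NA_real_, y = NA_real_,
                         stringsAsFactors = FALSE)
  if (!is.null(layout)) {
    m <- match(channels$name, layout$name)
    channels$x[!is.na(m)] <- layout$x[m[!is.na(m)]]
    channels$y[!is.na(m)] <- layout$y[m[!is.na(m)]]
  }
  epochset(data, times, channels, conditions,
           participant_id = basename(path))
}

# Parse EDF+ timestamped annotation lists. The raw annotation byte stream is a
# sequence of TALs ("+onset(\x15dur)?\x14text\x14...\x14") separated by NUL
# bytes; record-timestamp TALs carry an empty text and are dropped upstream.
parse_edf_annotations <- function(bytes) {
  nul <- as.raw(0)
  runs <- split(bytes, cumsum(bytes == nul))
  onset <- numeric(0); text <- character(0)
  for (run in runs) {
    run <- run[run != nul]
    if (!length(run)) next
    tal <- rawToChar(run)
    parts <- strsplit(tal, "\x14", fixed = TRUE)[[1]]
    head <- strsplit(parts[1], "\x15", fixed = TRUE)[[1]]
    t0 <- suppressWarnings(as.numeric(head[1]))
    if (is.na(t0)) next
    anns <- parts[-1]
    anns <- anns[nzchar(anns)]
    if (!length(anns)) {
      onset <- c(onset, t0); text <- c(text, "")
    } else {
      onset <- c(onset, rep(t0, length(anns))); text <- c(text, anns)
    }
  }
  data.frame(onset = onset, text = text, stringsAsFactors = FALSE)
}
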