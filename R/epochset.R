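# EpochSet: the package's core container for single-trial multichannel epochs.
# data is trial x channel x time (uV); times in ms relative to feedback onset.

.format_version <- c(major = 1L, minor = 0L)

#' Construct an EpochSet
#'
#' @param data numeric array trial x channel x time, in microvolts.
#' @param times numeric vector of time points (ms), strictly increasing and
#'   uniformly spaced.
#' @param channels data.frame with columns `name`, `x`, `y`.
#' @param conditions data.frame with one row per trial: string level columns
#'   `beneficiary`, `magnitude`, `time` and coded columns `ben`, `mag`, `tim`
#'   (values -0.5/+0.5).
#' @param participant_id character label.
#' @param baseline `NULL` if no baseline has been subtracted, else the
#'   (start, end) ms window that was.
#' @return object of class `epochset`.
#' @export
epochset <- function(data, times, channels, conditions,
                     participant_id = "P00", baseline = NULL) {
  stopifnot(length(dim(data)) == 3)
  dt <- diff(times)
  if (length(times) != dim(data)[3] || any(dt <= 0) ||
      (length(dt) > 1 && max(abs(dt - dt[1])) > 1e-6 * dt[1]))
    stop("times must be strictly increasing, uniformly spaced and match data")
  if (anyDuplicated(channels$name)) stop("duplicate channel names")
  if (nrow(channels) != dim(data)[2]) stop("channel table does not match data")
  if (nrow(conditions) != dim(data)[1]) stop("condition table does not match data")
  coded <- intersect(c("ben", "mag", "tim"), names(conditions))
  for (cc in coded)
    if (!all(conditions[[cc]] %in% c(-0.5, 0.5)))
      stop("coded condition values must be -0.5/+0.5 (column ", cc, ")")
  structure(list(data = data, times = as.numeric(times),
                 channels = channels, conditions = conditions,
                 participant_id = participant_id, baseline = baseline),
            class = "epochset")
}

#' @exportS3Method base::print
print.epochset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epochset> %s: %d trials x %d channels x %d samples, %g..%g ms @ %g Hz%s\n",
              x$participant_id, d[1], d[2], d[3], min(x$times), max(x$times),
              sampling_rate(x),
              if (is.null(x$baseline)) "" else
                sprintf(", baseline [%g, %g] ms", x$baseline[1], x$baseline[2])))
  invisible(x)
}

#' Sampling rate (Hz) of an EpochSet or TFR
#' @param x epochset or tfr object.
#' @export
sampling_rate <- function(x) 1000 / mean(diff(x$times))

#' Number of trials
#' @param x epochset object.
#' @export
n_trials <- function(x) dim(x$data)[1]

#' Index of channels by name (error if absent)
#' @keywords internal
channel_index <- function(x, names) {
  idx <- match(names, x$channels$name)
  if (anyNA(idx))
    stop("channel(s) not present: ", paste(names[is.na(idx)], collapse = ", "))
  idx
}

#' Indices of time points inside a window (endpoints inclusive on the grid)
#' @keywords internal
time_index <- function(times, window) {
  stopifnot(length(window) == 2, window[1] <= window[2])
  idx <- which(times >= window[1] - 1e-9 & times <= window[2] + 1e-9)
  if (!length(idx)) stop("window [", window[1], ", ", window[2],
                         "] ms contains no sample")
  idx
}

#' Subset an EpochSet
#'
#' @param e epochset.
#' @param trials,channels,time_window optional trial indices / channel names /
#'   (start, end) ms window to retain.
#' @return epochset.
#' @export
subset_epochs <- function(e, trials = NULL, channels = NULL, time_window = NULL) {
  ti <- if (is.null(trials)) seq_len(n_trials(e)) else trials
  ci <- if (is.null(channels)) seq_len(dim(e$data)[2]) else channel_index(e, channels)
  si <- if (is.null(time_window)) seq_along(e$times) else time_index(e$times, time_window)
  epochset(e$data[ti, ci, si, drop = FALSE], e$times[si],
           e$channels[ci, , drop = FALSE], e$conditions[ti, , drop = FALSE],
           e$participant_id, e$baseline)
}

# ---------------------------------------------------------------------------
# Internal on-disk container: a directory holding meta.json, channels.csv,
# conditions.csv and data.bin (little-endian float32, trial-major then channel
# then time). Versioned; readers reject unknown major versions.

#' Write an EpochSet to the internal directory container
#'
#' The container is a directory with `meta.json` (format version, participant,
#' time axis, dimensions, baseline state), `channels.csv`, `conditions.csv` and
#' `data.bin` (raw little-endian float32). Data round-trips to float32
#' precision; metadata round-trips exactly.
#'
#' @param e epochset.
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(e, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(e$data)
  meta <- list(format = "prosorew-epochs",
               version = list(major = .format_version[["major"]],
                              minor = .format_version[["minor"]]),
               participant_id = e$participant_id,
               n_trials = d[1], n_channels = d[2], n_times = d[3],
               t0_ms = e$times[1], dt_ms = mean(diff(e$times)),
               baseline = if (is.null(e$baseline)) NULL else as.numeric(e$baseline))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.csv(e$channels, file.path(path, "channels.csv"), row.names = FALSE)
  utils::write.csv(e$conditions, file.path(path, "conditions.csv"), row.names = FALSE)
  con <- file(file.path(path, "data.bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(aperm(e$data, c(3, 2, 1))), con, size = 4L,
           endian = "little")
  invisible(path)
}

#' Read an EpochSet
#'
#' @param path file or directory to read.
#' @param format one of `"internal"` (directory container written by
#'   [write_epochs()]) or `"edf"` (continuous EDF+ with annotation events,
#'   epoched on the fly). `"eeglab-set"` is recognized but unsupported.
#' @param event_map (EDF+ only) named character vector mapping annotation text
#'   codes to design cells `"beneficiary.magnitude.time"`,
#'   e.g. `c("11" = "self.small.immediate")`.
#' @param epoch_window (EDF+ only) (start, end) ms window around each event.
#' @param layout (EDF+ only) optional channel-position table to merge by name.
#' @return epochset.
#' @export
read_epochs <- function(path, format = c("internal", "edf", "eeglab-set"),
                        event_map = NULL, epoch_window = c(-200, 1000),
                        layout = NULL) {
  format <- match.arg(format)
  switch(format,
         "internal" = read_epochs_internal(path),
         "edf" = read_epochs_edf(path, event_map, epoch_window, layout),
         "eeglab-set" = stop("format 'eeglab-set' is not supported: no MATLAB ",
                             "v5 reader is available; export to EDF+ or the ",
                             "internal container instead"))
}

read_epochs_internal <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"))
  if (!identical(meta$format, "prosorew-epochs"))
    stop("not a prosorew epochs container: ", path)
  if (meta$version$major != .format_version[["major"]])
    stop("unsupported container major version ", meta$version$major)
  channels <- utils::read.csv(file.path(path, "channels.csv"),
                              stringsAsFactors = FALSE)
  conditions <- utils::read.csv(file.path(path, "conditions.csv"),
                                stringsAsFactors = FALSE)
  n <- meta$n_trials * meta$n_channels * meta$n_times
  con <- file(file.path(path, "data.bin"), "rb")
  on.exit(close(con))
  raw <- readBin(con, "numeric", n = n, size = 4L, endian = "little")
  data <- aperm(array(raw, dim = c(meta$n_times, meta$n_channels, meta$n_trials)),
                c(3, 2, 1))
  times <- meta$t0_ms + meta$dt_ms * (seq_len(meta$n_times) - 1)
  baseline <- if (is.null(meta$baseline)) NULL else unlist(meta$baseline)
  epochset(data, times, channels, conditions, meta$participant_id, baseline)
}
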