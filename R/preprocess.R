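#' Construct a multichannel recording
#'
#' A recording holds one continuous multichannel signal together with the
#' annotations the hierarchical analysis needs: animal (`cat`), recording
#' `session`, and the condition — either a vigilance state (`W`, `LS`,
#' `SWS`, `REM`) or a ketamine dose in mg/kg (0 denotes the pre-injection
#' baseline), plus an auditory-stimulation flag.
#'
#' @param signals Named list of equal-length numeric vectors (microvolts),
#'   one per channel; names are cortex labels and must be unique.
#' @param fs Sampling rate in Hz (the reference design uses 1024).
#' @param cat,session Identifiers for the animal and session.
#' @param state Vigilance state label, or `NA` for dose recordings.
#' @param dose Ketamine dose (mg/kg), or `NA` for sleep recordings.
#' @param stim Logical: auditory click stimulation present.
#' @return An object of class `lz_recording`.
#' @export
recording <- function(signals, fs, cat, session, state = NA, dose = NA,
                      stim = FALSE) {
  if (!is.list(signals) || length(signals) == 0L)
    stop("signals must be a non-empty named list of numeric vectors")
  if (is.null(names(signals)) || anyDuplicated(names(signals)))
    stop("channel labels must be present and unique within a recording")
  lens <- lengths(signals)
  if (length(unique(lens)) != 1L)
    stop("all channels must have equal length (got ",
         paste(unique(lens), collapse = ", "), ")")
  if (!is.numeric(fs) || fs <= 0) stop("fs must be a positive sampling rate")
  if (!is.na(state) && !is.na(dose))
    stop("exactly one of state/dose may be set")
  structure(
    list(signals = signals, fs = fs, cat = as.character(cat),
         session = as.character(session), state = state, dose = dose,
         stim = isTRUE(stim)),
    class = "lz_recording"
  )
}

# Cascade of order-4 Butterworth high-pass and low-pass sections, each
# applied forward-backward (zero phase). A single band-pass design with a
# 0.5 Hz edge at fs = 1024 is numerically fragile in transfer-function
# form; the cascade is stable and gives the same passband.
.bp_filter <- function(x, fs, lo, hi, order = 4L) {
  ny <- fs / 2
  # the mean (0 Hz) is below any admissible lo and is removed exactly,
  # so short windows are not dominated by the high-pass edge transient
  x <- x - mean(x)
  hp <- signal::butter(order, lo / ny, type = "high")
  lp <- signal::butter(order, hi / ny, type = "low")
  x <- signal::filtfilt(hp, x)
  signal::filtfilt(lp, x)
}

#' Zero-phase band-pass filter
#'
#' Band-passes every channel of a recording with a 4th-order Butterworth
#' filter applied forward-backward (zero phase, so the binarization
#' threshold crossing times are not shifted). Defaults match the analysis
#' band of 0.5-200 Hz.
#'
#' @param rec An `lz_recording`.
#' @param lo,hi Band edges in Hz; requires `0 < lo < hi < fs/2`.
#' @return The filtered recording (same class, same lengths).
#' @export
bandpass <- function(rec, lo = 0.5, hi = 200) {
  stopifnot(inherits(rec, "lz_recording"))
  if (lo <= 0 || lo >= hi)
    stop("band edges must satisfy 0 < lo < hi (got ", lo, ", ", hi, ")")
  if (hi >= rec$fs / 2)
    stop("upper edge ", hi, " Hz is at or above Nyquist (fs = ", rec$fs,
         " Hz) for channels ", paste(names(rec$signals), collapse = ", "))
  rec$signals <- lapply(rec$signals, .bp_filter, fs = rec$fs, lo = lo, hi = hi)
  rec
}

#' Split a recording into fixed-length epochs
#'
#' Cuts each channel into consecutive, non-overlapping, half-open windows
#' of `epoch_samples` samples, 0-indexed. A trailing remainder shorter than
#' one epoch is dropped (never zero-padded, since padding would bias the
#' complexity of the final epoch downward). A recording shorter than one
#' epoch yields an empty epoch set.
#'
#' @param rec An `lz_recording`.
#' @param epoch_samples Epoch length in samples (default 5120, i.e. 5 s at
#'   1024 Hz); must be at least 2.
#' @return An `lz_epochs` object: a list with `meta` (data frame of
#'   annotations, one row per epoch) and `samples` (list of numeric
#'   vectors), plus the sampling rate.
#' @export
segment_epochs <- function(rec, epoch_samples = 5120) {
  stopifnot(inherits(rec, "lz_recording"))
  if (epoch_samples < 2) stop("epoch_samples must be at least 2")
  n <- length(rec$signals[[1]])
  k <- n %/% epoch_samples
  meta <- list()
  samples <- list()
  for (ch in names(rec$signals)) {
    x <- rec$signals[[ch]]
    for (j in seq_len(k)) {
      idx <- ((j - 1L) * epoch_samples + 1L):(j * epoch_samples)
      samples[[length(samples) + 1L]] <- x[idx]
      meta[[length(meta) + 1L]] <- data.frame(
        cat = rec$cat, session = rec$session, channel = ch,
        state = rec$state, dose = rec$dose, stim = rec$stim,
        epoch = j - 1L, stringsAsFactors = FALSE)
    }
  }
  meta <- if (length(meta)) do.call(rbind, meta) else
    data.frame(cat = character(), session = character(), channel = character(),
               state = character(), dose = numeric(), stim = logical(),
               epoch = integer(), stringsAsFactors = FALSE)
  structure(list(meta = meta, samples = samples, fs = rec$fs),
            class = "lz_epochs")
}

#' Combine epoch sets
#'
#' @param ... `lz_epochs` objects with identical sampling rates.
#' @return A single `lz_epochs` object with rows concatenated in order.
#' @export
bind_epochs <- function(...) {
  sets <- list(...)
  sets <- sets[vapply(sets, function(e) nrow(e$meta) > 0, logical(1))]
  if (!length(sets))
    return(structure(list(meta = data.frame(), samples = list(), fs = NA_real_),
                     class = "lz_epochs"))
  fs <- unique(vapply(sets, `[[`, numeric(1), "fs"))
  stopifnot(length(fs) == 1L)
  structure(list(
    meta = do.call(rbind, lapply(sets, `[[`, "meta")),
    samples = do.call(c, lapply(sets, `[[`, "samples")),
    fs = fs
  ), class = "lz_epochs")
}

#' Amplitude-based artifact rejection
#'
#' Drops any epoch whose peak absolute amplitude exceeds `z_max` times a
#' robust (median-absolute-deviation based) scale estimate of its
#' channel's full-session signal, i.e. the concatenation of all epochs
#' sharing the same cat, session and channel. This is a deterministic
#' automated stand-in for visual artifact screening: large transients
#' (movement artifacts) exceed a robust amplitude envelope that stationary
#' physiological signal does not.
#'
#' @param epochs An `lz_epochs` object.
#' @param z_max Rejection threshold in robust-scale units (default 6).
#' @return A list with `epochs` (the survivors, original order preserved)
#'   and `log`, a data frame with one row per input epoch recording `kept`
#'   and `reject_reason`.
#' @export
reject_artifacts <- function(epochs, z_max = 6) {
  stopifnot(inherits(epochs, "lz_epochs"))
  if (z_max <= 0) stop("z_max must be positive")
  n <- length(epochs$samples)
  if (n == 0L) {
    return(list(epochs = epochs,
                log = cbind(epochs$meta,
                            data.frame(kept = logical(0),
                                       reject_reason = character(0)))))
  }
  grp <- interaction(epochs$meta$cat, epochs$meta$session,
                     epochs$meta$channel, drop = TRUE)
  keep <- logical(n)
  reason <- character(n)
  for (g in levels(grp)) {
    idx <- which(grp == g)
    scale <- stats::mad(unlist(epochs$samples[idx]))
    peaks <- vapply(epochs$samples[idx], function(x) max(abs(x)), numeric(1))
    bad <- peaks > z_max * scale
    keep[idx] <- !bad
    reason[idx][bad] <- sprintf("peak %.3g exceeds %g x channel scale %.3g",
                                peaks[bad], z_max, scale)
  }
  log <- epochs$meta
  log$kept <- keep
  log$reject_reason <- reason
  kept <- structure(list(meta = epochs$meta[keep, , drop = FALSE],
                         samples = epochs$samples[keep],
                         fs = epochs$fs),
                    class = "lz_epochs")
  rownames(kept$meta) <- NULL
  list(epochs = kept, log = log)
}
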