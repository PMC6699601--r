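#' Raw multichannel recording for one team member
#'
#' @param member integer member id.
#' @param channels character channel labels (10-20 names expected).
#' @param fs sampling rate in Hz, above 80.
#' @param samples numeric matrix, one row per channel, columns are samples.
#' @param start_s offset of the first sample on the task clock, whole seconds.
#' @return a `raw_recording` list.
#' @export
raw_recording <- function(member, channels, fs, samples, start_s = 0L) {
  samples <- as.matrix(samples)
  if (nrow(samples) != length(channels)) {
    stop("samples must have one row per channel")
  }
  if (fs <= 80) stop("sampling rate must exceed 80 Hz")
  rownames(samples) <- channels
  structure(list(member = as.integer(member), channels = channels,
                 fs = fs, samples = samples, start_s = as.integer(start_s)),
            class = "raw_recording")
}

#' Per-second band power in 1-Hz bins
#'
#' Splits each channel into non-overlapping 1-s epochs, computes a tapered
#' periodogram per epoch (Hann taper by default) and collects the power at
#' the 1-Hz bins centered at `bins` (with 1-s epochs the frequency resolution
#' is exactly 1 Hz, so each bin holds one Fourier coefficient, one-sided
#' scaling). The trailing partial second is dropped. Any epoch containing
#' `NaN`/`NA` samples is marked missing for that second.
#'
#' @param rec a [raw_recording()].
#' @param bins integer bin centers in Hz, default 1:40.
#' @param taper `"hann"` (default) or `"none"` (rectangular). A Hann taper on
#'   a 1-s epoch leaks about a sixth of a pure tone's power into each
#'   adjacent 1-Hz bin; the rectangular taper concentrates an integer-Hz tone
#'   entirely in its own bin but leaks badly off the grid.
#' @return a `power_tensor` with seconds aligned to the task clock via the
#'   recording's `start_s`. The channel labels become sensor labels.
#' @export
band_power_per_second <- function(rec, bins = 1:40, taper = c("hann", "none")) {
  taper <- match.arg(taper)
  stopifnot(inherits(rec, "raw_recording"))
  fs <- rec$fs
  if (fs != round(fs)) stop("sampling rate must be an integer number of Hz")
  fs <- as.integer(round(fs))
  if (fs < 2 * max(bins)) {
    stop("sampling rate below twice the highest bin (aliasing)")
  }
  n_sec <- ncol(rec$samples) %/% fs
  if (n_sec < 1L) stop("recording shorter than one second")
  w <- if (taper == "hann") {
    0.5 * (1 - cos(2 * pi * seq(0, fs - 1) / fs))
  } else rep(1, fs)
  scale <- 2 / (fs * sum(w^2))
  out <- vector("list", length(rec$channels))
  for (ci in seq_along(rec$channels)) {
    pw <- matrix(NA_real_, nrow = n_sec, ncol = length(bins))
    for (s in seq_len(n_sec)) {
      x <- rec$samples[ci, ((s - 1L) * fs + 1L):(s * fs)]
      if (anyNA(x) || any(is.nan(x))) next
      spec <- Mod(stats::fft(w * x))^2 * scale
      pw[s, ] <- spec[bins + 1L]
    }
    out[[ci]] <- data.frame(member = rec$member, sensor = rec$channels[ci],
                            freq_hz = rep(bins, each = n_sec),
                            second = rep(0:(n_sec - 1L) + rec$start_s,
                                         times = length(bins)),
                            power = as.numeric(pw))
  }
  as_power_tensor(do.call(rbind, out))
}

#' Align several members' power tensors on a common task clock
#'
#' Members must share the task clock and overlap in time; the result spans
#' the union of their time ranges, and seconds where a member is absent are
#' marked missing for that member (never dropped), so prolonged periods of a
#' member being out of the room stay visible downstream.
#'
#' @param tensors list of `power_tensor`s, one per member.
#' @param events optional data frame of [event_segment()] rows; when given,
#'   the result is cropped to the union span of the events.
#' @return a single `power_tensor`.
#' @export
align_members <- function(tensors, events = NULL) {
  tensors <- lapply(tensors, as_power_tensor)
  spans <- lapply(tensors, function(x) range(x$second))
  lo <- max(vapply(spans, `[`, 0, 1))
  hi <- min(vapply(spans, `[`, 0, 2))
  if (lo > hi) stop("member time spans are disjoint; no common task clock")
  all_sec <- seq(min(vapply(spans, `[`, 0, 1)),
                 max(vapply(spans, `[`, 0, 2)))
  filled <- lapply(tensors, function(x) {
    streams <- unique(x[c("member", "sensor", "freq_hz")])
    grid <- merge(streams, data.frame(second = all_sec))
    out <- merge(grid, x, all.x = TRUE,
                 by = c("member", "sensor", "freq_hz", "second"))
    out
  })
  out <- do.call(rbind, filled)
  if (!is.null(events)) {
    keep <- rep(FALSE, nrow(out))
    for (i in seq_len(nrow(events))) {
      keep <- keep | (out$second >= events$start_s[i] &
                        out$second < events$end_s[i])
    }
    out <- out[keep, ]
  }
  out <- out[order(out$member, out$sensor, out$freq_hz, out$second), ]
  rownames(out) <- NULL
  as_power_tensor(out)
}
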