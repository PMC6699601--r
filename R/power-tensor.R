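#' Validate a per-second power tensor
#'
#' A power tensor is a long data frame holding per-second EEG power for every
#' (member, sensor, 1-Hz frequency bin) stream. Power is non-negative where
#' present; `NA` marks seconds where a stream is missing (for example while a
#' team member was outside the room). The seconds axis is integer, 0-based and
#' aligned to the task clock.
#'
#' @param x data frame with columns `member` (integer), `sensor` (character),
#'   `freq_hz` (integer), `second` (integer), `power` (numeric, `NA` allowed).
#' @return `x`, invisibly coerced to canonical column order and classed
#'   `power_tensor`.
#' @export
as_power_tensor <- function(x) {
  required <- c("member", "sensor", "freq_hz", "second", "power")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    stop("power tensor is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  x <- as.data.frame(x)[required]
  x$member <- as.integer(x$member)
  x$sensor <- as.character(x$sensor)
  x$freq_hz <- as.integer(x$freq_hz)
  x$second <- as.integer(x$second)
  x$power <- as.numeric(x$power)
  if (any(x$power < 0, na.rm = TRUE)) stop("power must be >= 0 where present")
  if (any(x$second < 0)) stop("seconds are 0-based and must be >= 0")
  class(x) <- unique(c("power_tensor", class(x)))
  x
}

#' Labeled half-open event segment on the task clock
#'
#' @param label character scalar.
#' @param start_s,end_s segment bounds in seconds; the interval is
#'   `[start_s, end_s)` and must be non-empty.
#' @return a one-row data frame with columns `label`, `start_s`, `end_s`.
#' @export
event_segment <- function(label, start_s, end_s) {
  stopifnot(is.character(label), length(label) == 1L)
  if (!(end_s > start_s)) stop("event '", label, "': end_s must exceed start_s")
  data.frame(label = label, start_s = as.numeric(start_s), end_s = as.numeric(end_s))
}

#' Write a power tensor as tidy CSV with a missing-span sidecar
#'
#' Missing rows are omitted from the CSV; a JSON sidecar (`<path>.missing.json`)
#' lists, per member, the seconds that were present-but-missing so the tensor
#' round-trips exactly.
#'
#' @param tensor a `power_tensor`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_power_tensor <- function(tensor, path) {
  tensor <- as_power_tensor(tensor)
  miss <- tensor[is.na(tensor$power), c("member", "sensor", "freq_hz", "second")]
  present <- tensor[!is.na(tensor$power), ]
  utils::write.csv(present, path, row.names = FALSE, quote = FALSE)
  sidecar <- paste0(path, ".missing.json")
  jsonlite::write_json(miss, sidecar, dataframe = "columns")
  invisible(path)
}

#' Read a power tensor written by [write_power_tensor()]
#'
#' @param path CSV path; the `<path>.missing.json` sidecar is read when present.
#' @return a `power_tensor` with `NA` power restored for recorded missing rows.
#' @export
read_power_tensor <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  sidecar <- paste0(path, ".missing.json")
  if (file.exists(sidecar)) {
    miss <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (length(miss) && NROW(miss$member)) {
      miss <- data.frame(member = as.integer(miss$member),
                         sensor = as.character(miss$sensor),
                         freq_hz = as.integer(miss$freq_hz),
                         second = as.integer(miss$second),
                         power = NA_real_)
      x <- rbind(x, miss)
    }
  }
  x <- x[order(x$member, x$sensor, x$freq_hz, x$second), ]
  rownames(x) <- NULL
  as_power_tensor(x)
}

# internal: the stream key shared by tensors and level frames
stream_id <- function(x) paste(x$member, x$sensor, x$freq_hz, sep = "\r")
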