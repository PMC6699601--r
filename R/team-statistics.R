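#' Member-level neurodynamic information
#'
#' Deconstructs team organization into one member's contribution: each of the
#' member's (sensor, bin) level streams is converted to a 3-state symbol
#' stream, sliding NI is computed with S = 3, and the traces are averaged
#' across the member's sensors and bins.
#'
#' @param levels a level tensor (see [discretize_power()]).
#' @param member member index; required when the tensor holds several members.
#' @param window entropy window in seconds.
#' @param n_levels number of power categories (3 unless discretized finer).
#' @param ... passed to [sliding_ni()].
#' @return data frame `second, ni, n_traces`.
#' @export
member_ni <- function(levels, member = NULL, window = 60L,
                      n_levels = attr(levels, "n_levels"), ...) {
  if (is.null(n_levels)) n_levels <- 3L
  if (!is.null(member)) levels <- levels[levels$member == member, ]
  if (!nrow(levels)) stop("no level rows for the requested member")
  if (length(unique(levels$member)) > 1L) {
    stop("level tensor holds several members; pass `member`")
  }
  sid <- paste(levels$sensor, levels$freq_hz, sep = "\r")
  traces <- lapply(split(seq_len(nrow(levels)), sid), function(idx) {
    x <- levels[idx, ]
    x <- x[order(x$second), ]
    sym <- level_to_digit(x$level, n_levels)
    sliding_ni(sym, state_space = n_levels, window = window,
               second0 = x$second[1], ...)
  })
  average_ni(traces)
}

# internal: {-1,1,3} -> {0,1,2} (k = 3), or 1..k -> 0..k-1 otherwise
level_to_digit <- function(level, n_levels = 3L) {
  if (n_levels != 3L) return(as.integer(level) - 1L)
  d <- rep(NA_integer_, length(level))
  d[!is.na(level) & level == -1L] <- 0L
  d[!is.na(level) & level == 1L] <- 1L
  d[!is.na(level) & level == 3L] <- 2L
  d
}

#' Lagged cross-correlation of two NI traces
#'
#' Pearson correlation at every integer lag in `[-max_lag_s, max_lag_s]`,
#' computed on overlapping non-missing pairs. The best lag maximizes `|r|`
#' (ties broken toward the smaller `|lag|`); a positive reported lag means
#' the first series leads the second.
#'
#' @param a,b NI traces (data frames with `second` and `ni`).
#' @param max_lag_s maximum lag searched, default 60 s.
#' @return list with `r`, `lag_s` and the full `profile` (`lag`, `r`, `n`).
#' @export
cross_correlate <- function(a, b, max_lag_s = 60L) {
  secs <- min(a$second[1], b$second[1]):max(a$second[nrow(a)],
                                            b$second[nrow(b)])
  va <- rep(NA_real_, length(secs))
  vb <- rep(NA_real_, length(secs))
  va[match(a$second, secs)] <- a$ni
  vb[match(b$second, secs)] <- b$ni
  n_overlap <- sum(!is.na(va) & !is.na(vb))
  if (n_overlap < 3 * max_lag_s) {
    stop("need at least 3 * max_lag_s overlapping valid seconds (have ",
         n_overlap, ")")
  }
  lags <- (-max_lag_s):max_lag_s
  prof <- data.frame(lag = lags, r = NA_real_, n = NA_integer_)
  n <- length(secs)
  for (i in seq_along(lags)) {
    l <- lags[i]
    if (l >= 0) {
      x <- va[seq_len(n - l)]
      y <- vb[seq_len(n - l) + l]
    } else {
      x <- va[seq_len(n + l) - l]
      y <- vb[seq_len(n + l)]
    }
    ok <- !is.na(x) & !is.na(y)
    prof$n[i] <- sum(ok)
    if (sum(ok) >= 3 && stats::sd(x[ok]) > 0 && stats::sd(y[ok]) > 0) {
      prof$r[i] <- stats::cor(x[ok], y[ok])
    }
  }
  valid <- which(!is.na(prof$r))
  if (!length(valid)) stop("no lag had enough valid overlapping pairs")
  best <- valid[order(-abs(prof$r[valid]), abs(prof$lag[valid]))][1]
  list(r = prof$r[best], lag_s = prof$lag[best], profile = prof)
}

#' Frequency-band schemes
#'
#' Scheme `"A"`: delta/theta 3-7, alpha 8-11, mu 12-17, low beta 18-22, high
#' beta/gamma 23-40 Hz. Scheme `"B"` splits the top range into high beta
#' 23-32 and gamma 33-40 Hz. Ranges are inclusive, within 1-40 Hz, and
#' non-overlapping within a scheme.
#'
#' @param scheme `"A"`, `"B"`, or a named list of `c(lo, hi)` ranges.
#' @return named list of integer bin vectors.
#' @export
band_scheme <- function(scheme = c("A", "B")) {
  if (is.list(scheme)) {
    ranges <- scheme
  } else {
    scheme <- match.arg(scheme)
    ranges <- list(delta_theta = c(3, 7), alpha = c(8, 11), mu = c(12, 17),
                   low_beta = c(18, 22))
    ranges <- if (scheme == "A") {
      c(ranges, list(high_beta_gamma = c(23, 40)))
    } else {
      c(ranges, list(high_beta = c(23, 32), gamma = c(33, 40)))
    }
  }
  bands <- lapply(ranges, function(r) seq.int(r[1], r[2]))
  if (any(unlist(bands) < 1 | unlist(bands) > 40)) {
    stop("band ranges must lie within 1-40 Hz")
  }
  if (anyDuplicated(unlist(bands))) stop("bands overlap within the scheme")
  bands
}

#' Average NI within frequency bands
#'
#' @param ni_set data frame with `freq_hz`, `second`, `ni` (e.g. [team_ni()]
#'   output, possibly restricted to one sensor).
#' @param scheme a [band_scheme()] (or a scheme name).
#' @return data frame `band, second, ni, n_traces`.
#' @export
band_aggregate <- function(ni_set, scheme = "A") {
  if (!is.list(scheme)) scheme <- band_scheme(scheme)
  pieces <- lapply(names(scheme), function(bn) {
    rows <- ni_set[ni_set$freq_hz %in% scheme[[bn]], ]
    if (!nrow(rows)) {
      stop("band '", bn, "' has no bins present in the NI set")
    }
    avg <- average_ni(rows)
    cbind(band = bn, avg)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Scalp-region sensor maps
#'
#' Built-in anterior/posterior groupings for the two montages: the
#' simulation montage uses anterior F3, Fz, F4 and posterior P3, Pz, P4; the
#' live (headband) montage uses anterior Fp1, Fpz, Fp2, F7, F8 and posterior
#' P7, O1, Oz, O2, P8. Regions must be disjoint.
#'
#' @param montage `"simulation"`, `"live"`, or a named list of sensor-label
#'   vectors.
#' @return named list of character vectors.
#' @export
region_map <- function(montage = c("simulation", "live")) {
  if (is.list(montage)) {
    map <- montage
  } else {
    montage <- match.arg(montage)
    map <- if (montage == "simulation") {
      list(anterior = c("F3", "Fz", "F4"), posterior = c("P3", "Pz", "P4"))
    } else {
      list(anterior = c("Fp1", "Fpz", "Fp2", "F7", "F8"),
           posterior = c("P7", "O1", "Oz", "O2", "P8"))
    }
  }
  if (anyDuplicated(unlist(map))) stop("regions must be disjoint")
  map
}

# internal: rank-sum Z with tie correction (no continuity correction)
rank_sum_z <- function(x, y) {
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  rk <- rank(c(x, y))
  W <- sum(rk[seq_len(n1)])
  mu <- n1 * (N + 1) / 2
  ties <- table(rk)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
  if (sigma2 <= 0) return(0)
  (W - mu) / sqrt(sigma2)
}

#' Anterior/posterior (or any two-region) NI contrast
#'
#' Two-sided rank-sum (Wilcoxon/Mann-Whitney) test on the per-sensor
#' per-second NI samples of two scalp regions. The Z statistic uses the
#' normal approximation with tie correction; for fewer than 20 samples per
#' side (and no ties) the exact p-value is used. The fold ratio is the ratio
#' of region means (first over second). No multiple-testing correction is
#' applied; callers performing several contrasts should report the count.
#'
#' @param ni_set data frame with `sensor`, `second`, `ni` (e.g. [team_ni()]
#'   averaged over bins, or restricted to an event window with
#'   [bracket_event()]).
#' @param map a [region_map()].
#' @param regions character pair naming the regions to contrast (default the
#'   first two in the map).
#' @return list: `Z`, `p`, `median` (named pair), `fold_ratio`, `n` (named
#'   pair), `regions`.
#' @export
region_contrast <- function(ni_set, map, regions = names(map)[1:2]) {
  samples <- lapply(regions, function(rg) {
    sensors <- map[[rg]]
    if (is.null(sensors)) stop("region '", rg, "' not in the region map")
    present <- intersect(sensors, unique(ni_set$sensor))
    if (!length(present)) {
      stop("region '", rg, "' has no mapped sensors in the data (wanted: ",
           paste(sensors, collapse = ", "), ")")
    }
    v <- ni_set$ni[ni_set$sensor %in% present]
    v[!is.na(v)]
  })
  x <- samples[[1]]; y <- samples[[2]]
  if (!length(x) || !length(y)) stop("a region has no valid NI samples")
  Z <- rank_sum_z(x, y)
  has_ties <- anyDuplicated(c(x, y)) > 0
  p <- if (min(length(x), length(y)) < 20 && !has_ties) {
    stats::wilcox.test(x, y, exact = TRUE)$p.value
  } else {
    2 * stats::pnorm(-abs(Z))
  }
  list(Z = Z, p = p,
       median = stats::setNames(c(stats::median(x), stats::median(y)), regions),
       fold_ratio = mean(x) / mean(y),
       n = stats::setNames(c(length(x), length(y)), regions),
       regions = regions)
}

#' Bracket an event with surrounding context
#'
#' Restricts a trace or tensor (any data frame with a `second` column) to
#' `[start - pad_s, end + pad_s)` intersected with the recording span, and
#' flags the core interval.
#'
#' @param x data frame with a `second` column.
#' @param event one-row data frame from [event_segment()].
#' @param pad_s context padding in seconds, default 60.
#' @return the restricted data frame with a logical `core` column.
#' @export
bracket_event <- function(x, event, pad_s = 60L) {
  span <- range(x$second)
  lo <- max(event$start_s - pad_s, span[1])
  hi <- min(event$end_s + pad_s, span[2] + 1)
  if (event$start_s > span[2] || event$end_s <= span[1]) {
    stop("event '", event$label, "' lies outside the recording")
  }
  out <- x[x$second >= lo & x$second < hi, ]
  if (!nrow(out)) stop("event window does not intersect the recording")
  out$core <- out$second >= event$start_s & out$second < event$end_s
  rownames(out) <- NULL
  out
}

#' Raw-level composition within event windows
#'
#' Shifts the analysis from NI back to the underlying power levels: for each
#' event the distribution of {-1, 1, 3} and the mean level are computed over
#' the selected streams' seconds, separating organization driven by
#' persistently low power (e.g. gamma suppression) from persistently high
#' power. Across two or more events a Kruskal-Wallis test on the per-second
#' level values is reported (H, df = k - 1, p).
#'
#' @param levels a level tensor.
#' @param events data frame of [event_segment()] rows.
#' @param bins optional integer bins to keep (e.g. a gamma band).
#' @param sensors optional sensor labels to keep.
#' @return list: `composition` (data frame `event, n, p_low, p_avg, p_high,
#'   mean_level`) and `test` (list `H, df, p`, `NULL` with fewer than two
#'   usable events).
#' @export
level_composition <- function(levels, events, bins = NULL, sensors = NULL) {
  x <- levels
  if (!is.null(bins)) x <- x[x$freq_hz %in% bins, ]
  if (!is.null(sensors)) x <- x[x$sensor %in% sensors, ]
  if (!nrow(x)) stop("no level rows after band/sensor selection")
  rows <- list(); pooled <- list()
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    v <- x$level[x$second >= ev$start_s & x$second < ev$end_s]
    v <- v[!is.na(v)]
    if (!length(v)) {
      warning("event '", ev$label, "' has no valid seconds; excluded")
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      event = ev$label, n = length(v),
      p_low = mean(v == -1L), p_avg = mean(v == 1L), p_high = mean(v == 3L),
      mean_level = mean(v))
    pooled[[length(pooled) + 1L]] <- data.frame(event = ev$label, level = v)
  }
  if (!length(rows)) stop("no event had valid seconds")
  comp <- do.call(rbind, rows)
  test <- NULL
  if (length(pooled) >= 2L) {
    df <- do.call(rbind, pooled)
    kw <- stats::kruskal.test(df$level, factor(df$event))
    test <- list(H = unname(kw$statistic), df = unname(kw$parameter),
                 p = kw$p.value)
  }
  list(composition = comp, test = test)
}

#' Time-by-frequency NI matrix for one sensor
#'
#' @param ni_set data frame with `sensor`, `freq_hz`, `second`, `ni`.
#' @param sensor sensor label.
#' @return numeric matrix, rows = seconds (rownames), columns = frequency
#'   bins (colnames); missing cells are `NA`. Suitable for heat-map export.
#' @export
time_frequency_map <- function(ni_set, sensor) {
  x <- ni_set[ni_set$sensor == sensor, ]
  if (!nrow(x)) stop("sensor '", sensor, "' not present in the NI set")
  secs <- sort(unique(x$second))
  bins <- sort(unique(x$freq_hz))
  m <- matrix(NA_real_, nrow = length(secs), ncol = length(bins),
              dimnames = list(secs, bins))
  m[cbind(match(x$second, secs), match(x$freq_hz, bins))] <- x$ni
  m
}
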