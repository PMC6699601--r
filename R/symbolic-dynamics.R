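#' Tertile thresholds for power discretization
#'
#' Cuts a power stream at the empirical 33.33rd and 66.67th percentiles of its
#' non-missing values, computed over the whole analyzed recording, so the
#' low/average/high categories are (near-)balanced. Balanced categories put
#' the baseline entropy of a disorganized stream at its ceiling, which makes
#' elevated neurodynamic information a deviation from a common floor.
#'
#' @param power numeric vector of per-second power values (`NA` = missing).
#' @return list with `low_cut`, `high_cut` and a `degenerate` flag. The stream
#'   is degenerate when all non-missing values are identical; discretization
#'   then maps every present second to the average level (1).
#' @seealso [discretize_stream()]
#' @export
tertile_thresholds <- function(power) {
  x <- power[!is.na(power)]
  if (length(x) < 3L) stop("need at least 3 non-missing values for tertiles")
  degenerate <- length(unique(x)) == 1L
  q <- stats::quantile(x, probs = c(1 / 3, 2 / 3), names = FALSE, type = 7)
  list(low_cut = q[1], high_cut = q[2], degenerate = degenerate)
}

#' Mean +/- 1 SD thresholds (alternative categorization)
#'
#' @inheritParams tertile_thresholds
#' @return same shape as [tertile_thresholds()].
#' @export
mean_sd_thresholds <- function(power) {
  x <- power[!is.na(power)]
  if (length(x) < 3L) stop("need at least 3 non-missing values")
  s <- stats::sd(x)
  list(low_cut = mean(x) - s, high_cut = mean(x) + s,
       degenerate = isTRUE(s == 0))
}

#' Discretize a power stream into levels -1 / 1 / 3
#'
#' Boundary ties go to the lower category: power at or below `low_cut` is low
#' (-1); above `low_cut` up to and including `high_cut` is average (1); above
#' `high_cut` is high (3). Missing power propagates to a missing level.
#'
#' @param power numeric vector.
#' @param thresholds as returned by [tertile_thresholds()] (or frozen
#'   thresholds for streaming use).
#' @return integer vector of levels in `{-1, 1, 3}` with `NA` for missing.
#' @export
discretize_stream <- function(power, thresholds) {
  lev <- rep(NA_integer_, length(power))
  ok <- !is.na(power)
  if (isTRUE(thresholds$degenerate)) {
    lev[ok] <- 1L
    return(lev)
  }
  lev[ok] <- ifelse(power[ok] <= thresholds$low_cut, -1L,
                    ifelse(power[ok] <= thresholds$high_cut, 1L, 3L))
  lev
}

#' Discretize every stream of a power tensor
#'
#' Thresholds are estimated per (member, sensor, bin) stream over the whole
#' recording, then applied second by second.
#'
#' @param tensor a `power_tensor`.
#' @param method `"tertile"` (default) or `"mean_sd"` (3 levels only).
#' @param n_levels number of power categories (default 3). With `n_levels =
#'   3` levels use the conventional `{-1, 1, 3}` coding; with a finer
#'   granularity (fourths, fifths, ...) levels are the quantile-category
#'   indices `1..k` and the team state space grows as `k^n`.
#' @return a level tensor: data frame `member, sensor, freq_hz, second, level`
#'   with `n_levels` and `thresholds` attributes (for 3 levels, one row per
#'   stream: `member, sensor, freq_hz, low_cut, high_cut, degenerate`).
#' @export
discretize_power <- function(tensor, method = c("tertile", "mean_sd"),
                             n_levels = 3L) {
  method <- match.arg(method)
  tensor <- as_power_tensor(tensor)
  if (n_levels != 3L && method == "mean_sd") {
    stop("mean_sd thresholds are defined for 3 levels only")
  }
  sid <- stream_id(tensor)
  groups <- split(seq_len(nrow(tensor)), sid)
  out <- tensor
  out$level <- NA_integer_
  thr_rows <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    if (n_levels == 3L) {
      thr_fun <- if (method == "tertile") tertile_thresholds else mean_sd_thresholds
      thr <- thr_fun(tensor$power[idx])
      out$level[idx] <- discretize_stream(tensor$power[idx], thr)
      thr_rows[[g]] <- data.frame(member = tensor$member[idx[1]],
                                  sensor = tensor$sensor[idx[1]],
                                  freq_hz = tensor$freq_hz[idx[1]],
                                  low_cut = thr$low_cut, high_cut = thr$high_cut,
                                  degenerate = thr$degenerate)
    } else {
      out$level[idx] <- quantile_categories(tensor$power[idx], n_levels)
    }
  }
  out$power <- NULL
  class(out) <- "data.frame"
  attr(out, "n_levels") <- as.integer(n_levels)
  if (n_levels == 3L) attr(out, "thresholds") <- do.call(rbind, thr_rows)
  out
}

# internal: quantile categories 1..k with boundary ties to the lower
# category; degenerate streams map to the middle category
quantile_categories <- function(power, k) {
  x <- power[!is.na(power)]
  if (length(x) < k) stop("need at least ", k, " non-missing values")
  out <- rep(NA_integer_, length(power))
  ok <- !is.na(power)
  if (length(unique(x)) == 1L) {
    out[ok] <- as.integer(ceiling((k + 1) / 2))
    return(out)
  }
  cuts <- stats::quantile(x, probs = seq_len(k - 1) / k, names = FALSE,
                          type = 7)
  out[ok] <- 1L + vapply(power[ok], function(v) sum(v > cuts), 0L)
  out
}

#' Encode member levels as a team neurodynamic symbol
#'
#' The ordered tuple of member levels is encoded in base 3 with digit map
#' -1 -> 0, 1 -> 1, 3 -> 2 and member 1 as the most significant digit, a
#' bijection onto `[0, 3^n)`. For a triad the state space has 27 symbols.
#'
#' @param levels integer vector (or matrix with one row per member and one
#'   column per second) of levels in `{-1, 1, 3}`.
#' @return integer symbol index (vector when `levels` is a matrix). Any
#'   missing member level yields a missing symbol.
#' @export
encode_team_symbol <- function(levels) {
  digit <- function(l) {
    d <- rep(NA_integer_, length(l))
    d[!is.na(l) & l == -1L] <- 0L
    d[!is.na(l) & l == 1L] <- 1L
    d[!is.na(l) & l == 3L] <- 2L
    if (any(is.na(d) & !is.na(l))) stop("levels must be in {-1, 1, 3}")
    d
  }
  if (is.matrix(levels)) {
    n <- nrow(levels)
    d <- matrix(digit(as.integer(levels)), nrow = n)
    as.integer(colSums(d * 3^((n - 1):0)))
  } else {
    n <- length(levels)
    as.integer(sum(digit(as.integer(levels)) * 3^((n - 1):0)))
  }
}

#' Decode a team symbol back to member levels
#'
#' @param index integer symbol index in `[0, 3^n)`.
#' @param n_members team size.
#' @return integer vector of `n_members` levels (matrix with one column per
#'   index when `index` has length > 1).
#' @export
decode_team_symbol <- function(index, n_members) {
  if (any(index < 0 | index >= 3^n_members, na.rm = TRUE)) {
    stop("symbol index out of range [0, 3^n)")
  }
  level_of <- c(-1L, 1L, 3L)
  one <- function(ix) {
    if (is.na(ix)) return(rep(NA_integer_, n_members))
    d <- integer(n_members)
    for (m in n_members:1) {
      d[m] <- ix %% 3L
      ix <- ix %/% 3L
    }
    level_of[d + 1L]
  }
  if (length(index) == 1L) one(index) else vapply(index, one, integer(n_members))
}

#' Assemble team neurodynamic data streams
#'
#' Combines one level stream per member, for every (sensor, frequency-bin)
#' pair shared by all members, into per-second team symbols over the 3^n
#' state space. A second where any member is missing is missing in the team
#' stream. Sensors and bins must agree across members (montage mismatches are
#' resolved by the caller via the intersection of sensor labels, never
#' positionally).
#'
#' @param levels a level tensor from [discretize_power()] (or any data frame
#'   with columns `member, sensor, freq_hz, second, level`).
#' @param n_levels number of power categories (3 unless the tensor was
#'   discretized at a finer granularity; taken from the tensor's `n_levels`
#'   attribute when present).
#' @return data frame `sensor, freq_hz, second, symbol` with attributes
#'   `n_members`, `state_space` (`n_levels^n`) and `counts` (see
#'   [stream_counts()]).
#' @export
build_team_nds <- function(levels, n_levels = attr(levels, "n_levels")) {
  if (is.null(n_levels)) n_levels <- 3L
  members <- sort(unique(levels$member))
  n <- length(members)
  per_member <- lapply(members, function(m) {
    x <- levels[levels$member == m, c("sensor", "freq_hz", "second", "level")]
    x <- x[order(x$sensor, x$freq_hz, x$second), ]
    rownames(x) <- NULL
    x
  })
  key <- lapply(per_member, function(x) paste(x$sensor, x$freq_hz, sep = "\r"))
  streams <- lapply(key, unique)
  if (length(unique(vapply(streams, function(s) paste(sort(s), collapse = ";"),
                           ""))) != 1L) {
    stop("sensor/bin sets differ across members (montage mismatch); ",
         "restrict to the intersection of sensor labels first")
  }
  grid <- per_member[[1]][c("sensor", "freq_hz", "second")]
  for (m in seq_len(n)[-1]) {
    if (!identical(per_member[[m]][c("sensor", "freq_hz", "second")], grid)) {
      stop("members do not share a common (sensor, bin, second) grid")
    }
  }
  lev_mat <- do.call(rbind, lapply(per_member, function(x) x$level))
  if (n_levels == 3L) {
    grid$symbol <- encode_team_symbol(lev_mat)
  } else {
    if (any(lev_mat < 1L | lev_mat > n_levels, na.rm = TRUE)) {
      stop("levels must lie in 1..n_levels for finer granularities")
    }
    d <- lev_mat - 1L
    grid$symbol <- as.integer(colSums(d * n_levels^((n - 1):0)))
  }
  attr(grid, "n_members") <- n
  attr(grid, "state_space") <- as.integer(n_levels)^n
  attr(grid, "counts") <- stream_counts(n, length(unique(grid$sensor)),
                                        length(unique(grid$freq_hz)))
  grid
}

#' Stream bookkeeping for a team montage
#'
#' `m` members wearing `c`-sensor headsets analyzed in `f` frequency bins give
#' `c * f` team streams and `m * c * f` individual member streams (e.g., a
#' triad with 10 sensors and 40 bins: 400 team and 1,200 individual streams).
#'
#' @param n_members,n_sensors,n_bins counts.
#' @return list with `team_streams` and `member_streams`.
#' @export
stream_counts <- function(n_members, n_sensors, n_bins) {
  list(team_streams = as.integer(n_sensors * n_bins),
       member_streams = as.integer(n_members * n_sensors * n_bins))
}

#' The full symbol lookup table for a team
#'
#' @param n_members team size.
#' @return data frame with one row per symbol: `symbol` index and one
#'   `member<i>` level column per member. Useful as an audit artifact.
#' @export
symbol_lookup_table <- function(n_members = 3L) {
  ix <- 0:(3L^n_members - 1L)
  lev <- t(vapply(ix, decode_team_symbol, integer(n_members),
                  n_members = n_members))
  out <- data.frame(symbol = ix)
  for (m in seq_len(n_members)) out[[paste0("member", m)]] <- lev[, m]
  out
}
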