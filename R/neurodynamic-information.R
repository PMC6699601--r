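#' Maximum entropy of a symbol state space
#'
#' `log2(S)` bits for `S` symbols: 3.17 bits for 9 symbols, 4.755 bits for 27.
#'
#' @param n_symbols state-space size.
#' @return bits.
#' @export
hmax <- function(n_symbols) log2(n_symbols)

#' Plug-in Shannon entropy of a symbol window
#'
#' The plug-in estimate `-sum(p * log2(p))` (with `0 * log 0 = 0`) over the
#' non-missing symbols in the window. No bias correction is applied by
#' default; see [sliding_ni()] for the Miller-Madow option.
#'
#' @param symbols integer symbols (any coding); `NA` values are excluded.
#' @param base logarithm base, default 2 (bits).
#' @return entropy; `NA` when every symbol is missing.
#' @export
shannon_entropy <- function(symbols, base = 2) {
  s <- symbols[!is.na(symbols)]
  if (!length(s)) return(NA_real_)
  p <- tabulate(match(s, unique(s)))
  p <- p / sum(p)
  -sum(p * log(p, base = base))
}

# internal: sliding plug-in entropy over an integer symbol vector in [0, S).
# Windows with more than max_missing_frac missing yield NA; the first
# (window - 1) seconds are NA (warm-up).
sliding_entropy <- function(sym, window, S, step = 1L, max_missing_frac = 0.2,
                            align = c("end", "center"), miller_madow = FALSE) {
  align <- match.arg(align)
  n <- length(sym)
  H <- rep(NA_real_, n)
  if (n < window) return(H)
  for (t in seq(window, n, by = step)) {
    w <- sym[(t - window + 1L):t]
    w <- w[!is.na(w)]
    n_miss <- window - length(w)
    if (n_miss > max_missing_frac * window) next
    cnt <- tabulate(w + 1L, nbins = S)
    cnt <- cnt[cnt > 0L]
    p <- cnt / length(w)
    h <- -sum(p * log2(p))
    if (miller_madow) h <- h + (length(cnt) - 1L) / (2 * length(w) * log(2))
    H[t] <- h
  }
  if (align == "center") {
    shift <- (window - 1L) %/% 2L
    H <- c(H[(shift + 1L):n], rep(NA_real_, shift))
  }
  H
}

#' Sliding-window neurodynamic information of one symbol stream
#'
#' NI(t) = Hmax - H(window ending at t), in bits, where Hmax = log2(S) for the
#' stream's state space. Entropy is measured over a moving window (default
#' 60 s) updated each second; high NI marks persistent, organized symbol
#' patterns. The trace is timestamped at the window end (causal alignment,
#' suitable for real-time use); the first `window - 1` seconds are the
#' warm-up and are missing. Windows with more than 20% missing symbols are
#' reported missing rather than silently computed on fewer symbols.
#'
#' @param symbols integer vector of symbol indices in `[0, S)` (`NA` =
#'   missing), one value per second starting at `second0`.
#' @param state_space number of symbols S (27 for a triad team stream, 3 for
#'   an individual level stream).
#' @param window,step window length and update step in seconds.
#' @param align `"end"` (default, causal) or `"center"`.
#' @param max_missing_frac per-window missing tolerance (default 0.2).
#' @param miller_madow apply the Miller-Madow bias correction to the window
#'   entropy (off by default, matching the plug-in procedure).
#' @param second0 task-clock second of the first symbol.
#' @return an NI trace: data frame `second, ni` with attributes `window`,
#'   `step`, `state_space` and `hmax`. Empty (all-`NA`) with a warning when
#'   the stream is shorter than the window.
#' @export
sliding_ni <- function(symbols, state_space, window = 60L, step = 1L,
                       align = c("end", "center"), max_missing_frac = 0.2,
                       miller_madow = FALSE, second0 = 0L) {
  align <- match.arg(align)
  if (any(symbols < 0L | symbols >= state_space, na.rm = TRUE)) {
    stop("symbols must lie in [0, state_space)")
  }
  if (length(symbols) < window) {
    warning("stream shorter than the entropy window; returning empty trace")
    ni <- rep(NA_real_, length(symbols))
  } else {
    H <- sliding_entropy(symbols, window = window, S = state_space,
                         step = step, max_missing_frac = max_missing_frac,
                         align = align, miller_madow = miller_madow)
    ni <- hmax(state_space) - H
  }
  out <- data.frame(second = seq_along(symbols) - 1L + as.integer(second0),
                    ni = ni)
  structure(out, window = as.integer(window), step = as.integer(step),
            state_space = as.integer(state_space), hmax = hmax(state_space),
            class = c("ni_trace", "data.frame"))
}

#' NI traces for every team stream of a team NDS
#'
#' @param nds output of [build_team_nds()].
#' @param ... passed to [sliding_ni()].
#' @return data frame `sensor, freq_hz, second, ni` with the same attributes
#'   as an NI trace.
#' @export
team_ni <- function(nds, ...) {
  S <- attr(nds, "state_space")
  sid <- paste(nds$sensor, nds$freq_hz, sep = "\r")
  pieces <- lapply(split(seq_len(nrow(nds)), sid), function(idx) {
    x <- nds[idx, ]
    x <- x[order(x$second), ]
    tr <- sliding_ni(x$symbol, state_space = S, second0 = x$second[1], ...)
    data.frame(sensor = x$sensor[1], freq_hz = x$freq_hz[1],
               second = tr$second, ni = tr$ni)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  structure(out, state_space = S, class = c("ni_set", "data.frame"))
}

#' Average NI traces across sensors and/or frequency bins
#'
#' Per-second arithmetic mean over the non-missing traces, with the count of
#' contributing traces recorded. Seconds where no trace contributes are
#' missing.
#'
#' @param traces either a list of NI traces (data frames `second, ni`) or a
#'   single data frame with grouping columns plus `second, ni` (for example
#'   the output of [team_ni()]).
#' @return data frame `second, ni, n_traces`.
#' @export
average_ni <- function(traces) {
  if (is.data.frame(traces)) {
    df <- traces[c("second", "ni")]
  } else {
    df <- do.call(rbind, lapply(traces, function(tr) tr[c("second", "ni")]))
  }
  secs <- sort(unique(df$second))
  grp <- factor(df$second, levels = secs)
  n_ok <- as.integer(tapply(!is.na(df$ni), grp, sum))
  total <- tapply(df$ni, grp, function(v) sum(v, na.rm = TRUE))
  ni <- ifelse(n_ok > 0L, as.numeric(total) / n_ok, NA_real_)
  data.frame(second = secs, ni = ni, n_traces = n_ok)
}

#' Interquartile range of an NI trace
#'
#' 25th and 75th percentiles (linear interpolation) of the trace's
#' non-missing values.
#'
#' @param trace an NI trace or any data frame with an `ni` column, or a
#'   numeric vector.
#' @return named numeric vector `c(q25, q75)`.
#' @export
iqr_profile <- function(trace) {
  v <- if (is.data.frame(trace)) trace$ni else trace
  v <- v[!is.na(v)]
  if (length(v) < 4L) stop("need at least 4 valid seconds for an IQR")
  q <- stats::quantile(v, probs = c(0.25, 0.75), names = FALSE, type = 7)
  c(q25 = q[1], q75 = q[2])
}

#' Shuffle-baseline NI envelope from randomized member streams
#'
#' Destroys temporal structure while preserving each stream's level marginals:
#' every member's level stream is independently and uniformly permuted over
#' its non-missing positions, team symbols are rebuilt, NI is recomputed, and
#' the 25th/75th percentiles are pooled over all shuffles (and seconds). The
#' observed NI trace is compared against this envelope to flag organization
#' beyond the plug-in bias floor. A block-shuffle variant (blocks of
#' `block_s` seconds) preserves short-range autocorrelation.
#'
#' @param levels a level tensor (see [discretize_power()]) restricted to the
#'   streams of interest.
#' @param R number of shuffles (>= 2).
#' @param seed integer seed; the envelope is reproducible.
#' @param window,... passed to [sliding_ni()].
#' @param block_s `NULL` for unrestricted permutation (default) or a block
#'   length in seconds for block shuffling.
#' @return list `q25, q75, R, seed, ni` where `ni` is the pooled vector of
#'   shuffled NI values.
#' @export
shuffle_baseline <- function(levels, R = 100L, seed = 1L, window = 60L,
                             block_s = NULL, ...) {
  if (R < 2L) stop("need at least R = 2 shuffles")
  n_levels <- attr(levels, "n_levels")
  if (is.null(n_levels)) n_levels <- 3L
  levels <- levels[order(levels$member, levels$sensor, levels$freq_hz,
                         levels$second), ]
  sid <- stream_id(levels)
  groups <- split(seq_len(nrow(levels)), sid)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  pooled <- vector("list", R)
  for (r in seq_len(R)) {
    shuf <- levels
    for (idx in groups) {
      pos <- idx[!is.na(levels$level[idx])]
      if (length(pos) > 1L) {
        shuf$level[pos] <- levels$level[permute_positions(pos, block_s)]
      }
    }
    nds <- build_team_nds(shuf, n_levels = n_levels)
    tr <- team_ni(nds, window = window, ...)
    pooled[[r]] <- tr$ni[!is.na(tr$ni)]
  }
  ni <- unlist(pooled)
  q <- stats::quantile(ni, probs = c(0.25, 0.75), names = FALSE, type = 7)
  list(q25 = q[1], q75 = q[2], R = as.integer(R), seed = as.integer(seed),
       ni = ni)
}

# internal: permutation of a set of row positions, optionally in blocks
permute_positions <- function(pos, block_s = NULL) {
  n <- length(pos)
  if (is.null(block_s)) return(pos[sample.int(n)])
  blocks <- split(seq_len(n), (seq_len(n) - 1L) %/% block_s)
  pos[unlist(blocks[sample.int(length(blocks))], use.names = FALSE)]
}

# internal: save/restore the global RNG state so seeded helpers do not
# perturb the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
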