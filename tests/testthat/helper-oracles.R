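# Independent oracles, deliberately written differently from the package
# internals (table()-based counting, explicit loops, closed forms).

# plug-in Shannon entropy by direct counting
entropy_oracle <- function(symbols, base = 2) {
  s <- symbols[!is.na(symbols)]
  if (!length(s)) return(NA_real_)
  counts <- as.numeric(table(s))
  p <- counts / sum(counts)
  -sum(p * log(p) / log(base))
}

# windowed NI by brute force: one entropy per window, NA warm-up, 20% rule
sliding_ni_oracle <- function(sym, S, window = 60L, max_missing = 0.2) {
  n <- length(sym)
  out <- rep(NA_real_, n)
  for (t in seq_len(n)) {
    if (t < window) next
    w <- sym[(t - window + 1):t]
    if (sum(is.na(w)) > max_missing * window) next
    out[t] <- log2(S) - entropy_oracle(w)
  }
  out
}

# rank-based tertile levels: sorted-order thirds
rank_level_oracle <- function(x) {
  n <- length(x)
  r <- rank(x, ties.method = "first")
  cut_lo <- floor(n / 3)
  cut_hi <- floor(2 * n / 3)
  ifelse(r <= cut_lo, -1L, ifelse(r <= cut_hi, 1L, 3L))
}

# Kruskal-Wallis H with tie correction, from the textbook formula
kruskal_h_oracle <- function(values, groups) {
  N <- length(values)
  r <- rank(values)
  h <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, function(ri) length(ri) * mean(ri)^2)) -
    3 * (N + 1)
  ties <- table(values)
  correction <- 1 - sum(ties^3 - ties) / (N^3 - N)
  h / correction
}

# a small balanced level tensor built directly (no generator)
make_level_tensor <- function(levels_by_member, sensor = "F3", freq = 10L) {
  n_t <- length(levels_by_member[[1]])
  do.call(rbind, lapply(seq_along(levels_by_member), function(m) {
    data.frame(member = m, sensor = sensor, freq_hz = freq,
               second = 0:(n_t - 1L), level = levels_by_member[[m]])
  }))
}

# random iid level stream over {-1, 1, 3}
random_levels <- function(n) sample(c(-1L, 1L, 3L), n, replace = TRUE)
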