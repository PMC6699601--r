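#' Ground-truth organization epoch
#'
#' Describes a half-open interval during which designated streams are forced
#' into one power tertile, emulating a prolonged metastable neurodynamic
#' relationship. Occupancy must exceed chance (1/3) to create organization.
#'
#' @param member integer member index, or `"team"` to force every member
#'   (jointly, one occupancy coin per second, so the team-level occupancy of
#'   the forced symbol equals `occupancy`).
#' @param start_s,end_s half-open interval `[start_s, end_s)` in seconds.
#' @param level forced level, one of -1, 1, 3.
#' @param occupancy probability in (1/3, 1] that a second inside the epoch is
#'   forced into the level's tertile.
#' @param sensors,bins `"all"` or a subset of the configuration's sensors /
#'   frequency bins.
#' @return a `gt_epoch` list.
#' @export
gt_epoch <- function(member = "team", start_s, end_s, level = 3L,
                     occupancy = 1, sensors = "all", bins = "all") {
  if (!(identical(member, "team") || (is.numeric(member) && member >= 1))) {
    stop("member must be a positive index or \"team\"")
  }
  if (!(end_s > start_s)) stop("epoch interval must be non-empty")
  if (!level %in% c(-1L, 1L, 3L)) stop("level must be one of -1, 1, 3")
  if (!(occupancy > 1 / 3 && occupancy <= 1)) {
    stop("occupancy must lie in (1/3, 1]: below 1/3 it cannot exceed chance")
  }
  structure(list(member = member, start_s = as.integer(start_s),
                 end_s = as.integer(end_s), level = as.integer(level),
                 occupancy = occupancy, sensors = sensors, bins = bins),
            class = "gt_epoch")
}

#' Synthetic-recording configuration
#'
#' Defines a per-second power simulation for a team: background noise per
#' (member, sensor, bin) stream, injected organization epochs, optional
#' lagged cross-member coupling and missing spans (members outside the room).
#' Background log-power is standard normal (power is positive and
#' right-skewed), i.i.d. by default or AR(1) (`phi = 0.6`) for short-range
#' autocorrelation; either way the marginal tertiles split levels uniformly.
#'
#' @param n_members team size (default 3).
#' @param sensors character sensor labels.
#' @param bins integer 1-Hz bin centers (default 1:40).
#' @param duration_s recording length in seconds; at least 120 (one full
#'   entropy window plus warm-up).
#' @param epochs list of [gt_epoch()] objects, each within `[0, duration_s)`.
#' @param coupling `NULL`, or `list(leader =, follower =, lag_s =, start_s =,
#'   end_s =)` applied after background generation via [inject_coupling()].
#' @param missing_spans list of `list(member =, start_s =, end_s =)`.
#' @param noise_model `"iid-lognormal"` or `"ar1-lognormal"`.
#' @param seed integer; a fixed seed gives byte-identical output.
#' @return a validated `synth_config` list.
#' @export
synth_config <- function(n_members = 3L,
                         sensors = c("F3", "Fz", "F4", "P3", "Pz", "P4"),
                         bins = 1:40, duration_s = 800L, epochs = list(),
                         coupling = NULL, missing_spans = list(),
                         noise_model = c("iid-lognormal", "ar1-lognormal"),
                         seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (duration_s < 120) {
    stop("duration_s must be >= 120 (one entropy window plus warm-up)")
  }
  for (e in epochs) {
    if (!inherits(e, "gt_epoch")) stop("epochs must be gt_epoch objects")
    if (e$start_s < 0 || e$end_s > duration_s) {
      stop("epoch [", e$start_s, ", ", e$end_s, ") lies outside [0, ",
           duration_s, ")")
    }
    if (!identical(e$member, "team") && e$member > n_members) {
      stop("epoch member index ", e$member, " exceeds team size")
    }
  }
  for (ms in missing_spans) {
    stopifnot(is.list(ms), all(c("member", "start_s", "end_s") %in% names(ms)))
  }
  structure(list(n_members = as.integer(n_members), sensors = sensors,
                 bins = as.integer(bins), duration_s = as.integer(duration_s),
                 epochs = epochs, coupling = coupling,
                 missing_spans = missing_spans, noise_model = noise_model,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# internal: inverse-CDF draw from the standard lognormal restricted to the
# interior of one level's tertile. An epoch inflates its level's share of the
# recording, which drags the whole-recording empirical cut toward (and into)
# the forced distribution; sampling the outer/middle half of the tertile
# keeps forced values on the correct side of the shifted cut for epochs up
# to ~20% of the recording.
rlnorm_tertile <- function(n, level) {
  rng <- switch(as.character(level),
                "-1" = c(0, 1 / 6),
                "1" = c(5 / 12, 7 / 12),
                "3" = c(5 / 6, 1))
  stats::qlnorm(stats::runif(n, rng[1], rng[2]))
}

#' Generate a per-second power tensor with known ground truth
#'
#' Background power is standard lognormal per stream, so whole-recording
#' tertiles split the three levels near-uniformly. Inside each configured
#' epoch the designated streams' power is redrawn from the forced level's
#' tertile (by inverse-CDF sampling of the marginal) with probability
#' `occupancy`; epochs force tertile membership, not absolute power, so
#' downstream recovery is invariant to scale. Missing spans become `NA`
#' power, never zeros (zero is a valid power).
#'
#' @param config a [synth_config()].
#' @return list with `tensor` (a `power_tensor`) and `epochs` (the ground
#'   truth, returned unchanged).
#' @export
generate_power_tensor <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  n_t <- config$duration_s
  grid <- expand.grid(second = 0:(n_t - 1L), freq_hz = config$bins,
                      sensor = config$sensors,
                      member = seq_len(config$n_members),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[c("member", "sensor", "freq_hz", "second")]
  n_streams <- nrow(grid) / n_t

  if (config$noise_model == "iid-lognormal") {
    z <- stats::rnorm(nrow(grid))
  } else {
    phi <- 0.6
    z <- unlist(lapply(seq_len(n_streams), function(i) {
      as.numeric(stats::arima.sim(list(ar = phi), n = n_t,
                                  sd = sqrt(1 - phi^2)))
    }), use.names = FALSE)
  }
  grid$power <- exp(z)

  for (e in config$epochs) {
    members <- if (identical(e$member, "team")) {
      seq_len(config$n_members)
    } else as.integer(e$member)
    sensors <- if (identical(e$sensors, "all")) config$sensors else e$sensors
    bins <- if (identical(e$bins, "all")) config$bins else as.integer(e$bins)
    secs <- e$start_s:(e$end_s - 1L)
    forced_sec <- secs[stats::runif(length(secs)) <= e$occupancy]
    if (!length(forced_sec)) next
    rows <- which(grid$member %in% members & grid$sensor %in% sensors &
                    grid$freq_hz %in% bins & grid$second %in% forced_sec)
    grid$power[rows] <- rlnorm_tertile(length(rows), e$level)
  }

  for (ms in config$missing_spans) {
    rows <- which(grid$member == ms$member & grid$second >= ms$start_s &
                    grid$second < ms$end_s)
    grid$power[rows] <- NA_real_
  }

  tensor <- as_power_tensor(grid)
  if (!is.null(config$coupling)) {
    cp <- config$coupling
    tensor <- inject_coupling(tensor, leader = cp$leader,
                              follower = cp$follower, lag_s = cp$lag_s,
                              interval = c(cp$start_s, cp$end_s))
  }
  list(tensor = tensor, epochs = config$epochs)
}

#' Replicate one member's level pattern in another, at a lag
#'
#' Inside the interval, the follower's per-second levels copy the leader's
#' levels shifted by `lag_s` (positive lag: the leader leads). Power values
#' are resampled from the follower's own values within the matching tertile,
#' so the follower's marginal distribution is preserved while its symbolic
#' dynamics lock to the leader's. Seconds whose shifted source falls outside
#' the recording, or where the leader is missing, are left unchanged.
#'
#' @param tensor a `power_tensor`.
#' @param leader,follower distinct member indices.
#' @param lag_s signed integer lag in seconds; `|lag_s|` must be smaller than
#'   the interval length.
#' @param interval numeric `c(start_s, end_s)`, half-open.
#' @return the modified tensor, with attribute `coupling_thresholds` (the
#'   follower-stream tertile cuts used for the resampling, suitable as frozen
#'   thresholds when checking level replication exactly).
#' @export
inject_coupling <- function(tensor, leader, follower, lag_s, interval) {
  tensor <- as_power_tensor(tensor)
  if (leader == follower) stop("leader and follower must differ")
  start_s <- interval[1]; end_s <- interval[2]
  if (abs(lag_s) >= (end_s - start_s)) {
    stop("|lag_s| must be smaller than the interval length")
  }
  for (m in c(leader, follower)) {
    if (!m %in% tensor$member) stop("member ", m, " not present in tensor")
  }
  streams <- unique(tensor[tensor$member == leader, c("sensor", "freq_hz")])
  thr_rows <- vector("list", nrow(streams))
  for (i in seq_len(nrow(streams))) {
    sn <- streams$sensor[i]; fb <- streams$freq_hz[i]
    li <- which(tensor$member == leader & tensor$sensor == sn &
                  tensor$freq_hz == fb)
    fi <- which(tensor$member == follower & tensor$sensor == sn &
                  tensor$freq_hz == fb)
    if (!length(fi)) next
    li <- li[order(tensor$second[li])]
    fi <- fi[order(tensor$second[fi])]
    lead_thr <- tertile_thresholds(tensor$power[li])
    fol_thr <- tertile_thresholds(tensor$power[fi])
    lead_lev <- discretize_stream(tensor$power[li], lead_thr)
    fol_lev <- discretize_stream(tensor$power[fi], fol_thr)
    pools <- split(tensor$power[fi][!is.na(fol_lev)],
                   fol_lev[!is.na(fol_lev)])
    lead_sec <- tensor$second[li]
    fol_sec <- tensor$second[fi]
    for (t in seq.int(start_s, end_s - 1L)) {
      src <- match(t - lag_s, lead_sec)
      dst <- match(t, fol_sec)
      if (is.na(src) || is.na(dst)) next
      lv <- lead_lev[src]
      if (is.na(lv)) next
      pool <- pools[[as.character(lv)]]
      if (!length(pool)) next
      tensor$power[fi[dst]] <- pool[sample.int(length(pool), 1L)]
    }
    thr_rows[[i]] <- data.frame(member = follower, sensor = sn, freq_hz = fb,
                                low_cut = fol_thr$low_cut,
                                high_cut = fol_thr$high_cut,
                                degenerate = fol_thr$degenerate)
  }
  attr(tensor, "coupling_thresholds") <- do.call(rbind, thr_rows)
  tensor
}

#' Synthesize raw multichannel EEG realizing a configuration
#'
#' Each (member, sensor) channel is a sum of band-limited sinusoids, one per
#' configured 1-Hz bin, with per-second amplitude modulation realizing the
#' configured epochs (high level doubles the amplitude, low level quarters
#' it), plus broadband Gaussian noise. Deterministic under the
#' configuration's seed.
#'
#' @param config a [synth_config()].
#' @param fs sampling rate in Hz, at least 128 and at least twice the highest
#'   bin (aliasing).
#' @param amplitude base sinusoid amplitude (0 with `noise_sd = 0` yields an
#'   all-zero recording).
#' @param noise_sd standard deviation of the additive broadband noise.
#' @return list of `raw_recording` objects, one per member.
#' @export
generate_raw_eeg <- function(config, fs, amplitude = 1, noise_sd = 0.1) {
  stopifnot(inherits(config, "synth_config"))
  if (fs < 128) stop("fs must be >= 128 Hz")
  if (fs < 2 * max(config$bins)) {
    stop("fs must be at least twice the highest frequency bin (aliasing)")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  n_t <- config$duration_s
  n_samp <- n_t * fs
  tt <- (seq_len(n_samp) - 1L) / fs
  sec_of_sample <- floor(tt)
  recs <- vector("list", config$n_members)
  for (m in seq_len(config$n_members)) {
    samples <- matrix(0, nrow = length(config$sensors), ncol = n_samp,
                      dimnames = list(config$sensors, NULL))
    for (ci in seq_along(config$sensors)) {
      x <- numeric(n_samp)
      for (b in config$bins) {
        amp_sec <- rep(amplitude, n_t)
        for (e in config$epochs) {
          members <- if (identical(e$member, "team")) {
            seq_len(config$n_members)
          } else as.integer(e$member)
          sensors <- if (identical(e$sensors, "all")) config$sensors else e$sensors
          bins <- if (identical(e$bins, "all")) config$bins else as.integer(e$bins)
          if (!(m %in% members && config$sensors[ci] %in% sensors &&
                  b %in% bins)) next
          secs <- (e$start_s:(e$end_s - 1L)) + 1L
          forced <- secs[stats::runif(length(secs)) <= e$occupancy]
          gain <- switch(as.character(e$level), "3" = 2, "1" = 1, "-1" = 0.25)
          amp_sec[forced] <- amplitude * gain
        }
        phase <- stats::runif(1, 0, 2 * pi)
        x <- x + amp_sec[sec_of_sample + 1L] * sin(2 * pi * b * tt + phase)
      }
      if (noise_sd > 0) x <- x + stats::rnorm(n_samp, 0, noise_sd)
      samples[ci, ] <- x
    }
    recs[[m]] <- raw_recording(member = m, channels = config$sensors,
                               fs = fs, samples = samples)
  }
  recs
}
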