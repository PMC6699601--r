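# standard 10-20 / 10-10 labels used to flag unknown channels
TEN_TWENTY <- c("Fp1", "Fpz", "Fp2", "F7", "F3", "Fz", "F4", "F8",
                "T7", "T3", "C3", "Cz", "C4", "T4", "T8",
                "P7", "T5", "P3", "Pz", "P4", "T6", "P8",
                "O1", "Oz", "O2", "A1", "A2", "M1", "M2",
                "AFz", "FCz", "CPz", "POz")

#' Read a raw recording from tidy CSV
#'
#' Expects columns `member, channel, fs, t, value`: one sample per row,
#' `t` in seconds from the recording start. All channels must share the
#' sampling rate and length. Channel labels outside the 10-20/10-10
#' nomenclature are preserved but flagged with a warning.
#'
#' @param path CSV file path.
#' @param start_s task-clock offset of the first sample (whole seconds).
#' @return a [raw_recording()] (a list of them if the file holds several
#'   members).
#' @export
read_recording <- function(path, start_s = 0L) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                error = function(e) stop("malformed recording CSV '", path,
                                         "': ", conditionMessage(e)))
  required <- c("member", "channel", "fs", "t", "value")
  miss <- setdiff(required, names(x))
  if (length(miss)) {
    stop("recording CSV '", path, "' lacks columns: ",
         paste(miss, collapse = ", "))
  }
  if (!is.numeric(x$value) || !is.numeric(x$t)) {
    stop("recording CSV '", path, "': t and value must be numeric")
  }
  recs <- lapply(split(x, x$member), function(xm) {
    fs <- unique(xm$fs)
    if (length(fs) != 1L) stop("inconsistent fs within a member")
    chans <- unique(xm$channel)
    lens <- vapply(split(xm, xm$channel), nrow, 0L)
    if (length(unique(lens)) != 1L) {
      stop("channels differ in length for member ", xm$member[1])
    }
    unknown <- setdiff(chans, TEN_TWENTY)
    if (length(unknown)) {
      warning("channel labels outside the 10-20 nomenclature: ",
              paste(unknown, collapse = ", "))
    }
    samples <- do.call(rbind, lapply(chans, function(ch) {
      xc <- xm[xm$channel == ch, ]
      xc$value[order(xc$t)]
    }))
    raw_recording(member = xm$member[1], channels = chans, fs = fs,
                  samples = samples, start_s = start_s)
  })
  if (length(recs) == 1L) recs[[1]] else unname(recs)
}

#' Write a raw recording as tidy CSV (round-trips [read_recording()])
#'
#' @param rec a [raw_recording()] or a list of them.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  recs <- if (inherits(rec, "raw_recording")) list(rec) else rec
  rows <- lapply(recs, function(r) {
    n <- ncol(r$samples)
    data.frame(member = r$member,
               channel = rep(r$channels, each = n),
               fs = r$fs,
               t = rep((seq_len(n) - 1L) / r$fs, times = length(r$channels)),
               value = as.numeric(t(r$samples)))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Assemble and validate an end-to-end run configuration
#'
#' @param input a [synth_config()], a `power_tensor`, or a path to a power
#'   tensor CSV (see [read_power_tensor()]).
#' @param members member indices to analyze (`NULL` = all present).
#' @param window,step entropy window and update step, seconds.
#' @param scheme a [band_scheme()] name or list.
#' @param regions a [region_map()] name or list, or `NULL` to skip the
#'   region contrast.
#' @param n_levels power categories (default 3).
#' @param shuffles shuffle count for the baseline envelope (0 disables).
#' @param events optional data frame of [event_segment()] rows.
#' @param seed integer seed driving every stochastic stage.
#' @return a validated `run_config` list.
#' @export
run_config <- function(input, members = NULL, window = 60L, step = 1L,
                       scheme = "A", regions = NULL, n_levels = 3L,
                       shuffles = 100L, events = NULL, seed = 1L) {
  if (!(inherits(input, "synth_config") || inherits(input, "power_tensor") ||
          (is.character(input) && length(input) == 1L))) {
    stop("input must be a synth_config, a power_tensor, or a CSV path")
  }
  if (is.character(input) && !file.exists(input)) {
    stop("input file does not exist: ", input)
  }
  if (window < 2L) stop("window must be at least 2 s")
  if (!is.null(events)) {
    stopifnot(all(c("label", "start_s", "end_s") %in% names(events)))
  }
  structure(list(input = input, members = members,
                 window = as.integer(window), step = as.integer(step),
                 scheme = scheme, regions = regions,
                 n_levels = as.integer(n_levels),
                 shuffles = as.integer(shuffles), events = events,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full team-neurodynamics pipeline
#'
#' Orchestrates power acquisition, discretization, team-symbol assembly,
#' team and member NI, the shuffle baseline and event reports, writing every
#' artifact (tidy CSV / JSON) plus a manifest into `out_dir`. Identical
#' configuration and seed give byte-identical outputs. Any stage failure
#' aborts with the stage name and removes the partially written artifacts.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory artifacts (`tensor`,
#'   `levels`, `nds`, `team_ni`, `team_ni_avg`, `member_ni`, `baseline`,
#'   `events`, `manifest`) and `paths` of the written files.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character(0)
  emit <- function(obj, name, writer) {
    p <- file.path(out_dir, name)
    writer(obj, p)
    written <<- c(written, p)
    p
  }
  stage <- "validate"
  result <- tryCatch({
    if (!is.null(config$regions) && !is.list(config$regions)) {
      config$regions <- region_map(config$regions)
    }
    if (is.list(config$scheme) || is.character(config$scheme)) {
      config$scheme <- band_scheme(config$scheme)
    }

    stage <- "power"
    if (inherits(config$input, "synth_config")) {
      gen <- generate_power_tensor(config$input)
      tensor <- gen$tensor
    } else if (inherits(config$input, "power_tensor")) {
      tensor <- config$input
    } else {
      tensor <- read_power_tensor(config$input)
    }
    if (!is.null(config$members)) {
      tensor <- tensor[tensor$member %in% config$members, ]
    }
    if (!is.null(config$regions)) {
      wanted <- unlist(config$regions)
      absent <- setdiff(wanted, unique(tensor$sensor))
      if (length(absent) == length(wanted)) {
        stop("no region-map sensor present in the data: ",
             paste(absent, collapse = ", "))
      }
    }
    emit(tensor, "power.csv", write_power_tensor)

    stage <- "symbolize"
    levels <- discretize_power(tensor, n_levels = config$n_levels)
    emit(levels, "levels.csv", function(o, p) {
      utils::write.csv(o, p, row.names = FALSE, quote = FALSE)
    })
    thr <- attr(levels, "thresholds")
    if (!is.null(thr)) {
      emit(thr, "thresholds.csv", function(o, p) {
        utils::write.csv(o, p, row.names = FALSE, quote = FALSE)
      })
    }
    nds <- build_team_nds(levels)
    emit(nds, "team_nds.csv", function(o, p) {
      utils::write.csv(o, p, row.names = FALSE, quote = FALSE)
    })
    n_members <- attr(nds, "n_members")
    if (config$n_levels == 3L) {
      emit(symbol_lookup_table(n_members), "symbol_lookup.json",
           function(o, p) jsonlite::write_json(o, p, dataframe = "rows"))
    }

    stage <- "ni"
    tni <- team_ni(nds, window = config$window, step = config$step)
    emit(tni, "team_ni.csv", function(o, p) {
      utils::write.csv(o, p, row.names = FALSE, quote = FALSE)
    })
    tni_avg <- average_ni(tni)
    emit(tni_avg, "team_ni_avg.csv", function(o, p) {
      utils::write.csv(o, p, row.names = FALSE, quote = FALSE)
    })
    members <- sort(unique(levels$member))
    mni <- lapply(members, function(m) {
      tr <- member_ni(levels, member = m, window = config$window,
                      step = config$step)
      emit(tr, sprintf("member_ni_%d.csv", m), function(o, p) {
        utils::write.csv(o, p, row.names = FALSE, quote = FALSE)
      })
      tr
    })
    names(mni) <- paste0("member", members)

    stage <- "baseline"
    baseline <- NULL
    if (config$shuffles >= 2L) {
      baseline <- shuffle_baseline(levels, R = config$shuffles,
                                   seed = config$seed,
                                   window = config$window)
      emit(baseline[c("q25", "q75", "R", "seed")], "baseline.json",
           function(o, p) jsonlite::write_json(o, p, auto_unbox = TRUE))
    }

    stage <- "events"
    event_reports <- NULL
    if (!is.null(config$events)) {
      event_reports <- level_composition(levels, config$events)
      emit(event_reports$composition, "event_composition.csv",
           function(o, p) utils::write.csv(o, p, row.names = FALSE,
                                           quote = FALSE))
      if (!is.null(event_reports$test)) {
        emit(event_reports$test, "event_test.json",
             function(o, p) jsonlite::write_json(o, p, auto_unbox = TRUE))
      }
    }

    stage <- "manifest"
    cfg_plain <- config
    cfg_plain$input <- if (is.character(config$input)) config$input else
      class(config$input)[1]
    manifest <- list(
      package = "teamneuro",
      version = as.character(utils::packageVersion("teamneuro")),
      seed = config$seed, window = config$window, step = config$step,
      n_levels = config$n_levels, n_members = n_members,
      state_space = attr(nds, "state_space"),
      counts = attr(nds, "counts"),
      config_hash = config_hash(cfg_plain))
    emit(manifest, "manifest.json",
         function(o, p) jsonlite::write_json(o, p, auto_unbox = TRUE))

    list(tensor = tensor, levels = levels, nds = nds, team_ni = tni,
         team_ni_avg = tni_avg, member_ni = mni, baseline = baseline,
         events = event_reports, manifest = manifest, paths = written)
  }, error = function(e) {
    unlink(written)
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

# internal: stable hash of the (plain-text) configuration
config_hash <- function(x) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, force = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
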