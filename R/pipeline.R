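#' Validate a session bundle directory
#'
#' Schema and sanity checks on the input files of the pipeline: required
#' columns, strictly increasing tracking time with a constant nominal frame
#' interval (within 1%, noted when the rate is off-nominal), likelihoods in
#' `[0, 1]`, spike times inside the recorded span, per-trial event ordering,
#' and trial-id consistency across files.
#'
#' @param dir bundle directory (see [write_session_bundle()])
#' @return list with `ok` (logical), `violations` (data.frame: `file`,
#'   `check`, `message`) and `notes` (character)
#' @export
validate_inputs <- function(dir) {
  viol <- list()
  notes <- character()
  add <- function(file, check, message) {
    viol[[length(viol) + 1L]] <<- data.frame(file = file, check = check,
                                             message = message)
  }
  need_cols <- function(df, cols, file) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      add(file, "columns", paste("missing columns:",
                                 paste(miss, collapse = ", ")))
      FALSE
    } else TRUE
  }

  tf <- file.path(dir, "tracking.csv")
  if (file.exists(tf)) {
    tr <- utils::read.csv(tf)
    if (need_cols(tr, c("frame", "time_s", "hand_x_px", "hand_y_px",
                        "slit_x_px", "slit_y_px", "likelihood"),
                  "tracking.csv")) {
      if (is.unsorted(tr$time_s, strictly = TRUE)) {
        add("tracking.csv", "time", "time_s is not strictly increasing")
      } else {
        dt <- diff(tr$time_s)
        if (max(abs(dt - stats::median(dt))) > 0.01 * stats::median(dt)) {
          add("tracking.csv", "frame_interval",
              "frame interval varies by more than 1%")
        }
        fr <- 1 / stats::median(dt)
        if (abs(fr - 100) > 0 && abs(fr - 100) <= 1) {
          notes <- c(notes, sprintf(
            "tracking at %.1f frames/s (within 1%% of nominal 100)", fr))
        }
      }
      if (any(tr$likelihood < 0 | tr$likelihood > 1)) {
        add("tracking.csv", "likelihood", "likelihood outside [0, 1]")
      }
    }
  }

  sf <- file.path(dir, "spikes.csv")
  if (file.exists(sf)) {
    sp <- utils::read.csv(sf)
    if (need_cols(sp, c("neuron_id", "spike_time_s"), "spikes.csv")) {
      span_file <- file.path(dir, "session_span.csv")
      if (file.exists(span_file)) {
        span <- as.numeric(utils::read.csv(span_file)[1, c("start_s",
                                                           "stop_s")])
        if (any(sp$spike_time_s < span[1] | sp$spike_time_s >= span[2])) {
          add("spikes.csv", "span",
              "spike time outside the recorded session span")
        }
      }
      if (any(sp$spike_time_s < 0)) {
        add("spikes.csv", "sign", "negative spike time")
      }
    }
  }

  trf <- file.path(dir, "trials.csv")
  if (file.exists(trf)) {
    long <- utils::read.csv(trf)
    if (need_cols(long, c("trial_id", "event_name", "time_s", "trial_type"),
                  "trials.csv")) {
      if (anyDuplicated(long[, c("trial_id", "event_name")])) {
        add("trials.csv", "ids", "duplicated (trial_id, event_name) row")
      }
      wide <- split(long, long$trial_id)
      bad <- vapply(wide, function(w) {
        t_of <- function(e) {
          v <- w$time_s[w$event_name == e]
          if (length(v)) v[1] else NA_real_
        }
        rs <- t_of("reach_start"); sc <- t_of("slit_cross")
        ts <- t_of("retract_start"); te <- t_of("retract_stop")
        ord <- c(rs < sc, sc <= ts, ts < te)
        any(!ord, na.rm = TRUE)
      }, logical(1))
      if (any(bad)) {
        add("trials.csv", "ordering",
            paste("event ordering violated in trial(s):",
                  paste(names(wide)[bad], collapse = ", ")))
      }
    }
  }

  of <- file.path(dir, "opto_trials.csv")
  if (file.exists(of)) {
    ot <- utils::read.csv(of)
    if (need_cols(ot, c("trial_id", "cue_time_s", "laser"),
                  "opto_trials.csv")) {
      if ("press_time_s" %in% names(ot)) {
        lat <- ot$press_time_s - ot$cue_time_s
        if (any(lat < 0, na.rm = TRUE)) {
          add("opto_trials.csv", "latency", "press before cue")
        }
      }
    }
  }

  violations <- if (length(viol)) do.call(rbind, viol) else {
    data.frame(file = character(), check = character(),
               message = character())
  }
  list(ok = nrow(violations) == 0L, violations = violations, notes = notes)
}

#' Run the analysis pipeline on a session bundle
#'
#' Orchestrates the stages in dependency order with one top-level seed:
#' input validation, kinematic event detection and trial classification
#' (`events`), task-window modulation (`modulation`) and the population
#' summary (`summary`). Every run writes the exact configuration (including
#' the seed) next to its outputs and a line-delimited JSON log of counts at
#' each step, and is byte-identical when rerun with the same inputs and
#' seed.
#'
#' @param config list: `input_dir`, `output_dir`, `seed` (default 1),
#'   `stages` (default `c("events", "modulation", "summary")`), `params`
#'   (optional sub-lists `events`, `modulation` of stage parameters such as
#'   `scale_cm_per_px`, `n_groups`, `min_rate`)
#' @return list of stage outputs, invisibly; files are written under
#'   `output_dir`
#' @export
run_pipeline <- function(config) {
  cfg <- utils::modifyList(list(seed = 1L,
                                stages = c("events", "modulation",
                                           "summary"),
                                params = list()), config)
  if (is.null(cfg$input_dir) || is.null(cfg$output_dir)) {
    stop("config must name input_dir and output_dir")
  }
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(cfg$output_dir, "log.jsonl")
  unlink(log_path)
  log_line <- function(stage, ...) {
    kv <- list(...)
    fields <- vapply(names(kv), function(k) {
      v <- kv[[k]]
      if (is.numeric(v)) sprintf('"%s": %.10g', k, v)
      else sprintf('"%s": "%s"', k, v)
    }, "")
    cat(sprintf('{"stage": "%s", %s}\n', stage,
                paste(fields, collapse = ", ")),
        file = log_path, append = TRUE)
  }

  val <- validate_inputs(cfg$input_dir)
  if (!val$ok) {
    stop("input validation failed: ",
         paste(sprintf("[%s/%s] %s", val$violations$file,
                       val$violations$check, val$violations$message),
               collapse = "; "))
  }
  bundle <- read_session_bundle(cfg$input_dir)
  out <- list()

  if ("events" %in% cfg$stages) {
    if (is.null(bundle$track)) stop("events stage: tracking.csv is missing")
    ep <- cfg$params$events %||% list()
    events <- detect_reaches(bundle$track, ep)
    trials <- classify_trials(events, bundle$track,
                              utils::modifyList(
                                list(scale_cm_per_px = 0.02), ep))
    windows <- task_windows(trials)
    utils::write.csv(trials, file.path(cfg$output_dir,
                                       "trials_detected.csv"),
                     row.names = FALSE)
    utils::write.csv(windows[!is.na(windows$start), ],
                     file.path(cfg$output_dir, "windows.csv"),
                     row.names = FALSE)
    log_line("events", n_reaches = nrow(trials),
             n_isolated = sum(trials$isolated))
    out$trials <- trials
    out$windows <- windows
  }

  if ("modulation" %in% cfg$stages) {
    if (is.null(out$windows)) {
      stop("modulation stage requires the events stage ",
           "(enable \"events\" or provide its outputs)")
    }
    if (is.null(bundle$trains)) {
      stop("modulation stage: spikes.csv is missing")
    }
    mp <- utils::modifyList(list(n_groups = 1000L, min_rate = 5),
                            cfg$params$modulation %||% list())
    tonic <- filter_tonic_units(bundle$trains, mp$min_rate)
    log_line("modulation", n_units = length(bundle$trains),
             n_tonic = attr(tonic, "n_kept"))
    tab <- modulation_table(tonic, out$windows, n_groups = mp$n_groups,
                            seed = derive_seed(cfg$seed, "modulation"))
    utils::write.csv(tab, file.path(cfg$output_dir, "modulation.csv"),
                     row.names = FALSE)
    out$modulation <- tab
  }

  if ("summary" %in% cfg$stages) {
    if (is.null(out$modulation)) {
      stop("summary stage requires the modulation stage")
    }
    cls <- classify_bidirectional(out$modulation)
    utils::write.csv(cls$per_neuron,
                     file.path(cfg$output_dir, "neuron_classes.csv"),
                     row.names = FALSE)
    yaml::write_yaml(as.list(cls$fractions),
                     file.path(cfg$output_dir, "summary.yaml"),
                     precision = 17)
    log_line("summary", n_neurons = nrow(cls$per_neuron),
             frac_bidirectional = unname(cls$fractions["bidirectional"]))
    out$summary <- cls
  }

  yaml::write_yaml(list(seed = cfg$seed, stages = cfg$stages,
                        params = cfg$params,
                        input_dir = basename(cfg$input_dir)),
                   file.path(cfg$output_dir, "config.yaml"), precision = 17)
  invisible(out)
}
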