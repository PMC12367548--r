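#' Write a simulated session to a fixture bundle directory
#'
#' Writes the plain-text bundle consumed by the analysis stages:
#' `tracking.csv` (frame, time_s, hand/slit coordinates, likelihood),
#' `spikes.csv` (neuron_id, spike_time_s), `trials.csv` (long format:
#' trial_id, event_name, time_s, trial_type), optionally `opto_trials.csv`,
#' and `ground_truth.yaml` holding the generator's injected parameters.
#'
#' @param session a [simulate_behavior_session()] result (or NULL)
#' @param trains list of [spike_train()] (or NULL)
#' @param dir output directory (created if needed)
#' @param opto_trials optional opto trial table
#' @param truth ground-truth list; defaults to `session$truth`
#' @return `dir`, invisibly
#' @export
write_session_bundle <- function(session = NULL, trains = NULL, dir,
                                 opto_trials = NULL, truth = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(session)) {
    utils::write.csv(session$track, file.path(dir, "tracking.csv"),
                     row.names = FALSE)
    ev_cols <- intersect(c("reach_start", "slit_cross", "retract_start",
                           "retract_stop", "handle_start",
                           "manipulation_start", "manipulation_stop"),
                         names(session$trials))
    long <- do.call(rbind, lapply(ev_cols, function(cn) {
      data.frame(trial_id = session$trials$trial_id, event_name = cn,
                 time_s = session$trials[[cn]],
                 trial_type = session$trials$trial_type)
    }))
    long <- long[!is.na(long$time_s), , drop = FALSE]
    utils::write.csv(long[order(long$trial_id), ],
                     file.path(dir, "trials.csv"), row.names = FALSE)
  }
  if (!is.null(trains)) {
    sp <- do.call(rbind, lapply(trains, function(tr) {
      data.frame(neuron_id = tr$neuron_id, spike_time_s = tr$times)
    }))
    utils::write.csv(sp, file.path(dir, "spikes.csv"), row.names = FALSE)
    span <- trains[[1]]$span
    utils::write.csv(data.frame(start_s = span[1], stop_s = span[2]),
                     file.path(dir, "session_span.csv"), row.names = FALSE)
  }
  if (!is.null(opto_trials)) {
    utils::write.csv(opto_trials, file.path(dir, "opto_trials.csv"),
                     row.names = FALSE)
  }
  truth <- truth %||% session$truth
  if (!is.null(truth)) {
    write_ground_truth(truth, file.path(dir, "ground_truth.yaml"))
  }
  invisible(dir)
}

# Serialize ground truth to YAML at full double precision so the
# write -> read round trip is lossless; data.frames become column lists.
write_ground_truth <- function(truth, path) {
  to_plain <- function(x) {
    if (is.data.frame(x)) {
      c(list(.data_frame = TRUE), lapply(as.list(x), to_plain))
    } else if (is.list(x)) {
      lapply(unclass(x), to_plain)
    } else x
  }
  yaml::write_yaml(to_plain(truth), path, precision = 17)
  invisible(path)
}

#' Read ground truth written by [write_session_bundle()]
#' @param path path to `ground_truth.yaml`
#' @return the ground-truth list, with data.frames restored
#' @export
read_ground_truth <- function(path) {
  from_plain <- function(x) {
    if (is.list(x)) {
      if (isTRUE(x$.data_frame)) {
        x$.data_frame <- NULL
        as.data.frame(lapply(x, function(col) {
          if (is.list(col)) unlist(lapply(col, function(v) {
            if (is.null(v)) NA else v
          })) else col
        }))
      } else lapply(x, from_plain)
    } else x
  }
  from_plain(yaml::read_yaml(path))
}

#' Read spike trains from a spikes.csv file
#'
#' @param path path to a CSV with columns `neuron_id`, `spike_time_s`
#' @param span session span; defaults to `session_span.csv` next to the
#'   file if present, else `c(0, max spike time + 1)`
#' @return list of [spike_train()]
#' @export
read_spikes_csv <- function(path, span = NULL) {
  sp <- utils::read.csv(path)
  if (is.null(span)) {
    span_file <- file.path(dirname(path), "session_span.csv")
    span <- if (file.exists(span_file)) {
      as.numeric(utils::read.csv(span_file)[1, c("start_s", "stop_s")])
    } else c(0, max(sp$spike_time_s) + 1)
  }
  by_id <- split(sp$spike_time_s, sp$neuron_id)
  out <- lapply(names(by_id), function(id) {
    spike_train(sort(by_id[[id]]), span,
                if (grepl("^-?[0-9]+$", id)) as.integer(id) else id)
  })
  names(out) <- names(by_id)
  out
}

#' Read a session bundle directory
#'
#' @param dir a directory written by [write_session_bundle()]
#' @return list with `track`, `trials` (wide event table), `trains`,
#'   `opto_trials`, `truth` (elements NULL when the file is absent)
#' @export
read_session_bundle <- function(dir) {
  out <- list(track = NULL, trials = NULL, trains = NULL,
              opto_trials = NULL, truth = NULL)
  tf <- file.path(dir, "tracking.csv")
  if (file.exists(tf)) {
    tr <- utils::read.csv(tf)
    class(tr) <- c("hand_track", "data.frame")
    attr(tr, "frame_rate") <- 1 / stats::median(diff(tr$time_s))
    out$track <- tr
  }
  trf <- file.path(dir, "trials.csv")
  if (file.exists(trf)) {
    long <- utils::read.csv(trf)
    wide <- stats::reshape(long, idvar = c("trial_id", "trial_type"),
                           timevar = "event_name", direction = "wide")
    names(wide) <- sub("^time_s\\.", "", names(wide))
    out$trials <- wide[order(wide$trial_id), , drop = FALSE]
    rownames(out$trials) <- NULL
  }
  sf <- file.path(dir, "spikes.csv")
  if (file.exists(sf)) out$trains <- read_spikes_csv(sf)
  of <- file.path(dir, "opto_trials.csv")
  if (file.exists(of)) out$opto_trials <- utils::read.csv(of)
  gf <- file.path(dir, "ground_truth.yaml")
  if (file.exists(gf)) out$truth <- read_ground_truth(gf)
  out
}

# ---- minimal NumPy .npy support (1-D arrays), for Kilosort/Phy output ----

read_npy_1d <- function(path) {
  raw_all <- readBin(path, "raw", file.info(path)$size)
  if (raw_all[1] != as.raw(0x93) ||
        rawToChar(raw_all[2:6]) != "NUMPY") {
    stop("not an .npy file: ", path)
  }
  major <- as.integer(raw_all[7])
  if (major >= 2) {
    hlen <- readBin(raw_all[9:12], "integer", 1, size = 4,
                    endian = "little")
    off <- 12L + hlen
    header <- rawToChar(raw_all[13:(12 + hlen)])
  } else {
    hlen <- readBin(raw_all[9:10], "integer", 1, size = 2, signed = FALSE,
                    endian = "little")
    off <- 10L + hlen
    header <- rawToChar(raw_all[11:(10 + hlen)])
  }
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  if (grepl("'fortran_order':\\s*True", header)) {
    stop("fortran-ordered .npy arrays are not supported")
  }
  shape <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  dims <- as.numeric(strsplit(gsub("\\s", "", shape), ",")[[1]])
  n <- prod(dims[dims > 0])
  body <- raw_all[(off + 1):length(raw_all)]
  typ <- sub("^[<>|=]", "", descr)
  decode_i64 <- function(b) {
    w <- readBin(b, "integer", 2 * n, size = 4, endian = "little")
    lo <- w[seq(1, 2 * n, 2)]; hi <- w[seq(2, 2 * n, 2)]
    hi * 2^32 + ifelse(lo < 0, lo + 2^32, lo)
  }
  switch(typ,
    f8 = readBin(body, "double", n, size = 8, endian = "little"),
    f4 = readBin(body, "double", n, size = 4, endian = "little"),
    i4 = readBin(body, "integer", n, size = 4, endian = "little"),
    i2 = readBin(body, "integer", n, size = 2, endian = "little"),
    u4 = {
      v <- as.numeric(readBin(body, "integer", n, size = 4,
                              endian = "little"))
      ifelse(v < 0, v + 2^32, v)
    },
    i8 = decode_i64(body),
    u8 = decode_i64(body),
    stop("unsupported .npy dtype: ", descr))
}

#' Read spike trains from a Kilosort/Phy-style directory
#'
#' Reads the flat-array sorter output: `spike_times.npy` (sample indices)
#' and `spike_clusters.npy` (cluster id per spike). The sampling rate is
#' taken from `params.py` (`sample_rate = ...`) when present.
#'
#' @param dir directory containing the arrays
#' @param sample_rate samples/s; overrides `params.py`
#' @param span session span, s; defaults to `c(0, max time + 1)`
#' @return named list of [spike_train()], one per cluster
#' @export
read_phy_dir <- function(dir, sample_rate = NULL, span = NULL) {
  if (is.null(sample_rate)) {
    pf <- file.path(dir, "params.py")
    if (file.exists(pf)) {
      ln <- grep("^\\s*sample_rate", readLines(pf, warn = FALSE),
                 value = TRUE)
      if (length(ln)) {
        sample_rate <- as.numeric(sub(".*=\\s*", "", ln[1]))
      }
    }
    if (is.null(sample_rate) || is.na(sample_rate)) {
      stop("sample_rate not given and not found in params.py")
    }
  }
  st <- read_npy_1d(file.path(dir, "spike_times.npy")) / sample_rate
  cl <- read_npy_1d(file.path(dir, "spike_clusters.npy"))
  if (length(st) != length(cl)) {
    stop("spike_times and spike_clusters lengths differ")
  }
  span <- span %||% c(0, max(st) + 1)
  by_cl <- split(st, cl)
  out <- lapply(names(by_cl), function(id) {
    spike_train(sort(by_cl[[id]]), span, as.integer(id))
  })
  names(out) <- names(by_cl)
  out
}

# .npy writer used to build test fixtures in code (1-D arrays).
write_npy_1d <- function(x, path, dtype = c("f8", "i8", "u4")) {
  dtype <- match.arg(dtype)
  dict <- sprintf("{'descr': '<%s', 'fortran_order': False, 'shape': (%d,), }",
                  dtype, length(x))
  pad <- (64 - (10 + nchar(dict) + 1) %% 64) %% 64
  header <- paste0(dict, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(as.raw(0x93), as.raw(utf8ToInt("NUMPY")),
             as.raw(1), as.raw(0)), con)
  writeBin(as.integer(nchar(header)), con, size = 2, endian = "little")
  writeBin(charToRaw(header), con)
  if (dtype == "f8") {
    writeBin(as.numeric(x), con, size = 8, endian = "little")
  } else if (dtype == "i8") {
    lo <- as.integer(x %% 2^32 - ifelse(x %% 2^32 >= 2^31, 2^32, 0))
    hi <- as.integer(x %/% 2^32)
    w <- integer(2 * length(x))
    w[seq(1, 2 * length(x), 2)] <- lo
    w[seq(2, 2 * length(x), 2)] <- hi
    writeBin(w, con, size = 4, endian = "little")
  } else {
    v <- as.numeric(x)
    writeBin(as.integer(v - ifelse(v >= 2^31, 2^32, 0)), con, size = 4,
             endian = "little")
  }
  invisible(path)
}
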