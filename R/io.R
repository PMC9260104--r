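#' Construct an LFP recording
#'
#' Container for a multichannel local field potential recording. The full
#' pipeline expects at least one channel with role \code{"cortical"} (used
#' for slow-oscillation and spindle detection) and one with role
#' \code{"hippocampal"} (sharp-wave ripples), but single-role recordings are
#' valid for partial analyses.
#'
#' @param samples numeric matrix, one column per channel (rows are samples),
#'   or a list of equal-length numeric vectors.
#' @param fs sampling rate in Hz; must be positive.
#' @param channels data.frame with columns \code{label} and \code{role}
#'   (\code{"cortical"} or \code{"hippocampal"}), one row per channel.
#' @param t0 recording start time in seconds (default 0). All event and epoch
#'   times produced by the pipeline are seconds from \code{t0}.
#' @return An object of class \code{lfp_recording}: a list with elements
#'   \code{samples} (matrix), \code{fs}, \code{channels}, \code{t0}.
#' @export
lfp_recording <- function(samples, fs, channels, t0 = 0) {
  if (is.list(samples) && !is.data.frame(samples)) {
    lens <- vapply(samples, length, 1L)
    if (length(unique(lens)) > 1L) stop("channel-length mismatch")
    samples <- do.call(cbind, lapply(samples, as.numeric))
  }
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a positive number")
  channels <- as.data.frame(channels, stringsAsFactors = FALSE)
  if (!all(c("label", "role") %in% names(channels)))
    stop("channels needs 'label' and 'role' columns")
  if (nrow(channels) != ncol(samples))
    stop("channels rows must match sample columns")
  if (!all(channels$role %in% c("cortical", "hippocampal")))
    stop("channel roles must be 'cortical' or 'hippocampal'")
  colnames(samples) <- channels$label
  structure(list(samples = samples, fs = fs, channels = channels, t0 = t0),
            class = "lfp_recording")
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("<lfp_recording> %d channel(s), fs = %g Hz, duration = %.2f s\n",
              ncol(x$samples), x$fs, nrow(x$samples) / x$fs))
  for (i in seq_len(nrow(x$channels)))
    cat(sprintf("  %s [%s]\n", x$channels$label[i], x$channels$role[i]))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec an \code{lfp_recording}
#' @return duration in seconds
#' @export
rec_duration <- function(rec) nrow(rec$samples) / rec$fs

#' Extract one channel by role
#' @param rec an \code{lfp_recording}
#' @param role \code{"cortical"} or \code{"hippocampal"}
#' @return numeric vector of samples (first channel with that role)
#' @export
channel_by_role <- function(rec, role) {
  i <- which(rec$channels$role == role)
  if (!length(i)) stop(sprintf("no channel with role '%s'", role))
  rec$samples[, i[1]]
}

## ---- interval sets -------------------------------------------------------

#' Construct an interval set
#'
#' Half-open intervals \code{[start, end)} in seconds, sorted and
#' non-overlapping (overlapping or touching inputs are merged).
#'
#' @param start,end numeric vectors of equal length; \code{end > start}.
#' @return data.frame with columns \code{start}, \code{end}, class
#'   \code{interval_set}.
#' @export
interval_set <- function(start = numeric(), end = numeric()) {
  if (length(start) != length(end)) stop("start/end length mismatch")
  if (any(end <= start)) stop("intervals need end > start")
  o <- order(start)
  start <- start[o]; end <- end[o]
  if (length(start) > 1L) {
    ms <- start[1]; me <- end[1]; rs <- re <- numeric(0)
    for (i in 2:length(start)) {
      if (start[i] <= me) me <- max(me, end[i])
      else { rs <- c(rs, ms); re <- c(re, me); ms <- start[i]; me <- end[i] }
    }
    start <- c(rs, ms); end <- c(re, me)
  }
  structure(data.frame(start = start, end = end),
            class = c("interval_set", "data.frame"))
}

#' Total duration of an interval set in seconds
#' @param iv an \code{interval_set}
#' @return total covered time (s)
#' @export
iv_duration <- function(iv) if (nrow(iv) == 0L) 0 else sum(iv$end - iv$start)

#' Which interval contains each time point
#' @param iv an \code{interval_set}
#' @param t numeric vector of times (s)
#' @return integer vector: interval index per time, NA if uncovered
#' @export
iv_locate <- function(iv, t) {
  if (nrow(iv) == 0L) return(rep(NA_integer_, length(t)))
  idx <- findInterval(t, iv$start)
  inside <- idx >= 1L & t < iv$end[pmax(idx, 1L)]
  idx[!inside] <- NA_integer_
  idx
}

## ---- recording I/O -------------------------------------------------------

#' Read an LFP recording from disk
#'
#' Supported formats: \code{"csv"} (one column per channel, header row of
#' labels), \code{"raw"} (little-endian float32, sample-major interleaved,
#' with a JSON sidecar \code{<path>.json} declaring \code{fs} and
#' \code{channels}), and \code{"edf"} (16-bit continuous EDF). Format is
#' inferred from the extension when \code{format = "auto"}.
#'
#' @param path file path.
#' @param format one of \code{"auto"}, \code{"csv"}, \code{"raw"},
#'   \code{"edf"}.
#' @param fs sampling rate in Hz; required for CSV, ignored when the file
#'   carries it.
#' @param roles named character vector mapping channel labels to roles for
#'   formats that do not store roles (CSV, EDF), e.g.
#'   \code{c(MPtA = "cortical", CA1 = "hippocampal")}. Unmapped channels
#'   default to \code{"cortical"}.
#' @param target_fs if non-NULL, resample all channels to this rate on load
#'   (polyphase, via \code{signal::resample}). The pipeline's canonical rate
#'   is 1000 Hz.
#' @return an \code{lfp_recording}
#' @export
read_recording <- function(path, format = c("auto", "csv", "raw", "edf"),
                           fs = NULL, roles = NULL, target_fs = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", edf = "edf", raw = "raw", bin = "raw",
                     stop(sprintf("unknown format for extension '%s'", ext)))
  }
  rec <- switch(format,
    csv = {
      if (is.null(fs)) stop("missing fs: CSV carries no sampling rate")
      d <- utils::read.csv(path, check.names = FALSE)
      labels <- names(d)
      lfp_recording(as.matrix(d), fs,
                    data.frame(label = labels, role = .roles_for(labels, roles)))
    },
    raw = {
      sidecar <- paste0(path, ".json")
      if (!file.exists(sidecar)) stop("missing sidecar")
      meta <- jsonlite::fromJSON(sidecar, simplifyDataFrame = TRUE)
      if (is.null(meta$fs)) stop("missing fs in sidecar")
      ch <- as.data.frame(meta$channels, stringsAsFactors = FALSE)
      nch <- nrow(ch)
      x <- readBin(path, "numeric", n = file.size(path) / 4L, size = 4L,
                   endian = "little")
      if (length(x) %% nch != 0L) stop("channel-length mismatch in raw file")
      lfp_recording(matrix(x, ncol = nch, byrow = TRUE), meta$fs, ch,
                    t0 = if (is.null(meta$t0)) 0 else meta$t0)
    },
    edf = {
      e <- read_edf(path)
      lab <- e$channels$label
      lfp_recording(e$samples, e$fs,
                    data.frame(label = lab, role = .roles_for(lab, roles)))
    })
  if (!is.null(target_fs) && target_fs != rec$fs)
    rec <- resample_recording(rec, target_fs)
  rec
}

.roles_for <- function(labels, roles) {
  if (is.null(roles)) return(rep("cortical", length(labels)))
  r <- unname(roles[labels])
  r[is.na(r)] <- "cortical"
  r
}

#' Resample a recording to a new rate
#'
#' Zero-phase resampling: when downsampling, each channel is first
#' anti-alias filtered with a forward-backward Butterworth low-pass at
#' 80\% of the target Nyquist (no group delay, matching the zero-phase
#' convention of the rest of the package), then evaluated on the new time
#' grid by cubic spline interpolation. Upsampling interpolates directly.
#'
#' @param rec an \code{lfp_recording}
#' @param target_fs new sampling rate (Hz)
#' @return resampled \code{lfp_recording}
#' @export
resample_recording <- function(rec, target_fs) {
  n_out <- floor(nrow(rec$samples) / rec$fs * target_fs)
  t_in <- (seq_len(nrow(rec$samples)) - 1) / rec$fs
  t_out <- (seq_len(n_out) - 1) / target_fs
  bf <- if (target_fs < rec$fs)
    signal::butter(6, 0.8 * target_fs / rec$fs) else NULL
  y <- apply(rec$samples, 2, function(x) {
    if (!is.null(bf)) x <- signal::filtfilt(bf, x)
    stats::spline(t_in, x, xout = t_out)$y
  })
  lfp_recording(y, target_fs, rec$channels, rec$t0)
}

## ---- minimal EDF ---------------------------------------------------------

# Minimal continuous EDF support: 16-bit samples, identical rate across
# channels, 1-second data records. Enough for LFP interchange; no
# annotations, no EDF+ discontinuities.

.edf_pad <- function(x, n) formatC(substr(x, 1, n), width = n, flag = "-")

#' Write a recording to a minimal EDF file
#'
#' Samples are scaled to the 16-bit range per channel; read-back therefore
#' reproduces the signal up to quantization (~(max-min)/65535 per channel).
#'
#' @param rec an \code{lfp_recording}; fs must be an integer number of
#'   samples per second.
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_edf <- function(rec, path) {
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF writer requires integer fs")
  fs <- as.integer(round(fs))
  x <- rec$samples
  nrec <- ceiling(nrow(x) / fs)
  if (nrow(x) < nrec * fs)  # pad the final record with the last value
    x <- rbind(x, x[rep(nrow(x), nrec * fs - nrow(x)), , drop = FALSE])
  ns <- ncol(x)
  pmin <- apply(x, 2, min); pmax <- apply(x, 2, max)
  flat <- pmax - pmin < 1e-12
  pmax[flat] <- pmin[flat] + 1
  dmin <- -32768; dmax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_pad("0", 8), .edf_pad("sleeposc", 80), .edf_pad("recording", 80),
    .edf_pad("01.01.00", 8), .edf_pad("00.00.00", 8),
    .edf_pad(as.character(256L * (ns + 1L)), 8), .edf_pad("", 44),
    .edf_pad(as.character(nrec), 8), .edf_pad("1", 8),
    .edf_pad(as.character(ns), 4))
  writeChar(hdr, con, eos = NULL)
  wf <- function(vals, w) writeChar(paste0(vapply(as.character(vals),
      .edf_pad, "", n = w), collapse = ""), con, eos = NULL)
  wf(rec$channels$label, 16)
  wf(rep("", ns), 80)                       # transducer
  wf(rep("uV", ns), 8)                      # physical dimension
  wf(formatC(pmin, format = "g", digits = 7), 8)
  wf(formatC(pmax, format = "g", digits = 7), 8)
  wf(rep(dmin, ns), 8)
  wf(rep(dmax, ns), 8)
  wf(rep("", ns), 80)                       # prefiltering
  wf(rep(fs, ns), 8)                        # samples per record
  wf(rep("", ns), 32)                       # reserved
  scale <- (dmax - dmin) / (pmax - pmin)
  for (r in seq_len(nrec)) {
    rows <- ((r - 1L) * fs + 1L):(r * fs)
    for (ch in seq_len(ns)) {
      dig <- round((x[rows, ch] - pmin[ch]) * scale[ch]) + dmin
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2L,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read a minimal EDF file
#' @param path EDF file path
#' @return list with \code{samples} (matrix), \code{fs}, \code{channels}
#'   (data.frame with \code{label})
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                      # header bytes
  rd(44)
  nrec <- as.integer(rd(8))
  recdur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 1)
  pmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 1)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 1)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 1)
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 1L)
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1L)
    stop("EDF reader supports a single common sampling rate")
  fs <- spr[1] / recdur
  out <- matrix(0, nrow = nrec * spr[1], ncol = ns)
  gain <- (pmax - pmin) / (dmax - dmin)
  for (r in seq_len(nrec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2L, signed = TRUE,
                     endian = "little")
      out[((r - 1L) * spr[ch] + 1L):(r * spr[ch]), ch] <-
        (dig - dmin[ch]) * gain[ch] + pmin[ch]
    }
  }
  list(samples = out, fs = fs,
       channels = data.frame(label = labels, stringsAsFactors = FALSE))
}

## ---- event and epoch tables ----------------------------------------------

.event_cols <- c("event_type", "channel", "start_s", "end_s", "anchor_s",
                 "amplitude", "peak_freq_hz", "duration_s")

#' Construct an event set
#'
#' The canonical table of detected oscillatory events. One row per event;
#' \code{anchor_s} is the single timestamp used in coupling analyses (SO
#' trough, spindle envelope peak, SWR trough).
#'
#' @param event_type character: \code{"SO"}, \code{"SPINDLE"} or \code{"SWR"}
#' @param channel channel label
#' @param start_s,end_s event interval, seconds from recording start
#' @param anchor_s anchor timestamp (s)
#' @param amplitude event amplitude in z-units (SO: peak-to-trough;
#'   spindle/SWR: envelope maximum)
#' @param peak_freq_hz within-event oscillation frequency estimate (Hz)
#' @return data.frame of class \code{event_set} with a fixed column order
#' @export
event_set <- function(event_type = character(), channel = character(),
                      start_s = numeric(), end_s = numeric(),
                      anchor_s = numeric(), amplitude = numeric(),
                      peak_freq_hz = numeric()) {
  d <- data.frame(event_type = as.character(event_type),
                  channel = as.character(channel),
                  start_s = start_s, end_s = end_s, anchor_s = anchor_s,
                  amplitude = amplitude, peak_freq_hz = peak_freq_hz,
                  duration_s = end_s - start_s,
                  stringsAsFactors = FALSE)
  structure(d, class = c("event_set", "data.frame"))
}

#' Write events to CSV
#' @param events an \code{event_set}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_events <- function(events, path) {
  stopifnot(all(.event_cols %in% names(events)))
  utils::write.csv(as.data.frame(events)[, .event_cols], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read events from CSV
#' @param path CSV path written by \code{write_events}
#' @return an \code{event_set}
#' @export
read_events <- function(path) {
  hdr <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  if (!identical(hdr, .event_cols))
    stop("unexpected events CSV header")
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = c(event_type = "character",
                                      channel = "character"))
  structure(d, class = c("event_set", "data.frame"))
}

#' Write sleep epochs to CSV
#' @param epochs a \code{sleep_epochs} object (see \code{\link{kmeans_stage}})
#'   or any list with a \code{windows} data.frame (\code{state,start_s,end_s})
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_epochs <- function(epochs, path) {
  w <- epochs$windows
  utils::write.csv(w[, c("state", "start_s", "end_s")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read sleep epochs from CSV and rebuild retained NREM intervals
#' @param path CSV path written by \code{write_epochs}
#' @param min_dur_s,min_windows retention rule for NREM epochs (defaults:
#'   at least 30 s and 5 consecutive windows)
#' @return a \code{sleep_epochs} object
#' @export
read_epochs <- function(path, min_dur_s = 30, min_windows = 5L) {
  w <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(w), c("state", "start_s", "end_s")))
    stop("unexpected epochs CSV header")
  .sleep_epochs(w, min_dur_s, min_windows)
}

# assemble a sleep_epochs object from a per-window state table
.sleep_epochs <- function(windows, min_dur_s = 30, min_windows = 5L) {
  stopifnot(all(windows$state %in% c("NREM", "OTHER")))
  r <- rle(windows$state == "NREM")
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  ns <- ne <- numeric(0)
  for (k in keep) {
    dur <- windows$end_s[ends[k]] - windows$start_s[starts[k]]
    if (dur >= min_dur_s && r$lengths[k] >= min_windows) {
      ns <- c(ns, windows$start_s[starts[k]])
      ne <- c(ne, windows$end_s[ends[k]])
    }
  }
  structure(list(windows = windows,
                 nrem = if (length(ns)) interval_set(ns, ne) else
                   interval_set()),
            class = "sleep_epochs")
}

#' @export
print.sleep_epochs <- function(x, ...) {
  cat(sprintf("<sleep_epochs> %d windows, %d retained NREM epoch(s), %.1f NREM min\n",
              nrow(x$windows), nrow(x$nrem), nrem_minutes(x)))
  invisible(x)
}
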