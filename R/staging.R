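#' Z-score every channel of a recording
#'
#' Channel-wise standardization to mean 0 and SD 1, the normalization applied
#' to each LFP channel before staging and event detection. Makes all
#' downstream amplitude thresholds unit-free, and staging invariant to
#' channel-wise affine rescaling of the raw input.
#'
#' @param rec an \code{lfp_recording}
#' @return z-scored \code{lfp_recording}
#' @export
zscore_recording <- function(rec) {
  z <- apply(rec$samples, 2, function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) stop("zero-variance channel")
    (x - mean(x)) / s
  })
  lfp_recording(z, rec$fs, rec$channels, rec$t0)
}

#' Per-window band-power staging features
#'
#' Segments the recording into non-overlapping windows (default 5 s) and
#' computes, per window, the mean PSD of the cortical channel in the delta
#' band (0.5-4 Hz) and of the hippocampal channel in the theta band
#' (4-8 Hz), via Welch's method (1 s Hann segments, 50\% overlap). Windows
#' overlapping mobile periods are flagged so staging can ignore them.
#'
#' @param rec a z-scored \code{lfp_recording} with one cortical and one
#'   hippocampal channel
#' @param window_s window length in seconds (default 5)
#' @param immobile logical vector, one value per window (TRUE = the animal
#'   was immobile throughout the window); \code{NULL} means immobile
#'   everywhere
#' @param delta,theta band edges (Hz)
#' @return data.frame of class \code{stage_features}: \code{window_start},
#'   \code{window_end}, \code{delta_power}, \code{theta_power},
#'   \code{immobile}
#' @export
band_features <- function(rec, window_s = 5, immobile = NULL,
                          delta = c(0.5, 4), theta = c(4, 8)) {
  fs <- rec$fs
  L <- round(window_s * fs)
  n_win <- nrow(rec$samples) %/% L
  if (n_win < 1L) stop("recording shorter than one window")
  ctx <- channel_by_role(rec, "cortical")
  hpc <- channel_by_role(rec, "hippocampal")
  if (is.null(immobile)) immobile <- rep(TRUE, n_win)
  if (length(immobile) != n_win)
    stop(sprintf("immobility mask has %d entries for %d windows",
                 length(immobile), n_win))
  dp <- tp <- numeric(n_win)
  for (w in seq_len(n_win)) {
    idx <- ((w - 1L) * L + 1L):(w * L)
    dp[w] <- band_power(ctx[idx], fs, delta, seg_s = min(1, window_s))
    tp[w] <- band_power(hpc[idx], fs, theta, seg_s = min(1, window_s))
  }
  structure(data.frame(window_start = (seq_len(n_win) - 1L) * window_s,
                       window_end = seq_len(n_win) * window_s,
                       delta_power = dp, theta_power = tp,
                       immobile = immobile),
            class = c("stage_features", "data.frame"))
}

#' Stage windows into NREM vs other by k-means on band power
#'
#' k-means (k = 2, 10 restarts) on (log delta power, log theta power) of the
#' immobile windows. The cluster with the higher mean cortical delta power is
#' labeled NREM — making the output independent of the arbitrary cluster
#' numbering — and mobile windows are labeled OTHER. Runs of consecutive
#' NREM windows are retained as sleep epochs only when they last at least
#' \code{min_dur_s} seconds AND span at least \code{min_windows} windows.
#'
#' @param features a \code{stage_features} table from \code{band_features}
#' @param min_dur_s minimum epoch duration in seconds (default 30)
#' @param min_windows minimum consecutive windows per epoch (default 5)
#' @param seed RNG seed for the k-means restarts
#' @return object of class \code{sleep_epochs}: \code{windows} (data.frame
#'   \code{state,start_s,end_s}) and \code{nrem} (an \code{interval_set} of
#'   retained epochs)
#' @export
kmeans_stage <- function(features, min_dur_s = 30, min_windows = 5L,
                         seed = 1L) {
  imm <- which(features$immobile)
  if (length(imm) < 2L) stop("need at least 2 immobile windows")
  X <- cbind(log(pmax(features$delta_power[imm], .Machine$double.xmin)),
             log(pmax(features$theta_power[imm], .Machine$double.xmin)))
  state <- rep("OTHER", nrow(features))
  if (nrow(unique(X)) < 2L) {
    # degenerate: all immobile windows identical -> single NREM cluster
    state[imm] <- "NREM"
  } else {
    km <- local({ set.seed(seed); stats::kmeans(X, centers = 2L, nstart = 10L) })
    nrem_cluster <- which.max(tapply(features$delta_power[imm], km$cluster,
                                     mean))
    state[imm[km$cluster == as.integer(nrem_cluster)]] <- "NREM"
  }
  windows <- data.frame(state = state,
                        start_s = features$window_start,
                        end_s = features$window_end)
  .sleep_epochs(windows, min_dur_s, min_windows)
}

#' Total retained NREM time in minutes
#' @param epochs a \code{sleep_epochs} object
#' @return NREM minutes (numeric)
#' @export
nrem_minutes <- function(epochs) iv_duration(epochs$nrem) / 60
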