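#' Cross-correlogram of two event trains
#'
#' Histogram of target-minus-reference anchor lags within a symmetric
#' window. Anchor conventions for the canonical pairs: SO-spindle uses the
#' SO down-state (trough) vs the spindle envelope peak, spindle-SWR the
#' spindle envelope peak vs the SWR trough, and SO-SWR the SO trough vs the
#' SWR trough — i.e. always the single anchor timestamp of each event, so a
#' coupled pair's lag reflects the offset of the events' cores rather than
#' depending on event duration.
#'
#' @param ref,target sorted anchor times (s)
#' @param window half-width of the lag window (s; default 0.5)
#' @param binwidth histogram bin width (s; default 0.01)
#' @return list of class \code{coupling_result} with \code{bin_edges},
#'   \code{counts} (all (ref,target) pairs with lag in the window),
#'   \code{observed_coupled} (targets within \code{window} of at least one
#'   reference, counted once each), plus NULL permutation fields to be
#'   filled by \code{\link{montecarlo_coupling}}
#' @export
crosscorrelogram <- function(ref, target, window = 0.5, binwidth = 0.01) {
  if (!length(ref)) stop("empty reference train")
  ref <- sort(ref); target <- sort(target)
  edges <- seq(-window, window, by = binwidth)
  if (abs(edges[length(edges)] - window) > 1e-12) edges <- c(edges, window)
  lags <- numeric(0)
  if (length(target)) {
    lo <- findInterval(ref - window, target) + 1L
    hi <- findInterval(ref + window, target)
    keep <- which(hi >= lo)
    if (length(keep))
      lags <- unlist(lapply(keep, function(i)
        target[lo[i]:hi[i]] - ref[i]), use.names = FALSE)
  }
  counts <- if (length(lags))
    as.vector(table(cut(lags, edges, include.lowest = TRUE)))
  else rep(0L, length(edges) - 1L)
  structure(list(pair = NULL, bin_edges = edges, counts = counts,
                 observed_coupled = .count_coupled(ref, target, window),
                 coupled_density = NULL, null_mean = NULL, null_sd = NULL,
                 significant = NULL, window = window),
            class = "coupling_result")
}

# number of targets with at least one reference within +/- window
.count_coupled <- function(ref, target, window) {
  if (!length(target) || !length(ref)) return(0L)
  idx <- findInterval(target, ref)
  dlo <- ifelse(idx >= 1L, target - ref[pmax(idx, 1L)], Inf)
  dhi <- ifelse(idx < length(ref), ref[pmin(idx + 1L, length(ref))] - target,
                Inf)
  sum(pmin(dlo, dhi) <= window)
}

#' Monte-Carlo significance of event-train coupling
#'
#' The observed count of coupled targets (targets within \code{window} of at
#' least one reference) is compared against a permutation null built by
#' circularly shifting the target train within each retained NREM epoch by
#' an independent uniform offset, per permutation. This preserves the
#' within-epoch inter-event structure and each epoch's event occupancy.
#' Coupling is called significant when the observed count exceeds
#' null mean + 2 null SD (one-sided excess, following the mean +/- 2 SD
#' permutation rule).
#'
#' @param ref,target anchor times (s), both non-empty
#' @param epochs \code{sleep_epochs}; retained NREM epochs must cover all
#'   anchors
#' @param window coupling half-window (s)
#' @param binwidth correlogram bin width (s)
#' @param n_perm number of permutations (default 1000)
#' @param seed RNG seed
#' @param pair optional label, e.g. \code{"SO->SPINDLE"}
#' @return \code{coupling_result} with permutation fields filled:
#'   \code{null_mean}, \code{null_sd}, \code{significant},
#'   \code{coupled_density} (coupled targets per NREM minute),
#'   \code{null_counts}
#' @export
montecarlo_coupling <- function(ref, target, epochs, window = 0.5,
                                binwidth = 0.01, n_perm = 1000L, seed = 1L,
                                pair = NULL) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (!length(ref) || !length(target)) stop("empty event train")
  res <- crosscorrelogram(ref, target, window, binwidth)
  iv <- epochs$nrem
  ep <- iv_locate(iv, target)
  if (anyNA(ep)) stop("target anchors outside retained NREM epochs")
  ref <- sort(ref)
  null_counts <- integer(n_perm)
  set.seed(seed)
  starts <- iv$start[ep]; lens <- iv$end[ep] - iv$start[ep]
  rel <- target - starts
  for (p in seq_len(n_perm)) {
    off <- stats::runif(nrow(iv), 0, iv$end - iv$start)
    shifted <- starts + (rel + off[ep]) %% lens
    null_counts[p] <- .count_coupled(ref, shifted, window)
  }
  res$pair <- pair
  res$null_mean <- mean(null_counts)
  res$null_sd <- stats::sd(null_counts)
  res$null_counts <- null_counts
  res$significant <- res$observed_coupled > res$null_mean + 2 * res$null_sd
  res$coupled_density <- res$observed_coupled / nrem_minutes(epochs)
  res
}

#' @export
print.coupling_result <- function(x, ...) {
  cat(sprintf("<coupling_result>%s coupled = %d",
              if (!is.null(x$pair)) paste0(" ", x$pair, ":") else "",
              x$observed_coupled))
  if (!is.null(x$null_mean))
    cat(sprintf(" | null %.1f +/- %.1f | %s", x$null_mean, x$null_sd,
                if (isTRUE(x$significant)) "SIGNIFICANT" else "n.s."))
  cat("\n")
  invisible(x)
}

#' @export
plot.coupling_result <- function(x, ...) {
  mids <- (x$bin_edges[-1] + x$bin_edges[-length(x$bin_edges)]) / 2
  graphics::barplot(x$counts, names.arg = round(mids, 2), space = 0,
                    xlab = "lag (s)", ylab = "pair count", ...)
  invisible(x)
}

#' Slow-oscillation phase at event anchors
#'
#' Instantaneous phase of the 0.5-4 Hz filtered cortical trace at each
#' anchor time, from the analytic (Hilbert) signal, rotated so that 90
#' degrees is the SO up-state peak and 270 degrees the down-state trough
#' (0 degrees = rising zero crossing).
#'
#' @param so_filtered the 0.5-4 Hz band-passed cortical signal
#' @param fs sampling rate (Hz)
#' @param anchors anchor times (s) within the recording
#' @return numeric vector of phases in degrees, in [0, 360)
#' @export
event_phase <- function(so_filtered, fs, anchors) {
  idx <- round(anchors * fs) + 1L
  if (any(idx < 1L | idx > length(so_filtered)))
    stop("anchor outside recording")
  ph <- Arg(hilbert_analytic(so_filtered))[idx] * 180 / pi
  (ph + 90) %% 360
}

#' Circular summary and Rayleigh test of phase angles
#'
#' Circular mean direction and resultant length by vector summation, and the
#' Rayleigh test of non-uniformity (standard finite-n approximation to the
#' p-value).
#'
#' @param phases phases in degrees
#' @return list of class \code{phase_coupling_result}: \code{n},
#'   \code{preferred_phase} (deg, in [0,360)), \code{resultant_r},
#'   \code{rayleigh_p}
#' @export
circular_stats <- function(phases) {
  n <- length(phases)
  if (n < 1L) stop("empty phase list")
  rad <- phases * pi / 180
  C <- mean(cos(rad)); S <- mean(sin(rad))
  r <- sqrt(C^2 + S^2)
  mu <- (atan2(S, C) * 180 / pi) %% 360
  R <- n * r
  z <- R^2 / n
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - R^2)) - (1 + 2 * n))
  structure(list(n = n, preferred_phase = mu, resultant_r = r,
                 rayleigh_p = min(1, p)),
            class = "phase_coupling_result")
}

#' @export
print.phase_coupling_result <- function(x, ...) {
  cat(sprintf(
    "<phase_coupling> n = %d, preferred = %.1f deg, r = %.3f, Rayleigh p = %.3g\n",
    x$n, x$preferred_phase, x$resultant_r, x$rayleigh_p))
  invisible(x)
}

#' Draw from a von Mises distribution
#'
#' Best-Fisher rejection sampler; used by the simulator to place coupled
#' events at a preferred slow-oscillation phase.
#'
#' @param n number of draws
#' @param mu mean direction (degrees)
#' @param kappa concentration (>= 0; 0 = uniform)
#' @return phases in degrees in [0, 360)
#' @export
rvonmises <- function(n, mu, kappa) {
  if (kappa < 0) stop("kappa must be >= 0")
  mu_r <- mu * pi / 180
  if (kappa < 1e-8) return(stats::runif(n, 0, 360))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r0 <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r0 * z) / (r0 + z)
      c0 <- kappa * (r0 - f)
      if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
        out[i] <- mu_r + sign(u[3] - 0.5) * acos(f)
        break
      }
    }
  }
  (out * 180 / pi) %% 360
}
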