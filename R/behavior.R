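#' Object exploration bouts from a tracking table
#'
#' A sample counts as exploration of an object when the nose is within
#' \code{max_dist} of the object's boundary circle AND the heading (the
#' body-to-nose vector) points toward the object within
#' \code{heading_tol} degrees — operationalizing "active exploration" so
#' that sitting next to or facing away from an object is not scored.
#' Contiguous exploratory samples form bouts.
#'
#' @param track data.frame with columns \code{time_s, nose_x, nose_y,
#'   body_x, body_y} (cm), monotone time
#' @param objects data.frame with columns \code{label, x, y, radius} (cm)
#'   and logical \code{displaced}
#' @param max_dist maximum nose-to-boundary distance (cm; default 2)
#' @param heading_tol heading tolerance (degrees; default 45)
#' @return list: \code{bouts} (data.frame \code{object, start_s, end_s,
#'   duration_s, displaced}), \code{totals} (named seconds per object),
#'   \code{t_displaced}, \code{t_nondisplaced}
#' @export
exploration_bouts <- function(track, objects, max_dist = 2,
                              heading_tol = 45) {
  need <- c("time_s", "nose_x", "nose_y", "body_x", "body_y")
  if (!all(need %in% names(track))) stop("missing nose/body coordinates")
  if (anyNA(track$nose_x) || anyNA(track$nose_y))
    stop("missing nose coordinates")
  if (is.unsorted(track$time_s)) stop("time must be monotone")
  n <- nrow(track)
  dt <- diff(track$time_s)
  dt <- c(dt, if (length(dt)) stats::median(dt) else 0)  # weight per sample
  bouts <- list(); totals <- stats::setNames(numeric(nrow(objects)),
                                             objects$label)
  for (i in seq_len(nrow(objects))) {
    dx <- objects$x[i] - track$nose_x
    dy <- objects$y[i] - track$nose_y
    d_boundary <- sqrt(dx^2 + dy^2) - objects$radius[i]
    hx <- track$nose_x - track$body_x
    hy <- track$nose_y - track$body_y
    dot <- hx * dx + hy * dy
    cosang <- dot / (sqrt(hx^2 + hy^2) * sqrt(dx^2 + dy^2))
    cosang[!is.finite(cosang)] <- 1  # nose on center / zero heading: accept
    expl <- d_boundary <= max_dist & cosang >= cos(heading_tol * pi / 180)
    totals[i] <- sum(dt[expl])
    if (any(expl)) {
      runs <- .runs(expl)
      bouts[[i]] <- data.frame(object = objects$label[i],
                               start_s = track$time_s[runs[, 1]],
                               end_s = track$time_s[runs[, 2]] +
                                 dt[runs[, 2]],
                               displaced = objects$displaced[i])
    }
  }
  bouts <- if (length(Filter(Negate(is.null), bouts)))
    do.call(rbind, Filter(Negate(is.null), bouts)) else
    data.frame(object = character(), start_s = numeric(), end_s = numeric(),
               displaced = logical())
  bouts$duration_s <- bouts$end_s - bouts$start_s
  list(bouts = bouts, totals = totals,
       t_displaced = sum(totals[objects$displaced]),
       t_nondisplaced = sum(totals[!objects$displaced]))
}

#' Memory (discrimination) index
#'
#' \code{(t_d - t_n) / (t_d + t_n)}: +1 = exclusive exploration of the
#' displaced object, -1 = exclusive exploration of the non-displaced one,
#' 0 = no preference.
#'
#' @param t_d,t_n exploration seconds of the displaced / non-displaced
#'   object; the total must be positive
#' @return index in [-1, 1]
#' @export
memory_index <- function(t_d, t_n) {
  if (t_d + t_n <= 0) stop("zero total exploration")
  (t_d - t_n) / (t_d + t_n)
}

#' Cumulative memory index per time bin
#'
#' Exploration time of each object is accumulated up to each bin edge over
#' the trial; the index at a bin is the memory index of the cumulative
#' totals. Bins with zero cumulative exploration are NA. The final bin
#' equals the whole-trial index.
#'
#' @param bouts bout table from \code{\link{exploration_bouts}} (columns
#'   \code{start_s, end_s, displaced})
#' @param bin_s bin width (s; default 30)
#' @param total_s trial duration (s; default 300)
#' @return data.frame: \code{bin_end}, \code{t_d}, \code{t_n}, \code{index}
#' @export
binned_index <- function(bouts, bin_s = 30, total_s = 300) {
  edges <- seq(bin_s, total_s, by = bin_s)
  td <- tn <- numeric(length(edges))
  for (k in seq_along(edges)) {
    ov <- pmax(0, pmin(bouts$end_s, edges[k]) - bouts$start_s)
    td[k] <- sum(ov[bouts$displaced])
    tn[k] <- sum(ov[!bouts$displaced])
  }
  idx <- ifelse(td + tn > 0, (td - tn) / (td + tn), NA_real_)
  data.frame(bin_end = edges, t_d = td, t_n = tn, index = idx)
}

#' Trial inclusion filter
#'
#' A trial is excluded when the animal explored either object for less than
#' \code{min_each_s} during encoding, when its encoding-phase preference
#' exceeded \code{preference_cutoff} in absolute value (spontaneous object
#' preference), or when it did not sleep during the retention interval.
#'
#' @param trials data.frame with one row per trial and columns
#'   \code{enc_t_d, enc_t_n} (encoding exploration s) and logical
#'   \code{slept}
#' @param min_each_s minimum encoding exploration of each object (s)
#' @param preference_cutoff maximum |encoding index| tolerated
#' @return input with added \code{included} (logical) and \code{reason}
#'   (character, "" when included)
#' @export
inclusion_filter <- function(trials, min_each_s = 1,
                             preference_cutoff = 0.3) {
  need <- c("enc_t_d", "enc_t_n", "slept")
  if (!all(need %in% names(trials))) stop("unpaired trial records")
  reason <- character(nrow(trials))
  under <- trials$enc_t_d < min_each_s | trials$enc_t_n < min_each_s
  reason[under] <- "under-explored encoding"
  tot <- trials$enc_t_d + trials$enc_t_n
  pref <- abs(ifelse(tot > 0, (trials$enc_t_d - trials$enc_t_n) / tot, 0))
  sp <- !under & pref > preference_cutoff
  reason[sp] <- "spontaneous preference"
  ns <- !under & !sp & !trials$slept
  reason[ns] <- "no sleep in retention"
  trials$included <- reason == ""
  trials$reason <- reason
  trials
}

#' Total traveled distance
#' @param track tracking table with \code{body_x, body_y} (cm)
#' @return summed Euclidean displacement of the body point (cm)
#' @export
traveled_distance <- function(track) {
  if (nrow(track) < 2L) stop("need at least 2 samples")
  sum(sqrt(diff(track$body_x)^2 + diff(track$body_y)^2))
}

#' Wilcoxon signed-rank test of memory indices against chance
#'
#' Two-sided test of median 0. Exact for n <= 25 (distribution of the
#' positive-rank sum computed by convolution over average ranks, so tied
#' magnitudes are handled exactly); normal approximation with continuity
#' correction above. Zeros are dropped, as is standard.
#'
#' @param indices numeric vector of memory indices, n >= 5
#' @return list: \code{statistic} (positive-rank sum V), \code{p_value},
#'   \code{n} (after dropping zeros), \code{method}
#' @export
index_vs_chance <- function(indices) {
  if (length(indices) < 5L) stop("need at least 5 indices")
  x <- indices[indices != 0]
  if (!length(x)) stop("all indices are zero")
  n <- length(x)
  rk <- rank(abs(x))
  V <- sum(rk[x > 0])
  if (n <= 25L) {
    # exact distribution of V: gf product over (1 + z^(2*r_i)) / 2^n,
    # doubled ranks are integers even with ties
    r2 <- as.integer(round(2 * rk))
    dist <- c(1)  # dist[s+1] = #assignments with doubled sum s
    for (r in r2) {
      nd <- c(dist, numeric(r))
      nd[(r + 1):(length(dist) + r)] <-
        nd[(r + 1):(length(dist) + r)] + dist
      dist <- nd
    }
    tot <- 2^n
    v2 <- as.integer(round(2 * V))
    p_le <- sum(dist[1:(v2 + 1)]) / tot
    p_ge <- sum(dist[(v2 + 1):length(dist)]) / tot
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(rk)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  list(statistic = V, p_value = p, n = n, method = method)
}
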