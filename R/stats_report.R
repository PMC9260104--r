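#' Squared Spearman rank correlation with t-approximation p-value
#'
#' Rank correlation with average ranks on ties; the effect size reported is
#' rho squared, and the p-value comes from the t approximation on n - 2
#' degrees of freedom. Invariant to strictly monotone transforms of either
#' variable. Incomplete pairs are dropped.
#'
#' @param x,y numeric vectors of equal length; at least 4 complete pairs
#' @return list: \code{rho}, \code{rho2}, \code{p}, \code{n}
#' @export
spearman_r2 <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant input")
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1 - 1e-12) {
    p <- 0
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, rho2 = rho^2, p = p, n = n)
}

.battery_features <- c("power", "frequency", "duration", "density",
                       "amplitude")
.battery_types <- c("so", "spindle", "swr")
.battery_pairs <- c("so_spindle_coupled_density",
                    "spindle_swr_coupled_density",
                    "so_swr_coupled_density")

#' Regression battery over session-level features
#'
#' One Spearman regression per (event type x feature) and per coupled-event
#' density, against a chosen predictor, over all sessions or only those from
#' animals with a significant memory index. Sessions missing a value for a
#' given feature are dropped pairwise, and the n used is reported per row.
#' A Benjamini-Hochberg adjusted p-value column is emitted alongside the
#' raw p-values (which are the primary report, uncorrected).
#'
#' @param sessions data.frame, one row per animal x day, with columns
#'   \code{age}, \code{memory_index}, logical \code{sig_memory}, feature
#'   columns named \code{<type>_<feature>} for types so/spindle/swr and
#'   features power/frequency/duration/density/amplitude, and the three
#'   coupled-density columns \code{so_spindle_coupled_density},
#'   \code{spindle_swr_coupled_density}, \code{so_swr_coupled_density}
#' @param predictor \code{"age"} or \code{"memory_index"}
#' @param subset \code{"all"} or \code{"significant_memory"}
#' @return data.frame: \code{variable}, \code{n}, \code{rho2}, \code{p},
#'   \code{significant} (p < 0.05), \code{p_bh}
#' @export
regression_battery <- function(sessions,
                               predictor = c("age", "memory_index"),
                               subset = c("all", "significant_memory")) {
  predictor <- match.arg(predictor)
  subset <- match.arg(subset)
  if (subset == "significant_memory")
    sessions <- sessions[sessions$sig_memory %in% TRUE, , drop = FALSE]
  if (!nrow(sessions)) stop("empty subset")
  vars <- c(as.vector(outer(.battery_types, .battery_features, paste,
                            sep = "_")), .battery_pairs)
  rows <- lapply(vars, function(v) {
    if (!v %in% names(sessions))
      return(data.frame(variable = v, n = 0L, rho2 = NA_real_,
                        p = NA_real_))
    r <- tryCatch(spearman_r2(sessions[[predictor]], sessions[[v]]),
                  error = function(e) NULL)
    if (is.null(r))
      data.frame(variable = v, n = sum(is.finite(sessions[[v]]) &
                                         is.finite(sessions[[predictor]])),
                 rho2 = NA_real_, p = NA_real_)
    else data.frame(variable = v, n = r$n, rho2 = r$rho2, p = r$p)
  })
  out <- do.call(rbind, rows)
  out$significant <- !is.na(out$p) & out$p < 0.05
  out$p_bh <- stats::p.adjust(out$p, method = "BH")
  out
}
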