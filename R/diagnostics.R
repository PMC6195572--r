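#' Waiting-time (inter-event) distribution
#'
#' For each token, the waiting times are the differences between consecutive
#' occurrence indices on the event clock; a token occurring `m` times
#' contributes `m - 1` intervals, so the pooled interval count is `E - D'`
#' with `D'` the number of distinct tokens observed.  The pooled intervals
#' are binned either logarithmically (default, `bins_per_decade` bins per
#' decade) or linearly.
#'
#' @param seq a [token_sequence()].
#' @param binning `"log"` or `"linear"`.
#' @param bins_per_decade bins per decade for logarithmic binning.
#' @param binwidth width for linear binning.
#' @param segmentation optional [segmentation()] whose mean segment length is
#'   stored as a reference marker (the time scale separating within-segment
#'   from cross-segment recurrences).
#' @return an object of class `waiting_times` with `intervals` (pooled),
#'   `per_token` (list of interval vectors, named by token), `histogram`
#'   (`data.frame` with `bin_lo`, `bin_hi`, `count`, `density`) and
#'   `mean_segment_length` (or `NA`).
#' @export
waiting_times <- function(seq, binning = c("log", "linear"),
                          bins_per_decade = 10L, binwidth = 1,
                          segmentation = NULL) {
  stopifnot(inherits(seq, "token_sequence"))
  binning <- match.arg(binning)
  occ <- split(seq_len(seq$E), seq$tokens)
  per_token <- lapply(occ, diff)
  pooled <- unlist(per_token, use.names = FALSE)
  hist <- if (length(pooled)) {
    breaks <- if (binning == "log") {
      top <- ceiling(log10(max(pooled) + 1) * bins_per_decade) + 1L
      10^(seq(0L, top) / bins_per_decade)
    } else {
      seq(1, max(pooled) + binwidth, by = binwidth)
    }
    bin <- findInterval(pooled, breaks, rightmost.closed = FALSE)
    count <- tabulate(bin, nbins = length(breaks) - 1L)
    width <- diff(breaks)
    data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1L],
               count = count, density = count / (sum(count) * width))
  } else {
    data.frame(bin_lo = numeric(0), bin_hi = numeric(0),
               count = integer(0), density = numeric(0))
  }
  msl <- if (!is.null(segmentation))
    segmentation$E / (segmentation$M + 1) else NA_real_
  structure(list(intervals = pooled, per_token = per_token,
                 histogram = hist, mean_segment_length = msl),
            class = "waiting_times")
}

#' @export
print.waiting_times <- function(x, ...) {
  cat("Waiting-time distribution: ", length(x$intervals), " interval(s)",
      if (length(x$intervals))
        paste0(", range ", min(x$intervals), "..", max(x$intervals)),
      "\n", sep = "")
  if (!is.na(x$mean_segment_length))
    cat("  mean segment length: ", format(x$mean_segment_length), "\n",
        sep = "")
  invisible(x)
}

#' @export
plot.waiting_times <- function(x, log = "xy", ...) {
  h <- x$histogram[x$histogram$count > 0L, ]
  graphics::plot(sqrt(h$bin_lo * h$bin_hi), h$density, log = log,
                 xlab = expression(Delta * t), ylab = "density",
                 main = "Waiting-time distribution", ...)
  if (!is.na(x$mean_segment_length))
    graphics::abline(v = x$mean_segment_length, lty = 2, col = "red3")
  invisible(x)
}

#' Discrepancy between two infected curves
#'
#' Maximum and mean absolute difference between two mean-`X(t)` curves — a
#' scalar summary of the visual data-vs-surrogate comparisons.
#'
#' @param a,b numeric vectors of equal length, or `data.frame`s with a
#'   `mean_X` column (as returned by [ensemble_infected_curve()]).
#' @return named numeric vector `c(max_abs, mean_abs)`.
#' @export
curve_discrepancy <- function(a, b) {
  va <- if (is.data.frame(a)) a$mean_X else as.numeric(a)
  vb <- if (is.data.frame(b)) b$mean_X else as.numeric(b)
  if (length(va) != length(vb)) stop("curves have different lengths")
  d <- abs(va - vb)
  c(max_abs = max(d), mean_abs = mean(d))
}
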