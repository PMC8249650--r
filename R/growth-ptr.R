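## Replication-rate estimation: GC-skew origin prediction, coverage
## binning, outlier filtering, lowess smoothing, and the peak-to-trough
## ratio (PTR). In a mixed-age bacterial population, DNA copy number near
## the replication origin exceeds that near the terminus in proportion to
## the population growth rate; the PTR of smoothed coverage captures it.

#' Cumulative GC-skew profile and origin/terminus prediction
#'
#' Computes the per-window GC skew `(G - C) / (G + C)` around the sequence
#' and accumulates it. On a circular bacterial chromosome the cumulative
#' curve has its global minimum at the replication origin and its global
#' maximum at the terminus (leading strands are G-rich). Windows with no G
#' or C contribute zero skew; an all-N sequence is an error.
#'
#' @param genome A [genome_record()] or a plain nucleotide string.
#' @param window Window size in bp (default 1000); a trailing partial
#'   window is ignored. The sequence must be at least two windows long.
#' @param orientation `"min_ori"` (default: ori at the cumulative minimum)
#'   or `"max_ori"` to swap the convention, e.g. for C-rich leading
#'   strands.
#' @return An object of class `skew_profile`: list with `window`,
#'   `midpoints`, `skew`, `cumulative`, `ori_hat`, `ter_hat`,
#'   `seq_length`. Positions are window midpoints.
#' @export
cumulative_gc_skew <- function(genome, window = 1000L,
                               orientation = c("min_ori", "max_ori")) {
  orientation <- match.arg(orientation)
  seq <- if (inherits(genome, "genome_record")) genome$sequence else genome
  L <- nchar(seq)
  check_number(window, "window", lower = 1)
  if (L < 2 * window)
    stop("genome length must be >= 2 * window", call. = FALSE)

  raw <- charToRaw(seq)
  is_g <- cumsum(raw == as.raw(71L))  # 'G'
  is_c <- cumsum(raw == as.raw(67L))  # 'C'
  nw <- L %/% window
  idx <- seq_len(nw) * as.integer(window)
  g <- diff(c(0L, is_g[idx]))
  c_ <- diff(c(0L, is_c[idx]))
  denom <- g + c_
  if (all(denom == 0))
    stop("undefined skew: sequence contains no G or C", call. = FALSE)
  skew <- ifelse(denom == 0, 0, (g - c_) / denom)
  cumulative <- cumsum(skew)
  i_min <- which.min(cumulative)
  i_max <- which.max(cumulative)
  mids <- as.integer(round((seq_len(nw) - 0.5) * window))
  ori_i <- if (orientation == "min_ori") i_min else i_max
  ter_i <- if (orientation == "min_ori") i_max else i_min
  structure(list(window = as.integer(window), midpoints = mids,
                 skew = skew, cumulative = cumulative,
                 ori_hat = mids[ori_i], ter_hat = mids[ter_i],
                 seq_length = L),
            class = "skew_profile")
}

#' @export
print.skew_profile <- function(x, ...) {
  cat(sprintf(
    "<skew_profile> %d windows of %d bp; ori_hat = %d, ter_hat = %d\n",
    length(x$skew), x$window, x$ori_hat, x$ter_hat))
  invisible(x)
}

#' Bin a depth track into fixed-width windows
#'
#' Computes the arithmetic mean depth in consecutive `bin_size`-bp bins
#' tiling the sequence. Positions absent from the track count as depth 0;
#' a final partial bin is retained with its own length.
#'
#' @param track Depth-track data frame (`seqid`, `pos`, `depth`) covering
#'   one sequence.
#' @param bin_size Bin width in bp (default 10000).
#' @param seq_length Sequence length; defaults to the largest position in
#'   the track.
#' @return An object of class `binned_coverage`: list with `seqid`,
#'   `bin_size`, `bin_start`, `bin_len`, `bin_mean`, `kept` (all `TRUE`
#'   until [filter_outlier_bins()]), `seq_length`.
#' @export
bin_coverage <- function(track, bin_size = 10000L, seq_length = NULL) {
  check_number(bin_size, "bin_size", lower = 1)
  if (length(unique(track$seqid)) > 1L)
    stop("track must cover a single sequence", call. = FALSE)
  L <- as.integer(seq_length %||% max(track$pos))
  if (any(track$pos > L))
    stop("track positions exceed the sequence length", call. = FALSE)
  bin_size <- as.integer(bin_size)
  nbins <- as.integer(ceiling(L / bin_size))
  idx <- (track$pos - 1L) %/% bin_size + 1L
  sums <- numeric(nbins)
  rs <- rowsum(track$depth, idx)
  sums[as.integer(rownames(rs))] <- rs[, 1L]
  bin_len <- rep.int(bin_size, nbins)
  bin_len[nbins] <- L - (nbins - 1L) * bin_size
  structure(list(seqid = track$seqid[1L], bin_size = bin_size,
                 bin_start = (seq_len(nbins) - 1L) * bin_size + 1L,
                 bin_len = bin_len, bin_mean = sums / bin_len,
                 kept = rep.int(TRUE, nbins), seq_length = L),
            class = "binned_coverage")
}

#' @export
print.binned_coverage <- function(x, ...) {
  cat(sprintf("<binned_coverage> %s: %d bins of %d bp (%d kept)\n",
              x$seqid, length(x$bin_mean), x$bin_size, sum(x$kept)))
  invisible(x)
}

#' Flag coverage bins more than k standard deviations from the mean
#'
#' Single pass: the mean and the *population* standard deviation are
#' computed over all bins before any removal; bins deviating by more than
#' `k_sd` standard deviations are marked `kept = FALSE`. If the standard
#' deviation is zero nothing is removed.
#'
#' @param bins A [bin_coverage()] result (at least 3 bins).
#' @param k_sd Deviation threshold in standard deviations (default 2).
#' @return `bins` with its `kept` mask updated.
#' @export
filter_outlier_bins <- function(bins, k_sd = 2) {
  check_number(k_sd, "k_sd", lower = 0, strict_lower = TRUE)
  x <- bins$bin_mean
  if (length(x) < 3L)
    stop("need at least 3 bins to filter outliers", call. = FALSE)
  m <- mean(x)
  sd_pop <- sqrt(mean((x - m)^2))
  kept <- if (sd_pop == 0) rep.int(TRUE, length(x)) else
    abs(x - m) <= k_sd * sd_pop
  if (!any(kept))
    stop("all bins filtered as outliers; coverage is degenerate",
         call. = FALSE)
  bins$kept <- kept
  bins
}

#' Lowess-smooth binned coverage
#'
#' Locally weighted linear regression (one robustness iteration) over the
#' kept bins. By default the predictor is the bin index; when `center` is
#' supplied (normally the skew-predicted origin) the predictor is instead
#' the *circular distance of each bin midpoint from that position*, which
#' folds the two replichores onto a single axis along which the
#' replication gradient is monotone — so the local-linear fit has no
#' interior kink at the origin and the peak is not flattened.
#'
#' @param bins A `binned_coverage` with at least 5 kept bins.
#' @param frac Lowess smoother span in (0, 1] (default 0.3).
#' @param center Optional genome position to fold the axis around.
#' @param iter Number of robustness iterations (default 1).
#' @return `bins` with a `smoothed` element: fitted values for kept bins,
#'   `NA` elsewhere.
#' @export
smooth_lowess <- function(bins, frac = 0.3, center = NULL, iter = 1L) {
  if (!is.numeric(frac) || length(frac) != 1L || frac <= 0 || frac > 1)
    stop("`frac` must be in (0, 1]", call. = FALSE)
  kept <- bins$kept
  if (sum(kept) < 5L)
    stop("need at least 5 kept bins to smooth", call. = FALSE)
  y <- bins$bin_mean[kept]
  x <- if (is.null(center)) {
    seq_along(y)
  } else {
    mids <- bins$bin_start[kept] + bins$bin_len[kept] / 2
    circular_distance(mids, center, bins$seq_length)
  }
  fit <- stats::lowess(x, y, f = frac, iter = iter)
  sm <- numeric(length(y))
  sm[order(x)] <- fit$y
  out <- rep.int(NA_real_, length(kept))
  out[kept] <- sm
  bins$smoothed <- out
  bins$smooth_center <- center
  bins
}

#' Peak-to-trough ratio from smoothed coverage
#'
#' The peak is the smoothed coverage of the bin containing the
#' skew-predicted origin (nearest kept bin if that one was filtered); the
#' trough is the minimum of the smoothed series, whose location is
#' data-driven. `trough_vs_skew_ter_distance` reports the circular
#' distance between the coverage trough and the skew-predicted terminus —
#' on good data the two should overlap.
#'
#' @param bins A smoothed `binned_coverage` (see [smooth_lowess()]).
#' @param skew A [cumulative_gc_skew()] profile for the same sequence.
#' @return An object of class `ptr_result`: list with `peak_location`,
#'   `trough_location`, `peak_value`, `trough_value`, `ptr`,
#'   `trough_vs_skew_ter_distance`, `n_bins_kept`.
#' @export
compute_ptr <- function(bins, skew) {
  if (is.null(bins$smoothed))
    stop("bins must be smoothed first (smooth_lowess)", call. = FALSE)
  kept_idx <- which(bins$kept)
  mids <- bins$bin_start + bins$bin_len / 2
  L <- bins$seq_length
  d_ori <- circular_distance(mids[kept_idx], skew$ori_hat, L)
  peak_i <- kept_idx[which.min(d_ori)]
  peak_value <- bins$smoothed[peak_i]
  sm_kept <- bins$smoothed[kept_idx]
  trough_i <- kept_idx[which.min(sm_kept)]
  trough_value <- bins$smoothed[trough_i]
  if (!is.finite(trough_value) || trough_value <= 0)
    stop("smoothed trough coverage is not positive; cannot form a ratio",
         call. = FALSE)
  ptr <- peak_value / trough_value
  if (ptr < 1)
    warning("PTR < 1: the skew-predicted origin may be wrong for this ",
            "genome", call. = FALSE)
  structure(list(
    peak_location = as.integer(round(mids[peak_i])),
    trough_location = as.integer(round(mids[trough_i])),
    peak_value = peak_value, trough_value = trough_value, ptr = ptr,
    trough_vs_skew_ter_distance =
      as.integer(round(circular_distance(mids[trough_i], skew$ter_hat, L))),
    n_bins_kept = length(kept_idx)), class = "ptr_result")
}

#' @export
print.ptr_result <- function(x, ...) {
  cat(sprintf("<ptr_result> PTR = %.3f (peak %.2f @ %d, trough %.2f @ %d)\n",
              x$ptr, x$peak_value, x$peak_location, x$trough_value,
              x$trough_location))
  invisible(x)
}

#' Estimate a replication rate (PTR) from genome coverage
#'
#' End-to-end estimator: (1) predict the replication origin and terminus
#' from the cumulative GC skew of the reference sequence; (2) bin the
#' depth track (default 10-kb bins) and take the mean depth per bin;
#' (3) drop bins more than `k_sd` population standard deviations from the
#' mean; (4) lowess-smooth the kept bins against circular distance from
#' the predicted origin; (5) report the ratio of the smoothed coverage at
#' the predicted origin to the smoothed minimum (the trough). Coverage
#' should be built from uniquely aligned reads (see [extract_unique()]).
#'
#' @param track Depth-track data frame (`seqid`, `pos`, `depth`).
#' @param genome A [genome_record()] or nucleotide string for the same
#'   sequence.
#' @param bin_size Coverage bin width in bp (default 10000).
#' @param k_sd Outlier threshold in standard deviations (default 2).
#' @param lowess_frac Lowess span (default 0.3).
#' @param skew_window GC-skew window in bp (default 1000).
#' @param orientation Skew extremum convention, see
#'   [cumulative_gc_skew()].
#' @return An object of class `ptr_fit` with components `skew`
#'   (`skew_profile`), `bins` (smoothed `binned_coverage`), `result`
#'   (`ptr_result`) and `call`. Methods: `print`, `summary`, `coef`
#'   (the PTR), `fitted`, `plot`.
#' @examples
#' sim_g <- simulate_genome(2e5, ori = 1, ter = 1e5 + 1, seed = 1)
#' sim_c <- simulate_replication_coverage(2e5, 1, 1e5 + 1, ptr = 1.5,
#'                                        mean_depth = 50, seed = 1)
#' fit <- ptr_fit(sim_c$track, sim_g$genome)
#' coef(fit)
#' @export
ptr_fit <- function(track, genome, bin_size = 10000L, k_sd = 2,
                    lowess_frac = 0.3, skew_window = 1000L,
                    orientation = "min_ori") {
  seq_len_bp <- if (inherits(genome, "genome_record")) genome$length
                else nchar(genome)
  skew <- cumulative_gc_skew(genome, window = skew_window,
                             orientation = orientation)
  bins <- bin_coverage(track, bin_size = bin_size, seq_length = seq_len_bp)
  bins <- filter_outlier_bins(bins, k_sd = k_sd)
  bins <- smooth_lowess(bins, frac = lowess_frac, center = skew$ori_hat)
  result <- compute_ptr(bins, skew)
  structure(list(skew = skew, bins = bins, result = result,
                 call = match.call()),
            class = "ptr_fit")
}

#' @export
print.ptr_fit <- function(x, ...) {
  r <- x$result
  cat("Peak-to-trough ratio fit\n")
  cat(sprintf("  genome: %s (%s bp), ori_hat = %d, ter_hat = %d\n",
              x$bins$seqid, format(x$bins$seq_length, big.mark = ","),
              x$skew$ori_hat, x$skew$ter_hat))
  cat(sprintf("  bins: %d x %d bp, %d kept after outlier filter\n",
              length(x$bins$bin_mean), x$bins$bin_size, r$n_bins_kept))
  cat(sprintf("  PTR = %.3f\n", r$ptr))
  invisible(x)
}

#' @method coef ptr_fit
#' @export
coef.ptr_fit <- function(object, ...) c(ptr = object$result$ptr)

#' @export
fitted.ptr_fit <- function(object, ...) object$bins$smoothed

#' @method summary ptr_fit
#' @export
summary.ptr_fit <- function(object, ...) {
  r <- object$result
  out <- list(
    ptr = r$ptr, peak_value = r$peak_value, trough_value = r$trough_value,
    peak_location = r$peak_location, trough_location = r$trough_location,
    ori_hat = object$skew$ori_hat, ter_hat = object$skew$ter_hat,
    trough_vs_skew_ter_distance = r$trough_vs_skew_ter_distance,
    n_bins = length(object$bins$bin_mean), n_bins_kept = r$n_bins_kept,
    bin_size = object$bins$bin_size)
  class(out) <- "summary.ptr_fit"
  out
}

#' @export
print.summary.ptr_fit <- function(x, ...) {
  cat("Peak-to-trough ratio fit\n\n")
  cat(sprintf("  PTR:               %.3f\n", x$ptr))
  cat(sprintf("  peak:              %.2fx at %s bp (skew-predicted ori)\n",
              x$peak_value, format(x$peak_location, big.mark = ",")))
  cat(sprintf("  trough:            %.2fx at %s bp (smoothed minimum)\n",
              x$trough_value, format(x$trough_location, big.mark = ",")))
  cat(sprintf("  skew ter_hat:      %s bp (%s bp from coverage trough)\n",
              format(x$ter_hat, big.mark = ","),
              format(x$trough_vs_skew_ter_distance, big.mark = ",")))
  cat(sprintf("  bins kept:         %d / %d (%d bp bins)\n",
              x$n_bins_kept, x$n_bins, x$bin_size))
  invisible(x)
}

#' Plot a PTR fit (coverage bins and smoothed curve)
#'
#' Black points are kept bin means, grey crosses filtered outliers, and
#' the red line the lowess fit; vertical lines mark the skew-predicted
#' origin and terminus.
#'
#' @param x A `ptr_fit`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @method plot ptr_fit
#' @export
plot.ptr_fit <- function(x, ...) {
  b <- x$bins
  mids <- (b$bin_start + b$bin_len / 2) / 1e3
  graphics::plot(mids[b$kept], b$bin_mean[b$kept], pch = 20,
                 xlab = "genome position (kb)", ylab = "mean depth per bin",
                 main = sprintf("PTR = %.3f", x$result$ptr), ...)
  if (any(!b$kept))
    graphics::points(mids[!b$kept], b$bin_mean[!b$kept], pch = 4,
                     col = "grey60")
  ord <- order(mids[b$kept])
  graphics::lines(mids[b$kept][ord], b$smoothed[b$kept][ord],
                  col = "red", lwd = 2)
  graphics::abline(v = x$skew$ori_hat / 1e3, lty = 2, col = "blue")
  graphics::abline(v = x$skew$ter_hat / 1e3, lty = 3, col = "blue")
  invisible(x)
}

#' One-row report for a PTR fit
#'
#' @param fit A `ptr_fit`.
#' @param sample Sample label for the row.
#' @return Data frame with columns `sample`, `ptr`, `ori_hat`,
#'   `trough_location`, `n_bins_kept`.
#' @export
ptr_report <- function(fit, sample = "sample") {
  data.frame(sample = sample, ptr = fit$result$ptr,
             ori_hat = fit$skew$ori_hat,
             trough_location = fit$result$trough_location,
             n_bins_kept = fit$result$n_bins_kept,
             stringsAsFactors = FALSE)
}
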