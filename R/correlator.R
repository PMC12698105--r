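#' Uniformly binned photon-count series
#'
#' Discretized photon stream: non-negative counts in contiguous bins of a
#' fixed base resolution, the raw material of the multi-tau correlator.
#'
#' @param counts Integer-valued vector of photon counts per bin, >= 0.
#' @param bin_width Base bin width, s, > 0.
#' @param start_time Time of the first bin's left edge, s (default 0).
#' @return An object of class `photon_count_series`.
#' @examples
#' photon_count_series(rpois(1000, 2), bin_width = 1e-6)
#' @export
photon_count_series <- function(counts, bin_width, start_time = 0) {
  counts <- as.numeric(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("`counts` must be non-negative integers")
  if (bin_width <= 0) stop("`bin_width` must be > 0 (s)")
  structure(list(counts = counts, bin_width = bin_width,
                 start_time = start_time),
            class = "photon_count_series")
}

#' @export
print.photon_count_series <- function(x, ...) {
  cat(sprintf(paste0("<photon_count_series> %d bins x %.3g s = %.3g s, ",
                     "%d photons (%.3g counts/s)\n"),
              length(x$counts), x$bin_width,
              length(x$counts) * x$bin_width, sum(x$counts),
              sum(x$counts) / (length(x$counts) * x$bin_width)))
  invisible(x)
}

#' Multi-tau lag scheme
#'
#' Geometric lag-widening scheme of a hardware time-tagger correlator: a
#' fixed number of linearly spaced lags per block, with the bin width
#' multiplied by `widening_factor` at each new block. The defaults mirror a
#' 6.145 ns base resolution for the first 16 delays, tripling every
#' subsequent 16 values.
#'
#' @param base_bin Base bin width, s (default 6.145e-9).
#' @param lags_per_block Lags per block (default 16).
#' @param widening_factor Bin-width multiplier between blocks (default 3).
#' @param n_blocks Number of blocks (default 8).
#' @return An object of class `multi_tau_scheme`.
#' @export
multi_tau_scheme <- function(base_bin = 6.145e-9, lags_per_block = 16L,
                             widening_factor = 3L, n_blocks = 8L) {
  if (base_bin <= 0) stop("`base_bin` must be > 0 (s)")
  if (lags_per_block < 1) stop("`lags_per_block` must be >= 1")
  if (widening_factor < 2) stop("`widening_factor` must be >= 2")
  if (n_blocks < 1) stop("`n_blocks` must be >= 1")
  structure(list(base_bin = base_bin,
                 lags_per_block = as.integer(lags_per_block),
                 widening_factor = as.integer(widening_factor),
                 n_blocks = as.integer(n_blocks)),
            class = "multi_tau_scheme")
}

#' @export
print.multi_tau_scheme <- function(x, ...) {
  cat(sprintf(paste0("<multi_tau_scheme> base %.4g s, %d lags/block, ",
                     "bin width x%d per block, %d blocks\n"),
              x$base_bin, x$lags_per_block, x$widening_factor, x$n_blocks))
  invisible(x)
}

#' Lag times and bin widths of a multi-tau scheme
#'
#' Block `b` uses bin width `base_bin * widening_factor^(b-1)`. Within a
#' block consecutive lags differ by that block's bin width; each block
#' starts at the first multiple of its bin width beyond the previous
#' block's last lag.
#'
#' @param scheme A [multi_tau_scheme()].
#' @return A data.frame with columns `lag_time` (s, strictly increasing),
#'   `bin_width` (s), `block`, and `lag_index` (the integer lag in units of
#'   the block's bin width).
#' @examples
#' head(multi_tau_lags(multi_tau_scheme()), 20)
#' @export
multi_tau_lags <- function(scheme) {
  stopifnot(inherits(scheme, "multi_tau_scheme"))
  out <- vector("list", scheme$n_blocks)
  last_time <- 0
  for (b in seq_len(scheme$n_blocks)) {
    width <- scheme$base_bin * scheme$widening_factor^(b - 1)
    first_k <- floor(last_time / width + 1e-9) + 1L
    k <- first_k:(first_k + scheme$lags_per_block - 1L)
    out[[b]] <- data.frame(lag_time = k * width, bin_width = width,
                           block = b, lag_index = k)
    last_time <- max(out[[b]]$lag_time)
  }
  do.call(rbind, out)
}

# sum groups of `factor` consecutive bins, dropping a partial tail group
.rebin_counts <- function(counts, factor) {
  n <- (length(counts) %/% factor) * factor
  if (n == 0L) return(numeric(0))
  colSums(matrix(counts[seq_len(n)], nrow = factor))
}

# symmetric multi-tau estimator at integer lag k on one re-binned series:
# <I_t I_{t+k}> over the overlap, normalized by the overlap means of the
# leading and trailing segments
.g2_at_lag <- function(counts, k, symmetric = TRUE) {
  n <- length(counts)
  if (k >= n) return(NA_real_)
  head_i <- counts[seq_len(n - k)]
  tail_i <- counts[(k + 1L):n]
  num <- mean(head_i * tail_i)
  den <- if (symmetric) mean(head_i) * mean(tail_i) else mean(counts)^2
  num / den
}

#' Multi-tau autocorrelation of a photon-count series
#'
#' Estimates `g2(tau) = <I(t) I(t+tau)> / (<I(t)> <I(t+tau)>)` on the lag
#' grid of a multi-tau scheme. Counts entering each new block are re-binned
#' by summing `widening_factor` adjacent bins (photon totals conserved);
#' product averages use full-overlap terms only (no wrap-around). The
#' default symmetric normalization computes the denominator means over the
#' same overlapping support as the numerator, which removes most
#' finite-length bias; `symmetric = FALSE` uses the plain squared global
#' mean instead.
#'
#' @param series A [photon_count_series()]; its `bin_width` must equal the
#'   scheme's `base_bin`.
#' @param scheme A [multi_tau_scheme()].
#' @param symmetric Use the symmetric (overlap-mean) normalization
#'   (default TRUE).
#' @param min_terms Minimum number of product terms required at every
#'   requested lag (default 100).
#' @return A [correlation_curve()] on the scheme's lag grid, carrying the
#'   per-lag effective `bin_width` and `block` as extra columns.
#' @examples
#' s <- photon_count_series(rpois(20000, 3), 1e-6)
#' autocorrelate(s, multi_tau_scheme(base_bin = 1e-6, n_blocks = 3))
#' @export
autocorrelate <- function(series, scheme, symmetric = TRUE, min_terms = 100L) {
  stopifnot(inherits(series, "photon_count_series"),
            inherits(scheme, "multi_tau_scheme"))
  if (abs(series$bin_width - scheme$base_bin) >
      1e-9 * max(series$bin_width, scheme$base_bin))
    stop("series bin_width must equal the scheme's base_bin")
  if (sum(series$counts) == 0)
    stop("all-zero count series: g2 normalization undefined")
  lags <- multi_tau_lags(scheme)
  longest <- max(lags$lag_index[lags$block == scheme$n_blocks]) *
    scheme$widening_factor^(scheme$n_blocks - 1)
  n_base <- length(series$counts)
  if (n_base - longest < min_terms) {
    bad <- lags$lag_time[which(n_base / scheme$widening_factor^(lags$block - 1) -
                                 lags$lag_index < min_terms)[1]]
    stop(sprintf(paste0("series too short: lag %.4g s has fewer than %d ",
                        "product terms (%d base bins supplied)"),
                 bad, min_terms, n_base))
  }
  g2 <- numeric(nrow(lags))
  counts_b <- series$counts
  for (b in seq_len(scheme$n_blocks)) {
    if (b > 1L) counts_b <- .rebin_counts(counts_b, scheme$widening_factor)
    rows <- which(lags$block == b)
    g2[rows] <- vapply(lags$lag_index[rows], function(k)
      .g2_at_lag(counts_b, k, symmetric = symmetric), numeric(1))
  }
  curve <- correlation_curve(lags$lag_time, g2)
  curve$bin_width <- lags$bin_width
  curve$block <- lags$block
  curve
}

#' Histogram photon timestamps into a count series
#'
#' Time-tagger front end: bins sorted arrival times into
#' `floor(duration / bin_width)` contiguous bins starting at t = 0.
#'
#' @param timestamps Sorted arrival times, s, within `[0, duration)`.
#' @param bin_width Bin width, s.
#' @param duration Total acquisition time, s.
#' @return A [photon_count_series()]. Timestamps at or beyond
#'   `floor(duration/bin_width) * bin_width` are dropped.
#' @examples
#' timestamps_to_counts(c(0, 2.5e-6), bin_width = 1e-6, duration = 5e-6)
#' @export
timestamps_to_counts <- function(timestamps, bin_width, duration) {
  if (bin_width <= 0 || duration <= 0)
    stop("`bin_width` and `duration` must be > 0")
  if (is.unsorted(timestamps)) stop("`timestamps` must be sorted")
  if (length(timestamps) && (min(timestamps) < 0))
    stop("timestamps must be >= 0")
  n_bins <- floor(duration / bin_width)
  idx <- floor(timestamps / bin_width) + 1
  idx <- idx[idx >= 1 & idx <= n_bins]
  counts <- tabulate(idx, nbins = n_bins)
  photon_count_series(counts, bin_width)
}

#' Read photon timestamps from disk
#'
#' Delimited text (`.txt`/`.csv`: one arrival time in seconds per line) or
#' raw little-endian unsigned 64-bit tick counts at a stated base
#' resolution (`.bin`).
#'
#' @param path Input file; format chosen by extension.
#' @param tick Tick duration in s for raw `.bin` input (default 6.145e-9).
#' @return Sorted numeric vector of arrival times, s.
#' @export
read_timestamps <- function(path, tick = 6.145e-9) {
  ext <- tolower(tools::file_ext(path))
  ts <- if (ext == "bin") {
    n <- file.size(path) %/% 8
    words <- readBin(path, "integer", n = 2 * n, size = 4, endian = "little")
    words <- words + (words < 0) * 2^32  # reinterpret as unsigned
    lo <- words[seq(1, length(words), 2)]
    hi <- words[seq(2, length(words), 2)]
    (lo + hi * 2^32) * tick
  } else {
    utils::read.table(path, header = FALSE)[[1]]
  }
  sort(as.numeric(ts))
}
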