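# First-order (histogram) statistics of the VOI intensity distribution.
#
# Twelve statistics per modality: four moment statistics computed on the
# raw in-mask intensities (population normalization, plain -- not excess --
# kurtosis, so a Gaussian gives ~3), plus eight histogram-shape statistics.

fo_stat_names <- c("mean", "sd", "skewness", "kurtosis", "range", "width",
                   "energy", "entropy", "max_height", "max_level",
                   "n_rel_maxima", "energy_rel_maxima")

#' Intensity histogram of a VOI
#'
#' Equal-width bins spanning the in-mask `[min, max]` intensity range.
#' A constant VOI puts all counts in the first bin.
#'
#' @param voi An [`rad_voi`][extract_voi].
#' @param n_bins Number of bins (>= 2); default 64.
#' @return An object of class `rad_hist`: `breaks` (length `n_bins + 1`),
#'   `mids`, `counts`, probabilities `p` and the common `bin_width`.
#' @export
intensity_histogram <- function(voi, n_bins = 64L) {
  stopifnot(inherits(voi, "rad_voi"))
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) abort("`n_bins` must be >= 2")
  v <- voi$values
  lo <- min(v); hi <- max(v)
  if (hi > lo) {
    bin <- pmin(floor(n_bins * (v - lo) / (hi - lo)), n_bins - 1L) + 1L
    width <- (hi - lo) / n_bins
  } else {
    bin <- rep(1L, length(v))
    width <- 1
  }
  counts <- tabulate(bin, nbins = n_bins)
  breaks <- lo + width * 0:n_bins
  new_rad_hist(breaks = breaks, mids = (breaks[-1] + breaks[-(n_bins + 1)]) / 2,
               counts = counts, bin_width = width)
}

new_rad_hist <- function(breaks, mids, counts, bin_width) {
  structure(
    list(breaks = breaks, mids = mids, counts = counts,
         p = counts / sum(counts), bin_width = bin_width),
    class = "rad_hist"
  )
}

# Histogram over an explicit ordered value domain (one bin per possible
# value); used for LBP code histograms, where bin width is 1 code unit.
hist_from_codes <- function(codes, domain) {
  counts <- tabulate(match(codes, domain), nbins = length(domain))
  new_rad_hist(breaks = c(domain - 0.5, domain[length(domain)] + 0.5),
               mids = as.numeric(domain), counts = counts, bin_width = 1)
}

#' @export
print.rad_hist <- function(x, ...) {
  cat(sprintf("<rad_hist> %d bins on [%g, %g], %d observations\n",
              length(x$counts), min(x$breaks), max(x$breaks), sum(x$counts)))
  invisible(x)
}

# Relative maxima of the histogram after length-3 moving-average smoothing
# (window truncated at the boundaries). Runs of equal smoothed values count
# once; a run is a maximum when strictly greater than both adjacent runs
# (boundary runs compare against their single neighbour; a single run --
# e.g. a constant histogram -- counts as one maximum). Returns the number
# of maxima and the bin indices belonging to maximum runs.
relative_maxima <- function(p) {
  nb <- length(p)
  if (nb == 1L) return(list(n = 1L, bins = 1L))
  left <- c(NA, p[-nb]); right <- c(p[-1], NA)
  s <- rowMeans(cbind(left, p, right), na.rm = TRUE)
  r <- rle(s)
  k <- length(r$values)
  gt_prev <- c(TRUE, r$values[-1] > r$values[-k])
  gt_next <- c(r$values[-k] > r$values[-1], TRUE)
  is_max <- gt_prev & gt_next
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  list(n = sum(is_max),
       bins = unlist(map2(starts[is_max], ends[is_max], seq), use.names = FALSE))
}

# Full width at half maximum: length of the contiguous run of bins, around
# the absolute-maximum bin, whose height is >= half the maximum height;
# reported in intensity units (run length times bin width).
fwhm_width <- function(p, bin_width) {
  h <- max(p)
  im <- which.max(p)
  l <- im; r <- im
  while (l > 1L && p[l - 1L] >= h / 2) l <- l - 1L
  while (r < length(p) && p[r + 1L] >= h / 2) r <- r + 1L
  (r - l + 1L) * bin_width
}

# The 12 first-order statistics from a histogram plus the raw observation
# vector the histogram was built from (moments use the raw values).
histogram_stats <- function(hist, values) {
  p <- hist$p
  mu <- mean(values)
  s2 <- mean((values - mu)^2)
  s <- sqrt(s2)
  skew <- if (s > 0) mean((values - mu)^3) / s^3 else 0
  kurt <- if (s > 0) mean((values - mu)^4) / s2^2 else 0
  occ <- p > 0
  entropy <- -sum(p[occ] * log2(p[occ]))
  maxima <- relative_maxima(p)
  around <- unique(unlist(lapply(maxima$bins, function(i)
    max(1L, i - 2L):min(length(p), i + 2L))))
  c(
    mean = mu, sd = s, skewness = skew, kurtosis = kurt,
    range = max(values) - min(values),
    width = fwhm_width(p, hist$bin_width),
    energy = sum(p^2), entropy = entropy,
    max_height = max(p), max_level = hist$mids[which.max(p)],
    n_rel_maxima = as.numeric(maxima$n),
    energy_rel_maxima = sum(p[around]^2)
  )
}

#' First-order feature block
#'
#' The 12 first-order statistics: `mean`, `sd`, `skewness`, `kurtosis`
#' (population moments of the raw in-mask intensities; plain kurtosis, so a
#' Gaussian gives about 3), `range` (max - min), `width` (full width at
#' half the histogram's absolute maximum, in intensity units), `energy`
#' (sum of squared bin probabilities), `entropy` (bits), `max_height`
#' (tallest bin probability), `max_level` (its bin centre),
#' `n_rel_maxima` (relative maxima after length-3 moving-average
#' smoothing) and `energy_rel_maxima` (sum of squared probabilities within
#' two bins of any relative maximum).
#'
#' A single-voxel (or otherwise zero-spread) VOI has `sd = 0` and, by
#' convention, `skewness = kurtosis = 0`.
#'
#' @param hist An [`rad_hist`][intensity_histogram].
#' @param values The raw observations the histogram summarizes (for a VOI,
#'   its in-mask intensities).
#' @return Named numeric vector of length 12.
#' @export
first_order_features <- function(hist, values) {
  stopifnot(inherits(hist, "rad_hist"), length(values) > 0)
  histogram_stats(hist, values)
}

#' First-order features of a VOI
#'
#' Convenience wrapper: builds the intensity histogram and applies
#' [first_order_features()].
#'
#' @inheritParams intensity_histogram
#' @return Named numeric vector of length 12.
#' @export
voi_first_order <- function(voi, n_bins = 64L) {
  first_order_features(intensity_histogram(voi, n_bins), voi$values)
}
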