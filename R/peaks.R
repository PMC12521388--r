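#' Detect Bragg peaks in a baseline-subtracted curve
#'
#' Finds local maxima whose topographic prominence exceeds both a
#' relative threshold and a robust noise floor, then refines each peak
#' position below the grid spacing with a local quadratic (three-point)
#' fit. Prominence of a maximum is its height above the higher of the two
#' minima separating it from taller neighbours.
#'
#' @param curve Data frame with columns `q` and `intensity`
#'   (baseline-subtracted; see [subtract_baseline()]).
#' @param min_prominence Minimum prominence relative to the tallest point
#'   of the curve.
#' @param noise_mult Multiple of the robust noise estimate (MAD of the
#'   second difference) a prominence must also exceed.
#' @return A `peak_list` tibble, sorted in q, with columns `q`, `height`,
#'   `fwhm` (half-height width by linear interpolation) and `prominence`.
#'   Empty for a featureless curve.
#' @export
detect_peaks <- function(curve, min_prominence = 0.05, noise_mult = 5) {
  check_curve(curve)
  q <- curve$q
  y <- curve$intensity
  n <- length(y)
  empty <- tibble::tibble(q = double(), height = double(),
                          fwhm = double(), prominence = double())
  class(empty) <- c("peak_list", class(empty))
  if (n < 3 || max(y) <= 0) return(empty)
  cand <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  if (length(cand) == 0) return(empty)
  noise <- mad(diff(y, differences = 2)) / sqrt(6)
  prom <- vapply(cand, function(i) {
    h <- y[i]
    left <- y[seq_len(i - 1)]
    right <- y[seq(i + 1, n)]
    hl <- which(left >= h)
    lo_l <- if (length(hl)) min(left[seq(max(hl), i - 1)]) else min(left)
    hr <- which(right >= h)
    lo_r <- if (length(hr)) min(right[seq_len(min(hr))]) else min(right)
    h - max(lo_l, lo_r)
  }, numeric(1))
  thresh <- max(min_prominence * max(y), noise_mult * noise)
  keep <- prom >= thresh
  cand <- cand[keep]
  prom <- prom[keep]
  if (length(cand) == 0) return(empty)
  refine <- function(i) {
    if (i <= 1 || i >= n) return(c(q[i], y[i]))
    y0 <- y[i - 1]; y1 <- y[i]; y2 <- y[i + 1]
    denom <- y0 - 2 * y1 + y2
    if (denom >= 0) return(c(q[i], y1))
    d <- 0.5 * (y0 - y2) / denom
    d <- max(min(d, 0.5), -0.5)
    qc <- q[i] + d * (q[i + 1] - q[i - 1]) / 2
    c(qc, y1 - 0.25 * (y0 - y2) * d)
  }
  ref <- vapply(cand, refine, numeric(2))
  fwhm <- vapply(seq_along(cand), function(k) {
    i <- cand[k]
    half <- ref[2, k] / 2
    il <- i
    while (il > 1 && y[il] > half) il <- il - 1
    ir <- i
    while (ir < n && y[ir] > half) ir <- ir + 1
    ql <- if (y[il] <= half && il < i && y[il + 1] > y[il]) {
      q[il] + (half - y[il]) / (y[il + 1] - y[il]) * (q[il + 1] - q[il])
    } else q[il]
    qr <- if (y[ir] <= half && ir > i && y[ir - 1] > y[ir]) {
      q[ir] - (half - y[ir]) / (y[ir - 1] - y[ir]) * (q[ir] - q[ir - 1])
    } else q[ir]
    qr - ql
  }, numeric(1))
  out <- tibble::tibble(q = ref[1, ], height = ref[2, ], fwhm = fwhm,
                        prominence = prom)
  out <- dplyr::arrange(out, .data$q)
  class(out) <- c("peak_list", class(out))
  out
}
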