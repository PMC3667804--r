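#' Percentage signal change of a timecourse
#'
#' `100 * (x - mean(x)) / mean(x)`; the conventional display scale for
#' BOLD fluctuations. The output always has mean zero.
#'
#' @param x numeric timecourse with non-zero temporal mean.
#' @param reference_mean optional mean to normalize against (e.g. the mean
#'   of the raw series when `x` has already been detrended to mean zero);
#'   defaults to `mean(x)`.
#' @return Numeric timecourse in percent units.
#' @export
percent_signal_change <- function(x, reference_mean = NULL) {
  m <- if (is.null(reference_mean)) mean(x) else reference_mean
  if (!is.finite(m) || abs(m) < .Machine$double.eps * 100)
    stop("percent_signal_change: temporal mean is zero (degenerate input)")
  100 * (x - mean(x)) / m
}

#' One-sided discrete Fourier amplitude spectrum
#'
#' Amplitudes are normalized so that the sum of squared amplitudes equals
#' the time-domain energy `sum(x^2)` (Parseval): the two-sided coefficient
#' magnitudes are folded onto `0 .. Nyquist` with weight 2 on interior
#' bins. Frequency spacing is `1 / (n * tr_s)` and the spectrum has
#' `floor(n/2) + 1` points.
#'
#' @param x numeric timecourse (>= 4 points).
#' @param tr_s sampling interval, seconds.
#' @param source optional label recorded as an attribute.
#' @return data.frame `frequency` (Hz), `amplitude` (non-negative), of
#'   class `spectrum_result`.
#' @export
amplitude_spectrum <- function(x, tr_s, source = NULL) {
  n <- length(x)
  if (n < 4L) stop("amplitude_spectrum: need at least 4 points, got ", n)
  X <- fft(x)
  half <- floor(n / 2) + 1L
  w <- rep(2, half)
  w[1] <- 1
  if (n %% 2 == 0) w[half] <- 1
  amp <- sqrt(w / n) * Mod(X[seq_len(half)])
  out <- data.frame(frequency = (seq_len(half) - 1) / (n * tr_s),
                    amplitude = amp)
  attr(out, "source") <- source
  class(out) <- c("spectrum_result", class(out))
  out
}

#' Interhemispheric (homotopic) timecourse correlation
#'
#' Pearson correlation at lag 0 between the mean timecourses of a region
#' and its mirror in the opposite hemisphere; the study's index of
#' bilateral LFF synchronization.
#'
#' @param left_tc,right_tc equal-length numeric timecourses with non-zero
#'   variance.
#' @return Pearson correlation.
#' @export
homotopic_correlation <- function(left_tc, right_tc) {
  if (length(left_tc) != length(right_tc))
    stop("homotopic_correlation: timecourses have different lengths")
  if (var(left_tc) == 0 || var(right_tc) == 0)
    stop("homotopic_correlation: a timecourse has zero variance")
  cor(left_tc, right_tc)
}
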