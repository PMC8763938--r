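# Minimal IIR filtering toolbox: Butterworth low-pass design via bilinear
# transform and zero-phase (forward-backward) application. Kept in-package
# because no DSP package is available in the supported environment.

#' Design a digital low-pass Butterworth filter
#'
#' Returns transfer-function coefficients for an order-`n` low-pass
#' Butterworth filter obtained from the analog prototype by frequency
#' pre-warping and the bilinear transform.
#'
#' @param order Filter order (positive integer).
#' @param cutoff Cutoff frequency in Hz (-3 dB point).
#' @param fs Sampling rate in Hz. Must exceed `2 * cutoff`.
#' @return A list with numerator `b` and denominator `a` coefficient
#'   vectors (length `order + 1`, `a[1] == 1`).
#' @export
#' @examples
#' bf <- butter_lowpass(4, 20, 1000)
butter_lowpass <- function(order, cutoff, fs) {
  stopifnot(order >= 1, order == round(order), cutoff > 0, fs > 2 * cutoff)
  # pre-warped analog cutoff, then left-half-plane Butterworth poles
  wc <- 2 * fs * tan(pi * cutoff / fs)
  k <- seq_len(order)
  theta <- pi * (2 * k + order - 1) / (2 * order)
  p_analog <- wc * complex(real = cos(theta), imaginary = sin(theta))
  # bilinear transform: s -> 2*fs*(z-1)/(z+1)
  p_z <- (2 * fs + p_analog) / (2 * fs - p_analog)
  a <- Re(poly_from_roots(p_z))
  b <- Re(poly_from_roots(rep(-1 + 0i, order)))
  b <- b * sum(a) / sum(b)   # unit DC gain
  list(b = b, a = a)
}

# expand prod(x - r_i) into descending-power coefficients
poly_from_roots <- function(r) {
  coefs <- 1 + 0i
  for (ri in r) coefs <- c(coefs, 0) - c(0, coefs * ri)
  coefs
}

# causal direct-form IIR filter, zero initial conditions.
# Uses stats::filter for C-speed convolution + recursion.
iir_filter <- function(b, a, x) {
  b <- b / a[1]
  a <- a / a[1]
  nb <- length(b)
  v <- stats::filter(c(rep(0, nb - 1), x), b, method = "convolution",
                     sides = 1)
  v <- as.numeric(v)[nb:(nb - 1 + length(x))]
  if (length(a) > 1) {
    v <- as.numeric(stats::filter(v, -a[-1], method = "recursive"))
  }
  v
}

#' Zero-phase low-pass filtering
#'
#' Applies a Butterworth low-pass forward and backward so the net result
#' has zero phase distortion and squared magnitude response. Edges are
#' handled by odd reflection padding (3 filter lengths), matching common
#' scientific-computing practice.
#'
#' @param x Numeric vector.
#' @param cutoff Cutoff frequency, Hz.
#' @param fs Sampling rate, Hz.
#' @param order Butterworth order of each pass (default 4).
#' @return Filtered vector, same length as `x`.
#' @export
lowpass_filtfilt <- function(x, cutoff, fs, order = 4) {
  bf <- butter_lowpass(order, cutoff, fs)
  # pad by ~3 settling times so zero initial conditions cannot leak inwards
  filtfilt_ba(bf$b, bf$a, x, pad = ceiling(3 * fs / cutoff))
}

filtfilt_ba <- function(b, a, x, pad = NULL) {
  n <- length(x)
  if (is.null(pad)) pad <- 3 * (max(length(a), length(b)) - 1)
  pad <- min(pad, n - 1)
  if (pad < 1) stop("input too short for zero-phase filtering")
  ext <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- iir_filter(b, a, ext)
  y <- rev(iir_filter(b, a, rev(y)))
  y[(pad + 1):(pad + n)]
}
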