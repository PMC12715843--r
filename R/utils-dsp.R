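# Low-level DSP helpers shared across modules.

#' Analytic signal via the frequency domain
#'
#' Complex extension of a real series whose modulus is the instantaneous
#' amplitude and argument the instantaneous phase: negative frequencies
#' are zeroed, positive frequencies doubled (DC and Nyquist kept).
#'
#' @param x real numeric vector.
#' @return Complex vector of the same length.
#' @examples
#' a <- Mod(analyticSignal(3 * cos(2 * pi * 10 * seq(0, 1, by = 1e-3))))
#' @export
analyticSignal <- function(x) {
  n <- length(x)
  if (n == 0L) return(complex(0))
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1L] <- 1; h[n / 2 + 1L] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

# Windowed-sinc FIR coefficients (Hamming window), as used for every
# filtering step in the package. type: "pass" or "stop".
.firDesign <- function(edgesHz, fs, order = 1000, type = "pass") {
  w <- edgesHz / (fs / 2)
  if (any(w >= 1))
    stop("filter edge at or above the Nyquist frequency (", fs / 2, " Hz)")
  signal::fir1(order, w, type = type, window = signal::hamming(order + 1))
}

# Zero-phase FIR filtering: odd-reflection padding by one filter length,
# causal FFT convolution forward then backward, trim. Net phase response
# is zero and the magnitude response is squared.
.zeroPhaseFilter <- function(b, x) {
  nb <- length(b)
  n <- length(x)
  if (n <= 3 * nb)
    stop("series too short for stable bidirectional filtering: length ", n,
         " <= 3 x filter length ", nb)
  pre <- 2 * x[1L] - x[(nb + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - nb)]
  xp <- c(pre, x, post)
  y <- signal::fftfilt(b, xp)
  y <- rev(signal::fftfilt(b, rev(y)))
  # each causal pass delays by (nb-1)/2; forward+backward delays cancel
  y[(nb + 1L):(nb + n)]
}

# Apply a function over the time axis of a (electrode, trial, time) array.
.overTime <- function(arr, f) {
  d <- dim(arr)
  out <- arr
  for (e in seq_len(d[1L])) for (tr in seq_len(d[2L]))
    out[e, tr, ] <- f(arr[e, tr, ])
  out
}

# Wrap angles into (-pi, pi].
.wrapPhase <- function(phi) {
  w <- (phi + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

# Sample indices (at fs) of a window given in ms relative to stimulus
# onset, for a trial aligned at `alignment` ms.
.windowIndex <- function(windowMs, alignment, fs, n) {
  i0 <- round((alignment + windowMs[1L]) * fs / 1000) + 1L
  i1 <- round((alignment + windowMs[2L]) * fs / 1000)
  if (i0 < 1L || i1 > n)
    stop("analysis window [", windowMs[1L], ", ", windowMs[2L],
         "] ms lies outside the trial")
  seq.int(i0, i1)
}
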