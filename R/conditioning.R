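#' Filter settings for kinematic and EMG conditioning
#'
#' Bundles every tunable of the preprocessing chain: Savitzky-Golay smoothing
#' for kinematic streams, and the mains notch / demean / rectify / zero-lag
#' low-pass chain that turns raw surface EMG into a linear envelope.
#'
#' The Savitzky-Golay window is conventionally quoted in samples; an even
#' window length is rounded up to the next odd number of samples (a 40-point
#' request runs as a symmetric 41-point fit), since a symmetric least-squares
#' fit needs a centre sample. Zero lag for the low-pass is realised by running
#' a half-order Butterworth design forward and backward, so the default
#' `lp_order = 4` filters with a 2nd-order design applied twice — the
#' effective magnitude response is 4th order and the phase response is zero.
#'
#' @param sg_window Savitzky-Golay window length in samples (default 40).
#' @param sg_polyorder Savitzky-Golay polynomial order (default 3).
#' @param notch_hz Mains notch centre frequency in Hz (default 60).
#' @param notch_q Notch quality factor, centre/bandwidth (default 30).
#' @param lp_cutoff_hz Envelope low-pass cutoff in Hz (default 100).
#' @param lp_order Effective Butterworth order of the zero-lag low-pass
#'   (default 4; must be even).
#' @param baseline_s Length in seconds of the quiet-stance segment at the
#'   start of the trial used for DC-offset removal (default 0.5).
#' @return A `filter_spec` list.
#' @export
#' @examples
#' fs <- filter_spec()
#' fs$lp_cutoff_hz
filter_spec <- function(sg_window = 40L, sg_polyorder = 3L,
                        notch_hz = 60, notch_q = 30,
                        lp_cutoff_hz = 100, lp_order = 4L,
                        baseline_s = 0.5) {
  check_scalar_number(sg_window, "sg_window", positive = TRUE, integerish = TRUE)
  check_scalar_number(sg_polyorder, "sg_polyorder", positive = TRUE, integerish = TRUE)
  if (sg_window <= sg_polyorder)
    abort_config("`sg_window` must exceed `sg_polyorder`")
  check_scalar_number(notch_hz, "notch_hz", positive = TRUE)
  check_scalar_number(notch_q, "notch_q", positive = TRUE)
  check_scalar_number(lp_cutoff_hz, "lp_cutoff_hz", positive = TRUE)
  check_scalar_number(lp_order, "lp_order", positive = TRUE, integerish = TRUE)
  if (lp_order %% 2 != 0)
    abort_config("`lp_order` must be even (zero-lag forward-backward design)")
  check_scalar_number(baseline_s, "baseline_s", positive = TRUE)
  structure(
    list(sg_window = as.integer(sg_window),
         sg_polyorder = as.integer(sg_polyorder),
         notch_hz = notch_hz, notch_q = notch_q,
         lp_cutoff_hz = lp_cutoff_hz, lp_order = as.integer(lp_order),
         baseline_s = baseline_s),
    class = "filter_spec"
  )
}

# Odd window actually used for the SG fit.
sg_window_odd <- function(spec) {
  w <- spec$sg_window
  if (w %% 2L == 0L) w + 1L else w
}

#' Smooth a kinematic stream and remove its DC offset
#'
#' Applies Savitzky-Golay smoothing (reflect-padded, so trial edges are not
#' distorted) and then subtracts the mean of the initial quiet-stance segment.
#' Because the smoother is a local polynomial fit it reproduces any polynomial
#' of degree `sg_polyorder` or lower exactly, and it is linear, so metric
#' differences between conditions survive smoothing unchanged.
#'
#' @param x Numeric vector, one kinematic channel sampled at `rate` Hz.
#' @param spec A [filter_spec()].
#' @param rate Sampling rate in Hz (default 100).
#' @param remove_dc Subtract the quiet-stance baseline mean (default TRUE).
#' @return Numeric vector, same length as `x`.
#' @export
condition_kinematics <- function(x, spec = filter_spec(), rate = 100,
                                 remove_dc = TRUE) {
  if (!is.numeric(x)) abort_data("kinematic stream must be numeric")
  w <- sg_window_odd(spec)
  if (length(x) <= w)
    abort_data(sprintf("stream length (%d) must exceed the SG window (%d)",
                       length(x), w))
  half <- (w - 1L) %/% 2L
  padded <- reflect_pad(x, half)
  sg <- signal::sgolay(p = spec$sg_polyorder, n = w)
  y <- signal::filter(sg, padded$x)
  y <- y[(padded$n + 1L):(padded$n + length(x))]
  if (remove_dc) {
    nb <- max(1L, min(length(y), round(spec$baseline_s * rate)))
    y <- y - mean(y[seq_len(nb)])
  }
  as.numeric(y)
}

# RBJ-cookbook biquad notch; the installed signal package ships no notch
# design, so the two polynomial coefficients are written out directly.
notch_coefficients <- function(f0, q, rate) {
  w0 <- 2 * pi * f0 / rate
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

# Zero-phase filtering with explicit reflect padding (1 s or as much as the
# signal allows) so onset-bearing trial starts are not contaminated by filter
# start-up transients.
zero_phase <- function(x, b, a, rate) {
  pad <- reflect_pad(x, round(rate))
  y <- signal::filtfilt(signal::Arma(b = b, a = a), pad$x)
  y[(pad$n + 1L):(pad$n + length(x))]
}

#' Condition a raw EMG channel into a linear envelope
#'
#' Implements the chain: mains notch (60 Hz biquad, zero phase), demean,
#' full-wave rectify, zero-lag Butterworth low-pass. The low-pass runs a
#' design of half the requested order forward and backward, so a 4th-order
#' request has a 4th-order effective magnitude response and exactly zero phase
#' shift; small negative excursions left by filter ringing are clipped to 0 so
#' the output keeps envelope semantics.
#'
#' @param x Numeric vector, one raw EMG channel.
#' @param spec A [filter_spec()].
#' @param rate EMG sampling rate in Hz (default 2000).
#' @return Non-negative numeric vector, the linear envelope, same length.
#' @export
condition_emg <- function(x, spec = filter_spec(), rate = 2000) {
  if (!is.numeric(x)) abort_data("EMG stream must be numeric")
  if (rate <= 2 * spec$lp_cutoff_hz)
    abort_config(sprintf(
      "low-pass cutoff (%g Hz) must lie below the Nyquist frequency (%g Hz)",
      spec$lp_cutoff_hz, rate / 2))
  if (all(x == 0)) return(numeric(length(x)))
  nc <- notch_coefficients(spec$notch_hz, spec$notch_q, rate)
  y <- zero_phase(x, nc$b, nc$a, rate)
  y <- y - mean(y)
  y <- abs(y)
  bw <- signal::butter(spec$lp_order %/% 2L, spec$lp_cutoff_hz / (rate / 2),
                       type = "low")
  y <- zero_phase(y, bw$b, bw$a, rate)
  pmax(as.numeric(y), 0)
}

#' Normalize EMG envelopes to the per-participant, per-muscle maximum
#'
#' Each envelope is divided by the maximum amplitude that participant's
#' muscle reached across every trial of every condition, so amplitudes become
#' comparable within a participant while preserving between-condition
#' structure; the largest sample for each participant x muscle becomes
#' exactly 1.
#'
#' @param envelopes A list of numeric envelope vectors, all belonging to one
#'   participant x muscle (e.g. all trials, all conditions).
#' @return A list of the same shape with values in \[0, 1\].
#' @export
#' @examples
#' normalize_emg(list(c(0, 2), c(1, 4)))  # divided by 4
normalize_emg <- function(envelopes) {
  if (is.numeric(envelopes)) envelopes <- list(envelopes)
  if (!length(envelopes)) abort_data("no envelopes supplied")
  m <- max(vapply(envelopes, function(e) max(e, 0), numeric(1)))
  if (!is.finite(m) || m <= 0)
    abort_data("dead channel: all-zero envelopes cannot be normalized")
  lapply(envelopes, function(e) pmax(e, 0) / m)
}
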