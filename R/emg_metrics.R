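#' Muscle onset detection settings
#'
#' The detector declares an onset at the first sample whose envelope exceeds
#' the quiet-stance baseline mean by `k_sd` baseline standard deviations and
#' stays above that threshold for `sustain_s` seconds without interruption —
#' the classical sustained supra-threshold rule (defaults: 7 SD held for
#' 50 ms).
#'
#' @param k_sd Threshold in baseline standard deviations above the baseline
#'   mean (default 7).
#' @param sustain_s Minimum time the envelope must remain above threshold, in
#'   seconds (default 0.050).
#' @param baseline_window Two-element numeric, start and end (seconds) of the
#'   quiet-stance baseline segment (default `c(0, 0.5)`).
#' @return An `onset_params` list.
#' @export
onset_params <- function(k_sd = 7, sustain_s = 0.050,
                         baseline_window = c(0, 0.5)) {
  check_scalar_number(k_sd, "k_sd", positive = TRUE)
  check_scalar_number(sustain_s, "sustain_s", positive = TRUE)
  if (!is.numeric(baseline_window) || length(baseline_window) != 2L ||
      baseline_window[2] <= baseline_window[1] || baseline_window[1] < 0)
    abort_config("`baseline_window` must be increasing c(start_s, end_s), start >= 0")
  structure(list(k_sd = k_sd, sustain_s = sustain_s,
                 baseline_window = baseline_window),
            class = "onset_params")
}

#' Detect a sustained muscle-activity onset in an EMG envelope
#'
#' Returns the time (seconds, sample-aligned, time zero at the first sample)
#' of the first sample `t` such that the envelope exceeds
#' `baseline mean + k_sd * baseline SD` at every sample in
#' `[t, t + sustain_s]`, or `NA` when no such sample exists.
#'
#' @param envelope Conditioned (optionally normalized) EMG envelope.
#' @param params An [onset_params()].
#' @param rate Sampling rate of the envelope in Hz.
#' @return Onset time in seconds, or `NA_real_` if no onset.
#' @export
detect_muscle_onset <- function(envelope, params = onset_params(), rate) {
  check_scalar_number(rate, "rate", positive = TRUE)
  if (!is.numeric(envelope) || !length(envelope))
    abort_data("envelope must be a non-empty numeric vector")
  i0 <- floor(params$baseline_window[1] * rate) + 1L
  i1 <- min(length(envelope), ceiling(params$baseline_window[2] * rate))
  if (i1 <= i0) abort_data("baseline window shorter than two samples")
  base <- envelope[i0:i1]
  mu <- mean(base)
  s <- sd(base)
  if (s == 0 && any(envelope != mu))
    abort_data("degenerate baseline: zero variance in the baseline window")
  thr <- mu + params$k_sd * s
  n_sustain <- max(1L, round(params$sustain_s * rate))
  above <- envelope > thr
  if (!any(above)) return(NA_real_)
  # run-length view: first run of `above` of length >= n_sustain
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values & r$lengths >= n_sustain)
  if (!length(ok)) return(NA_real_)
  (starts[ok[1]] - 1L) / rate
}

#' Muscle onset latencies relative to reach initiation
#'
#' @param onsets Named numeric vector of onset times in seconds (`NA` for
#'   muscles with no detected onset).
#' @param events An [event_set()] (or any list with `reach_on`).
#' @return Named numeric vector of signed latencies; negative values are
#'   preparatory (activity preceding the reach).
#' @export
onsets_relative_to_reach <- function(onsets, events) {
  if (is.null(events$reach_on) || !is.finite(events$reach_on))
    abort_data("`reach_on` is undefined for this trial")
  onsets - events$reach_on
}

#' Phase windows for the co-contraction index
#'
#' Four analysis windows anchored to the reach: (i) early, 1.5 to 0.5 s
#' before reach onset; (ii) preparatory, the 0.5 s before reach onset;
#' (iii) movement, the 0.5 s after reach onset; (iv) termination, the 0.5 s
#' before target contact. Phases i-ii characterise movement preparation,
#' iii-iv the compensatory portion of the movement.
#'
#' @param events An [event_set()] with `reach_on` and `reach_off`.
#' @param half_width_s Window length in seconds (default 0.5).
#' @return Named list of `c(start, end)` windows: `early`, `preparatory`,
#'   `movement`, `termination`.
#' @export
cci_phases <- function(events, half_width_s = 0.5) {
  check_scalar_number(half_width_s, "half_width_s", positive = TRUE)
  if (!is.finite(events$reach_on) || !is.finite(events$reach_off))
    abort_data("reach events required to build the phase windows")
  h <- half_width_s
  list(
    early        = c(events$reach_on - 3 * h, events$reach_on - h),
    preparatory  = c(events$reach_on - h, events$reach_on),
    movement     = c(events$reach_on, events$reach_on + h),
    termination  = c(events$reach_off - h, events$reach_off)
  )
}

#' Co-contraction index of two normalized envelopes over a window
#'
#' The default (`method = "weighted"`) is the amplitude-weighted form: the
#' mean over window samples of `min(a,b)/max(a,b) * (a + b)`, with samples
#' where both envelopes are zero contributing 0. It is symmetric in the two
#' muscles, bounded by \[0, 2\] for envelopes in \[0, 1\], and — deliberately —
#' not scale invariant: doubling both envelopes doubles the index, so it
#' reflects how much the pair co-contracts, not merely how similar the traces
#' are. `method = "ratio"` drops the amplitude weight and averages
#' `min/max` alone (range \[0, 1\]).
#'
#' @param a,b Numeric envelope segments of equal length (normalized to
#'   \[0, 1\]).
#' @param method `"weighted"` (default) or `"ratio"`.
#' @return A single co-contraction value.
#' @export
#' @examples
#' compute_cci(c(0.2, 0.4), c(0.1, 0.4))  # 0.475
compute_cci <- function(a, b, method = c("weighted", "ratio")) {
  method <- match.arg(method)
  if (length(a) != length(b))
    abort_data("envelope segments have mismatched lengths")
  if (!length(a)) abort_data("empty window")
  hi <- pmax(a, b)
  lo <- pmin(a, b)
  ratio <- ifelse(hi > 0, lo / hi, 0)
  if (method == "weighted") mean(ratio * (a + b)) else mean(ratio)
}

#' Co-contraction indices of a muscle pair over the four movement phases
#'
#' @param envelope_a,envelope_b Full-trial normalized envelopes of the
#'   agonist and antagonist (equal length, common clock).
#' @param rate Envelope sampling rate in Hz.
#' @param events An [event_set()].
#' @param phases Optional phase windows; defaults to [cci_phases()] built
#'   from `events`.
#' @param method Passed to [compute_cci()].
#' @return A tibble with columns `phase` (i-iv), `label`, `role`
#'   (`"preparatory"` for i-ii, `"compensatory"` for iii-iv) and `cci`.
#' @export
cci_by_phase <- function(envelope_a, envelope_b, rate, events,
                         phases = NULL, method = c("weighted", "ratio")) {
  method <- match.arg(method)
  if (length(envelope_a) != length(envelope_b))
    abort_data("envelopes have mismatched lengths")
  if (is.null(phases)) phases <- cci_phases(events)
  n <- length(envelope_a)
  dur <- n / rate
  vals <- vapply(names(phases), function(ph) {
    w <- phases[[ph]]
    if (w[1] < 0 || w[2] > dur || w[2] <= w[1])
      abort_data(sprintf("phase window '%s' [%.3f, %.3f] s falls outside the trial",
                         ph, w[1], w[2]))
    idx <- (floor(w[1] * rate) + 1L):min(n, ceiling(w[2] * rate))
    compute_cci(envelope_a[idx], envelope_b[idx], method = method)
  }, numeric(1))
  tibble::tibble(
    phase = c("i", "ii", "iii", "iv"),
    label = names(phases),
    role = c("preparatory", "preparatory", "compensatory", "compensatory"),
    cci = unname(vals)
  )
}

#' Default agonist-antagonist muscle pairs
#'
#' Trunk (erector spinae vs rectus abdominis) and shank (tibialis anterior vs
#' gastrocnemius) pairs, bilaterally. Fully overridable: any data frame with
#' columns `pair`, `agonist`, `antagonist` whose labels exist in the EMG
#' channel inventory is accepted downstream.
#'
#' @return A tibble with columns `pair`, `agonist`, `antagonist`.
#' @export
default_muscle_pairs <- function() {
  tibble::tibble(
    pair = c("trunk_L", "trunk_R", "shank_L", "shank_R"),
    agonist = c("ES_L", "ES_R", "TA_L", "TA_R"),
    antagonist = c("RA_L", "RA_R", "GA_L", "GA_R")
  )
}
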