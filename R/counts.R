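# Raw 30 Hz signal -> per-second vector-magnitude activity counts.
#
# The vendor (ActiLife) conversion is proprietary; this open emulation
# band-pass filters each axis (0.25-2.5 Hz, zero-phase Butterworth), rectifies
# and sums within 1-s epochs, and quantizes at 1 count = 0.001664 g. Vendor
# epoch exports can be ingested directly with read_epoch_csv() to bypass it.

#' Zero-phase band-pass filter for accelerometer axes
#'
#' 4th-order Butterworth band-pass applied forward-backward (zero phase,
#' no time shift). Defaults match the activity-count convention for wrist
#' accelerometry: pass band 0.25-2.5 Hz.
#'
#' @param x Numeric signal (one axis, in g).
#' @param sample_rate Sampling rate in Hz; must exceed `2 * high`.
#' @param low,high Pass-band corner frequencies in Hz.
#' @return Filtered signal, same length as `x`.
#' @export
bandpass_filter <- function(x, sample_rate = 30, low = 0.25, high = 2.5) {
  if (sample_rate <= 2 * high)
    stop_ulperf("sample_rate must exceed twice the upper corner frequency")
  n <- length(x)
  if (n < 2) return(x - mean(x))
  bf <- signal::butter(2, c(low, high) / (sample_rate / 2), type = "pass")
  # reflect-pad so short inputs survive the filter warm-up
  pad <- min(n - 1L, as.integer(3 * sample_rate))
  xp <- c(2 * x[1] - x[pad:1 + 1], x, 2 * x[n] - x[n - seq_len(pad)])
  yp <- signal::filtfilt(bf, xp)
  yp[pad + seq_len(n)]
}

# Frequency response magnitude of the band-pass as applied (forward-backward
# doubles the attenuation). Used as an independent oracle in tests.
bandpass_gain <- function(freq, sample_rate = 30, low = 0.25, high = 2.5) {
  bf <- signal::butter(2, c(low, high) / (sample_rate / 2), type = "pass")
  w <- 2 * pi * freq / sample_rate
  ew <- function(coefs) vapply(w, function(wi)
    sum(coefs * exp(-1i * wi * (seq_along(coefs) - 1))), complex(1))
  Mod(ew(bf$b) / ew(bf$a))^2
}

#' Convert a filtered axis signal to per-second activity counts
#'
#' Each second's count is `floor(sum(|a|) / 0.001664)` over that second's
#' samples (rectify, sum, quantize at 1 count = 0.001664 g). A trailing
#' partial second is dropped.
#'
#' @param x Band-pass filtered axis signal in g.
#' @param sample_rate Sampling rate in Hz (samples per epoch).
#' @return Integer-valued vector of per-second counts.
#' @export
to_activity_counts <- function(x, sample_rate = 30) {
  spp <- as.integer(round(sample_rate))
  n_sec <- length(x) %/% spp
  if (n_sec == 0) return(numeric(0))
  m <- matrix(abs(x[seq_len(n_sec * spp)]), nrow = spp)
  floor(colSums(m) / COUNT_SCALE_G)
}

#' Combine per-axis counts into vector-magnitude counts
#'
#' `round(sqrt(cx^2 + cy^2 + cz^2))` per second.
#'
#' @param cx,cy,cz Per-second axis counts, equal length.
#' @return Per-second vector-magnitude counts (non-negative integers).
#' @export
vector_magnitude <- function(cx, cy, cz) {
  round(sqrt(cx^2 + cy^2 + cz^2))
}

#' Convert one limb's raw recording to per-second vector-magnitude counts
#'
#' Full preprocessing chain for one limb: band-pass filter each axis,
#' quantize to per-second counts per axis, combine axes.
#'
#' @param raw A [raw_recording()].
#' @param low,high Band-pass corners in Hz.
#' @return Per-second vector-magnitude count vector.
#' @export
raw_to_counts <- function(raw, low = 0.25, high = 2.5) {
  stopifnot(inherits(raw, "RawRecording"))
  fs <- raw$sample_rate
  vector_magnitude(
    to_activity_counts(bandpass_filter(raw$ax, fs, low, high), fs),
    to_activity_counts(bandpass_filter(raw$ay, fs, low, high), fs),
    to_activity_counts(bandpass_filter(raw$az, fs, low, high), fs))
}

#' Align left/right count series into limb roles
#'
#' Truncates both series to the common length and maps left/right to the
#' paretic/non-dominant vs non-paretic/dominant roles using subject
#' metadata: stroke subjects use the paretic side; controls use the
#' non-dominant side in the paretic role (ratios are non-dominant to
#' dominant for neurologically intact adults).
#'
#' @param left,right Per-second count vectors for the left and right wrist.
#' @param meta One-row data frame with `cohort`, `paretic_side`,
#'   `dominant_side` (see [read_meta_csv()]).
#' @param subject_id Optional subject identifier.
#' @return An [epoch_series()].
#' @export
align_limbs <- function(left, right, meta, subject_id = NA_character_) {
  if (!length(left) || !length(right))
    stop_ulperf("both limb series must be nonempty")
  n <- min(length(left), length(right))
  left <- left[seq_len(n)]; right <- right[seq_len(n)]
  side_p <- if (identical(meta$cohort, "control")) {
    if (!meta$dominant_side %in% c("left", "right"))
      stop_ulperf("unknown dominant side")
    setdiff(c("left", "right"), meta$dominant_side)
  } else {
    if (is.null(meta$paretic_side) || is.na(meta$paretic_side) ||
        !meta$paretic_side %in% c("left", "right"))
      stop_ulperf("unknown paretic side for stroke subject")
    meta$paretic_side
  }
  if (side_p == "left") epoch_series(left, right, subject_id)
  else epoch_series(right, left, subject_id)
}
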