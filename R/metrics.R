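# The twelve upper-limb performance variables.
#
# Nine are computed from the 1 Hz epoch-count series (durations, magnitudes,
# variability, symmetry ratios); three from the raw 30 Hz signals (jerk
# asymmetry and the two spectral arc length smoothness values). "Moving" is
# operationalized as vector-magnitude counts >= threshold (default 2
# counts/s); all summary statistics are taken over active seconds only, so
# long inactive (e.g., sleep) periods do not zero-inflate magnitudes.

#' Per-second activity mask
#'
#' A second is active when its vector-magnitude count is at or above the
#' movement threshold.
#'
#' @param series An [epoch_series()].
#' @param threshold Movement threshold in counts/s (default 2).
#' @return List with logical vectors `active_p`, `active_np` and the
#'   `threshold` used.
#' @export
active_mask <- function(series, threshold = 2) {
  stopifnot(threshold >= 0)
  list(active_p = series$vm_p >= threshold,
       active_np = series$vm_np >= threshold,
       threshold = threshold)
}

#' Duration variables: hours of activity and isolated activity
#'
#' Hours each limb is moving, and hours each limb moves while the other is
#' still, over the full recording.
#'
#' @param mask An [active_mask()].
#' @return Named list `hours_p`, `hours_np`, `iso_hours_p`, `iso_hours_np`
#'   (hours).
#' @export
duration_metrics <- function(mask) {
  list(hours_p = sum(mask$active_p) / 3600,
       hours_np = sum(mask$active_np) / 3600,
       iso_hours_p = sum(mask$active_p & !mask$active_np) / 3600,
       iso_hours_np = sum(mask$active_np & !mask$active_p) / 3600)
}

#' Magnitude variables: median paretic acceleration and bilateral magnitude
#'
#' Median vector-magnitude counts of the paretic/non-dominant limb over its
#' active seconds, and median of the summed bilateral counts over seconds
#' where at least one limb is active. Both are 0 when no second qualifies.
#'
#' @inheritParams duration_metrics
#' @param series An [epoch_series()].
#' @return Named list `med_accel_p`, `bilateral_magnitude` (counts).
#' @export
magnitude_metrics <- function(series, mask) {
  either <- mask$active_p | mask$active_np
  list(
    med_accel_p = if (any(mask$active_p))
      stats::median(series$vm_p[mask$active_p]) else 0,
    bilateral_magnitude = if (any(either))
      stats::median(series$vm_p[either] + series$vm_np[either]) else 0)
}

#' Variability variable: SD of paretic acceleration magnitude
#'
#' Sample standard deviation (n-1 denominator) of the paretic/non-dominant
#' vector-magnitude counts over its active seconds; 0 with fewer than two
#' active seconds.
#'
#' @inheritParams magnitude_metrics
#' @return `accel_var_p` (counts).
#' @export
variability_metric <- function(series, mask) {
  v <- series$vm_p[mask$active_p]
  if (length(v) < 2) 0 else stats::sd(v)
}

#' Symmetry variables: use ratio and magnitude ratio
#'
#' The use ratio is paretic active hours over non-paretic active hours
#' (`NA` when the non-paretic limb never moves). The magnitude ratio is the
#' median over both-active seconds of `ln(vm_p / vm_np)`; a second where
#' exactly one count is zero is capped at +/-7 and both-zero seconds are
#' excluded.
#'
#' @inheritParams magnitude_metrics
#' @return Named list `use_ratio`, `magnitude_ratio`.
#' @export
symmetry_metrics <- function(series, mask) {
  hp <- sum(mask$active_p); hnp <- sum(mask$active_np)
  use_ratio <- if (hnp == 0) NA_real_ else hp / hnp
  both <- mask$active_p & mask$active_np
  p <- series$vm_p[both]; np <- series$vm_np[both]
  keep <- !(p == 0 & np == 0)
  p <- p[keep]; np <- np[keep]
  lr <- ifelse(p == 0, -7, ifelse(np == 0, 7, log(p / np)))
  lr <- pmin(7, pmax(-7, lr))
  list(use_ratio = use_ratio,
       magnitude_ratio = if (length(lr)) stats::median(lr) else NA_real_)
}

# Mean jerk magnitude of one recording: Euclidean norm of the per-axis first
# difference scaled by the sample rate (g/s), averaged over samples.
mean_jerk <- function(raw) {
  if (length(raw) < 2) stop_ulperf("recording too short for jerk")
  fs <- raw$sample_rate
  j <- sqrt(diff(raw$ax)^2 + diff(raw$ay)^2 + diff(raw$az)^2) * fs
  mean(j)
}

#' Jerk asymmetry index
#'
#' `(J_p - J_np) / (J_p + J_np)` where `J` is each limb's mean jerk
#' magnitude (time derivative of acceleration, g/s). Bounded in [-1, 1];
#' 0 means similar smoothness, positive means the paretic/non-dominant limb
#' is less smooth. Defined as 0 when both limbs have zero jerk.
#'
#' @param raw_p,raw_np [raw_recording()]s for the paretic/non-dominant and
#'   non-paretic/dominant limb (equal sample rates).
#' @return Jerk asymmetry index in [-1, 1].
#' @export
jerk_asymmetry_index <- function(raw_p, raw_np) {
  if (!isTRUE(all.equal(raw_p$sample_rate, raw_np$sample_rate)))
    stop_ulperf("sample-rate mismatch between limbs")
  jp <- mean_jerk(raw_p); jnp <- mean_jerk(raw_np)
  if (jp + jnp == 0) return(0)
  (jp - jnp) / (jp + jnp)
}

# Spectral arc length of a single movement profile (here: acceleration
# magnitude of one bout). The magnitude spectrum is zero-padded to a
# frequency step <= freq_step, normalized by its DC value, and integrated as
# a discrete arc length up to an adaptive cutoff (highest frequency, capped
# at max_cutoff, where the normalized spectrum still reaches amp_th). When
# no frequency above DC reaches amp_th the spectrum is DC-concentrated and
# the arc length attains its smooth limit of exactly -1.
sparc_bout <- function(v, fs, max_cutoff = 10, amp_th = 0.05,
                       freq_step = 0.05) {
  n <- length(v)
  if (n < 2 || sum(v) <= 0) return(NA_real_)
  nfft <- max(n, ceiling(fs / freq_step))
  V <- Mod(stats::fft(c(v, numeric(nfft - n))))
  f <- (seq_len(nfft) - 1) * fs / nfft
  keep <- f <= fs / 2
  V <- V[keep]; f <- f[keep]
  Vh <- V / V[1]
  above <- which(f > 0 & f <= max_cutoff & Vh >= amp_th)
  if (!length(above)) return(-1)
  wc <- f[max(above)]
  sel <- which(f <= wc)
  -sum(sqrt((diff(f[sel]) / wc)^2 + diff(Vh[sel])^2))
}

#' Spectral arc length (SPARC) movement smoothness
#'
#' Segments one limb's recording into movement bouts (maximal runs of
#' active seconds in that limb's mask), computes each bout's
#' acceleration-magnitude spectral arc length, and returns the
#' bout-duration-weighted mean. Values are at most -1; less negative is
#' smoother. `NA` when the mask contains no bout.
#'
#' @param raw A [raw_recording()].
#' @param active Logical per-second activity vector for the same limb
#'   (length at least `floor(length(raw) / sample_rate)` seconds is not
#'   required; extra seconds are ignored).
#' @param max_cutoff Maximum adaptive cutoff frequency, Hz.
#' @param amp_th Normalized-amplitude threshold defining the cutoff.
#' @param freq_step Maximum spectral frequency step, Hz (zero-padding).
#' @return SPARC value (<= -1) or `NA`.
#' @export
sparc <- function(raw, active, max_cutoff = 10, amp_th = 0.05,
                  freq_step = 0.05) {
  fs <- raw$sample_rate
  n_sec <- length(raw) %/% as.integer(round(fs))
  active <- as.logical(active)[seq_len(min(n_sec, length(active)))]
  if (!length(active) || !any(active)) return(NA_real_)
  r <- rle(active)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  mag <- sqrt(raw$ax^2 + raw$ay^2 + raw$az^2)
  vals <- c(); wts <- c()
  for (i in which(r$values)) {
    s0 <- (starts[i] - 1L) * round(fs) + 1L
    s1 <- ends[i] * round(fs)
    sal <- sparc_bout(mag[s0:s1], fs, max_cutoff, amp_th, freq_step)
    if (!is.na(sal)) {
      vals <- c(vals, sal)
      wts <- c(wts, r$lengths[i])
    }
  }
  if (!length(vals)) return(NA_real_)
  sum(vals * wts) / sum(wts)
}

#' Compute all twelve upper-limb performance variables for one subject
#'
#' Assembles the full metric vector from the epoch series (nine 1 Hz
#' variables) and, when raw recordings are supplied, the three 30 Hz
#' variables (jerk asymmetry and the two SPARC values). Raw recordings are
#' converted through the counts pipeline to derive their own activity masks
#' for bout segmentation. The 30 Hz fields are `NA` when raw data are
#' absent.
#'
#' @param series An [epoch_series()].
#' @param raw_p,raw_np Optional [raw_recording()]s for the two limbs.
#' @param threshold Movement threshold in counts/s.
#' @return Named numeric vector with the 12 canonical variables
#'   (see [ul_variable_names()]).
#' @export
#' @examples
#' s <- epoch_series(c(0, 0, 5, 5, 5, 0, 0, 9, 0, 0),
#'                   c(0, 3, 3, 0, 0, 0, 0, 9, 9, 9))
#' compute_all_metrics(s)
compute_all_metrics <- function(series, raw_p = NULL, raw_np = NULL,
                                threshold = 2) {
  mask <- active_mask(series, threshold)
  dur <- duration_metrics(mask)
  mag <- magnitude_metrics(series, mask)
  sym <- symmetry_metrics(series, mask)
  out <- c(hours_p = dur$hours_p, hours_np = dur$hours_np,
           iso_hours_p = dur$iso_hours_p, iso_hours_np = dur$iso_hours_np,
           med_accel_p = mag$med_accel_p,
           bilateral_magnitude = mag$bilateral_magnitude,
           accel_var_p = variability_metric(series, mask),
           use_ratio = sym$use_ratio,
           magnitude_ratio = sym$magnitude_ratio,
           jerk_asym = NA_real_, sparc_p = NA_real_, sparc_np = NA_real_)
  if (!is.null(raw_p) && !is.null(raw_np)) {
    out["jerk_asym"] <- jerk_asymmetry_index(raw_p, raw_np)
    out["sparc_p"] <- sparc(raw_p, raw_to_counts(raw_p) >= threshold)
    out["sparc_np"] <- sparc(raw_np, raw_to_counts(raw_np) >= threshold)
  }
  out[ul_variable_names(12)]
}

#' Compute a metric table for a set of subjects
#'
#' Applies [compute_all_metrics()] to each subject of a cohort list and
#' binds the results into a metric table (data frame with `subject_id`
#' first).
#'
#' @param series_list Named list of [epoch_series()] (names = subject ids).
#' @param raw_list Optional named list; each element a list with `raw_p`,
#'   `raw_np` recordings for that subject.
#' @param threshold Movement threshold in counts/s.
#' @return Metric table data frame.
#' @export
compute_metric_table <- function(series_list, raw_list = NULL, threshold = 2) {
  ids <- names(series_list) %||% as.character(seq_along(series_list))
  rows <- lapply(seq_along(series_list), function(i) {
    rp <- raw_list[[ids[i]]]$raw_p
    rnp <- raw_list[[ids[i]]]$raw_np
    compute_all_metrics(series_list[[i]], rp, rnp, threshold)
  })
  out <- as.data.frame(do.call(rbind, rows))
  cbind(subject_id = ids, out, stringsAsFactors = FALSE)
}
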