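# Synthetic bilateral recordings with the statistical structure the analysis
# assumes, parameterized by five archetypes of upper-limb performance (the
# five category centroids: activity hours per limb, median and SD of active
# paretic counts, use ratio, with cluster sizes 29/41/43/57/41 in the
# default 211-subject cohort).
#
# Activity is modeled at the 1-s epoch level: each limb's active/inactive
# state follows a two-state Markov chain (mean active bout 30 s) with an
# 8 h contiguous sleep block forced inactive in both limbs; paretic activity
# is a subset-biased process coupled to the non-paretic stream so the
# expected use ratio hits its target (about 10% of paretic activity is
# isolated). Active-second magnitudes are lognormal with the target median,
# clamped at the movement threshold, with the spread solved numerically so
# the active-second SD matches its target; inactive seconds carry {0, 1}
# noise counts. Raw 30 Hz data (for the smoothness variables) are generated
# separately as minimum-jerk bouts with archetype-graded band-limited noise.

#' Default archetype parameters for the five performance categories
#'
#' Targets are the five category centroid means (paretic/non-dominant
#' hours, non-paretic/dominant hours, median paretic acceleration in
#' counts, paretic acceleration variability in counts, use ratio) with the
#' category sizes of the default 211-subject cohort.
#'
#' @param n_subjects Integer vector of length 5 (subjects per archetype).
#' @param subject_sd Relative (lognormal) between-subject jitter on targets.
#' @param record_hours Recording duration per subject, hours.
#' @return Data frame of archetype parameters, one row per archetype.
#' @export
ul_archetypes <- function(n_subjects = c(29, 41, 43, 57, 41),
                          subject_sd = 0.10, record_hours = 24) {
  data.frame(
    name = ul_category_names(),
    target_hours_p = c(1.5, 4.6, 4.5, 7.4, 10.2),
    target_hours_np = c(4.1, 8.4, 5.3, 8.0, 10.7),
    target_med_accel_p = c(0, 5, 25, 47, 61),
    target_accel_var_p = c(27.3, 34.8, 58.9, 75.9, 80.3),
    target_use_ratio = c(0.38, 0.55, 0.85, 0.94, 0.96),
    n_subjects = n_subjects,
    subject_sd = subject_sd,
    record_hours = record_hours,
    # paretic-limb raw-bout noise amplitude (fraction of peak), graded so
    # smoothness degrades toward the low-performance archetypes
    noise_amp_p = c(0.45, 0.35, 0.22, 0.12, 0.06),
    noise_amp_np = 0.06,
    stringsAsFactors = FALSE)
}

# Two-state Markov activity mask with stationary active fraction `frac` and
# mean active sojourn `mean_bout` seconds, generated by alternating
# geometric sojourns.
markov_mask <- function(n_sec, frac, mean_bout = 30) {
  if (frac <= 0) return(logical(n_sec))
  if (frac >= 1) return(rep(TRUE, n_sec))
  p_exit <- 1 / mean_bout
  p_enter <- frac * p_exit / (1 - frac)
  mean_cycle <- 1 / p_enter + mean_bout
  out <- logical(0)
  while (length(out) < n_sec) {
    n_runs <- ceiling((n_sec - length(out)) / mean_cycle) + 20L
    lens <- as.vector(rbind(stats::rgeom(n_runs, p_enter) + 1L,
                            stats::rgeom(n_runs, p_exit) + 1L))
    out <- c(out, rep(rep(c(FALSE, TRUE), n_runs), lens))
  }
  out[seq_len(n_sec)]
}

# SD of max(threshold, X) for X ~ lognormal(log(med), sigma): closed-form
# truncated moments.
clamped_lnorm_sd <- function(sigma, med, threshold) {
  mu <- log(med)
  a <- log(threshold)
  p_lo <- stats::pnorm((a - mu) / sigma)
  e1 <- exp(mu + sigma^2 / 2) * stats::pnorm((mu + sigma^2 - a) / sigma)
  e2 <- exp(2 * mu + 2 * sigma^2) * stats::pnorm((mu + 2 * sigma^2 - a) / sigma)
  m1 <- threshold * p_lo + e1
  m2 <- threshold^2 * p_lo + e2
  sqrt(max(0, m2 - m1^2))
}

# Solve sigma so the clamped lognormal SD matches `sd_target`.
solve_lnorm_sigma <- function(med, sd_target, threshold = 2) {
  if (sd_target <= 0) return(0.01)
  f <- function(s) clamped_lnorm_sd(s, med, threshold) - sd_target
  if (f(4) < 0) return(4)
  stats::uniroot(f, c(0.01, 4), tol = 1e-8)$root
}

#' Generate one subject's bilateral epoch series from archetype targets
#'
#' See the module description at the top of this file for the generative
#' model. Per-subject targets are jittered by a mean-preserving lognormal
#' factor (`subject_sd`); the paretic hours target is derived from the
#' jittered use-ratio and non-paretic-hours targets (the archetype targets
#' are mutually consistent), and an inconsistent combination raises an
#' error.
#'
#' @param params One-row data frame as in [ul_archetypes()].
#' @param seed Optional RNG seed.
#' @param threshold Movement threshold in counts/s (active magnitudes are
#'   clamped at it).
#' @return List with `series` (an [epoch_series()]) and `truth` (one-row
#'   data frame of realized per-subject targets).
#' @export
generate_epoch_subject <- function(params, seed = NULL, threshold = 2) {
  rec_s <- round(params$record_hours * 3600)
  sleep_s <- min(8 * 3600, rec_s)
  awake_s <- rec_s - sleep_s
  awake_h <- awake_s / 3600
  if (params$target_hours_np > awake_h || params$target_hours_p > awake_h)
    stop_ulperf("infeasible target: activity hours exceed awake time")
  if (params$target_hours_np > 0) {
    implied <- params$target_hours_p / params$target_hours_np
    if (abs(implied - params$target_use_ratio) >
        pmax(0.25 * pmax(implied, params$target_use_ratio), 0.05))
      stop_ulperf("infeasible target: use ratio inconsistent with hours")
  }
  with_seed(seed, {
    sdj <- params$subject_sd
    jit <- function(x) x * stats::rlnorm(1, -sdj^2 / 2, sdj)
    h_np <- min(jit(params$target_hours_np), 0.95 * awake_h)
    r <- if (params$target_hours_p == 0) 0 else jit(params$target_use_ratio)
    h_p <- min(r * h_np, 0.98 * awake_h)
    f_np <- h_np / awake_h
    f_p <- h_p / awake_h
    np_mask <- markov_mask(awake_s, f_np)
    if (f_p == 0 || f_np == 0) {
      p_mask <- logical(awake_s)
    } else {
      a <- 0.9 * f_p / f_np
      b <- 0.1 * f_p / (1 - f_np)
      if (a > 1) { a <- 1; b <- (f_p - f_np) / (1 - f_np) }
      u <- stats::runif(awake_s)
      p_mask <- ifelse(np_mask, u < a, u < b)
    }
    med_base <- max(params$target_med_accel_p, threshold)
    med_j <- max(threshold, jit(med_base))
    var_j <- max(1, jit(params$target_accel_var_p))
    sig_p <- solve_lnorm_sigma(med_j, var_j, threshold)
    med_np <- max(med_j, threshold) / max(min(r, 1.5), 0.35)
    draw_vm <- function(mask, med, sig) {
      vm <- stats::rbinom(awake_s, 1, 0.3)  # inactive-second noise in {0, 1}
      n_act <- sum(mask)
      if (n_act)
        vm[mask] <- pmax(threshold,
                         round(stats::rlnorm(n_act, log(med), sig)))
      vm
    }
    vm_p <- c(numeric(sleep_s), draw_vm(p_mask, med_j, sig_p))
    vm_np <- c(numeric(sleep_s), draw_vm(np_mask, med_np, sig_p))
    list(series = epoch_series(vm_p, vm_np),
         truth = data.frame(name = params$name, hours_p = h_p,
                            hours_np = h_np, med_accel_p = med_j,
                            accel_var_p = var_j, use_ratio = r,
                            stringsAsFactors = FALSE))
  })
}

#' Generate one raw 30 Hz movement bout
#'
#' A minimum-jerk (quintic) displacement profile differentiated twice to
#' acceleration, scaled to a given peak, distributed over the three axes by
#' a random unit vector. `smoothness = "noisy"` adds band-limited
#' (3-8 Hz) noise of amplitude `noise_amp` times the peak.
#'
#' @param duration_s Bout duration in seconds (>= 1).
#' @param sample_rate Sampling rate, Hz.
#' @param smoothness `"smooth"` or `"noisy"`.
#' @param noise_amp Noise amplitude as a fraction of the peak acceleration.
#' @param peak_g Peak acceleration magnitude, g.
#' @param seed Optional RNG seed.
#' @param limb Limb label for the resulting recording.
#' @return A [raw_recording()] covering the bout.
#' @export
generate_raw_bout <- function(duration_s, sample_rate = 30,
                              smoothness = c("smooth", "noisy"),
                              noise_amp = 0.1, peak_g = 0.3, seed = NULL,
                              limb = "paretic_nd") {
  if (duration_s < 1) stop_ulperf("bout duration must be >= 1 s")
  smoothness <- match.arg(smoothness)
  n <- round(duration_s * sample_rate)
  tau <- seq(0, 1, length.out = n)
  prof <- 60 * tau - 180 * tau^2 + 120 * tau^3  # d2/dtau2 of min-jerk quintic
  prof <- prof / max(abs(prof)) * peak_g
  with_seed(seed, {
    u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
    axes <- outer(prof, u)
    if (smoothness == "noisy" && noise_amp > 0) {
      # band-limited movement intermittency: a sparse sum of random
      # in-band (3.5-7.5 Hz) sinusoids along the movement direction, so
      # the added energy stays concentrated in the stop band of smooth
      # movement rather than diluted across many spectral bins
      tt <- seq_len(n) / sample_rate
      ripple <- rowSums(vapply(1:3, function(i) {
        sin(2 * pi * stats::runif(1, 3.5, 7.5) * tt +
              stats::runif(1, 0, 2 * pi))
      }, numeric(n)))
      axes <- axes + outer(ripple * noise_amp * peak_g, u)
    }
    raw_recording(axes[, 1], axes[, 2], axes[, 3], sample_rate, limb = limb)
  })
}

# A subject's raw pair: a few movement bouts separated by still gaps, with
# limb-specific noise amplitude.
generate_raw_subject <- function(noise_amp_p, noise_amp_np, seed = NULL,
                                 n_bouts = 3, bout_s = 8, gap_s = 2,
                                 sample_rate = 30) {
  with_seed(seed, {
    one_limb <- function(noise_amp, limb) {
      segs <- lapply(seq_len(n_bouts), function(i) {
        b <- generate_raw_bout(bout_s, sample_rate,
                               if (noise_amp > 0) "noisy" else "smooth",
                               noise_amp, limb = limb)
        cbind(b$ax, b$ay, b$az)
      })
      gap <- matrix(0, gap_s * sample_rate, 3)
      m <- do.call(rbind, Reduce(function(a, b) c(a, list(gap), list(b)),
                                 segs[-1], list(segs[[1]])))
      raw_recording(m[, 1], m[, 2], m[, 3], sample_rate, limb = limb)
    }
    list(raw_p = one_limb(noise_amp_p, "paretic_nd"),
         raw_np = one_limb(noise_amp_np, "nonparetic_d"))
  })
}

#' Generate a full synthetic cohort
#'
#' Default configuration: the five archetypes of [ul_archetypes()] with
#' 29/41/43/57/41 subjects (211 total). Cohort labels mirror the observed
#' cohort-by-category distribution: the two lowest archetypes are
#' stroke-only, the middle mostly stroke, and the top two mostly controls;
#' metadata includes sides, a concordance flag and plausible ARAT draws per
#' archetype (controls untested). With `raw = TRUE` each subject also gets
#' a short representative pair of 30 Hz bout recordings (smoothness graded
#' by archetype) from which the three 30 Hz variables can be computed.
#'
#' @param archetypes Archetype parameter data frame (default
#'   [ul_archetypes()]).
#' @param seed Optional RNG seed.
#' @param raw Generate raw 30 Hz bout pairs per subject?
#' @param threshold Movement threshold passed to the epoch generator.
#' @return List with `series` (named list of [epoch_series()]), `raw`
#'   (named list of `raw_p`/`raw_np` pairs or `NULL`), `meta` (metadata
#'   data frame), `truth` (per-subject generating archetype and realized
#'   targets).
#' @export
generate_cohort <- function(archetypes = ul_archetypes(), seed = NULL,
                            raw = TRUE, threshold = 2) {
  n_total <- sum(archetypes$n_subjects)
  if (n_total < 10) stop_ulperf("cohort too small")
  seeds <- derive_seeds(seed %||% sample.int(1e6, 1), n_total + 1L)
  stroke_frac <- c(1, 1, 38 / 43, 20 / 57, 7 / 41)[seq_len(nrow(archetypes))]
  stroke_frac[is.na(stroke_frac)] <- 0.5
  conc_prob <- c(0.38, 0.39, 0.50, 0.70, 0.57)[seq_len(nrow(archetypes))]
  conc_prob[is.na(conc_prob)] <- 0.5
  arat_mean <- c(18.5, 27.8, 45.3, 48.4, 44.1)[seq_len(nrow(archetypes))]
  arat_sd <- c(11, 12, 9, 6, 8)[seq_len(nrow(archetypes))]
  series <- list(); raws <- list(); truth <- list(); meta <- list()
  si <- 0L
  meta_rng <- seeds[n_total + 1L]
  for (ai in seq_len(nrow(archetypes))) {
    pars <- archetypes[ai, ]
    n_stroke <- round(stroke_frac[ai] * pars$n_subjects)
    for (j in seq_len(pars$n_subjects)) {
      si <- si + 1L
      id <- sprintf("S%03d", si)
      sub <- generate_epoch_subject(pars, seed = seeds[si],
                                    threshold = threshold)
      sub$series$subject_id <- id
      series[[id]] <- sub$series
      truth[[id]] <- cbind(subject_id = id, archetype = ai, sub$truth)
      if (raw)
        raws[[id]] <- generate_raw_subject(pars$noise_amp_p,
                                           pars$noise_amp_np,
                                           seed = seeds[si] + 1L)
      meta[[id]] <- with_seed(meta_rng + si, {
        is_stroke <- j <= n_stroke
        dom <- if (stats::runif(1) < 0.85) "right" else "left"
        if (is_stroke) {
          conc <- stats::runif(1) < conc_prob[ai]
          par_side <- if (conc) dom else setdiff(c("left", "right"), dom)
          cohort <- if (stats::runif(1) < 57 / 135) "stroke_1" else "stroke_2"
          arat <- min(57L, max(0L, round(stats::rnorm(1, arat_mean[ai],
                                                      arat_sd[ai]))))
        } else {
          cohort <- "control"; par_side <- NA_character_; arat <- NA_integer_
        }
        data.frame(subject_id = id, cohort = cohort,
                   paretic_side = par_side, dominant_side = dom,
                   arat = arat, stringsAsFactors = FALSE)
      })
    }
  }
  list(series = series,
       raw = if (raw) raws else NULL,
       meta = validate_meta(do.call(rbind, meta)),
       truth = do.call(rbind, truth))
}

#' Uniform null sample for clustering-tendency and gap checks
#'
#' `n` points uniform in the `d`-dimensional unit hypercube, then z-scored.
#'
#' @param n Number of points (>= 10).
#' @param d Dimensionality.
#' @param seed Optional RNG seed.
#' @return A `StandardizedMatrix`.
#' @export
uniform_null <- function(n, d, seed = NULL) {
  if (n < 10) stop_ulperf("need n >= 10")
  x <- with_seed(seed, matrix(stats::runif(n * d), n, d))
  colnames(x) <- paste0("V", seq_len(d))
  standardize(as.data.frame(x))
}
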