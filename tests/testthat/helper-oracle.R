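# Shared fixtures and independent oracles.

# Worked 10-second fixture (threshold 2): enumerated by hand.
fixture_series <- function() {
  epoch_series(c(0, 0, 5, 5, 5, 0, 0, 9, 0, 0),
               c(0, 3, 3, 0, 0, 0, 0, 9, 9, 9))
}

# Brute-force per-second enumeration oracle for the nine 1 Hz metrics.
# Deliberately loop-based and independent of the package's vectorized path;
# only the final median/sd reductions use stats:: on the collected values.
oracle_metrics <- function(vm_p, vm_np, threshold = 2) {
  n <- length(vm_p)
  hp <- 0L; hnp <- 0L; isop <- 0L; isonp <- 0L
  p_act <- numeric(0); bil <- numeric(0); lr <- numeric(0)
  for (i in seq_len(n)) {
    a_p <- vm_p[i] >= threshold
    a_np <- vm_np[i] >= threshold
    if (a_p) hp <- hp + 1L
    if (a_np) hnp <- hnp + 1L
    if (a_p && !a_np) isop <- isop + 1L
    if (a_np && !a_p) isonp <- isonp + 1L
    if (a_p) p_act <- c(p_act, vm_p[i])
    if (a_p || a_np) bil <- c(bil, vm_p[i] + vm_np[i])
    if (a_p && a_np && !(vm_p[i] == 0 && vm_np[i] == 0)) {
      r <- if (vm_p[i] == 0) -7 else if (vm_np[i] == 0) 7
           else log(vm_p[i] / vm_np[i])
      lr <- c(lr, min(7, max(-7, r)))
    }
  }
  c(hours_p = hp / 3600, hours_np = hnp / 3600,
    iso_hours_p = isop / 3600, iso_hours_np = isonp / 3600,
    med_accel_p = if (length(p_act)) stats::median(p_act) else 0,
    bilateral_magnitude = if (length(bil)) stats::median(bil) else 0,
    accel_var_p = if (length(p_act) >= 2) stats::sd(p_act) else 0,
    use_ratio = if (hnp == 0) NA_real_ else hp / hnp,
    magnitude_ratio = if (length(lr)) stats::median(lr) else NA_real_)
}

# Random integer count stream with zeros, threshold-edge values and a
# heavy tail, for the oracle-equivalence property.
random_stream <- function(n) {
  rpois(n, 3) * rbinom(n, 1, 0.6)
}

# The default synthetic cohort is expensive; cache one instance per test run.
.cohort_cache <- new.env(parent = emptyenv())
cached_cohort <- function(seed = 1, raw = FALSE) {
  key <- paste0("s", seed, "_", raw)
  if (is.null(.cohort_cache[[key]])) {
    sim <- generate_cohort(seed = seed, raw = raw)
    tab <- compute_metric_table(sim$series, sim$raw)
    .cohort_cache[[key]] <- list(sim = sim, tab = tab)
  }
  .cohort_cache[[key]]
}

# Adjusted Rand index (independent cross-check from mclust).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

with_seed <- ulperf:::with_seed
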