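# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
# A NULL seed leaves the RNG alone (caller manages reproducibility).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a stream of child seeds (< 2^31) from one parent seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_ulperf <- function(...) stop(..., call. = FALSE)

# g per activity count, fixed by the vendor epoch-count convention.
COUNT_SCALE_G <- 0.001664

#' Canonical upper-limb performance variable names
#'
#' Returns the ordered canonical names of the 12 upper-limb performance
#' variables, or one of the nested subsets used by the model ladder
#' (12, 9, 7 or 5 variables). The 5-variable set is the final solution:
#' paretic/non-dominant hours, non-paretic/dominant hours, median paretic
#' acceleration, paretic acceleration variability, and use ratio.
#'
#' @param n_vars One of 12, 9, 7, 5.
#' @return Character vector of variable names.
#' @export
#' @examples
#' ul_variable_names(5)
ul_variable_names <- function(n_vars = 12) {
  all12 <- c("hours_p", "hours_np", "iso_hours_p", "iso_hours_np",
             "med_accel_p", "bilateral_magnitude", "accel_var_p",
             "use_ratio", "magnitude_ratio",
             "jerk_asym", "sparc_p", "sparc_np")
  switch(as.character(n_vars),
    "12" = all12,
    # drop the three 30 Hz movement-quality variables
    "9"  = setdiff(all12, c("jerk_asym", "sparc_p", "sparc_np")),
    # additionally drop the two isolated-activity durations
    "7"  = setdiff(all12, c("jerk_asym", "sparc_p", "sparc_np",
                            "iso_hours_p", "iso_hours_np")),
    # final five: one variable from each retained aspect (duration x2,
    # magnitude, variability, symmetry)
    "5"  = c("hours_p", "hours_np", "med_accel_p", "accel_var_p", "use_ratio"),
    stop_ulperf("n_vars must be one of 12, 9, 7, 5")
  )
}

#' Names of the five upper-limb performance categories
#'
#' Fixed category labels in order of increasing overall performance.
#'
#' @return Character vector of length 5.
#' @export
ul_category_names <- function() {
  c("Minimal Activity/Rare Integration",
    "Minimal Activity/Limited Integration",
    "Moderate Activity/Moderate Integration",
    "Moderate Activity/Full Integration",
    "High Activity/Full Integration")
}
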