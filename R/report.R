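# Reporting surfaces: per-category summary tables (means and ranges in
# original units), univariate ANOVAs with Tukey HSD post-hoc comparisons,
# the scatterplot matrix of the five final variables, and coxcomb charts
# whose wedge areas are proportional to each variable's rescaled value.

#' Per-category summary of performance variables
#'
#' Means and (min-max) ranges per category in original (unstandardized)
#' units, plus category sizes and, when metadata is supplied, percent
#' concordant among stroke subjects and ARAT mean/range.
#'
#' @param table Metric table.
#' @param assignments Category labels aligned with `table` rows.
#' @param meta Optional metadata data frame (for concordance and ARAT).
#' @param variables Variables to summarize (default: all metric columns).
#' @return List with `n` (per category), `mean`, `min`, `max` (category x
#'   variable matrices), and optionally `pct_concordant`, `arat`.
#' @export
cluster_summary <- function(table, assignments, meta = NULL,
                            variables = NULL) {
  vars <- variables %||% setdiff(names(table), "subject_id")
  if (length(assignments) != nrow(table))
    stop_ulperf("assignments and table not aligned")
  f <- factor(assignments)
  agg <- function(fun) {
    m <- do.call(rbind, lapply(levels(f), function(g) {
      apply(table[f == g, vars, drop = FALSE], 2, fun)
    }))
    rownames(m) <- levels(f)
    m
  }
  out <- list(n = stats::setNames(as.integer(table(f)), levels(f)),
              mean = agg(mean), min = agg(min), max = agg(max))
  if (!is.null(meta)) {
    bd <- cohort_breakdown(as.character(f), meta)
    out$pct_concordant <- stats::setNames(bd$concordance$pct_concordant,
                                          bd$concordance$category)
    arat <- split(meta$arat, f)
    out$arat <- do.call(rbind, lapply(arat, function(a) {
      a <- a[!is.na(a)]
      if (!length(a)) return(c(mean = NA, min = NA, max = NA))
      c(mean = mean(a), min = min(a), max = max(a))
    }))
  }
  out
}

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' Omnibus F test of the category effect on one performance variable,
#' followed by all pairwise comparisons adjusted with Tukey's honestly
#' significant difference (studentized-range distribution; unbalanced
#' groups handled by `stats::TukeyHSD`).
#'
#' @param values Numeric per-subject variable.
#' @param assignments Category labels.
#' @return List with `F`, `p_omnibus`, `tukey` (data frame of pairwise
#'   differences with adjusted p values).
#' @export
univariate_anova_tukey <- function(values, assignments) {
  g <- factor(assignments)
  if (nlevels(g) < 2) stop_ulperf("need at least 2 groups")
  if (any(table(g) < 2)) stop_ulperf("each group needs n >= 2")
  fit <- stats::aov(values ~ g)
  an <- summary(fit)[[1]]
  tk <- as.data.frame(stats::TukeyHSD(fit)$g)
  names(tk) <- c("diff", "lwr", "upr", "p_adj")
  tk$comparison <- rownames(tk); rownames(tk) <- NULL
  list(F = an[["F value"]][1], p_omnibus = an[["Pr(>F)"]][1],
       tukey = tk[, c("comparison", "diff", "lwr", "upr", "p_adj")])
}

#' Coxcomb chart of one subject's (or category's) performance profile
#'
#' Each of the five final variables is rescaled to `u` in [0, 1] by the
#' sample min-max and drawn as a wedge of angular width 2*pi/5 with radius
#' `sqrt(u)`, so wedge area is proportional to the rescaled value. Values
#' outside [min, max] are clipped with a warning.
#'
#' @param metrics Named numeric vector of the five variables (any
#'   consistent scale, e.g. standardized).
#' @param sample_min_max Data frame with columns `variable`, `min`, `max`.
#' @param file Optional output path (`.svg` or `.png`); when `NULL`, draws
#'   on the current device.
#' @param main Title.
#' @return Invisibly, a data frame of the wedge geometry (`variable`, `u`,
#'   `radius`).
#' @export
coxcomb_chart <- function(metrics, sample_min_max, file = NULL, main = "") {
  vars <- sample_min_max$variable
  v <- metrics[vars]
  lo <- sample_min_max$min; hi <- sample_min_max$max
  if (any(hi <= lo)) stop_ulperf("min must be < max for every variable")
  if (any(v < lo | v > hi, na.rm = TRUE))
    warning("values outside [min, max] clipped")
  u <- pmin(1, pmax(0, (v - lo) / (hi - lo)))
  r <- sqrt(u)
  geom <- data.frame(variable = vars, u = unname(u), radius = unname(r))
  draw <- function() {
    graphics::plot.new()
    graphics::plot.window(c(-1.15, 1.15), c(-1.15, 1.15), asp = 1)
    graphics::title(main = main)
    k <- length(vars)
    for (i in seq_len(k)) {
      th <- seq((i - 1) * 2 * pi / k, i * 2 * pi / k, length.out = 60) +
        pi / 2
      graphics::polygon(c(0, r[i] * cos(th)), c(0, r[i] * sin(th)),
                        col = "grey40", border = "white")
      mid <- ((i - 0.5) * 2 * pi / k) + pi / 2
      graphics::text(1.08 * cos(mid), 1.08 * sin(mid), vars[i], cex = 0.7)
    }
    th <- seq(0, 2 * pi, length.out = 200)
    graphics::lines(cos(th), sin(th), col = "grey70", lty = 2)
  }
  if (!is.null(file)) {
    if (grepl("\\.svg$", file)) grDevices::svg(file, width = 5, height = 5)
    else grDevices::png(file, width = 600, height = 600)
    on.exit(grDevices::dev.off())
    draw()
  } else if (grDevices::dev.cur() != 1) draw()
  invisible(geom)
}

#' Scatterplot matrix of the five final variables by cluster
#'
#' Lower triangle: pairwise scatterplots colored by cluster; diagonal:
#' per-cluster density curves; upper triangle: Spearman rank-order
#' correlations across all subjects.
#'
#' @param table Metric table (five final variables are used).
#' @param assignments Category/cluster labels.
#' @param file Optional output path (`.svg`/`.png`).
#' @return Invisibly, the matrix of pairwise Spearman correlations.
#' @export
scatterplot_matrix <- function(table, assignments, file = NULL) {
  vars <- intersect(ul_variable_names(5), names(table))
  if (nrow(table) < 3) stop_ulperf("need at least 3 subjects")
  x <- as.matrix(table[, vars, drop = FALSE])
  rho <- stats::cor(x, method = "spearman")
  g <- as.integer(factor(assignments))
  draw <- function() {
    graphics::pairs(
      x, pch = g, col = g,
      upper.panel = function(xx, yy, ...) {
        r <- stats::cor(xx, yy, method = "spearman")
        graphics::text(mean(range(xx)), mean(range(yy)),
                       sprintf("%.2f", r), cex = 1.2)
      },
      diag.panel = function(xx, ...) {
        rng <- range(xx)
        for (gg in unique(g)) {
          d <- stats::density(xx[g == gg])
          graphics::lines(d$x, 0.2 + 0.75 * d$y / max(d$y), col = gg)
        }
      })
  }
  if (!is.null(file)) {
    if (grepl("\\.svg$", file)) grDevices::svg(file, width = 8, height = 8)
    else grDevices::png(file, width = 900, height = 900)
    on.exit(grDevices::dev.off())
    draw()
  } else if (grDevices::dev.cur() != 1) draw()
  invisible(rho)
}
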