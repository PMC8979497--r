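# The frozen category model: the final 5-variable, 5-cluster k-means
# solution with its scaler, centroids ordered by overall performance and the
# five fixed category names. New subjects are classified by nearest centroid
# in the frozen standardized space, never by re-clustering, so the model is
# auditable for clinical use.

order_centroids <- function(centroids) {
  # composite score = mean standardized centroid coordinate; all five final
  # variables increase with overall performance, so the mean orders the
  # categories lowest -> highest without ties in practice
  composite <- rowMeans(centroids)
  order(composite)
}

#' Freeze a 5-cluster solution into a named category model
#'
#' Orders the five centroids by their composite score (mean standardized
#' coordinate, ascending) and attaches the fixed category names from lowest
#' to highest overall performance. The ordering is content-derived, so any
#' relabeling of the input clusters yields the identical model.
#'
#' @param z The `StandardizedMatrix` the solution was fitted on (5 final
#'   variables).
#' @param solution A `ClusterSolution` with `k = 5`.
#' @return An object of class `ul_category_model`.
#' @export
build_category_model <- function(z, solution) {
  if (solution$k != 5) stop_ulperf("category model requires k = 5")
  if (!inherits(z, "StandardizedMatrix"))
    stop_ulperf("z must be a StandardizedMatrix (scaler needed)")
  ord <- order_centroids(solution$centroids)
  centroids <- solution$centroids[ord, , drop = FALSE]
  nms <- ul_category_names()
  rownames(centroids) <- nms
  colnames(centroids) <- z$variable_names
  relabel <- match(seq_len(5), ord)
  raw <- sweep(sweep(centroids, 2, z$sds, "*"), 2, z$means, "+")
  structure(list(
    variable_names = z$variable_names,
    scaler = list(means = z$means, sds = z$sds),
    centroids = centroids,
    centroids_raw = raw,
    category_names = nms,
    composite_order = rowMeans(centroids),
    solution = solution,
    training_categories = factor(nms[relabel[solution$assignments]],
                                 levels = nms),
    training_z = z$values,
    n = length(solution$assignments),
    seed = solution$seed),
    class = "ul_category_model")
}

#' Fit the upper-limb performance category model
#'
#' The main fitting entry point: takes a metric table, restricts it to the
#' five final performance variables (paretic/non-dominant hours,
#' non-paretic/dominant hours, median paretic acceleration, paretic
#' acceleration variability, use ratio), z-scores them, fits a 5-cluster
#' k-means solution (k-means++ seeding, best of `n_restarts` Lloyd runs),
#' and freezes it into an ordered, named category model.
#'
#' @param table Metric table with at least the five final variables.
#' @param n_restarts Number of k-means restarts.
#' @param seed Optional RNG seed for reproducibility.
#' @return An `ul_category_model`; see [build_category_model()] for the
#'   structure, and `print`, `summary`, `coef`, `predict`, `fitted`,
#'   `residuals`, `plot` methods.
#' @export
#' @examples
#' sim <- generate_cohort(seed = 7, raw = FALSE)
#' tab <- compute_metric_table(sim$series)
#' fit <- ul_category_model(tab, seed = 7)
#' print(fit)
#' head(predict(fit, tab))
ul_category_model <- function(table, n_restarts = 25, seed = NULL) {
  z <- standardize(table, ul_variable_names(5))
  sol <- kmeans_fit(z, k = 5, n_restarts = n_restarts, seed = seed)
  m <- build_category_model(z, sol)
  m$call <- match.call()
  m
}

#' Classify subjects with a frozen category model
#'
#' Projects each subject's five final variables through the stored scaler
#' and assigns the nearest centroid (Euclidean distance in standardized
#' space); ties go to the lower-ordered category.
#'
#' @param object An `ul_category_model`.
#' @param newdata Metric table (data frame) or named numeric vector with
#'   the five final variables.
#' @param ... Unused.
#' @return Data frame with `subject_id` (when available), `category`
#'   (ordered factor) and one distance column per category.
#' @export
predict.ul_category_model <- function(object, newdata, ...) {
  if (is.numeric(newdata) && !is.matrix(newdata))
    newdata <- as.data.frame(as.list(newdata))
  vars <- object$variable_names
  if (!all(vars %in% names(newdata)))
    stop_ulperf("newdata lacks variables: ",
                paste(setdiff(vars, names(newdata)), collapse = ", "))
  x <- as.matrix(newdata[, vars, drop = FALSE])
  if (anyNA(x)) stop_ulperf("undefined variable among the 5 final variables")
  zx <- sweep(sweep(x, 2, object$scaler$means), 2, object$scaler$sds, "/")
  d2 <- outer(rowSums(zx^2), rowSums(object$centroids^2), "+") -
    2 * tcrossprod(zx, object$centroids)
  d <- sqrt(pmax(d2, 0))
  colnames(d) <- object$category_names
  assigned <- apply(d, 1, which.min)  # which.min -> lower-ordered on ties
  out <- data.frame(
    category = factor(object$category_names[assigned],
                      levels = object$category_names),
    round(d, 10), check.names = FALSE)
  if ("subject_id" %in% names(newdata))
    out <- cbind(subject_id = newdata$subject_id, out)
  rownames(out) <- NULL
  out
}

#' Convenience wrapper: classify one metric vector
#'
#' @param metrics Named numeric vector (or one-row data frame) with the
#'   five final variables.
#' @param model An `ul_category_model`.
#' @return List with `category` (character) and `distances` (named numeric).
#' @export
assign_category <- function(metrics, model) {
  pr <- predict(model, metrics)
  list(category = as.character(pr$category[1]),
       distances = unlist(pr[1, model$category_names]))
}

#' @export
print.ul_category_model <- function(x, ...) {
  cat("Upper-limb performance category model (5 variables, 5 categories)\n")
  cat(sprintf("Fitted on %d subjects; %.1f%% total variance explained\n",
              x$n, x$solution$pct_total_variance))
  cat("\nCentroids (original units):\n")
  print(round(x$centroids_raw, 2))
  invisible(x)
}

#' @export
summary.ul_category_model <- function(object, ...) {
  counts <- table(object$training_categories)
  out <- list(n = object$n, counts = counts,
              centroids_raw = object$centroids_raw,
              pct_total_variance = object$solution$pct_total_variance,
              silhouette = object$solution$silhouette)
  class(out) <- "summary.ul_category_model"
  out
}

#' @export
print.summary.ul_category_model <- function(x, ...) {
  cat(sprintf("5-category UL performance model, n = %d\n", x$n))
  cat(sprintf("Total variance explained: %.1f%%; mean silhouette %.3f\n",
              x$pct_total_variance, x$silhouette))
  cat("\nSubjects per category:\n"); print(x$counts)
  cat("\nCentroids (original units):\n"); print(round(x$centroids_raw, 2))
  invisible(x)
}

#' @export
coef.ul_category_model <- function(object, standardized = FALSE, ...) {
  if (standardized) object$centroids else object$centroids_raw
}

#' @export
fitted.ul_category_model <- function(object, ...) object$training_categories

#' Residual distances of the training subjects
#'
#' Euclidean distance (standardized space) from each training subject to
#' its assigned centroid.
#' @param object An `ul_category_model`.
#' @param ... Unused.
#' @export
residuals.ul_category_model <- function(object, ...) {
  if (is.null(object$training_z))
    stop_ulperf("training z-scores not stored in this model")
  ctr <- object$centroids[as.integer(object$training_categories), ,
                          drop = FALSE]
  sqrt(rowSums((object$training_z - ctr)^2))
}

#' Coxcomb chart of the category centroids
#'
#' @param x An `ul_category_model`.
#' @param category Which category to draw (index or name); default draws a
#'   panel per category.
#' @param ... Passed to [coxcomb_chart()].
#' @export
plot.ul_category_model <- function(x, category = NULL, ...) {
  rng <- apply(x$centroids, 2, range)
  mm <- data.frame(variable = colnames(x$centroids),
                   min = rng[1, ], max = rng[2, ])
  cats <- category %||% seq_len(5)
  if (length(cats) > 1) {
    op <- graphics::par(mfrow = c(2, 3), mar = c(1, 1, 2, 1))
    on.exit(graphics::par(op))
  }
  for (ci in cats) {
    coxcomb_chart(x$centroids[ci, ], mm,
                  main = rownames(x$centroids)[ci], ...)
  }
  invisible(x)
}

#' Cohort-by-category breakdown
#'
#' Contingency counts of cohort membership per category, plus the percent
#' concordant (dominant limb = paretic limb) among stroke subjects in each
#' category; the concordance denominator excludes controls.
#'
#' @param assignments Factor/character of category (or cluster) labels.
#' @param meta Metadata data frame aligned with `assignments` (see
#'   [read_meta_csv()]).
#' @return List with `counts` (category x cohort table) and
#'   `concordance` data frame (`n_stroke`, `n_concordant`, `pct_concordant`).
#' @export
cohort_breakdown <- function(assignments, meta) {
  if (length(assignments) != nrow(meta))
    stop_ulperf("assignments and meta not aligned")
  counts <- table(category = assignments, cohort = meta$cohort)
  cats <- rownames(counts)
  conc <- do.call(rbind, lapply(cats, function(cc) {
    sel <- assignments == cc & meta$cohort != "control"
    ns <- sum(sel); nc <- sum(meta$concordant[sel], na.rm = TRUE)
    data.frame(category = cc, n_stroke = ns, n_concordant = nc,
               pct_concordant = if (ns > 0) 100 * nc / ns else NA_real_)
  }))
  list(counts = counts, concordance = conc)
}

#' Serialize / restore a category model as JSON
#'
#' The JSON schema stores the variable names, scaler, ordered centroids,
#' category names and fit provenance; reading it back restores a model
#' whose predictions are identical.
#'
#' @param model An `ul_category_model`.
#' @param path JSON file path.
#' @return `write_category_model()` returns `path` invisibly;
#'   `read_category_model()` returns the model.
#' @export
write_category_model <- function(model, path) {
  obj <- list(
    variables = model$variable_names,
    scaler = list(means = unname(model$scaler$means),
                  sds = unname(model$scaler$sds)),
    centroids = unname(model$centroids),
    names = model$category_names,
    created = list(seed = model$seed, n = model$n,
                   date = format(Sys.Date())))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_category_model
#' @export
read_category_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  centroids <- matrix(as.numeric(obj$centroids), nrow = 5,
                      dimnames = list(obj$names, obj$variables))
  means <- stats::setNames(obj$scaler$means, obj$variables)
  sds <- stats::setNames(obj$scaler$sds, obj$variables)
  raw <- sweep(sweep(centroids, 2, sds, "*"), 2, means, "+")
  structure(list(variable_names = obj$variables,
                 scaler = list(means = means, sds = sds),
                 centroids = centroids, centroids_raw = raw,
                 category_names = obj$names,
                 composite_order = rowMeans(centroids),
                 n = obj$created$n, seed = obj$created$seed),
            class = "ul_category_model")
}
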