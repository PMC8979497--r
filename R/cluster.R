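# The analysis workflow on a metric table: z-score standardization, Hopkins
# clustering tendency, PCA, k-means over the variable-count x cluster-count
# ladder, and model-selection diagnostics (elbow / silhouette / gap,
# MANOVA-refit AIC).

#' Standardize a metric table to z-scores
#'
#' Each variable is centered and scaled by its sample mean and sample SD
#' (n-1 denominator); the scaler is retained so new subjects can be
#' projected into the same space.
#'
#' @param table Metric table (data frame with `subject_id` plus variables).
#' @param variable_subset Character vector of variable names to keep
#'   (default: every column except `subject_id`).
#' @return A `StandardizedMatrix`: list with `values` (subjects x variables
#'   z-score matrix), `means`, `sds`, `variable_names`.
#' @export
standardize <- function(table, variable_subset = NULL) {
  vars <- variable_subset %||% setdiff(names(table), "subject_id")
  missing_cols <- setdiff(vars, names(table))
  if (length(missing_cols))
    stop_ulperf("variables not in table: ", paste(missing_cols, collapse = ", "))
  x <- as.matrix(table[, vars, drop = FALSE])
  if (nrow(x) < 2) stop_ulperf("need at least 2 subjects")
  if (anyNA(x)) stop_ulperf("undefined values in subset columns")
  mu <- colMeans(x)
  sd_ <- apply(x, 2, stats::sd)
  if (any(sd_ == 0))
    stop_ulperf("zero-variance column: ",
                paste(vars[sd_ == 0], collapse = ", "))
  z <- sweep(sweep(x, 2, mu), 2, sd_, "/")
  rownames(z) <- if ("subject_id" %in% names(table)) table$subject_id
                 else rownames(table)
  structure(list(values = z, means = mu, sds = sd_, variable_names = vars),
            class = "StandardizedMatrix")
}

as_z_matrix <- function(z) {
  if (inherits(z, "StandardizedMatrix")) z$values else as.matrix(z)
}

#' Hopkins clustering-tendency statistic
#'
#' For each draw, `m = ceil(fraction * n)` data points and `m` uniform
#' points in the data bounding box are sampled; with `u` the
#' nearest-data-point distances of the uniform points and `w` the
#' nearest-other-data-point distances of the sampled data points,
#' `H = sum(u^d) / (sum(u^d) + sum(w^d))` (d = dimensionality). The mean
#' over draws is returned. Values near 0.5 indicate spatial randomness;
#' values above 0.5 indicate clusters exist.
#'
#' @param z A `StandardizedMatrix` or numeric matrix.
#' @param sample_fraction Fraction of points sampled per draw.
#' @param n_draws Number of draws averaged.
#' @param seed Optional RNG seed.
#' @return Hopkins statistic in (0, 1).
#' @export
hopkins_statistic <- function(z, sample_fraction = 0.1, n_draws = 100,
                              seed = NULL) {
  x <- as_z_matrix(z)
  n <- nrow(x); d <- ncol(x)
  if (n < 10) stop_ulperf("need at least 10 points")
  m <- ceiling(sample_fraction * n)
  if (m < 2) stop_ulperf("sample too small; raise sample_fraction")
  lo <- apply(x, 2, min); hi <- apply(x, 2, max)
  # squared distances from each row of `a` to each row of `b`
  cross_d2 <- function(a, b) {
    outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  }
  with_seed(seed, {
    mean(vapply(seq_len(n_draws), function(i) {
      idx <- sample.int(n, m)
      u_pts <- matrix(stats::runif(m * d, rep(lo, each = m),
                                   rep(hi, each = m)), m, d)
      u2 <- pmax(0, apply(cross_d2(u_pts, x), 1, min))
      dm <- cross_d2(x[idx, , drop = FALSE], x)
      dm[cbind(seq_len(m), idx)] <- Inf
      w2 <- pmax(0, apply(dm, 1, min))
      u_d <- sum(u2^(d / 2)); w_d <- sum(w2^(d / 2))
      u_d / (u_d + w_d)
    }, numeric(1)))
  })
}

#' Principal component analysis of a standardized matrix
#'
#' Eigendecomposition of the correlation matrix (the covariance of z-scored
#' input). Loadings carry a deterministic sign convention: the
#' largest-magnitude loading of each component is positive.
#'
#' @param z A `StandardizedMatrix`.
#' @return A `PCAResult`: list with `loadings` (variables x components),
#'   `eigenvalues`, `pct_variance` (percent per component), `scores`.
#' @export
ul_pca <- function(z) {
  x <- as_z_matrix(z)
  if (nrow(x) <= ncol(x)) stop_ulperf("need more subjects than variables")
  ev <- eigen(stats::cov(x), symmetric = TRUE)
  vals <- pmax(ev$values, 0)
  load <- ev$vectors
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  dimnames(load) <- list(colnames(x), paste0("PC", seq_len(ncol(load))))
  structure(list(loadings = load, eigenvalues = vals,
                 pct_variance = 100 * vals / sum(vals),
                 scores = x %*% load),
            class = "PCAResult")
}

# k-means++ seeding: first center uniform, later centers sampled with
# probability proportional to squared distance to the nearest chosen center.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (all(d2 == 0)) {
      centers[j, ] <- x[sample.int(n, 1), ]
    } else {
      centers[j, ] <- x[sample.int(n, 1, prob = d2), ]
    }
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
  }
  centers
}

#' Fit k-means in standardized space
#'
#' Best (lowest within-cluster sum of squares) of `n_restarts` Lloyd runs
#' with k-means++ initialization, Euclidean distance. Additional starting
#' centroid matrices can be supplied (`extra_inits`), which the nested
#' model ladder uses to warm-start k from the k-1 solution so that WSS is
#' non-increasing in k.
#'
#' @param z A `StandardizedMatrix` or numeric matrix.
#' @param k Number of clusters.
#' @param n_restarts Number of k-means++ restarts.
#' @param seed Optional RNG seed (full determinism given seed).
#' @param extra_inits Optional list of k x q starting centroid matrices.
#' @return A `ClusterSolution`: list with `k`, `assignments`, `centroids`,
#'   `wss`, `bss`, `tss`, `pct_total_variance` (100 * bss / tss),
#'   `silhouette` (mean width, `NA` for k = 1), `seed`, `n_restarts`.
#' @export
kmeans_fit <- function(z, k, n_restarts = 25, seed = NULL,
                       extra_inits = list()) {
  x <- as_z_matrix(z)
  n <- nrow(x)
  if (k > n) stop_ulperf("k exceeds number of subjects")
  run_one <- function(centers) {
    for (attempt in 1:5) {
      fit <- tryCatch(
        suppressWarnings(stats::kmeans(x, centers = centers, iter.max = 300,
                                       algorithm = "Lloyd")),
        error = function(e) NULL)
      if (!is.null(fit) && all(fit$size > 0)) return(fit)
      centers <- kmeanspp_init(x, k)  # re-seed on empty cluster
    }
    stop_ulperf("persistent empty cluster for k = ", k)
  }
  best <- with_seed(seed, {
    inits <- c(extra_inits, lapply(seq_len(n_restarts),
                                   function(i) kmeanspp_init(x, k)))
    fits <- lapply(inits, run_one)
    fits[[which.min(vapply(fits, function(f) f$tot.withinss, numeric(1)))]]
  })
  sil <- if (k >= 2 && k < n) {
    mean(cluster::silhouette(best$cluster, stats::dist(x))[, "sil_width"])
  } else NA_real_  # undefined for k = 1 and for all-singleton partitions
  structure(list(k = k, assignments = best$cluster, centroids = best$centers,
                 wss = best$tot.withinss, bss = best$betweenss,
                 tss = best$totss,
                 pct_total_variance = 100 * best$betweenss / best$totss,
                 silhouette = sil, seed = seed, n_restarts = n_restarts),
            class = "ClusterSolution")
}

#' @export
print.ClusterSolution <- function(x, ...) {
  cat(sprintf(
    "k-means solution: k = %d, %.1f%% total variance explained, sizes %s\n",
    x$k, x$pct_total_variance,
    paste(tabulate(x$assignments, x$k), collapse = "/")))
  invisible(x)
}

# Warm start for k from a (k-1)-cluster solution: previous centroids plus
# the point farthest from its assigned centroid. Guarantees WSS(k) <= WSS(k-1).
warm_start <- function(x, prev) {
  d2 <- rowSums((x - prev$centroids[prev$assignments, , drop = FALSE])^2)
  rbind(prev$centroids, x[which.max(d2), ])
}

#' Cluster-count diagnostics: elbow, silhouette, gap
#'
#' For each k in `k_range`: the within-cluster sum of squares (elbow
#' curve, guaranteed non-increasing via nested warm starts), the mean
#' silhouette width (k >= 2), and the gap statistic with its standard
#' error. The gap reference distribution is uniform in the principal
#' component-aligned bounding box of the data, with `gap_refs` reference
#' sets; the selection rule is the smallest k whose gap is within one
#' standard error of the next k's gap.
#'
#' @param z A `StandardizedMatrix` or numeric matrix.
#' @param k_range Integer vector of cluster counts (from 1).
#' @param gap_refs Number of reference sets for the gap statistic.
#' @param n_restarts Restarts per k-means fit.
#' @param seed Optional RNG seed.
#' @return Data frame with columns `k`, `wss`, `silhouette`, `gap`,
#'   `gap_se`; attributes `k_gap` (gap rule) and `k_silhouette` (max mean
#'   width).
#' @export
choose_k_diagnostics <- function(z, k_range = 1:10, gap_refs = 50,
                                 n_restarts = 25, seed = NULL) {
  x <- as_z_matrix(z)
  if (max(k_range) > nrow(x) / 2) stop_ulperf("max k exceeds n/2")
  seeds <- derive_seeds(seed %||% sample.int(1e6, 1), 2)
  fits <- list()
  prev <- NULL
  for (k in sort(k_range)) {
    extra <- if (!is.null(prev) && prev$k == k - 1L)
      list(warm_start(x, prev)) else list()
    fits[[as.character(k)]] <- kmeans_fit(x, k, n_restarts, seeds[1] + k,
                                          extra_inits = extra)
    prev <- fits[[as.character(k)]]
  }
  gap <- with_seed(seeds[2], {
    cluster::clusGap(x, FUNcluster = function(xx, kk) {
      list(cluster = kmeans_fit(xx, kk, n_restarts = 10)$assignments)
    }, K.max = max(k_range), B = gap_refs, spaceH0 = "scaledPCA",
    verbose = FALSE)
  })
  tab <- gap$Tab[sort(k_range), , drop = FALSE]
  out <- data.frame(
    k = sort(k_range),
    wss = vapply(fits, function(f) f$wss, numeric(1)),
    silhouette = vapply(fits, function(f) f$silhouette, numeric(1)),
    gap = tab[, "gap"], gap_se = tab[, "SE.sim"])
  attr(out, "k_gap") <- cluster::maxSE(out$gap, out$gap_se,
                                       method = "Tibs2001SEmax")
  sil_ok <- which(!is.na(out$silhouette))
  attr(out, "k_silhouette") <- out$k[sil_ok[which.max(out$silhouette[sil_ok])]]
  out
}

#' MANOVA-style refit of a cluster classification, with AIC
#'
#' Refits the cluster labels as a multivariate Gaussian model with
#' cluster-specific mean vectors and one pooled full residual covariance
#' (maximum-likelihood estimate, stabilized by a 1e-6 ridge on the
#' diagonal). The parameter count is `k*q + q*(q+1)/2` and
#' `AIC = -2*loglik + 2*n_params`, so solutions with more clusters or more
#' variables pay an explicit complexity penalty.
#'
#' @param z A `StandardizedMatrix` or numeric matrix.
#' @param assignments Integer cluster labels, one per row.
#' @return List with `loglik`, `n_params`, `aic`.
#' @export
manova_refit_aic <- function(z, assignments) {
  x <- as_z_matrix(z)
  n <- nrow(x); q <- ncol(x)
  labs <- sort(unique(assignments))
  if (length(assignments) != n) stop_ulperf("assignments length mismatch")
  if (any(tabulate(match(assignments, labs)) == 0))
    stop_ulperf("every cluster must be nonempty")
  W <- matrix(0, q, q)
  for (g in labs) {
    xi <- x[assignments == g, , drop = FALSE]
    W <- W + crossprod(sweep(xi, 2, colMeans(xi)))
  }
  sigma <- W / n + diag(1e-6, q)
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch))
    stop_ulperf("singular pooled covariance; drop collinear variables")
  logdet <- 2 * sum(log(diag(ch)))
  tr <- sum(diag(chol2inv(ch) %*% W))
  loglik <- -n / 2 * (q * log(2 * pi) + logdet) - tr / 2
  n_params <- length(labs) * q + q * (q + 1) / 2
  list(loglik = loglik, n_params = n_params,
       aic = -2 * loglik + 2 * n_params)
}

#' Run the variable-count x cluster-count model ladder
#'
#' Fits all 12 solutions (variable sets of 12, 9, 7, 5 crossed with 3, 4,
#' 5 clusters). For each variable set it reports the PCA variance shares of
#' the first two components and, per cluster count, the percent total
#' variance explained (100 * BSS / TSS) and the MANOVA-refit AIC. Within a
#' variable set the k = 4 and k = 5 fits are warm-started from the previous
#' k, so total variance explained is non-decreasing in k.
#'
#' @param table Metric table with all 12 canonical variables defined.
#' @param k_values Cluster counts (default 3:5).
#' @param n_restarts Restarts per fit.
#' @param seed Optional RNG seed.
#' @return A `LadderResult` data frame with one row per (n_vars, k):
#'   columns `n_vars`, `k`, `pc1_pct`, `pc2_pct`, `pct_total_variance`,
#'   `aic`. The fitted `ClusterSolution`s are attached as attribute
#'   `solutions` (named `"<n_vars>_<k>"`).
#' @export
run_model_ladder <- function(table, k_values = 3:5, n_restarts = 25,
                             seed = NULL) {
  seeds <- derive_seeds(seed %||% sample.int(1e6, 1), 4)
  rows <- list(); sols <- list()
  for (i in seq_along(c(12, 9, 7, 5))) {
    nv <- c(12, 9, 7, 5)[i]
    vars <- ul_variable_names(nv)
    if (!all(vars %in% names(table)))
      stop_ulperf("ladder needs all 12 canonical variables")
    z <- standardize(table, vars)
    p <- ul_pca(z)
    prev <- NULL
    for (k in sort(k_values)) {
      extra <- if (!is.null(prev) && prev$k == k - 1L)
        list(warm_start(z$values, prev)) else list()
      sol <- kmeans_fit(z, k, n_restarts, seed = seeds[i] + k,
                        extra_inits = extra)
      fit <- manova_refit_aic(z, sol$assignments)
      rows[[length(rows) + 1L]] <- data.frame(
        n_vars = nv, k = k, pc1_pct = p$pct_variance[1],
        pc2_pct = p$pct_variance[2],
        pct_total_variance = sol$pct_total_variance, aic = fit$aic)
      sols[[paste0(nv, "_", k)]] <- sol
      prev <- sol
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "solutions") <- sols
  class(out) <- c("LadderResult", "data.frame")
  out
}
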