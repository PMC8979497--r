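test_that("category model orders centroids by content, not input labels", {
  co <- cached_cohort(seed = 1)
  z <- standardize(co$tab, ul_variable_names(5))
  sol <- kmeans_fit(z, 5, seed = 42)
  m1 <- build_category_model(z, sol)

  # relabel the clusters arbitrarily: identical model
  perm <- c(3, 5, 1, 2, 4)
  sol2 <- sol
  sol2$assignments <- perm[sol$assignments]
  sol2$centroids <- sol$centroids[order(perm), , drop = FALSE]
  m2 <- build_category_model(z, sol2)
  expect_equal(m1$centroids, m2$centroids, ignore_attr = TRUE)
  expect_equal(m1$training_categories, m2$training_categories)

  expect_equal(m1$category_names, ul_category_names())
  expect_true(all(diff(m1$composite_order) > 0))
  sol3 <- kmeans_fit(z, 3, seed = 1)
  expect_error(build_category_model(z, sol3), "k = 5")
})

test_that("back-transformed centroids approximate the archetype means", {
  co <- cached_cohort(seed = 1)
  fit <- ul_category_model(co$tab, seed = 42)
  raw <- coef(fit)
  arch <- ul_archetypes()
  # highest category: paretic hours near 10.2, use ratio near 0.96
  expect_equal(raw["High Activity/Full Integration", "hours_p"],
               arch$target_hours_p[5], tolerance = 0.1)
  expect_equal(raw["Minimal Activity/Rare Integration", "use_ratio"],
               arch$target_use_ratio[1], tolerance = 0.1)
  # monotone composite: every variable increases from category 1 to 5
  expect_true(all(raw[5, ] > raw[1, ]))
})

test_that("nearest-centroid assignment is exact, tied-down and idempotent", {
  co <- cached_cohort(seed = 1)
  fit <- ul_category_model(co$tab, seed = 42)

  # a subject exactly at a back-transformed centroid: distance 0
  x <- as.data.frame(as.list(coef(fit)[3, ]))
  pr <- predict(fit, x)
  expect_equal(as.character(pr$category), ul_category_names()[3])
  expect_equal(pr[[ul_category_names()[3]]], 0, tolerance = 1e-9)

  # training assignments are reproduced by nearest-centroid classification
  pr_train <- predict(fit, co$tab)
  expect_equal(as.character(pr_train$category),
               as.character(fit$training_categories))
  # and prediction is idempotent/deterministic
  expect_identical(predict(fit, co$tab), pr_train)

  expect_error(predict(fit, co$tab[, 1:3]), "lacks variables")
  xna <- x; xna$use_ratio <- NA
  expect_error(predict(fit, xna), "undefined")
})

test_that("exact midpoint between categories resolves to the lower one", {
  f <- withr::local_tempfile(fileext = ".json")
  obj <- list(variables = letters[1:5],
              scaler = list(means = rep(0, 5), sds = rep(1, 5)),
              centroids = lapply(0:4, function(i) as.list(rep(i, 5))),
              names = ul_category_names(),
              created = list(seed = 1, n = 10, date = "2026-01-01"))
  jsonlite::write_json(obj, f, auto_unbox = TRUE, digits = NA)
  m <- read_category_model(f)
  mid <- as.data.frame(as.list(setNames(rep(0.5, 5), letters[1:5])))
  expect_equal(as.character(predict(m, mid)$category),
               ul_category_names()[1])
})

test_that("JSON serialization round-trips the frozen model", {
  co <- cached_cohort(seed = 1)
  fit <- ul_category_model(co$tab, seed = 42)
  f <- withr::local_tempfile(fileext = ".json")
  write_category_model(fit, f)
  fit2 <- read_category_model(f)
  expect_equal(fit2$centroids, fit$centroids)
  expect_equal(fit2$scaler$means, fit$scaler$means)
  p1 <- predict(fit, co$tab); p2 <- predict(fit2, co$tab)
  expect_identical(p1$category, p2$category)
  expect_equal(p1[, -(1:2)], p2[, -(1:2)], tolerance = 1e-12)
})

test_that("fresh archetype draws classify into their generating category", {
  co <- cached_cohort(seed = 1)
  fit <- ul_category_model(co$tab, seed = 42)
  arch <- ul_archetypes()
  acc <- vapply(1:5, function(a) {
    hits <- vapply(1:30, function(j) {
      sub <- generate_epoch_subject(arch[a, ], seed = 50000 + a * 100 + j)
      m <- compute_all_metrics(sub$series)
      as.character(predict(fit, as.data.frame(as.list(m)))$category) ==
        ul_category_names()[a]
    }, logical(1))
    mean(hits)
  }, numeric(1))
  expect_true(all(acc >= 0.9))
})

test_that("cohort breakdown conserves counts and excludes controls from
           the concordance denominator", {
  co <- cached_cohort(seed = 1)
  fit <- ul_category_model(co$tab, seed = 42)
  bd <- cohort_breakdown(as.character(fit$training_categories), co$sim$meta)
  expect_equal(sum(bd$counts), 211)
  expect_equal(sum(bd$concordance$n_stroke), sum(co$sim$meta$cohort != "control"))
  # denominators never include controls
  for (i in seq_len(nrow(bd$concordance))) {
    cc <- bd$concordance$category[i]
    expect_equal(bd$concordance$n_stroke[i],
                 sum(fit$training_categories == cc &
                       co$sim$meta$cohort != "control"))
  }
  # single-cohort degenerate case
  n <- 6
  meta1 <- data.frame(subject_id = as.character(1:n), cohort = "control",
                      paretic_side = NA, dominant_side = "right",
                      arat = NA, concordant = NA)
  bd1 <- cohort_breakdown(rep("A", n), meta1)
  expect_equal(unname(as.vector(bd1$counts)), n)
  expect_true(is.na(bd1$concordance$pct_concordant[1]))
})
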