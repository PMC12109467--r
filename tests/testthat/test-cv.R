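test_that("exhaustive split enumeration is complete and disjoint", {
  splits <- enumerate_splits(11, "ltocv")
  expect_length(splits, 55)
  for (sp in splits) {
    expect_length(intersect(sp$train, sp$validation), 0)
    expect_setequal(c(sp$train, sp$validation), 1:11)
  }
  # every item is held out in exactly n-1 = 10 pairs
  held <- table(unlist(lapply(splits, `[[`, "validation")))
  expect_true(all(held == 10))

  expect_length(enumerate_splits(11, "loocv"), 11)
  expect_length(enumerate_splits(5, "ltocv"), 10) # brute-force C(5,2)
  expect_length(enumerate_splits(3, "ltocv"), 3)
  expect_error(enumerate_splits(2, "ltocv"), "at least 3")
})

test_that("ZeroR baseline pools training-majority predictions", {
  labels <- c(rep("NO", 8), rep("YES", 3))
  expect_equal(zeror_baseline(labels, "ltocv"), 80 / 110)
  expect_equal(zeror_baseline(labels, "loocv"), 8 / 11)
  expect_equal(as_percent(zeror_baseline(labels, "ltocv")), 72.7)
  expect_equal(zeror_baseline(rep("NO", 5), "ltocv"), 1)
  expect_equal(zeror_baseline(rep("YES", 5), "loocv"), 1)
})

test_that("KNN prediction follows distances and explicit tie rules", {
  tr <- data.frame(x = c(0, 1, 2, 10, 11))
  y <- c("NO", "NO", "NO", "YES", "YES")
  # hand-computed: neighbors of 9 at k=3 are {10, 11, 2} -> YES majority
  expect_equal(knn_predict(tr, y, data.frame(x = 9), k = 3, rescale = "none"),
               "YES")
  # query on a training row at k=1 returns that row's label
  expect_equal(knn_predict(tr, y, data.frame(x = 10), k = 1, rescale = "none"),
               "YES")
  # k = n reduces to the majority vote regardless of the query
  expect_equal(knn_predict(tr, y, data.frame(x = 100), k = 5, rescale = "none"),
               "NO")
  # vote tie at k = 2 (neighbors 10:YES at 3.8 and 2:NO at 4.2):
  # majority rule -> NO; nearest rule -> closest label -> YES
  q <- data.frame(x = 6.2)
  expect_equal(knn_predict(tr, y, q, k = 2, rescale = "none", tie = "majority"),
               "NO")
  expect_equal(knn_predict(tr, y, q, k = 2, rescale = "none", tie = "nearest"),
               "YES")
  # distance tie: equidistant neighbors resolved by training row order
  tr2 <- data.frame(x = c(-1, 1))
  expect_equal(knn_predict(tr2, c("YES", "NO"), data.frame(x = 0), k = 1,
                           rescale = "none"), "YES")
  expect_error(knn_predict(tr[0, , drop = FALSE], character(0),
                           data.frame(x = 1), k = 1), "empty")
  expect_error(knn_predict(tr, y, q, k = 6), "k must be")
})

test_that("KNN agrees with an independent implementation when ties are absent", {
  cohort <- generate_cohort(n_no = 20, n_yes = 15, cov = 4, seed = 9)
  tr <- cohort[1:25, harmonic_variables()[1:3]]
  q <- cohort[26:35, harmonic_variables()[1:3]]
  ours <- unname(knn_predict(tr, cohort$outcome[1:25], q, k = 1,
                             rescale = "none"))
  ref <- as.character(class::knn(tr, q, cl = cohort$outcome[1:25], k = 1))
  expect_equal(ours, ref)
})

test_that("PCA captures collinear structure and is rotation-stable", {
  # points on a line in 3D: one component explains everything
  t <- seq(-2, 2, length.out = 9)
  x <- cbind(t, 2 * t, -t) + 5
  pm <- fit_pca(x, 2)
  ev <- pm$prcomp$sdev^2
  expect_equal(ev[1] / sum(ev), 1, tolerance = 1e-10)

  # rotating a 2D cloud leaves the explained variance spectrum unchanged
  set.seed(11)
  cloud <- cbind(rnorm(30, sd = 3), rnorm(30, sd = 1))
  theta <- 0.7
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
  s1 <- fit_pca(cloud, 2, scale = FALSE)$prcomp$sdev
  s2 <- fit_pca(cloud %*% rot, 2, scale = FALSE)$prcomp$sdev
  expect_equal(s1, s2, tolerance = 1e-10)

  # the training center maps to the origin
  ctr <- matrix(colMeans(x), 1)
  expect_equal(as.numeric(predict(pm, ctr)), c(0, 0), tolerance = 1e-10)

  expect_error(fit_pca(x[1:2, ], 2), "more training rows")
  x0 <- x; x0[, 2] <- 7
  expect_warning(fit_pca(x0, 2), "zero-variance")
})

test_that("the cohort PCA plane groups thrombosis with HW-B and HW-G", {
  prof <- cohort_profiles()
  pm <- fit_pca(prof[, c("P_FF", "P_2H", "P_3H")], 2)
  z <- predict(pm, prof[, c("P_FF", "P_2H", "P_3H")])
  cluster <- prof$patient_id %in%
    c("HW-B", "HW-G", prof$patient_id[prof$outcome == "YES"])
  # each clustered recording's nearest neighbor is another cluster member
  for (i in which(cluster)) {
    d <- sqrt(rowSums((z - matrix(z[i, ], nrow(z), 2, byrow = TRUE))^2))
    d[i] <- Inf
    expect_true(cluster[which.min(d)])
  }
})

test_that("fold-embedded PCA never sees the validation rows", {
  prof <- cohort_profiles()
  vars <- c("P_FF", "P_2H", "P_3H")
  sp <- enumerate_splits(11, "ltocv")[[4]]
  fit_train <- fit_pca(prof[sp$train, vars], 2)
  fit_all <- fit_pca(prof[, vars], 2)
  va <- prof[sp$validation, vars]
  # leakage detector: all-rows fit produces different validation coordinates
  expect_false(isTRUE(all.equal(abs(predict(fit_train, va)),
                                abs(predict(fit_all, va)))))
})

test_that("metric identities hold for the pooled confusion matrices", {
  m <- compute_metrics(c(tp = 30, fp = 2, fn = 0, tn = 78))
  expect_equal(as_percent(m$accuracy), 98.2)
  expect_equal(as_percent(m$precision), 93.8)
  expect_equal(as_percent(m$recall), 100)
  expect_equal(as_percent(m$f1), 96.8)

  m <- compute_metrics(c(tp = 18, fp = 2, fn = 12, tn = 78))
  expect_equal(as_percent(m$accuracy), 87.3)
  expect_equal(as_percent(m$precision), 90)
  expect_equal(as_percent(m$recall), 60)
  expect_equal(as_percent(m$f1), 72)
  expect_equal(m$f1, 2 * m$precision * m$recall / (m$precision + m$recall))

  m <- compute_metrics(c(tp = 0, fp = 0, fn = 0, tn = 10))
  expect_equal(m$accuracy, 1)
  expect_true(is.na(m$precision))
  expect_true(is.na(m$f1))
  expect_error(compute_metrics(c(tp = 0, fp = 0, fn = 0, tn = 0)), "empty")
})

test_that("run bookkeeping pools the right number of predictions", {
  prof <- cohort_profiles()
  r <- run_cv(prof, c("P_FF", "P_2H"))
  expect_equal(sum(r$confusion), 110)
  expect_true(all(table(r$predictions$patient_id) == 10))
  r <- run_cv(prof, c("P_FF", "P_2H"), scheme = "loocv")
  expect_equal(sum(r$confusion), 11)
  expect_true(all(table(r$predictions$patient_id) == 1))
})

test_that("KNN with k = n_training reproduces the ZeroR baseline", {
  prof <- cohort_profiles()
  r <- run_cv(prof, c("P_FF", "P_2H", "P_3H"), k = 9, tie = "majority")
  expect_equal(r$metrics$accuracy, zeror_baseline(prof$outcome, "ltocv"))
})

test_that("identical runs are identical, including stochastic classifiers", {
  prof <- cohort_profiles()
  a <- run_cv(prof, c("P_FF", "P_2H", "P_3H"))
  b <- run_cv(prof, c("P_FF", "P_2H", "P_3H"))
  expect_identical(a$confusion, b$confusion)
  expect_identical(a$predictions, b$predictions)
  a <- run_cv(prof, c("P_FF", "P_2H"), algorithm = "random_forest",
              seed = 123, repeats = 5)
  b <- run_cv(prof, c("P_FF", "P_2H"), algorithm = "random_forest",
              seed = 123, repeats = 5)
  expect_identical(a$confusion, b$confusion)
})

test_that("non-KNN classifiers run through the same protocol", {
  cohort <- generate_cohort(n_no = 8, n_yes = 6, mean_no = c(0, 0),
                            mean_yes = c(12, 12), cov = 0.5, seed = 4)
  for (alg in c("logistic_regression", "svm", "naive_bayes")) {
    r <- run_cv(cohort, harmonic_variables()[1:2], algorithm = alg)
    expect_equal(sum(r$confusion), 2 * choose(14, 2))
    expect_gt(r$metrics$accuracy, 0.9)
  }
  r <- run_cv(cohort, harmonic_variables()[1:2], algorithm = "random_forest",
              repeats = 3)
  expect_gt(r$metrics$accuracy, 0.9)
  r <- run_cv(cohort, harmonic_variables()[1:2],
              algorithm = "gradient_boosted_trees", repeats = 3)
  expect_gt(r$metrics$accuracy, 0.9)
})

test_that("perfectly separated point-mass classes classify perfectly", {
  cohort <- generate_cohort(n_no = 6, n_yes = 5, mean_no = c(-30, -40),
                            mean_yes = c(-5, -10), cov = 0, seed = 2)
  r <- run_cv(cohort, harmonic_variables()[1:2], k = 1)
  expect_equal(r$metrics$accuracy, 1)
})

test_that("grid runs cover combinations and gate PCA on baseline", {
  prof <- cohort_profiles()
  vsets <- list(c("P_FF", "P_2H"), c("P_FF", "P_4H"), c("P_2H", "P_3H"))
  runs <- run_grid(prof, vsets, algorithms = c("knn", "logistic_regression"),
                   pca_modes = "none")
  expect_length(runs, 6)

  runs <- run_grid(prof, vsets, algorithms = "knn",
                   pca_modes = c("none", "2d"), gate_pca = TRUE)
  s <- summarize_runs(runs)
  plain <- s[s$pca == "none", ]
  pca <- s[s$pca == "2d", ]
  # a PCA run exists exactly for the plain runs that beat baseline
  expect_setequal(pca$variables, plain$variables[plain$exceeds_baseline])
})
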