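test_that("class encoding is a one-hot bijection in first-appearance order", {
  labels <- c("Spain", "Italy", "Turkey", "Spain")
  enc <- encode_classes(labels)
  expect_identical(enc$class_order, c("Spain", "Italy", "Turkey"))
  expect_equal(unname(enc$Y),
               rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 0, 0)))
  expect_true(all(rowSums(enc$Y) == 1))
  expect_identical(decode_classes(enc$Y, enc$class_order), labels)
  expect_error(encode_classes(c("a", "a")), "at least 2 classes")
})

test_that("the first NIPALS weight vector is proportional to X'y for a
           single response", {
  set.seed(4)
  X <- matrix(rnorm(20 * 6), 20, 6)
  y <- matrix(rnorm(20), 20, 1)
  m <- fit_plsda(X, y, n_lv = 1)
  w_direct <- crossprod(scale(X, scale = FALSE), scale(y, scale = FALSE))
  cosine <- abs(sum(m$weights[, 1] * w_direct)) /
    sqrt(sum(m$weights[, 1]^2) * sum(w_direct^2))
  expect_equal(cosine, 1, tolerance = 1e-10)
})

test_that("PLS with maximal components matches least squares at full rank", {
  set.seed(10)
  for (rep in 1:3) {
    X <- matrix(rnorm(25 * 6), 25, 6)
    B0 <- matrix(rnorm(6 * 3), 6, 3)
    Y <- X %*% B0
    m <- fit_plsda(X, Y, n_lv = 6)
    pred <- predict_class(m, X)$scores
    # independent oracle: pseudo-inverse least squares on centered data
    Xc <- scale(X, scale = FALSE); Yc <- scale(Y, scale = FALSE)
    B_ls <- MASS::ginv(Xc) %*% Yc
    pred_ls <- sweep(Xc %*% B_ls, 2, colMeans(Y), "+")
    expect_equal(pred, pred_ls, tolerance = 1e-6, ignore_attr = TRUE)
    expect_equal(pred, Y, tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("NIPALS score vectors are mutually orthogonal", {
  set.seed(14)
  X <- matrix(rnorm(30 * 15), 30, 15)
  Y <- encode_classes(rep(c("a", "b", "c"), 10))$Y
  m <- fit_plsda(X, Y, n_lv = 6)
  G <- crossprod(m$scores)
  offdiag <- abs(G[upper.tri(G)])
  norms <- sqrt(diag(G))
  expect_true(all(offdiag <= 1e-6 * tcrossprod(norms)[upper.tri(G)]))
  # columns of W are unit norm
  expect_equal(unname(colSums(m$weights^2)), rep(1, 6), tolerance = 1e-10)
})

test_that("fitting is equivariant under row permutation", {
  set.seed(6)
  X <- matrix(rnorm(18 * 5), 18, 5)
  y <- rep(c("a", "b", "c"), 6)
  m1 <- fit_plsda(X, y, n_lv = 3)
  perm <- sample(18)
  m2 <- fit_plsda(X[perm, ], y[perm], n_lv = 3)
  # class_order follows first appearance, so align columns before comparing
  expect_equal(m1$coefficients,
               m2$coefficients[, m1$class_order, drop = FALSE],
               tolerance = 1e-10)
})

test_that("prediction interpolates separable training data and breaks ties
           toward the earlier class", {
  s <- make_separable_set(n_per_class = 8, seed = 2)
  m <- fit_plsda(s$od, s$meta$class_label, n_lv = 4)
  pred <- predict_class(m, s$od)
  expect_identical(pred$class, s$meta$class_label)
  # argmax matches a brute-force per-row scan
  expect_identical(pred$class,
                   m$class_order[apply(pred$scores, 1, which.max)])
  # a row at the training mean scores exactly the class proportions:
  # balanced classes tie, and the first class in class_order wins
  at_mean <- predict_class(m, matrix(m$x_mean, 1))
  expect_equal(unname(at_mean$scores[1, ]), rep(1 / 3, 3), tolerance = 1e-8)
  expect_identical(at_mean$class, m$class_order[1])
  expect_error(predict_class(m, s$od[, 1:4]), "columns")
})

test_that("truncated coefficients reproduce a model fitted with fewer LVs", {
  set.seed(12)
  X <- matrix(rnorm(24 * 9), 24, 9)
  y <- rep(c("a", "b", "c"), 8)
  m_full <- fit_plsda(X, y, n_lv = 6)
  m_small <- fit_plsda(X, y, n_lv = 2)
  expect_equal(plsda_coefficients(m_full, 2), m_small$coefficients,
               tolerance = 1e-8)
})

test_that("PLS-DA agrees with an independent reference implementation", {
  set.seed(7)
  X <- matrix(rnorm(30 * 12), 30, 12,
              dimnames = list(NULL, paste0("v", 1:12)))
  y <- rep(c("a", "b", "c"), each = 10)
  X[y == "a", 1] <- X[y == "a", 1] + 2
  X[y == "b", 2] <- X[y == "b", 2] + 2
  m1 <- fit_plsda(X, y, n_lv = 3)
  m2 <- mixOmics::plsda(X, factor(y), ncomp = 3, scale = FALSE)
  for (a in 1:3) {
    cosine <- abs(sum(m1$weights[, a] * m2$loadings$X[, a])) /
      sqrt(sum(m1$weights[, a]^2) * sum(m2$loadings$X[, a]^2))
    expect_equal(cosine, 1, tolerance = 1e-6)
  }
  p2 <- predict(m2, X, dist = "max.dist")
  expect_identical(predict_class(m1, X)$class,
                   unname(p2$class$max.dist[, 3]))
})

test_that("stratified folds preserve class counts within one and reject
           too-small classes", {
  set.seed(3)
  labels <- rep(c("a", "b", "c"), times = c(20, 17, 23))
  fold <- platespec:::stratified_folds(labels, k = 5)
  for (cl in unique(labels)) {
    counts <- table(fold[labels == cl])
    expect_lte(max(counts) - min(counts), 1)
    expect_length(counts, 5)
  }
  expect_error(platespec:::stratified_folds(rep(c("a", "b"), c(3, 20)), 5),
               "cannot stratify")
})

test_that("cross-validation is seed-reproducible and perfect on separable
           data", {
  s <- make_separable_set(n_per_class = 10, seed = 5, noise_sd = 0.01)
  cfg <- cv_config(k = 5, repeats = 3, seed = 99, lv_grid = 1:4)
  r1 <- cross_validate(s, cfg, steps = "raw")
  r2 <- cross_validate(s, cfg, steps = "raw")
  expect_identical(r1$per_repeat_accuracy, r2$per_repeat_accuracy)
  expect_identical(r1$confusion, r2$confusion)
  # widely separated classes, low noise: perfect from 2 LVs on
  expect_true(all(r1$accuracy_by_lv[c("lv2", "lv3", "lv4")] == 1))
  # confusion row sums = per-class test counts over folds and repeats
  expect_equal(unname(rowSums(r1$confusion)), rep(10 * 3, 3))
})

test_that("grouped cross-validation keeps replicates together and errors
           when a class has fewer groups than folds", {
  gen <- generate_evoo_set(synthetic_config(seed = 1))
  s <- trim_band(cap_overflow(gen$set))
  # 4 brands per class cannot be split into 5 folds at sample grouping
  expect_error(
    cross_validate(s, cv_config(k = 5, repeats = 1, group_by = "sample",
                                lv_grid = 1:2)),
    "cannot stratify")
  r <- cross_validate(s, cv_config(k = 4, repeats = 1, seed = 7,
                                   group_by = "sample", lv_grid = 1:3))
  expect_true(all(r$accuracy_by_lv >= 0 & r$accuracy_by_lv <= 1))
})

test_that("label permutation drives accuracy to chance level", {
  # accuracies within one permutation are correlated, so the null is
  # averaged over independent permutations and the SE taken across them
  s0 <- make_separable_set(n_per_class = 20, seed = 5, noise_sd = 0.01)
  set.seed(1234)
  acc <- vapply(1:10, function(i) {
    s <- s0
    s$meta$class_label <- sample(s0$meta$class_label)
    r <- suppressWarnings(cross_validate(
      s, cv_config(k = 5, repeats = 1, seed = i, lv_grid = 2),
      steps = "raw"))
    mean(r$per_repeat_accuracy)
  }, 0)
  se <- stats::sd(acc) / sqrt(length(acc))
  expect_lt(abs(mean(acc) - 1 / 3), 3 * se)
})

test_that("select_n_lv picks the smallest count within tolerance of the
           best accuracy", {
  res <- list(accuracy_by_lv = c(0.70, 0.90, 0.95, 0.979, 0.98, 0.98),
              lv_grid = 1:6)
  expect_equal(select_n_lv(res, tolerance = 0.01), 4)
  expect_equal(select_n_lv(list(accuracy_by_lv = rep(0.9, 4),
                                lv_grid = 2:5)), 2)
  expect_equal(select_n_lv(list(accuracy_by_lv = 0.8, lv_grid = 7)), 7)
})

test_that("CV export writes the accuracy table and full JSON detail", {
  s <- make_separable_set(n_per_class = 6, seed = 8)
  r <- cross_validate(s, cv_config(k = 3, repeats = 2, seed = 5,
                                   lv_grid = 1:2), steps = "raw")
  dir <- withr::local_tempdir()
  paths <- export_cv(r, dir)
  expect_true(all(file.exists(paths)))
  tab <- utils::read.csv(paths[1])
  expect_identical(names(tab), c("lv", "mean_accuracy", "sd"))
  js <- jsonlite::read_json(paths[2], simplifyVector = TRUE)
  expect_equal(js$selected_lv, r$selected_lv)
  expect_equal(js$seed, 5)
})
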