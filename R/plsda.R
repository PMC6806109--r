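#' One-hot encode class labels for PLS-DA
#'
#' @param labels Character or factor vector of class labels (at least 2
#'   distinct classes).
#' @return List with `Y` (n x n_classes indicator matrix, one 1 per row) and
#'   `class_order` (classes in first-appearance order).
#' @export
encode_classes <- function(labels) {
  labels <- as.character(labels)
  class_order <- unique(labels)
  if (length(class_order) < 2) {
    stop("PLS-DA needs at least 2 classes, got ", length(class_order),
         call. = FALSE)
  }
  Y <- matrix(0, nrow = length(labels), ncol = length(class_order),
              dimnames = list(NULL, class_order))
  Y[cbind(seq_along(labels), match(labels, class_order))] <- 1
  list(Y = Y, class_order = class_order)
}

#' Recover labels from an indicator matrix
#' @param Y Indicator matrix with class columns.
#' @param class_order Class labels per column; defaults to `colnames(Y)`.
#' @return Character vector of labels.
#' @export
decode_classes <- function(Y, class_order = colnames(Y)) {
  class_order[apply(Y, 1, which.max)]
}

#' Fit a PLS-DA model by NIPALS (PLS2 on one-hot targets)
#'
#' X and Y are column-centered (0/1 one-hot coding for Y). Components are
#' extracted one at a time: starting from a Y column, iterate
#' `w = X'u / ||X'u||`, `t = X w`, `q = Y't / (t't)`, `u = Y q` until the
#' score vector changes by less than `tol` (relative), then deflate
#' `X <- X - t p'` with `p = X't/(t't)` and `Y <- Y - t q'`. The regression
#' coefficient matrix is `B = W (P'W)^{-1} Q'`.
#'
#' @param X Numeric matrix of pretreated spectra (n x p) or a `spectrum_set`.
#' @param Y Indicator matrix (n x n_classes), or a label vector which is
#'   encoded via [encode_classes()].
#' @param n_lv Number of latent variables, at most `min(n - 1, p)`.
#' @param tol NIPALS convergence tolerance on the score vector (default 1e-10).
#' @param max_iter Iteration cap per component (default 500); hitting it
#'   raises a convergence warning naming the component.
#' @return An object of class `plsda_model`: centering vectors `x_mean`,
#'   `y_mean`; `weights` W (p x n_lv), `x_loadings` P, `y_loadings` Q
#'   (n_classes x n_lv), `scores` T, `coefficients` B (p x n_classes),
#'   `class_order`, `n_lv`.
#' @export
fit_plsda <- function(X, Y, n_lv, tol = 1e-10, max_iter = 500) {
  X <- get_od(X)
  if (is.vector(Y) || is.factor(Y)) {
    enc <- encode_classes(Y)
    Y <- enc$Y
  }
  Y <- as.matrix(Y)
  class_order <- colnames(Y)
  if (is.null(class_order)) class_order <- paste0("class", seq_len(ncol(Y)))
  if (nrow(X) != nrow(Y)) stop("X and Y rows differ", call. = FALSE)
  n <- nrow(X); p <- ncol(X)
  if (n_lv > min(n - 1, p)) {
    stop("n_lv = ", n_lv, " exceeds min(n - 1, p) = ", min(n - 1, p),
         call. = FALSE)
  }
  x_mean <- colMeans(X); y_mean <- colMeans(Y)
  Xd <- sweep(X, 2, x_mean, "-")
  Yd <- sweep(Y, 2, y_mean, "-")
  if (sum(Xd^2) < 1e-300) stop("zero-variance X matrix", call. = FALSE)
  W <- matrix(0, p, n_lv); P <- matrix(0, p, n_lv)
  Q <- matrix(0, ncol(Y), n_lv); Tm <- matrix(0, n, n_lv)
  y_ss0 <- sum(Yd^2)
  n_extracted <- 0L
  for (a in seq_len(n_lv)) {
    # Y (or X) fully deflated: remaining components carry nothing
    if (sum(Yd^2) <= 1e-24 * max(y_ss0, 1) || sum(Xd^2) <= 1e-300) break
    u <- Yd[, which.max(colSums(Yd^2))]
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xd, u)
      w <- w / sqrt(sum(w^2))
      t_vec <- Xd %*% w
      q <- crossprod(Yd, t_vec) / sum(t_vec^2)
      u <- Yd %*% q
      if (sqrt(sum((t_vec - t_old)^2)) < tol * sqrt(sum(t_vec^2))) break
      t_old <- t_vec
      if (it == max_iter) {
        warning("NIPALS did not converge for component ", a, " after ",
                max_iter, " iterations", call. = FALSE)
      }
    }
    p_vec <- crossprod(Xd, t_vec) / sum(t_vec^2)
    Xd <- Xd - t_vec %*% t(p_vec)
    Yd <- Yd - t_vec %*% t(q)
    W[, a] <- w; P[, a] <- p_vec; Q[, a] <- q; Tm[, a] <- t_vec
    n_extracted <- a
  }
  if (n_extracted < n_lv) {
    keep <- seq_len(max(n_extracted, 1L))
    W <- W[, keep, drop = FALSE]; P <- P[, keep, drop = FALSE]
    Q <- Q[, keep, drop = FALSE]; Tm <- Tm[, keep, drop = FALSE]
    n_lv <- max(n_extracted, 1L)
  }
  B <- W %*% solve(crossprod(P, W), t(Q))
  colnames(B) <- class_order
  structure(list(
    x_mean = x_mean, y_mean = y_mean,
    weights = W, x_loadings = P, y_loadings = Q, scores = Tm,
    coefficients = B, class_order = class_order, n_lv = n_lv
  ), class = "plsda_model")
}

#' Coefficients of a truncated PLS-DA model
#'
#' NIPALS components are nested, so the coefficient matrix for the first `k`
#' latent variables can be recovered from a model fitted with more.
#' @param model A `plsda_model`.
#' @param k Number of latent variables to keep (`k <= model$n_lv`).
#' @return p x n_classes coefficient matrix.
#' @export
plsda_coefficients <- function(model, k = model$n_lv) {
  stopifnot(inherits(model, "plsda_model"), k >= 1)
  idx <- seq_len(min(k, model$n_lv))
  W <- model$weights[, idx, drop = FALSE]
  P <- model$x_loadings[, idx, drop = FALSE]
  Q <- model$y_loadings[, idx, drop = FALSE]
  B <- W %*% solve(crossprod(P, W), t(Q))
  colnames(B) <- model$class_order
  B
}

#' Predict classes from a PLS-DA model
#'
#' Continuous scores are `(X - x_mean) B + y_mean`; the predicted class is
#' the argmax over class columns, with ties broken toward the earlier class
#' in `class_order` (deterministic).
#'
#' @param model A `plsda_model`.
#' @param X Spectra matrix or `spectrum_set` on the model's variable grid.
#' @param n_lv Number of latent variables to use (default: all fitted).
#' @return List with `class` (character vector) and `scores` (continuous
#'   indicator predictions, n x n_classes).
#' @export
predict_class <- function(model, X, n_lv = model$n_lv) {
  stopifnot(inherits(model, "plsda_model"))
  X <- get_od(X)
  if (ncol(X) != length(model$x_mean)) {
    stop("X has ", ncol(X), " columns but the model was fitted on ",
         length(model$x_mean), call. = FALSE)
  }
  B <- plsda_coefficients(model, n_lv)
  Yhat <- sweep(X, 2, model$x_mean, "-") %*% B
  Yhat <- sweep(Yhat, 2, model$y_mean, "+")
  # which.max returns the first maximum: earlier class wins ties
  cls <- model$class_order[apply(Yhat, 1, which.max)]
  list(class = cls, scores = Yhat)
}

#' Cross-validation configuration
#'
#' @param k Number of folds (default 5).
#' @param repeats Number of repeats with reseeded partitions (default 10).
#' @param seed Master seed; one child seed is spawned per repeat.
#' @param lv_grid Latent-variable counts to evaluate (default 1:10).
#' @param stratified Preserve class proportions per fold (default TRUE).
#' @param group_by `"spectrum"` assigns each spectrum to a fold
#'   independently; `"sample"` keeps replicates of one oil (class x brand)
#'   together, avoiding replicate leakage.
#' @return A `cv_config` list.
#' @export
cv_config <- function(k = 5, repeats = 10, seed = 1, lv_grid = 1:10,
                      stratified = TRUE,
                      group_by = c("spectrum", "sample")) {
  group_by <- match.arg(group_by)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (repeats < 1) stop("repeats must be >= 1", call. = FALSE)
  structure(list(k = k, repeats = repeats, seed = seed,
                 lv_grid = sort(unique(as.integer(lv_grid))),
                 stratified = stratified, group_by = group_by),
            class = "cv_config")
}

# Stratified fold assignment for one repeat: within each class, units are
# shuffled and fold labels dealt out cyclically, keeping per-fold class
# counts within +/-1.
stratified_folds <- function(unit_class, k, stratified = TRUE) {
  n <- length(unit_class)
  fold <- integer(n)
  groups <- if (stratified) split(seq_len(n), unit_class) else
    list(seq_len(n))
  for (g in groups) {
    if (length(g) < k) {
      stop("class '", unit_class[g[1]], "' has only ", length(g),
           " unit(s) at the chosen grouping level; cannot stratify into ",
           k, " folds", call. = FALSE)
    }
    fold[sample(g)] <- rep_len(seq_len(k), length(g))
  }
  fold
}

#' Repeated stratified k-fold cross-validation of PLS-DA
#'
#' For each repeat (child-seeded from the master seed) the spectra are
#' partitioned into `k` stratified folds at the configured grouping level.
#' Per fold, pretreatment statistics (the MSC reference, centering) are
#' fitted on the training rows only and applied to the held-out rows, then a
#' PLS-DA model is fitted once at the largest LV count of the grid and
#' evaluated at every count. Accuracy is pooled over folds within a repeat
#' and averaged over repeats. Identical config and seed give identical
#' results.
#'
#' @param s A `spectrum_set` with a `class_label` metadata column (and
#'   `brand` when `group_by = "sample"`).
#' @param cfg A [cv_config()].
#' @param steps,sg,emsc_degree,msc_scope Pretreatment pipeline, see
#'   [apply_pretreatment()].
#' @return An object of class `cv_result`: `accuracy_by_lv` (named mean
#'   accuracy per LV), `per_repeat_accuracy` (repeats x LV matrix),
#'   `confusion` (pooled counts at the selected LV), `selected_lv`,
#'   `lv_grid`, `seed`, plus the echoed config.
#' @export
cross_validate <- function(s, cfg = cv_config(),
                           steps = c("msc", "der1"),
                           sg = list(window = 11, polyorder = 2),
                           emsc_degree = 2,
                           msc_scope = "fold") {
  stopifnot(inherits(s, "spectrum_set"), inherits(cfg, "cv_config"))
  if (!"class_label" %in% names(s$meta)) {
    stop("spectrum set lacks a class_label metadata column", call. = FALSE)
  }
  labels <- as.character(s$meta$class_label)
  classes <- unique(labels)
  unit_id <- if (cfg$group_by == "sample") {
    if (!"brand" %in% names(s$meta)) {
      stop("group_by = 'sample' needs a brand metadata column", call. = FALSE)
    }
    paste(labels, s$meta$brand, sep = "/")
  } else {
    seq_len(n_samples(s))
  }
  units <- unique(unit_id)
  unit_class <- labels[match(units, unit_id)]
  lv_grid <- cfg$lv_grid
  max_lv <- max(lv_grid)
  n_train_min <- n_samples(s) - ceiling(n_samples(s) / cfg$k)
  if (max_lv > n_train_min - 1) {
    stop("lv_grid maximum ", max_lv, " is too large for ", cfg$k,
         "-fold training sets of ~", n_train_min, " spectra", call. = FALSE)
  }

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(cfg$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  child_seeds <- sample.int(.Machine$integer.max - 1, cfg$repeats)

  per_repeat <- matrix(NA_real_, cfg$repeats, length(lv_grid),
                       dimnames = list(NULL, paste0("lv", lv_grid)))
  # predictions at every LV pooled across repeats, for the confusion matrix
  pooled_pred <- vector("list", length(lv_grid))
  pooled_truth <- character(0)

  for (r in seq_len(cfg$repeats)) {
    set.seed(child_seeds[r], kind = "Mersenne-Twister",
             normal.kind = "Inversion")
    unit_fold <- stratified_folds(unit_class, cfg$k, cfg$stratified)
    fold <- unit_fold[match(unit_id, units)]
    rep_pred <- matrix(NA_character_, n_samples(s), length(lv_grid))
    for (f in seq_len(cfg$k)) {
      tr <- which(fold != f); te <- which(fold == f)
      pre <- apply_pretreatment(subset_samples(s, tr), subset_samples(s, te),
                                steps = steps, sg = sg,
                                emsc_degree = emsc_degree,
                                msc_scope = msc_scope)
      model <- fit_plsda(pre$train, labels[tr], n_lv = max_lv)
      for (j in seq_along(lv_grid)) {
        rep_pred[te, j] <- predict_class(model, pre$test, lv_grid[j])$class
      }
    }
    per_repeat[r, ] <- colMeans(rep_pred == labels)
    for (j in seq_along(lv_grid)) {
      pooled_pred[[j]] <- c(pooled_pred[[j]], rep_pred[, j])
    }
    pooled_truth <- c(pooled_truth, labels)
  }

  accuracy_by_lv <- colMeans(per_repeat)
  names(accuracy_by_lv) <- paste0("lv", lv_grid)
  selected_lv <- select_n_lv(list(accuracy_by_lv = accuracy_by_lv,
                                  lv_grid = lv_grid))
  j_sel <- match(selected_lv, lv_grid)
  confusion <- table(
    truth = factor(pooled_truth, levels = classes),
    predicted = factor(pooled_pred[[j_sel]], levels = classes)
  )
  structure(list(
    accuracy_by_lv = accuracy_by_lv,
    per_repeat_accuracy = per_repeat,
    confusion = unclass(confusion),
    selected_lv = selected_lv,
    lv_grid = lv_grid,
    seed = cfg$seed,
    config = cfg,
    steps = steps
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result> ", x$config$k, "-fold x ", x$config$repeats,
      " repeats (seed ", x$seed, "), pretreatment: ",
      paste(x$steps, collapse = "+"), "\n", sep = "")
  acc <- data.frame(lv = x$lv_grid,
                    mean_accuracy = round(unname(x$accuracy_by_lv), 4))
  print(acc, row.names = FALSE)
  cat("selected LVs:", x$selected_lv, "(accuracy ",
      sprintf("%.4f", x$accuracy_by_lv[match(x$selected_lv, x$lv_grid)]),
      ")\n")
  invisible(x)
}

#' Select the number of latent variables from a CV curve
#'
#' The smallest LV count whose mean accuracy is within `tolerance` of the
#' maximum: more latent variables are not preferred once the gain is
#' negligible, to limit overfitting.
#'
#' @param result A `cv_result` (or list with `accuracy_by_lv` and `lv_grid`).
#' @param tolerance Accuracy slack below the maximum (default 0.01).
#' @return Integer LV count.
#' @export
select_n_lv <- function(result, tolerance = 0.01) {
  acc <- result$accuracy_by_lv
  if (length(acc) == 0) stop("empty accuracy curve", call. = FALSE)
  grid <- result$lv_grid
  if (is.null(grid)) grid <- seq_along(acc)
  grid[which(acc >= max(acc) - tolerance)[1]]
}

#' Export a CV result as CSV and JSON
#'
#' CSV: one row per LV count with mean accuracy and across-repeat SD.
#' JSON: full per-repeat detail, confusion matrix, seed and config echo.
#'
#' @param result A `cv_result`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
export_cv <- function(result, dir) {
  stopifnot(inherits(result, "cv_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("cv_accuracy.csv", "cv_result.json"))
  utils::write.csv(data.frame(
    lv = result$lv_grid,
    mean_accuracy = unname(result$accuracy_by_lv),
    sd = apply(result$per_repeat_accuracy, 2, stats::sd)
  ), paths[1], row.names = FALSE)
  jsonlite::write_json(list(
    lv_grid = result$lv_grid,
    accuracy_by_lv = unname(result$accuracy_by_lv),
    per_repeat_accuracy = result$per_repeat_accuracy,
    confusion = result$confusion,
    selected_lv = result$selected_lv,
    seed = result$seed,
    config = unclass(result$config),
    steps = result$steps
  ), paths[2], digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
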