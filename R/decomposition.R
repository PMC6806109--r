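#' Principal component analysis of a spectrum set
#'
#' Columns are mean-centered and the centered matrix decomposed by SVD.
#' Loadings are unit-norm rows (one per component), scores are the projections
#' of the centered samples, and the explained-variance ratio of each component
#' is its squared singular value over the total. Sign convention: the
#' largest-magnitude element of each loading is positive, which pins down the
#' SVD sign ambiguity and makes score plots reproducible.
#'
#' @param s A `spectrum_set` or numeric matrix.
#' @param n_components Number of components to retain; must be at most
#'   `min(n_samples - 1, n_wavelengths)`.
#' @return An object of class `pca_model`: list with `mean`, `loadings`
#'   (`n_components x n_wavelengths`), `scores`
#'   (`n_samples x n_components`), `explained_variance_ratio`, `wavelength`.
#' @export
fit_pca <- function(s, n_components) {
  od <- get_od(s)
  n <- nrow(od); p <- ncol(od)
  if (n < 2) stop("PCA needs at least 2 samples", call. = FALSE)
  kmax <- min(n - 1, p)
  if (n_components > kmax) {
    stop("n_components = ", n_components, " exceeds min(n_samples - 1, ",
         "n_wavelengths) = ", kmax, call. = FALSE)
  }
  mu <- colMeans(od)
  Xc <- sweep(od, 2, mu, "-")
  sv <- svd(Xc)
  evr <- sv$d^2 / sum(sv$d^2)
  k <- n_components
  loadings <- t(sv$v[, seq_len(k), drop = FALSE])   # k x p
  scores <- sv$u[, seq_len(k), drop = FALSE] *
    rep(sv$d[seq_len(k)], each = n)
  # sign convention: largest-|.| loading element positive
  for (a in seq_len(k)) {
    j <- which.max(abs(loadings[a, ]))
    if (loadings[a, j] < 0) {
      loadings[a, ] <- -loadings[a, ]
      scores[, a] <- -scores[, a]
    }
  }
  dimnames(loadings) <- list(paste0("PC", seq_len(k)), colnames(od))
  dimnames(scores) <- list(rownames(od), paste0("PC", seq_len(k)))
  structure(list(
    mean = mu,
    loadings = loadings,
    scores = scores,
    explained_variance_ratio = evr[seq_len(k)],
    all_variance_ratio = evr,
    wavelength = if (inherits(s, "spectrum_set")) s$wavelength else NULL
  ), class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  k <- nrow(x$loadings)
  cat("<pca_model> ", k, " components over ", ncol(x$loadings),
      " variables\n  explained variance: ",
      paste(sprintf("%.2f%%", 100 * x$explained_variance_ratio),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Noisiness of a principal-component loading
#'
#' Operationalises the visual judgement that a loading is "close to background
#' noise": the loading vector is Savitzky-Golay smoothed (window 11, degree 2)
#' and the statistic is `1 - R^2` of the loading against its smoothed version.
#' Structured, band-like loadings score near 0; white-noise-like loadings score
#' near 1. A constant loading (0/0 guard) returns 0 by convention.
#'
#' @param model A `pca_model`.
#' @param component Component index (1-based).
#' @param window,polyorder Savitzky-Golay settings for the smoother.
#' @return A fraction in [0, 1].
#' @export
loading_noise_score <- function(model, component, window = 11, polyorder = 2) {
  stopifnot(inherits(model, "pca_model"))
  if (component < 1 || component > nrow(model$loadings)) {
    stop("component ", component, " not fitted", call. = FALSE)
  }
  v <- model$loadings[component, ]
  tot <- sum((v - mean(v))^2)
  if (tot < 1e-300) return(0)
  w <- min(window, length(v))
  if (w %% 2 == 0) w <- w - 1
  sm <- sg_filter_vec(v, window = w, polyorder = min(polyorder, w - 1))
  score <- sum((v - sm)^2) / tot
  min(max(score, 0), 1)
}

#' Two-criterion selection of the number of principal components
#'
#' A component counts as informative if it explains at least `var_floor` of
#' the variance *or* its loading is structured (noise score at most
#' `noise_ceiling`). The selected count is the largest k such that every
#' component up to k is informative, with a minimum of 1. With spectra whose
#' leading ratios look like 96%, 2.5%, 0.9%, 0.2% and noisy third/fourth
#' loadings this selects 2.
#'
#' @param model A `pca_model` with at least 2 components.
#' @param var_floor Explained-variance floor (fraction, default 0.01).
#' @param noise_ceiling Maximum loading noise score to count as structured
#'   (default 0.3).
#' @return Integer number of components.
#' @export
select_n_pcs <- function(model, var_floor = 0.01, noise_ceiling = 0.3) {
  stopifnot(inherits(model, "pca_model"))
  k <- nrow(model$loadings)
  if (k < 2) stop("fit at least 2 components before selecting", call. = FALSE)
  ok <- vapply(seq_len(k), function(a) {
    model$explained_variance_ratio[a] >= var_floor ||
      loading_noise_score(model, a) <= noise_ceiling
  }, logical(1))
  if (!ok[1]) return(1L)
  bad <- which(!ok)
  if (length(bad) == 0) k else as.integer(bad[1] - 1L)
}

#' Export PCA scores, loadings and explained variance as CSV
#'
#' @param model A `pca_model`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
export_pca <- function(model, dir) {
  stopifnot(inherits(model, "pca_model"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("pca_scores.csv", "pca_loadings.csv",
                            "pca_variance.csv"))
  utils::write.csv(data.frame(sample_id = rownames(model$scores),
                              model$scores, check.names = FALSE),
                   paths[1], row.names = FALSE)
  load_df <- data.frame(wavelength_nm = colnames(model$loadings),
                        t(model$loadings), check.names = FALSE)
  utils::write.csv(load_df, paths[2], row.names = FALSE)
  utils::write.csv(data.frame(
    component = seq_along(model$explained_variance_ratio),
    explained_variance_ratio = model$explained_variance_ratio
  ), paths[3], row.names = FALSE)
  invisible(paths)
}
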