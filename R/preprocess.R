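#' Fit a multiplicative scatter correction (MSC) model
#'
#' MSC treats each spectrum A_i as an affine distortion of an ideal spectrum,
#' A_i = m_i * ref + b_i, with the set-mean spectrum standing in for the
#' unavailable ideal. The per-sample slope m_i and offset b_i are estimated by
#' ordinary least squares over wavelengths, solved through a QR decomposition
#' with a rank check (a constant reference is not correctable).
#'
#' @param s A `spectrum_set` (or numeric OD matrix).
#' @param reference Optional reference spectrum; defaults to the column mean
#'   of `s`. Supplying the training-fold mean here is how fold-scoped MSC is
#'   done inside cross-validation.
#' @return An object of class `msc_model`: list with `reference`, `slope`
#'   (m_i per sample), `offset` (b_i per sample).
#' @export
fit_msc <- function(s, reference = NULL) {
  od <- get_od(s)
  if (nrow(od) < 1) stop("need at least one sample", call. = FALSE)
  if (is.null(reference)) reference <- colMeans(od)
  reference <- as.numeric(reference)
  if (length(reference) != ncol(od)) {
    stop("reference length ", length(reference), " does not match the ",
         ncol(od), "-point grid", call. = FALSE)
  }
  co <- msc_coefficients(od, reference)
  structure(list(reference = reference, slope = co$slope, offset = co$offset),
            class = "msc_model")
}

# OLS of each spectrum on [1, reference], via one QR factorisation.
msc_coefficients <- function(od, reference) {
  X <- cbind(offset = 1, slope = reference)
  qrx <- qr(X)
  if (qrx$rank < 2) {
    stop("degenerate reference: zero variance across wavelengths, ",
         "scatter slope is unidentifiable", call. = FALSE)
  }
  beta <- qr.coef(qrx, t(od))             # 2 x n_samples
  list(offset = unname(beta[1, ]), slope = unname(beta[2, ]))
}

#' Apply multiplicative scatter correction
#'
#' Each spectrum becomes `(A_i - b_i) / m_i`. Coefficients are always
#' re-estimated against the model's stored reference, so a model fitted on a
#' training fold applies cleanly to held-out spectra without refitting the
#' reference.
#'
#' @param s A `spectrum_set`.
#' @param model An `msc_model` from [fit_msc()]; defaults to one fitted on
#'   `s` itself (global-scope MSC).
#' @return The corrected `spectrum_set`.
#' @export
apply_msc <- function(s, model = fit_msc(s)) {
  stopifnot(inherits(s, "spectrum_set"), inherits(model, "msc_model"))
  if (length(model$reference) != n_wavelengths(s)) {
    stop("MSC model grid (", length(model$reference), ") does not match the ",
         "set (", n_wavelengths(s), " wavelengths)", call. = FALSE)
  }
  co <- msc_coefficients(s$od, model$reference)
  bad <- abs(co$slope) < 1e-12
  if (any(bad)) {
    stop("non-correctable sample(s) with scatter slope ~ 0: ",
         paste(utils::head(s$meta$sample_id[bad], 5), collapse = ", "),
         call. = FALSE)
  }
  od <- sweep(sweep(s$od, 1, co$offset, "-"), 1, co$slope, "/")
  replace_od(s, od)
}

#' Finite-difference spectral derivative
#'
#' First-order: `y_i = x_{i+1} - x_i` along the (uniform) wavelength grid,
#' removing any additive background constant. Second order is the first
#' difference applied twice and removes a linear background shift. The output
#' grid is labelled by the left wavelength of each difference.
#'
#' @param s A `spectrum_set`.
#' @param order 1 or 2.
#' @return A `spectrum_set` with `n - order` columns.
#' @export
derivative <- function(s, order = 1) {
  stopifnot(inherits(s, "spectrum_set"))
  if (!order %in% c(1, 2)) stop("order must be 1 or 2", call. = FALSE)
  if (n_wavelengths(s) <= order) {
    stop("need more than ", order, " wavelengths for an order-", order,
         " derivative", call. = FALSE)
  }
  od <- s$od
  wl <- s$wavelength
  for (k in seq_len(order)) {
    od <- od[, -1, drop = FALSE] - od[, -ncol(od), drop = FALSE]
    wl <- wl[-length(wl)]
  }
  replace_od(s, od, wl)
}

#' Savitzky-Golay smoothing
#'
#' Moving local polynomial least-squares filter; each spectrum is filtered
#' independently. Edges are handled by the asymmetric polynomial fits of the
#' full filter matrix, so polynomials of degree at most `polyorder` pass
#' through unchanged everywhere, including the boundary points.
#'
#' @param s A `spectrum_set`.
#' @param window Odd window length in points (default 11).
#' @param polyorder Polynomial degree, must be `< window` (default 2).
#' @return The smoothed `spectrum_set`, same shape as the input.
#' @export
sg_smooth <- function(s, window = 11, polyorder = 2) {
  stopifnot(inherits(s, "spectrum_set"))
  od <- t(apply(s$od, 1, sg_filter_vec, window = window,
                polyorder = polyorder))
  if (n_samples(s) == 1) od <- matrix(od, nrow = 1)
  replace_od(s, od)
}

sg_filter_vec <- function(x, window, polyorder) {
  if (window %% 2 != 1 || window < 1) {
    stop("window must be a positive odd integer", call. = FALSE)
  }
  if (polyorder < 0 || polyorder >= window) {
    stop("polyorder must satisfy 0 <= polyorder < window", call. = FALSE)
  }
  if (window > length(x)) {
    stop("window (", window, ") exceeds the number of wavelengths (",
         length(x), ")", call. = FALSE)
  }
  if (window == 1) return(x)  # degenerate window: identity
  signal::sgolayfilt(x, p = polyorder, n = window)
}

#' Extended multiplicative scatter correction (EMSC)
#'
#' Per sample, OLS fit of the spectrum on the reference plus wavelength
#' polynomials up to `poly_degree` (wavelength scaled to [-1, 1] for
#' conditioning); the corrected spectrum is `(A_i - polynomial part) / m_i`.
#' With `poly_degree = 0` this reduces exactly to MSC.
#'
#' @param s A `spectrum_set`.
#' @param poly_degree Baseline polynomial degree (default 2).
#' @param reference Optional reference spectrum; defaults to the column mean.
#' @return The corrected `spectrum_set`.
#' @export
emsc <- function(s, poly_degree = 2, reference = NULL) {
  stopifnot(inherits(s, "spectrum_set"))
  if (poly_degree < 0) stop("poly_degree must be >= 0", call. = FALSE)
  od <- s$od
  if (is.null(reference)) reference <- colMeans(od)
  reference <- as.numeric(reference)
  if (length(reference) != ncol(od)) {
    stop("reference length does not match the grid", call. = FALSE)
  }
  wl <- s$wavelength
  t_scaled <- if (length(wl) > 1) {
    2 * (wl - min(wl)) / (max(wl) - min(wl)) - 1
  } else {
    0
  }
  P <- outer(t_scaled, 0:poly_degree, `^`)      # 1, t, t^2, ...
  X <- cbind(ref = reference, P)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    stop("rank-deficient EMSC design (reference collinear with the ",
         "wavelength polynomials)", call. = FALSE)
  }
  beta <- qr.coef(qrx, t(od))                   # (1 + degree + 1) x n
  m <- beta[1, ]
  bad <- abs(m) < 1e-12
  if (any(bad)) {
    stop("non-correctable sample(s) with scatter slope ~ 0: ",
         paste(utils::head(s$meta$sample_id[bad], 5), collapse = ", "),
         call. = FALSE)
  }
  baseline <- P %*% beta[-1, , drop = FALSE]    # p x n
  corrected <- (t(od) - baseline) / rep(m, each = ncol(od))
  replace_od(s, t(corrected))
}

#' MSC followed by the first derivative (the default pretreatment)
#'
#' The workhorse pretreatment for plate-reader oil spectra: multiplicative
#' scatter correction against the set mean, then the first finite difference.
#'
#' @param s A `spectrum_set`.
#' @return A `spectrum_set` with one fewer column than the input.
#' @export
msc_der1 <- function(s) {
  derivative(apply_msc(s, fit_msc(s)), order = 1)
}

#' Apply a pretreatment pipeline, optionally fold-scoped
#'
#' Fits the statistics-bearing steps (the MSC/EMSC reference) on `train` and
#' applies the whole pipeline to both `train` and `test`, the leakage-safe
#' protocol used inside cross-validation.
#'
#' @param train,test `spectrum_set`s on the same grid (`test` may be `NULL`).
#' @param steps Character vector drawn from
#'   `c("raw", "msc", "emsc", "der1", "der2", "sg")`, applied in order.
#'   `"raw"` is a no-op placeholder.
#' @param sg List of Savitzky-Golay parameters (`window`, `polyorder`).
#' @param emsc_degree EMSC baseline degree.
#' @param msc_scope `"fold"` (reference from `train` only, the default) or
#'   `"global"` (reference from train and test pooled).
#' @return List with elements `train` and `test` (pretreated sets).
#' @export
apply_pretreatment <- function(train, test = NULL, steps = c("msc", "der1"),
                               sg = list(window = 11, polyorder = 2),
                               emsc_degree = 2,
                               msc_scope = c("fold", "global")) {
  msc_scope <- match.arg(msc_scope)
  known <- c("raw", "msc", "emsc", "der1", "der2", "sg")
  if (!all(steps %in% known)) {
    stop("unknown pretreatment step(s): ",
         paste(setdiff(steps, known), collapse = ", "), call. = FALSE)
  }
  for (step in steps) {
    if (step == "raw") next
    if (step %in% c("msc", "emsc")) {
      ref <- if (msc_scope == "fold" || is.null(test)) {
        colMeans(train$od)
      } else {
        colMeans(rbind(train$od, test$od))
      }
      if (step == "msc") {
        model <- fit_msc(train, reference = ref)
        train <- apply_msc(train, model)
        if (!is.null(test)) test <- apply_msc(test, model)
      } else {
        train <- emsc(train, poly_degree = emsc_degree, reference = ref)
        if (!is.null(test)) {
          test <- emsc(test, poly_degree = emsc_degree, reference = ref)
        }
      }
    } else if (step %in% c("der1", "der2")) {
      ord <- if (step == "der1") 1 else 2
      train <- derivative(train, ord)
      if (!is.null(test)) test <- derivative(test, ord)
    } else if (step == "sg") {
      train <- sg_smooth(train, sg$window, sg$polyorder)
      if (!is.null(test)) test <- sg_smooth(test, sg$window, sg$polyorder)
    }
  }
  list(train = train, test = test)
}
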