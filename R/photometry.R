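#' Plate-well geometry for Beer-Lambert pathlength arithmetic
#'
#' In a microtiter well the light path is vertical, so the pathlength is the
#' fill height of the oil column and varies with the aliquot weight; in a
#' cuvette it is fixed by the cell. Defaults are a 0.86 cm well diameter,
#' oil density 0.9113 g/cm^3 and a 10 mm cuvette.
#'
#' @param well_diameter_cm Well diameter in cm.
#' @param oil_density_g_cm3 Oil density in g/cm^3.
#' @param cuvette_pathlength_mm Cuvette pathlength in mm.
#' @return A `plate_geometry` list.
#' @export
plate_geometry <- function(well_diameter_cm = 0.86,
                           oil_density_g_cm3 = 0.9113,
                           cuvette_pathlength_mm = 10) {
  vals <- c(well_diameter_cm, oil_density_g_cm3, cuvette_pathlength_mm)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all geometry parameters must be strictly positive", call. = FALSE)
  }
  structure(list(well_diameter_cm = well_diameter_cm,
                 oil_density_g_cm3 = oil_density_g_cm3,
                 cuvette_pathlength_mm = cuvette_pathlength_mm),
            class = "plate_geometry")
}

#' Vertical pathlength of an oil aliquot in a plate well
#'
#' Fill height of a cylinder with a flat meniscus:
#' `L = (w / 1000) / (rho * pi * (d/2)^2)` cm, returned in mm. Linear in
#' weight. With the defaults, 100/150/200/300 mg give 1.9/2.8/3.8/5.7 mm
#' (1 decimal).
#'
#' @param weight_mg Aliquot weight in mg (vectorised, must be >= 0).
#' @param geom A [plate_geometry()].
#' @return Pathlength(s) in mm, unrounded.
#' @export
estimate_pathlength <- function(weight_mg, geom = plate_geometry()) {
  stopifnot(inherits(geom, "plate_geometry"))
  if (any(weight_mg < 0)) stop("weight must be >= 0", call. = FALSE)
  area_cm2 <- pi * (geom$well_diameter_cm / 2)^2
  (weight_mg / 1000) / (geom$oil_density_g_cm3 * area_cm2) * 10
}

#' Cuvette-to-well pathlength ratio
#'
#' How many times longer the cuvette path is than the vertical path of a
#' given aliquot; with the defaults, 200 and 300 mg give 2.6 and 1.8
#' (1 decimal).
#'
#' @inheritParams estimate_pathlength
#' @return Dimensionless ratio(s), unrounded.
#' @export
pathlength_ratio <- function(weight_mg, geom = plate_geometry()) {
  if (any(weight_mg <= 0)) {
    stop("weight must be > 0 for a pathlength ratio", call. = FALSE)
  }
  geom$cuvette_pathlength_mm / estimate_pathlength(weight_mg, geom)
}

#' Fit the optical-density versus aliquot-weight line
#'
#' Ordinary least squares of mean OD at a reference wavelength (415 nm, a
#' typical absorbance peak of olive oil, by default) against aliquot weight.
#' Under Beer-Lambert behaviour the relation is linear because the vertical
#' pathlength is proportional to weight.
#'
#' @param weights Aliquot weights in mg (>= 2 distinct values).
#' @param mean_od Mean OD at the reference wavelength, one value per weight.
#' @return An object of class `linear_fit`: `slope` (OD per mg), `intercept`
#'   (OD), `r_squared`.
#' @export
fit_od_weight <- function(weights, mean_od) {
  if (length(weights) != length(mean_od)) {
    stop("weights and mean_od lengths differ", call. = FALSE)
  }
  if (length(unique(weights)) < 2) {
    stop("need at least 2 distinct weights to fit a line", call. = FALSE)
  }
  fit <- stats::lm(mean_od ~ weights)
  # R^2 computed directly; summary.lm warns on numerically perfect fits
  sst <- sum((mean_od - mean(mean_od))^2)
  sse <- sum(stats::residuals(fit)^2)
  r2 <- if (sst <= 1e-300) 1 else max(0, min(1, 1 - sse / sst))
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = r2),
            class = "linear_fit")
}

#' @export
print.linear_fit <- function(x, ...) {
  cat(sprintf("<linear_fit> OD = %.6g w + %.6g  (R^2 = %.6g)\n",
              x$slope, x$intercept, x$r_squared))
  invisible(x)
}

#' Aliquot weight equivalent to a target optical density
#'
#' Inverts the OD-weight line: `w = (target_od - intercept) / slope`.
#'
#' @param target_od Target OD at the fit's reference wavelength.
#' @param fit A `linear_fit` from [fit_od_weight()].
#' @return Weight in mg.
#' @export
equivalent_weight <- function(target_od, fit) {
  stopifnot(inherits(fit, "linear_fit"))
  if (abs(fit$slope) < 1e-300) {
    stop("cannot invert a zero-slope fit", call. = FALSE)
  }
  (target_od - fit$intercept) / fit$slope
}

#' Correlation matrix between measurement conditions
#'
#' Pearson correlation over wavelengths between the mean spectra (mean over
#' samples) of each pair of conditions — e.g. benchtop versus plate-reader
#' fills at several weights. All sets must share one trimmed grid. The
#' diagonal is exactly 1.
#'
#' @param sets List of `spectrum_set`s (>= 2), one per condition.
#' @param labels Condition names; default from the list names.
#' @return Symmetric correlation matrix with condition labels as dimnames.
#' @export
condition_correlation <- function(sets, labels = names(sets)) {
  if (length(sets) < 2) stop("need at least 2 conditions", call. = FALSE)
  if (is.null(labels)) labels <- paste0("condition", seq_along(sets))
  wl <- sets[[1]]$wavelength
  for (s in sets[-1]) {
    if (length(s$wavelength) != length(wl) ||
        any(abs(s$wavelength - wl) > 1e-9)) {
      stop("condition grids are not aligned; trim all sets to a common band ",
           "first", call. = FALSE)
    }
  }
  means <- vapply(sets, function(s) colMeans(s$od), numeric(length(wl)))
  cm <- stats::cor(means)
  diag(cm) <- 1
  dimnames(cm) <- list(labels, labels)
  cm
}

#' Write a condition correlation matrix as CSV (lower triangle)
#'
#' @param cm Correlation matrix from [condition_correlation()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_correlation <- function(cm, path) {
  out <- format(round(cm, 4), nsmall = 4)
  out[upper.tri(out)] <- ""
  df <- data.frame(condition = rownames(cm), out, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
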