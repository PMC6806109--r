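#' Construct a spectrum set
#'
#' A `spectrum_set` bundles an optical-density (OD) matrix with its wavelength
#' axis and per-sample metadata. It is the object every stage of the workflow
#' transforms: rows are wells/samples, columns are wavelengths.
#'
#' @param od Numeric matrix, `n_samples x n_wavelengths`. Optical density
#'   (dimensionless absorbance). `Inf` is tolerated (detector overflow awaiting
#'   [cap_overflow()]); `NA` is not.
#' @param wavelength Numeric vector of wavelengths in nm, strictly increasing
#'   and uniformly spaced, one per OD column.
#' @param meta Data frame of per-sample metadata with at least a `sample_id`
#'   column; recognised columns are `class_label`, `brand`, `replicate`,
#'   `weight_mg` and `instrument`, any others are carried along untouched.
#'   If `NULL`, a minimal frame with generated sample ids is created.
#'
#' @return An object of class `spectrum_set`: a list with elements `od`
#'   (matrix, rownames = sample ids), `wavelength` and `meta`.
#' @seealso [read_spectra()], [trim_band()], [cap_overflow()]
#' @export
spectrum_set <- function(od, wavelength, meta = NULL) {
  od <- as.matrix(od)
  storage.mode(od) <- "double"
  wavelength <- as.numeric(wavelength)
  if (ncol(od) != length(wavelength)) {
    stop("`od` has ", ncol(od), " columns but `wavelength` has length ",
         length(wavelength), call. = FALSE)
  }
  validate_grid(wavelength)
  if (anyNA(od)) {
    stop("`od` contains missing values; overflow markers must be resolved ",
         "at ingestion (see read_spectra) or capped (see cap_overflow)",
         call. = FALSE)
  }
  if (is.null(meta)) {
    ids <- rownames(od)
    if (is.null(ids)) ids <- sprintf("s%02d", seq_len(nrow(od)))
    meta <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  }
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(meta)) {
    stop("`meta` must contain a sample_id column", call. = FALSE)
  }
  meta$sample_id <- as.character(meta$sample_id)
  if (nrow(meta) != nrow(od)) {
    stop("metadata has ", nrow(meta), " rows but the OD matrix has ",
         nrow(od), call. = FALSE)
  }
  rownames(od) <- meta$sample_id
  colnames(od) <- format_wavelength(wavelength)
  structure(list(od = od, wavelength = wavelength, meta = meta),
            class = "spectrum_set")
}

#' Build a uniform wavelength grid
#'
#' @param start_nm,end_nm Grid limits in nm (closed interval).
#' @param step_nm Spacing in nm, must be positive and divide `end_nm - start_nm`.
#' @return Numeric vector of wavelengths. The default acquisition grid is
#'   230-1000 nm at 1 nm (771 points).
#' @export
wavelength_grid <- function(start_nm = 230, end_nm = 1000, step_nm = 1) {
  if (step_nm <= 0) stop("step_nm must be > 0", call. = FALSE)
  n_steps <- (end_nm - start_nm) / step_nm
  if (abs(n_steps - round(n_steps)) > 1e-8 || n_steps < 0) {
    stop("(end_nm - start_nm) must be a non-negative multiple of step_nm",
         call. = FALSE)
  }
  seq(start_nm, end_nm, by = step_nm)
}

validate_grid <- function(wavelength) {
  if (length(wavelength) == 0) stop("empty wavelength grid", call. = FALSE)
  if (anyNA(wavelength)) stop("wavelength grid contains NA", call. = FALSE)
  if (length(wavelength) > 1) {
    d <- diff(wavelength)
    if (any(d <= 0)) {
      stop("wavelength grid must be strictly increasing", call. = FALSE)
    }
    if (diff(range(d)) > 1e-6 * mean(d)) {
      stop("wavelength grid is not uniform (spacing varies from ",
           signif(min(d), 6), " to ", signif(max(d), 6), " nm)", call. = FALSE)
    }
  }
  invisible(wavelength)
}

format_wavelength <- function(w) {
  ifelse(abs(w - round(w)) < 1e-9, as.character(round(w)), as.character(w))
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat("<spectrum_set> ", nrow(x$od), " samples x ", ncol(x$od),
      " wavelengths (", x$wavelength[1], "-",
      x$wavelength[length(x$wavelength)], " nm)\n", sep = "")
  if ("class_label" %in% names(x$meta)) {
    tab <- table(x$meta$class_label)
    cat("  classes: ",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  }
  nc <- attr(x, "n_capped")
  if (!is.null(nc)) cat("  capped cells:", nc, "\n")
  invisible(x)
}

#' @export
dim.spectrum_set <- function(x) dim(x$od)

#' Number of samples / wavelengths in a spectrum set
#' @param s A `spectrum_set`.
#' @return Integer count.
#' @export
n_samples <- function(s) nrow(s$od)

#' @rdname n_samples
#' @export
n_wavelengths <- function(s) ncol(s$od)

#' Subset a spectrum set by sample
#'
#' @param s A `spectrum_set`.
#' @param i Row index (integer, logical or sample-id character vector).
#' @return A `spectrum_set` with the selected samples, metadata kept in step.
#' @export
subset_samples <- function(s, i) {
  stopifnot(inherits(s, "spectrum_set"))
  if (is.character(i)) i <- match(i, s$meta$sample_id)
  out <- spectrum_set(s$od[i, , drop = FALSE], s$wavelength,
                      s$meta[i, , drop = FALSE])
  out
}

#' Replace a spectrum set's OD matrix, keeping grid and metadata
#'
#' Internal workhorse used by the pretreatment functions; `wavelength` may be
#' supplied when the transformation changes the number of columns.
#' @noRd
replace_od <- function(s, od, wavelength = s$wavelength) {
  spectrum_set(od, wavelength, s$meta)
}

#' Extract the OD matrix from a spectrum set or pass a matrix through
#' @noRd
get_od <- function(x) {
  if (inherits(x, "spectrum_set")) x$od else as.matrix(x)
}
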