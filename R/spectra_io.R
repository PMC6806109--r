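#' Read an optical-density spectrum set from CSV
#'
#' Two layouts are supported. The *wide* dialect mirrors plate-reader exports:
#' first column `sample_id`, remaining column headers are wavelengths in nm,
#' one row per well. The *long* dialect has columns
#' `sample_id, wavelength_nm, od`. Detector-overflow tokens (by default
#' `"OVER"`, `"OVRFLW"`, the empty string and `"inf"`) are accepted in OD
#' cells and ingested as `Inf`, to be resolved by [cap_overflow()].
#'
#' @param path CSV file to read.
#' @param layout `"wide"` or `"long"`.
#' @param metadata_path Optional CSV of per-sample metadata joined on
#'   `sample_id` (columns such as `class_label`, `brand`, `replicate`,
#'   `weight_mg`, `instrument`; unknown columns are preserved).
#' @param overflow_markers Character tokens read as detector overflow.
#' @return A [spectrum_set()] on a validated uniform grid.
#' @export
read_spectra <- function(path, layout = c("wide", "long"),
                         metadata_path = NULL,
                         overflow_markers = c("OVER", "OVRFLW", "", "inf")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (nrow(raw) == 0) {
    stop("empty spectrum set: ", path, " has a header but no samples",
         call. = FALSE)
  }
  if (layout == "wide") {
    if (names(raw)[1] != "sample_id") {
      stop("wide layout requires first column 'sample_id' in ", path,
           call. = FALSE)
    }
    wl <- suppressWarnings(as.numeric(names(raw)[-1]))
    if (anyNA(wl)) {
      stop("non-numeric wavelength header in ", path, ": ",
           paste(utils::head(names(raw)[-1][is.na(wl)], 3), collapse = ", "),
           call. = FALSE)
    }
    od <- parse_od(as.matrix(raw[, -1, drop = FALSE]), overflow_markers, path)
    ids <- raw$sample_id
  } else {
    needed <- c("sample_id", "wavelength_nm", "od")
    if (!all(needed %in% names(raw))) {
      stop("long layout requires columns sample_id, wavelength_nm, od in ",
           path, call. = FALSE)
    }
    wl_col <- as.numeric(raw$wavelength_nm)
    if (anyNA(wl_col)) stop("non-numeric wavelength_nm in ", path, call. = FALSE)
    key <- paste(raw$sample_id, wl_col)
    if (anyDuplicated(key)) {
      stop("duplicate (sample, wavelength) pair in ", path, ": ",
           key[duplicated(key)][1], call. = FALSE)
    }
    wl <- sort(unique(wl_col))
    ids <- unique(raw$sample_id)
    od_vals <- parse_od(matrix(raw$od, ncol = 1), overflow_markers, path)
    od <- matrix(NA_real_, nrow = length(ids), ncol = length(wl),
                 dimnames = list(ids, NULL))
    od[cbind(match(raw$sample_id, ids), match(wl_col, wl))] <- od_vals
    if (anyNA(od)) {
      stop("long layout in ", path, " is not a complete sample x wavelength ",
           "grid", call. = FALSE)
    }
  }
  meta <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  if (!is.null(metadata_path)) {
    md <- utils::read.csv(metadata_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
    if (!"sample_id" %in% names(md)) {
      stop("metadata file ", metadata_path, " lacks a sample_id column",
           call. = FALSE)
    }
    md$sample_id <- as.character(md$sample_id)
    idx <- match(ids, md$sample_id)
    if (anyNA(idx)) {
      stop("metadata join misses sample(s): ",
           paste(utils::head(ids[is.na(idx)], 5), collapse = ", "),
           call. = FALSE)
    }
    meta <- md[idx, , drop = FALSE]
    rownames(meta) <- NULL
  }
  spectrum_set(od, wl, meta)
}

parse_od <- function(chr, overflow_markers, path) {
  chr <- trimws(chr)
  is_over <- chr %in% overflow_markers
  vals <- suppressWarnings(as.numeric(chr))
  vals[is_over] <- Inf
  if (anyNA(vals)) {
    bad <- unique(chr[is.na(vals)])
    stop("unparseable OD value(s) in ", path, ": ",
         paste(utils::head(bad, 3), collapse = ", "),
         " (not numeric and not a configured overflow marker)", call. = FALSE)
  }
  out <- matrix(vals, nrow = nrow(chr), ncol = ncol(chr))
  out
}

#' Write a spectrum set to CSV
#'
#' Serialization is lossless for grid, OD and metadata. In the wide layout the
#' spectra file holds `sample_id` plus one column per wavelength in ascending
#' order; metadata (when the set carries more than sample ids) goes to
#' `metadata_path`. The long layout writes `sample_id, wavelength_nm, od`.
#'
#' @param s A `spectrum_set`.
#' @param path Output CSV path for the spectra.
#' @param layout `"wide"` or `"long"`.
#' @param metadata_path Optional path for the metadata CSV; defaults to no
#'   metadata file when the set has none beyond `sample_id`.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(s, path, layout = c("wide", "long"),
                          metadata_path = NULL) {
  stopifnot(inherits(s, "spectrum_set"))
  layout <- match.arg(layout)
  wl_lab <- format_wavelength(s$wavelength)
  if (layout == "wide") {
    df <- data.frame(sample_id = s$meta$sample_id, stringsAsFactors = FALSE)
    od_df <- as.data.frame(s$od)
    names(od_df) <- wl_lab
    df <- cbind(df, od_df)
  } else {
    df <- data.frame(
      sample_id = rep(s$meta$sample_id, each = length(s$wavelength)),
      wavelength_nm = rep(s$wavelength, times = nrow(s$od)),
      od = as.vector(t(s$od)),
      stringsAsFactors = FALSE
    )
  }
  tryCatch(
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE),
    error = function(e) stop("failed writing ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (!is.null(metadata_path)) {
    utils::write.csv(s$meta, metadata_path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Cap detector overflow at the instrument maximum
#'
#' Plate readers report a bounded OD; saturated cells must be replaced by the
#' instrument maximum before any modelling. Every non-finite cell and every
#' cell above `cap` becomes exactly `cap`; all other cells are unchanged. The
#' number of replaced cells is attached as attribute `"n_capped"`.
#'
#' @param s A `spectrum_set`.
#' @param cap Saturation ceiling in OD units; the plate reader's maximum
#'   indication is 4.
#' @return The capped `spectrum_set`, with attribute `n_capped` (integer).
#' @export
cap_overflow <- function(s, cap = 4.0) {
  stopifnot(inherits(s, "spectrum_set"))
  if (cap <= 0) stop("cap must be > 0", call. = FALSE)
  od <- s$od
  hit <- !is.finite(od) | od > cap
  od[hit] <- cap
  out <- replace_od(s, od)
  attr(out, "n_capped") <- sum(hit)
  out
}

#' Trim a spectrum set to a wavelength band
#'
#' Columns outside the closed interval `[min_nm, max_nm]` are removed and the
#' grid updated; metadata is untouched. The defaults drop the saturated UV
#' region below 308 nm, taking the standard 230-1000 nm acquisition grid to
#' 693 retained variables.
#'
#' @param s A `spectrum_set`.
#' @param min_nm,max_nm Band limits in nm (closed interval).
#' @return The trimmed `spectrum_set`. Idempotent for fixed bounds.
#' @export
trim_band <- function(s, min_nm = 308, max_nm = 1000) {
  stopifnot(inherits(s, "spectrum_set"))
  keep <- s$wavelength >= min_nm & s$wavelength <= max_nm
  if (!any(keep)) {
    stop("trim window [", min_nm, ", ", max_nm, "] nm does not overlap the ",
         "grid (", s$wavelength[1], "-", s$wavelength[length(s$wavelength)],
         " nm)", call. = FALSE)
  }
  replace_od(s, s$od[, keep, drop = FALSE], s$wavelength[keep])
}
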