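#' Gaussian pigment absorption basis for edible-oil spectra
#'
#' Unit-height Gaussian extinction profiles for the chromophores that shape
#' olive-oil UV-Vis spectra: tocopherol (325 nm), the composite
#' carotenoid/pheophytin band near 420 nm, alpha-, beta- and gamma-carotene
#' (447, 451, 462 nm) and chlorophyll (670 nm). Band widths are 12 nm SD for
#' the pigment lines and 30 nm for the broad 420 nm composite, giving
#' resolvable carotene shoulders.
#'
#' @param wavelength Wavelength grid in nm.
#' @param centers_nm Band centers (nm).
#' @param widths_nm Gaussian SDs (nm), recycled against `centers_nm`.
#' @return Matrix `length(wavelength) x length(centers_nm)` of unit-height
#'   profiles, columns named by pigment.
#' @export
pigment_basis <- function(wavelength = wavelength_grid(),
                          centers_nm = c(325, 420, 447, 451, 462, 670),
                          widths_nm = c(12, 30, 12, 12, 12, 12)) {
  if (any(widths_nm <= 0)) stop("band widths must be > 0", call. = FALSE)
  if (any(centers_nm < min(wavelength) | centers_nm > max(wavelength))) {
    stop("band centers must lie within the wavelength grid", call. = FALSE)
  }
  widths_nm <- rep_len(widths_nm, length(centers_nm))
  B <- vapply(seq_along(centers_nm), function(j) {
    exp(-((wavelength - centers_nm[j])^2) / (2 * widths_nm[j]^2))
  }, numeric(length(wavelength)))
  colnames(B) <- c("tocopherol_325", "carotenoid_420", "alpha_carotene_447",
                   "beta_carotene_451", "gamma_carotene_462",
                   "chlorophyll_670")[seq_along(centers_nm)]
  B
}

#' Default synthetic class profiles
#'
#' `default_oil_classes()` returns the three producing-region EVOO profiles
#' (mean pigment extinction per mm of pathlength and relative between-brand
#' SD); the regions differ in tocopherol level, carotene balance and
#' chlorophyll:carotenoid ratio. `default_vegetable_types()` returns the
#' non-olive profiles (corn, sunflower, soy): chlorophyll nearly absent,
#' paler carotenoid bands and a stronger UV edge (`uv_multiplier`).
#'
#' @return Named list of per-class specifications.
#' @export
default_oil_classes <- function() {
  pig <- c("tocopherol_325", "carotenoid_420", "alpha_carotene_447",
           "beta_carotene_451", "gamma_carotene_462", "chlorophyll_670")
  mk <- function(m) stats::setNames(m, pig)
  list(
    Spain  = list(mean = mk(c(0.12, 0.26, 0.065, 0.050, 0.030, 0.030)),
                  brand_rel_sd = 0.08),
    Italy  = list(mean = mk(c(0.17, 0.30, 0.045, 0.080, 0.060, 0.018)),
                  brand_rel_sd = 0.08),
    Turkey = list(mean = mk(c(0.09, 0.22, 0.035, 0.050, 0.025, 0.055)),
                  brand_rel_sd = 0.08)
  )
}

#' @rdname default_oil_classes
#' @export
default_vegetable_types <- function() {
  pig <- c("tocopherol_325", "carotenoid_420", "alpha_carotene_447",
           "beta_carotene_451", "gamma_carotene_462", "chlorophyll_670")
  mk <- function(m) stats::setNames(m, pig)
  list(
    corn      = list(mean = mk(c(0.20, 0.10, 0.020, 0.080, 0.010, 0.002)),
                     brand_rel_sd = 0.08, uv_multiplier = 2.5),
    sunflower = list(mean = mk(c(0.25, 0.05, 0.010, 0.020, 0.005, 0.001)),
                     brand_rel_sd = 0.08, uv_multiplier = 3.0),
    soy       = list(mean = mk(c(0.18, 0.08, 0.015, 0.030, 0.060, 0.004)),
                     brand_rel_sd = 0.08, uv_multiplier = 2.8)
  )
}

#' Configuration for the synthetic oil-spectrum generator
#'
#' The generator emulates a plate-reader acquisition of edible-oil spectra on
#' the 230-1000 nm grid: per-brand pigment concentrations drawn around class
#' means, a steep exponential UV absorption edge that saturates the detector
#' below ~308 nm, Beer-Lambert scaling by the vertical pathlength of the
#' aliquot, per-replicate multiplicative scatter (slope m_i, offset b_i),
#' additive point noise, and capping at the instrument maximum (OD 4).
#' Concentrations are extinction amplitudes per mm of pathlength.
#'
#' @param classes Named list of class specs (`mean` pigment concentration
#'   vector, `brand_rel_sd` relative between-brand SD); default: three
#'   producing-region profiles separated chiefly in chlorophyll:carotenoid
#'   ratio and 325 nm amplitude.
#' @param n_brands_per_class,n_replicates Sample design (default 4 brands x
#'   5 replicates, so 3 classes give 60 spectra).
#' @param weight_mg Aliquot weight (default 200 mg).
#' @param scatter_slope_sd SD of m_i around 1 (default 0.05).
#' @param scatter_offset_sd SD of b_i around 0, OD units (default 0.01).
#' @param noise_sd Additive point noise SD, OD units (default 0.002, the
#'   photometric repeatability scale of a monochromator plate reader).
#' @param uv_tail List `amplitude` (extinction per mm at 230 nm, default 700)
#'   and `decay_nm` (exponential decay constant, default 12), tuned so a
#'   200 mg EVOO aliquot saturates below ~308 nm.
#' @param plate_background List `amplitude` (OD at 230 nm, default 0.05) and
#'   `decay_nm` (default 80): the fixed near-UV absorption of the polystyrene
#'   well itself, added to every plate-reader spectrum regardless of fill and
#'   absent from the quartz-cuvette benchtop condition.
#' @param saturation_cap Detector maximum in OD (default 4).
#' @param grid Wavelength grid (default 230-1000 nm at 1 nm).
#' @param geom A [plate_geometry()] for the Beer-Lambert scaling.
#' @param seed Integer seed; identical seeds give bitwise-identical sets.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(classes = default_oil_classes(),
                             n_brands_per_class = 4,
                             n_replicates = 5,
                             weight_mg = 200,
                             scatter_slope_sd = 0.05,
                             scatter_offset_sd = 0.01,
                             noise_sd = 0.002,
                             uv_tail = list(amplitude = 700, decay_nm = 12),
                             plate_background = list(amplitude = 0.05,
                                                     decay_nm = 80),
                             saturation_cap = 4,
                             grid = wavelength_grid(),
                             geom = plate_geometry(),
                             seed = 0) {
  if (any(c(scatter_slope_sd, scatter_offset_sd, noise_sd) < 0)) {
    stop("all SDs must be >= 0", call. = FALSE)
  }
  if (saturation_cap <= 0) stop("saturation_cap must be > 0", call. = FALSE)
  if (n_brands_per_class < 1 || n_replicates < 1) {
    stop("sample design counts must be >= 1", call. = FALSE)
  }
  if (any(unlist(lapply(classes, `[[`, "mean")) < 0)) {
    stop("pigment concentrations must be >= 0", call. = FALSE)
  }
  structure(list(classes = classes,
                 n_brands_per_class = n_brands_per_class,
                 n_replicates = n_replicates,
                 weight_mg = weight_mg,
                 scatter_slope_sd = scatter_slope_sd,
                 scatter_offset_sd = scatter_offset_sd,
                 noise_sd = noise_sd,
                 uv_tail = uv_tail,
                 plate_background = plate_background,
                 saturation_cap = saturation_cap,
                 grid = grid,
                 geom = geom,
                 seed = seed),
            class = "synthetic_config")
}

with_seed <- function(seed, code) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  code
}

# Extinction-per-mm spectrum for one brand: pigment bands + UV edge.
true_extinction <- function(conc, basis, cfg, uv_multiplier = 1) {
  as.numeric(basis %*% conc) +
    uv_multiplier * cfg$uv_tail$amplitude *
      exp(-(cfg$grid - cfg$grid[1]) / cfg$uv_tail$decay_nm)
}

# Fixed additive OD of the polystyrene well (zero for the quartz cuvette).
plate_background_od <- function(cfg) {
  cfg$plate_background$amplitude *
    exp(-(cfg$grid - cfg$grid[1]) / cfg$plate_background$decay_nm)
}

rnorm_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(x <= 0)) x[x <= 0] <- stats::rnorm(sum(x <= 0), mean, sd)
  x
}

#' Generate a synthetic extra-virgin-olive-oil spectrum set
#'
#' The default configuration emulates the study design of 3 producing
#' regions x 4 brands x 5 replicate wells = 60 plate-reader spectra at
#' 200 mg per well, saturated below ~308 nm. Per brand a pigment
#' concentration vector is drawn around its class mean; per replicate the
#' true Beer-Lambert spectrum is distorted as `m_i * A + b_i`, point noise is
#' added, and the result capped at the detector maximum.
#'
#' @param cfg A [synthetic_config()].
#' @return List with `set` (a `spectrum_set`) and `truth` (the injected
#'   per-brand concentrations and per-replicate scatter slopes/offsets).
#' @export
generate_evoo_set <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(cfg$seed, {
    basis <- pigment_basis(cfg$grid)
    L <- estimate_pathlength(cfg$weight_mg, cfg$geom)
    bg <- plate_background_od(cfg)
    rows <- list(); meta <- list(); truth_conc <- list(); truth_sc <- list()
    for (cls in names(cfg$classes)) {
      spec <- cfg$classes[[cls]]
      for (b in seq_len(cfg$n_brands_per_class)) {
        brand <- paste0(substr(cls, 1, 1), b)
        conc <- rnorm_pos(length(spec$mean), spec$mean,
                          spec$brand_rel_sd * spec$mean)
        names(conc) <- names(spec$mean)
        od_true <- true_extinction(conc, basis, cfg) * L
        for (r in seq_len(cfg$n_replicates)) {
          m_i <- rnorm_pos(1, 1, cfg$scatter_slope_sd)
          b_i <- stats::rnorm(1, 0, cfg$scatter_offset_sd)
          od <- m_i * od_true + bg + b_i +
            stats::rnorm(length(od_true), 0, cfg$noise_sd)
          od <- pmin(od, cfg$saturation_cap)
          id <- paste0(brand, "_r", r)
          rows[[id]] <- od
          meta[[id]] <- data.frame(sample_id = id, class_label = cls,
                                   brand = brand, replicate = r,
                                   weight_mg = cfg$weight_mg,
                                   instrument = "plate_reader",
                                   stringsAsFactors = FALSE)
          truth_sc[[id]] <- data.frame(sample_id = id, slope = m_i,
                                       offset = b_i,
                                       stringsAsFactors = FALSE)
        }
        truth_conc[[brand]] <- data.frame(brand = brand, class_label = cls,
                                          t(conc), stringsAsFactors = FALSE)
      }
    }
    set <- spectrum_set(do.call(rbind, rows), cfg$grid,
                        do.call(rbind, c(meta, make.row.names = FALSE)))
    list(set = set,
         truth = list(
           concentrations = do.call(rbind,
                                    c(truth_conc, make.row.names = FALSE)),
           scatter = do.call(rbind, c(truth_sc, make.row.names = FALSE))))
  })
}

#' Generate synthetic non-olive vegetable-oil spectra
#'
#' Produces plate-reader spectra of refined vegetable oils (by default two
#' corn, four sunflower and two soy): chlorophyll nearly absent, shifted
#' carotenoid balance, and a stronger UV absorption edge so that some spectra
#' remain saturated above 308 nm — exercising overflow capping inside the
#' analysed band.
#'
#' @param cfg A [synthetic_config()] (EVOO class list is ignored here).
#' @param oil_types Character vector of oil types, one entry per generated
#'   spectrum; types must be names of `type_specs`.
#' @param type_specs Named list of per-type profiles (`mean`, `brand_rel_sd`,
#'   `uv_multiplier`).
#' @return List with `set` (a `spectrum_set` labelled by oil type) and
#'   `truth` (injected concentrations).
#' @export
generate_vegetable_oils <- function(cfg = synthetic_config(),
                                    oil_types = c("corn", "corn",
                                                  "sunflower", "sunflower",
                                                  "sunflower", "sunflower",
                                                  "soy", "soy"),
                                    type_specs = default_vegetable_types()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (!all(oil_types %in% names(type_specs))) {
    stop("unknown oil type(s): ",
         paste(setdiff(oil_types, names(type_specs)), collapse = ", "),
         call. = FALSE)
  }
  with_seed(cfg$seed + 104729, {   # offset so EVOO and veg draws differ
    basis <- pigment_basis(cfg$grid)
    L <- estimate_pathlength(cfg$weight_mg, cfg$geom)
    rows <- list(); meta <- list(); truth_conc <- list()
    counter <- stats::setNames(integer(length(type_specs)), names(type_specs))
    for (ty in oil_types) {
      spec <- type_specs[[ty]]
      counter[ty] <- counter[ty] + 1
      id <- paste0(ty, counter[ty])
      conc <- rnorm_pos(length(spec$mean), spec$mean,
                        spec$brand_rel_sd * spec$mean)
      od_true <- true_extinction(conc, basis, cfg, spec$uv_multiplier) * L
      m_i <- rnorm_pos(1, 1, cfg$scatter_slope_sd)
      b_i <- stats::rnorm(1, 0, cfg$scatter_offset_sd)
      od <- m_i * od_true + plate_background_od(cfg) + b_i +
        stats::rnorm(length(od_true), 0, cfg$noise_sd)
      od <- pmin(od, cfg$saturation_cap)
      rows[[id]] <- od
      meta[[id]] <- data.frame(sample_id = id, class_label = ty,
                               brand = id, replicate = 1L,
                               weight_mg = cfg$weight_mg,
                               instrument = "plate_reader",
                               stringsAsFactors = FALSE)
      truth_conc[[id]] <- data.frame(brand = id, class_label = ty, t(conc),
                                     stringsAsFactors = FALSE)
    }
    set <- spectrum_set(do.call(rbind, rows), cfg$grid,
                        do.call(rbind, c(meta, make.row.names = FALSE)))
    list(set = set,
         truth = list(concentrations =
                        do.call(rbind, c(truth_conc,
                                         make.row.names = FALSE))))
  })
}

#' Generate a weight series plus a benchtop-like condition
#'
#' The same true brand spectra (drawn once under the seed) are measured at
#' several aliquot weights with independent scatter and noise, Beer-Lambert
#' scaled by the vertical pathlength of each fill; a benchtop-like set is
#' generated at the fixed cuvette pathlength (10 mm, in triplicate). This is
#' the input for the OD-weight linearity fit and the cross-condition
#' correlation matrix.
#'
#' @param cfg A [synthetic_config()].
#' @param weights Aliquot weights in mg (default 100, 150, 200, 300).
#' @param n_benchtop_replicates Replicates per brand in the benchtop-like set
#'   (default 3).
#' @return List with `plate` (named list of `spectrum_set`s, names
#'   `MTP<weight>`) and `benchtop` (a `spectrum_set`).
#' @export
generate_weight_series <- function(cfg = synthetic_config(),
                                   weights = c(100, 150, 200, 300),
                                   n_benchtop_replicates = 3) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  with_seed(cfg$seed, {
    basis <- pigment_basis(cfg$grid)
    # one concentration draw per brand, shared by every condition
    ext <- list(); cls_of <- list()
    for (cls in names(cfg$classes)) {
      spec <- cfg$classes[[cls]]
      for (b in seq_len(cfg$n_brands_per_class)) {
        brand <- paste0(substr(cls, 1, 1), b)
        conc <- rnorm_pos(length(spec$mean), spec$mean,
                          spec$brand_rel_sd * spec$mean)
        ext[[brand]] <- true_extinction(conc, basis, cfg)
        cls_of[[brand]] <- cls
      }
    }
    measure <- function(pathlength_mm, weight_mg, instrument, n_rep) {
      rows <- list(); meta <- list()
      bg <- if (instrument == "plate_reader") plate_background_od(cfg) else 0
      for (brand in names(ext)) {
        od_true <- ext[[brand]] * pathlength_mm
        for (r in seq_len(n_rep)) {
          m_i <- rnorm_pos(1, 1, cfg$scatter_slope_sd)
          b_i <- stats::rnorm(1, 0, cfg$scatter_offset_sd)
          od <- m_i * od_true + bg + b_i +
            stats::rnorm(length(od_true), 0, cfg$noise_sd)
          od <- pmin(od, cfg$saturation_cap)
          id <- paste0(brand, "_", instrument,
                       if (is.na(weight_mg)) "" else weight_mg, "_r", r)
          rows[[id]] <- od
          meta[[id]] <- data.frame(sample_id = id,
                                   class_label = cls_of[[brand]],
                                   brand = brand, replicate = r,
                                   weight_mg = weight_mg,
                                   instrument = instrument,
                                   stringsAsFactors = FALSE)
        }
      }
      spectrum_set(do.call(rbind, rows), cfg$grid,
                   do.call(rbind, c(meta, make.row.names = FALSE)))
    }
    plate <- lapply(weights, function(w) {
      measure(estimate_pathlength(w, cfg$geom), w, "plate_reader",
              cfg$n_replicates)
    })
    names(plate) <- paste0("MTP", weights)
    benchtop <- measure(cfg$geom$cuvette_pathlength_mm, NA_real_,
                        "benchtop", n_benchtop_replicates)
    list(plate = plate, benchtop = benchtop)
  })
}
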