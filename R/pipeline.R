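#' Load and validate a pipeline run configuration
#'
#' Configurations are plain lists (or YAML files) with the blocks
#' `input` (`spectra`, optional `metadata`, `layout`), `trim`
#' (`min_nm`, `max_nm`), `cap`, `pretreatment` (`steps`, `sg`, `emsc`,
#' `msc_scope`), `pca` (`n_components`), `cv` (`k`, `repeats`, `lv_grid`,
#' `group_by`), `photometry` (geometry fields, `reference_nm`), `output_dir`
#' and `seed`. Missing blocks fall back to the documented defaults. The
#' validated configuration is echoed verbatim into the run manifest.
#'
#' @param x Path to a YAML file, or a list.
#' @return A validated `run_config` list.
#' @export
run_config <- function(x = list()) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  if (!is.list(cfg)) stop("config must be a list or YAML file", call. = FALSE)
  dflt <- list(
    input = list(spectra = NULL, metadata = NULL, layout = "wide"),
    trim = list(min_nm = 308, max_nm = 1000),
    cap = 4,
    pretreatment = list(steps = c("msc", "der1"),
                        sg = list(window = 11, polyorder = 2),
                        emsc = list(degree = 2),
                        msc_scope = "fold"),
    pca = list(n_components = 4),
    cv = list(k = 5, repeats = 10, lv_grid = 1:10, group_by = "spectrum"),
    photometry = list(well_diameter_cm = 0.86, oil_density_g_cm3 = 0.9113,
                      cuvette_pathlength_mm = 10, reference_nm = 415,
                      weights = c(100, 150, 200, 300)),
    output_dir = "platespec_run",
    seed = 1
  )
  cfg <- utils::modifyList(dflt, cfg)
  if (!cfg$pretreatment$msc_scope %in% c("fold", "global")) {
    stop("pretreatment$msc_scope must be 'fold' or 'global'", call. = FALSE)
  }
  if (cfg$cap <= 0) stop("cap must be > 0", call. = FALSE)
  structure(cfg, class = "run_config")
}

stage_log <- function(con, stage, ...) {
  line <- paste0(format(Sys.time(), "%H:%M:%S"), " [", stage, "] ",
                 paste0(..., collapse = ""))
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

#' Run the end-to-end plate-reader chemometric pipeline
#'
#' Stages, in fixed order: ingest (or accept an in-memory set), overflow cap,
#' band trim, pretreatment, PCA report, PLS-DA repeated-CV report, photometry
#' report. Outputs (scores/loadings/variance CSVs, CV CSV + JSON, photometry
#' CSVs, a structured run log and a JSON manifest with config echo, seed and
#' per-stage shapes) land in `cfg$output_dir`. Identical config and seed give
#' identical outputs. Any stage error aborts the run and removes partial
#' outputs.
#'
#' @param cfg A [run_config()] (or list/YAML path coercible to one).
#' @param spectra Optional in-memory `spectrum_set`, used instead of
#'   `cfg$input$spectra`; when both are absent the default synthetic EVOO
#'   preset is generated under `cfg$seed`.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(cfg = run_config(), spectra = NULL) {
  if (!inherits(cfg, "run_config")) cfg <- run_config(cfg)
  out_dir <- cfg$output_dir
  created <- !dir.exists(out_dir)
  if (created) dir.create(out_dir, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  con <- file(log_path, open = "wt")
  ok <- FALSE
  on.exit({
    close(con)
    if (!ok) {
      # remove partial outputs of a failed run (only files this run owns)
      own <- c("run.log", "pca_scores.csv", "pca_loadings.csv",
               "pca_variance.csv", "cv_accuracy.csv", "cv_result.json",
               "photometry_pathlengths.csv", "manifest.json")
      unlink(file.path(out_dir, own))
      if (created) unlink(out_dir, recursive = TRUE)
    }
  })
  manifest <- list(package_version = as.character(
    utils::packageVersion("platespec")),
    seed = cfg$seed, config = unclass(cfg), stages = list())

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  s <- run_stage("ingest", {
    if (!is.null(spectra)) {
      spectra
    } else if (!is.null(cfg$input$spectra)) {
      read_spectra(cfg$input$spectra, layout = cfg$input$layout,
                   metadata_path = cfg$input$metadata)
    } else {
      generate_evoo_set(synthetic_config(seed = cfg$seed))$set
    }
  })
  stage_log(con, "ingest", n_samples(s), " samples x ", n_wavelengths(s),
            " wavelengths")
  manifest$stages$ingest <- dim(s$od)

  s <- run_stage("cap", cap_overflow(s, cap = cfg$cap))
  stage_log(con, "cap", attr(s, "n_capped"), " cells capped at ", cfg$cap)
  manifest$stages$cap <- list(dim = dim(s$od),
                              n_capped = attr(s, "n_capped"))

  s <- run_stage("trim", trim_band(s, cfg$trim$min_nm, cfg$trim$max_nm))
  stage_log(con, "trim", n_wavelengths(s), " variables retained in [",
            cfg$trim$min_nm, ", ", cfg$trim$max_nm, "] nm")
  manifest$stages$trim <- dim(s$od)

  pre <- run_stage("pretreat", apply_pretreatment(
    s, NULL, steps = cfg$pretreatment$steps, sg = cfg$pretreatment$sg,
    emsc_degree = cfg$pretreatment$emsc$degree, msc_scope = "global")$train)
  stage_log(con, "pretreat", paste(cfg$pretreatment$steps, collapse = "+"),
            " -> ", n_wavelengths(pre), " variables")
  manifest$stages$pretreat <- dim(pre$od)

  pca <- run_stage("pca", fit_pca(pre, cfg$pca$n_components))
  export_pca(pca, out_dir)
  n_pcs <- select_n_pcs(pca)
  stage_log(con, "pca", "variance ",
            paste(sprintf("%.2f%%", 100 * pca$explained_variance_ratio),
                  collapse = "/"), "; selected ", n_pcs, " PCs")
  manifest$stages$pca <- list(
    explained_variance_ratio = unname(pca$explained_variance_ratio),
    selected_n_pcs = n_pcs)

  cv <- run_stage("plsda_cv", cross_validate(
    s, cv_config(k = cfg$cv$k, repeats = cfg$cv$repeats, seed = cfg$seed,
                 lv_grid = cfg$cv$lv_grid, group_by = cfg$cv$group_by),
    steps = cfg$pretreatment$steps, sg = cfg$pretreatment$sg,
    emsc_degree = cfg$pretreatment$emsc$degree,
    msc_scope = cfg$pretreatment$msc_scope))
  export_cv(cv, out_dir)
  stage_log(con, "plsda_cv", "selected ", cv$selected_lv, " LVs, accuracy ",
            sprintf("%.4f", cv$accuracy_by_lv[match(cv$selected_lv,
                                                    cv$lv_grid)]))
  manifest$stages$plsda_cv <- list(
    accuracy_by_lv = as.list(cv$accuracy_by_lv),
    selected_lv = cv$selected_lv)

  phot <- run_stage("photometry", {
    geom <- plate_geometry(cfg$photometry$well_diameter_cm,
                           cfg$photometry$oil_density_g_cm3,
                           cfg$photometry$cuvette_pathlength_mm)
    w <- cfg$photometry$weights
    df <- data.frame(weight_mg = w,
                     pathlength_mm = estimate_pathlength(w, geom),
                     cuvette_ratio = pathlength_ratio(w, geom))
    utils::write.csv(df, file.path(out_dir, "photometry_pathlengths.csv"),
                     row.names = FALSE)
    df
  })
  stage_log(con, "photometry", "pathlengths ",
            paste(sprintf("%.1f", phot$pathlength_mm), collapse = "/"), " mm")
  manifest$stages$photometry <- phot

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  ok <- TRUE
  invisible(manifest)
}

#' Compare pretreatment pipelines under shared cross-validation folds
#'
#' Runs [cross_validate()] once per candidate pretreatment with the same
#' master seed, so every candidate sees identical fold assignments, and
#' tabulates the accuracy at each candidate's selected latent-variable count.
#'
#' @param s A `spectrum_set` (capped and trimmed).
#' @param candidates Named list of pretreatment step vectors, e.g.
#'   `list(raw = "raw", msc = "msc", msc_der1 = c("msc", "der1"))`.
#' @param cfg A [cv_config()] shared by all candidates.
#' @return Data frame, one row per candidate, sorted by descending accuracy:
#'   `pretreatment`, `selected_lv`, `accuracy`, `accuracy_5lv` (accuracy at
#'   5 LVs when on the grid). The per-candidate `cv_result`s are attached as
#'   attribute `"cv_results"`.
#' @export
compare_pretreatments <- function(s,
                                  candidates = list(
                                    raw = "raw",
                                    msc = "msc",
                                    msc_der1 = c("msc", "der1")),
                                  cfg = cv_config()) {
  if (length(candidates) < 1) stop("need at least one candidate",
                                   call. = FALSE)
  if (is.null(names(candidates))) {
    names(candidates) <- vapply(candidates, paste, "", collapse = "+")
  }
  results <- lapply(candidates, function(steps) {
    cross_validate(s, cfg, steps = steps)
  })
  acc_at <- function(r, lv) {
    j <- match(lv, r$lv_grid)
    if (is.na(j)) NA_real_ else unname(r$accuracy_by_lv[j])
  }
  tab <- data.frame(
    pretreatment = names(candidates),
    selected_lv = vapply(results, `[[`, 0L, "selected_lv"),
    accuracy = vapply(results, function(r) acc_at(r, r$selected_lv), 0),
    accuracy_5lv = vapply(results, function(r) acc_at(r, 5L), 0),
    stringsAsFactors = FALSE
  )
  tab <- tab[order(-tab$accuracy), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "cv_results") <- results
  tab
}
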