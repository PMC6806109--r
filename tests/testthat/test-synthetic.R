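test_that("the default preset reproduces the study design: 60 balanced
           spectra, 693 variables after trimming", {
  gen <- generate_evoo_set(synthetic_config(seed = 0))
  s <- gen$set
  expect_equal(n_samples(s), 60)
  expect_equal(unname(table(s$meta$class_label)), rep(20L, 3),
               ignore_attr = TRUE)
  expect_equal(n_wavelengths(s), 771)
  expect_equal(n_wavelengths(trim_band(cap_overflow(s))), 693)
  # the far-UV region is saturated, as on the instrument
  uv <- s$od[, s$wavelength <= 300]
  expect_true(all(uv == 4))
  expect_equal(nrow(gen$truth$concentrations), 12)
  expect_equal(nrow(gen$truth$scatter), 60)
})

test_that("generation is bitwise deterministic under a seed and leaves the
           global RNG state unchanged", {
  cfg <- synthetic_config(seed = 42)
  g1 <- generate_evoo_set(cfg)
  set.seed(999)
  state <- .Random.seed
  g2 <- generate_evoo_set(cfg)
  expect_identical(state, .Random.seed)
  expect_identical(g1$set$od, g2$set$od)
  expect_identical(g1$truth, g2$truth)
  g3 <- generate_evoo_set(synthetic_config(seed = 43))
  expect_false(identical(g1$set$od, g3$set$od))
})

test_that("replicates collapse to identical spectra when scatter and noise
           vanish", {
  cfg <- synthetic_config(seed = 5, scatter_slope_sd = 0,
                          scatter_offset_sd = 0, noise_sd = 0)
  s <- generate_evoo_set(cfg)$set
  for (b in unique(s$meta$brand)) {
    reps <- s$od[s$meta$brand == b, ]
    expect_lt(max(abs(sweep(reps, 2, reps[1, ], "-"))), 1e-12)
  }
})

test_that("MSC recovers the injected scatter slopes and offsets from a
           noise-free brand", {
  cfg <- synthetic_config(seed = 9, noise_sd = 0,
                          uv_tail = list(amplitude = 0, decay_nm = 12),
                          plate_background = list(amplitude = 0,
                                                  decay_nm = 80))
  gen <- generate_evoo_set(cfg)
  s <- gen$set
  brand <- s$meta$brand[1]
  idx <- which(s$meta$brand == brand)
  # the brand's true spectrum: invert the first replicate's known scatter
  sc <- gen$truth$scatter[idx, ]
  truth_spec <- (s$od[idx[1], ] - sc$offset[1]) / sc$slope[1]
  model <- fit_msc(subset_samples(s, idx), reference = truth_spec)
  expect_equal(model$slope, sc$slope, tolerance = 1e-8)
  expect_equal(model$offset, sc$offset, tolerance = 1e-8)
})

test_that("class structure is the dominant signal: class means separate
           beyond within-class spread in derivative space", {
  # brand-mean spectra (replicate noise averaged out) must cluster by class:
  # mean silhouette over the 12 brand means, grouped by region, is positive
  s <- trim_band(cap_overflow(generate_evoo_set(synthetic_config(seed = 3))$set))
  d <- msc_der1(s)
  brand_means <- do.call(rbind, lapply(
    split(seq_len(n_samples(d)), d$meta$brand),
    function(i) colMeans(d$od[i, , drop = FALSE])))
  cls <- d$meta$class_label[match(rownames(brand_means), d$meta$brand)]
  D <- as.matrix(stats::dist(brand_means))
  sil <- vapply(seq_len(nrow(brand_means)), function(i) {
    own <- cls == cls[i] & seq_len(nrow(brand_means)) != i
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(cls), cls[i]),
                    function(cl) mean(D[i, cls == cl]), 0))
    (b - a) / max(a, b)
  }, 0)
  expect_gt(mean(sil), 0)
})

test_that("vegetable oils carry in-band saturation and separate from olive
           oils in the first two PCs", {
  cfg <- synthetic_config(seed = 0)
  veg <- generate_vegetable_oils(cfg)
  expect_equal(n_samples(veg$set), 8)
  expect_identical(veg$set$meta$class_label,
                   c("corn", "corn", "sunflower", "sunflower", "sunflower",
                     "sunflower", "soy", "soy"))
  trimmed <- trim_band(cap_overflow(veg$set))
  expect_gt(sum(trimmed$od == 4), 0)   # capped cells inside 308-1000 nm
  # combined with EVOOs: olive vs non-olive is linearly separable in PC1-2
  evoo <- generate_evoo_set(cfg)$set
  combined <- spectrum_set(rbind(evoo$od, veg$set$od), evoo$wavelength,
                           rbind(evoo$meta, veg$set$meta))
  pre <- msc_der1(trim_band(cap_overflow(combined)))
  sc <- fit_pca(pre, 2)$scores
  is_olive <- as.integer(seq_len(nrow(sc)) <= n_samples(evoo))
  fit <- suppressWarnings(stats::glm(is_olive ~ sc[, 1] + sc[, 2],
                                     family = stats::binomial))
  expect_true(all((fit$fitted.values > 0.5) == (is_olive == 1)))
})

test_that("zero-noise vegetable oil types have pairwise distinct mean
           spectra", {
  cfg <- synthetic_config(seed = 2, noise_sd = 0, scatter_slope_sd = 0,
                          scatter_offset_sd = 0)
  veg <- trim_band(generate_vegetable_oils(cfg)$set, 330, 1000)
  types <- unique(veg$meta$class_label)
  for (i in seq_along(types)) for (j in seq_along(types)) {
    if (i >= j) next
    mi <- colMeans(veg$od[veg$meta$class_label == types[i], , drop = FALSE])
    mj <- colMeans(veg$od[veg$meta$class_label == types[j], , drop = FALSE])
    expect_gt(max(abs(mi - mj)), 10 * 0.002)
  }
})

test_that("the weight series obeys Beer-Lambert scaling against the
           benchtop condition", {
  # UV edge and plate background off: no saturation and no well absorption,
  # so every condition is an exact scalar multiple of the benchtop shape
  cfg <- synthetic_config(seed = 6, noise_sd = 0, scatter_slope_sd = 0,
                          scatter_offset_sd = 0,
                          uv_tail = list(amplitude = 0, decay_nm = 12),
                          plate_background = list(amplitude = 0,
                                                  decay_nm = 80))
  ws <- generate_weight_series(cfg, weights = c(100, 200))
  # zero noise: plate OD = (L(w)/10) x benchtop OD away from saturation
  keep <- ws$benchtop$wavelength >= 400 & ws$benchtop$wavelength <= 700
  bench <- colMeans(ws$benchtop$od)[keep]
  for (w in c(100, 200)) {
    plate <- colMeans(ws$plate[[paste0("MTP", w)]]$od)[keep]
    L <- estimate_pathlength(w, cfg$geom)
    expect_equal(plate, bench * L / 10, tolerance = 1e-10)
  }
  # zero noise: all condition correlations are 1
  cm <- condition_correlation(c(ws$plate, list(benchtop = ws$benchtop)))
  expect_equal(unname(cm), matrix(1, 3, 3), tolerance = 1e-9)
})

test_that("mean OD at 415 nm is affine in aliquot weight at default noise", {
  ws <- generate_weight_series(synthetic_config(seed = 1))
  j <- match(415, ws$plate[[1]]$wavelength)
  od415 <- vapply(ws$plate, function(s) mean(s$od[, j]), 0)
  fit <- fit_od_weight(c(100, 150, 200, 300), od415)
  expect_gt(fit$r_squared, 0.999)
  expect_gt(fit$slope, 0)
})

test_that("invalid generator configurations are rejected", {
  expect_error(synthetic_config(noise_sd = -1), "SDs")
  expect_error(synthetic_config(saturation_cap = 0), "saturation_cap")
  expect_error(synthetic_config(n_replicates = 0), "design")
  cls <- default_oil_classes()
  cls$Spain$mean[1] <- -0.1
  expect_error(synthetic_config(classes = cls), "concentrations")
  expect_error(generate_vegetable_oils(synthetic_config(),
                                       oil_types = "palm"), "unknown")
})
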