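# Small in-code fixtures shared across test files.

# A deterministic toy spectrum set: smooth Gaussian-band spectra plus seeded
# noise on an arbitrary uniform grid.
make_toy_set <- function(n = 6, wl = seq(400, 500, by = 5), seed = 42,
                         noise_sd = 0.01, labels = NULL) {
  set.seed(seed)
  base <- exp(-((wl - 440)^2) / (2 * 15^2)) + 0.5 * exp(-((wl - 480)^2) /
                                                          (2 * 10^2))
  od <- t(vapply(seq_len(n), function(i) {
    (0.5 + i / n) * base + rnorm(length(wl), 0, noise_sd)
  }, numeric(length(wl))))
  meta <- data.frame(sample_id = sprintf("t%02d", seq_len(n)),
                     stringsAsFactors = FALSE)
  if (!is.null(labels)) meta$class_label <- rep_len(labels, n)
  spectrum_set(od, wl, meta)
}

# Scatter-corrupted copies of one reference spectrum: od_i = m_i * ref + b_i.
make_scatter_set <- function(ref, m, b, wl = seq_along(ref) + 299) {
  od <- t(vapply(seq_along(m), function(i) m[i] * ref + b[i],
                 numeric(length(ref))))
  spectrum_set(od, wl)
}

# A well-separated 3-class set for classification tests: class-specific band
# amplitudes, small noise.
make_separable_set <- function(n_per_class = 10, wl = seq(400, 600, by = 4),
                               seed = 1, noise_sd = 0.01) {
  set.seed(seed)
  shapes <- list(
    A = 1.0 * exp(-((wl - 430)^2) / 800) + 0.2 * exp(-((wl - 560)^2) / 500),
    B = 0.5 * exp(-((wl - 430)^2) / 800) + 0.9 * exp(-((wl - 560)^2) / 500),
    C = 0.8 * exp(-((wl - 490)^2) / 700) + 0.4 * exp(-((wl - 560)^2) / 500)
  )
  od <- do.call(rbind, lapply(names(shapes), function(cl) {
    t(replicate(n_per_class, shapes[[cl]] + rnorm(length(wl), 0, noise_sd)))
  }))
  meta <- data.frame(
    sample_id = sprintf("%s%02d", rep(names(shapes), each = n_per_class),
                        seq_len(n_per_class)),
    class_label = rep(names(shapes), each = n_per_class),
    stringsAsFactors = FALSE
  )
  spectrum_set(od, wl, meta)
}
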