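# Shared fixtures: everything is generated in code at test time.

# Reduced study design: 2 weeks x 4 cards x triplicates, 3 classes
# (72 samples) - small enough for Monte-Carlo loops, still card/day
# structured.
smallDesign <- function(n_weeks = 2, cards_per_week = 4) {
  generateDesign(designConfig(n_weeks = n_weeks,
                              cards_per_week = cards_per_week))
}

# Minimal custom catalog: six fragments, two per voltage, with known
# per-voltage support and one noise fragment far below the selection
# threshold. Used as the generator-catalog oracle in selection tests.
toyModel <- function(noise_sd = 0.15, week_effect_sd = 0,
                     week_shared_sd = 0, mass_jitter = 0, ...) {
  catalog <- data.frame(
    fragment = paste0("t", 1:7),
    voltage = c(30, 30, 60, 60, 90, 90, 60),
    mz = c(150.060, 121.040, 150.060, 93.060, 77.035, 65.039, 180.110),
    log_mean = log(c(1e6, 5e4, 3e5, 6e4, 2e5, 4e4, 6e2)))
  effects <- rbind(c(0, 0, 0),
                   c(0, 0.8, -0.8),
                   c(0, 0.2, -0.2),
                   c(0, -0.9, 0.8),
                   c(0, 0.3, -0.3),
                   c(0, 0.9, -0.7),
                   c(0, 0, 0))
  spectrumModel(catalog = catalog, class_log_effect = effects,
                noise_sd = noise_sd, week_effect_sd = week_effect_sd,
                week_shared_sd = week_shared_sd,
                mass_jitter = mass_jitter, ...)
}

# Raw binned table from the toy generator.
toyTable <- function(seed = 1, design = smallDesign(), model = toyModel()) {
  assembleTable(applyAbundanceFloor(simulateSpectra(design, model,
                                                    seed = seed), 120))
}

# Normalised toy table with all selection machinery applied
# (min_spectra scaled to the smaller design).
toyNormalized <- function(seed = 1, scheme = "ion_current",
                          design = smallDesign(), model = toyModel(),
                          min_spectra = 30) {
  tab <- toyTable(seed, design, model)
  vars <- selectVariables(tab, pct_threshold = 1,
                          min_spectra = min_spectra)
  normalizeSpectra(tab, vars, scheme)
}

# Hand-built CentroidSpectra from a peak data.frame (fills metadata).
makeSpectra <- function(peaks) {
  ids <- unique(peaks$sample_id)
  md <- data.frame(sample_id = ids, class = "a", week = 1L,
                   card = "W1.C1", replicate = seq_along(ids),
                   volume = 3, batch = "main", day = 1L)
  CentroidSpectra(peaks, md)
}

# Misclassification rate with a tied/NA call counted as wrong.
errorRate <- function(predicted, truth) {
  predicted[is.na(predicted)] <- "<tie>"
  mean(predicted != as.character(truth))
}
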