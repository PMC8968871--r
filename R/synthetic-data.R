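#' Study design configuration for the synthetic generator
#'
#' Describes the acquisition design the generator replicates: a set of
#' positional isomers deposited in triplicate on QuickStrip cards, several
#' cards per weekly session, at alternating deposition volumes, and three
#' Orifice-1 voltages recorded per analysis. The defaults reproduce the
#' reference design: 3 isomers, 8 weeks x 4 cards/week x 3 replicates/card
#' = 96 analyses per compound (288 per isomer set), two cards per week at
#' 3 uL and two at 6 uL, and 30/60/90 V channels.
#'
#' @param n_classes number of isomer classes.
#' @param n_weeks number of weekly acquisition sessions.
#' @param cards_per_week QuickStrip cards analysed per week.
#' @param replicates_per_card triplicate size: analyses of each compound
#'   per card.
#' @param volumes deposition volumes (uL); cards within a week are split
#'   into contiguous groups, one volume per group.
#' @param voltages ordered Orifice-1 voltage labels (V).
#' @param classes optional class labels; defaults to positional names
#'   (`"ortho"`, `"meta"`, `"para"`, then `"iso4"`, ...).
#' @param seed default seed recorded with generated data.
#' @return A list of class `"DesignConfig"`.
#' @examples
#' cfg <- designConfig()
#' nrow(generateDesign(cfg))  # 288
#' @export
designConfig <- function(n_classes = 3, n_weeks = 8, cards_per_week = 4,
                         replicates_per_card = 3, volumes = c(3, 6),
                         voltages = c(30, 60, 90), classes = NULL,
                         seed = 20210317) {
  n_classes <- .assertCount(n_classes, "n_classes")
  n_weeks <- .assertCount(n_weeks, "n_weeks")
  cards_per_week <- .assertCount(cards_per_week, "cards_per_week")
  replicates_per_card <- .assertCount(replicates_per_card,
                                      "replicates_per_card")
  if (!length(volumes) || any(volumes <= 0))
    stop("configuration error: volumes must be positive", call. = FALSE)
  if (is.null(classes)) {
    base <- c("ortho", "meta", "para")
    classes <- if (n_classes <= 3) base[seq_len(n_classes)] else
      c(base, paste0("iso", 4:n_classes))
  }
  if (length(classes) != n_classes)
    stop("configuration error: length(classes) must equal n_classes",
         call. = FALSE)
  structure(list(n_classes = n_classes, n_weeks = n_weeks,
                 cards_per_week = cards_per_week,
                 replicates_per_card = replicates_per_card,
                 volumes = volumes, voltages = voltages,
                 classes = classes, seed = as.integer(seed)),
            class = "DesignConfig")
}

# Volume for card index c within a week: cards are split into
# length(volumes) contiguous groups (two 3-uL cards then two 6-uL cards in
# the default design).
.cardVolume <- function(card_index, cards_per_week, volumes) {
  g <- ceiling(cards_per_week / length(volumes))
  volumes[pmin(((card_index - 1L) %/% g) + 1L, length(volumes))]
}

#' Generate the per-sample metadata records of a study design
#'
#' Expands a [designConfig()] into one metadata record per analysis:
#' every card carries each isomer class in triplicate, cards are numbered
#' uniquely within week, and deposition volume follows the card rule.
#' Each weekly session is a single acquisition day, so `day` equals `week`.
#'
#' @param config a [designConfig()].
#' @return `data.frame` with columns `sample_id`, `class`, `week`, `card`,
#'   `replicate`, `volume`, `batch`, `day`; one row per analysis,
#'   `n_weeks * cards_per_week * replicates_per_card` rows per class.
#' @export
generateDesign <- function(config = designConfig()) {
  stopifnot(inherits(config, "DesignConfig"))
  grid <- expand.grid(replicate = seq_len(config$replicates_per_card),
                      class = config$classes,
                      card_index = seq_len(config$cards_per_week),
                      week = seq_len(config$n_weeks),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  volume <- .cardVolume(grid$card_index, config$cards_per_week,
                        config$volumes)
  card <- sprintf("W%d.C%d", grid$week, grid$card_index)
  data.frame(
    sample_id = sprintf("%s_W%d_C%d_R%d", grid$class, grid$week,
                        grid$card_index, grid$replicate),
    class = grid$class,
    week = grid$week,
    card = card,
    replicate = grid$replicate,
    volume = volume,
    batch = "main",
    day = grid$week,
    stringsAsFactors = FALSE)
}

#' Spectral generating model for synthetic multi-voltage spectra
#'
#' Defines the fragment catalog and variance components used by
#' [simulateSpectra()]. Abundances are generated multiplicatively on the
#' log scale: for fragment f of sample s,
#' `log A = log_mean(f) + e * effect(class(s), f) + W(week(s)) +
#'  U(week(s), f) + log v(volume(s)) + N(0, noise_sd^2)`,
#' where `e` is `class_effect_size`, `W` a week-level intensity drift
#' shared by all fragments, `U` an idiosyncratic per-(fragment, week)
#' drift, and `v` the deposition-volume factor. Observed peak m/z is the
#' true fragment m/z plus a small uniform mass jitter.
#'
#' The default catalog emulates a protonated fluorinated-amphetamine-type
#' compound: an uninformative molecular-ion region at 30 V and
#' fragment-rich 60/90 V channels produced by in-source CID, with the
#' positional information carried by fragment ratios — including one
#' low-abundance fragment near the percent-abundance selection threshold
#' — and with one abundant fragment carrying no class effect at all (a
#' negative control for importance and ANOVA screening). Two further
#' trace fragments sit below the 1% selection threshold so that variable
#' selection has something to discard.
#'
#' @param catalog `data.frame` with columns `fragment`, `voltage`, `mz`,
#'   `log_mean` (log counts for the reference class).
#' @param class_log_effect numeric matrix, fragments x classes, of log
#'   multiplicative class effects (reference class column all zero).
#' @param class_effect_size global scalar multiplying all class effects;
#'   0 removes every class difference.
#' @param week_effect_sd SD (log scale) of the per-(fragment, week) drift.
#' @param week_shared_sd SD (log scale) of the week-level drift shared by
#'   all fragments (cancelled by per-voltage normalisation).
#' @param volume_effect named multiplicative factors per deposition
#'   volume (uL); sub-proportional in volume, reflecting ionisation
#'   saturation.
#' @param noise_sd per-peak lognormal noise SD (log scale).
#' @param mass_jitter half-width (Da) of the uniform mass jitter; the
#'   default is one fifth of the 0.025 Da bin width so a fragment maps to
#'   a stable bin.
#' @return A list of class `"SpectrumModel"`.
#' @export
spectrumModel <- function(catalog = NULL, class_log_effect = NULL,
                          class_effect_size = 1,
                          week_effect_sd = 0.35, week_shared_sd = 0.25,
                          volume_effect = c("3" = 1, "6" = 1.8, "10" = 2.6),
                          noise_sd = 0.25, mass_jitter = 0.005) {
  if (is.null(catalog)) {
    def <- .defaultCatalog()
    catalog <- def$catalog
    if (is.null(class_log_effect)) class_log_effect <- def$effects
  }
  catalog <- as.data.frame(catalog)
  stopifnot(all(c("fragment", "voltage", "mz", "log_mean") %in%
                  names(catalog)))
  if (is.null(class_log_effect))
    stop("class_log_effect is required with a custom catalog")
  class_log_effect <- as.matrix(class_log_effect)
  if (nrow(class_log_effect) != nrow(catalog))
    stop("class_log_effect must have one row per catalog fragment")
  if (any(!is.finite(catalog$log_mean)))
    stop("all fragment mean abundances must be strictly positive")
  if (week_effect_sd < 0 || week_shared_sd < 0 || noise_sd < 0 ||
      mass_jitter < 0)
    stop("variance components must be non-negative")
  structure(list(catalog = catalog, class_log_effect = class_log_effect,
                 class_effect_size = class_effect_size,
                 week_effect_sd = week_effect_sd,
                 week_shared_sd = week_shared_sd,
                 volume_effect = volume_effect, noise_sd = noise_sd,
                 mass_jitter = mass_jitter),
            class = "SpectrumModel")
}

# Default fragment catalog: 3 classes (ortho/meta/para-type). Effects are
# log multipliers relative to the first class.
.defaultCatalog <- function() {
  catalog <- data.frame(
    fragment = paste0("f", 1:16),
    voltage = c(30, 30, 30, 30,
                60, 60, 60, 60, 60, 60,
                90, 90, 90, 90, 90,
                30),
    mz = c(154.112, 155.106, 136.090, 196.113,
           154.112, 137.088, 109.045, 91.060, 119.086, 65.039,
           137.088, 109.045, 83.060, 57.070, 39.035,
           278.120),
    log_mean = log(c(1.0e6, 1.1e5, 3.0e4, 3.0e3,
                     4.0e5, 2.5e5, 8.0e4, 1.5e4, 7.0e3, 1.2e3,
                     1.2e5, 1.5e5, 2.0e5, 4.0e4, 8.0e2,
                     150)),
    stringsAsFactors = FALSE)
  effects <- rbind(
    c(0,  0.00,  0.00),   # f1  molecular ion, zero class effect
    c(0,  0.00,  0.00),   # f2  isotope-like satellite, zero effect
    c(0,  0.34, -0.38),   # f3  weak in-source fragment
    c(0,  0.00,  0.00),   # f4  adduct below selection threshold
    c(0,  0.18, -0.14),   # f5  surviving molecular ion at 60 V
    c(0,  0.77, -0.78),   # f6  strong diagnostic fragment
    c(0, -0.90,  0.83),   # f7  strong diagnostic fragment
    c(0,  0.61, -0.56),   # f8  mid-abundance diagnostic
    c(0,  0.72, -0.72),   # f9  low-abundance diagnostic near threshold
    c(0,  0.00,  0.00),   # f10 trace, below threshold
    c(0,  0.69, -0.66),   # f11
    c(0, -1.04,  0.77),   # f12
    c(0,  0.29, -0.29),   # f13 base peak at 90 V, weak effect
    c(0, -0.66,  0.53),   # f14 low-abundance diagnostic
    c(0,  0.00,  0.00),   # f15 trace, below threshold
    c(0,  0.00,  0.00))   # f16 near the centroid abundance floor
  list(catalog = catalog, effects = effects)
}

# Core sampler shared by the main and external batches. week_scale
# multiplies both week-drift SDs; log_scale shifts every log abundance.
.simulate <- function(design, model, seed, week_scale = 1, log_scale = 0) {
  stopifnot(inherits(model, "SpectrumModel"), nrow(design) > 0)
  classes <- sort(unique(design$class))
  if (ncol(model$class_log_effect) < length(classes))
    stop("model has fewer class-effect columns than classes in the design")
  weeks <- sort(unique(design$week))
  nf <- nrow(model$catalog)
  vols <- unique(as.character(design$volume))
  if (!all(vols %in% names(model$volume_effect)))
    stop("volume_effect has no factor for volume(s): ",
         paste(setdiff(vols, names(model$volume_effect)), collapse = ", "))
  .withSeed(seed, {
    w_shared <- stats::rnorm(length(weeks), 0,
                             model$week_shared_sd * week_scale)
    names(w_shared) <- as.character(weeks)
    w_idio <- matrix(stats::rnorm(length(weeks) * nf, 0,
                                  model$week_effect_sd * week_scale),
                     nrow = length(weeks),
                     dimnames = list(as.character(weeks), NULL))
    n <- nrow(design)
    out <- vector("list", n)
    for (i in seq_len(n)) {
      cls <- match(design$class[i], classes)
      wk <- as.character(design$week[i])
      la <- model$catalog$log_mean +
        model$class_effect_size * model$class_log_effect[, cls] +
        w_shared[[wk]] + w_idio[wk, ] +
        log(model$volume_effect[[as.character(design$volume[i])]]) +
        stats::rnorm(nf, 0, model$noise_sd) + log_scale
      mz <- model$catalog$mz +
        stats::runif(nf, -model$mass_jitter, model$mass_jitter)
      out[[i]] <- data.frame(sample_id = design$sample_id[i],
                             voltage = model$catalog$voltage,
                             mz = mz, abundance = exp(la),
                             stringsAsFactors = FALSE)
    }
    CentroidSpectra(do.call(rbind, out), design,
                    runInfo = list(seed = as.integer(seed),
                                   week_scale = week_scale,
                                   log_scale = log_scale))
  })
}

#' Simulate centroided multi-voltage spectra for a study design
#'
#' Draws one centroided spectrum per sample per voltage from a
#' [spectrumModel()], reproducing the variance structure the downstream
#' analysis assumes: multiplicative class effects, week-level batch drift
#' shared within an acquisition session, deposition-volume response, and
#' per-peak lognormal noise. Output is bit-identical for a given seed.
#'
#' @param design metadata records from [generateDesign()].
#' @param model a [spectrumModel()].
#' @param seed integer RNG seed.
#' @return A [CentroidSpectra-class] object.
#' @examples
#' sim <- simulateSpectra(generateDesign(designConfig(n_weeks = 1,
#'   cards_per_week = 1)), spectrumModel(), seed = 1)
#' sim
#' @export
simulateSpectra <- function(design, model = spectrumModel(),
                            seed = 20210317) {
  .simulate(design, model, seed)
}

#' Generate a shifted external validation batch
#'
#' Emulates an independently acquired validation set: the same fragment
#' catalog, but a globally rescaled intensity (a different solution
#' concentration), its own card-level sessions with amplified week-type
#' drift, and its own deposition-volume pattern (first three cards at
#' 10 uL, the rest at 3 uL, mirroring an 11-card external set). Each card
#' is treated as its own acquisition day.
#'
#' @param model a [spectrumModel()].
#' @param n_cards number of external QuickStrip cards.
#' @param shift list with `intensity_scale` (global multiplicative
#'   abundance factor) and `drift_scale` (multiplier on both week-drift
#'   SDs); `list(intensity_scale = 1, drift_scale = 1)` makes the batch
#'   distributionally identical to a main batch of the same shape.
#' @param classes isomer labels (defaults to the reference three).
#' @param replicates_per_card triplicate size.
#' @param volumes per-card deposition volumes (uL); recycled/truncated to
#'   `n_cards`.
#' @param seed integer RNG seed.
#' @return A [CentroidSpectra-class] object with `batch = "external"`.
#' @export
generateExternalBatch <- function(model = spectrumModel(), n_cards = 11,
                                  shift = list(intensity_scale = 10,
                                               drift_scale = 1.5),
                                  classes = c("ortho", "meta", "para"),
                                  replicates_per_card = 3,
                                  volumes = c(10, 10, 10,
                                              rep(3, max(0, n_cards - 3))),
                                  seed = 20200901) {
  n_cards <- .assertCount(n_cards, "n_cards")
  volumes <- rep_len(volumes, n_cards)
  grid <- expand.grid(replicate = seq_len(replicates_per_card),
                      class = classes, card_index = seq_len(n_cards),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design <- data.frame(
    sample_id = sprintf("X_%s_C%d_R%d", grid$class, grid$card_index,
                        grid$replicate),
    class = grid$class,
    week = 100L + grid$card_index,   # each card its own session
    card = sprintf("X.C%d", grid$card_index),
    replicate = grid$replicate,
    volume = volumes[grid$card_index],
    batch = "external",
    day = 100L + grid$card_index,
    stringsAsFactors = FALSE)
  scale <- if (is.null(shift$intensity_scale)) 1 else shift$intensity_scale
  drift <- if (is.null(shift$drift_scale)) 1 else shift$drift_scale
  .simulate(design, model, seed, week_scale = drift,
            log_scale = log(scale))
}

#' Write / read a spectrum collection as plain-text files
#'
#' `writeSpectra()` writes the long-format peak table
#' (`<stem>_spectra.csv`: sample_id, voltage, mz, abundance), the sample
#' metadata (`<stem>_metadata.csv`) and a JSON sidecar
#' (`<stem>_run.json`) recording the generator provenance.
#' `readSpectra()` reads them back; the round trip is value-exact.
#'
#' @param object a [CentroidSpectra-class] object.
#' @param stem file path stem (directory + basename without suffix).
#' @return `writeSpectra()` the stem, invisibly; `readSpectra()` a
#'   [CentroidSpectra-class] object.
#' @export
writeSpectra <- function(object, stem) {
  stopifnot(is(object, "CentroidSpectra"))
  pk <- peaksTable(object)
  pk$mz <- sprintf("%.17g", pk$mz)
  pk$abundance <- sprintf("%.17g", pk$abundance)
  utils::write.csv(pk, paste0(stem, "_spectra.csv"), row.names = FALSE)
  utils::write.csv(sampleData(object), paste0(stem, "_metadata.csv"),
                   row.names = FALSE)
  jsonlite::write_json(object@runInfo, paste0(stem, "_run.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' @rdname writeSpectra
#' @export
readSpectra <- function(stem) {
  pk <- utils::read.csv(paste0(stem, "_spectra.csv"),
                        stringsAsFactors = FALSE)
  pk$sample_id <- as.character(pk$sample_id)
  pk$mz <- as.numeric(pk$mz)
  pk$abundance <- as.numeric(pk$abundance)
  md <- utils::read.csv(paste0(stem, "_metadata.csv"),
                        stringsAsFactors = FALSE)
  md$sample_id <- as.character(md$sample_id)
  run <- paste0(stem, "_run.json")
  info <- if (file.exists(run)) jsonlite::read_json(run,
                                                    simplifyVector = TRUE)
          else list()
  CentroidSpectra(pk, md, runInfo = as.list(info))
}
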