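#' Default pipeline configuration
#'
#' @param ... named overrides of the defaults, e.g.
#'   `welch = list(n_replicates = 2)`; sublists are merged field-wise.
#' @return Nested configuration list for [runPipeline()].
#' @export
pipelineConfig <- function(...) {
  cfg <- list(
    seed = 20210317,
    design = list(),            # designConfig() arguments
    model = list(),             # spectrumModel() arguments
    floor = 120,
    bin_width = 0.025,
    selection = list(pct_threshold = 1, min_spectra = 50,
                     rule = "count_meeting"),
    scheme = "ion_current",
    welch = list(n_replicates = 20, scope = "full"),
    lda = list(tolerance = 1.0e-8),
    rf = list(n_trees = 500, elimination = FALSE, folds = 12,
              importance_repeats = 5),
    thresholds = seq(0.5, 0.95, by = 0.05))
  over <- list(...)
  for (nm in names(over)) {
    cfg[[nm]] <- if (is.list(over[[nm]]) && is.list(cfg[[nm]]))
      utils::modifyList(cfg[[nm]], over[[nm]]) else over[[nm]]
  }
  cfg
}

.writeCsv <- function(df, outdir, name) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  utils::write.csv(df, file.path(outdir, name), row.names = FALSE)
}

#' Run the full analysis pipeline end to end
#'
#' Simulate -> floor -> bin -> select -> normalise -> ANOVA -> Welch /
#' LDA / random-forest classification -> rate tables, writing every
#' declared CSV artifact plus a run manifest (configuration, seeds,
#' package version) to `outdir`. Reruns with the same configuration
#' produce byte-identical numeric outputs.
#'
#' @param config a [pipelineConfig()], or a path to a JSON file of
#'   overrides.
#' @param outdir output directory (created if needed).
#' @param quiet suppress stage messages.
#' @return Invisibly, a list with the main in-memory results
#'   (`spectra`, `table`, `variables`, `ntable`, `anova`, `welch`,
#'   `lda`, `forest`, `rates`).
#' @export
runPipeline <- function(config = pipelineConfig(), outdir, quiet = FALSE) {
  if (is.character(config))
    config <- do.call(pipelineConfig,
                      jsonlite::read_json(config, simplifyVector = TRUE))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[", ..., "]")
  stage <- function(name, expr) {
    say(name)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  seed <- config$seed

  spectra <- stage("simulate", {
    cfg <- do.call(designConfig, c(config$design, list(seed = seed)))
    model <- do.call(spectrumModel, config$model)
    simulateSpectra(generateDesign(cfg), model, seed = seed)
  })
  tab <- stage("bin", {
    assembleTable(applyAbundanceFloor(spectra, config$floor),
                  bin_width = config$bin_width)
  })
  vars <- stage("select", {
    v <- selectVariables(tab, config$selection$pct_threshold,
                         config$selection$min_spectra,
                         config$selection$rule)
    .writeCsv(v[, c("bin_upper", "voltage")], outdir, "variables.csv")
    v
  })
  ntab <- stage("normalize", {
    nt <- normalizeSpectra(tab, vars, config$scheme)
    writeBinnedTable(nt, file.path(outdir, "normalized.csv"))
    nt
  })
  anova <- stage("anova", {
    a <- multiwayAnova(ntab)
    .writeCsv(a, outdir, "anova.csv")
    a
  })
  welch <- stage("welch", {
    w <- runWelchReplicates(tab, vars,
                            n_replicates = config$welch$n_replicates,
                            scope = config$welch$scope,
                            seed = .subSeed(seed, 101))
    .writeCsv(w$summary, outdir, "welch_auc.csv")
    .writeCsv(w$roc, outdir, "welch_roc.csv")
    for (r in seq_along(w$comparisons))
      .writeCsv(w$comparisons[[r]], outdir,
                sprintf("welch_replicate_%02d.csv", r))
    acc <- perBinAccuracy(welchCardComparisons(ntab, 95))
    .writeCsv(data.frame(variable = names(acc), accuracy = acc),
              outdir, "welch_bin_accuracy.csv")
    w
  })
  lda <- stage("lda", {
    fit <- fitLda(ntab, tolerance = config$lda$tolerance)
    post <- ldaPosterior(fit, ntab)
    .writeCsv(post, outdir, "lda_posteriors.csv")
    sc <- scalingInfluence(fit)
    .writeCsv(sc, outdir, "lda_scaling.csv")
    proj <- stats::predict(fit$fit,
                           t(abundanceMatrix(ntab))[, fit$variables,
                                                    drop = FALSE])$x
    .writeCsv(data.frame(sample_id = sampleData(ntab)$sample_id, proj),
              outdir, "lda_scores.csv")
    list(fit = fit, posteriors = post, scaling = sc)
  })
  forest <- stage("rf", {
    fit <- fitForest(ntab, n_trees = config$rf$n_trees,
                     seed = .subSeed(seed, 202))
    prof <- oobVoteProfiles(fit)
    .writeCsv(prof, outdir, "rf_votes.csv")
    imp <- permutationImportance(fit,
                                 repeats = config$rf$importance_repeats,
                                 seed = .subSeed(seed, 203))
    .writeCsv(imp, outdir, "rf_importance.csv")
    elim <- NULL
    if (isTRUE(config$rf$elimination)) {
      elim <- eliminationCurve(ntab, folds = config$rf$folds,
                               n_trees = config$rf$n_trees,
                               seed = .subSeed(seed, 204))
      .writeCsv(elim, outdir, "rf_elimination.csv")
    }
    list(fit = fit, votes = prof, importance = imp, elimination = elim)
  })
  rates <- stage("rates", {
    md <- sampleData(ntab)
    cls <- forest$fit$classes
    rf_rate <- rateTable(forest$votes[, cls], md$class,
                         config$thresholds)
    .writeCsv(rf_rate, outdir, "rf_rate_table.csv")
    lda_rate <- rateTable(lda$posteriors[, cls], md$class,
                          config$thresholds)
    .writeCsv(lda_rate, outdir, "lda_rate_table.csv")
    list(rf = rf_rate, lda = lda_rate)
  })
  say("manifest")
  manifest <- list(package = "isomerMS",
                   version = as.character(utils::packageVersion("isomerMS")),
                   config = config,
                   n_samples = ncol(tab), n_variables = nrow(ntab))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(spectra = spectra, table = tab, variables = vars,
                 ntable = ntab, anova = anova, welch = welch, lda = lda,
                 forest = forest, rates = rates))
}
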