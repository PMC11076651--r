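# Orchestration: generate/load -> extract -> select -> classify ->
# evaluate, over all configured stage combinations, with fold-safe
# fitting (extraction and selection are fit on training folds only).

#' Pipeline configuration
#'
#' @param dataset a `gw_dataset`, or a path to a CSV written by
#'   [write_expression_csv()], or a [synth_config()] to generate from.
#' @param extractions character vector of extraction methods.
#' @param k number of features retained by extraction.
#' @param selections character vector from `"none"`, `"HS"`, `"FF"`,
#'   `"EHO"`.
#' @param classifiers character vector of classifier kinds.
#' @param folds outer CV folds (default 10).
#' @param seed global seed.
#' @param selection_config optional shared config for the selectors (a
#'   [hs_config()]/[ff_config()]/[eho_config()] is chosen by algorithm
#'   when NULL).
#' @param fitness_folds internal CV folds of the wrapper fitness.
#' @param fitness_classifier `"wrapper"` (the downstream classifier, the
#'   default) or `"surrogate"` (nearest-centroid, much cheaper).
#' @param extraction_params per-method settings passed to
#'   [extractor_fit()].
#' @return a `gw_pipeline_config`.
#' @export
pipeline_config <- function(dataset, extractions = c("DCT", "PCA"),
                            k = 50L, selections = c("none", "EHO"),
                            classifiers = c("SVM_RBF", "QDA", "XGBOOST"),
                            folds = 10L, seed = 1L,
                            selection_config = NULL,
                            fitness_folds = 3L,
                            fitness_classifier = c("wrapper", "surrogate"),
                            extraction_params = list()) {
  if (!length(extractions) || !length(selections) || !length(classifiers))
    stop("need at least one method per stage", call. = FALSE)
  extractions <- vapply(extractions, match.arg, "", choices = GW_METHODS)
  selections <- vapply(selections, match.arg, "",
                       choices = c("none", "HS", "FF", "EHO"))
  classifiers <- vapply(classifiers, match.arg, "", choices = GW_KINDS)
  if (folds < 2) stop("folds must be >= 2", call. = FALSE)
  structure(list(dataset = dataset, extractions = unname(extractions),
                 k = as.integer(k), selections = unname(selections),
                 classifiers = unname(classifiers),
                 folds = as.integer(folds), seed = as.integer(seed),
                 selection_config = selection_config,
                 fitness_folds = as.integer(fitness_folds),
                 fitness_classifier = match.arg(fitness_classifier),
                 extraction_params = extraction_params),
            class = "gw_pipeline_config")
}

resolve_dataset <- function(dataset) {
  if (inherits(dataset, "gw_dataset")) dataset
  else if (inherits(dataset, "gw_synth_config")) generate_dataset(dataset)
  else if (is.character(dataset)) read_expression_csv(dataset)
  else stop("dataset must be a gw_dataset, a synth_config or a CSV path",
            call. = FALSE)
}

default_sel_config <- function(algorithm, max_iter = 20L) {
  switch(algorithm,
    HS = hs_config(max_iter = max_iter * 10L),
    FF = ff_config(population = 10L, max_iter = max_iter),
    EHO = eho_config(population = 12L, n_clans = 3L, max_iter = max_iter))
}

# One (extraction, selection, classifier) cell under fold-safe pooled CV:
# for each outer fold the extractor retention rule and the selected mask
# are fit on the training samples only.
run_cell <- function(x, y, extraction, selection, clf_kind, cfg) {
  scheme <- stratified_folds(y, k = cfg$folds, seed = cfg$seed)
  spec <- classifier_spec(clf_kind, seed = cfg$seed)
  fit_spec <- if (cfg$fitness_classifier == "surrogate")
    classifier_spec("CENTROID", seed = cfg$seed) else spec
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  n_selected <- integer(0)
  for (f in seq_len(scheme$k)) {
    test <- scheme$test_indices[[f]]
    xtr <- x[-test, , drop = FALSE]; ytr <- y[-test]
    ex <- extractor_fit(xtr, ytr, method = extraction, k = cfg$k,
                        params = cfg$extraction_params, seed = cfg$seed)
    ftr <- extractor_transform(ex, xtr)
    fte <- extractor_transform(ex, x[test, , drop = FALSE])
    if (selection != "none") {
      sel <- select_features(ftr, ytr, algorithm = selection,
                             clf_spec = fit_spec,
                             config = cfg$selection_config %||%
                               default_sel_config(selection),
                             folds = cfg$fitness_folds, seed = cfg$seed)
      ftr <- ftr[, sel$selected, drop = FALSE]
      fte <- fte[, sel$selected, drop = FALSE]
      n_selected <- c(n_selected, length(sel$selected))
    }
    model <- train_classifier(spec, ftr, ytr)
    pred[test] <- predict(model, fte)
  }
  cm <- confusion(y, pred)
  m <- compute_metrics(cm)
  data.frame(extraction = extraction, selection = selection,
             classifier = clf_kind,
             accuracy = m$accuracy, precision = m$precision, f1 = m$f1,
             mcc = m$mcc, fm = m$fm, error_rate = m$error_rate,
             jaccard = m$jaccard, csi = m$csi, gmean = m$gmean,
             kappa = m$kappa,
             n_selected = if (length(n_selected)) round(mean(n_selected))
                          else NA_integer_,
             failed = FALSE, message = "",
             stringsAsFactors = FALSE)
}

#' Run the full benchmarking pipeline
#'
#' Executes every (extraction, selection, classifier) combination under
#' pooled stratified k-fold cross-validation with fold-safe fitting, and
#' reports the ten-metric row per combination plus overall averages. A
#' failing combination is isolated: the run continues and the report
#' marks the failed cell.
#'
#' @param config a [pipeline_config()].
#' @param verbose print per-cell progress lines.
#' @return a `gw_report`: list with `results` (data.frame), `summary`
#'   (per-selection overall average accuracy), `best` (best row;
#'   ties broken by MCC then name order), `seed`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "gw_pipeline_config"))
  ds <- resolve_dataset(config$dataset)
  x <- ds$matrix; y <- ds$labels
  rows <- list()
  for (ext in config$extractions)
    for (sel in config$selections)
      for (clf in config$classifiers) {
        t0 <- proc.time()[["elapsed"]]
        row <- tryCatch(
          run_cell(x, y, ext, sel, clf, config),
          error = function(e)
            data.frame(extraction = ext, selection = sel, classifier = clf,
                       accuracy = NA_real_, precision = NA_real_,
                       f1 = NA_real_, mcc = NA_real_, fm = NA_real_,
                       error_rate = NA_real_, jaccard = NA_real_,
                       csi = NA_real_, gmean = NA_real_, kappa = NA_real_,
                       n_selected = NA_integer_, failed = TRUE,
                       message = conditionMessage(e),
                       stringsAsFactors = FALSE))
        if (verbose)
          message(sprintf("[%s/%s/%s] acc=%s (%.1fs)", ext, sel, clf,
                          formatC(row$accuracy, format = "f", digits = 2),
                          proc.time()[["elapsed"]] - t0))
        rows[[length(rows) + 1L]] <- row
      }
  results <- do.call(rbind, rows)
  ok <- results[!results$failed, , drop = FALSE]
  summary <- if (nrow(ok))
    stats::aggregate(accuracy ~ selection, data = ok,
                     FUN = function(a) round_half_up(mean(a)))
  else data.frame(selection = character(0), accuracy = numeric(0))
  best <- if (nrow(ok)) aggregate_report(ok)$best else NULL
  structure(list(results = results, summary = summary, best = best,
                 seed = config$seed),
            class = "gw_report")
}

#' @export
print.gw_report <- function(x, ...) {
  cat("<gw_report>", nrow(x$results), "configuration cells\n")
  df <- x$results
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) round_half_up(v))
  print(df[, c("extraction", "selection", "classifier", "accuracy",
               "error_rate", "mcc", "kappa")], row.names = FALSE)
  cat("\nOverall average accuracy by selection regime:\n")
  print(x$summary, row.names = FALSE)
  if (!is.null(x$best))
    cat(sprintf("\nBest: %s + %s + %s (accuracy %.2f)\n",
                x$best$extraction, x$best$selection, x$best$classifier,
                x$best$accuracy))
  invisible(x)
}

#' Write the pipeline report tables as CSV
#'
#' @param report a `gw_report`.
#' @param dir output directory (created if needed).
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "gw_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  data.table::fwrite(report$results, file.path(dir, "results.csv"))
  data.table::fwrite(report$summary, file.path(dir, "summary.csv"))
  invisible(NULL)
}
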