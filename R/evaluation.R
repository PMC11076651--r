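# Confusion-matrix metric suite: the ten reported metrics, descriptive
# statistics of extracted feature sets, the MCC/Kappa region analysis, and
# the inverse problem -- reconstructing integer confusion matrices from
# published (accuracy, precision, F1) triples so printed metric rows can
# be verified arithmetically.

#' Build a confusion matrix from label vectors
#'
#' @param y_true,y_pred equal-length label vectors.
#' @param positive_label the class counted as positive (default
#'   `"malignant"`).
#' @return a `gw_confusion`: `tp`, `fp`, `fn`, `tn`, `positive_label`.
#' @export
confusion <- function(y_true, y_pred, positive_label = GW_POSITIVE) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length", call. = FALSE)
  if (!length(y_true)) stop("need at least one sample", call. = FALSE)
  tpos <- y_true == positive_label
  ppos <- y_pred == positive_label
  confusion_counts(sum(tpos & ppos), sum(!tpos & ppos),
                   sum(tpos & !ppos), sum(!tpos & !ppos),
                   positive_label)
}

#' Build a confusion matrix directly from counts
#'
#' @param tp,fp,fn,tn non-negative integer counts (N >= 1).
#' @param positive_label class identity of the positive class.
#' @return a `gw_confusion`.
#' @export
confusion_counts <- function(tp, fp, fn, tn, positive_label = GW_POSITIVE) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || sum(counts) < 1)
    stop("counts must be non-negative with N >= 1", call. = FALSE)
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn),
                 positive_label = positive_label),
            class = "gw_confusion")
}

# Round half away from zero at `digits` decimals (base round() rounds
# half to even, which does not match printed tables).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' The ten-metric suite of a confusion matrix
#'
#' Accuracy, precision, recall, specificity, F1, MCC, Fowlkes-Mallows
#' (geometric mean of precision and recall), error rate, Jaccard, CSI,
#' Gmean (geometric mean of recall and specificity) and Cohen's kappa.
#' Jaccard and CSI are the standard intersection-over-union
#' `TP / (TP + FP + FN)`. Ratios with zero denominators are reported as 0
#' and flagged in `degenerate`.
#'
#' @param cm a `gw_confusion`.
#' @param percent if `TRUE` (default) report accuracy, precision, recall,
#'   specificity, F1, error rate, Jaccard, CSI and Gmean on the 0-100
#'   scale (MCC, FM and kappa stay on their natural scales, as reported
#'   in the benchmark tables).
#' @return a named list of metrics plus `degenerate` (character vector of
#'   zero-denominator metrics).
#' @export
compute_metrics <- function(cm, percent = TRUE) {
  stopifnot(inherits(cm, "gw_confusion"))
  tp <- cm$tp; fp <- cm$fp; fn <- cm$fn; tn <- cm$tn
  n <- tp + fp + fn + tn
  degenerate <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) {
      degenerate <<- c(degenerate, name)
      0
    } else num / den
  }
  accuracy <- (tp + tn) / n
  precision <- safe(tp, tp + fp, "precision")
  recall <- safe(tp, tp + fn, "recall")
  specificity <- safe(tn, tn + fp, "specificity")
  f1 <- safe(2 * precision * recall, precision + recall, "f1")
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den == 0) { degenerate <- c(degenerate, "mcc"); 0 } else
    (tp * tn - fp * fn) / mcc_den
  fm <- sqrt(precision * recall)
  jaccard <- safe(tp, tp + fp + fn, "jaccard")
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (pe == 1) { degenerate <- c(degenerate, "kappa"); 0 } else
    (accuracy - pe) / (1 - pe)
  gmean <- sqrt(recall * specificity)
  s <- if (percent) 100 else 1
  list(accuracy = s * accuracy, precision = s * precision,
       recall = s * recall, specificity = s * specificity,
       f1 = s * f1, mcc = mcc, fm = fm,
       error_rate = s - s * accuracy, jaccard = s * jaccard,
       csi = s * jaccard, gmean = s * gmean, kappa = kappa,
       degenerate = unique(degenerate))
}

#' Reconstruct integer confusion matrices from printed metrics
#'
#' Exhaustively enumerates `TP` in `0..n_pos` and `FP` in `0..n_neg`
#' (FN and TN are implied by the class totals) and keeps every matrix
#' whose recomputed accuracy, precision and F1, rounded half away from
#' zero to two decimals, equal the printed percentages. This inverts the
#' metric definitions for rows of published results, making them
#' verifiable: a unique solution pins down the full matrix, from which
#' MCC, kappa, Jaccard and FM follow.
#'
#' Published tables occasionally carry a one-unit slip in the last printed
#' digit (an F1 recomputed from already-rounded precision and recall, for
#' instance), so by default a matrix is accepted when each recomputed,
#' rounded metric is within `tol = 0.01` (one unit in the last place) of
#' the printed value; set `tol = 0` for exact matching.
#'
#' @param accuracy_pct,precision_pct,f1_pct printed 2-dp percentages.
#' @param n_pos,n_neg class totals (positive = malignant).
#' @param tol acceptance slack on the rounded metrics (printed units).
#' @return list of `gw_confusion` (possibly empty; an empty result means
#'   no integer matrix is consistent with the printed row).
#' @export
reconstruct_confusion <- function(accuracy_pct, precision_pct, f1_pct,
                                  n_pos = 77L, n_neg = 59L, tol = 0.01) {
  vals <- c(accuracy_pct, precision_pct, f1_pct)
  if (any(vals < 0 | vals > 100)) stop("metrics must lie in [0, 100]", call. = FALSE)
  if (n_pos < 1 || n_neg < 1) stop("class totals must be >= 1", call. = FALSE)
  grid <- expand.grid(tp = 0:n_pos, fp = 0:n_neg)
  tp <- grid$tp; fp <- grid$fp
  fn <- n_pos - tp; tn <- n_neg - fp
  n <- n_pos + n_neg
  # arithmetic mirrors compute_metrics() exactly (same operation order),
  # so rounding agrees with it on half-way floating-point boundaries
  acc <- 100 * ((tp + tn) / n)
  p <- ifelse(tp + fp == 0, 0, tp / (tp + fp))
  r <- tp / n_pos
  prec <- 100 * p
  f1 <- 100 * ifelse(p + r == 0, 0, 2 * p * r / (p + r))
  keep <- abs(round_half_up(acc) - round_half_up(accuracy_pct)) <= tol + 1e-9 &
    abs(round_half_up(prec) - round_half_up(precision_pct)) <= tol + 1e-9 &
    abs(round_half_up(f1) - round_half_up(f1_pct)) <= tol + 1e-9
  lapply(which(keep), function(i)
    confusion_counts(tp[i], fp[i], fn[i], tn[i]))
}

#' Descriptive statistics of two extracted feature sets
#'
#' Per group: mean, variance, standard deviation, skewness and kurtosis,
#' each computed per feature column and averaged over columns (constant
#' columns are excluded from skewness/kurtosis, with the exclusion count
#' reported). Across groups: `pcc`, the mean Pearson correlation between
#' matched feature columns (rows truncated to the shorter group); the
#' Welch two-sample t-test comparing the per-feature group means; and the
#' first canonical correlation between the two sets (dimension-capped).
#'
#' @param features_a,features_b samples x features matrices (same feature
#'   count; sample counts may differ).
#' @param kurtosis_type `"excess"` (Fisher, default) or `"pearson"`.
#' @param cca_dim cap on the number of columns entering the canonical
#'   correlation (default 10).
#' @return list with per-group profiles (`a`, `b`), `pcc`, `ttest_p`,
#'   `cca`, `n_constant_excluded`.
#' @export
descriptive_stats <- function(features_a, features_b,
                              kurtosis_type = c("excess", "pearson"),
                              cca_dim = 10L) {
  kurtosis_type <- match.arg(kurtosis_type)
  a <- as.matrix(features_a); b <- as.matrix(features_b)
  if (!nrow(a) || !nrow(b)) stop("both groups must be non-empty", call. = FALSE)
  if (ncol(a) != ncol(b)) stop("feature counts must match", call. = FALSE)
  excl <- 0L
  profile <- function(x) {
    mu <- colMeans(x)
    v <- apply(x, 2, stats::var)
    ok <- v > 0
    excl <<- excl + sum(!ok)
    skew <- vapply(which(ok), function(j) {
      z <- (x[, j] - mu[j])
      mean(z^3) / (sqrt(mean(z^2)))^3
    }, numeric(1))
    kurt <- vapply(which(ok), function(j) {
      z <- (x[, j] - mu[j])
      k <- mean(z^4) / (mean(z^2))^2
      if (kurtosis_type == "excess") k - 3 else k
    }, numeric(1))
    list(mean = mean(mu), variance = mean(v), std_dev = mean(sqrt(v)),
         skewness = if (length(skew)) mean(skew) else NA_real_,
         kurtosis = if (length(kurt)) mean(kurt) else NA_real_)
  }
  pa <- profile(a); pb <- profile(b)
  nr <- min(nrow(a), nrow(b))
  cors <- vapply(seq_len(ncol(a)), function(j) {
    suppressWarnings(stats::cor(a[seq_len(nr), j], b[seq_len(nr), j]))
  }, numeric(1))
  pcc <- mean(cors, na.rm = TRUE)
  ma <- colMeans(a); mb <- colMeans(b)
  tt <- if (isTRUE(all.equal(ma, mb))) list(statistic = 0, p.value = 1) else
    stats::t.test(ma, mb)
  nc <- min(ncol(a), cca_dim, nr - 1L)
  cca <- tryCatch({
    cc <- stats::cancor(a[seq_len(nr), seq_len(nc), drop = FALSE],
                        b[seq_len(nr), seq_len(nc), drop = FALSE])
    cc$cor[1]
  }, error = function(e) NA_real_)
  list(a = pa, b = pb, pcc = pcc,
       ttest_t = unname(tt$statistic), ttest_p = tt$p.value,
       cca = cca, n_constant_excluded = excl)
}

#' MCC/kappa region labelling and agreement slope
#'
#' Labels each (MCC, kappa) pair by the benchmark's region scheme --
#' R1 for MCC in `[0, 0.3]`, R2 for `(0.3, 0.5]`, R3 for `[0.6, 0.7]`,
#' `unclassified` otherwise -- and reports the least-squares slope of
#' kappa on MCC.
#'
#' @param mcc,kappa numeric vectors of equal length (>= 2 for the slope).
#' @return list with `regions` (character), `slope`, `intercept`.
#' @export
mcc_kappa_analysis <- function(mcc, kappa) {
  if (length(mcc) != length(kappa))
    stop("mcc and kappa must have equal length", call. = FALSE)
  regions <- vapply(mcc, function(m) {
    if (is.na(m)) "unclassified"
    else if (m >= 0 && m <= 0.3) "R1"
    else if (m > 0.3 && m <= 0.5) "R2"
    else if (m >= 0.6 && m <= 0.7) "R3"
    else "unclassified"
  }, character(1))
  slope <- intercept <- NA_real_
  if (length(mcc) >= 2 && stats::var(mcc) > 0) {
    fit <- stats::lm.fit(cbind(1, mcc), kappa)
    intercept <- unname(fit$coefficients[1])
    slope <- unname(fit$coefficients[2])
  }
  list(regions = regions, slope = slope, intercept = intercept)
}

#' Load a shipped benchmark metric table
#'
#' The package ships the published per-configuration metric tables of the
#' prostate microarray benchmark (40 rows each: five extraction methods
#' by eight classifiers), one per selection regime.
#'
#' @param selection `"none"`, `"harmony"`, `"firefly"` or `"eho"`.
#' @return data.frame with `extraction`, `classifier` and the ten metric
#'   columns.
#' @export
benchmark_table <- function(selection = c("none", "harmony", "firefly", "eho")) {
  selection <- match.arg(selection)
  fname <- switch(selection, none = "metrics_no_selection.csv",
                  harmony = "metrics_harmony_search.csv",
                  firefly = "metrics_firefly.csv", eho = "metrics_eho.csv")
  path <- system.file("extdata", fname, package = "genewrap", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Aggregate per-configuration metric rows into a report
#'
#' @param results data.frame with at least `extraction`, `classifier` and
#'   `accuracy` columns (e.g. a [benchmark_table()] or a
#'   [run_pipeline()] report).
#' @return list with `table` (the rows), `overall_average` (mean accuracy
#'   rounded half away from zero to 2 dp), `best` (row with maximum
#'   accuracy; ties broken by MCC then by name order).
#' @export
aggregate_report <- function(results) {
  results <- as.data.frame(results)
  if (!nrow(results)) stop("need at least one result row", call. = FALSE)
  ord <- order(-results$accuracy,
               if ("mcc" %in% names(results)) -results$mcc else
                 rep(0, nrow(results)),
               results$extraction, results$classifier)
  list(table = results,
       overall_average = round_half_up(mean(results$accuracy)),
       best = results[ord[1], , drop = FALSE])
}
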