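#' Configuration for the synthetic expression generator
#'
#' The defaults emulate the shape of the prostate microarray cohort the
#' package benchmarks against: 59 healthy and 77 malignant samples with
#' 12,600 genes, of which a subset carries a standardized between-class
#' mean shift. Noise families other than `"gaussian"` produce the
#' heavy-tailed, positively skewed per-gene distributions characteristic
#' of raw microarray intensities.
#'
#' @param n_healthy,n_malignant number of samples per class.
#' @param n_genes total number of genes.
#' @param n_informative number of genes carrying a between-class shift.
#' @param effect_size standardized mean shift (in within-class SD units)
#'   applied to informative genes in the malignant class.
#' @param noise_family one of `"lognormal"` (default), `"gaussian"`,
#'   `"gamma"`; controls per-gene skewness/kurtosis.
#' @param seed integer RNG seed; identical configs produce identical data.
#' @return an object of class `gw_synth_config`.
#' @export
synth_config <- function(n_healthy = 59L, n_malignant = 77L,
                         n_genes = 12600L, n_informative = 600L,
                         effect_size = 1.5, noise_family = "lognormal",
                         seed = 1L) {
  n_healthy <- as.integer(n_healthy); n_malignant <- as.integer(n_malignant)
  n_genes <- as.integer(n_genes); n_informative <- as.integer(n_informative)
  if (any(is.na(c(n_healthy, n_malignant, n_genes, n_informative))))
    stop("counts must be integer-valued", call. = FALSE)
  if (n_healthy < 1L || n_malignant < 1L || n_genes < 1L)
    stop("all sample/gene counts must be >= 1", call. = FALSE)
  if (n_informative < 0L || n_informative > n_genes)
    stop("n_informative must lie in [0, n_genes]", call. = FALSE)
  if (!is.numeric(effect_size) || effect_size < 0)
    stop("effect_size must be >= 0", call. = FALSE)
  noise_family <- match.arg(noise_family, c("lognormal", "gaussian", "gamma"))
  structure(list(n_healthy = n_healthy, n_malignant = n_malignant,
                 n_genes = n_genes, n_informative = n_informative,
                 effect_size = effect_size, noise_family = noise_family,
                 seed = as.integer(seed)),
            class = "gw_synth_config")
}

#' Read a generator configuration from a JSON or YAML document
#'
#' Field names mirror [synth_config()] arguments; absent fields keep their
#' defaults.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @return a `gw_synth_config`.
#' @export
read_synth_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  doc <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(synth_config))
  bad <- setdiff(names(doc), known)
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  do.call(synth_config, doc)
}

# Draw an n x m matrix from the chosen family, standardized to mean 0 /
# SD 1 using the family's theoretical moments so that effect_size stays
# interpretable as a within-class SD shift.
standardized_noise <- function(n, m, family) {
  switch(family,
    gaussian = matrix(rnorm(n * m), n, m),
    lognormal = {
      mu <- exp(0.5); s <- sqrt((exp(1) - 1) * exp(1))
      matrix((rlnorm(n * m) - mu) / s, n, m)
    },
    gamma = {
      shape <- 2
      matrix((rgamma(n * m, shape = shape, rate = 1) - shape) / sqrt(shape), n, m)
    })
}

#' Generate a seeded two-class synthetic expression dataset
#'
#' Each gene is an independent standardized draw from the configured noise
#' family; the `n_informative` genes (chosen uniformly at random) receive
#' an additive `effect_size` shift in the malignant class. The informative
#' gene indices are recorded so downstream feature-selection quality can be
#' scored.
#'
#' @param config a [synth_config()].
#' @return a `gw_dataset`: list with `matrix` (samples x genes), `labels`
#'   (factor, levels healthy/malignant), `gene_ids`, `sample_ids`,
#'   `informative` (integer gene indices), `config`.
#' @export
generate_dataset <- function(config = synth_config()) {
  stopifnot(inherits(config, "gw_synth_config"))
  set.seed(config$seed)
  n <- config$n_healthy + config$n_malignant
  x <- standardized_noise(n, config$n_genes, config$noise_family)
  informative <- sort(sample.int(config$n_genes, config$n_informative))
  labels <- factor(rep(GW_CLASSES, c(config$n_healthy, config$n_malignant)),
                   levels = GW_CLASSES)
  if (length(informative))
    x[labels == GW_POSITIVE, informative] <-
      x[labels == GW_POSITIVE, informative] + config$effect_size
  gene_ids <- sprintf("g%05d", seq_len(config$n_genes))
  sample_ids <- sprintf("s%03d", seq_len(n))
  dimnames(x) <- list(sample_ids, gene_ids)
  new_dataset(x, labels, informative = informative, config = config)
}

new_dataset <- function(x, labels, informative = integer(), config = NULL) {
  if (nrow(x) != length(labels))
    stop("matrix row count must equal label count", call. = FALSE)
  if (anyNA(x) || any(!is.finite(x)))
    stop("expression matrix contains NA/Inf", call. = FALSE)
  if (anyDuplicated(colnames(x)))
    stop("gene_ids must be unique", call. = FALSE)
  structure(list(matrix = x, labels = labels,
                 gene_ids = colnames(x), sample_ids = rownames(x),
                 informative = as.integer(informative), config = config),
            class = "gw_dataset")
}

#' @export
print.gw_dataset <- function(x, ...) {
  cat(sprintf("<gw_dataset> %d samples x %d genes (%s)\n",
              nrow(x$matrix), ncol(x$matrix),
              paste(sprintf("%s: %d", levels(x$labels), table(x$labels)),
                    collapse = ", ")))
  if (length(x$informative))
    cat(sprintf("  informative genes: %d\n", length(x$informative)))
  invisible(x)
}

#' Write an expression dataset as delimited text
#'
#' Comma-delimited, '.' decimal, UTF-8: one header row of gene IDs, a
#' leading `sample_id` column and a trailing `label` column.
#'
#' @param dataset a `gw_dataset`.
#' @param path output file path.
#' @export
write_expression_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "gw_dataset"))
  if (anyDuplicated(dataset$gene_ids))
    stop("gene_ids must be unique", call. = FALSE)
  dt <- data.table::data.table(sample_id = dataset$sample_ids)
  dt <- cbind(dt, data.table::as.data.table(dataset$matrix))
  dt[["label"]] <- as.character(dataset$labels)
  tryCatch(data.table::fwrite(dt, path, sep = ",", dec = "."),
           error = function(e) stop("cannot write ", path, ": ",
                                    conditionMessage(e), call. = FALSE))
  invisible(NULL)
}

#' Read an expression dataset written by [write_expression_csv()]
#'
#' @param path input file path.
#' @return a `gw_dataset` (without informative-gene bookkeeping).
#' @export
read_expression_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = ",", dec = ".", header = TRUE,
                          colClasses = list(character = "sample_id"))
  if (!"label" %in% names(dt) || !"sample_id" %in% names(dt))
    stop("parse error: expected 'sample_id' first and 'label' last column",
         call. = FALSE)
  gene_cols <- setdiff(names(dt), c("sample_id", "label"))
  for (g in gene_cols) {
    col <- dt[[g]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))))[1]
      stop(sprintf("parse error: non-numeric expression value in column '%s' at line %d",
                   g, bad + 1L), call. = FALSE)
    }
  }
  lab <- dt$label
  if (!all(lab %in% GW_CLASSES))
    stop("validation error: labels outside {",
         paste(GW_CLASSES, collapse = ", "), "}: ",
         paste(unique(setdiff(lab, GW_CLASSES)), collapse = ", "),
         call. = FALSE)
  x <- as.matrix(dt[, gene_cols, with = FALSE])
  rownames(x) <- dt$sample_id
  new_dataset(x, factor(lab, levels = GW_CLASSES))
}
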