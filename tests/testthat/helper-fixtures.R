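# Small in-code fixtures shared across test files.

# Tiny two-class dataset with a planted signal in the first `n_informative`
# genes (gaussian noise keeps the classifiers' behavior easy to reason about).
tiny_dataset <- function(n_per_class = 20, n_genes = 30, n_informative = 4,
                         effect = 2.5, seed = 42) {
  cfg <- synth_config(n_healthy = n_per_class, n_malignant = n_per_class,
                      n_genes = n_genes, n_informative = n_informative,
                      effect_size = effect, noise_family = "gaussian",
                      seed = seed)
  generate_dataset(cfg)
}

# Linearly separable 2-D data.
separable_xy <- function(n = 20, gap = 5, seed = 7) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n * 2), ncol = 2),
             matrix(rnorm(n * 2) + gap, ncol = 2))
  y <- factor(rep(c("healthy", "malignant"), each = n),
              levels = c("healthy", "malignant"))
  list(x = x, y = y)
}

sphere_fn <- function(x) sum(x^2)

# Independent metric computation used as an oracle against compute_metrics:
# tallies by table() and applies the textbook formulas directly.
oracle_metrics <- function(y_true, y_pred, positive = "malignant") {
  tp <- sum(y_true == positive & y_pred == positive)
  fp <- sum(y_true != positive & y_pred == positive)
  fn <- sum(y_true == positive & y_pred != positive)
  tn <- sum(y_true != positive & y_pred != positive)
  n <- tp + fp + fn + tn
  p <- tp / (tp + fp); r <- tp / (tp + fn)
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       accuracy = (tp + tn) / n, precision = p, recall = r,
       f1 = 2 * p * r / (p + r),
       mcc = (tp * tn - fp * fn) /
         sqrt((tp + fp) * (tp + fn)) / sqrt((tn + fp) * (tn + fn)),
       kappa = ((tp + tn) / n - pe) / (1 - pe))
}
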