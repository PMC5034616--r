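# Fixture builders and independent brute-force oracles. The oracles
# deliberately avoid the package's vectorised code paths: they loop
# chemical by chemical, so agreement is a genuine cross-check.

# A seeded random panel whose tools are noisy copies of the label, so
# posteriors span (0, 1) and keys are unevenly occupied.
random_panel <- function(n, m, seed, flip = 0.25, prevalence = 0.4) {
  set.seed(seed)
  labels <- rbinom(n, 1, prevalence)
  predictions <- sapply(seq_len(m), function(j) {
    flips <- rbinom(n, 1, flip)
    ifelse(flips == 1, 1L - labels, labels)
  })
  prediction_panel(matrix(predictions, nrow = n), labels)
}

toy_panel <- function(predictions, labels) {
  prediction_panel(matrix(unlist(predictions), nrow = length(labels),
                          byrow = TRUE), labels)
}

# Brute-force posterior: for one key, loop over all chemicals and count.
recount_posterior <- function(panel, key) {
  hits <- 0L; pos <- 0L
  for (i in seq_len(panel$n)) {
    if (all(panel$predictions[i, ] == key)) {
      hits <- hits + 1L
      if (panel$labels[i] == 1L) pos <- pos + 1L
    }
  }
  if (hits == 0L) NA_real_ else pos / hits
}

# Literal LOOCV: n refits through the public fit/lookup API, one
# chemical held out at a time.
naive_loocv_predictions <- function(panel, config) {
  vapply(seq_len(panel$n), function(i) {
    train <- prediction_panel(panel$predictions[-i, , drop = FALSE],
                              panel$labels[-i],
                              chemical_ids = panel$chemical_ids[-i],
                              tool_names = panel$tool_names)
    tab <- fit_bayes_ensemble(train, smoothing_alpha = config$smoothing_alpha)
    classify_key(tab, panel$predictions[i, ], config)
  }, integer(1))
}

# Manual trapezoid sum over (fpr, tpr) points assumed sorted by fpr.
manual_trapezoid <- function(fpr, tpr) {
  total <- 0
  for (i in seq_len(length(fpr) - 1L))
    total <- total + (fpr[i + 1L] - fpr[i]) * (tpr[i + 1L] + tpr[i]) / 2
  total
}

# Metrics recomputed longhand from raw vectors (no package code).
longhand_metrics <- function(truth, pred) {
  tp <- sum(truth == 1 & pred == 1); fn <- sum(truth == 1 & pred == 0)
  tn <- sum(truth == 0 & pred == 0); fp <- sum(truth == 0 & pred == 1)
  n <- length(truth)
  p_o <- (tp + tn) / n
  p_e <- ((tp + fn) * (tp + fp) + (fp + tn) * (fn + tn)) / n^2
  list(tp = tp, fn = fn, tn = tn, fp = fp,
       accuracy = (tp + tn) / n,
       sn = tp / (tp + fn), sp = tn / (tn + fp),
       kappa = if (p_e == 1) NA_real_ else (p_o - p_e) / (1 - p_e))
}
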