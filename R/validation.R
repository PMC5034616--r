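#' Confusion counts between truth and prediction
#'
#' @param truth,predicted equal-length 0/1 vectors (1 = carcinogenic).
#' @return An object of class `confusion_counts` with fields `tp`,
#'   `fn`, `tn`, `fp` partitioning the number of chemicals.
#' @export
confusion <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    abort_validation(sprintf("truth (%d) and predicted (%d) differ in length",
                             length(truth), length(predicted)))
  if (length(truth) < 1L)
    abort_validation("need at least one chemical")
  if (!is_binary(truth) || !is_binary(predicted))
    abort_validation("truth and predicted must contain only 0 and 1")
  truth <- as.integer(truth); predicted <- as.integer(predicted)
  structure(list(tp = sum(truth == 1L & predicted == 1L),
                 fn = sum(truth == 1L & predicted == 0L),
                 tn = sum(truth == 0L & predicted == 0L),
                 fp = sum(truth == 0L & predicted == 1L)),
            class = "confusion_counts")
}

confusion_counts <- function(tp, fn, tn, fp) {
  counts <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    abort_validation("confusion counts must be nonnegative integers")
  structure(lapply(counts, as.integer), class = "confusion_counts")
}

#' Confusion-matrix performance statistics
#'
#' Computes, from TP/FN/TN/FP counts, the standard panel statistics:
#' accuracy `(TP+TN)/N`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, balanced accuracy `(SN+SP)/2`, positive predictive
#' value `TP/(TP+FP)`, negative predictive value `TN/(TN+FN)`, and
#' Cohen's kappa. A statistic whose denominator is zero is reported as
#' `NA` (an explicit undefined flag) rather than silently as 0.
#'
#' @param counts a [confusion()] object, or anything coercible via
#'   `confusion()` when `truth` is also given.
#' @return An object of class `metrics_report`: the counts plus
#'   `accuracy`, `sensitivity`, `specificity`, `balanced_accuracy`,
#'   `ppv`, `npv`, `kappa`.
#' @export
classification_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; fn <- counts$fn; tn <- counts$tn; fp <- counts$fp
  n <- tp + fn + tn + fp
  if (n == 0L) abort_validation("all confusion counts are zero")
  frac <- function(num, den) if (den == 0) NA_real_ else num / den
  sn <- frac(tp, tp + fn)
  sp <- frac(tn, tn + fp)
  structure(list(counts = counts,
                 n = n,
                 accuracy = (tp + tn) / n,
                 sensitivity = sn,
                 specificity = sp,
                 balanced_accuracy = (sn + sp) / 2,
                 ppv = frac(tp, tp + fp),
                 npv = frac(tn, tn + fn),
                 kappa = cohen_kappa(counts)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  c0 <- x$counts
  cat(sprintf("N = %d (TP %d, FN %d, TN %d, FP %d)\n",
              x$n, c0$tp, c0$fn, c0$tn, c0$fp))
  stats <- c(Accuracy = x$accuracy, SN = x$sensitivity, SP = x$specificity,
             BA = x$balanced_accuracy, PPV = x$ppv, NPV = x$npv,
             Kappa = x$kappa)
  print(round(stats, digits))
  invisible(x)
}

#' Cohen's kappa from confusion counts
#'
#' Chance-corrected agreement between predictions and experimental
#' labels: \eqn{\kappa = (p_o - p_e) / (1 - p_e)} with observed
#' agreement \eqn{p_o = (TP+TN)/N} and chance agreement
#' \eqn{p_e = [(TP+FN)(TP+FP) + (FP+TN)(FN+TN)] / N^2}. Both terms are
#' proportions; the degenerate case \eqn{p_e = 1} (single-class truth
#' and prediction) is flagged `NA`.
#'
#' @param counts a [confusion()] object.
#' @return Kappa in `[-1, 1]`, or `NA` when undefined.
#' @export
cohen_kappa <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; fn <- counts$fn; tn <- counts$tn; fp <- counts$fp
  n <- tp + fn + tn + fp
  if (n == 0L) abort_validation("all confusion counts are zero")
  p_o <- (tp + tn) / n
  p_e <- ((tp + fn) * (tp + fp) + (fp + tn) * (fn + tn)) / n^2
  if (p_e == 1) return(NA_real_)
  (p_o - p_e) / (1 - p_e)
}

#' Qualitative agreement band for a kappa value
#'
#' Maps kappa onto the conventional interpretation bands: exactly 0 is
#' `"none"`, strictly between 0.41 and 0.60 `"moderate"`, strictly
#' between 0.61 and 0.80 `"substantial"`, exactly 1 `"perfect"`. The
#' bands as conventionally quoted leave gaps (e.g. 0.60-0.61); values
#' falling in a gap are labelled `"other"` rather than silently
#' assigned to a neighbour.
#'
#' @param kappa_value a number in `[-1, 1]`.
#' @return One of `"none"`, `"moderate"`, `"substantial"`, `"perfect"`,
#'   `"other"`.
#' @export
kappa_band <- function(kappa_value) {
  if (!is.numeric(kappa_value) || length(kappa_value) != 1L ||
      is.na(kappa_value) || kappa_value < -1 || kappa_value > 1)
    abort_validation("kappa_value must be a single number in [-1, 1]")
  if (kappa_value == 0) "none"
  else if (kappa_value > 0.41 && kappa_value < 0.60) "moderate"
  else if (kappa_value > 0.61 && kappa_value < 0.80) "substantial"
  else if (kappa_value == 1) "perfect"
  else "other"
}

#' Leave-one-out cross-validation of the Bayesian ensemble
#'
#' For each chemical `i`, fits the decision table on the remaining
#' `n - 1` chemicals and classifies chemical `i` with it; reports the
#' held-out predictions and the aggregate statistics over all `n`
#' folds. Because the classifier is a pure count table, each fold is
#' obtained exactly by decrementing chemical `i`'s own contribution
#' from the full-panel counts, so the protocol runs in `O(n)` while
#' remaining identical to `n` literal refits. A chemical that is the
#' sole occupant of its combination sees that combination as unseen in
#' its fold and is resolved by the unseen policy (with the `"prior"`
#' policy, the fold's own prevalence `(N_pos - y_i) / (n - 1)`).
#'
#' @param panel a [prediction_panel()] with `n >= 2`.
#' @param config an [ensemble_config()].
#' @return An object of class `loocv_result`: list with `predictions`
#'   and `posteriors` (length `n`, fold-held-out), `unseen` (logical:
#'   combination absent from the fold's training half), and `metrics`
#'   (a [classification_metrics()] report).
#' @export
loocv <- function(panel, config = ensemble_config()) {
  stopifnot(inherits(panel, "prediction_panel"),
            inherits(config, "ensemble_config"))
  if (panel$n < 2L)
    abort_validation("LOOCV needs at least 2 chemicals")
  posteriors <- loocv_posteriors(panel, config)
  predictions <- as.integer(posteriors$posterior >= config$cutoff)
  structure(list(predictions = predictions,
                 posteriors = posteriors$posterior,
                 unseen = posteriors$unseen,
                 metrics = classification_metrics(confusion(panel$labels,
                                                            predictions))),
            class = "loocv_result")
}

# Held-out posterior of every chemical, by decrementing its own
# contribution from the full-panel counts (exact LOOCV).
loocv_posteriors <- function(panel, config) {
  a <- config$smoothing_alpha
  idx <- key_index(panel$predictions)
  n_total <- tabulate(idx, nbins = 2L^panel$m)
  n_pos <- tabulate(idx[panel$labels == 1L], nbins = 2L^panel$m)
  y <- panel$labels
  nt <- n_total[idx] - 1L
  np <- n_pos[idx] - y
  unseen <- nt == 0L
  if (a > 0) {
    post <- (np + a) / (nt + 2 * a)
  } else {
    post <- ifelse(unseen, NA_real_, np / nt)
    if (any(unseen)) {
      npos_fold <- sum(y) - y[unseen]          # positives in the fold's training half
      post[unseen] <- switch(config$unseen_policy,
                             "prior" = npos_fold / (panel$n - 1L),
                             "abstain-as-negative" = 0,
                             "abstain-as-positive" = 1)
    }
  }
  list(posterior = post, unseen = unseen)
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf("LOOCV over %d chemicals (%d held-out combinations unseen in training)\n",
              length(x$predictions), sum(x$unseen)))
  print(x$metrics)
  invisible(x)
}

#' ROC curve of the ensemble over a cut-off grid
#'
#' Runs the LOOCV protocol and traces sensitivity against the false
#' positive rate as the cut-off sweeps the grid (default 0 to 1 in
#' steps of 0.1, i.e. 11 decision points). Held-out posteriors do not
#' depend on the cut-off, so they are computed once and thresholded at
#' each grid value; the result is identical to one full LOOCV per
#' cut-off. With the `>=` tie rule, sensitivity is non-increasing and
#' specificity non-decreasing along the grid.
#'
#' @param panel a [prediction_panel()].
#' @param config an [ensemble_config()]; its `cutoff` is ignored in
#'   favour of the grid.
#' @param grid increasing cut-off values in `[0, 1]`.
#' @return An object of class `roc_curve`: `points` data frame
#'   (`cutoff`, `sensitivity`, `fpr`) and `auc`.
#' @export
roc_curve <- function(panel, config = ensemble_config(),
                      grid = seq(0, 1, by = 0.1)) {
  stopifnot(inherits(panel, "prediction_panel"),
            inherits(config, "ensemble_config"))
  if (length(grid) == 0L)
    abort_validation("cutoff grid must be nonempty")
  if (anyNA(grid) || any(grid < 0 | grid > 1))
    abort_validation("every grid cutoff must lie in [0, 1]")
  grid <- sort(grid)
  post <- loocv_posteriors(panel, config)$posterior
  y <- panel$labels
  pos <- sum(y == 1L); neg <- sum(y == 0L)
  sn <- vapply(grid, function(c0) {
    if (pos == 0L) NA_real_ else sum(post >= c0 & y == 1L) / pos
  }, numeric(1))
  fpr <- vapply(grid, function(c0) {
    if (neg == 0L) NA_real_ else sum(post >= c0 & y == 0L) / neg
  }, numeric(1))
  points <- data.frame(cutoff = grid, sensitivity = sn, fpr = fpr)
  structure(list(points = points, auc = roc_auc(points)),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, digits = 4, ...) {
  cat(sprintf("ROC over %d decision points, AUC = %s\n", nrow(x$points),
              format(round(x$auc, digits))))
  print(round(x$points, digits), row.names = FALSE)
  invisible(x)
}

#' Area under a traced ROC curve
#'
#' Trapezoidal area over the curve's `(fpr, sensitivity)` points,
#' sorted by false positive rate, with the `(0, 0)` and `(1, 1)`
#' anchors appended when absent so the trace spans the unit square.
#'
#' @param x a [roc_curve()] object, or a data frame with columns
#'   `fpr` and `sensitivity` (at least 2 points).
#' @return The area, in `[0, 1]` for a monotone trace.
#' @export
roc_auc <- function(x) {
  if (inherits(x, "roc_curve")) x <- x$points
  if (!is.data.frame(x) || !all(c("fpr", "sensitivity") %in% names(x)))
    abort_validation("need a data frame with 'fpr' and 'sensitivity' columns")
  keep <- stats::complete.cases(x[, c("fpr", "sensitivity")])
  fpr <- x$fpr[keep]; tpr <- x$sensitivity[keep]
  if (length(fpr) < 2L)
    abort_validation("AUC needs at least 2 ROC points")
  if (!any(fpr == 0 & tpr == 0)) { fpr <- c(fpr, 0); tpr <- c(tpr, 0) }
  if (!any(fpr == 1 & tpr == 1)) { fpr <- c(fpr, 1); tpr <- c(tpr, 1) }
  o <- order(fpr, tpr)
  fpr <- fpr[o]; tpr <- tpr[o]
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Paired significance test between two classifiers
#'
#' Compares two classifiers on the same chemicals through their
#' per-chemical correctness indicators (1 = chemical classified
#' correctly). The default is a paired two-sided Student's t-test on
#' the indicator differences; McNemar's test on the discordant pairs is
#' available as an alternative. When every difference is zero the
#' statistic is undefined and flagged `NA`; when the differences are
#' constant but nonzero (one classifier uniformly better) the t
#' statistic is infinite and the result is reported as significant with
#' `p_value = 0` rather than crashing on zero variance.
#'
#' @param correct_a,correct_b equal-length 0/1 correctness vectors,
#'   `n >= 2`.
#' @param alpha significance level (default 0.05).
#' @param method `"t"` (paired Student) or `"mcnemar"`.
#' @return A list with `statistic`, `p_value`, `significant` (logical
#'   or `NA` when undefined), `method`, `n`.
#' @export
paired_comparison <- function(correct_a, correct_b, alpha = 0.05,
                              method = c("t", "mcnemar")) {
  method <- match.arg(method)
  if (length(correct_a) != length(correct_b))
    abort_validation("correctness vectors differ in length")
  n <- length(correct_a)
  if (n < 2L) abort_validation("need at least 2 paired observations")
  if (!is_binary(correct_a) || !is_binary(correct_b))
    abort_validation("correctness vectors must contain only 0 and 1")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    abort_validation("alpha must lie in (0, 1)")

  if (method == "t") {
    d <- as.integer(correct_a) - as.integer(correct_b)
    if (stats::sd(d) == 0) {
      if (mean(d) == 0)
        return(list(statistic = NA_real_, p_value = NA_real_,
                    significant = NA, method = "t", n = n))
      return(list(statistic = sign(mean(d)) * Inf, p_value = 0,
                  significant = TRUE, method = "t", n = n))
    }
    tt <- stats::t.test(d, mu = 0, alternative = "two.sided")
    list(statistic = unname(tt$statistic), p_value = tt$p.value,
         significant = tt$p.value < alpha, method = "t", n = n)
  } else {
    n01 <- sum(correct_a == 0L & correct_b == 1L)
    n10 <- sum(correct_a == 1L & correct_b == 0L)
    if (n01 + n10 == 0L)
      return(list(statistic = NA_real_, p_value = NA_real_,
                  significant = NA, method = "mcnemar", n = n))
    stat <- (abs(n10 - n01) - 1)^2 / (n10 + n01)  # continuity-corrected
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    list(statistic = stat, p_value = p, significant = p < alpha,
         method = "mcnemar", n = n)
  }
}

#' Write a metrics report to CSV or JSON
#'
#' Columns/fields follow the conventional panel-report naming:
#' `Accuracy, SN, SP, BA, PPV, NPV, Kappa` plus the raw counts.
#'
#' @param report a [classification_metrics()] report, or a named list
#'   of them (one row per model).
#' @param path output path.
#' @param format `"csv"` or `"json"`.
#' @return Invisibly, `path`.
#' @export
write_metrics_report <- function(report, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (inherits(report, "metrics_report")) report <- list(model = report)
  stopifnot(all(vapply(report, inherits, logical(1), "metrics_report")))
  rows <- lapply(names(report), function(nm) {
    r <- report[[nm]]
    data.frame(Model = nm, N = r$n,
               TP = r$counts$tp, FN = r$counts$fn,
               TN = r$counts$tn, FP = r$counts$fp,
               Accuracy = r$accuracy, SN = r$sensitivity,
               SP = r$specificity, BA = r$balanced_accuracy,
               PPV = r$ppv, NPV = r$npv, Kappa = r$kappa,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  ok <- tryCatch({
    if (format == "csv")
      utils::write.csv(df, path, row.names = FALSE, na = "")
    else
      jsonlite::write_json(df, path, dataframe = "rows", na = "null",
                           digits = NA)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    abort_io(sprintf("cannot write %s: %s", path, conditionMessage(ok)))
  invisible(path)
}
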