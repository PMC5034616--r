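#' Fit the Bayesian ensemble decision table
#'
#' Tabulates, for each of the `2^m` possible tool prediction
#' combinations \eqn{s_k}, how many training chemicals carry that
#' combination (\eqn{N_{s_k}}) and how many of those are carcinogens
#' (\eqn{N_{\omega=1, s_k}}), and stores the empirical posterior
#' probability of carcinogenicity
#' \deqn{P(\omega=1 \mid s = s_k) = N_{\omega=1,s_k} / N_{s_k}.}
#' Rows never observed in training carry an `unseen` flag instead of a
#' posterior (their ratio is 0/0); how they are resolved at prediction
#' time is governed by the unseen policy of [ensemble_config()].
#'
#' With `smoothing_alpha > 0` a symmetric pseudocount is added to both
#' classes, `(n_pos + alpha) / (n_total + 2 alpha)`, which defines a
#' posterior for every row including unseen ones. The default `0`
#' reproduces the plain empirical ratio.
#'
#' @param panel training [prediction_panel()].
#' @param smoothing_alpha nonnegative pseudocount (default 0).
#' @param method `"ratio"` computes the posterior directly as
#'   `n_pos / n_total`; `"quotient"` computes the algebraically
#'   identical full Bayes quotient
#'   \eqn{P(s_k|\omega=1) P(\omega=1) / P(s_k)} from its three
#'   estimated factors. Both paths are exposed so their exact agreement
#'   can be verified; `"quotient"` requires `smoothing_alpha = 0`.
#' @return An object of class `decision_table`: a list with a `table`
#'   data frame (`combination`, `n_total`, `n_pos`, `posterior`,
#'   `unseen`; one row per combination in lexicographic bitstring
#'   order) plus `m`, `tool_names`, `training_n`, `training_n_pos`,
#'   `smoothing_alpha`.
#' @examples
#' pan <- simulate_panel(simulation_config(n = 100, seed = 1))
#' fit_bayes_ensemble(pan)
#' @export
fit_bayes_ensemble <- function(panel, smoothing_alpha = 0,
                               method = c("ratio", "quotient")) {
  stopifnot(inherits(panel, "prediction_panel"))
  method <- match.arg(method)
  if (!is.numeric(smoothing_alpha) || length(smoothing_alpha) != 1L ||
      is.na(smoothing_alpha) || smoothing_alpha < 0)
    abort_validation("smoothing_alpha must be a single nonnegative number")
  if (method == "quotient" && smoothing_alpha > 0)
    abort_validation("the quotient posterior path is defined only for smoothing_alpha = 0")

  m <- panel$m
  n_rows <- 2L^m
  idx <- key_index(panel$predictions)
  n_total <- tabulate(idx, nbins = n_rows)
  n_pos <- tabulate(idx[panel$labels == 1L], nbins = n_rows)
  n <- panel$n
  npos <- sum(panel$labels == 1L)
  unseen <- n_total == 0L

  if (smoothing_alpha > 0) {
    posterior <- (n_pos + smoothing_alpha) / (n_total + 2 * smoothing_alpha)
  } else if (method == "ratio") {
    posterior <- ifelse(unseen, NA_real_, n_pos / n_total)
  } else {
    # P(s_k | w=1) * P(w=1) / P(s_k), each factor estimated from counts
    p_s_given_pos <- if (npos > 0) n_pos / npos else rep(0, n_rows)
    p_pos <- npos / n
    p_s <- n_total / n
    posterior <- ifelse(unseen, NA_real_, p_s_given_pos * p_pos / p_s)
  }

  structure(
    list(table = data.frame(combination = key_string(enumerate_keys(m)),
                            n_total = as.integer(n_total),
                            n_pos = as.integer(n_pos),
                            posterior = posterior,
                            unseen = unseen,
                            stringsAsFactors = FALSE),
         m = m,
         tool_names = panel$tool_names,
         training_n = n,
         training_n_pos = npos,
         smoothing_alpha = smoothing_alpha),
    class = "decision_table")
}

#' @export
print.decision_table <- function(x, ...) {
  cat(sprintf("decision_table: m = %d tools, %d combinations, N = %d (%d carcinogenic), alpha = %g\n",
              x$m, nrow(x$table), x$training_n, x$training_n_pos,
              x$smoothing_alpha))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Ensemble classification configuration
#'
#' @param cutoff posterior-probability threshold in `[0, 1]`; a chemical
#'   is called carcinogenic iff its posterior is `>= cutoff`. The `>=`
#'   tie rule makes `cutoff = 0` classify everything positive (perfect
#'   sensitivity); perfect specificity needs a cutoff strictly above the
#'   largest occupied posterior, which `cutoff = 1` provides only when no
#'   occupied combination is purely carcinogenic.
#' @param unseen_policy how to resolve a prediction combination never
#'   observed in training (its empirical posterior is 0/0): `"prior"`
#'   (default) falls back to the training prevalence
#'   \eqn{N_{\omega=1}/N}; `"abstain-as-negative"` and
#'   `"abstain-as-positive"` force the posterior to 0 or 1 for
#'   conservative use in either direction.
#' @param smoothing_alpha pseudocount passed through to fitting inside
#'   protocols such as [loocv()]; default 0.
#' @return An object of class `ensemble_config`.
#' @export
ensemble_config <- function(cutoff = 0.5,
                            unseen_policy = c("prior", "abstain-as-negative",
                                              "abstain-as-positive"),
                            smoothing_alpha = 0) {
  unseen_policy <- match.arg(unseen_policy)
  if (!is.numeric(cutoff) || length(cutoff) != 1L || is.na(cutoff) ||
      cutoff < 0 || cutoff > 1)
    abort_validation("cutoff must be a single number in [0, 1]")
  if (!is.numeric(smoothing_alpha) || length(smoothing_alpha) != 1L ||
      is.na(smoothing_alpha) || smoothing_alpha < 0)
    abort_validation("smoothing_alpha must be a single nonnegative number")
  structure(list(cutoff = cutoff, unseen_policy = unseen_policy,
                 smoothing_alpha = smoothing_alpha),
            class = "ensemble_config")
}

#' Look up the posterior probability for one prediction combination
#'
#' @param table a fitted [fit_bayes_ensemble()] decision table.
#' @param key length-`m` 0/1 vector, one bit per tool in panel order.
#' @param unseen_policy see [ensemble_config()].
#' @return The posterior probability of carcinogenicity in `[0, 1]`.
#' @export
posterior_lookup <- function(table, key,
                             unseen_policy = c("prior", "abstain-as-negative",
                                               "abstain-as-positive")) {
  stopifnot(inherits(table, "decision_table"))
  unseen_policy <- match.arg(unseen_policy)
  key <- check_key(key, table$m)
  i <- key_index(key)
  row <- table$table[i, ]
  if (!row$unseen || table$smoothing_alpha > 0) return(row$posterior)
  switch(unseen_policy,
         "prior" = table$training_n_pos / table$training_n,
         "abstain-as-negative" = 0,
         "abstain-as-positive" = 1)
}

#' Classify one prediction combination against the cut-off
#'
#' Returns 1 (carcinogenic) iff the looked-up posterior is greater than
#' or equal to the configured cut-off.
#'
#' @inheritParams posterior_lookup
#' @param config an [ensemble_config()].
#' @return 0 or 1.
#' @export
classify_key <- function(table, key, config = ensemble_config()) {
  stopifnot(inherits(config, "ensemble_config"))
  p <- posterior_lookup(table, key, config$unseen_policy)
  as.integer(p >= config$cutoff)
}

#' Classify every chemical of a panel
#'
#' Vectorised lookup-and-threshold of each chemical's prediction
#' combination. The panel must carry the same tools in the same order
#' as the fitted table.
#'
#' @param table a [fit_bayes_ensemble()] decision table.
#' @param panel a [prediction_panel()] with matching tools.
#' @param config an [ensemble_config()].
#' @return Integer vector of length `n` over `{0, 1}`.
#' @export
predict_panel <- function(table, panel, config = ensemble_config()) {
  stopifnot(inherits(table, "decision_table"),
            inherits(panel, "prediction_panel"),
            inherits(config, "ensemble_config"))
  if (panel$m != table$m || !identical(panel$tool_names, table$tool_names))
    abort_validation("panel tools do not match the decision table (same tools, same order required)")
  post <- posterior_batch(table, panel$predictions, config$unseen_policy)
  as.integer(post >= config$cutoff)
}

# Vectorised posterior lookup for an n x m 0/1 matrix of combinations.
posterior_batch <- function(table, predictions, unseen_policy) {
  idx <- key_index(predictions)
  post <- table$table$posterior[idx]
  if (table$smoothing_alpha == 0) {
    miss <- table$table$unseen[idx]
    if (any(miss)) {
      fallback <- switch(unseen_policy,
                         "prior" = table$training_n_pos / table$training_n,
                         "abstain-as-negative" = 0,
                         "abstain-as-positive" = 1)
      post[miss] <- fallback
    }
  }
  post
}

#' Export a decision table to CSV
#'
#' Writes `combination, n_total, n_pos, posterior` with the combination
#' as a bitstring (e.g. `"0101"`); unseen rows (alpha = 0) have an
#' empty posterior field.
#'
#' @param table a [fit_bayes_ensemble()] decision table.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_decision_table <- function(table, path) {
  stopifnot(inherits(table, "decision_table"))
  df <- table$table[, c("combination", "n_total", "n_pos", "posterior")]
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    abort_io(sprintf("cannot write %s: %s", path, conditionMessage(ok)))
  invisible(path)
}
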