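#' Configuration of a synthetic prediction panel
#'
#' Describes a panel of `m` binary classifiers evaluated on `n`
#' chemicals: the fraction of true carcinogens (`prevalence`), each
#' tool's operating point (sensitivity, specificity), and a single
#' dependence knob inducing positive inter-tool correlation beyond
#' what the shared label explains.
#'
#' The defaults emulate a realistic regulatory panel: 332 chemicals
#' with a carcinogen fraction of 114/332, screened by four tools with
#' operating points (SN, SP) of (0.68, 0.80), (0.75, 0.76),
#' (0.81, 0.71) and (0.69, 0.80) — the sensitivity/specificity range
#' reported for rule- and fragment-based carcinogenicity predictors —
#' and conditional independence (`dependence = 0`).
#'
#' @param n number of chemicals (`n >= 1`).
#' @param tool_profiles per-tool `(sensitivity, specificity)` pairs: a
#'   2-column matrix, a list of length-2 vectors, or a data frame with
#'   columns `sn` and `sp`; all rates in `[0, 1]`.
#' @param prevalence fraction of carcinogens, strictly inside `(0, 1)`.
#' @param dependence inter-tool dependence knob in `[0, 1)`. For each
#'   chemical one shared latent uniform is drawn; each tool's decision
#'   uniform is the shared one with probability `dependence` and an
#'   independent draw otherwise, then thresholded at the tool's
#'   class-conditional positive rate. `0` gives conditional
#'   independence given the label; larger values make tools agree more
#'   while leaving every marginal SN/SP exact.
#' @param seed integer seed; identical configurations produce
#'   bit-identical panels.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n = 332,
                              tool_profiles = list(c(0.68, 0.80),
                                                   c(0.75, 0.76),
                                                   c(0.81, 0.71),
                                                   c(0.69, 0.80)),
                              prevalence = 114 / 332,
                              dependence = 0,
                              seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1 || n != round(n))
    abort_validation("n must be a positive integer")
  profiles <- normalise_profiles(tool_profiles)
  if (!is.numeric(prevalence) || length(prevalence) != 1L ||
      is.na(prevalence) || prevalence <= 0 || prevalence >= 1)
    abort_validation("prevalence must lie strictly inside (0, 1)")
  if (!is.numeric(dependence) || length(dependence) != 1L ||
      is.na(dependence) || dependence < 0 || dependence >= 1)
    abort_validation("dependence must lie in [0, 1)")
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed != round(seed))
    abort_validation("seed must be a single integer")
  structure(list(n = as.integer(n), tool_profiles = profiles,
                 prevalence = prevalence, dependence = dependence,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

normalise_profiles <- function(tool_profiles) {
  if (is.data.frame(tool_profiles)) {
    if (!all(c("sn", "sp") %in% names(tool_profiles)))
      abort_validation("tool_profiles data frame needs columns 'sn' and 'sp'")
    profiles <- cbind(sn = tool_profiles$sn, sp = tool_profiles$sp)
  } else if (is.list(tool_profiles)) {
    if (length(tool_profiles) == 0L)
      abort_validation("need at least one tool profile")
    if (!all(lengths(tool_profiles) == 2L))
      abort_validation("each tool profile must be a (sensitivity, specificity) pair")
    profiles <- do.call(rbind, tool_profiles)
    colnames(profiles) <- c("sn", "sp")
  } else if (is.matrix(tool_profiles) && ncol(tool_profiles) == 2L) {
    profiles <- tool_profiles
    colnames(profiles) <- c("sn", "sp")
  } else {
    abort_validation("tool_profiles must be a 2-column matrix, a list of pairs, or a data frame")
  }
  if (nrow(profiles) < 1L)
    abort_validation("need at least one tool profile")
  if (anyNA(profiles) || any(profiles < 0) || any(profiles > 1))
    abort_validation("all sensitivities and specificities must lie in [0, 1]")
  profiles
}

#' Simulate a synthetic prediction panel
#'
#' Draws labels with the configured prevalence; given label 1, tool `j`
#' predicts 1 with probability `sn_j`, given label 0 with probability
#' `1 - sp_j`. Dependence between tools (beyond the shared label) comes
#' from a shared latent uniform per chemical: each tool reuses it in
#' place of its own decision uniform with probability `dependence`
#' before thresholding, which preserves every marginal operating point
#' exactly. The generator uses one seeded RNG stream and restores the
#' caller's RNG state.
#'
#' @param config a [simulation_config()].
#' @return A [prediction_panel()] with ids `chem_0001, ...` and tool
#'   names `tool_1, ...`.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n
  m <- nrow(config$tool_profiles)
  with_seed(config$seed, {
    labels <- stats::rbinom(n, 1L, config$prevalence)
    shared <- stats::runif(n)
    predictions <- matrix(0L, n, m)
    for (j in seq_len(m)) {
      sn <- config$tool_profiles[j, "sn"]
      sp <- config$tool_profiles[j, "sp"]
      own <- stats::runif(n)
      use_shared <- stats::runif(n) < config$dependence
      u <- ifelse(use_shared, shared, own)
      p_pos <- ifelse(labels == 1L, sn, 1 - sp)
      predictions[, j] <- as.integer(u < p_pos)
    }
    prediction_panel(predictions, labels,
                     chemical_ids = sprintf("chem_%0*d", nchar(n), seq_len(n)),
                     tool_names = paste0("tool_", seq_len(m)))
  })
}

#' Closed-form posterior under the conditional-independence model
#'
#' For `dependence = 0` the generative model factorises given the
#' label, so the posterior probability of carcinogenicity for a
#' prediction combination `s` is available in closed form:
#' \deqn{P(\omega=1 \mid s) = \frac{\pi \prod_j q_j(s_j \mid 1)}
#'   {\pi \prod_j q_j(s_j \mid 1) + (1-\pi) \prod_j q_j(s_j \mid 0)}}
#' with \eqn{\pi} the prevalence, \eqn{q_j(1|1) = SN_j},
#' \eqn{q_j(0|1) = 1 - SN_j}, \eqn{q_j(1|0) = 1 - SP_j},
#' \eqn{q_j(0|0) = SP_j}. This is the oracle a fitted decision table
#' must converge to as the panel grows.
#'
#' @param config a [simulation_config()] with `dependence = 0`.
#' @param key length-`m` 0/1 prediction combination.
#' @return `P(carcinogenic | key)` in `[0, 1]`.
#' @export
true_posterior <- function(config, key) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$dependence != 0)
    abort_validation("the closed-form posterior is defined only for dependence = 0")
  m <- nrow(config$tool_profiles)
  key <- check_key(key, m)
  sn <- config$tool_profiles[, "sn"]
  sp <- config$tool_profiles[, "sp"]
  lik1 <- prod(ifelse(key == 1L, sn, 1 - sn))
  lik0 <- prod(ifelse(key == 1L, 1 - sp, sp))
  num <- config$prevalence * lik1
  den <- num + (1 - config$prevalence) * lik0
  if (den == 0) return(NA_real_)  # combination impossible under both classes
  num / den
}
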