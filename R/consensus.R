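# Rule-based consensus combiners used as baselines for the Bayesian
# ensemble: a chemical is flagged when all (AND), any (OR), or most
# (majority) of the selected tools flag it.

select_tools <- function(panel, tool_subset) {
  stopifnot(inherits(panel, "prediction_panel"))
  if (is.null(tool_subset)) tool_subset <- panel$tool_names
  if (length(tool_subset) == 0L)
    abort_validation("tool_subset must be nonempty")
  missing <- setdiff(tool_subset, panel$tool_names)
  if (length(missing))
    abort_validation(sprintf("unknown tool(s): %s",
                             paste(missing, collapse = ", ")))
  panel$predictions[, tool_subset, drop = FALSE]
}

#' AND consensus: positive only when every selected tool is positive
#'
#' @param panel a [prediction_panel()].
#' @param tool_subset tool names to combine; default all tools.
#' @return Integer 0/1 vector of length `n`.
#' @export
consensus_and <- function(panel, tool_subset = NULL) {
  p <- select_tools(panel, tool_subset)
  as.integer(rowSums(p) == ncol(p))
}

#' OR consensus: positive when any selected tool is positive
#'
#' @inheritParams consensus_and
#' @return Integer 0/1 vector of length `n`.
#' @export
consensus_or <- function(panel, tool_subset = NULL) {
  p <- select_tools(panel, tool_subset)
  as.integer(rowSums(p) > 0L)
}

#' Majority consensus over the selected tools
#'
#' Positive when strictly more than half of the selected tools are
#' positive; an exact half (possible only for an even number of tools)
#' resolves to `tie_value`, which defaults to 1 — conservative toward
#' flagging potential carcinogens.
#'
#' @inheritParams consensus_and
#' @param tie_value 0 or 1, the call for an exact half split.
#' @return Integer 0/1 vector of length `n`.
#' @export
consensus_majority <- function(panel, tool_subset = NULL, tie_value = 1L) {
  if (!is_binary(tie_value) || length(tie_value) != 1L)
    abort_validation("tie_value must be 0 or 1")
  p <- select_tools(panel, tool_subset)
  votes <- rowSums(p)
  half <- ncol(p) / 2
  out <- integer(nrow(p))
  out[votes > half] <- 1L
  out[votes == half] <- as.integer(tie_value)
  out
}
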