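#' Construct a prediction panel
#'
#' A prediction panel holds, for each of `n` chemicals, the binary
#' carcinogenicity calls of `m` QSAR tools (1 = carcinogenic,
#' 0 = non-carcinogenic) together with the binary experimental label.
#' Panels are complete-case by construction: missing or non-binary
#' entries are rejected, never imputed, because the method's counts are
#' only meaningful when every chemical carries a call from every tool.
#'
#' @param predictions an `n x m` matrix (or data frame) of 0/1 tool calls,
#'   one column per tool.
#' @param labels length-`n` vector of 0/1 experimental labels
#'   (1 = carcinogenic).
#' @param chemical_ids length-`n` character vector of unique chemical
#'   identifiers; defaults to `chem_1 ... chem_n`.
#' @param tool_names length-`m` character vector of unique tool names;
#'   defaults to the column names of `predictions` or `tool_1 ... tool_m`.
#' @return An object of class `prediction_panel`: a list with elements
#'   `chemical_ids`, `predictions` (integer matrix with tool names as
#'   column names), `labels`, and helpers `n`, `m`.
#' @seealso [read_panel()], [write_panel()], [simulate_panel()]
#' @export
prediction_panel <- function(predictions, labels, chemical_ids = NULL,
                             tool_names = NULL) {
  predictions <- as.matrix(predictions)
  if (nrow(predictions) < 1L || ncol(predictions) < 1L)
    abort_validation("a panel needs at least one chemical and one tool")
  if (is.null(tool_names)) tool_names <- colnames(predictions)
  if (is.null(tool_names)) tool_names <- paste0("tool_", seq_len(ncol(predictions)))
  if (is.null(chemical_ids)) chemical_ids <- paste0("chem_", seq_len(nrow(predictions)))
  chemical_ids <- as.character(chemical_ids)
  tool_names <- as.character(tool_names)

  if (length(labels) != nrow(predictions))
    abort_validation(sprintf("labels has length %d but predictions has %d rows",
                             length(labels), nrow(predictions)))
  if (length(chemical_ids) != nrow(predictions))
    abort_validation("chemical_ids length must equal the number of rows")
  if (length(tool_names) != ncol(predictions))
    abort_validation("tool_names length must equal the number of columns")
  if (anyDuplicated(chemical_ids))
    abort_validation("chemical_ids contains duplicates")
  if (anyDuplicated(tool_names))
    abort_validation("tool_names contains duplicates")
  if (!is_binary(predictions))
    abort_validation("every prediction must be exactly 0 or 1 (no missing values)")
  if (!is_binary(labels))
    abort_validation("every label must be exactly 0 or 1 (no missing values)")

  storage.mode(predictions) <- "integer"
  dimnames(predictions) <- list(NULL, tool_names)
  structure(
    list(chemical_ids = chemical_ids,
         predictions = predictions,
         tool_names = tool_names,
         labels = as.integer(labels),
         n = nrow(predictions),
         m = ncol(predictions)),
    class = "prediction_panel")
}

#' @export
print.prediction_panel <- function(x, ...) {
  cat(sprintf("prediction_panel: %d chemicals x %d tools (%d carcinogenic, %d non-carcinogenic)\n",
              x$n, x$m, sum(x$labels == 1L), sum(x$labels == 0L)))
  cat("tools:", paste(x$tool_names, collapse = ", "), "\n")
  invisible(x)
}

#' Read a prediction panel from CSV
#'
#' Expects a comma-separated, UTF-8, RFC-4180 file with a header row.
#' One column carries the chemical identifier, one the experimental
#' label; every remaining column is taken to be a tool column, in file
#' order. All prediction and label cells must be exactly `0` or `1`;
#' anything else (including blanks) is a validation error naming the
#' offending row and column, because silent coercion of an equivocal
#' tool output would corrupt the decision-table counts.
#'
#' @param path path to the CSV file.
#' @param label_column,id_column names of the label and identifier
#'   columns (defaults `"label"`, `"id"`).
#' @return A [prediction_panel()].
#' @export
read_panel <- function(path, label_column = "label", id_column = "id") {
  if (!file.exists(path))
    abort_io(sprintf("panel file not found: %s", path))
  df <- tryCatch(
    utils::read.csv(path, colClasses = "character", check.names = FALSE,
                    fileEncoding = "UTF-8"),
    error = function(e) abort_io(sprintf("cannot read %s: %s", path,
                                         conditionMessage(e))))
  if (nrow(df) == 0L)
    abort_validation(sprintf("panel file %s has a header but no rows", path))
  cols <- names(df)
  if (anyDuplicated(cols))
    abort_validation(sprintf("duplicate column names in %s: %s", path,
                             paste(unique(cols[duplicated(cols)]), collapse = ", ")))
  for (needed in c(id_column, label_column))
    if (!needed %in% cols)
      abort_validation(sprintf("column '%s' not found in %s", needed, path))
  tool_cols <- setdiff(cols, c(id_column, label_column))
  if (length(tool_cols) == 0L)
    abort_validation(sprintf("no tool columns in %s", path))

  parse_bits <- function(column) {
    v <- trimws(df[[column]])
    bad <- which(!(v %in% c("0", "1")))
    if (length(bad))
      abort_validation(sprintf(
        "cell '%s' at row %d, column '%s' is not 0 or 1",
        df[[column]][bad[1L]], bad[1L], column))
    as.integer(v)
  }
  predictions <- vapply(tool_cols, parse_bits, integer(nrow(df)))
  predictions <- matrix(predictions, nrow = nrow(df),
                        dimnames = list(NULL, tool_cols))
  labels <- parse_bits(label_column)
  prediction_panel(predictions, labels,
                   chemical_ids = df[[id_column]], tool_names = tool_cols)
}

#' Write a prediction panel to CSV
#'
#' Writes `id, <tool_1>, ..., <tool_m>, label` with RFC-4180 quoting of
#' the identifier and header fields, so that [read_panel()] on the
#' result reproduces the panel bit-exactly (tool names containing
#' commas are quoted rather than rejected).
#'
#' @param panel a [prediction_panel()].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "prediction_panel"))
  df <- data.frame(id = panel$chemical_ids, check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (j in seq_len(panel$m)) df[[panel$tool_names[j]]] <- panel$predictions[, j]
  df[["label"]] <- panel$labels
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    abort_io(sprintf("cannot write %s: %s", path, conditionMessage(ok)))
  invisible(path)
}
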