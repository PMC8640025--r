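# Delimited-text I/O. All output tables are plain TSV with a '#'-prefixed
# metadata header (version, seed, parameters); JSON for structured results.

delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a feature matrix from delimited text
#'
#' Samples in rows, features in columns, header row of feature names;
#' comma-separated for `.csv`, tab otherwise. Lines starting with `#` are
#' skipped.
#'
#' @param path input file.
#' @param outcome_col optional name of a column to split off as the
#'   outcome.
#' @return a numeric matrix, or (with `outcome_col`) a list with elements
#'   `x` and `y`.
#' @export
read_feature_matrix <- function(path, outcome_col = NULL) {
  if (!file.exists(path)) stop_user("input file '%s' does not exist", path)
  d <- tryCatch(
    utils::read.table(path, header = TRUE, sep = delim_for(path),
                      comment.char = "#", check.names = FALSE),
    error = function(e) stop_user("could not parse '%s': %s", path,
                                  conditionMessage(e)))
  if (!is.null(outcome_col)) {
    if (!outcome_col %in% names(d))
      stop_user("outcome column '%s' not found in '%s'", outcome_col, path)
    y <- as.numeric(d[[outcome_col]])
    x <- as.matrix(d[, setdiff(names(d), outcome_col), drop = FALSE])
    storage.mode(x) <- "double"
    return(list(x = x, y = y))
  }
  x <- as.matrix(d)
  storage.mode(x) <- "double"
  x
}

#' Read a single-column outcome file
#' @param path input file (optional header; `#` comments skipped).
#' @return numeric vector.
#' @export
read_outcome <- function(path) {
  if (!file.exists(path)) stop_user("outcome file '%s' does not exist", path)
  d <- utils::read.table(path, header = FALSE, sep = delim_for(path),
                         comment.char = "#")
  v <- d[[ncol(d)]]
  if (is.character(v) || is.factor(v)) {  # header present
    v <- utils::read.table(path, header = TRUE, sep = delim_for(path),
                           comment.char = "#")[[1L]]
  }
  as.numeric(v)
}

meta_header <- function(seed = NULL, ...) {
  extra <- list(...)
  fields <- c(sprintf("ecar %s",
                      as.character(utils::packageVersion("ecar"))),
              if (!is.null(seed)) sprintf("seed=%s", seed),
              if (length(extra)) sprintf("%s=%s", names(extra),
                                         vapply(extra, format, "")))
  paste0("# ", paste(fields, collapse = "; "))
}

#' Write a table as TSV with a metadata comment header
#' @param x data frame.
#' @param path output file.
#' @param seed,... recorded in the `#` header line.
#' @export
write_tsv <- function(x, path, seed = NULL, ...) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta_header(seed = seed, ...), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a score table written by the CLI
#' @param path TSV file with columns feature_id, score, abs_score, rank,
#'   alpha.
#' @return an `ecar_scores` data frame.
#' @export
read_score_table <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         comment.char = "#", stringsAsFactors = FALSE)
  need <- c("feature_id", "score")
  if (!all(need %in% names(d)))
    stop_user("'%s' lacks required columns %s", path,
              paste(setdiff(need, names(d)), collapse = ", "))
  if (is.null(d$alpha)) d$alpha <- NA_real_
  structure(data.frame(feature_id = as.character(d$feature_id),
                       score = d$score,
                       abs_score = d$abs_score %||% abs(d$score),
                       rank = d$rank %||% rank_by_abs(d$score),
                       alpha = d$alpha,
                       stringsAsFactors = FALSE),
            class = c("ecar_scores", "data.frame"))
}
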