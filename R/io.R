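# Delimited-text I/O: comma-separated, UTF-8, header mandatory, classes
# serialized as integers 0-6, missing raw labels as empty fields.

class_columns <- function() c("true_class", "raw_label", "label",
                              "final_label", "answer")

#' Write label records to a CSV file
#'
#' @param records data.frame of label records.
#' @param path Destination file.
#' @return The path, invisibly.
#' @export
write_labels <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE,
                   na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read label records from a CSV file
#'
#' The header row is mandatory. Class-coded columns (`true_class`,
#' `raw_label`, `label`, `final_label`, `answer`) are validated to codes
#' 0-6; a malformed code raises a parse error naming the file line. Empty
#' fields in `raw_label` become `NA`; unknown columns are preserved
#' verbatim.
#'
#' @param path CSV file to read.
#' @return data.frame of records (possibly zero rows).
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        fileEncoding = "UTF-8")
  for (col in intersect(class_columns(), names(df))) {
    raw <- df[[col]]
    blank <- is.na(raw) | !nzchar(trimws(raw))
    val <- suppressWarnings(as.integer(raw))
    bad <- !blank & (is.na(val) | !(val %in% 0:6))
    if (any(bad)) {
      line <- which(bad)[1L] + 1L  # header occupies line 1
      stop(sprintf("parse error in %s, line %d: invalid %s '%s' (expected 0-6)",
                   path, line, col, raw[which(bad)[1L]]), call. = FALSE)
    }
    val[blank] <- NA_integer_
    df[[col]] <- val
  }
  if ("excluded" %in% names(df)) df$excluded <- as.logical(df$excluded)
  if ("referrable" %in% names(df))
    df$referrable <- as.logical(as.integer(df$referrable))
  df
}

#' Read AUT referral calls, auto-detecting the output format
#'
#' Accepts either binary-call files (`image_id`, `referrable` in {0, 1})
#' or 7-class output files (`image_id`, `label` 0-6), detected from the
#' header; class outputs are mapped through [to_referrable()].
#'
#' @param path CSV file.
#' @return data.frame `image_id`, `referrable`.
#' @export
read_aut_calls <- function(path) {
  df <- read_labels(path)
  if ("referrable" %in% names(df)) {
    data.frame(image_id = df$image_id, referrable = as.logical(df$referrable),
               stringsAsFactors = FALSE)
  } else if ("label" %in% names(df)) {
    data.frame(image_id = df$image_id, referrable = to_referrable(df$label),
               stringsAsFactors = FALSE)
  } else {
    stop(sprintf("%s: expected a 'referrable' or 'label' column", path),
         call. = FALSE)
  }
}

#' Serialize / restore a run configuration
#'
#' Configurations round-trip losslessly through YAML.
#'
#' @param config A [run_config()].
#' @param path Destination / source file.
#' @return `write_run_config` returns the path invisibly;
#'   `read_run_config` returns the restored `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw)
}

# Stable digest of a configuration's scientific content (the output
# location is excluded), recorded in the run manifest.
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$output_dir <- NULL
  hash_string(paste(utils::capture.output(utils::str(cfg)), collapse = "\n"))
}
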