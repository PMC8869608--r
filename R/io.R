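#' Read a long intensity table
#'
#' TSV with header \code{feature_id, tapping, replicate, value}; UTF-8,
#' '.' decimal. Duplicate (feature, tapping, replicate) combinations and
#' non-numeric or non-positive values are rejected with the offending line
#' number.
#'
#' @param path Path to the TSV file.
#' @return Validated data frame (possibly with zero rows).
#' @export
read_intensity_table <- function(path) {
  if (!file.exists(path)) stop_tapseq("input file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!nrow(df)) {
    check_columns(df, c("feature_id", "tapping", "replicate", "value"),
                  basename(path))
    return(df)
  }
  check_columns(df, c("feature_id", "tapping", "replicate", "value"),
                basename(path))
  tap <- suppressWarnings(as.integer(df$tapping))
  rep_ <- suppressWarnings(as.integer(df$replicate))
  val <- suppressWarnings(as.numeric(df$value))
  bad <- which(is.na(tap) | is.na(rep_) | !is.finite(val) | val <= 0)
  if (length(bad))
    stop_tapseq(sprintf("%s: malformed row at line %d (+header)",
                        basename(path), bad[1] + 1L))
  df$tapping <- tap; df$replicate <- rep_; df$value <- val
  key <- paste(df$feature_id, tap, rep_, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key))[1]
    stop_tapseq(sprintf("%s: duplicate (feature, tapping, replicate) at line %d",
                        basename(path), dup + 1L))
  }
  df
}

#' Write a table as TSV
#'
#' @param df Data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a Ct table
#'
#' TSV with header \code{feature_id, tapping, replicate, ct_target,
#' ct_reference}.
#'
#' @param path Path to the TSV file.
#' @return Validated data frame.
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) stop_tapseq("input file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_columns(df, c("feature_id", "tapping", "replicate", "ct_target",
                      "ct_reference"), basename(path))
  df
}
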