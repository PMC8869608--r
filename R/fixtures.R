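# Loaders for the validation-study fixtures shipped under inst/extdata:
# the sqRT-PCR validation series, the qRT-PCR panel of latex-regeneration
# TDFs, the category-by-pattern count tables, and a synthetic reconstruction
# of the transcript-protein counterpart set.

extdata <- function(name) {
  path <- system.file("extdata", name, package = "tapseq")
  if (path == "") stop_tapseq("fixture not found: ", name)
  path
}

#' Load the sqRT-PCR validation fixture
#'
#' 80 gel-validated TDFs with their relative sqRT-PCR series (first tapping
#' = 1.00; \code{NA} where the PCR produced no band) and the printed
#' consistency flag against the cDNA-AFLP gel profile.
#'
#' @return Data frame: \code{tdf_id, r1..r5, flag} ("+" or "-").
#' @export
load_sq_validation <- function() {
  df <- utils::read.delim(extdata("table2.tsv"), stringsAsFactors = FALSE,
                          na.strings = "NO_BAND")
  for (k in paste0("r", 1:5)) df[[k]] <- as.numeric(df[[k]])
  df
}

#' Load the qRT-PCR validation fixture
#'
#' The 29 latex-regeneration-related TDFs profiled by qRT-PCR, with their
#' BLAST annotation, pathway, gel-derived regulation model and the printed
#' consistency flag.
#'
#' @return Data frame: \code{tdf_id, annotation, pathway, model, flag}.
#' @export
load_qpcr_validation <- function() {
  utils::read.delim(extdata("table3.tsv"), stringsAsFactors = FALSE)
}

#' Load a category-by-pattern count fixture
#'
#' Per-category counts of up/down/irregular features for the transcript
#' (\code{"tdf"}) or protein (\code{"protein"}) screen.
#'
#' @param which \code{"tdf"} or \code{"protein"}.
#' @return Data frame: \code{category, up, down, irregular}.
#' @export
load_category_counts <- function(which = c("tdf", "protein")) {
  which <- match.arg(which)
  utils::read.delim(extdata(sprintf("table1_%s.tsv", which)),
                    stringsAsFactors = FALSE)
}

#' Expand a category-by-pattern count table into per-feature records
#'
#' Turns a count table (one row per category with up/down/irregular counts)
#' into per-feature pattern calls and annotations, so that the summary
#' operation can be exercised against its own cross-tabulation.
#'
#' @param counts Data frame from \code{\link{load_category_counts}}.
#' @param prefix Feature-id prefix.
#' @return List with \code{calls} (\code{feature_id, major}) and
#'   \code{annotations} (\code{feature_id, category}).
#' @export
expand_category_counts <- function(counts, prefix = "f") {
  check_columns(counts, c("category", "up", "down", "irregular"), "count table")
  rows <- list(); k <- 0L
  for (i in seq_len(nrow(counts))) {
    for (maj in c("up", "down", "irregular")) {
      n <- counts[[maj]][i]
      if (n > 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          feature_id = sprintf("%s%04d", prefix, k + seq_len(n)),
          major = maj, category = counts$category[i],
          stringsAsFactors = FALSE)
        k <- k + n
      }
    }
  }
  all <- do.call(rbind, rows)
  list(calls = all[, c("feature_id", "major")],
       annotations = all[, c("feature_id", "category")])
}

#' Load the transcript-protein counterpart fixture
#'
#' Synthetic reconstruction of the counterpart set: six protein spots and
#' five TDFs joined by gene identifier, with patterns set so that exactly
#' one pair agrees in direction. The real spot-level patterns and gene ids
#' are not printed anywhere; this fixture encodes only the documented join
#' structure.
#'
#' @return List with \code{protein} (\code{spot_id, gene_id, major}) and
#'   \code{tdf} (\code{tdf_id, gene_id, major}).
#' @export
load_overlap_fixture <- function() {
  df <- utils::read.delim(extdata("overlap_counterparts_synthetic.tsv"),
                          stringsAsFactors = FALSE)
  pr <- df[df$side == "protein", ]
  td <- df[df$side == "tdf", ]
  list(protein = data.frame(spot_id = pr$id, gene_id = pr$gene_id,
                            major = pr$major, stringsAsFactors = FALSE),
       tdf = data.frame(tdf_id = td$id, gene_id = td$gene_id,
                        major = td$major, stringsAsFactors = FALSE))
}

# Reconstruct the two call tables of a validation fixture from observed
# calls plus printed consistency flags. The gel-side calls are shown in the
# source material only as images, so the gel call is taken equal to the
# observed call on concordant rows and set to a differing placeholder major
# on discordant rows; rows with a missing observed call keep a placeholder
# gel call so they enter the denominator as inconsistent.
calls_from_flags <- function(ids, observed_major, flag) {
  rotate <- c(up = "down", down = "up", irregular = "up", unchanged = "up")
  gel <- ifelse(flag == "+", observed_major,
                ifelse(is.na(observed_major), "up",
                       unname(rotate[observed_major])))
  list(gel = data.frame(feature_id = ids, major = gel,
                        stringsAsFactors = FALSE),
       observed = data.frame(feature_id = ids[!is.na(observed_major)],
                             major = observed_major[!is.na(observed_major)],
                             stringsAsFactors = FALSE))
}

#' Pattern-call tables for the sqRT-PCR validation set
#'
#' Classifies the 80 sqRT-PCR trajectories (skipping no-band rows) and
#' reconstructs the cDNA-AFLP gel calls from the printed consistency flags,
#' yielding the two call tables whose \code{\link{score_consistency}}
#' reproduces the validation percentage.
#'
#' @param params \code{\link{classifier_params}} for the sqRT-PCR side.
#' @return List with \code{gel} and \code{observed} call tables.
#' @export
sq_validation_calls <- function(params = classifier_params()) {
  df <- load_sq_validation()
  major <- rep(NA_character_, nrow(df))
  for (i in seq_len(nrow(df))) {
    r <- as.numeric(df[i, paste0("r", 1:5)])
    if (all(is.finite(r)))
      major[i] <- classify_trajectory(r, params)$major
  }
  calls_from_flags(df$tdf_id, major, df$flag)
}

#' Pattern-call tables for the qRT-PCR validation set
#'
#' The qRT-PCR panel prints the gel-derived regulation model per TDF; the
#' PCR-side call is reconstructed from the printed flag (equal on
#' concordant rows, differing on discordant rows).
#'
#' @return List with \code{gel} and \code{observed} call tables.
#' @export
qpcr_validation_calls <- function() {
  df <- load_qpcr_validation()
  gel <- tolower(df$model)
  gel[gel == "irregular"] <- "irregular"
  rotate <- c(up = "down", down = "up", irregular = "up")
  observed <- ifelse(df$flag == "+", gel, unname(rotate[gel]))
  list(gel = data.frame(feature_id = df$tdf_id, major = gel,
                        stringsAsFactors = FALSE),
       observed = data.frame(feature_id = df$tdf_id, major = observed,
                             stringsAsFactors = FALSE))
}
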