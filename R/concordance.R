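#' Score pattern-call consistency between two platforms
#'
#' Pairs features by id across two pattern-call tables (e.g. cDNA-AFLP gel
#' calls vs sqRT-PCR calls) and flags each pair consistent when both calls
#' are present and the major regulation types agree. A feature present in
#' only one table (e.g. "No band" on the validation platform) still counts
#' in the denominator, as inconsistent. Subtypes are deliberately ignored:
#' cross-platform consistency is a coarse, type-level comparison.
#'
#' @param calls_a,calls_b Data frames: \code{feature_id, major}; an NA major
#'   is treated as a missing call.
#' @return List with \code{pairs} (data frame: \code{feature_id, major_a,
#'   major_b, consistent}), \code{n_consistent}, \code{n_pairs} and
#'   \code{percent} (half-up, 1 decimal).
#' @export
score_consistency <- function(calls_a, calls_b) {
  check_columns(calls_a, c("feature_id", "major"), "calls_a")
  check_columns(calls_b, c("feature_id", "major"), "calls_b")
  if (!length(intersect(calls_a$feature_id, calls_b$feature_id)))
    stop_tapseq("no shared feature ids between the two call tables")
  ids <- union(calls_a$feature_id, calls_b$feature_id)
  ma <- calls_a$major[match(ids, calls_a$feature_id)]
  mb <- calls_b$major[match(ids, calls_b$feature_id)]
  consistent <- !is.na(ma) & !is.na(mb) & ma == mb
  pairs <- data.frame(feature_id = ids, major_a = ma, major_b = mb,
                      consistent = consistent, stringsAsFactors = FALSE)
  list(pairs = pairs,
       n_consistent = sum(consistent),
       n_pairs = length(ids),
       percent = round_half_up(100 * sum(consistent) / length(ids), 1))
}

#' Transcript-protein overlap by shared gene identifier
#'
#' Joins differentially expressed protein spots to TDFs on an explicit gene
#' identifier and counts the counterpart pairs whose major regulation types
#' agree (direction agreement).
#'
#' @param protein_table Data frame: \code{spot_id, gene_id, major}.
#' @param tdf_table Data frame: \code{tdf_id, gene_id, major}.
#' @return List with \code{pairs} (data frame: \code{spot_id, tdf_id,
#'   gene_id, major_protein, major_tdf, agree}), \code{n_pairs} and
#'   \code{direction_agreement_count}. An empty join gives an empty report.
#' @export
transcript_protein_overlap <- function(protein_table, tdf_table) {
  check_columns(protein_table, c("spot_id", "gene_id", "major"), "protein table")
  check_columns(tdf_table, c("tdf_id", "gene_id", "major"), "TDF table")
  m <- merge(protein_table, tdf_table, by = "gene_id",
             suffixes = c("_protein", "_tdf"), sort = FALSE)
  pairs <- data.frame(spot_id = m$spot_id, tdf_id = m$tdf_id,
                      gene_id = m$gene_id,
                      major_protein = m$major_protein,
                      major_tdf = m$major_tdf,
                      agree = m$major_protein == m$major_tdf,
                      stringsAsFactors = FALSE)
  list(pairs = pairs, n_pairs = nrow(pairs),
       direction_agreement_count = sum(pairs$agree))
}
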