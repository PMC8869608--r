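#' Remove redundant TDF records
#'
#' TDFs that derive from the same transcript and share the same expression
#' pattern (major regulation type; subtype boundaries are tolerance-dependent
#' and are ignored) are clustered, and only the longest fragment of each
#' cluster is kept. Length ties are broken by the lexicographically smallest
#' \code{tdf_id}. Records without a transcript assignment pass through
#' unclustered.
#'
#' @param records Data frame: \code{tdf_id, transcript_id, major, length_bp}
#'   (\code{transcript_id} may be NA).
#' @return The non-redundant subset, input order preserved.
#' @export
#' @examples
#' recs <- data.frame(tdf_id = c("a", "b", "c"),
#'                    transcript_id = "T1", major = "up",
#'                    length_bp = c(120, 250, 180))
#' remove_redundancy(recs)  # keeps "b"
remove_redundancy <- function(records) {
  check_columns(records, c("tdf_id", "transcript_id", "major", "length_bp"),
                "TDF table")
  if (anyDuplicated(records$tdf_id))
    stop_tapseq("duplicate tdf_id in input")
  if (!nrow(records)) return(records)
  has_tr <- !is.na(records$transcript_id) & records$transcript_id != ""
  key <- ifelse(has_tr,
                paste(records$transcript_id, records$major, sep = "\r"),
                paste0("\r#singleton#", records$tdf_id))
  keep <- unlist(lapply(split(seq_len(nrow(records)), key), function(idx) {
    sub <- records[idx, ]
    best <- idx[order(-sub$length_bp, sub$tdf_id)][1]
    best
  }), use.names = FALSE)
  out <- records[sort(keep), ]
  rownames(out) <- NULL
  out
}

#' Default keyword lexicon for functional categorization
#'
#' Reads the editable keyword lexicon shipped with the package: a mapping
#' from each of the 11 functional categories of plant genes (with rubber
#' biosynthesis singled out of secondary metabolism) to lower-case keywords
#' matched against BLAST hit descriptions.
#'
#' @param path Optional path to an alternative lexicon JSON file
#'   (category -> character vector of keywords).
#' @return Named list of character vectors.
#' @export
default_lexicon <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "lexicon.json", package = "tapseq")
  lex <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(lex, tolower)
}

predicted_markers <- function() {
  c("predicted protein", "hypothetical protein", "uncharacterized",
    "unnamed protein", "unknown protein")
}

# category of one description under the lexicon (NA if no keyword matches)
lexicon_category <- function(description, lexicon) {
  d <- tolower(description)
  for (cat in names(lexicon)) {
    if (any(vapply(lexicon[[cat]], grepl, logical(1), x = d, fixed = TRUE)))
      return(cat)
  }
  NA_character_
}

#' Triage BLAST hits for one feature into an annotation bucket
#'
#' Hits must pass both thresholds (E-value < \code{e_max} and score >
#' \code{score_min}) to count. Buckets:
#' \itemize{
#'   \item \code{no_hit}: no hit passes the thresholds.
#'   \item \code{predicted}: the best passing hit (highest score, ties by
#'     lower E-value then description) is a predicted/hypothetical/
#'     uncharacterized protein.
#'   \item \code{unclassified}: passing hits map to two or more functional
#'     categories with no majority, or to none at all.
#'   \item \code{known}: otherwise; the majority category is assigned.
#' }
#'
#' @param feature_id Feature identifier.
#' @param hits Data frame (possibly empty): \code{description, e_value,
#'   score}.
#' @param lexicon Keyword lexicon, see \code{\link{default_lexicon}}.
#' @param e_max E-value threshold (exclusive). Default 1e-4.
#' @param score_min Score threshold (exclusive). Default 50.
#' @return One-row data frame: \code{feature_id, hit_description, e_value,
#'   score, bucket, category}.
#' @export
triage_annotation <- function(feature_id, hits, lexicon = default_lexicon(),
                              e_max = 1e-4, score_min = 50) {
  empty <- function(bucket, desc = NA_character_, e = NA_real_, s = NA_real_,
                    category = NA_character_) {
    data.frame(feature_id = feature_id, hit_description = desc, e_value = e,
               score = s, bucket = bucket, category = category,
               stringsAsFactors = FALSE)
  }
  if (is.null(hits) || !nrow(hits)) return(empty("no_hit"))
  check_columns(hits, c("description", "e_value", "score"), "hit table")
  ev <- suppressWarnings(as.numeric(hits$e_value))
  sc <- suppressWarnings(as.numeric(hits$score))
  if (any(is.na(ev)) || any(is.na(sc)))
    stop_tapseq(sprintf("feature '%s': malformed e_value/score", feature_id))
  pass <- ev < e_max & sc > score_min
  if (!any(pass)) return(empty("no_hit"))
  ph <- hits[pass, , drop = FALSE]
  ph$e_value <- ev[pass]; ph$score <- sc[pass]
  ph <- ph[order(-ph$score, ph$e_value, ph$description), , drop = FALSE]
  best <- ph[1, ]
  if (any(vapply(predicted_markers(), grepl, logical(1),
                 x = tolower(best$description), fixed = TRUE)))
    return(empty("predicted", best$description, best$e_value, best$score))
  cats <- vapply(ph$description, lexicon_category, character(1),
                 lexicon = lexicon)
  cats <- cats[!is.na(cats)]
  if (!length(cats))
    return(empty("unclassified", best$description, best$e_value, best$score))
  tab <- sort(table(cats), decreasing = TRUE)
  if (length(tab) >= 2 && tab[1] == tab[2])   # >= 2 categories, no majority
    return(empty("unclassified", best$description, best$e_value, best$score))
  empty("known", best$description, best$e_value, best$score,
        category = names(tab)[1])
}

#' Triage an annotation hit table for many features
#'
#' @param hits Data frame: \code{feature_id, description, e_value, score};
#'   features absent from the table get \code{no_hit}.
#' @param feature_ids Features to annotate (defaults to those in
#'   \code{hits}).
#' @inheritParams triage_annotation
#' @return Data frame of one \code{\link{triage_annotation}} row per feature.
#' @export
triage_table <- function(hits, feature_ids = unique(hits$feature_id),
                         lexicon = default_lexicon(),
                         e_max = 1e-4, score_min = 50) {
  check_columns(hits, c("feature_id", "description", "e_value", "score"),
                "hit table")
  out <- lapply(feature_ids, function(id)
    triage_annotation(id, hits[hits$feature_id == id, , drop = FALSE],
                      lexicon = lexicon, e_max = e_max, score_min = score_min))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cross-tabulate functional categories against regulation patterns
#'
#' Builds the category-by-pattern summary table of a differential screen:
#' one row per category with the feature count, its percentage of the total,
#' and the up/down/irregular split with within-row percentages, plus a
#' totals row. Percentages are rounded half-up to one decimal.
#'
#' @param calls A data frame of pattern calls (\code{feature_id, major}).
#' @param annotations Data frame with \code{feature_id} and \code{category}
#'   (the display category: a functional category, or a bucket label such as
#'   "Unclassified proteins", "Predicted proteins", "No hit sequence").
#' @param category_order Optional character vector fixing row order;
#'   defaults to first-appearance order.
#' @return Data frame of class \code{"tap_summary"}: \code{category, n,
#'   percent, up, up_pct, down, down_pct, irregular, irregular_pct}, last
#'   row \code{"Total"}.
#' @export
summarize_patterns <- function(calls, annotations, category_order = NULL) {
  check_columns(calls, c("feature_id", "major"), "pattern calls")
  check_columns(annotations, c("feature_id", "category"), "annotations")
  missing <- setdiff(calls$feature_id, annotations$feature_id)
  if (length(missing))
    stop_tapseq("feature(s) missing annotation: ",
                paste(utils::head(missing, 5), collapse = ", "))
  m <- merge(calls[, c("feature_id", "major")],
             annotations[, c("feature_id", "category")],
             by = "feature_id", sort = FALSE)
  if (is.null(category_order)) category_order <- unique(annotations$category)
  cat_f <- factor(m$category, levels = category_order)
  maj_f <- factor(m$major, levels = c("up", "down", "irregular"))
  tab <- table(cat_f, maj_f)
  n_cat <- as.integer(rowSums(tab))
  total <- sum(n_cat)
  pct <- function(num, den) {
    den <- rep_len(den, length(num))
    ifelse(den > 0, round_half_up(100 * num / ifelse(den > 0, den, 1), 1), 0)
  }
  out <- data.frame(category = category_order,
                    n = n_cat,
                    percent = pct(n_cat, total),
                    up = as.integer(tab[, "up"]),
                    up_pct = pct(as.integer(tab[, "up"]), n_cat),
                    down = as.integer(tab[, "down"]),
                    down_pct = pct(as.integer(tab[, "down"]), n_cat),
                    irregular = as.integer(tab[, "irregular"]),
                    irregular_pct = pct(as.integer(tab[, "irregular"]), n_cat),
                    stringsAsFactors = FALSE)
  totals <- data.frame(category = "Total", n = total,
                       percent = if (total > 0) 100.0 else 0,
                       up = sum(out$up), up_pct = pct(sum(out$up), total),
                       down = sum(out$down), down_pct = pct(sum(out$down), total),
                       irregular = sum(out$irregular),
                       irregular_pct = pct(sum(out$irregular), total),
                       stringsAsFactors = FALSE)
  res <- rbind(out, totals)
  rownames(res) <- NULL
  structure(res, class = c("tap_summary", "data.frame"))
}

#' @export
print.tap_summary <- function(x, ...) {
  cat("Functional category x regulation pattern summary\n")
  print.data.frame(x, row.names = FALSE, ...)
  invisible(x)
}

#' Fraction of features with a known functional annotation
#'
#' @param summary A \code{\link{summarize_patterns}} table.
#' @param known_categories Categories counted as "known function"; defaults
#'   to every row that is not a triage bucket or the totals row.
#' @return Percentage (half-up, 1 decimal) of the total in known categories.
#' @export
known_function_percent <- function(summary,
                                   known_categories = NULL) {
  buckets <- c("Unclassified proteins", "Predicted proteins",
               "No hit sequence", "Unknown proteins", "Total")
  if (is.null(known_categories))
    known_categories <- setdiff(summary$category, buckets)
  total <- summary$n[summary$category == "Total"]
  known <- sum(summary$n[summary$category %in% known_categories])
  round_half_up(100 * known / total, 1)
}
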