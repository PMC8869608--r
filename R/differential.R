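#' One-way ANOVA across the five tappings
#'
#' Fixed-effects one-way ANOVA of raw intensity over the tapping factor,
#' the across-tapping significance test used for transcript bands. Degenerate
#' inputs are resolved by the sum-of-squares limits: zero between- and
#' within-group variation gives p = 1; positive between- with zero
#' within-group variation gives p = 0.
#'
#' @param series Long data frame (\code{tapping}, \code{replicate},
#'   \code{value}) for one feature.
#' @return The ANOVA p-value.
#' @export
anova_across_tappings <- function(series) {
  check_columns(series, c("tapping", "value"), "intensity series")
  g <- factor(series$tapping)
  reps <- table(g)
  if (length(reps) < 2) stop_tapseq("need at least 2 tapping groups")
  if (any(reps < 2))
    stop_tapseq("need >= 2 replicates per tapping for ANOVA")
  x <- series$value
  gm <- tapply(x, g, mean)
  ssb <- sum(reps * (gm - mean(x))^2)
  ssw <- sum((x - gm[g])^2)
  tol <- 1e-12 * max(1, mean(x)^2)
  if (ssw <= tol) {
    return(if (ssb <= tol) 1 else 0)
  }
  stats::oneway.test(value ~ g, data = data.frame(value = x, g = g),
                     var.equal = TRUE)$p.value
}

#' Student's t-test of one tapping against the first
#'
#' Two-sample, two-sided, equal-variance t-test comparing replicate
#' intensities at the given tapping with tapping 1. Degenerate zero-variance
#' inputs follow the same limits as \code{\link{anova_across_tappings}}.
#'
#' @param series Long data frame (\code{tapping}, \code{replicate},
#'   \code{value}) for one feature.
#' @param tapping Tapping index in 2..5 to compare against tapping 1.
#' @return The t-test p-value.
#' @export
ttest_vs_first <- function(series, tapping) {
  check_columns(series, c("tapping", "value"), "intensity series")
  if (!tapping %in% 2:5) stop_tapseq("'tapping' must be in 2..5")
  x <- series$value[series$tapping == 1]
  y <- series$value[series$tapping == tapping]
  if (length(x) < 2 || length(y) < 2)
    stop_tapseq("need >= 2 replicates in both groups for a t-test")
  v <- stats::var(c(x - mean(x), y - mean(y)))
  if (v <= 1e-12 * max(1, mean(c(x, y))^2)) {
    return(if (abs(mean(x) - mean(y)) <= 1e-12 * max(1, abs(mean(x)))) 1 else 0)
  }
  stats::t.test(x, y, var.equal = TRUE)$p.value
}

#' Call a differentially expressed protein spot
#'
#' A spot is differentially expressed when its abundance changes at least
#' \code{fold}-fold between the first tapping and any other tapping
#' (\code{max(r, 1/r) >= fold}, so 3-fold up and 3-fold down are equivalent)
#' and that same tapping's Student's t-test against tapping 1 has p <=
#' \code{alpha}. Ties at exactly \code{alpha} count as significant.
#'
#' @param series Long data frame (\code{tapping}, \code{replicate},
#'   \code{value}) for one feature.
#' @param fold Fold-change threshold. Default 3.
#' @param alpha Significance level. Default 0.05.
#' @param feature_id Optional id copied into the result.
#' @return One-row data frame: \code{feature_id, is_de, max_abs_ratio,
#'   p_t_min}.
#' @export
call_de_protein <- function(series, fold = 3, alpha = 0.05,
                            feature_id = NA_character_) {
  r <- normalize_to_reference(series)
  ratio <- pmax(r[2:5], 1 / r[2:5])
  candidates <- which(ratio >= fold)
  p_at <- rep(NA_real_, 4)
  for (k in candidates) p_at[k] <- ttest_vs_first(series, tapping = k + 1)
  is_de <- length(candidates) > 0 && any(p_at[candidates] <= alpha)
  p_t_min <- if (length(candidates)) min(p_at[candidates]) else NA_real_
  data.frame(feature_id = feature_id, is_de = is_de,
             max_abs_ratio = max(ratio), p_t_min = p_t_min,
             stringsAsFactors = FALSE)
}

#' Call a differentially expressed transcript band
#'
#' Transcript bands were screened visually on gels; the computable surrogate
#' calls a band differentially expressed when the across-tapping ANOVA is
#' significant (p <= \code{alpha}) and the normalized trajectory excurses at
#' least \code{delta}-fold from the first tapping in either direction.
#'
#' @inheritParams call_de_protein
#' @param delta Excursion fold threshold, shared with the trajectory
#'   classifier. Default 1.25.
#' @return One-row data frame: \code{feature_id, is_de, max_abs_ratio,
#'   p_anova}.
#' @export
call_de_tdf <- function(series, alpha = 0.05, delta = 1.25,
                        feature_id = NA_character_) {
  r <- normalize_to_reference(series)
  ratio <- pmax(r[2:5], 1 / r[2:5])
  p <- anova_across_tappings(series)
  data.frame(feature_id = feature_id,
             is_de = p <= alpha && max(ratio) >= delta,
             max_abs_ratio = max(ratio), p_anova = p,
             stringsAsFactors = FALSE)
}

#' Differential-expression calls for a full intensity table
#'
#' Applies \code{\link{call_de_protein}} or \code{\link{call_de_tdf}} per
#' feature of a long intensity table.
#'
#' @param intensities Long data frame: \code{feature_id, tapping, replicate,
#'   value}.
#' @param mode \code{"protein"} (fold + t-test rule) or \code{"tdf"}
#'   (ANOVA + excursion rule).
#' @param fold Fold threshold for protein mode. Default 3.
#' @param alpha Significance level. Default 0.05.
#' @param delta Excursion threshold for tdf mode. Default 1.25.
#' @return Data frame of per-feature calls, input feature order preserved.
#' @export
call_de_table <- function(intensities, mode = c("protein", "tdf"),
                          fold = 3, alpha = 0.05, delta = 1.25) {
  mode <- match.arg(mode)
  check_columns(intensities, c("feature_id", "tapping", "replicate", "value"),
                "intensity table")
  ids <- unique(intensities$feature_id)
  rows <- lapply(ids, function(id) {
    s <- intensities[intensities$feature_id == id, ]
    if (mode == "protein") call_de_protein(s, fold, alpha, feature_id = id)
    else call_de_tdf(s, alpha, delta, feature_id = id)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
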