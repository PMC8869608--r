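#' Run the full tapping-series analysis pipeline on simulated data
#'
#' End-to-end run: simulate intensity and Ct tables, normalize and classify
#' trajectories, call differential expression, remove redundant TDFs,
#' summarize categories against patterns, quantify the qPCR table by
#' 2^-ddCt, and score concordance of the classified trajectories against the
#' qPCR-derived trajectories. A JSON manifest records every parameter and
#' per-stage record counts.
#'
#' @param config A \code{\link{sim_config}} describing the study to
#'   simulate.
#' @param params \code{\link{classifier_params}} for trajectory
#'   classification.
#' @param de_alpha Significance level for DE calling. Default 0.05.
#' @param out_dir Optional directory; when given, every stage table plus
#'   \code{manifest.json} is written there as TSV/JSON.
#' @return Object of class \code{"tap_pipeline"}: list with
#'   \code{intensities, truth, ct, patterns, de_calls, tdf_records,
#'   nonredundant, summary, rq, concordance, manifest}.
#' @export
run_pipeline <- function(config = sim_config(), params = classifier_params(),
                         de_alpha = 0.05, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  sim <- simulate_trajectories(config)
  ct <- simulate_qpcr(sim$truth, config)

  traj <- trajectories_from_intensities(sim$intensities)
  patterns <- classify_trajectories(traj, params)

  de <- call_de_table(sim$intensities, mode = "tdf",
                      alpha = de_alpha, delta = params$delta)

  tdf_records <- data.frame(tdf_id = patterns$feature_id,
                            transcript_id = sim$truth$transcript_id[
                              match(patterns$feature_id, sim$truth$feature_id)],
                            major = patterns$major,
                            length_bp = sim$truth$length_bp[
                              match(patterns$feature_id, sim$truth$feature_id)],
                            stringsAsFactors = FALSE)
  nonredundant <- remove_redundancy(tdf_records)

  display_cat <- ifelse(sim$truth$bucket == "known", sim$truth$category,
                        c(unclassified = "Unclassified proteins",
                          predicted = "Predicted proteins",
                          no_hit = "No hit sequence")[sim$truth$bucket])
  annotations <- data.frame(feature_id = sim$truth$feature_id,
                            category = display_cat, stringsAsFactors = FALSE)
  de_ids <- patterns$feature_id[patterns$major != "unchanged"]
  summary_tab <- summarize_patterns(
    patterns[patterns$feature_id %in% de_ids, c("feature_id", "major")],
    annotations)

  rq <- ddct(ct, calibrator = 1L)
  rq_traj <- rq_to_trajectories(rq)
  qpcr_patterns <- classify_trajectories(rq_traj, params)
  conc <- score_consistency(patterns[, c("feature_id", "major")],
                            qpcr_patterns[, c("feature_id", "major")])

  manifest <- list(
    parameters = list(
      n_features = config$n_features, n_replicates = config$n_replicates,
      subtype_mix = as.list(config$subtype_mix),
      effect_fold = config$effect_fold, noise_sd = config$noise_sd,
      redundancy_rate = config$redundancy_rate, seed = config$seed,
      delta = params$delta, eps_mono = params$eps_mono,
      eps_end = params$eps_end, de_alpha = de_alpha),
    counts = list(
      features = config$n_features,
      intensity_rows = nrow(sim$intensities),
      ct_rows = nrow(ct),
      pattern_calls = nrow(patterns),
      de_features = sum(de$is_de),
      tdf_records = nrow(tdf_records),
      nonredundant = nrow(nonredundant),
      concordance_pairs = conc$n_pairs),
    concordance_percent = conc$percent)

  res <- structure(list(intensities = sim$intensities, truth = sim$truth,
                        ct = ct, patterns = patterns, de_calls = de,
                        tdf_records = tdf_records, nonredundant = nonredundant,
                        summary = summary_tab, rq = rq, concordance = conc,
                        manifest = manifest),
                   class = "tap_pipeline")
  if (!is.null(out_dir)) write_pipeline(res, out_dir)
  res
}

#' Normalized trajectories from a long intensity table
#'
#' @param intensities Long data frame: \code{feature_id, tapping,
#'   replicate, value}.
#' @return Data frame: \code{feature_id, r1..r5}, one row per feature.
#' @export
trajectories_from_intensities <- function(intensities) {
  check_columns(intensities, c("feature_id", "tapping", "value"),
                "intensity table")
  ids <- unique(intensities$feature_id)
  rows <- lapply(ids, function(id) {
    r <- normalize_to_reference(intensities[intensities$feature_id == id, ])
    data.frame(feature_id = id, r1 = r[1], r2 = r[2], r3 = r[3], r4 = r[4],
               r5 = r[5], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# wide trajectories from a ddct() result (rq at calibrator is 1)
rq_to_trajectories <- function(rq) {
  ids <- unique(rq$feature_id)
  rows <- lapply(ids, function(id) {
    sub <- rq[rq$feature_id == id, ]
    sub <- sub[order(sub$tapping), ]
    r <- sub$rq / sub$rq[1]
    data.frame(feature_id = id, r1 = 1, r2 = r[2], r3 = r[3], r4 = r[4],
               r5 = r[5], stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

write_pipeline <- function(x, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(x$intensities, file.path(out_dir, "intensities.tsv"))
  write_tsv(x$truth, file.path(out_dir, "truth.tsv"))
  write_tsv(x$ct, file.path(out_dir, "ct.tsv"))
  write_tsv(as.data.frame(x$patterns), file.path(out_dir, "calls.tsv"))
  write_tsv(x$de_calls, file.path(out_dir, "decalls.tsv"))
  write_tsv(x$nonredundant, file.path(out_dir, "nonredundant.tsv"))
  write_tsv(as.data.frame(x$summary), file.path(out_dir, "summary.tsv"))
  write_tsv(x$rq, file.path(out_dir, "rq.tsv"))
  jsonlite::write_json(x$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.tap_pipeline <- function(x, ...) {
  cnt <- x$manifest$counts
  cat("Tapping-series pipeline run\n")
  cat(sprintf("  features: %d (non-redundant TDFs: %d, DE: %d)\n",
              cnt$features, cnt$nonredundant, cnt$de_features))
  cat(sprintf("  platform concordance: %.1f%% over %d pairs\n",
              x$concordance$percent, cnt$concordance_pairs))
  invisible(x)
}

#' @export
summary.tap_pipeline <- function(object, ...) {
  list(manifest = object$manifest,
       patterns = summary(object$patterns),
       summary_table = object$summary)
}
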