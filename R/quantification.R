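#' Relative quantification of qRT-PCR data by the 2^-ddCt method
#'
#' For each feature and replicate, \code{dCt = ct_target - ct_reference};
#' per tapping, \code{ddCt = mean(dCt) - mean(dCt at the calibrator)} and
#' \code{rq = 2^-ddCt} (the Livak method's standard per-group-mean form).
#' The spread is reported as the standard deviation of per-replicate
#' \code{rq} values (each replicate's dCt referenced to the calibrator
#' mean), matching "averages +/- STDEV of technical replicates" reporting.
#'
#' @param measurements Long data frame: \code{feature_id, tapping,
#'   replicate, ct_target, ct_reference}. Ct values must lie in (0, 50).
#' @param calibrator Calibrator tapping (default 1).
#' @return Data frame: \code{feature_id, tapping, rq, sd}; \code{rq == 1} at
#'   the calibrator tapping by construction.
#' @export
#' @examples
#' ct <- data.frame(feature_id = "f", tapping = rep(1:2, each = 2),
#'                  replicate = rep(1:2, 2),
#'                  ct_target = c(24, 24, 22, 22), ct_reference = 18)
#' ddct(ct)  # rq = 4 at tapping 2
ddct <- function(measurements, calibrator = 1L) {
  check_columns(measurements,
                c("feature_id", "tapping", "replicate", "ct_target",
                  "ct_reference"), "Ct table")
  ct <- c(measurements$ct_target, measurements$ct_reference)
  if (any(!is.finite(ct) | ct <= 0 | ct >= 50))
    stop_tapseq("Ct values must be finite and in (0, 50) cycles")
  if (any(is.na(measurements$ct_reference)))
    stop_tapseq("missing reference Ct")
  out <- lapply(split(measurements, measurements$feature_id), function(m) {
    if (!calibrator %in% m$tapping)
      stop_tapseq(sprintf("feature '%s': calibrator tapping %d absent",
                          m$feature_id[1], calibrator))
    dct <- m$ct_target - m$ct_reference
    cal_mean <- mean(dct[m$tapping == calibrator])
    taps <- sort(unique(m$tapping))
    rq <- vapply(taps, function(t)
      2^-(mean(dct[m$tapping == t]) - cal_mean), numeric(1))
    sdv <- vapply(taps, function(t) {
      rq_rep <- 2^-(dct[m$tapping == t] - cal_mean)
      if (length(rq_rep) > 1) stats::sd(rq_rep) else NA_real_
    }, numeric(1))
    data.frame(feature_id = m$feature_id[1], tapping = taps, rq = rq, sd = sdv,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Relative trajectories from semi-quantitative RT-PCR band intensities
#'
#' Target band intensities are first equalized by the reference-gene band
#' per tapping (template loading adjusted on a constitutive reference such
#' as 18S rRNA), then normalized to the first tapping, so the result has
#' \code{r1 = 1}.
#'
#' @param band_intensities Data frame: \code{feature_id, tapping,
#'   intensity}.
#' @param reference_intensities Data frame with the same tappings:
#'   \code{tapping, intensity} (one reference row per tapping; a
#'   \code{feature_id} column, if present, is ignored).
#' @return Data frame: \code{feature_id, r1..r5}.
#' @export
#' @examples
#' target <- data.frame(feature_id = "f", tapping = 1:5,
#'                      intensity = c(50, 55, 60, 65, 70))
#' ref <- data.frame(tapping = 1:5, intensity = 50)
#' sq_relative(target, ref)
sq_relative <- function(band_intensities, reference_intensities) {
  check_columns(band_intensities, c("feature_id", "tapping", "intensity"),
                "band intensities")
  check_columns(reference_intensities, c("tapping", "intensity"),
                "reference intensities")
  ref <- reference_intensities
  if (anyDuplicated(ref$tapping))
    stop_tapseq("reference table must have one row per tapping")
  if (any(!is.finite(ref$intensity) | ref$intensity <= 0))
    stop_tapseq("reference intensities must be positive")
  ref_val <- stats::setNames(ref$intensity, ref$tapping)
  out <- lapply(split(band_intensities, band_intensities$feature_id),
                function(b) {
    b <- b[order(b$tapping), ]
    if (!identical(as.integer(b$tapping), 1:5))
      stop_tapseq(sprintf("feature '%s': need exactly tappings 1..5",
                          b$feature_id[1]))
    if (any(!is.finite(b$intensity) | b$intensity <= 0))
      stop_tapseq(sprintf("feature '%s': intensities must be positive",
                          b$feature_id[1]))
    if (!all(as.character(1:5) %in% names(ref_val)))
      stop_tapseq("reference table must cover tappings 1..5")
    adj <- b$intensity / ref_val[as.character(1:5)]
    r <- as.numeric(adj / adj[1])
    r[1] <- 1
    data.frame(feature_id = b$feature_id[1],
               r1 = r[1], r2 = r[2], r3 = r[3], r4 = r[4], r5 = r[5],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
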