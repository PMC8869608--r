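#' Classifier parameters for tapping trajectories
#'
#' Tolerances used when assigning a five-tapping trajectory to a regulation
#' type and subtype. The underlying gel read-outs carry no printed numeric
#' thresholds, so all three are exposed as tunable parameters.
#'
#' @param delta Excursion fold-threshold (unitless, > 1). A trajectory is
#'   considered to excurse upward when \code{max(r) >= delta} and downward
#'   when \code{min(r) <= 1/delta}. Default 1.25.
#' @param eps_mono Relative tolerance for monotonicity / plateau decisions on
#'   consecutive tapping-to-tapping changes (0 <= eps_mono < 1). Default 0.15.
#' @param eps_end Relative tolerance for comparing the final relative
#'   abundance \code{r5} against the baseline 1 (0 <= eps_end < 1).
#'   Default 0.05.
#' @return A list of class \code{"classifier_params"}.
#' @export
#' @examples
#' classifier_params(delta = 1.5)
classifier_params <- function(delta = 1.25, eps_mono = 0.15, eps_end = 0.05) {
  if (!is.numeric(delta) || length(delta) != 1 || !is.finite(delta) || delta <= 1)
    stop_tapseq("'delta' must be a single finite number > 1")
  if (!is.numeric(eps_mono) || length(eps_mono) != 1 || eps_mono < 0 || eps_mono >= 1)
    stop_tapseq("'eps_mono' must be in [0, 1)")
  if (!is.numeric(eps_end) || length(eps_end) != 1 || eps_end < 0 || eps_end >= 1)
    stop_tapseq("'eps_end' must be in [0, 1)")
  structure(list(delta = delta, eps_mono = eps_mono, eps_end = eps_end),
            class = "classifier_params")
}

#' Normalize a five-tapping intensity series to the first tapping
#'
#' Replicate values are averaged per tapping (arithmetic mean, matching
#' single-lane gel quantification) and the tapping means are divided by the
#' first-tapping mean, so the returned trajectory has \code{r[1] == 1}
#' exactly.
#'
#' @param series Data frame with columns \code{tapping} (integer 1..5),
#'   \code{replicate} and \code{value} (positive raw intensity), for one
#'   feature. A plain numeric vector of 5 tapping means is also accepted.
#' @return Numeric vector of length 5 of relative abundances, \code{r[1] = 1}.
#' @export
#' @examples
#' normalize_to_reference(c(200, 288, 582, 684, 762))
normalize_to_reference <- function(series) {
  means <- tapping_means(series)
  if (!is.finite(means[1]) || means[1] <= 0)
    stop_tapseq("tapping-1 mean must be positive to serve as the reference")
  if (any(!is.finite(means) | means <= 0))
    stop_tapseq("all tapping means must be positive")
  r <- means / means[1]
  r[1] <- 1
  r
}

# Per-tapping replicate means for one feature; accepts a length-5 numeric
# vector of means or a long data frame (tapping, value).
tapping_means <- function(series, n_tappings = 5L) {
  if (is.numeric(series)) {
    if (length(series) != n_tappings)
      stop_tapseq(sprintf("expected %d tapping values", n_tappings))
    return(as.numeric(series))
  }
  check_columns(series, c("tapping", "value"), "intensity series")
  tap <- as.integer(series$tapping)
  if (!all(tap %in% seq_len(n_tappings)))
    stop_tapseq(sprintf("tapping indices must be in 1..%d", n_tappings))
  if (!all(seq_len(n_tappings) %in% tap))
    stop_tapseq("every tapping 1..5 must be present")
  as.numeric(tapply(series$value, factor(tap, levels = seq_len(n_tappings)), mean))
}

#' Classify a normalized trajectory into regulation type and subtype
#'
#' Trajectories relative to the first tapping fall into three regulation
#' types, each with printed subtypes, plus "unchanged":
#' \itemize{
#'   \item up: 1 rises successively; 2 rises then stabilizes; 3 rises then
#'     declines but stays above the first tapping; 0 other up-shapes.
#'   \item down: the mirrored subtypes on the reciprocal trajectory.
#'   \item irregular: 1 rises past a high threshold then ends below the first
#'     tapping; 2 the mirror image.
#'   \item unchanged: no excursion beyond \code{delta} in either direction.
#' }
#'
#' The decision procedure: with \code{hi = max(r)}, \code{lo = min(r)}, an
#' up-excursion is \code{hi >= delta} and a down-excursion \code{lo <=
#' 1/delta}. Neither excursion gives "unchanged". A single excursion whose
#' endpoint has returned across the baseline (more than a factor
#' \code{1 + eps_end} on the opposite side, so the test is symmetric under
#' reciprocals) is irregular; otherwise the excursion's direction is the
#' major type. Both
#' excursions give irregular, subtype by whether the maximum precedes the
#' minimum. Subtypes within up: consecutive ratios within \code{eps_mono}
#' count as flat; a series with no falling step that ends at its maximum is
#' subtype 1 when still rising at the last step and subtype 2 when it ends on
#' a plateau; an interior maximum with a discounted endpoint is subtype 3;
#' anything else is subtype 0 (major type clear, shape not one of the three
#' idealized ones). Down subtypes are computed on \code{1/r}.
#'
#' @param r Numeric trajectory of length 5 with \code{r[1] == 1}.
#' @param params A \code{\link{classifier_params}} object.
#' @return A list with elements \code{major} (one of \code{"up"},
#'   \code{"down"}, \code{"irregular"}, \code{"unchanged"}) and
#'   \code{subtype} (integer; 0-3 for up/down, 1-2 for irregular, NA for
#'   unchanged).
#' @export
#' @examples
#' classify_trajectory(c(1, 1.44, 2.91, 3.42, 3.81))  # up, subtype 1
#' classify_trajectory(c(1, 0.78, 0.48, 0.40, 0.20))  # down, subtype 1
classify_trajectory <- function(r, params = classifier_params()) {
  r <- as.numeric(r)
  if (length(r) != 5 || any(!is.finite(r)) || any(r <= 0))
    stop_tapseq("trajectory must be 5 finite positive values")
  if (abs(r[1] - 1) > 1e-8)
    stop_tapseq("trajectory must be normalized to the first tapping (r[1] = 1)")
  delta <- params$delta; eps_end <- params$eps_end
  hi <- max(r); lo <- min(r)
  up_exc <- hi >= delta
  down_exc <- lo <= 1 / delta
  r5 <- r[5]

  if (!up_exc && !down_exc)
    return(list(major = "unchanged", subtype = NA_integer_))

  if (up_exc && down_exc) {
    sub <- if (which.max(r) < which.min(r)) 1L else 2L
    return(list(major = "irregular", subtype = sub))
  }

  if (up_exc) {
    if (r5 * (1 + eps_end) < 1)                 # returned below baseline
      return(list(major = "irregular", subtype = 1L))
    return(list(major = "up", subtype = up_subtype(r, params$eps_mono)))
  }

  # down-excursion only
  if (r5 > 1 + eps_end)                         # returned above baseline
    return(list(major = "irregular", subtype = 2L))
  list(major = "down", subtype = up_subtype(1 / r, params$eps_mono))
}

# Subtype within the up type; down subtypes reuse this on the reciprocal.
up_subtype <- function(r, eps_mono) {
  q <- r[-1] / r[-5]                  # consecutive ratios, steps 1..4
  hi <- max(r)
  no_down_step <- all(q >= 1 - eps_mono)
  ends_at_max <- r[5] >= hi * (1 - eps_mono)
  if (no_down_step && ends_at_max) {
    # still rising at the end -> successive increase; else rise-then-plateau
    return(if (r[5] > r[4]) 1L else 2L)
  }
  if (which.max(r) < 5 && r[5] < hi * (1 - eps_mono)) return(3L)
  0L
}

#' Classify many trajectories
#'
#' Row-wise application of \code{\link{classify_trajectory}} over a table of
#' trajectories, preserving input order.
#'
#' @param trajectories Data frame with columns \code{feature_id},
#'   \code{r1}..\code{r5}, or a named list / matrix of length-5 trajectories.
#' @param params A \code{\link{classifier_params}} object.
#' @return A data frame of class \code{"tap_patterns"} with columns
#'   \code{feature_id}, \code{major}, \code{subtype}, \code{r1}..\code{r5};
#'   classifier parameters attached as attribute \code{"params"}.
#' @export
classify_trajectories <- function(trajectories, params = classifier_params()) {
  tr <- as_trajectory_table(trajectories)
  n <- nrow(tr)
  major <- character(n); subtype <- rep(NA_integer_, n)
  rmat <- as.matrix(tr[, c("r1", "r2", "r3", "r4", "r5")])
  for (i in seq_len(n)) {
    call <- tryCatch(classify_trajectory(rmat[i, ], params),
                     error = function(e) stop_tapseq(sprintf(
                       "feature '%s': %s", tr$feature_id[i], conditionMessage(e))))
    major[i] <- call$major
    subtype[i] <- call$subtype
  }
  out <- data.frame(feature_id = tr$feature_id, major = major,
                    subtype = subtype, stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(rmat))
  structure(out, params = params, class = c("tap_patterns", "data.frame"))
}

as_trajectory_table <- function(x) {
  if (is.matrix(x)) {
    x <- data.frame(feature_id = rownames(x) %||% as.character(seq_len(nrow(x))),
                    r1 = x[, 1], r2 = x[, 2], r3 = x[, 3], r4 = x[, 4], r5 = x[, 5],
                    stringsAsFactors = FALSE)
  }
  if (!is.data.frame(x)) stop_tapseq("expected a data frame or matrix of trajectories")
  check_columns(x, c("feature_id", paste0("r", 1:5)), "trajectory table")
  x
}

#' @export
print.tap_patterns <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("Tapping-trajectory pattern calls: %d feature(s)\n", nrow(x)))
  if (!is.null(p))
    cat(sprintf("  delta = %g, eps_mono = %g, eps_end = %g\n",
                p$delta, p$eps_mono, p$eps_end))
  if (nrow(x)) {
    tab <- table(factor(x$major, levels = c("up", "down", "irregular", "unchanged")))
    cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.tap_patterns <- function(object, ...) {
  tab <- table(major = factor(object$major,
                              levels = c("up", "down", "irregular", "unchanged")),
               subtype = factor(object$subtype, levels = 0:3, exclude = NULL))
  structure(list(n = nrow(object), counts = tab,
                 params = attr(object, "params")),
            class = "summary.tap_patterns")
}

#' @export
print.summary.tap_patterns <- function(x, ...) {
  cat(sprintf("Pattern calls for %d feature(s)\n", x$n))
  print(x$counts)
  invisible(x)
}

#' @export
plot.tap_patterns <- function(x, max_per_class = 25, ...) {
  classes <- c("up", "down", "irregular", "unchanged")
  present <- classes[classes %in% x$major]
  if (!length(present)) return(invisible(x))
  old <- graphics::par(mfrow = c(1, length(present)))
  on.exit(graphics::par(old))
  rmat <- t(as.matrix(x[, paste0("r", 1:5)]))
  for (cl in present) {
    idx <- which(x$major == cl)
    if (length(idx) > max_per_class) idx <- idx[seq_len(max_per_class)]
    graphics::matplot(1:5, rmat[, idx, drop = FALSE], type = "l", lty = 1,
                      log = "y", xlab = "tapping", ylab = "relative abundance",
                      main = cl, ...)
    graphics::abline(h = 1, lty = 3)
  }
  invisible(x)
}
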