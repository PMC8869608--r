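#' Simulation configuration for tapping-series data
#'
#' Bundles the parameters of the synthetic-data generator that emulates
#' five-tapping abundance trajectories (cDNA-AFLP band densitometry / 2-DE
#' spot volumes) and qRT-PCR Ct tables.
#'
#' @param n_features Number of features (TDF bands or protein spots).
#' @param n_replicates Biological replicates per tapping. Default 3,
#'   matching the three biological replicates used per tapping in the assays
#'   this generator emulates.
#' @param subtype_mix Named probability vector over the eight subtypes plus
#'   \code{"unchanged"}: names \code{up1, up2, up3, down1, down2, down3,
#'   irr1, irr2, unchanged}. Must sum to 1. The default splits 43.0\% up,
#'   35.6\% down and 21.4\% irregular evenly within each type, with no
#'   unchanged features (the mix of a differential-expression screen).
#' @param effect_fold Multiplicative effect size f (> 1) reached by the
#'   shape templates. Default 3, the fold-change scale at which the assays
#'   call differential abundance.
#' @param noise_sd Standard deviation of lognormal abundance noise on the
#'   log scale (and, for qPCR, of Ct noise in cycles). Default 0.2.
#' @param redundancy_rate Expected TDFs per transcript (>= 1). Default
#'   651/505, the redundancy of the screen this generator emulates.
#' @param seed Integer master seed; child streams are derived per table.
#' @return A list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_features = 500L,
                       n_replicates = 3L,
                       subtype_mix = NULL,
                       effect_fold = 3,
                       noise_sd = 0.2,
                       redundancy_rate = 651 / 505,
                       seed = 1L) {
  if (is.null(subtype_mix)) {
    subtype_mix <- c(up1 = 0.430 / 3, up2 = 0.430 / 3, up3 = 0.430 / 3,
                     down1 = 0.356 / 3, down2 = 0.356 / 3, down3 = 0.356 / 3,
                     irr1 = 0.214 / 2, irr2 = 0.214 / 2, unchanged = 0)
  }
  nm <- c("up1", "up2", "up3", "down1", "down2", "down3", "irr1", "irr2", "unchanged")
  if (!all(nm %in% names(subtype_mix)))
    stop_tapseq("subtype_mix must be named over: ", paste(nm, collapse = ", "))
  subtype_mix <- subtype_mix[nm]
  if (abs(sum(subtype_mix) - 1) > 1e-9)
    stop_tapseq("subtype_mix must sum to 1")
  if (any(subtype_mix < 0)) stop_tapseq("subtype_mix entries must be >= 0")
  if (!is.numeric(effect_fold) || effect_fold <= 1)
    stop_tapseq("effect_fold must be > 1")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop_tapseq("noise_sd must be >= 0")
  if (redundancy_rate < 1) stop_tapseq("redundancy_rate must be >= 1")
  n_features <- as.integer(n_features)
  if (n_features < 0) stop_tapseq("n_features must be >= 0")
  structure(list(n_features = n_features, n_tappings = 5L,
                 n_replicates = as.integer(n_replicates),
                 subtype_mix = subtype_mix, effect_fold = effect_fold,
                 noise_sd = noise_sd, redundancy_rate = redundancy_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

subtype_levels <- function() {
  c("up1", "up2", "up3", "down1", "down2", "down3", "irr1", "irr2", "unchanged")
}

subtype_major <- function(subtype) {
  map <- c(up1 = "up", up2 = "up", up3 = "up",
           down1 = "down", down2 = "down", down3 = "down",
           irr1 = "irregular", irr2 = "irregular", unchanged = "unchanged")
  unname(map[subtype])
}

subtype_code <- function(subtype) {
  code <- c(up1 = 1L, up2 = 2L, up3 = 3L, down1 = 1L, down2 = 2L, down3 = 3L,
            irr1 = 1L, irr2 = 2L, unchanged = NA_integer_)
  unname(code[subtype])
}

#' Shape template for a subtype
#'
#' Deterministic five-tapping abundance shape \code{s(t)} for each subtype,
#' anchored at \code{s(1) = 1}:
#' \itemize{
#'  \item up1: geometric rise to \code{f} at tapping 5.
#'  \item up2: rise to \code{f} by tapping 3, then constant.
#'  \item up3: peak \code{f} at tapping 3, then decline to \code{sqrt(f)}
#'    (still above baseline).
#'  \item down1/2/3: element-wise reciprocals of up1/2/3.
#'  \item irr1: peak \code{f} at tapping 3 then fall to \code{1/sqrt(f)}
#'    (below baseline); irr2 its reciprocal.
#'  \item unchanged: constant 1.
#' }
#'
#' @param subtype One of the subtype codes (see \code{\link{sim_config}}).
#' @param f Effect fold (> 1).
#' @return Numeric vector of length 5.
#' @export
#' @examples
#' shape_template("up1", f = 2)
shape_template <- function(subtype, f = 3) {
  stopifnot(f > 1)
  s <- switch(subtype,
    up1 = f^((0:4) / 4),
    up2 = c(1, sqrt(f), f, f, f),
    up3 = c(1, sqrt(f), f, f^0.75, sqrt(f)),
    down1 = 1 / f^((0:4) / 4),
    down2 = 1 / c(1, sqrt(f), f, f, f),
    down3 = 1 / c(1, sqrt(f), f, f^0.75, sqrt(f)),
    irr1 = c(1, sqrt(f), f, 1, 1 / sqrt(f)),
    irr2 = 1 / c(1, sqrt(f), f, 1, 1 / sqrt(f)),
    unchanged = rep(1, 5),
    stop_tapseq("unknown subtype: ", subtype))
  s
}

# Derive a reproducible child seed (< 2^31) from the master seed.
child_seed <- function(seed, stream) {
  (as.numeric(seed) * 101 + stream * 9973) %% 2147483647
}

#' Simulate five-tapping intensity trajectories
#'
#' Draws a subtype for each feature, builds its shape template and emits raw
#' abundance \code{mu * s(t) * exp(noise_sd * Z)} per replicate, where
#' \code{Z} is standard normal (multiplicative lognormal noise: densitometry
#' values are positive and right-skewed). Features are grouped into
#' transcripts according to \code{redundancy_rate}; TDFs of one transcript
#' share the transcript's regulation type but draw subtype-within-type and
#' fragment lengths independently. Each feature also receives an annotation
#' bucket and, for the "known" bucket, a functional category (drawn from the
#' category frequencies of the latex screen this generator emulates).
#'
#' @param config A \code{\link{sim_config}}.
#' @return List with elements \code{intensities} (long data frame:
#'   \code{feature_id, tapping, replicate, value}) and \code{truth}
#'   (\code{feature_id, true_type, true_subtype, subtype_label,
#'   transcript_id, length_bp, bucket, category}).
#' @export
simulate_trajectories <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_features
  set.seed(child_seed(config$seed, 1L))

  # transcripts first: each carries a major type; features inherit it
  n_transcripts <- max(1L, as.integer(round(n / config$redundancy_rate)))
  if (n == 0) n_transcripts <- 0L
  mix <- config$subtype_mix
  type_prob <- c(up = sum(mix[c("up1", "up2", "up3")]),
                 down = sum(mix[c("down1", "down2", "down3")]),
                 irregular = sum(mix[c("irr1", "irr2")]),
                 unchanged = mix[["unchanged"]])
  tr_type <- if (n_transcripts)
    sample(names(type_prob), n_transcripts, replace = TRUE, prob = type_prob)
  else character(0)

  # every transcript gets at least one TDF; extras are spread at random
  feat_transcript <- if (n > 0) {
    extra <- n - n_transcripts
    idx <- c(seq_len(n_transcripts),
             if (extra > 0) sample.int(n_transcripts, extra, replace = TRUE))
    sample(idx)   # shuffle so redundancy is not positional
  } else integer(0)

  # subtype within the transcript's type, drawn per feature
  subtype <- vapply(feat_transcript, function(tr) {
    ty <- tr_type[tr]
    subs <- switch(ty,
                   up = c("up1", "up2", "up3"),
                   down = c("down1", "down2", "down3"),
                   irregular = c("irr1", "irr2"),
                   unchanged = "unchanged")
    p <- mix[subs]
    if (sum(p) <= 0) p <- rep(1, length(subs))
    sample(subs, 1L, prob = p)
  }, character(1))

  feature_id <- sprintf("F%04d", seq_len(n))
  transcript_id <- sprintf("T%04d", feat_transcript)
  length_bp <- if (n) sample(100:800, n, replace = TRUE) else integer(0)

  bucket_prob <- c(known = 366, unclassified = 30, predicted = 59, no_hit = 50) / 505
  bucket <- if (n) sample(names(bucket_prob), n, replace = TRUE, prob = bucket_prob)
            else character(0)
  cats <- table1_known_categories()
  category <- rep(NA_character_, n)
  is_known <- bucket == "known"
  if (any(is_known))
    category[is_known] <- sample(cats$category, sum(is_known), replace = TRUE,
                                 prob = cats$weight)

  truth <- data.frame(feature_id = feature_id,
                      true_type = subtype_major(subtype),
                      true_subtype = subtype_code(subtype),
                      subtype_label = subtype,
                      transcript_id = transcript_id,
                      length_bp = length_bp,
                      bucket = bucket,
                      category = category,
                      stringsAsFactors = FALSE)

  set.seed(child_seed(config$seed, 2L))
  nt <- config$n_tappings; nr <- config$n_replicates
  mu <- exp(stats::rnorm(n, mean = log(100), sd = 0.5))
  grid <- expand.grid(replicate = seq_len(nr), tapping = seq_len(nt),
                      fi = seq_len(n))
  s_mat <- vapply(subtype, shape_template, numeric(5), f = config$effect_fold)
  value <- mu[grid$fi] * s_mat[cbind(grid$tapping, grid$fi)] *
    exp(config$noise_sd * stats::rnorm(nrow(grid)))
  intensities <- data.frame(feature_id = feature_id[grid$fi],
                            tapping = grid$tapping,
                            replicate = grid$replicate,
                            value = value,
                            stringsAsFactors = FALSE)
  intensities <- intensities[order(intensities$feature_id, intensities$tapping,
                                   intensities$replicate), ]
  rownames(intensities) <- NULL
  list(intensities = intensities, truth = truth)
}

# category frequencies among known-function features of the latex screen
# (11 functional categories; weights are the screen's category counts)
table1_known_categories <- function() {
  data.frame(
    category = c("Primary metabolism", "Energy", "Cell growth and division",
                 "Transcription and protein synthesis",
                 "Protein degradation and storage",
                 "Transporters and intracellular transport",
                 "Cellular structure", "Signal transduction",
                 "Stress and defense", "Secondary metabolism",
                 "Rubber biosynthesis"),
    weight = c(30, 20, 19, 96, 34, 45, 13, 42, 46, 11, 10),
    stringsAsFactors = FALSE)
}

#' Simulate a qRT-PCR Ct table from a truth table
#'
#' Target-gene Ct decreases by one cycle per doubling of template abundance:
#' \code{ct_target = c0 - log2(s(t)) + e}, with the reference gene constant
#' in expectation across tappings (a stable internal-standard gene), and
#' independent normal noise of \code{config$noise_sd} cycles on every Ct.
#'
#' @param truth Truth table from \code{\link{simulate_trajectories}}.
#' @param config A \code{\link{sim_config}}.
#' @param c0 Baseline target Ct at tapping 1 (cycles). Default 24.
#' @param c_ref Reference-gene Ct (cycles). Default 18.
#' @return Long data frame: \code{feature_id, tapping, replicate, ct_target,
#'   ct_reference}.
#' @export
simulate_qpcr <- function(truth, config = sim_config(), c0 = 24, c_ref = 18) {
  stopifnot(inherits(config, "sim_config"))
  check_columns(truth, c("feature_id", "subtype_label"), "truth table")
  set.seed(child_seed(config$seed, 3L))
  nt <- config$n_tappings; nr <- config$n_replicates
  n <- nrow(truth)
  grid <- expand.grid(replicate = seq_len(nr), tapping = seq_len(nt),
                      fi = seq_len(n))
  s_mat <- vapply(truth$subtype_label, shape_template, numeric(5),
                  f = config$effect_fold)
  ct_target <- c0 - log2(s_mat[cbind(grid$tapping, grid$fi)]) +
    stats::rnorm(nrow(grid), sd = config$noise_sd)
  ct_reference <- c_ref + stats::rnorm(nrow(grid), sd = config$noise_sd)
  out <- data.frame(feature_id = truth$feature_id[grid$fi],
                    tapping = grid$tapping, replicate = grid$replicate,
                    ct_target = ct_target, ct_reference = ct_reference,
                    stringsAsFactors = FALSE)
  out <- out[order(out$feature_id, out$tapping, out$replicate), ]
  rownames(out) <- NULL
  out
}

#' Simulate redundant TDF records with a fixed non-redundant target
#'
#' Builds a TDF table whose redundancy structure collapses to exactly
#' \code{n_unique} records under \code{\link{remove_redundancy}}: each of the
#' \code{n_unique} (transcript, major-type) groups gets one TDF, and the
#' remaining \code{n_tdfs - n_unique} TDFs are duplicated into randomly
#' chosen groups with independent lengths.
#'
#' @param n_tdfs Total TDF records (e.g. 651 cloned fragments).
#' @param n_unique Non-redundant groups (e.g. 505).
#' @param seed Integer seed.
#' @return Data frame: \code{tdf_id, transcript_id, major, length_bp}.
#' @export
simulate_tdf_records <- function(n_tdfs = 651L, n_unique = 505L, seed = 1L) {
  n_tdfs <- as.integer(n_tdfs); n_unique <- as.integer(n_unique)
  if (n_unique > n_tdfs) stop_tapseq("n_unique cannot exceed n_tdfs")
  set.seed(child_seed(seed, 4L))
  majors <- sample(c("up", "down", "irregular"), n_unique, replace = TRUE,
                   prob = c(217, 180, 108))
  group <- c(seq_len(n_unique),
             sample.int(n_unique, n_tdfs - n_unique, replace = TRUE))
  data.frame(tdf_id = sprintf("TDF%04d", seq_len(n_tdfs)),
             transcript_id = sprintf("T%04d", group),
             major = majors[group],
             length_bp = sample(100:800, n_tdfs, replace = TRUE),
             stringsAsFactors = FALSE)
}

#' Write synthetic TDF sequences as FASTA
#'
#' Random nucleotide sequences with the lengths recorded in the truth table,
#' for exercising sequence-facing tooling; no biological signal.
#'
#' @param truth Truth table with \code{feature_id} and \code{length_bp}.
#' @param path Output FASTA path.
#' @param seed Integer seed.
#' @return The path, invisibly.
#' @export
write_tdf_fasta <- function(truth, path, seed = 1L) {
  check_columns(truth, c("feature_id", "length_bp"), "truth table")
  set.seed(child_seed(seed, 5L))
  seqs <- lapply(truth$length_bp, function(L)
    sample(c("a", "c", "g", "t"), L, replace = TRUE))
  seqinr::write.fasta(seqs, names = truth$feature_id, file.out = path)
  invisible(path)
}
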