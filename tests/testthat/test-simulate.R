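test_that("config validation rejects impossible parameters", {
  expect_error(sim_config(effect_fold = 1), "effect_fold")
  expect_error(sim_config(noise_sd = -0.1), "noise_sd")
  expect_error(sim_config(redundancy_rate = 0.5), "redundancy_rate")
  bad_mix <- c(up1 = 0.5, up2 = 0.5, up3 = 0.5, down1 = 0, down2 = 0,
               down3 = 0, irr1 = 0, irr2 = 0, unchanged = 0)
  expect_error(sim_config(subtype_mix = bad_mix), "sum to 1")
})

test_that("zero-noise trajectories reproduce their shape templates exactly", {
  mix <- c(up1 = 1, up2 = 0, up3 = 0, down1 = 0, down2 = 0, down3 = 0,
           irr1 = 0, irr2 = 0, unchanged = 0)
  cfg <- sim_config(n_features = 8, noise_sd = 0, effect_fold = 2,
                    subtype_mix = mix, seed = 3)
  sim <- simulate_trajectories(cfg)
  traj <- trajectories_from_intensities(sim$intensities)
  for (i in seq_len(nrow(traj))) {
    expect_equal(as.numeric(traj[i, paste0("r", 1:5)]),
                 shape_template("up1", 2), tolerance = 1e-12)
  }
  # unchanged features have equal tapping means
  cfg_u <- sim_config(n_features = 4, noise_sd = 0,
                      subtype_mix = c(up1 = 0, up2 = 0, up3 = 0, down1 = 0,
                                      down2 = 0, down3 = 0, irr1 = 0,
                                      irr2 = 0, unchanged = 1), seed = 3)
  tr_u <- trajectories_from_intensities(simulate_trajectories(cfg_u)$intensities)
  expect_true(all(abs(as.matrix(tr_u[, paste0("r", 1:5)]) - 1) < 1e-12))
})

test_that("simulated intensities are positive and ids match the truth table", {
  cfg <- sim_config(n_features = 60, seed = 5)
  sim <- simulate_trajectories(cfg)
  expect_true(all(sim$intensities$value > 0))
  expect_setequal(unique(sim$intensities$feature_id), sim$truth$feature_id)
  expect_identical(nrow(sim$intensities), 60L * 5L * 3L)
  expect_true(all(sim$truth$length_bp >= 100))
  expect_true(all((sim$truth$bucket == "known") == !is.na(sim$truth$category)))
  # redundancy: features of one transcript share the true major type
  split_types <- tapply(sim$truth$true_type, sim$truth$transcript_id,
                        function(x) length(unique(x)))
  expect_true(all(split_types == 1))
})

test_that("identical seeds give bit-identical tables, different seeds differ", {
  cfg <- sim_config(n_features = 30, seed = 9)
  a <- simulate_trajectories(cfg)
  b <- simulate_trajectories(cfg)
  expect_identical(a, b)
  expect_identical(simulate_qpcr(a$truth, cfg), simulate_qpcr(b$truth, cfg))
  c_ <- simulate_trajectories(sim_config(n_features = 30, seed = 10))
  expect_false(identical(a$intensities$value, c_$intensities$value))
})

test_that("mean final relative abundance converges to the template value", {
  # with sigma = 0.1 the lognormal-mean correction exp(sigma^2/2) is ~0.5%,
  # well inside the Monte-Carlo band used here
  cfg <- sim_config(n_features = 1000, noise_sd = 0.1, effect_fold = 2,
                    seed = 1)
  sim <- simulate_trajectories(cfg)
  traj <- trajectories_from_intensities(sim$intensities)
  r5 <- traj$r5[match(sim$truth$feature_id, traj$feature_id)]
  for (st in unique(sim$truth$subtype_label)) {
    idx <- sim$truth$subtype_label == st
    if (sum(idx) < 30) next
    s5 <- shape_template(st, 2)[5]
    expect_equal(mean(r5[idx]), s5 * exp(0.1^2 / 2), tolerance = 0.05,
                 label = sprintf("mean r5 for %s", st))
  }
})

test_that("qPCR simulation encodes the template in Ct space", {
  mix <- c(up1 = 0, up2 = 1, up3 = 0, down1 = 0, down2 = 0, down3 = 0,
           irr1 = 0, irr2 = 0, unchanged = 0)
  cfg <- sim_config(n_features = 3, noise_sd = 0, effect_fold = 4,
                    subtype_mix = mix, seed = 2)
  sim <- simulate_trajectories(cfg)
  ct <- simulate_qpcr(sim$truth, cfg)
  one <- ct[ct$feature_id == sim$truth$feature_id[1] & ct$replicate == 1, ]
  one <- one[order(one$tapping), ]
  # s = (1, 2, 4, 4, 4) at f = 4: Ct drops by log2(s)
  expect_equal(one$ct_target, 24 - log2(c(1, 2, 4, 4, 4)))
  expect_equal(one$ct_reference, rep(18, 5))
  # unchanged features give identical Ct at all tappings
  cfg_u <- sim_config(n_features = 2, noise_sd = 0,
                      subtype_mix = c(up1 = 0, up2 = 0, up3 = 0, down1 = 0,
                                      down2 = 0, down3 = 0, irr1 = 0,
                                      irr2 = 0, unchanged = 1), seed = 2)
  sim_u <- simulate_trajectories(cfg_u)
  ct_u <- simulate_qpcr(sim_u$truth, cfg_u)
  expect_true(all(ct_u$ct_target == 24))
})

test_that("fasta export writes one synthetic sequence per feature", {
  cfg <- sim_config(n_features = 5, seed = 4)
  sim <- simulate_trajectories(cfg)
  path <- tempfile(fileext = ".fasta")
  write_tdf_fasta(sim$truth, path, seed = 4)
  fa <- seqinr::read.fasta(path)
  expect_setequal(names(fa), sim$truth$feature_id)
  expect_identical(unname(lengths(fa)[sim$truth$feature_id]),
                   sim$truth$length_bp)
})
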