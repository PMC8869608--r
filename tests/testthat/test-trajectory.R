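test_that("normalization divides tapping means by the first tapping", {
  expect_equal(normalize_to_reference(c(10, 10, 10, 10, 10)), rep(1, 5))
  # hand division of a printed band series
  r <- normalize_to_reference(c(200, 288, 582, 684, 762))
  expect_equal(round(r, 2), c(1.00, 1.44, 2.91, 3.42, 3.81))
  # replicate structure: arithmetic replicate means feed the ratio
  s <- make_series(c(200, 288, 582, 684, 762))
  expect_equal(normalize_to_reference(s), c(200, 288, 582, 684, 762) / 200)
})

test_that("normalization is scale invariant and rejects bad references", {
  m <- c(3, 7, 2, 9, 4)
  for (c_ in c(0.01, 1, 250)) {
    expect_equal(normalize_to_reference(c_ * m), normalize_to_reference(m))
  }
  expect_error(normalize_to_reference(c(0, 1, 1, 1, 1)), "positive")
  expect_error(normalize_to_reference(c(1, -2, 1, 1, 1)), "positive")
})

test_that("printed validation trajectories classify to their gel patterns", {
  cases <- list(
    list(r = c(1.00, 1.44, 2.91, 3.42, 3.81), major = "up", subtype = 1L),
    list(r = c(1, 1, 1, 1, 1), major = "unchanged", subtype = NA_integer_),
    list(r = c(1.00, 0.78, 0.48, 0.40, 0.20), major = "down", subtype = 1L),
    # non-monotone rise ending at the maximum: up but none of the 3 shapes
    list(r = c(1.00, 1.16, 0.89, 2.85, 3.23), major = "up", subtype = 0L))
  for (cs in cases) {
    call <- classify_trajectory(cs$r)
    expect_identical(call$major, cs$major)
    expect_identical(call$subtype, cs$subtype)
  }
})

test_that("all eight zero-noise shape templates recover their subtype", {
  expected <- list(up1 = c("up", 1L), up2 = c("up", 2L), up3 = c("up", 3L),
                   down1 = c("down", 1L), down2 = c("down", 2L),
                   down3 = c("down", 3L),
                   irr1 = c("irregular", 1L), irr2 = c("irregular", 2L))
  for (f in c(2, 3, 5)) {
    for (st in all_subtypes) {
      call <- classify_trajectory(shape_template(st, f))
      expect_identical(call$major, expected[[st]][[1]],
                       label = sprintf("%s major at f=%g", st, f))
      expect_identical(call$subtype, as.integer(expected[[st]][[2]]),
                       label = sprintf("%s subtype at f=%g", st, f))
    }
    expect_identical(classify_trajectory(shape_template("unchanged", f))$major,
                     "unchanged")
  }
})

test_that("reciprocal symmetry swaps up/down and irregular subtypes", {
  set.seed(42)
  swap <- c(up = "down", down = "up", irregular = "irregular",
            unchanged = "unchanged")
  for (i in 1:200) {
    r <- c(1, exp(stats::rnorm(4, sd = 0.6)))
    a <- classify_trajectory(r)
    b <- classify_trajectory(1 / r)
    expect_identical(b$major, unname(swap[a$major]))
    if (a$major %in% c("up", "down")) expect_identical(b$subtype, a$subtype)
    if (a$major == "irregular") expect_identical(b$subtype, 3L - a$subtype)
  }
})

test_that("raising delta only moves calls toward unchanged, never up<->down", {
  set.seed(7)
  deltas <- c(1.1, 1.25, 1.5, 2, 3)
  for (i in 1:100) {
    r <- c(1, exp(stats::rnorm(4, sd = 0.5)))
    majors <- vapply(deltas, function(d)
      classify_trajectory(r, classifier_params(delta = d))$major, character(1))
    # once unchanged, stays unchanged as delta grows
    if (any(majors == "unchanged")) {
      first <- match("unchanged", majors)
      expect_true(all(majors[first:length(majors)] == "unchanged"))
    }
    expect_false(any(majors == "up") && any(majors == "down"))
  }
})

test_that("classify_trajectories preserves order, handles empty input, and names errors", {
  empty <- data.frame(feature_id = character(0), r1 = numeric(0),
                      r2 = numeric(0), r3 = numeric(0), r4 = numeric(0),
                      r5 = numeric(0))
  expect_identical(nrow(classify_trajectories(empty)), 0L)
  tab <- data.frame(feature_id = c("b", "a"),
                    r1 = 1, r2 = c(1.5, 0.9), r3 = c(2, 0.7),
                    r4 = c(2.5, 0.6), r5 = c(3, 0.5))
  calls <- classify_trajectories(tab)
  expect_identical(calls$feature_id, c("b", "a"))
  expect_identical(calls$major, c("up", "down"))
  bad <- data.frame(feature_id = "x", r1 = 1, r2 = -1, r3 = 1, r4 = 1, r5 = 1)
  expect_error(classify_trajectories(bad), "x")
})

test_that("the 77 banded validation rows all receive a major type", {
  df <- load_sq_validation()
  banded <- df[is.finite(df$r2), ]
  expect_identical(nrow(df), 80L)
  expect_identical(nrow(banded), 77L)
  calls <- classify_trajectories(
    banded[, c("tdf_id", paste0("r", 1:5))] |>
      stats::setNames(c("feature_id", paste0("r", 1:5))))
  expect_true(all(calls$major %in% c("up", "down", "irregular", "unchanged")))
})
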