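test_that("redundancy removal keeps the longest fragment per (transcript, pattern)", {
  recs <- data.frame(tdf_id = c("a", "b", "c"), transcript_id = "T1",
                     major = "up", length_bp = c(120, 250, 180),
                     stringsAsFactors = FALSE)
  expect_identical(remove_redundancy(recs)$tdf_id, "b")
  # differing patterns on the same transcript are kept apart
  two <- data.frame(tdf_id = c("a", "b"), transcript_id = "T1",
                    major = c("up", "down"), length_bp = c(120, 100),
                    stringsAsFactors = FALSE)
  expect_identical(nrow(remove_redundancy(two)), 2L)
  # length ties resolved by lexicographically smallest id
  tie <- data.frame(tdf_id = c("z", "a"), transcript_id = "T1",
                    major = "up", length_bp = c(200, 200),
                    stringsAsFactors = FALSE)
  expect_identical(remove_redundancy(tie)$tdf_id, "a")
  # missing transcript ids pass through unclustered
  loose <- data.frame(tdf_id = c("a", "b"), transcript_id = NA_character_,
                      major = "up", length_bp = c(120, 100),
                      stringsAsFactors = FALSE)
  expect_identical(nrow(remove_redundancy(loose)), 2L)
  dup <- data.frame(tdf_id = c("a", "a"), transcript_id = "T1",
                    major = "up", length_bp = c(1, 2))
  expect_error(remove_redundancy(dup), "duplicate")
})

test_that("redundancy removal is idempotent and never increases counts", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(5:80, 1)
    recs <- data.frame(tdf_id = sprintf("t%03d", seq_len(n)),
                       transcript_id = sprintf("T%d", sample(1:15, n, TRUE)),
                       major = sample(c("up", "down", "irregular"), n, TRUE),
                       length_bp = sample(100:500, n, TRUE),
                       stringsAsFactors = FALSE)
    once <- remove_redundancy(recs)
    expect_lte(nrow(once), nrow(recs))
    expect_identical(remove_redundancy(once), once)
  }
})

test_that("annotation triage applies the E-value/score thresholds and buckets", {
  lex <- default_lexicon()
  none <- triage_annotation("f1", data.frame(description = character(0),
                                             e_value = numeric(0),
                                             score = numeric(0)), lex)
  expect_identical(none$bucket, "no_hit")
  srpp <- triage_annotation("f2", data.frame(
    description = "small rubber particle protein", e_value = 1e-30,
    score = 200), lex)
  expect_identical(srpp$bucket, "known")
  expect_identical(srpp$category, "Rubber biosynthesis")
  # fails both thresholds -> no hit
  weak <- triage_annotation("f3", data.frame(
    description = "small rubber particle protein", e_value = 1e-3,
    score = 40), lex)
  expect_identical(weak$bucket, "no_hit")
  # thresholds are strict: e = 1e-4 or score = 50 do not pass
  border <- triage_annotation("f4", data.frame(
    description = "small rubber particle protein", e_value = 1e-4,
    score = 51), lex)
  expect_identical(border$bucket, "no_hit")
  pred <- triage_annotation("f5", data.frame(
    description = "hypothetical protein OsJ_1", e_value = 1e-20, score = 90),
    lex)
  expect_identical(pred$bucket, "predicted")
  # two categories with no majority -> unclassified
  multi <- triage_annotation("f6", data.frame(
    description = c("rubber elongation factor", "sugar transporter"),
    e_value = c(1e-20, 1e-20), score = c(100, 100)), lex)
  expect_identical(multi$bucket, "unclassified")
})

test_that("triage is order-independent via deterministic best-hit selection", {
  lex <- default_lexicon()
  hits <- data.frame(
    description = c("pyruvate kinase, putative", "rubber elongation factor",
                    "rubber elongation factor b"),
    e_value = c(1e-10, 1e-40, 1e-35), score = c(80, 180, 170))
  a <- triage_annotation("f", hits, lex)
  b <- triage_annotation("f", hits[c(3, 1, 2), ], lex)
  expect_identical(a, b)
  expect_identical(a$category, "Rubber biosynthesis")   # 2-of-3 majority
  expect_identical(a$hit_description, "rubber elongation factor")
})

test_that("summaries conserve features and reproduce the screen's totals", {
  counts <- load_category_counts("tdf")
  ex <- expand_category_counts(counts)
  s <- summarize_patterns(ex$calls, ex$annotations,
                          category_order = counts$category)
  tot <- s[s$category == "Total", ]
  expect_identical(tot$n, 505L)
  expect_identical(c(tot$up, tot$down, tot$irregular), c(217L, 180L, 108L))
  expect_equal(c(tot$up_pct, tot$down_pct, tot$irregular_pct),
               c(43.0, 35.6, 21.4))
  # conservation: per-row pattern counts sum to the row count,
  # category counts sum to the total
  body <- s[s$category != "Total", ]
  expect_identical(body$up + body$down + body$irregular, body$n)
  expect_identical(sum(body$n), tot$n)
  expect_equal(known_function_percent(s), 72.5)
  # empty input gives a zero totals row
  s0 <- summarize_patterns(data.frame(feature_id = character(0),
                                      major = character(0)),
                           data.frame(feature_id = character(0),
                                      category = character(0)),
                           category_order = character(0))
  expect_identical(s0$n, 0L)
  # a call without annotation is reported as missing
  expect_error(summarize_patterns(data.frame(feature_id = "x", major = "up"),
                                  data.frame(feature_id = "y",
                                             category = "Energy")),
               "missing annotation")
})
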