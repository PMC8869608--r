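# shared fixture builders for the test suite

# long intensity series for one feature from per-tapping means, with
# replicate offsets (additive, so means are exact)
make_series <- function(means, jitter = c(-0.5, 0, 0.5), feature_id = "f1") {
  data.frame(feature_id = feature_id,
             tapping = rep(seq_along(means), each = length(jitter)),
             replicate = rep(seq_along(jitter), length(means)),
             value = rep(means, each = length(jitter)) + jitter,
             stringsAsFactors = FALSE)
}

# long series with exactly the given replicate values per tapping
series_from_groups <- function(groups, feature_id = "f1") {
  data.frame(feature_id = feature_id,
             tapping = rep(seq_along(groups), lengths(groups)),
             replicate = unlist(lapply(groups, seq_along)),
             value = unlist(groups),
             stringsAsFactors = FALSE)
}

all_subtypes <- c("up1", "up2", "up3", "down1", "down2", "down3",
                  "irr1", "irr2")

# independent one-way ANOVA oracle: textbook sum-of-squares decomposition
anova_oracle <- function(values, groups) {
  g <- factor(groups)
  k <- nlevels(g); n <- length(values)
  gm <- tapply(values, g, mean)
  ni <- tabulate(g)
  ssb <- sum(ni * (gm - mean(values))^2)
  ssw <- sum((values - gm[g])^2)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  stats::pf(f, k - 1, n - k, lower.tail = FALSE)
}

# independent equal-variance two-sample t-test oracle via closed-form t CDF
ttest_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  tstat <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  2 * stats::pt(-abs(tstat), df = nx + ny - 2)
}
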