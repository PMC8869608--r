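# internal helpers shared across modules

# Half-up decimal rounding (printed tables use 83.8, 43.0 style), as opposed
# to base round()'s round-half-even.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_tapseq <- function(..., call. = FALSE) {
  stop(..., call. = call.)
}

# Check that a data frame has the named columns, with a readable error.
check_columns <- function(df, cols, what = "input table") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_tapseq(sprintf("%s is missing column(s): %s",
                        what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}
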