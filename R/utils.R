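# internal helpers shared across modules

# fail early with the missing column named (schema contract for all readers)
check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column%s: %s",
      what, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
    ), class = "reefnet_schema_error")
  }
  invisible(df)
}

as_utc <- function(x) {
  stopifnot(inherits(x, "POSIXct"))
  attr(x, "tzone") <- "UTC"
  x
}

utc_time <- function(x) as.POSIXct(x, tz = "UTC")

PERIOD_LEVELS <- c("dawn", "day", "dusk", "night")

period_factor <- function(x) factor(x, levels = PERIOD_LEVELS)

# derive independent substream seeds from one top-level seed, keeping them
# valid 32-bit integers
substream_seeds <- function(seed, n = 3L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
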