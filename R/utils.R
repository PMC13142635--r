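# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_canid <- function(class, message, ...) {
  cond <- structure(
    class = c(class, "canid_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
  stop(cond)
}

validation_error <- function(message, ...) {
  stop_canid("canid_validation_error", message, ...)
}

format_error   <- function(message, ...) stop_canid("canid_format_error", message, ...)
fitting_error  <- function(message, ...) stop_canid("canid_fitting_error", message, ...)

assert_cols <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    format_error(sprintf("file '%s' is missing required column(s): %s",
                         path, paste(missing, collapse = ", ")))
  }
}

assert_in <- function(x, levels, what, context = "") {
  bad <- !is.na(x) & !(x %in% levels)
  if (any(bad)) {
    validation_error(sprintf(
      "%s%s contains invalid value(s): %s (allowed: %s)",
      if (nzchar(context)) paste0(context, ": ") else "", what,
      paste(unique(x[bad]), collapse = ", "),
      paste(levels, collapse = ", ")))
  }
}

# deterministic fingerprint of a data frame (used to tie submodels to the
# dataset they were fitted on)
dataset_fingerprint <- function(df) {
  tf <- tempfile()
  on.exit(unlink(tf))
  utils::write.csv(df[do.call(order, df), , drop = FALSE], tf, row.names = FALSE)
  unname(tools::md5sum(tf))
}

# derive a substream seed below 2^31 from a master seed and a stream label
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 69069 + h * 1013 + 1) %% 2147480000)
}
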