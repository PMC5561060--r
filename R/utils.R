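`%||%` <- function(x, y) if (is.null(x)) y else x

stop_earlinc <- function(fmt, ..., call. = FALSE) {
  stop(sprintf(fmt, ...), call. = call.)
}

warn_earlinc <- function(fmt, ...) {
  warning(sprintf(fmt, ...), call. = FALSE)
}

assert_cols <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop_earlinc("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", "))
  }
  invisible(df)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

STRAND_TOKENS <- c("+", "-", ".")
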