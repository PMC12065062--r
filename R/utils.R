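#' @keywords internal
"_PACKAGE"

# internal helpers ------------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# check that a data frame has the named columns; error names the missing ones
need_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0L) {
    stopf("%s is missing required column(s): %s", what,
          paste(miss, collapse = ", "))
  }
  invisible(df)
}

is_finite_num <- function(x) is.numeric(x) && all(is.finite(x))

# mean of daily tmax/tmin, the FAO-56 convention for daily air temperature
tmean_of <- function(tmax, tmin) (tmax + tmin) / 2
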