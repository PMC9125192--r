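# Internal argument checks shared across modules.

check_numeric <- function(x, name, allow_na = FALSE, min = NULL, max = NULL,
                          strict_min = FALSE) {
  if (!is.numeric(x)) {
    stop(sprintf("`%s` must be numeric.", name), call. = FALSE)
  }
  bad_na <- is.na(x)
  if (!allow_na && any(bad_na)) {
    stop(sprintf("`%s` contains missing values.", name), call. = FALSE)
  }
  ok <- !bad_na
  if (any(!is.finite(x[ok]))) {
    stop(sprintf("`%s` must be finite.", name), call. = FALSE)
  }
  if (!is.null(min)) {
    viol <- if (strict_min) x[ok] <= min else x[ok] < min
    if (any(viol)) {
      stop(sprintf("`%s` must be %s %s.", name,
                   if (strict_min) ">" else ">=", format(min)), call. = FALSE)
    }
  }
  if (!is.null(max) && any(x[ok] > max)) {
    stop(sprintf("`%s` must be <= %s.", name, format(max)), call. = FALSE)
  }
  invisible(x)
}

check_scalar <- function(x, name, ...) {
  if (length(x) != 1L) {
    stop(sprintf("`%s` must be a single value.", name), call. = FALSE)
  }
  check_numeric(x, name, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Value of `x` at the grid time closest to `t` (ties -> earlier time).
nearest_time <- function(time, x, t) {
  if (length(time) == 0L) return(NA_real_)
  x[which.min(abs(time - t))]
}
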