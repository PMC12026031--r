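# internal helpers shared across the package

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stop_field <- function(field, msg) {
  stop(sprintf("%s: %s", field, msg), call. = FALSE)
}

check_positive <- function(x, field, allow_na = FALSE) {
  if (allow_na) {
    bad <- !is.na(x) & (!is.finite(x) | x <= 0)
  } else {
    bad <- !is.finite(x) | x <= 0
  }
  if (any(bad)) {
    stop_field(field, sprintf(
      "must be a positive finite number (offending value: %s)",
      paste(utils::head(x[bad], 3), collapse = ", ")
    ))
  }
  invisible(x)
}

check_flag <- function(x, field) {
  if (!is.logical(x) || anyNA(x)) stop_field(field, "must be TRUE/FALSE")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
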