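#' @keywords internal
"_PACKAGE"

# Internal validation helpers. All user-facing constructors funnel through
# these so error messages carry the offending field name.

stop_user <- function(...) {
  stop(errorCondition(paste0(...), class = c("pc_user_error", "error")))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_user(name, " must be a single finite number")
  }
  ok_lo <- if (strict_lower) x > lower else x >= lower
  ok_hi <- if (strict_upper) x < upper else x <= upper
  if (!ok_lo || !ok_hi) {
    stop_user(name, " = ", format(x), " outside allowed range ",
              if (strict_lower) "(" else "[", lower, ", ", upper,
              if (strict_upper) ")" else "]")
  }
  x
}

check_choice <- function(x, name, choices) {
  if (!is.character(x) || length(x) != 1L || !(x %in% choices)) {
    stop_user(name, " must be one of: ", paste(choices, collapse = ", "))
  }
  x
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a
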