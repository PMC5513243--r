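# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

fl_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "flightloc_error", "error", "condition")))
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    fl_stop(sprintf("`%s` must be a single positive finite number", name),
            "flightloc_invalid_parameter")
  invisible(x)
}

check_nonnegative <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    fl_stop(sprintf("`%s` must be a single non-negative finite number", name),
            "flightloc_invalid_parameter")
  invisible(x)
}

# Euclidean norm of the rows of a matrix (or of a single vector)
row_norms <- function(m) {
  if (is.null(dim(m))) sqrt(sum(m^2)) else sqrt(rowSums(m^2))
}
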