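# Internal helpers: classed errors and angle arithmetic.

po_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "pointorigin_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

deg2rad <- function(d) d * pi / 180

# Normalize an angle in degrees to (-180, 180].
norm_angle <- function(a) {
  r <- a %% 360
  ifelse(r > 180, r - 360, r)
}

check_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    po_stop(sprintf("`%s` must be a single finite number", name),
            "po_invalid_parameter")
  }
  invisible(x)
}
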