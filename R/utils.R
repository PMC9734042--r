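# Internal validation helpers -------------------------------------------------

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid("`%s` must be a single finite number", name)
  if (strict_lower) {
    if (x <= lower) stop_invalid("`%s` must be > %g", name, lower)
  } else if (x < lower) {
    stop_invalid("`%s` must be >= %g", name, lower)
  }
  if (x > upper) stop_invalid("`%s` must be <= %g", name, upper)
  invisible(x)
}

check_times <- function(times, name = "times") {
  if (length(times) < 1L || anyNA(times))
    stop_invalid("`%s` must be a nonempty numeric vector without NA", name)
  if (is.unsorted(times, strictly = TRUE))
    stop_invalid("`%s` must be strictly increasing", name)
  invisible(as.numeric(times))
}

# Dense matrix exponential (Ward's Pade via the Matrix package).
mat_expm <- function(A) {
  as.matrix(Matrix::expm(Matrix::Matrix(A)))
}

# Linear interpolation of a sampled curve, erroring outside its support.
interp_curve <- function(times, values, at, what = "input function") {
  if (min(at) < min(times) - 1e-9 || max(at) > max(times) + 1e-9)
    stop_invalid("requested times fall outside the support of the %s", what)
  approxfun(times, values, rule = 2)(at)
}
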