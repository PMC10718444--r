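#' Wrap angles to (-pi, pi]
#'
#' @param x numeric vector of angles in radians.
#' @return angles wrapped to the half-open interval (-pi, pi].
#' @examples
#' wrap_angle(c(0, pi, -pi, 3 * pi / 2))
#' @export
wrap_angle <- function(x) {
  y <- x %% (2 * pi)
  ifelse(y > pi, y - 2 * pi, y)
}

#' Circular (wrapped) difference between two angles
#'
#' Signed smallest rotation taking `b` onto `a`, in (-pi, pi].
#'
#' @param a,b numeric vectors of angles in radians.
#' @return `wrap_angle(a - b)`.
#' @export
angle_diff <- function(a, b) wrap_angle(a - b)

# internal: stop with a classed condition, so callers can test on class
stop_tvbo <- function(msg, class) {
  stop(structure(class = c(class, "tvbo_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# internal: check a single positive scalar
check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_tvbo(sprintf("'%s' must be a single finite number", name),
              "tvbo_invalid_parameter")
  if (x < lower || (strict_lower && x <= lower) || x > upper)
    stop_tvbo(sprintf("'%s' = %g out of range", name, x),
              "tvbo_invalid_parameter")
  invisible(x)
}
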