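#' @keywords internal
"_PACKAGE"

# Angle helpers: everything user-facing is in degrees, internal trig in radians.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap an angle in degrees into (-180, 180]
#'
#' @param x numeric vector of angles in degrees.
#' @return angles mapped onto the half-open circle (-180, 180].
#' @export
wrap_angle <- function(x) {
  y <- x - 360 * floor((x + 180) / 360)
  # floor maps +180 -> -180; put it back on the closed end
  y[y <= -180] <- y[y <= -180] + 360
  y
}

vec_norm <- function(v) sqrt(sum(v^2))

unit_vec <- function(v) {
  n <- vec_norm(v)
  if (n == 0) stop("zero-length vector", call. = FALSE)
  v / n
}

# numerically safe acos in degrees
acos_deg <- function(x) rad2deg(acos(pmin(1, pmax(-1, x))))

`%||%` <- function(a, b) if (is.null(a)) b else a
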