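#' Cubic design space
#'
#' The axis-aligned cube `[origin, origin + L]^3` inside which all structures
#' are generated. The default side length of 100 matches the reference design
#' space (L = 100 cm); the cube can be scaled freely since vertex and edge
#' counts are scale-invariant and only the mean edge length carries units.
#'
#' @param side_length Positive side length L, in model units.
#' @param origin Numeric 3-vector, the minimum corner (default `c(0, 0, 0)`).
#' @return An object of class `bounding_cube`.
#' @examples
#' bounding_cube(150)
#' @export
bounding_cube <- function(side_length = 100, origin = c(0, 0, 0)) {
  if (!is.numeric(side_length) || length(side_length) != 1 ||
      !is.finite(side_length) || side_length <= 0) {
    abort("`side_length` must be a single positive number.",
          class = "voroscaffold_invalid_parameter")
  }
  if (!is.numeric(origin) || length(origin) != 3 || any(!is.finite(origin))) {
    abort("`origin` must be a finite numeric 3-vector.",
          class = "voroscaffold_invalid_parameter")
  }
  structure(
    list(side_length = as.numeric(side_length), origin = as.numeric(origin)),
    class = "bounding_cube"
  )
}

#' @export
print.bounding_cube <- function(x, ...) {
  cat(sprintf("<bounding_cube> L = %g, origin = (%g, %g, %g)\n",
              x$side_length, x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

is_bounding_cube <- function(x) inherits(x, "bounding_cube")

assert_cube <- function(cube) {
  if (!is_bounding_cube(cube)) {
    abort("`cube` must be created with `bounding_cube()`.",
          class = "voroscaffold_invalid_parameter")
  }
  invisible(cube)
}

#' Cube volume
#' @param cube A [bounding_cube()].
#' @return L^3.
#' @export
cube_volume <- function(cube) {
  assert_cube(cube)
  cube$side_length^3
}
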