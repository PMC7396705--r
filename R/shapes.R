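#' Generate uniform random points on a centered square
#'
#' Draws `Q` points whose coordinates are i.i.d. uniform on
#' \eqn{[-L/2, L/2]^2}. This is the raw material for the synthetic
#' validation geometries (see [filter_shape()]); the square is centered at
#' the origin so the filters below can be written in terms of the global
#' centroid.
#'
#' @param Q Number of points to draw (positive integer).
#' @param L Side length of the generation square (positive).
#' @param seed Integer RNG seed; the same `(Q, L, seed)` always yields the
#'   same point set.
#' @return A data frame with columns `x` and `y` (`Q` rows).
#' @examples
#' p <- generate_square(100, L = 1, seed = 1)
#' range(p$x)  # inside [-0.5, 0.5]
#' @export
generate_square <- function(Q, L, seed) {
  if (length(Q) != 1L || !is.finite(Q) || Q < 1)
    stop("`Q` must be a positive integer")
  if (length(L) != 1L || !is.finite(L) || L <= 0)
    stop("`L` must be a positive length")
  Q <- as.integer(Q)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  data.frame(x = stats::runif(Q, -L / 2, L / 2),
             y = stats::runif(Q, -L / 2, L / 2))
}

# Save/restore of .Random.seed so shape generation does not perturb the
# caller's RNG stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Filter a raw square sample into a synthetic validation geometry
#'
#' Keeps the subset of a uniform square sample that satisfies the geometric
#' membership rule of one of four shapes used to validate the dissimilarity
#' quantifiers:
#'
#' * `ball`: the disc \eqn{x^2 + y^2 \le (L/2)^2} — uniform spread, no
#'   clustering tendency.
#' * `ring`: the annulus \eqn{(L/2-\delta)^2 \le x^2+y^2 \le (L/2)^2} —
#'   points cluster far from, and uniformly around, the global centroid.
#' * `sum`: the union of the two axis-aligned bands \eqn{|x| \le \delta/2}
#'   or \eqn{|y| \le \delta/2} (a "+" sign).
#' * `cross`: the sum geometry rotated by 45 degrees; the band rule is
#'   applied in \eqn{(\xi, \eta)} and kept points are mapped through
#'   \eqn{x = (\xi-\eta)/2, y = (\xi+\eta)/2}.
#'
#' All inequalities are closed: boundary points are kept.
#'
#' @param raw Data frame with columns `x`, `y`, generated on the
#'   \eqn{[-L/2, L/2]^2} square (see [generate_square()]).
#' @param shape One of `"ball"`, `"ring"`, `"sum"`, `"cross"`.
#' @param L Side of the generation square.
#' @param delta Band half-width / annulus width parameter \eqn{\delta}
#'   (default `L/9`).
#' @param ring_literal If `TRUE`, use the literal inner-radius term
#'   \eqn{(L^2/2-\delta)^2} instead of the dimensionally consistent
#'   \eqn{(L/2-\delta)^2}. The literal term compares a squared length
#'   against \eqn{L^2/2 - \delta} and is kept only for strict
#'   reproduction of the original script's formula.
#' @param cross_scaled If `TRUE`, the cross map divides by 2 instead of
#'   \eqn{\sqrt 2} — a 45-degree rotation composed with shrinking by
#'   \eqn{1/\sqrt 2}, which pulls the cross arms inside the ring's inner
#'   radius and makes the two shapes exactly orthogonal. The default is
#'   the proper rotation (divide by \eqn{\sqrt 2}), which preserves the
#'   arm length of the sum shape.
#' @return A data frame with columns `x`, `y` and attributes `raw_count`
#'   (`nrow(raw)`) and `shape`.
#' @seealso [synth_shape()] for the one-call generator.
#' @export
filter_shape <- function(raw, shape, L, delta = L / 9,
                         ring_literal = FALSE, cross_scaled = FALSE) {
  shape <- match.arg(shape, c("ball", "ring", "sum", "cross"))
  if (!is.finite(delta) || delta <= 0 || delta >= L / 2)
    stop("`delta` must satisfy 0 < delta < L/2")
  x <- raw$x
  y <- raw$y
  r2 <- x^2 + y^2
  keep <- switch(shape,
    ball = r2 <= (L / 2)^2,
    ring = {
      inner <- if (ring_literal) (L^2 / 2 - delta)^2 else (L / 2 - delta)^2
      inner <= r2 & r2 <= (L / 2)^2
    },
    sum = abs(x) <= delta / 2 | abs(y) <= delta / 2,
    cross = abs(x) <= delta / 2 | abs(y) <= delta / 2
  )
  out <- data.frame(x = x[keep], y = y[keep])
  if (shape == "cross") {
    s <- if (cross_scaled) 2 else sqrt(2)
    out <- data.frame(x = (out$x - out$y) / s, y = (out$x + out$y) / s)
  }
  attr(out, "raw_count") <- nrow(raw)
  attr(out, "shape") <- shape
  out
}

#' Generate a synthetic shape point set
#'
#' Convenience wrapper: draws `Q` uniform points on the square of side `L`
#' and applies the shape filter, so the retained count is shape-dependent
#' and strictly below `Q` in general.
#'
#' @inheritParams filter_shape
#' @inheritParams generate_square
#' @param ... Passed to [filter_shape()] (`ring_literal`, `cross_scaled`).
#' @return As [filter_shape()]; the `label` attribute is set to the shape
#'   name.
#' @examples
#' ring <- synth_shape("ring", Q = 500, L = 1, seed = 7)
#' nrow(ring)                  # retained points (< 500)
#' attr(ring, "raw_count")     # 500
#' @export
synth_shape <- function(shape, Q, L = 1, delta = L / 9, seed = 1L, ...) {
  raw <- generate_square(Q, L, seed)
  out <- filter_shape(raw, shape, L = L, delta = delta, ...)
  attr(out, "label") <- shape
  out
}
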