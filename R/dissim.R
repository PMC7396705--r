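same_space <- function(df_a, df_b) {
  identical(df_a$space, df_b$space) &&
    identical(unclass(df_a$grid), unclass(df_b$grid))
}

check_space <- function(df_a, df_b) {
  if (!inherits(df_a, "dfun") || !inherits(df_b, "dfun"))
    stop("both arguments must be `dfun` objects")
  if (!same_space(df_a, df_b))
    stop("distribution functions live in different inner-product spaces; ",
         "build them together with build_batch()")
}

#' Inner product of two distribution functions
#'
#' With both functions built on one shared grid and shared per-cell
#' covariances (one [build_batch()] call), distinct cells are orthogonal
#' and the reproducing property \eqn{\langle k(\cdot,z), k(\cdot,w)\rangle
#' = k(z,w)} collapses the inner product to kernel evaluations:
#' \deqn{\langle\Phi_a, \Phi_b\rangle = \sum_{ij} R^a_{ij} R^b_{ij}\,
#'   k_{ij}(\bar z^a_{ij}, \bar z^b_{ij}),}
#' where \eqn{k_{ij}(z, w) = \exp(-\tfrac12 (z-w)^t \Sigma_{ij}^{-1}
#' (z-w))}. Cells empty in either function contribute zero.
#'
#' @param df_a,df_b `dfun` objects from the same batch.
#' @return A nonnegative number (when `df_a == df_b`), symmetric in its
#'   arguments.
#' @export
inner_product <- function(df_a, df_b) {
  check_space(df_a, df_b)
  total <- 0
  for (k in seq_along(df_a$cells)) {
    ma <- df_a$cells[[k]]
    mb <- df_b$cells[[k]]
    if (ma$provenance == "empty" || mb$provenance == "empty") next
    total <- total + ma$count * mb$count *
      evaluate_kernel(ma, mb$centroid)
  }
  total
}

#' Distance between two distribution functions
#'
#' The norm of the difference in the shared inner-product space,
#' \eqn{d = \sqrt{\langle a,a\rangle - 2\langle a,b\rangle +
#' \langle b,b\rangle}}; tiny negative radicands from floating-point
#' cancellation are clamped to zero.
#'
#' @inheritParams inner_product
#' @return Nonnegative distance `d`. Distances grow with the number of
#'   points (the functions are count-weighted); see
#'   [normalized_distance()] for the bounded variant.
#' @export
df_distance <- function(df_a, df_b) {
  aa <- inner_product(df_a, df_a)
  bb <- inner_product(df_b, df_b)
  ab <- inner_product(df_a, df_b)
  r <- aa - 2 * ab + bb
  scale <- max(aa, bb, 1)
  if (r < 0 && r > -1e-10 * scale) r <- 0
  if (r < 0) stop("negative squared distance beyond tolerance: ", r)
  sqrt(r)
}

#' Angle between two distribution functions
#'
#' \eqn{\theta = \arccos\big(\langle a,b\rangle / (\|a\|\,\|b\|)\big)} in
#' degrees. Because all kernel inner products are nonnegative the angle
#' lands in \eqn{[0, 90]}; angles below 45 degrees are read as "similar"
#' distributions and above 45 degrees as "dissimilar".
#'
#' @inheritParams inner_product
#' @return Angle in degrees in \eqn{[0, 90]}.
#' @export
df_angle <- function(df_a, df_b) {
  aa <- inner_product(df_a, df_a)
  bb <- inner_product(df_b, df_b)
  if (aa == 0 || bb == 0)
    stop("angle is undefined for a zero distribution function")
  cosv <- inner_product(df_a, df_b) / sqrt(aa * bb)
  cosv <- min(1, max(-1, cosv))
  acos(cosv) * 180 / pi
}

#' Normalized distance
#'
#' \eqn{D = d / (1 + d)}: bounded in \eqn{[0, 1)}, strictly increasing in
#' `d`, and still a metric; removes the raw distance's growth with the
#' size of the point sets.
#'
#' @inheritParams inner_product
#' @return Number in \eqn{[0, 1)}.
#' @export
normalized_distance <- function(df_a, df_b) {
  d <- df_distance(df_a, df_b)
  d / (1 + d)
}

#' All dissimilarity quantifiers at once
#'
#' @inheritParams inner_product
#' @return A `dissimilarity` list: `distance`, `angle` (degrees),
#'   `normalized_distance`, and the three `inner_products`
#'   (\eqn{\langle a,a\rangle, \langle a,b\rangle, \langle b,b\rangle}).
#' @examples
#' b <- build_batch(list(ring = synth_shape("ring", 500, seed = 1),
#'                       ball = synth_shape("ball", 500, seed = 2)))
#' dissimilarity(b$dfs$ring, b$dfs$ball)
#' @export
dissimilarity <- function(df_a, df_b) {
  aa <- inner_product(df_a, df_a)
  bb <- inner_product(df_b, df_b)
  ab <- inner_product(df_a, df_b)
  r <- aa - 2 * ab + bb
  if (r < 0 && r > -1e-10 * max(aa, bb, 1)) r <- 0
  d <- sqrt(r)
  theta <- if (aa > 0 && bb > 0)
    acos(min(1, max(-1, ab / sqrt(aa * bb)))) * 180 / pi
  else NA_real_
  structure(list(distance = d, angle = theta,
                 normalized_distance = d / (1 + d),
                 inner_products = c(aa = aa, ab = ab, bb = bb)),
            class = "dissimilarity")
}

#' @export
print.dissimilarity <- function(x, ...) {
  cat(sprintf("distance d        : %.4f\n", x$distance))
  cat(sprintf("angle (degrees)   : %.4f  [%s]\n", x$angle,
              if (is.na(x$angle)) "undefined"
              else if (x$angle < 45) "similar" else "dissimilar"))
  cat(sprintf("normalized D      : %.4f\n", x$normalized_distance))
  invisible(x)
}
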