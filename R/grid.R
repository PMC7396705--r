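#' @importFrom stats runif cor cov var sd
NULL

as_xy <- function(points) {
  if (is.matrix(points)) points <- data.frame(x = points[, 1], y = points[, 2])
  if (!all(c("x", "y") %in% names(points)))
    stop("points must have columns `x` and `y`")
  if (nrow(points) > 0 && !all(is.finite(points$x) & is.finite(points$y)))
    stop("coordinates must be finite")
  points[c("x", "y")]
}

#' Center a point set at its centroid
#'
#' @param points Data frame with columns `x`, `y` (at least one row).
#' @return List with `points` (centered set, centroid at the origin) and
#'   `centroid` (length-2 numeric, the arithmetic mean of the input).
#' @export
center_points <- function(points) {
  points <- as_xy(points)
  if (nrow(points) == 0) stop("cannot center an empty point set")
  ctr <- c(mean(points$x), mean(points$y))
  list(points = data.frame(x = points$x - ctr[1], y = points$y - ctr[2]),
       centroid = ctr)
}

#' Bounding box with margin
#'
#' Computes the compact box \eqn{[a, A] \times [b, B]} with
#' \eqn{a = \min x_j - \epsilon}, \eqn{A = \max x_j + \epsilon} (and
#' likewise in `y`), so every point is strictly interior.
#'
#' @param points Nonempty data frame with columns `x`, `y`.
#' @param margin Positive margin \eqn{\epsilon}; if `NULL`, 1% of the larger
#'   coordinate span (floor of `1e-8` times the span scale for degenerate,
#'   zero-span sets).
#' @return Named numeric vector `c(a, A, b, B)`.
#' @export
make_box <- function(points, margin = NULL) {
  points <- as_xy(points)
  if (nrow(points) == 0) stop("cannot box an empty point set")
  rx <- range(points$x)
  ry <- range(points$y)
  if (is.null(margin)) {
    span <- max(diff(rx), diff(ry))
    if (span == 0) span <- max(abs(unlist(points)), 1)
    margin <- 0.01 * span
  }
  if (!is.finite(margin) || margin <= 0) stop("`margin` must be positive")
  c(a = rx[1] - margin, A = rx[2] + margin,
    b = ry[1] - margin, B = ry[2] + margin)
}

#' Uniform N-by-N grid over a box
#'
#' @param box Named vector `c(a, A, b, B)` with `a < A`, `b < B`.
#' @param N Cells per side (positive integer, default 11; the default grid
#'   size gives cells holding few, many and very many fibers on typical
#'   fascicle sections, which is what makes the per-cell covariances
#'   informative).
#' @return A `grid_spec` object: the box, `N`, and the cell edge vectors.
#' @export
grid_spec <- function(box, N = 11L) {
  if (length(N) != 1L || !is.finite(N) || N < 1) stop("`N` must be >= 1")
  N <- as.integer(N)
  a <- unname(box["a"]); A <- unname(box["A"])
  b <- unname(box["b"]); B <- unname(box["B"])
  if (!(a < A && b < B)) stop("degenerate box: need a < A and b < B")
  structure(list(a = a, A = A, b = b, B = B, N = N,
                 xs = a + (0:N) * (A - a) / N,
                 ys = b + (0:N) * (B - b) / N),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells over [%.4g, %.4g] x [%.4g, %.4g]\n",
              x$N, x$N, x$a, x$A, x$b, x$B))
  invisible(x)
}

# Cell index pair for each point. Cells are half-open (a_{i-1}, a_i] except
# the first, which is closed below, so assignment is unique: a point exactly
# on an interior edge goes to the lower-index cell.
cell_index <- function(points, grid) {
  ix <- findInterval(points$x, grid$xs, left.open = TRUE)
  iy <- findInterval(points$y, grid$ys, left.open = TRUE)
  ix[ix == 0L & points$x >= grid$xs[1]] <- 1L
  iy[iy == 0L & points$y >= grid$ys[1]] <- 1L
  bad <- ix < 1 | ix > grid$N | iy < 1 | iy > grid$N
  if (any(bad)) {
    k <- which(bad)[1]
    stop(sprintf("point (%g, %g) lies outside the grid box",
                 points$x[k], points$y[k]))
  }
  cbind(i = ix, j = iy)
}

#' Assign points to grid cells
#'
#' Every point lands in exactly one cell; interior-edge ties go to the
#' lower-index cell so the cells partition the box.
#'
#' @param points Data frame with columns `x`, `y`, all inside the grid box.
#' @param grid A [grid_spec()].
#' @return An `N` x `N` list matrix; element `[i, j]` is the data frame of
#'   points in cell \eqn{C_{ij}} (column-`i` runs along x).
#' @export
assign_cells <- function(points, grid) {
  points <- as_xy(points)
  out <- matrix(vector("list", grid$N^2), grid$N, grid$N)
  if (nrow(points) == 0) {
    for (k in seq_along(out)) out[[k]] <- points
    return(out)
  }
  idx <- cell_index(points, grid)
  flat <- (idx[, "j"] - 1L) * grid$N + idx[, "i"]
  groups <- split(seq_len(nrow(points)), flat)
  for (k in seq_along(out)) out[[k]] <- points[integer(0), ]
  for (nm in names(groups)) out[[as.integer(nm)]] <- points[groups[[nm]], ]
  out
}

inv2x2 <- function(S) {
  det <- S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1]
  matrix(c(S[2, 2], -S[2, 1], -S[1, 2], S[1, 1]), 2, 2) / det
}

#' Per-cell Gaussian kernel model
#'
#' Builds the (count, centroid, covariance) triple for one grid cell,
#' handling the degenerate cases:
#'
#' * empty cell: the kernel is identically zero (`provenance = "empty"`);
#' * a single point \eqn{z_p}: \eqn{\Sigma = (\delta/3)^2 I_2} with
#'   \eqn{\delta} the point's distance to the cell boundary, i.e.
#'   \eqn{\phi(z) = \exp(-9\,\|z-z_p\|^2 / (2\delta^2))};
#' * \eqn{\ge 2} points with well-conditioned sample covariance
#'   (denominator \eqn{|S_{ij}|-1}): used as is (`"regular"`);
#' * \eqn{\ge 2} points with \eqn{\det\Sigma \le \epsilon_0}: replaced by
#'   \eqn{M \Lambda M^t} with \eqn{\lambda_1 = \max_k \|z_k-\bar z\|^2},
#'   \eqn{\lambda_2 = \lambda_1/9}, \eqn{u_1} the unit vector toward the
#'   farthest point (lowest index on ties) and \eqn{u_2} its 90-degree
#'   rotation (`"regularized"`). If all points coincide
#'   (\eqn{\lambda_1 = 0}) the single-point rule is applied at the common
#'   location.
#'
#' @param subset Data frame of the points in the cell (possibly empty).
#' @param cell Numeric `c(x0, x1, y0, y1)`, the closed cell rectangle.
#' @param eps0 Near-singularity threshold for \eqn{\det\Sigma}; if `NULL`,
#'   `1e-12 * (cell area)^2` (dimensionally a squared determinant, so the
#'   gate is invariant to rescaling the coordinates).
#' @param single_point_delta `"nearest"` (default): \eqn{\delta} is the
#'   minimum distance from the point to the four cell edges. `"literal"`
#'   uses \eqn{\max\{x_1 - x_p,\; y_1 - y_p\}} (the upper-edge gaps), kept
#'   for strict reproduction of the original formula.
#' @param delta_min_frac Floor for \eqn{\delta} as a fraction of the cell
#'   side, used when the point sits exactly on the boundary (default
#'   `1e-3`).
#' @return A `cell_model` list: `count`, `centroid`, `Sigma`, `Sigma_inv`,
#'   `provenance`.
#' @export
cell_model <- function(subset, cell, eps0 = NULL,
                       single_point_delta = c("nearest", "literal"),
                       delta_min_frac = 1e-3) {
  single_point_delta <- match.arg(single_point_delta)
  subset <- as_xy(subset)
  n <- nrow(subset)
  cw <- cell[2] - cell[1]
  ch <- cell[4] - cell[3]
  if (is.null(eps0)) eps0 <- 1e-12 * (cw * ch)^2
  if (n == 0)
    return(structure(list(count = 0L, centroid = NULL, Sigma = NULL,
                          Sigma_inv = NULL, provenance = "empty"),
                     class = "cell_model"))

  single_point <- function(zp) {
    delta <- if (single_point_delta == "literal")
      max(cell[2] - zp[1], cell[4] - zp[1])
    else
      min(zp[1] - cell[1], cell[2] - zp[1], zp[2] - cell[3], cell[4] - zp[2])
    delta <- max(delta, delta_min_frac * min(cw, ch))
    S <- diag(2) * (delta / 3)^2
    structure(list(count = n, centroid = zp, Sigma = S,
                   Sigma_inv = diag(2) * (3 / delta)^2,
                   provenance = "single_point"),
              class = "cell_model")
  }

  if (n == 1) return(single_point(c(subset$x, subset$y)))

  ctr <- c(mean(subset$x), mean(subset$y))
  Z <- cbind(subset$x - ctr[1], subset$y - ctr[2])
  S <- crossprod(Z) / (n - 1)
  det <- S[1, 1] * S[2, 2] - S[1, 2] * S[2, 1]
  if (det > eps0)
    return(structure(list(count = n, centroid = ctr, Sigma = S,
                          Sigma_inv = inv2x2(S), provenance = "regular"),
                     class = "cell_model"))
  d2 <- Z[, 1]^2 + Z[, 2]^2
  lambda1 <- max(d2)
  if (lambda1 == 0) {
    # all points coincide: single-point rule at the common location,
    # flagged by count > 1 together with the single_point provenance
    return(single_point(ctr))
  }
  k <- which.max(d2)            # first maximum = lowest input index on ties
  u1 <- Z[k, ] / sqrt(lambda1)
  u2 <- c(-u1[2], u1[1])
  M <- cbind(u1, u2)
  S <- M %*% diag(c(lambda1, lambda1 / 9)) %*% t(M)
  S <- (S + t(S)) / 2
  structure(list(count = n, centroid = ctr, Sigma = S,
                 Sigma_inv = inv2x2(S), provenance = "regularized"),
            class = "cell_model")
}

#' Evaluate one cell's Gaussian kernel
#'
#' \eqn{\phi_{ij}(z) = \exp(-\tfrac12 (z-\bar z_{ij})^t \Sigma_{ij}^{-1}
#' (z-\bar z_{ij}))}, the Mahalanobis Gaussian of the cell model; an empty
#' model evaluates to 0 by contract.
#'
#' @param model A [cell_model()].
#' @param z Numeric matrix (n x 2) or length-2 vector of evaluation points.
#' @return Numeric vector of kernel values in \eqn{[0, 1]}.
#' @export
evaluate_kernel <- function(model, z) {
  if (is.null(dim(z))) z <- matrix(z, ncol = 2)
  if (model$provenance == "empty") return(rep(0, nrow(z)))
  dx <- z[, 1] - model$centroid[1]
  dy <- z[, 2] - model$centroid[2]
  P <- model$Sigma_inv
  q <- P[1, 1] * dx^2 + 2 * P[1, 2] * dx * dy + P[2, 2] * dy^2
  exp(-0.5 * q)
}

# Process-wide counter tagging the inner-product space a dfun was built in;
# does not touch the RNG stream so seeded pipelines stay reproducible.
.space_counter <- new.env(parent = emptyenv())

next_space_id <- function() {
  n <- get0("n", envir = .space_counter, ifnotfound = 0L) + 1L
  assign("n", n, envir = .space_counter)
  n
}

new_dfun <- function(grid, cells, label, n, space) {
  structure(list(grid = grid, cells = cells, label = label,
                 n = n, space = space),
            class = "dfun")
}

#' Distribution function of a single point set
#'
#' Builds \eqn{\Phi(z) = \sum_{ij} R_{ij} \phi_{ij}(z)}: the point set is
#' split over the grid cells, each nonempty cell gets a Gaussian kernel
#' from its points ([cell_model()]) weighted by the cell count
#' \eqn{R_{ij}}, and the distribution function is their linear
#' superposition — a smooth version of the cell histogram. The object
#' stores the per-cell models (lazy evaluation), not a raster.
#'
#' @param points Data frame with columns `x`, `y`; expected centered (see
#'   [center_points()]) and inside the grid box.
#' @param grid A [grid_spec()].
#' @param eps0,single_point_delta,delta_min_frac Passed to [cell_model()].
#' @param label Optional tag naming the source image / fiber type.
#' @return A `dfun` object; evaluate with [predict.dfun()].
#' @seealso [build_batch()] to place several distribution functions in one
#'   comparable inner-product space.
#' @export
build_distribution <- function(points, grid, eps0 = NULL,
                               single_point_delta = "nearest",
                               delta_min_frac = 1e-3, label = NULL) {
  points <- as_xy(points)
  cells <- assign_cells(points, grid)
  models <- matrix(vector("list", grid$N^2), grid$N, grid$N)
  for (i in seq_len(grid$N)) {
    for (j in seq_len(grid$N)) {
      rect <- c(grid$xs[i], grid$xs[i + 1], grid$ys[j], grid$ys[j + 1])
      models[[i, j]] <- cell_model(cells[[i, j]], rect, eps0 = eps0,
                                   single_point_delta = single_point_delta,
                                   delta_min_frac = delta_min_frac)
    }
  }
  new_dfun(grid, models, label, nrow(points),
           space = paste0("single-", next_space_id()))
}

#' Distribution functions for a batch of images
#'
#' Builds one distribution function per point set on a single shared grid,
#' with per-cell covariances pooled over all sets (the global sample
#' covariance about the global cell centroid), so all returned functions
#' live in the same inner-product space and can be compared with
#' [dissimilarity()]. Each image's kernels are centered at that image's
#' own cell centroids but use the shared covariance; degenerate pooled
#' cells follow the same empty / single-point / regularized rules as
#' [cell_model()].
#'
#' @param images List of point sets (data frames with `x`, `y`), length
#'   \eqn{r \ge 2}; names become labels.
#' @param N Grid cells per side (default 11).
#' @param margin Box margin; `NULL` for 1% of the pooled span.
#' @param eps0,single_point_delta,delta_min_frac Passed to the pooled
#'   [cell_model()] construction.
#' @param center If `TRUE` (default), each image is first centered at its
#'   own centroid.
#' @param global_centers If `TRUE`, kernels are centered at the global
#'   (pooled) cell centroids rather than per-image centroids; the default
#'   keeps per-image centers so two images differing only in within-cell
#'   placement remain distinguishable.
#' @return A `df_batch` object: `grid`, `pooled` cell models, and `dfs`, a
#'   list of `dfun` objects sharing the space.
#' @export
build_batch <- function(images, N = 11L, margin = NULL, eps0 = NULL,
                        single_point_delta = "nearest",
                        delta_min_frac = 1e-3, center = TRUE,
                        global_centers = FALSE) {
  if (!is.list(images) || length(images) < 2)
    stop("`images` must be a list of at least two point sets; ",
         "use build_distribution() for a single image")
  images <- lapply(images, as_xy)
  empties <- vapply(images, nrow, 1L) == 0
  if (any(empties))
    warning("image(s) ", paste(which(empties), collapse = ", "),
            " have zero points; their distribution functions are ",
            "identically zero")
  if (center)
    images <- lapply(images, function(p)
      if (nrow(p) == 0) p else center_points(p)$points)
  pooled <- do.call(rbind, images)
  if (nrow(pooled) == 0) stop("all images are empty")
  grid <- grid_spec(make_box(pooled, margin), N)

  pooled_cells <- assign_cells(pooled, grid)
  per_image_cells <- lapply(images, assign_cells, grid = grid)

  space <- paste0("batch-", next_space_id())
  Nc <- grid$N
  pooled_models <- matrix(vector("list", Nc^2), Nc, Nc)
  dfs <- lapply(images, function(p)
    matrix(vector("list", Nc^2), Nc, Nc))
  for (i in seq_len(Nc)) {
    for (j in seq_len(Nc)) {
      rect <- c(grid$xs[i], grid$xs[i + 1], grid$ys[j], grid$ys[j + 1])
      gm <- cell_model(pooled_cells[[i, j]], rect, eps0 = eps0,
                       single_point_delta = single_point_delta,
                       delta_min_frac = delta_min_frac)
      pooled_models[[i, j]] <- gm
      for (b in seq_along(images)) {
        sub <- per_image_cells[[b]][[i, j]]
        nb <- nrow(sub)
        dfs[[b]][[i, j]] <- if (nb == 0) {
          structure(list(count = 0L, centroid = NULL, Sigma = NULL,
                         Sigma_inv = NULL, provenance = "empty"),
                    class = "cell_model")
        } else {
          ctr <- if (global_centers) gm$centroid
                 else c(mean(sub$x), mean(sub$y))
          structure(list(count = nb, centroid = ctr, Sigma = gm$Sigma,
                         Sigma_inv = gm$Sigma_inv,
                         provenance = gm$provenance),
                    class = "cell_model")
        }
      }
    }
  }
  labels <- names(images)
  if (is.null(labels)) labels <- paste0("image", seq_along(images))
  dfuns <- lapply(seq_along(images), function(b)
    new_dfun(grid, dfs[[b]], labels[b], nrow(images[[b]]), space))
  names(dfuns) <- labels
  structure(list(grid = grid, pooled = pooled_models, dfs = dfuns),
            class = "df_batch")
}

#' @export
print.df_batch <- function(x, ...) {
  cat(sprintf("df_batch: %d distribution functions on a shared %dx%d grid\n",
              length(x$dfs), x$grid$N, x$grid$N))
  for (d in x$dfs)
    cat(sprintf("  %-14s %6d points\n", d$label, d$n))
  invisible(x)
}

#' Evaluate a distribution function
#'
#' @param object A `dfun`.
#' @param newdata Data frame with columns `x`, `y` (or an n x 2 matrix).
#' @param ... Unused.
#' @return Numeric vector \eqn{\Phi(z)} at each row of `newdata`.
#' @export
predict.dfun <- function(object, newdata, ...) {
  if (is.numeric(newdata) && is.null(dim(newdata)) && length(newdata) == 2)
    newdata <- data.frame(x = newdata[1], y = newdata[2])
  z <- as_xy(newdata)
  zm <- cbind(z$x, z$y)
  out <- numeric(nrow(zm))
  for (m in object$cells) {
    if (m$provenance == "empty") next
    out <- out + m$count * evaluate_kernel(m, zm)
  }
  out
}

#' @export
print.dfun <- function(x, ...) {
  occ <- sum(vapply(x$cells, function(m) m$count > 0, logical(1)))
  cat(sprintf("dfun '%s': %d points on a %dx%d grid (%d occupied cells)\n",
              if (is.null(x$label)) "" else x$label,
              x$n, x$grid$N, x$grid$N, occ))
  invisible(x)
}

#' Rasterize a distribution function
#'
#' Evaluates \eqn{\Phi} on a `resolution` x `resolution` lattice over the
#' grid box; useful for heat maps of the fiber-type distribution.
#'
#' @param df A `dfun`.
#' @param resolution Pixels per side (positive integer).
#' @return Matrix of \eqn{\Phi} values with `x`/`y` coordinate attributes
#'   (rows index x, columns index y, as for [graphics::image()]).
#' @export
render_df_map <- function(df, resolution = 100L) {
  if (length(resolution) != 1L || !is.finite(resolution) || resolution < 1)
    stop("`resolution` must be a positive integer")
  resolution <- as.integer(resolution)
  g <- df$grid
  xs <- seq(g$a, g$A, length.out = resolution)
  ys <- seq(g$b, g$B, length.out = resolution)
  pts <- expand.grid(x = xs, y = ys)
  z <- matrix(predict(df, pts), resolution, resolution)
  attr(z, "x") <- xs
  attr(z, "y") <- ys
  z
}

#' @export
plot.dfun <- function(x, resolution = 100L, ...) {
  z <- render_df_map(x, resolution)
  graphics::image(attr(z, "x"), attr(z, "y"), z, xlab = "x", ylab = "y",
                  main = if (is.null(x$label)) "distribution function"
                         else x$label,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE), ...)
  invisible(z)
}
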