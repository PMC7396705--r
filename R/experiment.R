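shape_names <- c("ball", "ring", "sum", "cross")

shape_pairs <- function() {
  data.frame(a = c("ring", "ring", "ring", "ball", "ball", "cross"),
             b = c("ball", "cross", "sum", "cross", "sum", "sum"))
}

# One sub-seed per (shape, Q) cell so any single table entry can be
# regenerated in isolation: seed(shape, Q) = master + 100 * q_index +
# shape_index (ball = 1, ring = 2, sum = 3, cross = 4).
shape_seed <- function(master_seed, q_index, shape) {
  as.integer(master_seed) + 100L * as.integer(q_index) +
    match(shape, shape_names)
}

#' Run the synthetic-shape dissimilarity experiment
#'
#' For each point count `Q`, generates the four validation geometries
#' (ball, ring, sum, cross) on a square of side `L` with band width
#' `delta`, builds their distribution functions in one shared batch (all
#' four in one inner-product space per `Q`), and computes distance and
#' angle for the six shape pairs. This is the experiment that checks the
#' dissimilarity quantifiers can tell apart deliberately challenging
#' geometries.
#'
#' @param Q_list Point counts drawn on the square before filtering
#'   (default `c(500, 1000, 2000, 3000, 4000)`).
#' @param L Side of the generation square (default 1; the quantifiers'
#'   angles are invariant to `L` through the Mahalanobis kernels).
#' @param delta Band parameter (default `L/9`).
#' @param N Grid size (default 11).
#' @param seed Master seed; per-(shape, Q) sub-seeds are derived from it.
#' @param batch_scope `"collection"` (default): the four shapes of one `Q`
#'   are built in a single batch and all pairs compared inside it.
#'   `"pair"`: each pair gets its own two-image batch.
#' @param ... Passed to [synth_shape()] (e.g. `ring_literal`).
#' @return A `comparison_table` data frame with columns `pair`, `Q`,
#'   `distance`, `angle`, `normalized_distance`; `summary()` adds the
#'   per-pair mean and standard error rows.
#' @examples
#' tab <- run_synthetic_experiment(Q_list = c(500, 1000), seed = 1)
#' summary(tab)
#' @export
run_synthetic_experiment <- function(Q_list = c(500L, 1000L, 2000L, 3000L,
                                                4000L),
                                     L = 1, delta = L / 9, N = 11L,
                                     seed = 1L,
                                     batch_scope = c("collection", "pair"),
                                     ...) {
  batch_scope <- match.arg(batch_scope)
  if (length(Q_list) == 0 || any(Q_list < 1))
    stop("`Q_list` must be a nonempty vector of positive counts")
  pairs <- shape_pairs()
  rows <- list()
  for (qi in seq_along(Q_list)) {
    Q <- Q_list[qi]
    sets <- lapply(shape_names, function(s)
      synth_shape(s, Q = Q, L = L, delta = delta,
                  seed = shape_seed(seed, qi, s), ...))
    names(sets) <- shape_names
    if (batch_scope == "collection") {
      batch <- build_batch(sets, N = N)
      for (p in seq_len(nrow(pairs))) {
        dd <- dissimilarity(batch$dfs[[pairs$a[p]]],
                            batch$dfs[[pairs$b[p]]])
        rows[[length(rows) + 1L]] <-
          data.frame(pair = paste(pairs$a[p], "vs", pairs$b[p]), Q = Q,
                     distance = dd$distance, angle = dd$angle,
                     normalized_distance = dd$normalized_distance)
      }
    } else {
      for (p in seq_len(nrow(pairs))) {
        batch <- build_batch(sets[c(pairs$a[p], pairs$b[p])], N = N)
        dd <- dissimilarity(batch$dfs[[1]], batch$dfs[[2]])
        rows[[length(rows) + 1L]] <-
          data.frame(pair = paste(pairs$a[p], "vs", pairs$b[p]), Q = Q,
                     distance = dd$distance, angle = dd$angle,
                     normalized_distance = dd$normalized_distance)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("comparison_table", "data.frame")
  out
}

sem <- function(x) stats::sd(x) / sqrt(length(x))

#' @export
summary.comparison_table <- function(object, ...) {
  sp <- split(as.data.frame(object), object$pair)
  out <- do.call(rbind, lapply(names(sp), function(nm) {
    d <- sp[[nm]]
    data.frame(pair = nm,
               mean_distance = mean(d$distance), sem_distance = sem(d$distance),
               mean_angle = mean(d$angle), sem_angle = sem(d$angle))
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.comparison_table <- function(x, digits = 2, ...) {
  df <- as.data.frame(x)
  df$distance <- round(df$distance, digits)
  df$angle <- round(df$angle, digits)
  df$normalized_distance <- round(df$normalized_distance, 4)
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}

#' Correlate dissimilarity quantifiers with point-set size
#'
#' Pearson correlation of distance vs `Q` and angle vs `Q` per shape pair,
#' reported as \eqn{r^2} with the correlation-test p-value. Distances are
#' expected to grow nearly linearly with the number of points, while
#' angles stabilize (no significant trend).
#'
#' @param table A `comparison_table` from [run_synthetic_experiment()]
#'   with at least 3 sizes per pair.
#' @return Data frame with one row per pair: `r2_distance`, `p_distance`,
#'   `r2_angle`, `p_angle`.
#' @export
correlate_with_size <- function(table) {
  sp <- split(as.data.frame(table), table$pair)
  out <- do.call(rbind, lapply(names(sp), function(nm) {
    d <- sp[[nm]]
    if (nrow(d) < 3) stop("need at least 3 sizes per pair (", nm, ")")
    if (stats::sd(d$distance) == 0 || stats::sd(d$angle) == 0 ||
        stats::sd(d$Q) == 0)
      stop("correlation undefined for constant series (", nm, ")")
    td <- stats::cor.test(d$distance, d$Q)
    ta <- stats::cor.test(d$angle, d$Q)
    data.frame(pair = nm,
               r2_distance = unname(td$estimate)^2,
               p_distance = td$p.value,
               r2_angle = unname(ta$estimate)^2,
               p_angle = ta$p.value)
  }))
  rownames(out) <- NULL
  out
}

#' Two-group comparison with a normality screen
#'
#' Screens each group for normality with a Kolmogorov–Smirnov-type test
#' (Lilliefors correction for estimated parameters); if both groups pass
#' at the screening level, an unpaired Student's t-test is used, otherwise
#' the Mann–Whitney rank test. Groups with fewer than 5 values (or zero
#' spread) fall through to the rank test, since the normality screen is
#' uninformative there.
#'
#' @param values_a,values_b Numeric vectors, each with at least 3 values.
#' @param alpha Significance level (default 0.05).
#' @return A `group_comparison` list: `test`, `statistic`, `p.value`,
#'   `significant`, and a per-group summary (mean, SEM, n, normality p).
#' @export
compare_groups <- function(values_a, values_b, alpha = 0.05) {
  if (length(values_a) < 3 || length(values_b) < 3)
    stop("each group needs at least 3 values")
  norm_p <- function(x) {
    if (length(x) < 5 || stats::sd(x) == 0) return(NA_real_)
    nortest::lillie.test(x)$p.value
  }
  pa <- norm_p(values_a)
  pb <- norm_p(values_b)
  normal <- !is.na(pa) && !is.na(pb) && pa > alpha && pb > alpha
  res <- if (normal)
    stats::t.test(values_a, values_b, var.equal = FALSE)
  else
    suppressWarnings(stats::wilcox.test(values_a, values_b, exact = FALSE,
                                        correct = FALSE))
  structure(list(
    test = if (normal) "Student t (unpaired)" else "Mann-Whitney",
    statistic = unname(res$statistic),
    p.value = res$p.value,
    significant = res$p.value <= alpha,
    alpha = alpha,
    groups = data.frame(
      group = c("a", "b"),
      n = c(length(values_a), length(values_b)),
      mean = c(mean(values_a), mean(values_b)),
      sem = c(sem(values_a), sem(values_b)),
      normality_p = c(pa, pb))),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (%ssignificant at %.2g)\n",
              x$test, x$statistic, x$p.value,
              if (x$significant) "" else "not ", x$alpha))
  g <- x$groups
  for (k in 1:2)
    cat(sprintf("  group %s: mean %.4g +/- %.4g SEM (n = %d)\n",
                g$group[k], g$mean[k], g$sem[k], g$n[k]))
  invisible(x)
}

#' Read a fiber coordinate table
#'
#' Delimited text with header `x,y,label`; labels name fiber types
#' (typically `slow`, `intermediate`, `fast`).
#'
#' @param file Path to a CSV file.
#' @param allowed Allowed label set; `NULL` skips the check.
#' @return Data frame with columns `x`, `y`, `label`.
#' @export
read_fiber_csv <- function(file,
                           allowed = c("slow", "intermediate", "fast")) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("x", "y", "label") %in% names(d)))
    stop("file ", file, " must have columns x, y, label")
  if (!is.null(allowed)) {
    bad <- which(!(d$label %in% allowed))
    if (length(bad))
      stop(sprintf("unknown fiber label '%s' in %s (row %d)",
                   d$label[bad[1]], file, bad[1]))
  }
  d
}

#' Intra-fascicle fiber-type analysis
#'
#' For each fascicle coordinate table: builds the distribution functions
#' of all fiber types present in one shared batch and reports the
#' pairwise dissimilarity quantifiers; and fits the generalized fractal
#' law to each type's rasterized binary image. Fiber types with fewer
#' than `min_fractal` fibers are excluded from the fractal analysis (too
#' few points for a meaningful correlation curve — in practice this drops
#' the scarce slow fibers).
#'
#' Because histological sections carry no anatomical orientation, only
#' within-fascicle comparisons are produced; cross-animal statistics
#' should be run on these quantifiers with [compare_groups()].
#'
#' @param files Character vector of CSV paths (see [read_fiber_csv()]), or
#'   a list of data frames with columns `x`, `y`, `label`.
#' @param N Grid size for the distribution functions (default 11).
#' @param min_fractal Minimum fiber count for fractal analysis
#'   (default 30).
#' @param pixel_size,i_max Passed to [rasterize_points()] and
#'   [correlation_curve()].
#' @return List with data frames `dissimilarity` (fascicle, pair, d,
#'   angle, normalized D) and `fractal` (fascicle, label, n, a, D, c,
#'   r2_star, verdict).
#' @export
run_fiber_analysis <- function(files, N = 11L, min_fractal = 30L,
                               pixel_size = NULL, i_max = NULL) {
  if (is.character(files)) {
    nms <- if (!is.null(names(files))) names(files) else basename(files)
    data <- lapply(files, read_fiber_csv)
    names(data) <- nms
  } else {
    data <- files
    if (is.null(names(data)))
      names(data) <- paste0("fascicle", seq_along(data))
  }
  diss <- list()
  frac <- list()
  for (nm in names(data)) {
    d <- data[[nm]]
    types <- split(d[c("x", "y")], d$label)
    if (length(types) >= 2) {
      batch <- build_batch(types, N = N)
      cmb <- utils::combn(names(types), 2)
      for (k in seq_len(ncol(cmb))) {
        dd <- dissimilarity(batch$dfs[[cmb[1, k]]], batch$dfs[[cmb[2, k]]])
        diss[[length(diss) + 1L]] <-
          data.frame(fascicle = nm,
                     pair = paste(cmb[1, k], "vs", cmb[2, k]),
                     distance = dd$distance, angle = dd$angle,
                     normalized_distance = dd$normalized_distance)
      }
    }
    for (ty in names(types)) {
      pts <- types[[ty]]
      if (nrow(pts) < min_fractal) next
      img <- rasterize_points(pts, pixel_size)
      fit <- fit_fractal(correlation_curve(img, i_max))
      co <- coef(fit)
      frac[[length(frac) + 1L]] <-
        data.frame(fascicle = nm, label = ty, n = nrow(pts),
                   a = co[["a"]], D = co[["D"]], c = co[["c"]],
                   r2_star = fit$r2_star, verdict = fit$verdict)
    }
  }
  list(dissimilarity = if (length(diss)) do.call(rbind, diss) else NULL,
       fractal = if (length(frac)) do.call(rbind, frac) else NULL)
}
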