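test_that("centering and box construction follow the definitions", {
  ctr <- center_points(data.frame(x = 3, y = 4))
  expect_equal(ctr$centroid, c(3, 4))
  expect_equal(unlist(ctr$points), c(x = 0, y = 0))

  sym <- center_points(data.frame(x = c(-1, 1), y = c(0, 0)))
  expect_equal(sym$points$x, c(-1, 1))
  expect_equal(sym$centroid, c(0, 0))

  set.seed(1)
  p <- random_cloud(1000)
  out <- center_points(p)$points
  expect_lt(abs(mean(out$x)), 1e-9)
  expect_lt(abs(mean(out$y)), 1e-9)

  box <- make_box(data.frame(x = c(-1, 1), y = c(-0.5, 0.5)), margin = 0.1)
  expect_equal(unname(box), c(-1.1, 1.1, -0.6, 0.6))
  box1 <- make_box(data.frame(x = 0, y = 0), margin = 0.5)
  expect_equal(unname(box1), c(-0.5, 0.5, -0.5, 0.5))
  expect_true(min(p$x) > make_box(p)["a"] && max(p$x) < make_box(p)["A"])
  expect_error(make_box(p, margin = 0), "positive")
  expect_error(center_points(p[0, ]), "empty")
})

test_that("cell assignment partitions the box with the lower-index tie rule", {
  set.seed(2)
  p <- random_cloud(500)
  g <- grid_spec(make_box(p), N = 11)
  cells <- assign_cells(p, g)
  expect_equal(sum(vapply(cells, nrow, 1L)), 500)

  g1 <- grid_spec(c(a = 0, A = 1, b = 0, B = 1), N = 1)
  expect_equal(nrow(assign_cells(p / 3 + 0.5, g1)[[1, 1]]), 500)

  g2 <- grid_spec(c(a = 0, A = 1, b = 0, B = 1), N = 2)
  onedge <- assign_cells(data.frame(x = 0.5, y = 0.25), g2)
  expect_equal(nrow(onedge[[1, 1]]), 1)  # x = (a+A)/2 goes to the lower cell
  expect_error(assign_cells(data.frame(x = 2, y = 0.5), g2), "outside")
})

test_that("cell models reproduce hand-computed covariances", {
  cell <- c(-2, 2, -2, 2)
  m <- cell_model(data.frame(x = c(0, 1, 0), y = c(0, 0, 1)), cell)
  expect_equal(m$provenance, "regular")
  expect_equal(m$centroid, c(1 / 3, 1 / 3))
  expect_equal(m$Sigma,
               matrix(c(1 / 3, -1 / 6, -1 / 6, 1 / 3), 2, 2))

  # collinear pair: singular sample covariance -> spectral regularization
  m2 <- cell_model(data.frame(x = c(-1, 1), y = c(0, 0)), cell)
  expect_equal(m2$provenance, "regularized")
  expect_equal(m2$Sigma, matrix(c(1, 0, 0, 1 / 9), 2, 2))
  ev <- eigen(m2$Sigma, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(ev, c(1, 1 / 9))

  # empty cell contributes the zero function
  m0 <- cell_model(data.frame(x = numeric(0), y = numeric(0)), cell)
  expect_equal(m0$provenance, "empty")
  expect_equal(evaluate_kernel(m0, c(0, 0)), 0)

  # coincident points fall back to the single-point rule
  mc <- cell_model(data.frame(x = c(0.5, 0.5), y = c(0.5, 0.5)), cell)
  expect_equal(mc$provenance, "single_point")
  expect_equal(mc$count, 2L)
})

test_that("single-point cells use the (delta/3)^2 identity covariance", {
  cell <- c(0, 1, 0, 1)
  zp <- c(0.2, 0.6)
  m <- cell_model(data.frame(x = zp[1], y = zp[2]), cell)
  delta <- 0.2  # nearest edge
  expect_equal(m$Sigma, diag(2) * (delta / 3)^2)
  z <- c(0.35, 0.7)
  expect_equal(evaluate_kernel(m, z),
               exp(-9 / 2 * sum((z - zp)^2) / delta^2))

  # literal reading: max of the two upper-edge gaps against x_p
  ml <- cell_model(data.frame(x = zp[1], y = zp[2]), cell,
                   single_point_delta = "literal")
  expect_equal(ml$Sigma, diag(2) * (0.8 / 3)^2)

  # boundary point: configurable floor keeps the kernel definable
  mb <- cell_model(data.frame(x = 0, y = 0.5), cell)
  expect_equal(mb$Sigma, diag(2) * (1e-3 / 3)^2)
})

test_that("kernel evaluation is a Mahalanobis Gaussian", {
  m <- cell_model(data.frame(x = c(0, 2, 0, 2), y = c(0, 0, 2, 2)),
                  c(-3, 3, -3, 3))
  expect_equal(evaluate_kernel(m, m$centroid), 1)
  # identity covariance at distance sqrt(2) -> exp(-1)
  ms <- structure(list(count = 1L, centroid = c(0, 0), Sigma = diag(2),
                       Sigma_inv = diag(2), provenance = "regular"),
                  class = "cell_model")
  expect_equal(evaluate_kernel(ms, c(1, 1)), exp(-1))
  # strictly decreasing along rays from the centroid
  for (ang in c(0.3, 1.2, 2.5, 4.4)) {
    u <- c(cos(ang), sin(ang))
    vals <- evaluate_kernel(m, t(sapply(seq(0.1, 3, 0.1),
                                        function(t) m$centroid + t * u)))
    expect_true(all(diff(vals) < 0))
  }
})

test_that("distribution functions conserve weight and match brute force", {
  set.seed(3)
  p <- random_cloud(400)
  p <- center_points(p)$points
  g <- grid_spec(make_box(p), N = 11)
  df <- build_distribution(p, g)
  expect_equal(sum(vapply(df$cells, function(m) m$count, 1L)), 400L)

  z <- as.matrix(random_cloud(200, radius = 0.9))
  expect_equal(predict(df, z), brute_force_phi(df, z), tolerance = 1e-10)

  # all points in one cell: Phi at the cell centroid equals the count
  q <- data.frame(x = rnorm(25, 0, 0.01), y = rnorm(25, 0, 0.01))
  g1 <- grid_spec(c(a = -1, A = 1, b = -1, B = 1), N = 1)
  df1 <- build_distribution(q, g1)
  expect_equal(predict(df1, df1$cells[[1, 1]]$centroid), 25)
})

test_that("kernel evaluations are invariant to global rescaling", {
  set.seed(4)
  p <- center_points(random_cloud(300))$points
  s <- 57.3
  g <- grid_spec(make_box(p, margin = 0.05), N = 7)
  gs <- grid_spec(make_box(p * s, margin = 0.05 * s), N = 7)
  df <- build_distribution(p, g)
  dfs <- build_distribution(p * s, gs)
  z <- as.matrix(random_cloud(100, 0.8))
  expect_equal(predict(df, z), predict(dfs, z * s), tolerance = 1e-9)
})

test_that("batch construction pools covariances and reduces correctly", {
  set.seed(5)
  a <- random_cloud(200)
  b <- random_cloud(150, radius = 0.7)
  batch <- build_batch(list(a = a, b = b), N = 11)
  counts <- vapply(batch$dfs$a$cells, function(m) m$count, 1L)
  expect_equal(sum(counts), 200L)
  expect_equal(sum(vapply(batch$dfs$b$cells, function(m) m$count, 1L)), 150L)

  # two identical images -> identical DFs, zero distance, zero angle
  batch2 <- build_batch(list(x = a, y = a), N = 11)
  expect_equal(df_distance(batch2$dfs$x, batch2$dfs$y), 0)
  expect_equal(df_angle(batch2$dfs$x, batch2$dfs$y), 0)

  # r = 2 in one cell: shared covariance equals pooled sample covariance
  p1 <- data.frame(x = c(0.1, 0.2), y = c(0.1, 0.3))
  p2 <- data.frame(x = c(-0.2, 0.05, 0.15), y = c(0.0, -0.25, 0.2))
  bb <- build_batch(list(p1, p2), N = 1, center = FALSE, margin = 0.5)
  pooled <- rbind(p1, p2)
  expect_equal(bb$pooled[[1, 1]]$Sigma, unname(cov(pooled)))
  expect_equal(bb$dfs[[1]]$cells[[1, 1]]$Sigma, unname(cov(pooled)))
  # per-image kernels centered at the image's own cell centroid
  expect_equal(bb$dfs[[1]]$cells[[1, 1]]$centroid,
               c(mean(p1$x), mean(p1$y)))

  expect_error(build_batch(list(a), N = 5), "at least two")
  expect_warning(build_batch(list(a, a[0, ]), N = 5), "zero points")
})
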