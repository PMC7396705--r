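test_that("rasterization anchors at the minimum and preserves points", {
  one <- rasterize_points(data.frame(x = 0, y = 0), pixel_size = 1)
  expect_equal(dim(one), c(3, 3))
  expect_equal(sum(one), 1)

  # collision-free grid of points -> one pixel each
  g <- expand.grid(x = seq(0, 4), y = seq(0, 3))
  img <- rasterize_points(g, pixel_size = 0.9)
  expect_equal(sum(img), nrow(g))
  expect_equal(attr(img, "collisions"), 0)

  shifted <- rasterize_points(g + 17.3, pixel_size = 0.9)
  expect_identical(unclass(img), unclass(shifted))

  two <- rasterize_points(data.frame(x = c(0, 0.1), y = c(0, 0)),
                          pixel_size = 1)
  expect_equal(attr(two, "collisions"), 1)
  expect_error(rasterize_points(g, pixel_size = -1), "positive")
})

test_that("correlation curve counts windows correctly", {
  # single set pixel: N == 1 at every scale
  img1 <- matrix(FALSE, 9, 9); img1[5, 5] <- TRUE
  c1 <- correlation_curve(img1, i_max = 4)
  expect_equal(c1$N, rep(1, 4))
  expect_equal(c1$epsilon, c(3, 5, 7, 9))

  # two pixels at Chebyshev distance 2: seen at eps = 5, not at eps = 3
  img2 <- matrix(FALSE, 11, 11); img2[5, 5] <- TRUE; img2[7, 7] <- TRUE
  c2 <- correlation_curve(img2, i_max = 3)
  expect_equal(c2$N, c(1, 2, 2))

  # fully set image with border clipping: closed-form mean count
  w <- 8
  full <- matrix(TRUE, w, w)
  c3 <- correlation_curve(full, i_max = 2)
  mean_width <- function(h) mean(sapply(1:w, function(x)
    min(x + h, w) - max(x - h, 1) + 1))
  expect_equal(c3$N, c(mean_width(1)^2, mean_width(2)^2))
  # interior pixels see the full 3x3 window
  expect_lt(c3$N[1], 9)

  # summed-area counting equals the naive nested-loop oracle
  set.seed(10)
  rnd <- matrix(runif(30 * 25) < 0.2, 30, 25)
  rnd[1, 1] <- TRUE
  expect_equal(correlation_curve(rnd, i_max = 6)$N,
               brute_force_curve(rnd, 6))

  # monotone and bounded below by the self-count under clipping
  cr <- correlation_curve(rnd, i_max = 10)
  expect_true(all(diff(cr$N) >= 0))
  expect_true(all(cr$N >= 1))

  expect_error(correlation_curve(matrix(FALSE, 4, 4)), "no set pixels")
})

test_that("power-law fit recovers noiseless parameters exactly", {
  eps <- seq(3, 41, by = 2)
  fit <- fit_fractal(data.frame(epsilon = eps, N = 2 * eps^1.5 + 3))
  expect_equal(unname(coef(fit)), c(2, 1.5, 3), tolerance = 1e-6)
  expect_equal(fit$r2_star, 1, tolerance = 1e-9)
  expect_equal(predict(fit, 9), 2 * 9^1.5 + 3, tolerance = 1e-5)

  sfit <- fit_fractal(data.frame(epsilon = eps, N = eps^1.2 + 5),
                      model = "simplified")
  expect_equal(coef(sfit)[["a"]], 1)
  expect_equal(coef(sfit)[["D"]], 1.2, tolerance = 1e-6)
  expect_equal(coef(sfit)[["c"]], 5, tolerance = 1e-4)

  # nested models: generalized SSE never exceeds simplified SSE
  set.seed(11)
  for (k in 1:5) {
    N <- runif(1, 0.5, 3) * eps^runif(1, 0.8, 2) + rnorm(length(eps), 0, 2)
    curve <- data.frame(epsilon = eps, N = N)
    expect_lte(sum(residuals(fit_fractal(curve))^2),
               sum(residuals(fit_fractal(curve, "simplified"))^2) + 1e-8)
  }
})

test_that("degenerate and limiting images give the expected dimensions", {
  # one pixel: flat curve, D = 0, a + c = 1
  img1 <- matrix(FALSE, 9, 9); img1[5, 5] <- TRUE
  f1 <- fit_fractal(correlation_curve(img1, i_max = 4))
  expect_lt(coef(f1)[["D"]], 0.1)
  expect_equal(coef(f1)[["a"]] + coef(f1)[["c"]], 1)

  # dense filled raster at window sizes well inside the frame: D near 2
  fd <- fit_fractal(correlation_curve(matrix(TRUE, 600, 600), i_max = 10))
  expect_lt(abs(coef(fd)[["D"]] - 2), 0.05)
  expect_gt(fd$r2_star, 0.99)

  # uniform random scatter filling a region behaves like D in (1.6, 2]
  set.seed(12)
  sc <- matrix(runif(150 * 150) < 0.3, 150, 150)
  fs <- fit_fractal(correlation_curve(sc, i_max = 10))
  expect_gt(coef(fs)[["D"]], 1.6)
  expect_lte(coef(fs)[["D"]], 2.05)
})

test_that("Sierpinski carpet dimension is recovered in the scaling regime", {
  carpet <- sierpinski_carpet(4)
  fit <- fit_fractal(correlation_curve(carpet, i_max = 8,
                                       border = "interior"))
  expect_lt(abs(coef(fit)[["D"]] - log(8) / log(3)), 0.1)
  expect_gt(fit$r2_star, 0.99)
  expect_equal(fit$verdict, "fractal")
})

test_that("fit quality is the correlation ratio of the two curves", {
  eps <- seq(3, 21, 2)
  obs <- 1.4 * eps^1.7 + 2
  expect_equal(fit_quality(obs, data.frame(N = obs)), 1)
  # invariant under positive affine maps of the estimate
  expect_equal(fit_quality(3 * obs + 7, data.frame(N = obs)), 1)
  expect_error(fit_quality(rep(1, 5), data.frame(N = obs[1:5])),
               "zero variance")
})

test_that("the pre-form factor gates the fractality verdict", {
  eps <- seq(3, 21, 2)
  mk <- function(a) fit_fractal(data.frame(epsilon = eps,
                                           N = a * eps^1.5 + 1))
  expect_equal(classify_fractal(mk(0.22))$verdict, "fractal")
  expect_equal(classify_fractal(mk(0.05))$verdict, "not_confirmed")
  expect_equal(classify_fractal(mk(4.5))$verdict, "not_confirmed")
  expect_match(mk(0.5)$interpretation, "clusters")
  expect_error(classify_fractal(fit_fractal(
    data.frame(epsilon = eps, N = eps^1.5 + 1), "simplified")),
    "generalized")
})
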