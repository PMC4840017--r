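test_that("piecewise-linear interpolation is exact where it should be", {
  grid <- scalp_grid2d(32, extent = 50)
  # channels placed exactly on pixel centers
  px <- grid$x[c(8, 8, 24, 24, 16)]
  py <- grid$y[c(8, 24, 8, 24, 16)]
  xy <- cbind(px, py)
  w <- c(1, 2, 3, 4, 10)
  img <- interp2d_linear(xy, w, grid)
  at_channel <- match(paste(px, py), paste(grid$xy[, 1], grid$xy[, 2]))
  expect_equal(img$values[at_channel], w, tolerance = 1e-12)
  # constant data give a constant image inside the hull
  imgc <- interp2d_linear(xy, rep(5, 5), grid)
  expect_equal(unique(round(imgc$values[imgc$mask], 9)), 5)
  # affine data are reproduced exactly at every interior pixel
  f <- function(x, y) 0.3 * x - 0.7 * y + 2
  imga <- interp2d_linear(xy, f(px, py), grid)
  expect_lt(max(abs(imga$values[imga$mask] -
                      f(grid$xy[imga$mask, 1], grid$xy[imga$mask, 2]))),
            1e-9)
  # range bound from barycentric convexity
  set.seed(51)
  wr <- rnorm(5)
  imgr <- interp2d_linear(xy, wr, grid)
  expect_gte(min(imgr$values, na.rm = TRUE), min(wr) - 1e-12)
  expect_lte(max(imgr$values, na.rm = TRUE), max(wr) + 1e-12)
  # linear operator in w
  w2 <- rnorm(5)
  lhs <- interp2d_linear(xy, 2 * wr - 3 * w2, grid)$values
  rhs <- 2 * imgr$values - 3 * interp2d_linear(xy, w2, grid)$values
  expect_equal(lhs, rhs, tolerance = 1e-9)
  # collinear channels cannot be triangulated
  expect_error(interp2d_linear(cbind(1:4, 2 * (1:4)), 1:4, grid),
               "triangulation")
})

test_that("the interpolation operator reproduces direct interpolation", {
  geo <- standard_geometry()
  op <- interp_operator_2d(geo$xy, geo$grid)
  set.seed(52)
  w <- rnorm(52)
  img <- interp2d_linear(geo$xy, w, geo$grid)
  expect_equal(op$mask, img$mask)
  expect_equal((op$P %*% w)[op$mask], img$values[img$mask],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("Gaussian smoothing preserves constants and matches the kernel", {
  expect_equal(fwhm_to_sigma(14), 5.9447, tolerance = 1e-4)
  grid <- scalp_grid2d(64, extent = 63)   # pixel size 2 mm
  n <- 64
  # constant image unchanged inside an irregular mask
  mask <- sqrt(rowSums(sweep(grid$xy, 2, c(10, -5))^2)) < 40
  img <- contrast_image("grid2d", ifelse(mask, 7, NA), mask, grid)
  sm <- smooth_gaussian(img, 14)
  expect_lt(max(abs(sm$values[mask] - 7)), 1e-8)
  # centered unit impulse on a full mask matches the sampled Gaussian
  vals <- numeric(n * n); vals[(32 - 1) * n + 32] <- 1
  full <- contrast_image("grid2d", vals, rep(TRUE, n * n), grid)
  smi <- smooth_gaussian(full, 14)
  sig <- fwhm_to_sigma(14) / grid$pixel_size
  h <- ceiling(4 * sig)
  k1 <- dnorm(seq(-h, h), sd = sig); k1 <- k1 / sum(k1)
  ii <- ((seq_len(n * n) - 1) %% n) + 1
  jj <- ((seq_len(n * n) - 1) %/% n) + 1
  expected <- ifelse(abs(ii - 32) <= h & abs(jj - 32) <= h,
                     k1[pmax(1, abs(ii - 32) + h + 1)] *
                       k1[pmax(1, abs(jj - 32) + h + 1)], 0)
  expected[abs(ii - 32) > h | abs(jj - 32) > h] <- 0
  expect_lt(max(abs(smi$values - expected)), 1e-6)
  expect_equal(sum(smi$values), 1, tolerance = 1e-6)
  expect_error(smooth_gaussian(full, -1), "fwhm")
})

test_that("the spherical-spline kernel matches high-precision summation", {
  # truncation control
  expect_lt(abs(spline_g(0.3, 4, tol = 1e-12) -
                  spline_g(0.3, 4, tol = 1e-15)), 1e-11)
  # oracle: direct 500-term sums at the endpoints where P_n(+-1) = +-1
  n <- 1:500
  g1 <- sum((2 * n + 1) / (n * (n + 1))^4) / (4 * pi)
  gm1 <- sum((-1)^n * (2 * n + 1) / (n * (n + 1))^4) / (4 * pi)
  expect_equal(spline_g(1, 4, tol = 1e-15), g1, tolerance = 1e-12)
  expect_equal(spline_g(-1, 4, tol = 1e-15), gm1, tolerance = 1e-12)
  expect_error(spline_g(0.5, m = 1), "diverges")
})

test_that("spherical splines reproduce channel data exactly", {
  set.seed(53)
  # constant data: offset carries everything, kernel coefficients vanish
  dirs <- random_sphere_dirs(12)
  mc <- fit_spherical_spline(dirs, rep(3.5, 12))
  expect_equal(mc$k0, 3.5, tolerance = 1e-8)
  expect_lt(max(abs(mc$k)), 1e-6)
  # random data, J = 10: reproduction and oracle equality
  dirs <- random_sphere_dirs(10)
  w <- rnorm(10)
  m <- fit_spherical_spline(dirs, w)
  expect_lt(max(abs(eval_spherical_spline(m, dirs) - w)), 1e-8)
  # independent dense solve of the augmented system
  G <- matrix(spline_g(tcrossprod(dirs)), 10)
  A <- rbind(cbind(G, 1), c(rep(1, 10), 0))
  sol <- qr.solve(A, c(w, 0))
  expect_equal(m$k, sol[1:10], tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(m$k0, sol[11], tolerance = 1e-9, ignore_attr = TRUE)
  # zero-sum constraint
  expect_lt(abs(sum(m$k)), 1e-10)
  # a kernel-free model is constant everywhere
  m0 <- m; m0$k <- rep(0, 10); m0$k0 <- 2
  pts <- random_sphere_dirs(30)
  expect_equal(eval_spherical_spline(m0, pts), rep(2, 30))
  expect_error(fit_spherical_spline(rbind(dirs, dirs[1, ]), c(w, 1)),
               "duplicate")
  expect_error(eval_spherical_spline(m, 2 * pts), "unit-norm")
})

test_that("spline interpolation is rotation-equivariant and linear", {
  set.seed(54)
  dirs <- random_sphere_dirs(15)
  w <- rnorm(15)
  pts <- random_sphere_dirs(40)
  v0 <- eval_spherical_spline(fit_spherical_spline(dirs, w), pts)
  Rm <- rotation_matrix(c(1, 2, -1), 0.83)
  v1 <- eval_spherical_spline(fit_spherical_spline(dirs %*% t(Rm), w),
                              pts %*% t(Rm))
  expect_equal(v1, v0, tolerance = 1e-9)
  # linearity in the data
  w2 <- rnorm(15)
  lhs <- eval_spherical_spline(fit_spherical_spline(dirs, 2 * w - w2), pts)
  rhs <- 2 * v0 - eval_spherical_spline(fit_spherical_spline(dirs, w2), pts)
  expect_equal(lhs, rhs, tolerance = 1e-9)
})

test_that("grid and mesh images of one smooth field agree", {
  geo <- standard_geometry()
  mesh <- make_canonical_mesh(3, radius = geo$proj$head_radius)
  # a smooth underlying field sampled at the channels
  f <- function(d) 2 * d[, 1] + d[, 2] - 0.5 * d[, 3]
  w <- f(geo$proj$dirs)
  img2 <- contrast_image_2d(w, geo$xy, geo$grid, fwhm = 14,
                            mask = geo$mask2d)
  mask3 <- make_search_mask(mesh, geo$proj, 30)
  img3 <- contrast_image_mesh(w, geo$proj, mesh, mask = mask3)
  # co-locate mesh vertices on the grid through the disc projection
  vin <- which(mask3 & mesh$vertices[, 3] > -0.9)
  vxy <- project_channels_disc(mesh$vertices[vin, ],
                               geo$proj$head_radius)
  pix <- cbind(findInterval(vxy[, 1], geo$grid$x + geo$grid$pixel_size / 2) + 1,
               findInterval(vxy[, 2], geo$grid$y + geo$grid$pixel_size / 2) + 1)
  ok <- pix[, 1] >= 1 & pix[, 1] <= 64 & pix[, 2] >= 1 & pix[, 2] <= 64
  idx <- (pix[ok, 2] - 1) * 64 + pix[ok, 1]
  pairs <- cbind(img3$values[vin[ok]], img2$values[idx])
  pairs <- pairs[stats::complete.cases(pairs), ]
  expect_gt(nrow(pairs), 100)
  expect_gt(cor(pairs[, 1], pairs[, 2]), 0.9)
})
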