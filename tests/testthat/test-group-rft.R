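make_images <- function(W, values_mask, grid) {
  lapply(seq_len(nrow(W)), function(n)
    contrast_image("grid2d", ifelse(values_mask, W[n, ], NA), values_mask,
                   grid, paste0("s", n)))
}

test_that("stacking intersects masks and validates inputs", {
  grid <- scalp_grid2d(16, extent = 20)
  V <- 16 * 16
  m1 <- rep(TRUE, V)
  m2 <- m1; m2[1:30] <- FALSE
  set.seed(71)
  i1 <- contrast_image("grid2d", rnorm(V), m1, grid, "a")
  i2 <- contrast_image("grid2d", ifelse(m2, rnorm(V), NA), m2, grid, "b")
  st <- stack_contrasts(list(i1, i2))
  expect_equal(st$mask, m1 & m2)
  expect_equal(nrow(st$W), 2)
  st_same <- stack_contrasts(list(i1, i1))
  expect_equal(st_same$mask, m1)
  expect_error(stack_contrasts(list(i1)), "at least 2")
  mesh <- make_canonical_mesh(1)
  i3 <- contrast_image("mesh3d", rnorm(42), rep(TRUE, 42), mesh, "c")
  expect_error(stack_contrasts(list(i1, i3)), "mix")
})

test_that("the second-level fit is the classical one-sample t-test", {
  set.seed(72)
  W <- matrix(rnorm(8 * 50), 8, 50)
  fit <- fit_second_level(W)
  tt <- apply(W, 2, function(x) mean(x) / (sd(x) / sqrt(8)))
  expect_equal(fit$T, tt, tolerance = 1e-10)
  expect_equal(fit$dof, 7)
  # N = 21 cohort: 20 degrees of freedom
  expect_equal(fit_second_level(matrix(rnorm(21 * 5), 21, 5))$dof, 20)
  # identical subjects: zero variance flagged, not crashed
  W0 <- matrix(2, 6, 3)
  f0 <- fit_second_level(W0)
  expect_true(all(is.na(f0$T)))
  expect_equal(f0$beta[1, ], rep(2, 3))
  expect_error(fit_second_level(matrix(1:4, 2, 2),
                                group_design(cbind(1, c(0, 1)), c(1, 0))),
               "more subjects")
})

test_that("Bonferroni thresholds match t quantiles", {
  expect_equal(round(bonferroni_threshold(0.02, 52, 20), 2), 3.96)
  expect_equal(round(bonferroni_threshold(0.05, 52, 20), 2), 3.57)
  expect_equal(bonferroni_threshold(0.05, 1, 20), qt(0.95, 20))
})

test_that("EC densities follow the closed forms and decrease in t", {
  expect_equal(ec_density(0, 20, 0), 0.5)
  expect_equal(ec_density(3.96, 20, 0), pt(3.96, 20, lower.tail = FALSE),
               tolerance = 1e-10)
  # direct transcription of the closed forms as oracle
  rho1 <- function(t, v) sqrt(4 * log(2)) / (2 * pi) *
    (1 + t^2 / v)^(-(v - 1) / 2)
  rho2 <- function(t, v) 4 * log(2) / (2 * pi)^1.5 *
    exp(lgamma((v + 1) / 2) - lgamma(v / 2)) / sqrt(v / 2) * t *
    (1 + t^2 / v)^(-(v - 1) / 2)
  expect_equal(ec_density(2.7, 20, 1), rho1(2.7, 20), tolerance = 1e-12)
  expect_equal(ec_density(3, 20, 2), rho2(3, 20), tolerance = 1e-12)
  expect_gt(ec_density(3, 20, 2), ec_density(4, 20, 2))
  expect_error(ec_density(2, 20, 3), "unsupported")
})

smoothed_noise_images <- function(n_img, n, grid, fwhm, seed) {
  set.seed(seed)
  sig <- fwhm_to_sigma(fwhm) / grid$pixel_size
  h <- ceiling(4 * sig)
  k <- dnorm(seq(-h, h), sd = sig); k <- k / sum(k)
  sm <- function(X) {
    X <- apply(X, 2, function(cc)
      convolve(c(numeric(h), cc, numeric(h)), k, type = "filter"))
    t(apply(t(X), 2, function(cc)
      convolve(c(numeric(h), cc, numeric(h)), k, type = "filter")))
  }
  t(sapply(seq_len(n_img), function(i)
    as.vector(sm(matrix(rnorm(n * n), n, n)))))
}

test_that("resel counts scale with mask area at fixed smoothness", {
  grid <- scalp_grid2d(64, extent = 63)
  R <- smoothed_noise_images(60, 64, grid, 12, seed = 73)
  idx <- matrix(seq_len(64 * 64), 64, 64)
  m1 <- rep(FALSE, 64 * 64); m1[idx[17:32, 17:48]] <- TRUE
  m2 <- rep(FALSE, 64 * 64); m2[idx[17:48, 17:48]] <- TRUE   # double area
  r1 <- estimate_smoothness(R, m1, grid)
  r2 <- estimate_smoothness(R, m2, grid)
  expect_equal(r2$resels[["R2"]] / r1$resels[["R2"]], 2, tolerance = 0.05)
  # simply-connected masks have Euler characteristic 1
  expect_equal(r1$resels[["R0"]], 1)
  expect_equal(r2$resels[["R0"]], 1)
  expect_error(estimate_smoothness(matrix(1, 5, 10), rep(TRUE, 10), grid),
               "constant residuals")
})

test_that("RFT thresholds and p-values are mutually consistent", {
  res <- structure(list(fwhm = c(20, 20), resels = c(R0 = 1, R1 = 2, R2 = 2.5),
                        search_volume = 1000, area_per_location = 1),
                   class = "resel_info")
  # single-test limit
  r0 <- structure(list(fwhm = c(20, 20), resels = c(1, 0, 0),
                       search_volume = 1, area_per_location = 1),
                  class = "resel_info")
  expect_equal(rft_peak_threshold(0.05, r0, 20), qt(0.95, 20),
               tolerance = 1e-5)
  # independent bisection via uniroot over the same EC sum
  ec_sum <- function(t) ec_density(t, 20, 0) + 2 * ec_density(t, 20, 1) +
    2.5 * ec_density(t, 20, 2)
  oracle <- uniroot(function(t) ec_sum(t) - 0.05, c(1, 20),
                    tol = 1e-10)$root
  expect_equal(rft_peak_threshold(0.05, res, 20), oracle,
               tolerance = 1e-6)
  # monotone in alpha
  expect_gt(rft_peak_threshold(0.01, res, 20),
            rft_peak_threshold(0.05, res, 20))
  # inverse pair
  tc <- rft_peak_threshold(0.05, res, 20)
  expect_equal(peak_pvalue(tc, res, 20), 0.05, tolerance = 1e-6)
  expect_equal(peak_pvalue(4, res, 20), ec_sum(4), tolerance = 1e-12)
  expect_lt(peak_pvalue(50, res, 20), 1e-10)
})

test_that("clusters are labelled correctly and ranked by extent", {
  grid <- scalp_grid2d(32, extent = 31)
  V <- 32 * 32
  idx <- matrix(seq_len(V), 32, 32)
  tmap <- rep(0, V)
  blob1 <- idx[5:8, 5:8]          # 16 pixels
  blob2 <- idx[20:25, 20:22]      # 18 pixels
  tmap[blob1] <- 5
  tmap[blob2] <- 4.5
  res <- structure(list(fwhm = c(10, 10), resels = c(R0 = 1, R1 = 3, R2 = 5),
                        search_volume = V,
                        area_per_location = grid$pixel_size^2),
                   class = "resel_info")
  cl <- cluster_inference(tmap, 3.5, res, 20, grid)
  expect_equal(nrow(cl), 2)
  expect_setequal(cl$k_E, c(16, 18))
  expect_true(all(cl$p_fwe > 0 & cl$p_fwe <= 1))
  # p decreases with extent at fixed threshold
  big <- rep(0, V); big[idx[5:20, 5:20]] <- 5
  cl_big <- cluster_inference(big, 3.5, res, 20, grid)
  small <- rep(0, V); small[idx[5:7, 5:7]] <- 5
  cl_small <- cluster_inference(small, 3.5, res, 20, grid)
  expect_lt(cl_big$p_fwe, cl_small$p_fwe)
  # empty excursion set
  expect_equal(nrow(cluster_inference(rep(0, V), 3.5, res, 20, grid)), 0)
})

test_that("group inference orchestrates both correction routes", {
  geo <- standard_geometry()
  truth <- simulation_truth()
  W <- simulate_channel_contrasts(truth, geo$layout, N = 12, seed = 74)
  # bonferroni route delegates to the channel threshold
  infb <- run_group_inference(method = "bonferroni", channel_w = W,
                              alpha = 0.02)
  expect_equal(infb$T_c, bonferroni_threshold(0.02, 52, 11))
  expect_equal(infb$dof, 11)
  expect_equal(nrow(infb$channel_table), 52)
  # rft route returns resels, peaks and clusters coherently
  imgs <- lapply(1:12, function(n)
    contrast_image_2d(W[n, ], geo$xy, geo$grid, 14, geo$mask2d,
                      paste0("s", n)))
  infr <- run_group_inference(imgs, alpha = 0.05)
  expect_s3_class(infr$resels, "resel_info")
  expect_true(all(infr$peaks$T >= infr$T_c))
  tab <- results_table(infr)
  expect_true(all(c("RESELS", "T_c", "k_E", "peak_p_FWE") %in% names(tab)))
  f <- file.path(tempdir(), "res.tsv")
  write_results_table(infr, f)
  expect_true(file.exists(f))
})
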