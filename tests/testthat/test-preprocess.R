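test_that("motion correction is a no-op on clean data and repairs spikes", {
  set.seed(21)
  x <- as.numeric(stats::filter(rnorm(800, sd = 0.1), 0.5,
                                method = "recursive"))
  hb <- make_hb(x)
  out <- correct_motion(hb, window = 1, threshold = Inf)
  expect_identical(out$hb$hbo, hb$hbo)
  expect_equal(nrow(out$segments), 0)
  # all-constant series: zero moving SD, nothing flagged
  outc <- correct_motion(make_hb(rep(2, 300)), 1, 3)
  expect_identical(outc$hb$hbo, make_hb(rep(2, 300))$hbo)
  expect_equal(nrow(outc$segments), 0)
  # flat-ish signal plus a large transient spike
  clean <- x
  spike_at <- 400
  artifact <- numeric(800)
  artifact[spike_at + (0:9)] <- 10 * stats::sd(clean) * exp(-(0:9) / 2)
  dirty <- make_hb(clean + artifact)
  fixed <- correct_motion(dirty, window = 1, threshold = 3)
  expect_gt(nrow(fixed$segments), 0)
  covered <- any(fixed$segments$start_s <= (spike_at - 1) / 10 &
                   fixed$segments$end_s >= (spike_at - 1) / 10)
  expect_true(covered)
  expect_lt(max(abs(fixed$hb$hbo[, 1] - clean)),
            max(abs(dirty$hbo[, 1] - clean)))
  # untouched samples are bit-identical
  w <- round(1 * 10)
  seg_idx <- unlist(lapply(seq_len(nrow(fixed$segments)), function(k)
    (fixed$segments$start_s[k] * 10 + 1):(fixed$segments$end_s[k] * 10 + 1)))
  untouched <- setdiff(seq_len(800), seg_idx)
  expect_identical(fixed$hb$hbo[untouched, 1], dirty$hbo[untouched, 1])
  expect_error(correct_motion(make_hb(rnorm(5)), window = 10),
               "longer than series")
})

test_that("band-stop filtering removes stopband tones and preserves DC", {
  fs <- 10; M <- 6000; t <- (0:(M - 1)) / fs
  # DC preserved
  out <- bandstop_physio(make_hb(rep(3, M), fs))
  expect_lt(max(abs(out$hbo - 3)), 1e-8)
  # 1 Hz (cardiac band) strongly attenuated; oracle from the designed
  # filter's frequency response at 1 Hz
  bt <- signal::butter(5, c(0.7, 2.0) / 5, type = "stop")
  H <- function(f) {
    z <- exp(-1i * 2 * pi * f / fs * (seq_along(bt$b) - 1))
    abs(sum(bt$b * z) / sum(bt$a * z))
  }
  gain2pass <- H(1)^2         # forward-backward squares the magnitude
  x <- sin(2 * pi * 1 * t)
  y <- bandstop_physio(make_hb(x, fs))$hbo
  ratio <- sqrt(mean(y^2)) / sqrt(mean(x^2))
  expect_lt(ratio, 0.05)
  expect_lt(abs(ratio - gain2pass), 0.05)
  # 0.05 Hz (task band) passes within 5%
  x <- sin(2 * pi * 0.05 * t)
  y <- bandstop_physio(make_hb(x, fs))$hbo
  expect_lt(abs(sqrt(mean(y^2)) / sqrt(mean(x^2)) - 1), 0.05)
  expect_error(bandstop_physio(make_hb(rnorm(500), fs),
                               stopbands = list(c(3, 6))),
               "Nyquist")
})

test_that("DCT high-pass removes slow drift with the standard basis size", {
  # constant series lies in the removed subspace
  out <- dct_highpass(make_hb(rep(4, 500), fs = 1), 1 / 64)
  expect_lt(max(abs(out$hb$hbo)), 1e-8)
  # idempotency
  set.seed(22)
  hb <- make_hb(rnorm(500), fs = 1)
  once <- dct_highpass(hb, 1 / 64)$hb
  twice <- dct_highpass(once, 1 / 64)$hb
  expect_equal(twice$hbo, once$hbo, tolerance = 1e-10)
  # basis size: frequency of regressor k is k / (2 M dt)
  b <- dct_highpass(make_hb(rnorm(600), fs = 1), 1 / 64)$basis
  expect_equal(ncol(b), floor(2 * 600 * (1 / 64)) + 1)
  expect_equal(crossprod(b), diag(ncol(b)), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("downsampling preserves the passband and suppresses aliases", {
  fs <- 10; M <- 6000; t <- (0:(M - 1)) / fs
  out <- downsample_hb(make_hb(rep(2.5, M), fs), 1)
  expect_equal(nrow(out$hbo), M / 10)
  expect_lt(max(abs(out$hbo - 2.5)), 1e-6)
  expect_equal(out$fs, 1)
  # 0.1 Hz amplitude preserved within 2% (projection-based estimate)
  x <- sin(2 * pi * 0.1 * t)
  y <- as.numeric(downsample_hb(make_hb(x, fs), 1)$hbo)
  td <- t[seq(1, M, 10)]
  amp <- sqrt(sum(coef(lm(y ~ sin(2 * pi * 0.1 * td) +
                            cos(2 * pi * 0.1 * td) - 1))^2))
  expect_lt(abs(amp - 1), 0.02)
  # above the target Nyquist must vanish
  x <- sin(2 * pi * 4.9 * t)
  y <- as.numeric(downsample_hb(make_hb(x, fs), 1)$hbo)
  expect_lt(sqrt(mean(y^2)), 0.05)
  expect_error(downsample_hb(make_hb(rnorm(100), fs), 3),
               "not an integer")
})

test_that("AR(1) estimation recovers the generating coefficient", {
  set.seed(23)
  # white noise: estimate within sampling error of zero
  R <- matrix(rnorm(5000 * 10), 5000, 10)
  m <- estimate_ar1(R)
  expect_lt(abs(m$rho), 3 * 2 / sqrt(5000 * 10))
  # known AR(1)
  x <- apply(matrix(rnorm(10000 * 2), ncol = 2), 2, function(z)
    as.numeric(stats::filter(z, 0.7, method = "recursive")))
  m <- estimate_ar1(x)
  expect_lt(abs(m$rho - 0.7), 0.05)
  # whitening removes the modelled correlation
  S <- whitening_matrix(m, nrow(x))
  white <- as.matrix(S %*% x)
  expect_lt(abs(estimate_ar1(white)$rho), 0.05)
  expect_error(estimate_ar1(matrix(1, 100, 2)), "zero-variance")
  expect_error(estimate_ar1(matrix(rnorm(8), 4, 2)), "at least 10")
})

test_that("whitening matrix satisfies S V S' = I", {
  expect_equal(as.matrix(whitening_matrix(list(rho = 0, M = 5))), diag(5),
               ignore_attr = TRUE)
  M <- 6
  V <- 0.5^abs(outer(1:M, 1:M, "-"))
  S <- whitening_matrix(list(rho = 0.5, M = M))
  expect_equal(as.matrix(S %*% V %*% Matrix::t(S)), diag(M),
               tolerance = 1e-10, ignore_attr = TRUE)
  # whitened AR(1) noise has near-zero lag-1 autocorrelation
  set.seed(24)
  Mlen <- 4000
  x <- as.numeric(stats::filter(rnorm(Mlen), 0.6, method = "recursive"))
  w <- as.numeric(whitening_matrix(list(rho = 0.6, M = Mlen)) %*% x)
  r1 <- cor(w[-1], w[-Mlen])
  expect_lt(abs(r1), 3 / sqrt(Mlen))
  expect_error(whitening_matrix(list(rho = 1.2, M = 5)), "rho")
})

test_that("preprocessing is linear, channel-independent, and kills zero", {
  fs <- 10; M <- 1500
  set.seed(25)
  X <- matrix(rnorm(M * 2), M, 2)
  hb2 <- hb_series(X, -X, fs)
  joint <- bandstop_physio(hb2)
  sep1 <- bandstop_physio(hb_series(X[, 1, drop = FALSE],
                                    -X[, 1, drop = FALSE], fs))
  expect_equal(joint$hbo[, 1], sep1$hbo[, 1], tolerance = 1e-12)
  # zero in, zero out through the full chain
  z <- preprocess_hb(hb_series(matrix(0, M, 2), matrix(0, M, 2), fs))
  expect_true(all(z$hb$hbo == 0))
  # band-stop and DCT high-pass approximately commute: both are linear
  # and (away from the series ends) shift-invariant; the commutator is
  # bounded by finite-length edge effects, so compare away from the ends
  # relative to the signal scale
  t <- (0:(M - 1)) / fs
  x <- sin(2 * pi * 0.03 * t) + 0.5 * sin(2 * pi * 0.08 * t)
  hbs <- hb_series(matrix(x), matrix(-x), fs)
  a <- dct_highpass(bandstop_physio(hbs), 1 / 64)$hb$hbo
  b <- bandstop_physio(dct_highpass(hbs, 1 / 64)$hb)$hbo
  mid <- 300:(M - 300)
  expect_lt(max(abs(a[mid, ] - b[mid, ])) / stats::sd(x), 1e-3)
})
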