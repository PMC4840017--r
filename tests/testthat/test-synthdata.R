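test_that("event simulation matches the Stroop session design", {
  ev <- simulate_events(seed = 81)
  expect_equal(nrow(ev), 100)
  expect_equal(sum(ev$condition == "congruent"), 80)
  expect_equal(sum(ev$condition == "incongruent"), 20)
  isi <- diff(ev$onset)
  expect_true(all(isi >= 9 - 1e-9 & isi <= 12 + 1e-9))
  expect_identical(simulate_events(seed = 81), ev)
  expect_false(identical(simulate_events(seed = 82), ev))
})

test_that("noiseless subjects carry exactly the scaled HRF", {
  lay <- default_probe_layout()
  truth <- simulation_truth(active_channels = "CH10",
                            effect_size = c(a = 2), sigma_w = 0,
                            sigma_b = 0, physio = list())
  ev <- event_table(5, 0, "a")
  sub <- simulate_subject(truth, lay, ev, fs = 10, duration = 60,
                          seed = 81)
  hrf <- canonical_hrf(0.1)
  expected <- numeric(600)
  expected[51 + seq_along(hrf) - 1] <- 2 * hrf
  expect_equal(sub$hb$hbo[, 10], expected, tolerance = 1e-10)
  expect_true(all(sub$hb$hbo[, -10] == 0))
  expect_error(simulate_subject(truth, lay, ev, fs = 10, duration = 20),
               "shorter")
})

test_that("generated noise has the requested AR(1) structure", {
  lay <- default_probe_layout()
  truth <- simulation_truth(rho = 0.3, sigma_w = 1, sigma_b = 0,
                            physio = list())
  ev <- event_table(numeric(0), numeric(0), character(0))
  sub <- simulate_subject(truth, lay, ev, fs = 10, duration = 1000,
                          seed = 83)
  x <- sub$hb$hbo[, 1:5]
  m <- estimate_ar1(x)
  expect_lt(abs(m$rho - 0.3), 0.05)
})

test_that("null effects average to zero across subjects", {
  lay <- default_probe_layout()
  truth <- simulation_truth(sigma_w = 0.3, sigma_b = 0.5)
  W <- simulate_channel_contrasts(truth, lay, N = 100, seed = 84)
  mu <- colMeans(W)
  se <- apply(W, 2, sd) / sqrt(100)
  # pooled CLT bound across all channels, plus a Bonferroni-adjusted
  # per-channel bound over the 52 simultaneous checks
  expect_lt(abs(mean(W)), 3 * sd(W) / sqrt(length(W)))
  expect_true(all(abs(mu) < 4.6 * se))
})

test_that("between-subject variance decomposes as the two-level model", {
  lay <- default_probe_layout()
  # with within-subject noise off, the contrast variance approaches
  # sigma_b^2
  t0 <- simulation_truth(sigma_w = 0, sigma_b = 0.5)
  W <- simulate_channel_contrasts(t0, lay, N = 200, seed = 85)
  expect_equal(mean(apply(W, 2, var)), 0.25, tolerance = 0.2 * 0.25)
  # and with both sources on, variances add
  t1 <- simulation_truth(sigma_w = 0.3, sigma_b = 0.4)
  W1 <- simulate_channel_contrasts(t1, lay, N = 200, seed = 86)
  expect_equal(mean(apply(W1, 2, var)), 0.09 + 0.16,
               tolerance = 0.15 * 0.25)
})

test_that("group simulation is reproducible from the master seed", {
  lay <- default_probe_layout()
  truth <- simulation_truth(sigma_w = 0.2, sigma_b = 0.1)
  g1 <- simulate_group(truth, lay, N = 2, fs = 5, n_freq = 3, n_rare = 1,
                       seed = 87)
  g2 <- simulate_group(truth, lay, N = 2, fs = 5, n_freq = 3, n_rare = 1,
                       seed = 87)
  expect_identical(g1$subjects[[1]]$hb$hbo, g2$subjects[[1]]$hb$hbo)
  expect_identical(g1$subjects[[2]]$events, g2$subjects[[2]]$events)
  # distinct subjects differ
  expect_false(identical(g1$subjects[[1]]$hb$hbo,
                         g1$subjects[[2]]$hb$hbo))
})

test_that("the full pipeline recovers a known focal effect", {
  # reduced-scale end-to-end run: time series -> preprocessing -> GLM ->
  # interpolation -> group fit, with ground truth known
  geo <- standard_geometry()
  lay <- geo$layout
  ctr <- colMeans(geo$xy)
  act <- lay$channel_ids[order(rowSums(sweep(geo$xy, 2, ctr)^2))[1:3]]
  truth <- simulation_truth(active_channels = act,
                            effect_size = c(congruent = 1, incongruent = 1),
                            sigma_w = 0.2, sigma_b = 0.15, rho = 0.3)
  N <- 6
  grp <- simulate_group(truth, lay, N = N, fs = 10, n_freq = 10,
                        n_rare = 5, isi_range = c(9, 12), seed = 88)
  cons <- matrix(NA_real_, N, 52)
  true_w <- matrix(NA_real_, N, 52)
  for (n in seq_len(N)) {
    s <- grp$subjects[[n]]
    fl <- first_level_pipeline(
      s$hb, s$events, c(congruent.canonical = 1),
      preprocess = preprocess_config(target_fs = 2),
      basis = "canonical", subject_id = s$subject_id)
    cons[n, ] <- fl$contrast$w
    true_w[n, ] <- s$w[, "congruent"]
  }
  ai <- match(act, lay$channel_ids)
  # channel-level recovery: estimated group effect within 2 SE of the
  # true population effect at every active channel
  for (k in ai) {
    se_k <- sd(cons[, k]) / sqrt(N)
    expect_lt(abs(mean(cons[, k]) - 1), 2 * se_k + 0.1)
  }
  # inactive channels stay near zero
  expect_lt(mean(abs(colMeans(cons)[-ai])), 0.15)
  imgs <- lapply(seq_len(N), function(n)
    contrast_image_2d(cons[n, ], geo$xy, geo$grid, 14, geo$mask2d,
                      paste0("s", n)))
  st <- stack_contrasts(imgs)
  fit <- fit_second_level(st)
  # the group mask covers all active channels
  act_xy <- geo$xy[ai, , drop = FALSE]
  act_pix <- apply(act_xy, 1, function(p)
    which.min((geo$grid$xy[, 1] - p[1])^2 + (geo$grid$xy[, 2] - p[2])^2))
  expect_true(all(st$mask[act_pix]))
  # at image level the smoothed focus dominates distant inactive scalp
  focus <- act_pix[2]
  far <- which.max(rowSums(sweep(geo$grid$xy, 2, colMeans(act_xy))^2) *
                     as.numeric(st$mask))
  expect_gt(fit$beta[1, focus], fit$beta[1, far] + 0.3)
})
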