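#' Default 52-channel prefrontal probe layout
#'
#' Builds the standard 3 x 11 optode array used by multichannel
#' prefrontal fNIRS systems: 17 sources and 16 detectors in a
#' checkerboard, 3 cm apart, giving 52 channels (midpoints of adjacent
#' source-detector pairs: 30 horizontal + 22 vertical). The band is
#' laid out on a spherical head surface along three latitude rows
#' centered on the forehead, with the column step sized so the middle
#' row has the nominal optode spacing.
#'
#' @param head_radius Scalp sphere radius, mm.
#' @param head_center Sphere center (MNI mm).
#' @param separation Optode spacing, cm.
#' @param mid_polar Polar angle of the middle optode row, degrees from
#'   the vertex (default 70, a band across the forehead).
#' @return A [probe_layout()] with 52 channels.
#' @export
default_probe_layout <- function(head_radius = 90, head_center = c(0, 0, 0),
                                 separation = 3, mid_polar = 70) {
  sp_mm <- separation * 10
  dtheta <- sp_mm / head_radius
  rows <- 3; cols <- 11
  theta_mid <- mid_polar * pi / 180
  dphi <- dtheta / sin(theta_mid)   # column step sized at the middle row
  pos <- matrix(0, rows * cols, 3)
  type <- character(rows * cols)
  rc <- matrix(0L, rows * cols, 2)
  k <- 0
  for (r in seq_len(rows)) for (cc in seq_len(cols)) {
    k <- k + 1
    theta <- theta_mid + (r - 2) * dtheta
    phi <- pi / 2 + (cc - (cols + 1) / 2) * dphi   # centered anterior (+y)
    pos[k, ] <- head_center + head_radius *
      c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
    type[k] <- if ((r + cc) %% 2 == 0) "source" else "detector"
    rc[k, ] <- c(r, cc)
  }
  src_idx <- which(type == "source"); det_idx <- which(type == "detector")
  find_opt <- function(r, cc) which(rc[, 1] == r & rc[, 2] == cc)
  pairs <- NULL
  for (r in seq_len(rows)) for (cc in seq_len(cols - 1)) {
    a <- find_opt(r, cc); b <- find_opt(r, cc + 1)
    pairs <- rbind(pairs, c(a, b))
  }
  for (r in seq_len(rows - 1)) for (cc in seq_len(cols)) {
    a <- find_opt(r, cc); b <- find_opt(r + 1, cc)
    pairs <- rbind(pairs, c(a, b))
  }
  # orient each pair as (source, detector)
  sd_pairs <- t(apply(pairs, 1, function(p)
    if (type[p[1]] == "source") p else rev(p)))
  probe_layout(
    source_pos = pos[src_idx, , drop = FALSE],
    detector_pos = pos[det_idx, , drop = FALSE],
    channel_pairs = cbind(match(sd_pairs[, 1], src_idx),
                          match(sd_pairs[, 2], det_idx)),
    channel_ids = paste0("CH", seq_len(nrow(sd_pairs))),
    separation = separation)
}

#' Ground truth for synthetic multi-subject simulations
#'
#' Describes the generative model mirrored from the two-level summary
#' -statistics scheme: a population effect on a set of active channels,
#' between-subject effect variability, within-subject noise (AR(1) plus
#' sinusoidal physiology), and the event design scale.
#'
#' @param active_channels Channel labels carrying the effect.
#' @param effect_size Named vector of effect amplitudes per condition
#'   (contrast units), applied at active channels.
#' @param sigma_w Within-subject noise SD: the marginal SD of the AR(1)
#'   noise in time-series simulation, and the SD of the first-level
#'   estimation error in contrast-level simulation.
#' @param sigma_b Between-subject effect SD (applied at every channel).
#' @param spatial_scale Spatial correlation length (mm) of the
#'   between-subject deviations over the channel array: 0 (default)
#'   draws them independently per channel, a positive value draws them
#'   from a Gaussian process with squared-exponential covariance
#'   `sigma_b^2 exp(-d^2 / (2 scale^2))` over channel distances,
#'   emulating spatially coherent anatomical/vascular variability.
#' @param rho AR(1) coefficient of the temporal noise.
#' @param physio List of `c(amplitude, frequency_hz)` sinusoidal
#'   components (cardiac and respiratory defaults sit inside the
#'   standard band-stop stopbands).
#' @param seed Master seed.
#' @return A list of class `simulation_truth`.
#' @export
simulation_truth <- function(active_channels = character(),
                             effect_size = c(congruent = 1, incongruent = 1),
                             sigma_w = 0.3, sigma_b = 0.5, rho = 0.3,
                             spatial_scale = 0,
                             physio = list(cardiac = c(amplitude = 0.2,
                                                       frequency = 1.1),
                                           respiratory = c(amplitude = 0.3,
                                                           frequency = 0.25)),
                             seed = 1L) {
  stopifnot(sigma_w >= 0, sigma_b >= 0, abs(rho) < 1, spatial_scale >= 0)
  structure(list(active_channels = active_channels,
                 effect_size = effect_size, sigma_w = sigma_w,
                 sigma_b = sigma_b, rho = rho,
                 spatial_scale = spatial_scale, physio = physio,
                 seed = seed),
            class = "simulation_truth")
}

#' Simulate an event sequence
#'
#' Randomized ordering of frequent and rare events (80 and 20 by
#' default, mirroring a congruent/incongruent Stroop session) with
#' inter-stimulus intervals drawn uniformly from `isi_range`.
#'
#' @param n_freq,n_rare Event counts for the two conditions.
#' @param isi_range Inter-stimulus interval range, seconds.
#' @param labels Condition labels, frequent first.
#' @param start Onset of the first event, seconds.
#' @param seed Optional seed for reproducibility.
#' @return An [event_table()].
#' @export
simulate_events <- function(n_freq = 80, n_rare = 20,
                            isi_range = c(9, 12),
                            labels = c("congruent", "incongruent"),
                            start = 10, seed = NULL) {
  stopifnot(n_freq >= 0, n_rare >= 0, isi_range[1] < isi_range[2])
  if (!is.null(seed)) set.seed(seed)
  n <- n_freq + n_rare
  cond <- sample(c(rep(labels[1], n_freq), rep(labels[2], n_rare)))
  isi <- stats::runif(n, isi_range[1], isi_range[2])
  onsets <- start + cumsum(c(0, isi[-n]))
  event_table(onsets, rep(0, n), cond)
}

# Cholesky factor of the between-subject spatial covariance (unit
# variance); identity when the correlation length is zero.
spatial_chol <- function(layout, spatial_scale) {
  J <- nrow(layout$channel_pos)
  if (is.null(spatial_scale) || spatial_scale <= 0) return(NULL)
  D <- as.matrix(stats::dist(layout$channel_pos))
  K <- exp(-D^2 / (2 * spatial_scale^2))
  chol(K + diag(1e-8, J))
}

draw_zn <- function(layout, truth, n_draws) {
  J <- nrow(layout$channel_pos)
  L <- spatial_chol(layout, truth$spatial_scale)
  Z <- matrix(stats::rnorm(J * n_draws), J, n_draws)
  if (!is.null(L)) Z <- crossprod(L, Z)
  truth$sigma_b * Z
}

ar1_noise <- function(M, J, rho, marginal_sd) {
  innov_sd <- marginal_sd * sqrt(1 - rho^2)
  e <- matrix(stats::rnorm(M * J, sd = innov_sd), M, J)
  apply(e, 2, function(z)
    as.numeric(stats::filter(z, rho, method = "recursive")))
}

#' Simulate one subject's hemoglobin time series
#'
#' Generative mirror of the within-subject GLM: each condition's event
#' train is convolved with the canonical hemodynamic response and scaled
#' by the subject effect `w_n = w_pop + z_n` (population effect on
#' active channels plus between-subject deviation `z_n ~ N(0,
#' sigma_b^2)` at every channel), then AR(1) noise at marginal SD
#' `sigma_w` and fixed-frequency sinusoidal physiology with
#' subject-random phase are added. HbR is generated as an inverted,
#' scaled copy of the HbO signal with its own noise.
#'
#' @param truth A [simulation_truth()].
#' @param layout A [probe_layout()].
#' @param events An [event_table()].
#' @param fs Sampling rate, Hz (default 10).
#' @param duration Recording length, seconds (default: last onset +
#'   32 s); must cover the last event plus the response.
#' @param zn Optional J x n_conditions matrix of between-subject
#'   deviations (drawn when `NULL`).
#' @param seed Optional seed.
#' @return List: `hb` ([hb_series()]), `w` (J x n_conditions true
#'   subject effects), `events`.
#' @export
simulate_subject <- function(truth, layout, events, fs = 10,
                             duration = NULL, zn = NULL, seed = NULL) {
  stopifnot(inherits(truth, "simulation_truth"),
            inherits(layout, "probe_layout"))
  if (!is.null(seed)) set.seed(seed)
  need <- if (nrow(events)) max(events$onset) + 32 else 32
  if (is.null(duration)) duration <- need
  if (duration < need)
    stop("duration ", duration, " s shorter than last event + 32 s (",
         need, " s)", call. = FALSE)
  M <- round(duration * fs)
  J <- nrow(layout$channel_pos)
  conds <- names(truth$effect_size)
  hrf <- canonical_hrf(1 / fs)
  active <- layout$channel_ids %in% truth$active_channels
  if (is.null(zn)) zn <- draw_zn(layout, truth, length(conds))
  w <- matrix(0, J, length(conds), dimnames = list(layout$channel_ids,
                                                   conds))
  signal <- matrix(0, M, J)
  for (ci in seq_along(conds)) {
    ev <- events[events$condition == conds[ci], , drop = FALSE]
    stick <- numeric(M)
    if (nrow(ev)) stick[pmin(M, floor(ev$onset * fs) + 1)] <- 1
    reg <- stats::convolve(c(stick, numeric(length(hrf))), rev(hrf),
                           type = "open")[seq_len(M)]
    w[, ci] <- ifelse(active, truth$effect_size[ci], 0) + zn[, ci]
    signal <- signal + outer(reg, w[, ci])
  }
  noise <- ar1_noise(M, J, truth$rho, truth$sigma_w)
  t_s <- (seq_len(M) - 1) / fs
  physio <- matrix(0, M, J)
  for (p in truth$physio) {
    phase <- stats::runif(J, 0, 2 * pi)
    physio <- physio + p[["amplitude"]] *
      sin(outer(2 * pi * p[["frequency"]] * t_s, phase, "+"))
  }
  hbo <- signal + noise + physio
  hbr <- -0.4 * signal + ar1_noise(M, J, truth$rho, 0.5 * truth$sigma_w) -
    0.4 * physio
  list(hb = hb_series(hbo, hbr, fs, layout$channel_ids), w = w,
       events = events)
}

#' Simulate a multi-subject group
#'
#' N independent subjects sharing the population effect, each with its
#' own randomized event sequence, between-subject effect deviation and
#' noise, generated from per-subject substreams of the master seed.
#'
#' @param truth A [simulation_truth()].
#' @param layout A [probe_layout()].
#' @param N Number of subjects (default 21).
#' @param fs Sampling rate, Hz.
#' @param n_freq,n_rare,isi_range Event design passed to
#'   [simulate_events()].
#' @param seed Master seed (default from `truth`).
#' @return List of class `simulated_group`: `subjects` (each with `hb`,
#'   `events`, `w`), `truth`, `layout`, `seed`.
#' @export
simulate_group <- function(truth, layout, N = 21, fs = 10,
                           n_freq = 80, n_rare = 20, isi_range = c(9, 12),
                           seed = truth$seed) {
  stopifnot(N >= 2)
  subjects <- vector("list", N)
  for (n in seq_len(N)) {
    sub_seed <- seed + 7919L * n
    ev <- simulate_events(n_freq, n_rare, isi_range,
                          names(truth$effect_size)[c(1, min(2, length(truth$effect_size)))],
                          seed = sub_seed)
    subjects[[n]] <- simulate_subject(truth, layout, ev, fs,
                                      seed = sub_seed + 1L)
    subjects[[n]]$subject_id <- sprintf("sub%02d", n)
  }
  structure(list(subjects = subjects, truth = truth, layout = layout,
                 seed = seed),
            class = "simulated_group")
}

#' Simulate channel contrasts directly from the two-level model
#'
#' Draws per-subject channel contrast estimates from the summary
#' -statistics generative model `w_bar_n = w_pop + z_n + e_n`, with
#' `z_n ~ N(0, sigma_b^2)` and `e_n ~ N(0, sigma_w^2)` independent over
#' subjects and channels. This bypasses time-series generation and
#' first-level estimation, which is exactly what the second-level model
#' assumes the first level delivers; it is the natural scale for
#' operating-characteristic simulations of the spatial group inference.
#'
#' @param truth A [simulation_truth()] (`effect_size[1]` is used as the
#'   contrast's population effect at active channels).
#' @param layout A [probe_layout()] (defines channels).
#' @param N Number of subjects.
#' @param seed Optional seed.
#' @return N x J matrix of channel contrasts (columns named by channel).
#' @export
simulate_channel_contrasts <- function(truth, layout, N = 21, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  J <- nrow(layout$channel_pos)
  w_pop <- ifelse(layout$channel_ids %in% truth$active_channels,
                  truth$effect_size[1], 0)
  W <- matrix(rep(w_pop, each = N), N, J) +
    t(draw_zn(layout, truth, N)) +
    matrix(stats::rnorm(N * J, sd = truth$sigma_w), N, J)
  colnames(W) <- layout$channel_ids
  W
}

#' Serialize a simulation truth record as JSON
#'
#' @param truth A [simulation_truth()].
#' @param path Output path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
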