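#' @title Temporal preprocessing of hemoglobin time series
#' @name preprocess
#' @description Motion-artifact reduction, physiological band-stop
#'   filtering, DCT high-pass filtering, downsampling, and AR(1)
#'   whitening. All filters are linear and applied channel-wise.
NULL

#' Preprocessing configuration
#'
#' @param motion_window Moving-SD window, seconds.
#' @param motion_threshold Multiplier on the median moving SD above which
#'   samples are flagged as motion artifact.
#' @param stopbands List of `c(low, high)` Hz pairs for the physiological
#'   band-stop (defaults: Mayer-wave/respiration 0.12-0.35 Hz, cardiac
#'   0.7-2.0 Hz).
#' @param filter_order IIR Butterworth order (applied forward-backward,
#'   so the effective order doubles).
#' @param hp_cutoff DCT high-pass cutoff, Hz.
#' @param target_fs Target sampling rate after decimation, Hz.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(motion_window = 1, motion_threshold = 3,
                              stopbands = list(c(0.12, 0.35), c(0.7, 2.0)),
                              filter_order = 5, hp_cutoff = 1 / 64,
                              target_fs = 1) {
  stopifnot(motion_window > 0, motion_threshold > 0, filter_order >= 1,
            hp_cutoff > 0, target_fs > 0)
  for (b in stopbands)
    if (!(length(b) == 2 && b[1] > 0 && b[1] < b[2]))
      stop("each stopband must be c(low, high) with 0 < low < high",
           call. = FALSE)
  structure(list(motion_window = motion_window,
                 motion_threshold = motion_threshold,
                 stopbands = stopbands, filter_order = filter_order,
                 hp_cutoff = hp_cutoff, target_fs = target_fs),
            class = "preprocess_config")
}

# One causal IIR pass started from steady state at the first sample's
# value: filter(x, steady-state state) = filter(x - x[1], rest) +
# x[1] * DC gain. Exact for constant inputs, C-speed via signal::filter.
iir_pass <- function(b, a, x, dc = sum(b) / sum(a)) {
  x0 <- x[1]
  as.numeric(signal::filter(b, a, x - x0)) + x0 * dc
}

# Zero-phase (forward-backward) IIR filtering of the columns of X with
# odd-reflection end padding; exact for constant inputs.
zero_phase_filter <- function(b, a, X, pad = NULL, dc = sum(b) / sum(a)) {
  X <- as.matrix(X)
  M <- nrow(X)
  if (is.null(pad)) pad <- 3 * (max(length(a), length(b)) - 1)
  pad <- max(1L, min(M - 1L, as.integer(pad)))
  one_pass <- function(x) {
    ext <- c(2 * x[1] - x[(pad + 1):2],
             x,
             2 * x[M] - x[(M - 1):(M - pad)])
    y <- rev(iir_pass(b, a, ext, dc))
    y <- rev(iir_pass(b, a, y, dc))
    y[(pad + 1):(pad + M)]
  }
  apply(X, 2, one_pass)
}

moving_sd <- function(x, w) {
  M <- length(x)
  k <- rep(1 / w, w)
  m1 <- stats::filter(x, k, sides = 2)
  m2 <- stats::filter(x^2, k, sides = 2)
  v <- pmax(m2 - m1^2, 0)
  s <- sqrt(as.numeric(v))
  # extend to the ends with the nearest defined value
  idx <- which(!is.na(s))
  if (length(idx) == 0) return(rep(0, M))
  s[seq_len(idx[1] - 1)] <- s[idx[1]]
  if (idx[length(idx)] < M) s[(idx[length(idx)] + 1):M] <- s[idx[length(idx)]]
  s
}

#' Motion-artifact reduction by moving SD and spline smoothing
#'
#' Flags samples whose moving standard deviation exceeds
#' `threshold` times the channel's median moving SD, groups them into
#' contiguous artifact segments, and replaces each segment by a smoothing
#' -spline fit of the segment, linearly adjusted so the segment end
#' points join the surrounding untouched samples continuously. Samples
#' outside artifact segments are returned unchanged.
#'
#' @param hb An [hb_series()].
#' @param window Moving-SD window, seconds (>= 2 samples).
#' @param threshold Multiplier on the median moving SD.
#' @return A list: `hb` (corrected series) and `segments`, a data.frame
#'   (channel, chromophore, start_s, end_s) of corrected segments.
#' @export
correct_motion <- function(hb, window = 1, threshold = 3) {
  stopifnot(inherits(hb, "hb_series"))
  w <- round(window * hb$fs)
  if (w < 2) stop("motion window must span at least 2 samples", call. = FALSE)
  if (w > nrow(hb$hbo)) stop("motion window longer than series", call. = FALSE)
  segs <- list()
  fix_plane <- function(X, plane) {
    M <- nrow(X)
    for (j in seq_len(ncol(X))) {
      x <- X[, j]
      s <- moving_sd(x, w)
      med <- stats::median(s)
      bad <- if (is.finite(threshold)) s > threshold * med else rep(FALSE, M)
      bad[is.na(bad)] <- FALSE
      if (!any(bad)) next
      r <- rle(bad)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      for (k in which(r$values)) {
        i0 <- starts[k]; i1 <- ends[k]
        idx <- i0:i1
        seg <- x[idx]
        fit <- if (length(idx) >= 8) {
          stats::smooth.spline(idx, seg, df = max(2, length(idx) / 20))$y
        } else {
          rep(stats::median(seg), length(idx))
        }
        # re-join continuously to the neighbouring untouched samples
        left <- if (i0 > 1) x[i0 - 1] else fit[1]
        right <- if (i1 < M) x[i1 + 1] else fit[length(fit)]
        ramp <- seq(left - fit[1], right - fit[length(fit)],
                    length.out = length(fit))
        x[idx] <- fit + ramp
        segs[[length(segs) + 1]] <<- data.frame(
          channel = hb$channel_ids[j], chromophore = plane,
          start_s = (i0 - 1) / hb$fs, end_s = (i1 - 1) / hb$fs)
      }
      X[, j] <- x
    }
    X
  }
  hbo <- fix_plane(hb$hbo, "hbo")
  hbr <- fix_plane(hb$hbr, "hbr")
  segments <- if (length(segs)) do.call(rbind, segs) else
    data.frame(channel = character(), chromophore = character(),
               start_s = numeric(), end_s = numeric())
  list(hb = hb_series(hbo, hbr, hb$fs, hb$channel_ids), segments = segments)
}

#' Write a motion-artifact segment log as TSV
#'
#' @param segments Segment data.frame from [correct_motion()].
#' @param path File path.
#' @export
write_artifact_log <- function(segments, path) {
  utils::write.table(segments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

apply_to_planes <- function(hb, f) {
  hb_series(f(hb$hbo), f(hb$hbr), hb$fs, hb$channel_ids)
}

#' Band-stop filtering of physiological oscillations
#'
#' Zero-phase (forward-backward) Butterworth band-stop filtering, one
#' pass per stopband, removing respiration / Mayer waves and cardiac
#' pulsation while leaving DC and the task band untouched.
#'
#' @param hb An [hb_series()].
#' @param stopbands List of `c(low, high)` Hz pairs.
#' @param order Butterworth order (default 5; doubled effectively by the
#'   forward-backward pass).
#' @return Filtered [hb_series()].
#' @export
bandstop_physio <- function(hb, stopbands = list(c(0.12, 0.35), c(0.7, 2.0)),
                            order = 5) {
  stopifnot(inherits(hb, "hb_series"))
  nyq <- hb$fs / 2
  M <- nrow(hb$hbo)
  for (band in stopbands) {
    if (band[2] >= nyq)
      stop("stopband edge ", band[2], " Hz at or above Nyquist (", nyq,
           " Hz)", call. = FALSE)
    if (M <= 3 * (2 * order + 1))
      stop("series too short for filter order ", order, call. = FALSE)
    bt <- signal::butter(order, band / nyq, type = "stop")
    pad <- min(M - 1, round(5 * hb$fs / band[1]))
    # a Butterworth band-stop has unit DC gain analytically; pinning it
    # avoids ill-conditioned sum(b)/sum(a) evaluation at narrow bands
    hb <- apply_to_planes(hb, function(X)
      zero_phase_filter(bt$b, bt$a, X, pad = pad, dc = 1))
  }
  hb
}

#' Discrete cosine transform basis and high-pass projection
#'
#' Builds the orthonormal DCT regressor set spanning frequencies below
#' `cutoff` (including the constant term) and returns the series with
#' that low-frequency subspace projected out. The k-th basis function has
#' frequency `k / (2 M dt)`, so the basis holds
#' `floor(2 * duration * cutoff) + 1` columns.
#'
#' @param hb An [hb_series()].
#' @param cutoff High-pass cutoff, Hz (< fs/2).
#' @return A list: `hb` (filtered series) and `basis` (M x K orthonormal
#'   DCT matrix; zero columns when the series is a single sample).
#' @export
dct_highpass <- function(hb, cutoff = 1 / 64) {
  stopifnot(inherits(hb, "hb_series"), cutoff > 0, cutoff < hb$fs / 2)
  M <- nrow(hb$hbo)
  C <- dct_basis(M, hb$fs, cutoff)
  if (ncol(C) == 0) return(list(hb = hb, basis = C))
  proj <- function(X) X - C %*% crossprod(C, X)
  list(hb = apply_to_planes(hb, proj), basis = C)
}

#' @rdname dct_highpass
#' @param M Number of samples.
#' @param fs Sampling rate, Hz.
#' @export
dct_basis <- function(M, fs, cutoff) {
  if (M < 2) return(matrix(0, M, 0))
  K <- floor(2 * (M / fs) * cutoff) + 1
  K <- min(K, M)
  i <- seq_len(M)
  C <- vapply(seq_len(K) - 1, function(k)
    sqrt(2 / M) * cos(pi * (2 * i - 1) * k / (2 * M)), numeric(M))
  C[, 1] <- 1 / sqrt(M)
  C
}

#' Downsample a hemoglobin series
#'
#' Anti-alias low-pass filtering (zero-phase Butterworth with cutoff at
#' 80% of the target Nyquist) followed by decimation. Only integer
#' decimation ratios are supported.
#'
#' @param hb An [hb_series()].
#' @param target_fs Target rate, Hz; `fs / target_fs` must be a whole
#'   number.
#' @return Decimated [hb_series()] at `target_fs`.
#' @export
downsample_hb <- function(hb, target_fs = 1) {
  stopifnot(inherits(hb, "hb_series"), target_fs > 0)
  ratio <- hb$fs / target_fs
  if (abs(ratio - round(ratio)) > 1e-8)
    stop("fs / target_fs = ", format(ratio),
         " is not an integer decimation ratio", call. = FALSE)
  ratio <- round(ratio)
  if (ratio == 1) return(hb)
  wc <- 0.8 / ratio                       # 0.8 x target Nyquist, normalized
  bt <- signal::butter(4, wc)
  M <- nrow(hb$hbo)
  pad <- min(M - 1, 100 * ratio)
  keep <- seq(1, M, by = ratio)
  lp <- apply_to_planes(hb, function(X)
    zero_phase_filter(bt$b, bt$a, X, pad = pad, dc = 1)[keep, , drop = FALSE])
  hb_series(lp$hbo, lp$hbr, target_fs, hb$channel_ids)
}

#' Estimate a global AR(1) temporal autocorrelation model
#'
#' Pools the lag-1 autocorrelation of residuals across channels (a single
#' global temporal correlation structure), and estimates the innovation
#' variance per channel. The coefficient is clipped to |rho| <= 0.99.
#'
#' @param residuals M x J numeric matrix of residual time series.
#' @return A list of class `ar1_model`: `rho` (global), `sigma2`
#'   (innovation variance per channel), `M` (series length).
#' @export
estimate_ar1 <- function(residuals) {
  R <- as.matrix(residuals)
  M <- nrow(R)
  if (M < 10) stop("need at least 10 samples to estimate AR(1)",
                   call. = FALSE)
  R <- sweep(R, 2, colMeans(R))
  ss <- colSums(R^2)
  if (any(ss <= 0))
    stop("zero-variance residuals in channel(s) ",
         paste(which(ss <= 0), collapse = ", "), call. = FALSE)
  num <- sum(R[-1, , drop = FALSE] * R[-M, , drop = FALSE])
  rho <- num / sum(ss)
  rho <- max(min(rho, 0.99), -0.99)
  innov <- R[-1, , drop = FALSE] - rho * R[-M, , drop = FALSE]
  sigma2 <- colMeans(innov^2)
  structure(list(rho = rho, sigma2 = sigma2, M = M), class = "ar1_model")
}

#' AR(1) whitening filter matrix
#'
#' Returns a sparse lower-bidiagonal matrix S satisfying
#' `S V t(S) = I` for the AR(1) correlation matrix `V[i, j] = rho^|i-j|`:
#' the first sample passes through unchanged and every later sample is
#' replaced by its scaled innovation `(x_i - rho x_{i-1}) / sqrt(1 -
#' rho^2)`. Stored sparse, so matrix-vector products never materialize a
#' dense M x M matrix.
#'
#' @param model An `ar1_model` from [estimate_ar1()], or a list with
#'   `rho` and `M`.
#' @param M Series length (overrides `model$M`).
#' @return A sparse `Matrix` of dimension M x M.
#' @export
whitening_matrix <- function(model, M = model$M) {
  rho <- model$rho
  if (abs(rho) >= 1) stop("AR(1) coefficient must satisfy |rho| < 1",
                          call. = FALSE)
  s <- sqrt(1 - rho^2)
  d <- c(1, rep(1 / s, M - 1))
  sub <- rep(-rho / s, M - 1)
  Matrix::bandSparse(M, M, k = c(0, -1), diagonals = list(d, sub))
}

#' Run the full temporal preprocessing chain
#'
#' Applies, in order: motion correction, physiological band-stop, DCT
#' high-pass, and downsampling.
#'
#' @param hb An [hb_series()].
#' @param config A [preprocess_config()].
#' @return A list: `hb` (preprocessed series), `segments` (motion
#'   artifact log), `dct_basis`.
#' @export
preprocess_hb <- function(hb, config = preprocess_config()) {
  stopifnot(inherits(config, "preprocess_config"))
  mc <- correct_motion(hb, config$motion_window, config$motion_threshold)
  x <- bandstop_physio(mc$hb, config$stopbands, config$filter_order)
  hp <- dct_highpass(x, config$hp_cutoff)
  out <- downsample_hb(hp$hb, config$target_fs)
  list(hb = out, segments = mc$segments, dct_basis = hp$basis)
}
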