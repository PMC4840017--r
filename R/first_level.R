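#' Canonical hemodynamic response function
#'
#' Double-gamma impulse response: a positive gamma density peaking at
#' `peak_delay` seconds minus a scaled gamma density peaking at
#' `undershoot_delay` seconds, normalized to unit peak. The gamma
#' components are parameterized by their mode and a dispersion (scale)
#' parameter, so the kernel's maximum falls exactly at `peak_delay`.
#'
#' @param dt Sampling interval, seconds.
#' @param peak_delay Response peak, seconds (default 6).
#' @param undershoot_delay Undershoot peak, seconds (default 16).
#' @param dispersion,u_dispersion Gamma scale parameters, seconds
#'   (default 1).
#' @param ratio Undershoot amplitude ratio (default 1/6).
#' @param length_s Kernel support, seconds (default 32).
#' @param derivative If `TRUE`, return the temporal derivative of the
#'   kernel instead.
#' @return Numeric vector sampled at `0, dt, 2 dt, ...` up to
#'   `length_s`.
#' @export
canonical_hrf <- function(dt, peak_delay = 6, undershoot_delay = 16,
                          dispersion = 1, u_dispersion = 1, ratio = 1 / 6,
                          length_s = 32, derivative = FALSE) {
  stopifnot(dt > 0)
  t <- seq(0, length_s, by = dt)
  h_fun <- function(tt) {
    # gamma density with mode = delay and scale = dispersion
    k1 <- peak_delay / dispersion + 1
    k2 <- undershoot_delay / u_dispersion + 1
    stats::dgamma(tt, shape = k1, scale = dispersion) -
      ratio * stats::dgamma(tt, shape = k2, scale = u_dispersion)
  }
  h <- h_fun(t)
  peak <- max(h_fun(seq(0, length_s, by = min(dt, 0.01))))
  if (derivative) {
    eps <- 1e-4
    d <- (h_fun(t + eps) - h_fun(t - eps)) / (2 * eps)
    return(d / peak)
  }
  h / peak
}

#' Build a first-level design matrix
#'
#' For each condition, events are represented as delta sticks (or
#' boxcars when a duration is positive), convolved with each basis
#' function of the hemodynamic response basis set, and truncated to the
#' series length. Confound columns and a constant are appended.
#'
#' @param events An [event_table()].
#' @param M Number of samples.
#' @param fs Sampling rate, Hz.
#' @param basis Character vector, subset of `c("canonical",
#'   "derivative")`.
#' @param confounds Optional M x K matrix of confound regressors (e.g. a
#'   DCT basis).
#' @param conditions Declared condition set (default: those present).
#' @param add_constant Append a constant column (default `TRUE`).
#' @param hrf_args List of extra arguments for [canonical_hrf()].
#' @return A list of class `design_matrix`: `X` (M x L), `column_names`,
#'   `fs`, `task_cols` (indices of task regressors), and
#'   `empty_conditions` (labels with no events, flagged).
#' @export
build_design <- function(events, M, fs, basis = c("canonical", "derivative"),
                         confounds = NULL, conditions = NULL,
                         add_constant = TRUE, hrf_args = list()) {
  stopifnot(inherits(events, "event_table") || is.data.frame(events), M > 0)
  basis <- match.arg(basis, c("canonical", "derivative"),
                     several.ok = TRUE)
  if (is.null(conditions)) conditions <- unique(events$condition)
  unknown <- setdiff(events$condition, conditions)
  if (length(unknown))
    stop("unknown condition label(s) ", paste(unknown, collapse = ", "),
         "; declared: ", paste(conditions, collapse = ", "), call. = FALSE)
  dur <- M / fs
  if (nrow(events) && any(events$onset > dur))
    stop("event onsets beyond recording end (", dur, " s)", call. = FALSE)
  dt <- 1 / fs
  kernels <- list()
  if ("canonical" %in% basis)
    kernels$canonical <- do.call(canonical_hrf, c(list(dt = dt), hrf_args))
  if ("derivative" %in% basis)
    kernels$derivative <- do.call(canonical_hrf,
                                  c(list(dt = dt, derivative = TRUE),
                                    hrf_args))
  cols <- list()
  empty <- character()
  for (cond in conditions) {
    ev <- events[events$condition == cond, , drop = FALSE]
    stick <- numeric(M)
    if (nrow(ev) == 0) {
      empty <- c(empty, cond)
    } else {
      for (r in seq_len(nrow(ev))) {
        i0 <- floor(ev$onset[r] * fs) + 1
        i1 <- if (ev$duration[r] > 0)
          min(M, floor((ev$onset[r] + ev$duration[r]) * fs) + 1) else i0
        if (i0 <= M) stick[i0:min(i1, M)] <- stick[i0:min(i1, M)] + 1
      }
    }
    for (bn in names(kernels)) {
      reg <- stats::convolve(c(stick, numeric(length(kernels[[bn]]))),
                             rev(kernels[[bn]]), type = "open")
      reg <- reg[seq_len(M)]
      cols[[paste0(cond, ".", bn)]] <- reg
    }
  }
  X <- if (length(cols)) do.call(cbind, cols) else matrix(0, M, 0)
  task_cols <- seq_len(ncol(X))
  nm <- names(cols)
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    stopifnot(nrow(confounds) == M)
    cn <- colnames(confounds)
    if (is.null(cn)) cn <- paste0("confound", seq_len(ncol(confounds)))
    X <- cbind(X, confounds)
    nm <- c(nm, cn)
  }
  if (add_constant) {
    X <- cbind(X, 1)
    nm <- c(nm, "constant")
  }
  colnames(X) <- nm
  if (length(empty))
    warning("condition(s) with no events: ", paste(empty, collapse = ", "),
            call. = FALSE)
  structure(list(X = X, column_names = nm, fs = fs, task_cols = task_cols,
                 conditions = conditions, empty_conditions = empty),
            class = "design_matrix")
}

#' Fit a prewhitened general linear model per channel
#'
#' Ordinary least squares on the whitened model `S Y = S X beta + S e`:
#' `beta = (X*' X*)^-1 X*' Y*` with `X* = S X`, `Y* = S Y`. Residual
#' variance per channel uses `M - L` degrees of freedom.
#'
#' @param Y M x J matrix of responses (one chromophore), or an
#'   [hb_series()] with `chromophore` selecting the plane.
#' @param design A [build_design()] result or a plain matrix.
#' @param S Optional whitening matrix (from [whitening_matrix()]) or
#'   `NULL` for identity.
#' @param chromophore `"hbo"` or `"hbr"` when `Y` is an [hb_series()].
#' @return A list of class `glm_fit`: `beta` (L x J), `sigma2` (per
#'   channel), `residuals` (whitened, M x J), `dof`, `design`,
#'   `whitening`.
#' @export
fit_glm <- function(Y, design, S = NULL, chromophore = c("hbo", "hbr")) {
  channel_ids <- NULL
  if (inherits(Y, "hb_series")) {
    chromophore <- match.arg(chromophore)
    channel_ids <- Y$channel_ids
    Y <- Y[[chromophore]]
  }
  Y <- as.matrix(Y)
  X <- if (inherits(design, "design_matrix")) design$X else as.matrix(design)
  M <- nrow(Y); L <- ncol(X)
  stopifnot(nrow(X) == M, M > L)
  if (is.null(channel_ids)) channel_ids <- colnames(Y)
  if (is.null(channel_ids)) channel_ids <- paste0("CH", seq_len(ncol(Y)))
  if (!is.null(S)) {
    Xw <- as.matrix(S %*% X)
    Yw <- as.matrix(S %*% Y)
  } else {
    Xw <- X; Yw <- Y
  }
  qrX <- qr(Xw)
  if (qrX$rank < L) {
    dep <- colnames(X)[qrX$pivot[(qrX$rank + 1):L]]
    stop("rank-deficient design; collinear column(s): ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qrX, Yw)
  res <- Yw - Xw %*% beta
  sigma2 <- colSums(res^2) / (M - L)
  rownames(beta) <- colnames(X)
  colnames(beta) <- channel_ids
  structure(list(beta = beta, sigma2 = sigma2, residuals = res,
                 dof = M - L, design = design, whitening = S,
                 channel_ids = channel_ids),
            class = "glm_fit")
}

#' Channel-wise contrast of GLM parameter estimates
#'
#' Computes `w_j = c' beta_j` for every channel j.
#'
#' @param fit A [fit_glm()] result.
#' @param contrast Numeric contrast vector of length L, or a named vector
#'   matched against design column names (unnamed columns get 0).
#' @param subject_id Optional subject label carried along.
#' @return A list of class `channel_contrast`: `w` (named per channel),
#'   `contrast`, `subject_id`.
#' @export
contrast_channels <- function(fit, contrast, subject_id = NA_character_) {
  stopifnot(inherits(fit, "glm_fit"))
  L <- nrow(fit$beta)
  if (!is.null(names(contrast))) {
    cv <- numeric(L)
    idx <- match(names(contrast), rownames(fit$beta))
    if (anyNA(idx))
      stop("contrast names not in design: ",
           paste(names(contrast)[is.na(idx)], collapse = ", "),
           call. = FALSE)
    cv[idx] <- contrast
    contrast <- cv
  }
  if (length(contrast) != L)
    stop("contrast length ", length(contrast), " != number of regressors ",
         L, call. = FALSE)
  w <- drop(crossprod(contrast, fit$beta))
  names(w) <- fit$channel_ids
  structure(list(w = w, contrast = as.numeric(contrast),
                 subject_id = subject_id),
            class = "channel_contrast")
}
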