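#' Group-level design
#'
#' Second-level design matrix and contrast for the summary-statistics
#' random-effects model. The default is the one-sample t-test design
#' (a column of ones with contrast 1).
#'
#' @param X N x P design matrix.
#' @param contrast Length-P contrast vector.
#' @param subject_ids Optional subject labels (rownames of X).
#' @return A list of class `group_design`.
#' @export
group_design <- function(X, contrast, subject_ids = NULL) {
  X <- as.matrix(X)
  N <- nrow(X); P <- ncol(X)
  if (N <= P) stop("need more subjects (", N, ") than group parameters (",
                   P, ")", call. = FALSE)
  if (qr(X)$rank < P) stop("group design is rank deficient", call. = FALSE)
  stopifnot(length(contrast) == P)
  if (is.null(subject_ids)) subject_ids <- paste0("sub", seq_len(N))
  structure(list(X = X, contrast = as.numeric(contrast),
                 subject_ids = subject_ids, N = N, P = P),
            class = "group_design")
}

#' @rdname group_design
#' @param N Number of subjects.
#' @export
one_sample_design <- function(N, subject_ids = NULL) {
  group_design(matrix(1, N, 1), 1, subject_ids)
}

#' Stack per-subject contrast images into a group data matrix
#'
#' Rows are subjects, columns are image locations. The group mask is the
#' intersection of the per-subject validity masks: group inference is
#' only defined where every subject's interpolation is.
#'
#' @param images List of [contrast_image()] objects in a common space.
#' @return A list of class `contrast_stack`: `W` (N x V), `mask`
#'   (intersection), `space`, `geometry`, `subject_ids`.
#' @export
stack_contrasts <- function(images) {
  N <- length(images)
  if (N < 2) stop("need at least 2 subjects (between-subject variance is ",
                  "not estimable from one)", call. = FALSE)
  spaces <- unique(vapply(images, `[[`, "", "space"))
  if (length(spaces) != 1)
    stop("images mix spaces: ", paste(spaces, collapse = ", "),
         call. = FALSE)
  V <- length(images[[1]]$values)
  if (any(vapply(images, function(i) length(i$values), 0L) != V))
    stop("images differ in size", call. = FALSE)
  mask <- Reduce(`&`, lapply(images, `[[`, "mask"))
  if (!any(mask)) stop("empty group mask: subject masks do not overlap",
                       call. = FALSE)
  W <- do.call(rbind, lapply(images, `[[`, "values"))
  structure(list(W = W, mask = mask, space = spaces,
                 geometry = images[[1]]$geometry,
                 subject_ids = vapply(images, `[[`, "", "subject_id")),
            class = "contrast_stack")
}

#' Fit the second-level random-effects model
#'
#' Least-squares fit of the group design to the stacked per-subject
#' contrast estimates at every location. The residual variance estimates
#' the mixed-effects error (the sum of within- and between-subject
#' contributions), and the t-statistic is
#' `c' beta / sqrt(Var * c' (X'X)^-1 c)` with `N - P` degrees of
#' freedom. For the one-sample design this is the classical one-sample
#' t-test. Locations with zero residual variance get `T = NA` (flagged,
#' not dropped).
#'
#' @param stack A [stack_contrasts()] result, or an N x V matrix.
#' @param design A [group_design()]; default one-sample.
#' @param mask Logical mask when `stack` is a plain matrix.
#' @return A list of class `second_level`: `beta` (P x V), `var_e`, `T`
#'   (length V, NA outside mask), `se`, `dof`, `residuals` (N x V),
#'   `mask`, `design`, `geometry`, `space`.
#' @export
fit_second_level <- function(stack, design = NULL, mask = NULL) {
  if (inherits(stack, "contrast_stack")) {
    W <- stack$W; mask <- stack$mask
    geometry <- stack$geometry; space <- stack$space
  } else {
    W <- as.matrix(stack)
    if (is.null(mask)) mask <- rep(TRUE, ncol(W))
    geometry <- NULL; space <- NA_character_
  }
  N <- nrow(W)
  if (is.null(design)) design <- one_sample_design(N)
  stopifnot(inherits(design, "group_design"), design$N == N)
  X <- design$X; P <- design$P
  dof <- N - P
  V <- ncol(W)
  Wm <- W[, mask, drop = FALSE]
  XtXi <- solve(crossprod(X))
  pinv <- XtXi %*% t(X)
  beta_m <- pinv %*% Wm
  res_m <- Wm - X %*% beta_m
  var_m <- colSums(res_m^2) / dof
  cvec <- design$contrast
  se_scale <- sqrt(drop(t(cvec) %*% XtXi %*% cvec))
  eff_m <- drop(crossprod(cvec, beta_m))
  se_m <- sqrt(var_m) * se_scale
  T_m <- ifelse(se_m > 0, eff_m / se_m, NA_real_)
  expand <- function(v, fill = NA_real_) {
    out <- rep(fill, V); out[mask] <- v; out
  }
  beta <- matrix(NA_real_, P, V); beta[, mask] <- beta_m
  residuals <- matrix(NA_real_, N, V); residuals[, mask] <- res_m
  structure(list(beta = beta, var_e = expand(var_m), T = expand(T_m),
                 se = expand(se_m), effect = expand(eff_m), dof = dof,
                 residuals = residuals, mask = mask, design = design,
                 geometry = geometry, space = space),
            class = "second_level")
}

#' Bonferroni-corrected t threshold over channels
#'
#' One-sided upper t quantile at `alpha / n_tests`.
#'
#' @param alpha Nominal family-wise error level.
#' @param n_tests Number of channels (tests).
#' @param dof Degrees of freedom.
#' @return Threshold T.
#' @export
bonferroni_threshold <- function(alpha, n_tests, dof) {
  stopifnot(alpha > 0, alpha < 1, n_tests >= 1, dof > 0)
  stats::qt(1 - alpha / n_tests, df = dof)
}

#' Euler-characteristic densities of a t random field
#'
#' Closed-form EC densities for a t field in resel (FWHM) units:
#' `rho_0` is the one-sided tail probability, `rho_1` and `rho_2` the
#' 1- and 2-dimensional densities. All are strictly decreasing in t for
#' t > 0; scalp surfaces are 2-manifolds so dimensions above 2 are not
#' supported.
#'
#' @param t Threshold value(s).
#' @param dof Degrees of freedom (> 2 recommended for stability).
#' @param d Dimension: 0, 1 or 2.
#' @return EC density value(s).
#' @export
ec_density <- function(t, dof, d) {
  if (!d %in% 0:2)
    stop("unsupported EC dimension ", d, " (scalp surfaces are ",
         "2-manifolds)", call. = FALSE)
  if (d == 0) return(stats::pt(t, df = dof, lower.tail = FALSE))
  a <- 4 * log(2)
  shape <- (1 + t^2 / dof)^(-(dof - 1) / 2)
  if (d == 1) return(sqrt(a) / (2 * pi) * shape)
  b <- exp(lgamma((dof + 1) / 2) - lgamma(dof / 2))
  a / (2 * pi)^(3 / 2) * shape * t * b / sqrt(dof / 2)
}

mask_euler_grid <- function(Mk) {
  # Euler characteristic of a binary image under 8-connectivity
  # (Gray's 2x2 quad counting)
  n1 <- nrow(Mk); n2 <- ncol(Mk)
  P <- matrix(0L, n1 + 2, n2 + 2)
  P[2:(n1 + 1), 2:(n2 + 1)] <- Mk * 1L
  a <- P[-(n1 + 2), -(n2 + 2)]; b <- P[-(n1 + 2), -1]
  cc <- P[-1, -(n2 + 2)]; d <- P[-1, -1]
  s <- a + b + cc + d
  q1 <- sum(s == 1)
  q3 <- sum(s == 3)
  qd <- sum(s == 2 & ((a == 1 & d == 1) | (b == 1 & cc == 1)))
  (q1 - q3 - 2 * qd) / 4
}

#' Estimate field smoothness and resel counts
#'
#' Estimates the residual field's smoothness (FWHM per dimension, mm)
#' from the spatial derivatives of the standardized second-level
#' residuals, then converts the search region to resolution-element
#' (resel) counts: `R_2` = area / (FWHM_x FWHM_y), `R_1` =
#' half-boundary-length / FWHM, `R_0` = Euler characteristic of the
#' mask.
#'
#' @param residuals N x V matrix of residual images (from
#'   [fit_second_level()]), or a `second_level` fit.
#' @param mask Logical mask (taken from the fit if given).
#' @param geometry [scalp_grid2d()] or [make_canonical_mesh()].
#' @return A list of class `resel_info`: `fwhm` (per-dimension, mm),
#'   `resels` (R0, R1, R2), `search_volume` (locations in mask),
#'   `area_per_location` (mm^2).
#' @export
estimate_smoothness <- function(residuals, mask = NULL, geometry = NULL) {
  if (inherits(residuals, "second_level")) {
    if (is.null(mask)) mask <- residuals$mask
    if (is.null(geometry)) geometry <- residuals$geometry
    residuals <- residuals$residuals
  }
  R <- as.matrix(residuals)
  if (nrow(R) < 2) stop("need at least 2 residual images", call. = FALSE)
  ss <- sqrt(colSums(R^2))
  U <- sweep(R, 2, pmax(ss, 1e-300), "/")   # standardized residuals
  if (all(!is.finite(U[, mask])) || stats::sd(R[, mask]) == 0)
    stop("constant residuals: smoothness undefined", call. = FALSE)
  if (inherits(geometry, "scalp_grid2d")) {
    n <- geometry$n; ps <- geometry$pixel_size
    Mk <- matrix(mask, n, n)
    idx <- matrix(seq_len(n * n), n, n)
    ex <- which(Mk[-n, ] & Mk[-1, ])            # x-neighbour pairs
    i1 <- idx[-n, ][ex]; i2 <- idx[-1, ][ex]
    lx <- mean(colSums((U[, i2, drop = FALSE] - U[, i1, drop = FALSE])^2)) / ps^2
    ey <- which(Mk[, -n] & Mk[, -1])
    j1 <- idx[, -n][ey]; j2 <- idx[, -1][ey]
    ly <- mean(colSums((U[, j2, drop = FALSE] - U[, j1, drop = FALSE])^2)) / ps^2
    fwhm <- sqrt(4 * log(2) / c(x = lx, y = ly))
    if (any(!is.finite(fwhm))) fwhm[!is.finite(fwhm)] <- Inf
    area <- sum(mask) * ps^2
    fgeo <- sqrt(prod(fwhm))
    # boundary length: exposed 4-neighbour pixel sides
    Pd <- matrix(FALSE, n + 2, n + 2); Pd[2:(n + 1), 2:(n + 1)] <- Mk
    core <- Pd[2:(n + 1), 2:(n + 1)]
    exposed <- (core & !Pd[1:n, 2:(n + 1)]) + (core & !Pd[3:(n + 2), 2:(n + 1)]) +
      (core & !Pd[2:(n + 1), 1:n]) + (core & !Pd[2:(n + 1), 3:(n + 2)])
    perim <- sum(exposed) * ps
    resels <- c(R0 = mask_euler_grid(Mk),
                R1 = (perim / 2) / fgeo,
                R2 = area / prod(fwhm))
    return(structure(list(fwhm = fwhm, resels = resels,
                          search_volume = sum(mask),
                          area_per_location = area / sum(mask)),
                     class = "resel_info"))
  }
  if (inherits(geometry, "scalp_mesh")) {
    Vx <- geometry$vertices * geometry$radius
    f <- geometry$faces
    fin <- mask[f[, 1]] & mask[f[, 2]] & mask[f[, 3]]
    if (!any(fin)) stop("mask contains no complete triangle", call. = FALSE)
    fs <- f[fin, , drop = FALSE]
    # per-triangle linear-interpolant gradient, pooled over images
    grad2 <- 0; areas <- numeric(nrow(fs))
    for (k in seq_len(nrow(fs))) {
      p1 <- Vx[fs[k, 1], ]; p2 <- Vx[fs[k, 2], ]; p3 <- Vx[fs[k, 3], ]
      e1 <- p2 - p1; e2 <- p3 - p1
      nrm <- c(e1[2] * e2[3] - e1[3] * e2[2],
               e1[3] * e2[1] - e1[1] * e2[3],
               e1[1] * e2[2] - e1[2] * e2[1])
      A2 <- sqrt(sum(nrm^2))
      areas[k] <- A2 / 2
      # local orthonormal frame in the triangle plane
      b1 <- e1 / sqrt(sum(e1^2))
      b2v <- e2 - sum(e2 * b1) * b1
      b2 <- b2v / sqrt(sum(b2v^2))
      x2 <- sum(e1 * b1)
      x3 <- sum(e2 * b1); y3 <- sum(e2 * b2)
      d1 <- U[, fs[k, 2]] - U[, fs[k, 1]]
      d2 <- U[, fs[k, 3]] - U[, fs[k, 1]]
      gx <- d1 / x2
      gy <- (d2 - gx * x3) / y3
      grad2 <- grad2 + sum(gx^2 + gy^2)
    }
    lambda <- (grad2 / nrow(fs)) / 2     # per-dimension derivative variance
    fwhm <- sqrt(4 * log(2) / lambda)
    area <- sum(areas)
    # boundary: edges used by exactly one masked triangle
    ed <- rbind(fs[, 1:2], fs[, 2:3], fs[, c(3, 1)])
    ed <- cbind(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
    key <- paste(ed[, 1], ed[, 2])
    tab <- table(key)
    bkey <- names(tab)[tab == 1]
    blen <- 0
    if (length(bkey)) {
      bidx <- do.call(rbind, strsplit(bkey, " "))
      bidx <- matrix(as.integer(bidx), ncol = 2)
      blen <- sum(sqrt(rowSums((Vx[bidx[, 1], , drop = FALSE] -
                                  Vx[bidx[, 2], , drop = FALSE])^2)))
    }
    nV <- length(unique(as.vector(fs)))
    nE <- length(tab)
    chi <- nV - nE + nrow(fs)
    resels <- c(R0 = chi, R1 = (blen / 2) / fwhm, R2 = area / fwhm^2)
    return(structure(list(fwhm = c(iso = fwhm), resels = resels,
                          search_volume = sum(mask),
                          area_per_location = area / sum(mask)),
                     class = "resel_info"))
  }
  stop("geometry must be a scalp_grid2d or scalp_mesh", call. = FALSE)
}

#' @export
print.resel_info <- function(x, ...) {
  cat(sprintf("resel_info: FWHM %s mm; R0=%.1f R1=%.1f R2=%.1f (%d locations)\n",
              paste(sprintf("%.1f", x$fwhm), collapse = "/"),
              x$resels[1], x$resels[2], x$resels[3], x$search_volume))
  invisible(x)
}

ec_expectation <- function(t, resels, dof) {
  r <- if (inherits(resels, "resel_info")) resels$resels else resels
  r[1] * ec_density(t, dof, 0) + r[2] * ec_density(t, dof, 1) +
    r[3] * ec_density(t, dof, 2)
}

#' Random-field-theory peak (cluster-forming) threshold
#'
#' Smallest t at which the expected Euler characteristic of the
#' excursion set, `sum_d R_d rho_d(t)`, drops to `alpha`; found by
#' bisection to 1e-6. Decreasing in `alpha`, increasing in every resel
#' count.
#'
#' @param alpha Family-wise error level.
#' @param resels A `resel_info` or numeric `c(R0, R1, R2)`.
#' @param dof Degrees of freedom.
#' @return Threshold T_c.
#' @export
rft_peak_threshold <- function(alpha, resels, dof) {
  stopifnot(alpha > 0, alpha < 1)
  f <- function(t) ec_expectation(t, resels, dof) - alpha
  lo <- 1e-3; hi <- 100
  while (f(hi) > 0 && hi < 1e6) hi <- hi * 4
  if (f(hi) > 0)
    stop("alpha = ", alpha, " unreachable: expected EC exceeds alpha even ",
         "at t = ", hi, " (resels too large / dof too small)",
         call. = FALSE)
  if (f(lo) < 0) return(lo)
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Peak-level family-wise error p-value
#'
#' `min(1, sum_d R_d rho_d(t))`; inverse of [rft_peak_threshold()].
#'
#' @param t Peak height.
#' @param resels A `resel_info` or numeric `c(R0, R1, R2)`.
#' @param dof Degrees of freedom.
#' @return Corrected p-value in (0, 1].
#' @export
peak_pvalue <- function(t, resels, dof) {
  pmin(1, ec_expectation(t, resels, dof))
}

grid_components <- function(idx, n) {
  # 8-connectivity connected components of pixel indices idx on an n x n
  # grid; returns a list of index vectors
  inset <- logical(n * n); inset[idx] <- TRUE
  labs <- integer(n * n)
  comp <- list()
  for (start in idx) {
    if (labs[start]) next
    lab <- length(comp) + 1L
    queue <- start; labs[start] <- lab
    members <- integer(0)
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      members <- c(members, v)
      i <- ((v - 1) %% n) + 1; j <- ((v - 1) %/% n) + 1
      for (dj in -1:1) for (di in -1:1) {
        if (di == 0 && dj == 0) next
        ii <- i + di; jj <- j + dj
        if (ii < 1 || ii > n || jj < 1 || jj > n) next
        u <- (jj - 1) * n + ii
        if (inset[u] && !labs[u]) { labs[u] <- lab; queue <- c(queue, u) }
      }
    }
    comp[[lab]] <- members
  }
  comp
}

mesh_components <- function(idx, edges) {
  inset <- logical(max(edges)); inset[idx] <- TRUE
  adj <- split(c(edges[inset[edges[, 1]] & inset[edges[, 2]], 2],
                 edges[inset[edges[, 1]] & inset[edges[, 2]], 1]),
               c(edges[inset[edges[, 1]] & inset[edges[, 2]], 1],
                 edges[inset[edges[, 1]] & inset[edges[, 2]], 2]))
  labs <- integer(length(inset))
  comp <- list()
  for (start in idx) {
    if (labs[start]) next
    lab <- length(comp) + 1L
    queue <- start; labs[start] <- lab
    members <- integer(0)
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      members <- c(members, v)
      nb <- adj[[as.character(v)]]
      for (u in nb) if (!labs[u]) { labs[u] <- lab; queue <- c(queue, u) }
    }
    comp[[lab]] <- members
  }
  comp
}

#' Cluster-level inference on the excursion set
#'
#' Labels the connected components of `{T >= T_c}` (8-connectivity on
#' the grid, edge connectivity on the mesh) and assigns each cluster a
#' family-wise error p-value from the stationary 2D Gaussian-field
#' cluster-extent approximation: the number of clusters is Poisson with
#' mean the expected Euler characteristic, extents are exponential with
#' mean the expected suprathreshold volume per cluster (in resels, at
#' the Gaussianized threshold), and
#' `p = 1 - exp(-E[clusters] * P(extent >= k))`.
#'
#' @param T_map Numeric vector of t-values (NA outside mask).
#' @param T_c Cluster-forming threshold.
#' @param resels A `resel_info`.
#' @param dof Degrees of freedom.
#' @param geometry [scalp_grid2d()] or [make_canonical_mesh()].
#' @return data.frame with one row per cluster: `cluster`, `k_E`
#'   (locations), `p_fwe`, `max_T`, `peak_location` (index of the
#'   cluster maximum); empty when nothing survives.
#' @export
cluster_inference <- function(T_map, T_c, resels, dof, geometry) {
  above <- which(!is.na(T_map) & T_map >= T_c)
  empty <- data.frame(cluster = integer(), k_E = integer(),
                      p_fwe = numeric(), max_T = numeric(),
                      peak_location = integer())
  if (!length(above)) return(empty)
  comp <- if (inherits(geometry, "scalp_grid2d"))
    grid_components(above, geometry$n)
  else mesh_components(above, mesh_edges(geometry))
  r <- resels$resels
  # Gaussianized-threshold convention for the extent distribution
  tg <- stats::qnorm(stats::pt(T_c, dof, lower.tail = FALSE),
                     lower.tail = FALSE)
  Em <- ec_expectation(T_c, resels, dof)
  EN <- r[3] * stats::pnorm(tg, lower.tail = FALSE)
  En <- max(EN / max(Em, 1e-300), 1e-300)  # expected extent per cluster
  loc_resel <- resels$area_per_location /
    (if (length(resels$fwhm) == 2) prod(resels$fwhm) else resels$fwhm^2)
  out <- lapply(seq_along(comp), function(i) {
    members <- comp[[i]]
    kE <- length(members)
    k_res <- kE * loc_resel
    p <- 1 - exp(-Em * exp(-k_res / En))
    pk <- members[which.max(T_map[members])]
    data.frame(cluster = i, k_E = kE, p_fwe = min(max(p, 0), 1),
               max_T = T_map[pk], peak_location = pk)
  })
  out <- do.call(rbind, out)
  out[order(-out$max_T), , drop = FALSE]
}

find_peaks <- function(T_map, T_c, geometry) {
  above <- which(!is.na(T_map) & T_map >= T_c)
  if (!length(above)) return(integer(0))
  if (inherits(geometry, "scalp_grid2d")) {
    n <- geometry$n
    is_peak <- vapply(above, function(v) {
      i <- ((v - 1) %% n) + 1; j <- ((v - 1) %/% n) + 1
      for (dj in -1:1) for (di in -1:1) {
        if (di == 0 && dj == 0) next
        ii <- i + di; jj <- j + dj
        if (ii < 1 || ii > n || jj < 1 || jj > n) next
        u <- (jj - 1) * n + ii
        if (!is.na(T_map[u]) && T_map[u] > T_map[v]) return(FALSE)
      }
      TRUE
    }, logical(1))
  } else {
    edges <- mesh_edges(geometry)
    nbrs <- function(v) c(edges[edges[, 1] == v, 2], edges[edges[, 2] == v, 1])
    is_peak <- vapply(above, function(v) {
      nb <- nbrs(v)
      all(is.na(T_map[nb]) | T_map[nb] <= T_map[v])
    }, logical(1))
  }
  above[is_peak]
}

#' Run group inference on stacked contrast images
#'
#' Orchestrates the second-level fit, smoothness estimation,
#' thresholding and topological inference. With `method = "rft"`,
#' peaks and clusters of the statistical map are assigned family-wise
#' error corrected p-values over the scalp search region; with
#' `method = "bonferroni"`, channel-wise t-tests are corrected over the
#' number of channels (`channel_w` must then hold the per-subject
#' channel contrasts).
#'
#' @param images List of [contrast_image()] (rft route), or `NULL`.
#' @param design A [group_design()]; default one-sample.
#' @param alpha Nominal FWE level (default 0.05).
#' @param method `"rft"` or `"bonferroni"`.
#' @param channel_w N x J matrix of channel contrasts (bonferroni
#'   route).
#' @param T_c Optional user-specified cluster-forming threshold
#'   (otherwise the RFT peak threshold at `alpha`).
#' @return A list of class `inference_result`: `method`, `space`,
#'   `alpha`, `T_c`, `dof`, `fit`, `resels` (rft), `peaks`, `clusters`
#'   (rft), or `channel_table` (bonferroni).
#' @export
run_group_inference <- function(images = NULL, design = NULL, alpha = 0.05,
                                method = c("rft", "bonferroni"),
                                channel_w = NULL, T_c = NULL) {
  method <- match.arg(method)
  stopifnot(alpha > 0, alpha < 1)
  if (method == "bonferroni") {
    if (is.null(channel_w))
      stop("bonferroni route needs the per-subject channel contrasts",
           call. = FALSE)
    W <- as.matrix(channel_w)
    if (is.null(design)) design <- one_sample_design(nrow(W))
    fit <- fit_second_level(W, design)
    thr <- bonferroni_threshold(alpha, ncol(W), fit$dof)
    p_unc <- stats::pt(fit$T, fit$dof, lower.tail = FALSE)
    tab <- data.frame(channel = colnames(W) %||% paste0("CH", seq_len(ncol(W))),
                      T = fit$T,
                      p_fwe = pmin(1, ncol(W) * p_unc),
                      significant = !is.na(fit$T) & fit$T >= thr)
    return(structure(list(method = method, space = "channels",
                          alpha = alpha, T_c = thr, dof = fit$dof,
                          fit = fit, channel_table = tab),
                     class = "inference_result"))
  }
  stack <- stack_contrasts(images)
  fit <- fit_second_level(stack, design)
  resels <- estimate_smoothness(fit)
  if (is.null(T_c)) T_c <- rft_peak_threshold(alpha, resels, fit$dof)
  peaks_idx <- find_peaks(fit$T, T_c, stack$geometry)
  peaks <- data.frame(location = peaks_idx,
                      T = fit$T[peaks_idx],
                      p_fwe = if (length(peaks_idx))
                        peak_pvalue(fit$T[peaks_idx], resels, fit$dof)
                      else numeric(0))
  peaks <- peaks[order(-peaks$T), , drop = FALSE]
  clusters <- cluster_inference(fit$T, T_c, resels, fit$dof, stack$geometry)
  structure(list(method = method, space = stack$space, alpha = alpha,
                 T_c = T_c, dof = fit$dof, fit = fit, resels = resels,
                 peaks = peaks, clusters = clusters),
            class = "inference_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.inference_result <- function(x, ...) {
  cat(sprintf("inference_result [%s, %s]: alpha=%g, T_c=%.3f, dof=%d\n",
              x$method, x$space, x$alpha, x$T_c, x$dof))
  if (x$method == "rft") {
    cat(sprintf("  resels: R0=%.1f R1=%.1f R2=%.1f\n",
                x$resels$resels[1], x$resels$resels[2], x$resels$resels[3]))
    cat(sprintf("  %d peak(s), %d cluster(s) above threshold\n",
                nrow(x$peaks), nrow(x$clusters)))
  } else {
    cat(sprintf("  %d of %d channels significant\n",
                sum(x$channel_table$significant), nrow(x$channel_table)))
  }
  invisible(x)
}

#' Tabulate an inference result
#'
#' One row per cluster (rft) or per significant channel (bonferroni),
#' with resel counts, thresholds, cluster extent and peak statistics.
#'
#' @param x An `inference_result`.
#' @return data.frame with columns method, space, RESELS, T_c,
#'   cluster_p_FWE, k_E, peak_p_FWE, T.
#' @export
results_table <- function(x) {
  stopifnot(inherits(x, "inference_result"))
  if (x$method == "bonferroni") {
    sig <- x$channel_table[x$channel_table$significant, , drop = FALSE]
    if (!nrow(sig))
      return(data.frame(method = character(), space = character(),
                        RESELS = numeric(), T_c = numeric(),
                        cluster_p_FWE = numeric(), k_E = integer(),
                        peak_p_FWE = numeric(), T = numeric()))
    return(data.frame(method = "bonferroni", space = x$space,
                      RESELS = NA_real_, T_c = round(x$T_c, 2),
                      cluster_p_FWE = NA_real_, k_E = NA_integer_,
                      peak_p_FWE = sig$p_fwe, T = sig$T))
  }
  cl <- x$clusters
  if (!nrow(cl))
    return(data.frame(method = "rft", space = x$space,
                      RESELS = round(sum(x$resels$resels[3]), 1),
                      T_c = round(x$T_c, 2), cluster_p_FWE = NA_real_,
                      k_E = NA_integer_, peak_p_FWE = NA_real_,
                      T = NA_real_)[0, ])
  data.frame(method = "rft", space = x$space,
             RESELS = round(x$resels$resels[3], 1),
             T_c = round(x$T_c, 2),
             cluster_p_FWE = cl$p_fwe, k_E = cl$k_E,
             peak_p_FWE = peak_pvalue(cl$max_T, x$resels, x$dof),
             T = cl$max_T)
}

#' @rdname results_table
#' @param path Output TSV path.
#' @export
write_results_table <- function(x, path) {
  utils::write.table(results_table(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
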