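#' Per-subject contrast image container
#'
#' Holds interpolated contrast values on either the 2D scalp grid
#' (`space = "grid2d"`, column-major vector with x fastest) or the 3D
#' scalp mesh (`space = "mesh3d"`, one value per vertex). Values outside
#' the validity mask are `NA`.
#'
#' @param space `"grid2d"` or `"mesh3d"`.
#' @param values Numeric vector (n^2 pixels or V vertices).
#' @param mask Logical vector of the same length.
#' @param geometry The [scalp_grid2d()] or [make_canonical_mesh()] the
#'   values live on.
#' @param subject_id Subject label.
#' @param smoothing_fwhm Gaussian smoothing FWHM in mm (grid images).
#' @return A list of class `contrast_image`.
#' @export
contrast_image <- function(space = c("grid2d", "mesh3d"), values, mask,
                           geometry = NULL, subject_id = NA_character_,
                           smoothing_fwhm = NA_real_) {
  space <- match.arg(space)
  values <- as.numeric(values)
  mask <- as.logical(mask)
  stopifnot(length(values) == length(mask))
  if (any(!is.finite(values[mask])))
    stop("non-finite contrast values inside the mask", call. = FALSE)
  values[!mask] <- NA_real_
  structure(list(space = space, values = values, mask = mask,
                 geometry = geometry, subject_id = subject_id,
                 smoothing_fwhm = smoothing_fwhm),
            class = "contrast_image")
}

#' @export
print.contrast_image <- function(x, ...) {
  cat(sprintf("contrast_image [%s]: %d locations, %d in mask, subject %s\n",
              x$space, length(x$values), sum(x$mask), x$subject_id))
  invisible(x)
}

#' Piecewise-linear interpolation of channel values onto the 2D grid
#'
#' Delaunay-triangulates the planar channel positions and interpolates
#' barycentrically, so the interpolant is exact at channels, reproduces
#' affine functions exactly, and stays within the range of the data.
#' Pixels outside the channel convex hull are masked `NA`.
#'
#' @param channel_xy J x 2 planar channel coordinates, mm.
#' @param w Channel values: numeric vector or `channel_contrast`.
#' @param grid A [scalp_grid2d()].
#' @param subject_id Subject label for the resulting image.
#' @return A [contrast_image()] in `grid2d` space (unsmoothed).
#' @export
interp2d_linear <- function(channel_xy, w, grid, subject_id = NA_character_) {
  subject_id_in <- subject_id
  if (inherits(w, "channel_contrast")) {
    if (is.na(subject_id_in)) subject_id_in <- w$subject_id
    w <- w$w
  }
  channel_xy <- as.matrix(channel_xy)
  stopifnot(nrow(channel_xy) == length(w), nrow(channel_xy) >= 3)
  w <- as.numeric(w)
  tris <- delaunay_triangles(channel_xy)
  vals <- rep(NA_real_, nrow(grid$xy))
  px <- grid$xy[, 1]; py <- grid$xy[, 2]
  for (k in seq_len(nrow(tris))) {
    i <- tris[k, ]
    x1 <- channel_xy[i[1], 1]; y1 <- channel_xy[i[1], 2]
    x2 <- channel_xy[i[2], 1]; y2 <- channel_xy[i[2], 2]
    x3 <- channel_xy[i[3], 1]; y3 <- channel_xy[i[3], 2]
    det <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
    l1 <- ((y2 - y3) * (px - x3) + (x3 - x2) * (py - y3)) / det
    l2 <- ((y3 - y1) * (px - x3) + (x1 - x3) * (py - y3)) / det
    l3 <- 1 - l1 - l2
    eps <- 1e-9
    inside <- l1 >= -eps & l2 >= -eps & l3 >= -eps
    vals[inside] <- l1[inside] * w[i[1]] + l2[inside] * w[i[2]] +
      l3[inside] * w[i[3]]
  }
  mask <- !is.na(vals)
  if (!any(mask)) stop("no grid pixel falls inside the channel hull",
                       call. = FALSE)
  contrast_image("grid2d", ifelse(mask, vals, NA_real_), mask, grid,
                 subject_id_in)
}

#' Linear interpolation operator for a fixed layout
#'
#' Because piecewise-linear interpolation is linear in the channel
#' values, the whole grid image is `P %*% w` for a fixed matrix `P`.
#' This precomputes `P` column by column (one interpolation of each
#' channel indicator), which makes repeated interpolation of many
#' subjects or simulation replicates cheap.
#'
#' @param channel_xy J x 2 planar channel coordinates, mm.
#' @param grid A [scalp_grid2d()].
#' @return List: `P` (n^2 x J matrix), `mask` (pixels inside the channel
#'   hull).
#' @export
interp_operator_2d <- function(channel_xy, grid) {
  channel_xy <- as.matrix(channel_xy)
  J <- nrow(channel_xy)
  tris <- delaunay_triangles(channel_xy)
  P <- matrix(0, nrow(grid$xy), J)
  assigned <- logical(nrow(grid$xy))
  px <- grid$xy[, 1]; py <- grid$xy[, 2]
  for (k in seq_len(nrow(tris))) {
    i <- tris[k, ]
    x1 <- channel_xy[i[1], 1]; y1 <- channel_xy[i[1], 2]
    x2 <- channel_xy[i[2], 1]; y2 <- channel_xy[i[2], 2]
    x3 <- channel_xy[i[3], 1]; y3 <- channel_xy[i[3], 2]
    det <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
    l1 <- ((y2 - y3) * (px - x3) + (x3 - x2) * (py - y3)) / det
    l2 <- ((y3 - y1) * (px - x3) + (x1 - x3) * (py - y3)) / det
    l3 <- 1 - l1 - l2
    inside <- which(l1 >= -1e-9 & l2 >= -1e-9 & l3 >= -1e-9)
    P[inside, ] <- 0
    P[cbind(inside, i[1])] <- l1[inside]
    P[cbind(inside, i[2])] <- l2[inside]
    P[cbind(inside, i[3])] <- l3[inside]
    assigned[inside] <- TRUE
  }
  list(P = P, mask = assigned)
}

# Delaunay triangulation indices via deldir; errors on collinear input.
delaunay_triangles <- function(xy) {
  dd <- tryCatch(
    deldir::deldir(xy[, 1], xy[, 2], suppressMsge = TRUE,
                   round = FALSE),
    error = function(e) stop("degenerate channel triangulation: ",
                             conditionMessage(e), call. = FALSE))
  tl <- deldir::triang.list(dd)
  if (!length(tl))
    stop("degenerate channel triangulation: channels are collinear",
         call. = FALSE)
  do.call(rbind, lapply(tl, function(t3) t3$ptNum))
}

conv_same_1d <- function(x, k) {
  # 'same' convolution with zero padding; k has odd length
  h <- (length(k) - 1) / 2
  xp <- c(numeric(h), x, numeric(h))
  stats::convolve(xp, k, type = "filter")
}

#' Gaussian smoothing of a 2D contrast image
#'
#' Convolution with an isotropic Gaussian kernel of the given full width
#' at half maximum, `sigma = fwhm / (2 sqrt(2 ln 2))`. The kernel is
#' renormalized over the defined (mask) pixels, so constants are
#' preserved inside the mask and edge pixels are not biased toward zero.
#'
#' @param img A grid-space [contrast_image()].
#' @param fwhm Full width at half maximum, mm.
#' @return Smoothed [contrast_image()] with `smoothing_fwhm` recorded.
#' @export
smooth_gaussian <- function(img, fwhm = 14) {
  stopifnot(inherits(img, "contrast_image"))
  if (img$space != "grid2d") stop("smoothing applies to grid2d images",
                                  call. = FALSE)
  if (fwhm <= 0) stop("fwhm must be positive", call. = FALSE)
  grid <- img$geometry
  n <- grid$n
  sigma <- fwhm_to_sigma(fwhm) / grid$pixel_size
  h <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-h, h), sd = sigma)
  k <- k / sum(k)
  sm2d <- function(Mt) {
    Mt <- apply(Mt, 2, conv_same_1d, k = k)
    t(apply(t(Mt), 2, conv_same_1d, k = k))
  }
  V <- matrix(ifelse(img$mask, img$values, 0), n, n)
  W <- matrix(as.numeric(img$mask), n, n)
  num <- sm2d(V)
  den <- sm2d(W)
  out <- rep(NA_real_, n * n)
  out[img$mask] <- (as.vector(num) / pmax(as.vector(den), 1e-12))[img$mask]
  contrast_image("grid2d", out, img$mask, grid, img$subject_id,
                 smoothing_fwhm = fwhm)
}

#' @rdname smooth_gaussian
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Spherical-spline kernel (Legendre series)
#'
#' Evaluates `g_m(x) = (1/4pi) * sum_{n>=1} (2n+1) / (n (n+1))^m P_n(x)`
#' for `x = cos(angle)` in `[-1, 1]`, truncating the series once the
#' term bound `(2n+1)/(n(n+1))^m` falls below `tol`. Legendre
#' polynomials are evaluated by the stable three-term recurrence. The
#' series diverges for `m < 2`.
#'
#' @param x Cosine(s) of the angular distance, in `[-1, 1]`.
#' @param m Spline order (integer >= 2; default 4).
#' @param tol Truncation tolerance on the term bound.
#' @return Kernel value(s), same length as `x`.
#' @export
spline_g <- function(x, m = 4, tol = 1e-10) {
  if (m < 2) stop("spherical-spline series diverges for m < 2",
                  call. = FALSE)
  stopifnot(all(abs(x) <= 1 + 1e-9))
  x <- pmin(pmax(x, -1), 1)
  g <- numeric(length(x))
  p_prev <- rep(1, length(x))   # P_0
  p_cur <- x                    # P_1
  n <- 1
  repeat {
    coef <- (2 * n + 1) / (n * (n + 1))^m
    g <- g + coef * p_cur
    if (coef < tol) break
    p_next <- ((2 * n + 1) * x * p_cur - n * p_prev) / (n + 1)
    p_prev <- p_cur
    p_cur <- p_next
    n <- n + 1
    if (n > 10000) break
  }
  g / (4 * pi)
}

#' Fit a spherical spline to channel values
#'
#' Solves the augmented linear system that makes the interpolant
#' reproduce the channel values exactly while constraining the kernel
#' coefficients to sum to zero:
#' `[G + ridge I, 1; 1', 0] [k; k0] = [w; 0]`, with
#' `G[j, l] = g_m(cos(r_j, r_l))`.
#'
#' @param channel_dirs J x 3 unit direction matrix (or
#'   `sphere_projection`).
#' @param w Channel values (numeric or `channel_contrast`).
#' @param m Spline order (default 4).
#' @param tol Series truncation tolerance for [spline_g()].
#' @param ridge Optional diagonal regularization of G. The default is 0:
#'   the smooth order-4 kernel makes the system ill-conditioned for
#'   densely packed channel arrays, so the coefficients can be large and
#'   even a tiny ridge visibly perturbs the interpolant away from exact
#'   channel reproduction; one step of iterative refinement is used
#'   instead to polish the unregularized solution.
#' @return A list of class `spline_model`: `k0`, `k`, `channel_dirs`,
#'   `m`, `tol`.
#' @export
fit_spherical_spline <- function(channel_dirs, w, m = 4, tol = 1e-10,
                                 ridge = 0) {
  if (inherits(channel_dirs, "sphere_projection"))
    channel_dirs <- channel_dirs$dirs
  if (inherits(w, "channel_contrast")) w <- w$w
  D <- as.matrix(channel_dirs)
  J <- nrow(D)
  stopifnot(J >= 3, length(w) == J)
  D <- D / sqrt(rowSums(D^2))
  C <- tcrossprod(D)
  dup <- which(C > 1 - 1e-10 & upper.tri(C), arr.ind = TRUE)
  if (nrow(dup))
    stop("duplicate channel directions: ",
         paste(apply(dup, 1, paste, collapse = "/"), collapse = ", "),
         call. = FALSE)
  G <- spline_g(C, m = m, tol = tol)
  dim(G) <- dim(C)
  A <- rbind(cbind(G + diag(ridge, J), 1), c(rep(1, J), 0))
  b <- c(as.numeric(w), 0)
  sol <- solve(A, b)
  sol <- sol + solve(A, b - A %*% sol)   # one iterative-refinement step
  structure(list(k = sol[seq_len(J)], k0 = sol[J + 1], channel_dirs = D,
                 m = m, tol = tol),
            class = "spline_model")
}

#' Evaluate a spherical spline at points on the sphere
#'
#' `value(r) = k0 + sum_j k_j g_m(cos(r, r_j))`.
#'
#' @param model A [fit_spherical_spline()] result.
#' @param points N x 3 matrix of unit directions.
#' @return Numeric vector of interpolated values.
#' @export
eval_spherical_spline <- function(model, points) {
  P <- as.matrix(points)
  nrm <- sqrt(rowSums(P^2))
  if (any(abs(nrm - 1) > 1e-6))
    stop("evaluation points must be unit-norm directions", call. = FALSE)
  P <- P / nrm
  Gp <- spline_g(P %*% t(model$channel_dirs), m = model$m, tol = model$tol)
  dim(Gp) <- c(nrow(P), nrow(model$channel_dirs))
  as.numeric(model$k0 + Gp %*% model$k)
}

#' Per-subject contrast image on the 2D grid
#'
#' Convenience wrapper: piecewise-linear interpolation of channel
#' contrasts followed by Gaussian smoothing, restricted to an optional
#' search mask.
#'
#' @param w Channel contrasts (vector or `channel_contrast`).
#' @param channel_xy J x 2 planar channel coordinates, mm.
#' @param grid A [scalp_grid2d()].
#' @param fwhm Smoothing FWHM, mm (default 14).
#' @param mask Optional logical search mask intersected with the
#'   interpolation support.
#' @param subject_id Subject label.
#' @return A smoothed grid-space [contrast_image()].
#' @export
contrast_image_2d <- function(w, channel_xy, grid, fwhm = 14, mask = NULL,
                              subject_id = NA_character_) {
  img <- interp2d_linear(channel_xy, w, grid, subject_id)
  img <- smooth_gaussian(img, fwhm)
  if (!is.null(mask)) {
    keep <- img$mask & mask
    img <- contrast_image("grid2d", ifelse(keep, img$values, NA_real_),
                          keep, grid, img$subject_id, fwhm)
  }
  img
}

#' Per-subject contrast image on the 3D mesh
#'
#' Fits a spherical spline to the channel contrasts and evaluates it at
#' the mesh vertices (restricted to an optional search mask).
#'
#' @param w Channel contrasts (vector or `channel_contrast`).
#' @param channel_dirs J x 3 unit directions (or `sphere_projection`).
#' @param mesh A [make_canonical_mesh()].
#' @param m Spline order (default 4).
#' @param mask Optional logical vertex mask.
#' @param subject_id Subject label.
#' @return A mesh-space [contrast_image()].
#' @export
contrast_image_mesh <- function(w, channel_dirs, mesh, m = 4, mask = NULL,
                                subject_id = NA_character_) {
  if (inherits(w, "channel_contrast")) {
    if (is.na(subject_id)) subject_id <- w$subject_id
    w <- w$w
  }
  model <- fit_spherical_spline(channel_dirs, w, m = m)
  vals <- eval_spherical_spline(model, mesh$vertices)
  if (is.null(mask)) mask <- rep(TRUE, nrow(mesh$vertices))
  contrast_image("mesh3d", ifelse(mask, vals, NA_real_), mask, mesh,
                 subject_id)
}
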