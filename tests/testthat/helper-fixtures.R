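# Shared fixtures: every object is built in code, nothing read from disk.

# MBLL coefficients with hand-picked, well-conditioned test values
test_coeffs <- function() {
  mbll_coefficients(wavelengths = c(695, 830), distance = 3,
                    alpha_hbo = c(0.3, 1.0), alpha_hbr = c(1.9, 0.7),
                    dpf = c(6.0, 5.5))
}

make_hb <- function(x, fs = 10, J = 1) {
  X <- matrix(x, ncol = J)
  hb_series(X, -0.4 * X, fs)
}

random_sphere_dirs <- function(J, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  P <- matrix(stats::rnorm(3 * J), J, 3)
  P / sqrt(rowSums(P^2))
}

# One shared spatial setup for the standard 52-channel band
standard_geometry <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      lay <- default_probe_layout()
      proj <- project_channels_sphere(lay)
      xy <- project_channels_disc(proj)
      grid <- scalp_grid2d(64)
      cache <<- list(layout = lay, proj = proj, xy = xy, grid = grid,
                     mask2d = make_search_mask(grid, xy, 30))
    }
    cache
  }
})

rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}
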