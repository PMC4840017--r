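#' Optical probe layout
#'
#' Source, detector and channel positions in MNI coordinates (mm). When
#' channel positions are not supplied they are taken as source-detector
#' midpoints (the conventional definition of an fNIRS channel site).
#'
#' @param source_pos,detector_pos Matrices (n x 3) of positions, mm.
#' @param channel_pairs J x 2 integer matrix of (source, detector) row
#'   indices per channel.
#' @param channel_pos Optional J x 3 matrix of channel positions; checked
#'   against the pair midpoints (1 mm tolerance) when pairs are given.
#' @param channel_ids Channel labels.
#' @param separation Nominal source-detector separation, cm.
#' @return A list of class `probe_layout`.
#' @export
probe_layout <- function(source_pos, detector_pos, channel_pairs,
                         channel_pos = NULL, channel_ids = NULL,
                         separation = 3) {
  source_pos <- as.matrix(source_pos); detector_pos <- as.matrix(detector_pos)
  channel_pairs <- as.matrix(channel_pairs)
  stopifnot(ncol(source_pos) == 3, ncol(detector_pos) == 3,
            ncol(channel_pairs) == 2)
  J <- nrow(channel_pairs)
  mid <- (source_pos[channel_pairs[, 1], , drop = FALSE] +
            detector_pos[channel_pairs[, 2], , drop = FALSE]) / 2
  if (is.null(channel_pos)) {
    channel_pos <- mid
  } else {
    channel_pos <- as.matrix(channel_pos)
    stopifnot(nrow(channel_pos) == J)
    if (max(sqrt(rowSums((channel_pos - mid)^2))) > 1)
      warning("channel positions deviate from source-detector midpoints ",
              "by more than 1 mm", call. = FALSE)
  }
  if (is.null(channel_ids)) channel_ids <- paste0("CH", seq_len(J))
  structure(list(source_pos = source_pos, detector_pos = detector_pos,
                 channel_pairs = channel_pairs, channel_pos = channel_pos,
                 channel_ids = as.character(channel_ids),
                 separation = separation),
            class = "probe_layout")
}

#' @export
print.probe_layout <- function(x, ...) {
  cat(sprintf("probe_layout: %d sources, %d detectors, %d channels (%g cm)\n",
              nrow(x$source_pos), nrow(x$detector_pos),
              nrow(x$channel_pos), x$separation))
  invisible(x)
}

#' Canonical scalp mesh (subdivided icosahedron)
#'
#' Builds an icosphere: a regular icosahedron whose triangles are
#' subdivided `subdivisions` times (each subdivision splits every
#' triangle in four, merging shared edge midpoints) with all vertices
#' projected onto the unit sphere. Vertex count is `10 * 4^s + 2` and
#' face count `20 * 4^s`. The default of four subdivisions gives the
#' 2562-vertex canonical scalp surface.
#'
#' @param subdivisions Integer in 0..6.
#' @param radius Scalp radius in mm applied when evaluating areas and
#'   distances (vertices are stored unit-norm).
#' @return A list of class `scalp_mesh`: `vertices` (V x 3, unit norm),
#'   `faces` (F x 3, 1-based), `radius`.
#' @export
make_canonical_mesh <- function(subdivisions = 4, radius = 90) {
  stopifnot(subdivisions >= 0, subdivisions <= 6)
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    nv <- nrow(v)
    edge_key <- function(i, j) paste0(pmin(i, j), "_", pmax(i, j))
    mid_cache <- new.env(hash = TRUE)
    verts <- v
    midpoint <- function(i, j) {
      key <- edge_key(i, j)
      idx <- mid_cache[[key]]
      if (!is.null(idx)) return(idx)
      m <- (verts[i, ] + verts[j, ]) / 2
      m <- m / sqrt(sum(m^2))
      verts <<- rbind(verts, m)
      idx <- nrow(verts)
      mid_cache[[key]] <- idx
      idx
    }
    newf <- matrix(0L, 4 * nrow(f), 3)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; c3 <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c3); ca <- midpoint(c3, a)
      newf[(4 * k - 3):(4 * k), ] <- rbind(
        c(a, ab, ca), c(b, bc, ab), c(c3, ca, bc), c(ab, bc, ca))
    }
    v <- verts
    f <- newf
  }
  structure(list(vertices = v, faces = f, radius = radius),
            class = "scalp_mesh")
}

#' @export
print.scalp_mesh <- function(x, ...) {
  cat(sprintf("scalp_mesh: %d vertices, %d faces, radius %g mm\n",
              nrow(x$vertices), nrow(x$faces), x$radius))
  invisible(x)
}

#' Mesh edges (unique vertex pairs)
#'
#' @param mesh A [make_canonical_mesh()] result.
#' @return Integer matrix E x 2 with `[, 1] < [, 2]`.
#' @export
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  unique(e)
}

#' Regular 2D scalp grid
#'
#' Square pixel raster covering the planar 10-20 disc obtained from the
#' azimuthal-equidistant projection ([project_channels_disc()]). Pixel
#' centers span `[-extent, extent]` mm in each direction so the disc
#' inscribes the grid.
#'
#' @param n Pixels per side (default 64).
#' @param extent Disc radius, mm (default 90 * pi / 2, a 90 mm head
#'   sphere down to 90 degrees polar angle).
#' @return A list of class `scalp_grid2d`: `n`, `extent`, `pixel_size`,
#'   `x`, `y` (pixel center coordinates), `xy` (n^2 x 2, column-major
#'   over x then y), `disc` (logical n x n, inside the disc).
#' @export
scalp_grid2d <- function(n = 64, extent = 90 * pi / 2) {
  stopifnot(n >= 16, extent > 0)
  x <- seq(-extent, extent, length.out = n)
  pixel_size <- x[2] - x[1]
  xy <- cbind(rep(x, times = n), rep(x, each = n))
  disc <- matrix(sqrt(rowSums(xy^2)) <= extent + 1e-9, n, n)
  structure(list(n = n, extent = extent, pixel_size = pixel_size,
                 x = x, y = x, xy = xy, disc = disc),
            class = "scalp_grid2d")
}

#' Least-squares sphere fit
#'
#' Fits center and radius to points by the algebraic least-squares
#' linearization of `|x - c|^2 = r^2`.
#'
#' @param points n x 3 matrix.
#' @return List with `center` (length 3) and `radius`.
#' @export
fit_head_sphere <- function(points) {
  P <- as.matrix(points)
  stopifnot(nrow(P) >= 4)
  A <- cbind(2 * P, 1)
  b <- rowSums(P^2)
  sol <- qr.solve(A, b)
  center <- sol[1:3]
  radius <- sqrt(sol[4] + sum(center^2))
  list(center = as.numeric(center), radius = as.numeric(radius))
}

#' Project channel positions onto the head sphere
#'
#' Each channel is mapped to the unit sphere along the ray from the head
#' center; the head sphere is fitted to the channel positions when not
#' supplied.
#'
#' @param layout A [probe_layout()] or a J x 3 position matrix.
#' @param head_center,head_radius Optional sphere parameters (mm).
#' @return A list of class `sphere_projection`: `dirs` (J x 3 unit
#'   vectors), `head_center`, `head_radius`, `channel_ids`.
#' @export
project_channels_sphere <- function(layout, head_center = NULL,
                                    head_radius = NULL) {
  pos <- if (inherits(layout, "probe_layout")) layout$channel_pos else
    as.matrix(layout)
  ids <- if (inherits(layout, "probe_layout")) layout$channel_ids else
    rownames(pos)
  if (is.null(head_center) || is.null(head_radius)) {
    fit <- fit_head_sphere(pos)
    if (is.null(head_center)) head_center <- fit$center
    if (is.null(head_radius)) head_radius <- fit$radius
  }
  d <- sweep(pos, 2, head_center)
  nrm <- sqrt(rowSums(d^2))
  if (any(nrm < 1e-9))
    stop("channel position coincides with head center; projection ray ",
         "undefined", call. = FALSE)
  structure(list(dirs = d / nrm, head_center = head_center,
                 head_radius = head_radius, channel_ids = ids),
            class = "sphere_projection")
}

#' Azimuthal-equidistant projection onto the 10-20 disc
#'
#' Maps unit directions to the plane about the vertex (`+z`, the Cz
#' analogue): planar radius equals `head_radius` times the polar angle
#' (arc length from the vertex), azimuth preserved. The vertex maps to
#' the origin; the projection is undefined at its antipode.
#'
#' @param dirs J x 3 unit direction matrix, or a `sphere_projection`.
#' @param head_radius Scalp radius in mm (default taken from the
#'   projection object, else 90).
#' @return J x 2 matrix of planar coordinates, mm.
#' @export
project_channels_disc <- function(dirs, head_radius = NULL) {
  if (inherits(dirs, "sphere_projection")) {
    if (is.null(head_radius)) head_radius <- dirs$head_radius
    dirs <- dirs$dirs
  }
  if (is.null(head_radius)) head_radius <- 90
  dirs <- as.matrix(dirs)
  z <- pmin(pmax(dirs[, 3], -1), 1)
  theta <- acos(z)
  if (any(theta > pi - 1e-6))
    stop("channel at the antipode of the vertex: azimuth undefined",
         call. = FALSE)
  r <- head_radius * theta
  az <- atan2(dirs[, 2], dirs[, 1])
  az[theta < 1e-12] <- 0
  cbind(x = r * cos(az), y = r * sin(az))
}

#' Inverse of the disc projection
#'
#' @param xy J x 2 planar coordinates, mm.
#' @param head_radius Scalp radius, mm.
#' @return J x 3 unit direction matrix.
#' @export
disc_to_sphere <- function(xy, head_radius = 90) {
  xy <- as.matrix(xy)
  r <- sqrt(rowSums(xy^2))
  theta <- r / head_radius
  az <- atan2(xy[, 2], xy[, 1])
  az[r < 1e-12] <- 0
  cbind(sin(theta) * cos(az), sin(theta) * sin(az), cos(theta))
}

dist_point_segment <- function(p, a, b) {
  ab <- b - a
  t <- sum((p - a) * ab) / sum(ab^2)
  t <- min(max(t, 0), 1)
  sqrt(sum((p - (a + t * ab))^2))
}

point_in_polygon <- function(pts, poly) {
  # ray casting; poly is an ordered (closed implicitly) vertex matrix
  n <- nrow(poly)
  inside <- rep(FALSE, nrow(pts))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > pts[, 2]) != (yj > pts[, 2])) &
      (pts[, 1] < (xj - xi) * (pts[, 2] - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

#' Search-region mask around the channel array
#'
#' On the 2D grid: pixels within `support_radius` (Euclidean, mm) of any
#' channel, intersected with the channel convex hull dilated by the same
#' radius, and with the 10-20 disc. On the mesh: vertices within
#' `support_radius` geodesic distance (great-circle arc on the scalp
#' sphere) of any channel. The mask grows monotonically with
#' `support_radius`.
#'
#' @param geom A [scalp_grid2d()] or [make_canonical_mesh()].
#' @param channels For the grid, a J x 2 matrix of planar channel
#'   coordinates (mm); for the mesh, a J x 3 matrix of unit directions
#'   (or a `sphere_projection`).
#' @param support_radius Radius, mm (default 30, matching the 3 cm
#'   source-detector separation).
#' @return Logical mask: length n^2 (grid, column-major with x fastest)
#'   or V (mesh).
#' @export
make_search_mask <- function(geom, channels, support_radius = 30) {
  stopifnot(support_radius > 0)
  if (inherits(channels, "sphere_projection")) channels <- channels$dirs
  channels <- as.matrix(channels)
  if (inherits(geom, "scalp_grid2d")) {
    pts <- geom$xy
    d2 <- matrix(Inf, nrow(pts), 1)
    dmin <- rep(Inf, nrow(pts))
    for (j in seq_len(nrow(channels))) {
      dj <- sqrt((pts[, 1] - channels[j, 1])^2 +
                   (pts[, 2] - channels[j, 2])^2)
      dmin <- pmin(dmin, dj)
    }
    mask <- dmin <= support_radius
    if (nrow(channels) >= 3) {
      h <- grDevices::chull(channels)
      poly <- channels[h, , drop = FALSE]
      inside <- point_in_polygon(pts, poly)
      dh <- rep(Inf, nrow(pts))
      idx <- which(!inside & mask)
      if (length(idx)) {
        nh <- nrow(poly)
        for (k in seq_len(nh)) {
          a <- poly[k, ]; b <- poly[if (k == nh) 1 else k + 1, ]
          dh[idx] <- pmin(dh[idx], vapply(idx, function(i)
            dist_point_segment(pts[i, ], a, b), numeric(1)))
        }
      }
      dh[inside] <- 0
      mask <- mask & (dh <= support_radius)
    }
    mask <- mask & as.vector(geom$disc)
    if (!any(mask)) stop("empty search mask", call. = FALSE)
    return(mask)
  }
  if (inherits(geom, "scalp_mesh")) {
    V <- geom$vertices
    cosang <- V %*% t(channels)
    cosang <- pmin(pmax(cosang, -1), 1)
    arc <- geom$radius * acos(cosang)      # geodesic distance, mm
    mask <- unname(apply(arc, 1, min) <= support_radius)
    if (!any(mask)) stop("empty search mask", call. = FALSE)
    return(mask)
  }
  stop("geom must be a scalp_grid2d or scalp_mesh", call. = FALSE)
}

#' Nearest mesh vertex per channel
#'
#' @param mesh A [make_canonical_mesh()].
#' @param dirs J x 3 unit directions (or `sphere_projection`).
#' @return Integer vector of vertex indices.
#' @export
map_channels_to_vertices <- function(mesh, dirs) {
  if (inherits(dirs, "sphere_projection")) dirs <- dirs$dirs
  apply(as.matrix(dirs) %*% t(mesh$vertices), 1, which.max)
}
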