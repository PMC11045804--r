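# Core tetrahedral-mesh utilities shared by the generator, the mesh-motion
# pipeline and the flow solver. All coordinates are in meters; volumes are
# reported in mL (1 m^3 = 1e6 mL).

#' Signed volumes of tetrahedra
#'
#' @param vertices numeric matrix (n x 3) of vertex coordinates in meters.
#' @param tets integer matrix (m x 4) of 1-based vertex indices.
#' @return numeric vector of signed volumes in m^3 (positive for
#'   positively oriented elements).
#' @export
tet_volumes <- function(vertices, tets) {
  a <- vertices[tets[, 1], , drop = FALSE]
  b <- vertices[tets[, 2], , drop = FALSE] - a
  c <- vertices[tets[, 3], , drop = FALSE] - a
  d <- vertices[tets[, 4], , drop = FALSE] - a
  # det[b c d] / 6, expanded component-wise so it vectorizes over elements
  (b[, 1] * (c[, 2] * d[, 3] - c[, 3] * d[, 2]) -
    b[, 2] * (c[, 1] * d[, 3] - c[, 3] * d[, 1]) +
    b[, 3] * (c[, 1] * d[, 2] - c[, 2] * d[, 1])) / 6
}

# Reorder tets so all signed volumes are positive.
orient_tets <- function(vertices, tets) {
  v <- tet_volumes(vertices, tets)
  flip <- which(v < 0)
  if (length(flip)) {
    tmp <- tets[flip, 3]
    tets[flip, 3] <- tets[flip, 4]
    tets[flip, 4] <- tmp
  }
  dimnames(tets) <- NULL
  tets
}

#' Extract the boundary surface of a tetrahedral mesh
#'
#' Faces belonging to exactly one element form the boundary; for a mesh of
#' positively oriented tets the returned triangles are consistently
#' outward-oriented.
#'
#' @inheritParams tet_volumes
#' @return integer matrix (f x 3) of outward-oriented boundary triangles.
#' @export
boundary_facets <- function(vertices, tets) {
  m <- nrow(tets)
  # outward faces of a positively oriented tet (v1,v2,v3,v4)
  f <- rbind(
    cbind(tets[, 2], tets[, 3], tets[, 4]),
    cbind(tets[, 1], tets[, 4], tets[, 3]),
    cbind(tets[, 1], tets[, 2], tets[, 4]),
    cbind(tets[, 1], tets[, 3], tets[, 2])
  )
  key <- apply(f, 1L, function(r) paste(sort.int(r), collapse = "_"))
  tab <- table(key)
  f[key %in% names(tab)[tab == 1L], , drop = FALSE]
}

# Facet normals (not normalized), areas and centroids, vectorized.
facet_geometry <- function(vertices, facets) {
  a <- vertices[facets[, 1], , drop = FALSE]
  b <- vertices[facets[, 2], , drop = FALSE]
  c <- vertices[facets[, 3], , drop = FALSE]
  e1 <- b - a
  e2 <- c - a
  n2 <- cbind(
    e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
    e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
    e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  ) # = 2 * area * unit normal
  area <- 0.5 * sqrt(rowSums(n2^2))
  nrm <- n2 / pmax(2 * area, .Machine$double.xmin)
  list(normal = nrm, area = area, centroid = (a + b + c) / 3)
}

#' Enclosed volume of a closed triangulated surface
#'
#' Divergence-theorem volume \eqn{V = (1/3) \sum_f (x_c \cdot n) A_f},
#' evaluated through the equivalent origin-based determinant form (exactly
#' origin-invariant for closed surfaces).
#'
#' @param vertices numeric matrix (n x 3), meters.
#' @param facets integer matrix (f x 3) of outward-oriented triangles, or a
#'   `chamber_geometry` in place of `vertices` (facets then taken from it).
#' @param displacement optional (n x 3) displacement added to the vertices.
#' @return enclosed volume in mL.
#' @export
enclosed_volume <- function(vertices, facets = NULL, displacement = NULL) {
  if (inherits(vertices, "chamber_geometry")) {
    geom <- vertices
    facets <- geom$boundary_facets
    vertices <- geom$vertices
  }
  if (!is.null(displacement)) vertices <- vertices + displacement
  a <- vertices[facets[, 1], , drop = FALSE]
  b <- vertices[facets[, 2], , drop = FALSE]
  c <- vertices[facets[, 3], , drop = FALSE]
  v <- sum(a[, 1] * (b[, 2] * c[, 3] - b[, 3] * c[, 2]) -
    a[, 2] * (b[, 1] * c[, 3] - b[, 3] * c[, 1]) +
    a[, 3] * (b[, 1] * c[, 2] - b[, 2] * c[, 1])) / 6
  v * 1e6 # m^3 -> mL
}

#' Validate a closed, consistently oriented surface
#'
#' Checks that every edge is shared by exactly two triangles traversed in
#' opposite directions and that the enclosed volume is positive. This is the
#' orientation/closedness gate used on every displaced frame; it is a cheap
#' surrogate and does not attempt a full self-intersection sweep.
#'
#' @inheritParams enclosed_volume
#' @return TRUE invisibly; stops with a topology error otherwise.
#' @export
check_surface <- function(vertices, facets) {
  he <- rbind(
    facets[, c(1, 2)], facets[, c(2, 3)], facets[, c(3, 1)]
  )
  fwd <- paste(he[, 1], he[, 2])
  rev <- paste(he[, 2], he[, 1])
  if (anyDuplicated(fwd)) {
    stop("surface is not consistently oriented (duplicated directed edge)")
  }
  if (!all(fwd %in% rev)) {
    stop("surface is not closed (unmatched boundary edge)")
  }
  if (enclosed_volume(vertices, facets) <= 0) {
    stop("surface is inverted (non-positive enclosed volume)")
  }
  invisible(TRUE)
}

#' Euler characteristic of a triangulated surface
#'
#' @param facets integer matrix (f x 3).
#' @return integer V - E + F (2 for a closed genus-0 surface).
#' @export
surface_euler_characteristic <- function(facets) {
  vb <- length(unique(as.vector(facets)))
  e <- rbind(facets[, c(1, 2)], facets[, c(2, 3)], facets[, c(3, 1)])
  e <- unique(cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  vb - nrow(e) + nrow(facets)
}

#' Element quality (scaled-Jacobian surrogate)
#'
#' \eqn{q = 6\sqrt{2}\, V / l_{rms}^3} with \eqn{l_{rms}} the RMS edge
#' length; equals 1 on a regular tet, tends to 0 for slivers and is
#' negative for inverted elements.
#'
#' @inheritParams tet_volumes
#' @param displacement optional per-vertex displacement (n x 3).
#' @return numeric vector of per-element qualities.
#' @export
element_quality <- function(vertices, tets, displacement = NULL) {
  if (!is.null(displacement)) vertices <- vertices + displacement
  v <- tet_volumes(vertices, tets)
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  l2 <- 0
  for (k in seq_len(6)) {
    d <- vertices[tets[, pairs[k, 1]], , drop = FALSE] -
      vertices[tets[, pairs[k, 2]], , drop = FALSE]
    l2 <- l2 + rowSums(d^2)
  }
  lrms <- sqrt(l2 / 6)
  6 * sqrt(2) * v / lrms^3
}

#' Icosphere surface
#'
#' Recursively subdivided icosahedron projected to radius `r`; a standard
#' analytic fixture for the divergence-theorem volume.
#'
#' @param r radius in meters.
#' @param level number of 4-way subdivision levels (0 = icosahedron).
#' @return list with `vertices` (n x 3) and `facets` (f x 3, outward).
#' @export
icosphere <- function(r = 1, level = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (lev in seq_len(level)) {
    env <- new.env(hash = TRUE, parent = emptyenv())
    vlist <- lapply(seq_len(nrow(v)), function(i) v[i, ])
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      id <- env[[key]]
      if (is.null(id)) {
        vlist[[length(vlist) + 1L]] <<- (vlist[[i]] + vlist[[j]]) / 2
        id <- length(vlist)
        env[[key]] <- id
      }
      id
    }
    nf <- matrix(0L, nrow(f) * 4L, 3L)
    for (k in seq_len(nrow(f))) {
      i <- f[k, 1]; j <- f[k, 2]; l <- f[k, 3]
      a <- midpoint(i, j); b <- midpoint(j, l); c <- midpoint(l, i)
      nf[(k - 1L) * 4L + 1:4, ] <- rbind(
        c(i, a, c), c(j, b, a), c(l, c, b), c(a, b, c)
      )
    }
    f <- nf
    v <- do.call(rbind, vlist)
  }
  v <- v * (r / sqrt(rowSums(v^2)))
  list(vertices = v, facets = f)
}

# --- structured cube-to-ball tetrahedral meshing -------------------------

# 6-tet (Kuhn) decomposition of the unit cell, face-compatible across cells
# because every cell uses the same main diagonal.
.kuhn_tets <- matrix(
  c(
    1, 2, 4, 8,
    1, 4, 3, 8,
    1, 3, 7, 8,
    1, 7, 5, 8,
    1, 5, 6, 8,
    1, 6, 2, 8
  ),
  ncol = 4, byrow = TRUE
)

# Structured tet mesh of the cube [-1,1]^3 with n cells per axis.
# Returns list(vertices, tets); vertices include the origin when n is even.
structured_cube_mesh <- function(n) {
  g <- seq(-1, 1, length.out = n + 1)
  idx <- function(i, j, k) i + (n + 1L) * (j - 1L + (n + 1L) * (k - 1L))
  vv <- as.matrix(expand.grid(x = g, y = g, z = g))
  dimnames(vv) <- NULL
  cells <- expand.grid(i = seq_len(n), j = seq_len(n), k = seq_len(n))
  # corner order: (i,j,k),(i+1,j,k),(i,j+1,k),(i+1,j+1,k), then k+1 layer
  corner <- cbind(
    idx(cells$i, cells$j, cells$k),
    idx(cells$i + 1L, cells$j, cells$k),
    idx(cells$i, cells$j + 1L, cells$k),
    idx(cells$i + 1L, cells$j + 1L, cells$k),
    idx(cells$i, cells$j, cells$k + 1L),
    idx(cells$i + 1L, cells$j, cells$k + 1L),
    idx(cells$i, cells$j + 1L, cells$k + 1L),
    idx(cells$i + 1L, cells$j + 1L, cells$k + 1L)
  )
  tets <- do.call(rbind, lapply(seq_len(6), function(t) {
    corner[, .kuhn_tets[t, ], drop = FALSE]
  }))
  list(vertices = vv, tets = tets)
}

# Structured hexahedral grid on [0,1]^3 split into 24 tets per cell (cell
# center + 4 tets per face). Unlike the 6-tet Kuhn split, no tet has all
# four vertices on one grid shell, so curved boundary mappings (sphere,
# cylinder) cannot collapse corner elements into slivers.
structured_hex24_mesh <- function(nx, ny = nx, nz = nx) {
  gx <- seq(0, 1, length.out = nx + 1)
  gy <- seq(0, 1, length.out = ny + 1)
  gz <- seq(0, 1, length.out = nz + 1)
  mx <- (gx[-1] + gx[-(nx + 1)]) / 2
  my <- (gy[-1] + gy[-(ny + 1)]) / 2
  mz <- (gz[-1] + gz[-(nz + 1)]) / 2

  grid_pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  fx_pts <- as.matrix(expand.grid(x = gx, y = my, z = mz))
  fy_pts <- as.matrix(expand.grid(x = mx, y = gy, z = mz))
  fz_pts <- as.matrix(expand.grid(x = mx, y = my, z = gz))
  cc_pts <- as.matrix(expand.grid(x = mx, y = my, z = mz))
  dimnames(grid_pts) <- dimnames(fx_pts) <- dimnames(fy_pts) <-
    dimnames(fz_pts) <- dimnames(cc_pts) <- NULL
  vv <- rbind(grid_pts, fx_pts, fy_pts, fz_pts, cc_pts)

  ng <- nrow(grid_pts)
  o_fx <- ng
  o_fy <- o_fx + nrow(fx_pts)
  o_fz <- o_fy + nrow(fy_pts)
  o_cc <- o_fz + nrow(fz_pts)
  G <- function(i, j, k) i + (nx + 1L) * (j - 1L + (ny + 1L) * (k - 1L))
  FX <- function(i, j, k) o_fx + i + (nx + 1L) * (j - 1L + ny * (k - 1L))
  FY <- function(i, j, k) o_fy + i + nx * (j - 1L + (ny + 1L) * (k - 1L))
  FZ <- function(i, j, k) o_fz + i + nx * (j - 1L + ny * (k - 1L))
  CC <- function(i, j, k) o_cc + i + nx * (j - 1L + ny * (k - 1L))

  cl <- expand.grid(i = seq_len(nx), j = seq_len(ny), k = seq_len(nz))
  i <- cl$i; j <- cl$j; k <- cl$k
  cc <- CC(i, j, k)
  # per face: center id and the 4 corners in cyclic order
  faces <- list(
    list(FX(i, j, k),
         cbind(G(i, j, k), G(i, j + 1L, k), G(i, j + 1L, k + 1L),
               G(i, j, k + 1L))),
    list(FX(i + 1L, j, k),
         cbind(G(i + 1L, j, k), G(i + 1L, j + 1L, k),
               G(i + 1L, j + 1L, k + 1L), G(i + 1L, j, k + 1L))),
    list(FY(i, j, k),
         cbind(G(i, j, k), G(i + 1L, j, k), G(i + 1L, j, k + 1L),
               G(i, j, k + 1L))),
    list(FY(i, j + 1L, k),
         cbind(G(i, j + 1L, k), G(i + 1L, j + 1L, k),
               G(i + 1L, j + 1L, k + 1L), G(i, j + 1L, k + 1L))),
    list(FZ(i, j, k),
         cbind(G(i, j, k), G(i + 1L, j, k), G(i + 1L, j + 1L, k),
               G(i, j + 1L, k))),
    list(FZ(i, j, k + 1L),
         cbind(G(i, j, k + 1L), G(i + 1L, j, k + 1L),
               G(i + 1L, j + 1L, k + 1L), G(i, j + 1L, k + 1L)))
  )
  tets <- vector("list", 24L)
  t_i <- 0L
  for (f in faces) {
    fc <- f[[1]]
    cr <- f[[2]]
    for (e in 1:4) {
      a <- cr[, e]
      b <- cr[, if (e == 4L) 1L else e + 1L]
      t_i <- t_i + 1L
      tets[[t_i]] <- cbind(cc, fc, a, b)
    }
  }
  list(vertices = vv, tets = do.call(rbind, tets))
}

# Map cube vertices to the closed star-shaped solid with direction-dependent
# radius `radius_fun(dirs) -> r` (meters). Nested cube shells map to nested
# scaled copies of the boundary, so the radial coordinate survives as the
# max-norm of the parametric point.
map_cube_to_star <- function(vertices, radius_fun) {
  s <- pmax(abs(vertices[, 1]), abs(vertices[, 2]), abs(vertices[, 3]))
  l2 <- sqrt(rowSums(vertices^2))
  nz <- l2 > 0
  dir <- vertices
  dir[nz, ] <- dir[nz, ] / l2[nz]
  r <- rep(0, nrow(vertices))
  r[nz] <- radius_fun(dir[nz, , drop = FALSE])
  dir * (s * r)
}
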