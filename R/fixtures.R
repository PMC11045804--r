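# Analytic mesh fixtures: straight and bent tubes (Poiseuille flow and
# appendage-centerline validation), a box (simple-shear checks) and a ball.
# All are synthetic constructions with known closed forms, returned as
# `chamber_geometry` objects so the downstream operators apply unchanged.

#' Tube mesh fixture (straight or quarter-torus)
#'
#' A structured tetrahedral tube of radius `radius`. For
#' `kind = "straight"` the axis is the z-segment of length `length`; for
#' `kind = "quarter_torus"` the axis is a quarter circle of arc length
#' `length` (bend radius 2*length/pi) starting along +z. The lateral
#' surface is tagged WALL, the starting cross-section `end_tags[1]` and the
#' far cross-section `end_tags[2]`. The whole tube is registered as the
#' appendage (`laa_cells`, `laa_wall_vertices`) with the starting rim as
#' `ostium_ring`, so the centerline and tortuosity operators can be
#' validated against the analytic axis.
#'
#' @param kind "straight" or "quarter_torus".
#' @param length axis (arc) length in meters.
#' @param radius tube radius in meters.
#' @param n_cross grid cells across the diameter.
#' @param n_axial grid cell layers along the axis.
#' @param end_tags length-2 character, region tags of the two end disks.
#' @param closed_end tag the far cross-section as WALL instead of
#'   `end_tags[2]`, turning the tube into a closed pouch whose apex is the
#'   natural centerline endpoint (used by the appendage fixtures).
#' @return a `chamber_geometry`.
#' @export
tube_mesh <- function(kind = c("straight", "quarter_torus"),
                      length = 0.02, radius = 0.005,
                      n_cross = 4, n_axial = 8,
                      end_tags = c("MV", "PV1"), closed_end = FALSE) {
  kind <- match.arg(kind)
  stopifnot(length > 0, radius > 0, n_cross >= 2, n_axial >= 2)
  hm <- structured_hex24_mesh(as.integer(n_cross), as.integer(n_cross),
                              as.integer(n_axial))
  pv <- hm$vertices
  ab <- 2 * pv[, 1:2, drop = FALSE] - 1
  smax <- pmax(abs(ab[, 1]), abs(ab[, 2]))
  l2 <- sqrt(rowSums(ab^2))
  nz <- l2 > 0
  disk <- ab
  disk[nz, ] <- disk[nz, ] / l2[nz]
  disk <- disk * (smax * radius)
  s <- pv[, 3]
  if (closed_end) {
    # round the far end into a near-hemispherical dome (apex slightly
    # truncated so the cap keeps nonzero area): the pouch then has an
    # unambiguous tip for the centerline operators
    zeta <- pmax(0, (s * length - (length - radius)) / radius)
    f <- sqrt(pmax(1 - (0.95 * zeta)^2, 0))
    disk <- disk * f
  }
  if (kind == "straight") {
    vv <- cbind(disk[, 1], disk[, 2], s * length)
  } else {
    rb <- 2 * length / pi
    phi <- s * pi / 2
    # center curve rb*(1-cos, 0, sin); cross-section basis
    # e1 = (cos, 0, -sin), e2 = (0, 1, 0)
    vv <- cbind(
      rb * (1 - cos(phi)) + disk[, 1] * cos(phi),
      disk[, 2],
      rb * sin(phi) - disk[, 1] * sin(phi)
    )
  }
  tets <- orient_tets(vv, hm$tets)
  bf <- boundary_facets(vv, tets)
  s_f <- (s[bf[, 1]] + s[bf[, 2]] + s[bf[, 3]]) / 3
  tag <- rep(REGION_TAGS[["WALL"]], nrow(bf))
  tag[s_f < 1e-9] <- REGION_TAGS[[end_tags[1]]]
  if (!closed_end) tag[s_f > 1 - 1e-9] <- REGION_TAGS[[end_tags[2]]]

  wall_f <- tag == REGION_TAGS[["WALL"]]
  start_f <- tag == REGION_TAGS[[end_tags[1]]]
  ring <- .order_ring(.region_boundary_edges(bf, start_f))

  geom <- structure(list(
    vertices = vv, tets = tets, boundary_facets = bf,
    boundary_tag = as.integer(tag), tag_legend = REGION_TAGS,
    laa_wall_vertices = sort(unique(as.vector(bf[wall_f, , drop = FALSE]))),
    laa_cells = seq_len(nrow(tets)), ostium_ring = ring,
    params = list(kind = kind, length = length, radius = radius),
    laa_axis = c(0, 0, 1)
  ), class = "chamber_geometry")
  check_surface(vv, bf)
  geom
}

#' Box mesh fixture
#'
#' Structured tetrahedral mesh of the box `[0, Lx] x [0, Ly] x [0, Lz]`
#' with the `y = 0` face tagged WALL and all remaining faces tagged MV (a
#' plain catch-all); used for simple-shear wall-stress checks.
#'
#' @param dims length-3 box edge lengths (m).
#' @param n grid cells per axis.
#' @return a `chamber_geometry` (without appendage metadata).
#' @export
box_mesh <- function(dims = c(0.01, 0.01, 0.01), n = 4) {
  hm <- structured_hex24_mesh(as.integer(n))
  vv <- sweep(hm$vertices, 2, dims, `*`)
  tets <- orient_tets(vv, hm$tets)
  bf <- boundary_facets(vv, tets)
  fg <- facet_geometry(vv, bf)
  tag <- rep(REGION_TAGS[["MV"]], nrow(bf))
  tag[abs(fg$centroid[, 2]) < 1e-12] <- REGION_TAGS[["WALL"]]
  structure(list(
    vertices = vv, tets = tets, boundary_facets = bf,
    boundary_tag = as.integer(tag), tag_legend = REGION_TAGS,
    laa_wall_vertices = integer(0), laa_cells = integer(0),
    ostium_ring = integer(0),
    params = list(kind = "box", dims = dims), laa_axis = c(0, 0, 1)
  ), class = "chamber_geometry")
}

#' Tetrahedral ball mesh
#'
#' Structured cube-to-ball mesh of a sphere of radius `r`; analytic fixture
#' for volume, distance-field and rotation checks.
#'
#' @param r radius (m).
#' @param n grid cells per axis of the parametric cube.
#' @return a `chamber_geometry` whose whole boundary is tagged WALL.
#' @export
ball_mesh <- function(r = 0.01, n = 4) {
  hm <- structured_hex24_mesh(as.integer(n))
  vv <- map_cube_to_star(2 * hm$vertices - 1, function(dirs) {
    rep(r, nrow(dirs))
  })
  tets <- orient_tets(vv, hm$tets)
  bf <- boundary_facets(vv, tets)
  structure(list(
    vertices = vv, tets = tets, boundary_facets = bf,
    boundary_tag = rep(REGION_TAGS[["WALL"]], nrow(bf)),
    tag_legend = REGION_TAGS,
    laa_wall_vertices = integer(0), laa_cells = integer(0),
    ostium_ring = integer(0),
    params = list(kind = "ball", r = r), laa_axis = c(0, 0, 1)
  ), class = "chamber_geometry")
}
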