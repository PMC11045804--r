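# Volumetric mesh motion: stiffened harmonic lifting of the wall
# displacement into the interior. The scalar diffusion coefficient
# psi(x) = max(d(x), alpha)^(-beta), with d the distance to the endocardial
# wall, stiffens near-wall elements so they move nearly rigidly and avoid
# distortion; the problem decouples into three scalar SPD solves sharing
# one factorization, reused across all collocation times.

#' Lifting configuration
#'
#' @param alpha distance floor (m); default 1.5 mm.
#' @param beta stiffening exponent; default 2 (0 disables stiffening).
#' @param linear_tolerance relative residual accepted from the linear solve.
#' @return object of class `lifting_config`.
#' @export
lifting_config <- function(alpha = 1.5e-3, beta = 2,
                           linear_tolerance = 1e-9) {
  if (alpha <= 0) stop("alpha must be > 0")
  if (beta < 0) stop("beta must be >= 0")
  structure(list(alpha = alpha, beta = beta,
                 linear_tolerance = linear_tolerance),
            class = "lifting_config")
}

#' Distance of every mesh vertex to the endocardial wall
#'
#' Exact point-to-triangle-set distance against the WALL-tagged facets of
#' the reference configuration (zero on wall vertices).
#'
#' @param geom a `chamber_geometry`.
#' @return numeric vector, one distance (m) per vertex.
#' @export
wall_distance_field <- function(geom) {
  wf <- geom$boundary_facets[
    geom$boundary_tag == geom$tag_legend[["WALL"]], , drop = FALSE
  ]
  if (nrow(wf) == 0) stop("tagging error: no WALL facets")
  .point_tri_dist_cpp(geom$vertices, geom$vertices, wf)
}

# assemble the stiffened Laplacian and return a solve operator for the
# interior values given wall Dirichlet data; factorization is cached
.lifting_operator <- function(geom, cfg) {
  dist <- wall_distance_field(geom)
  tets <- geom$tets
  d_elem <- (dist[tets[, 1]] + dist[tets[, 2]] + dist[tets[, 3]] +
    dist[tets[, 4]]) / 4
  psi <- pmax(d_elem, cfg$alpha)^(-cfg$beta)
  tr <- .asm_scalar_stiffness_cpp(geom$vertices, tets, psi)
  n <- nrow(geom$vertices)
  K <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x, dims = c(n, n))
  w <- wall_vertices(geom)
  f <- setdiff(seq_len(n), w)
  Kff <- K[f, f, drop = FALSE]
  Kfd <- K[f, w, drop = FALSE]
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(Kff), LDL = FALSE)
  list(
    wall = w, free = f,
    solve = function(G) {
      # G: n_wall x m Dirichlet data; returns full n x m field
      rhs <- -(Kfd %*% G)
      xf <- as.matrix(Matrix::solve(ch, rhs))
      out <- matrix(0, n, ncol(G))
      out[w, ] <- as.matrix(G)
      out[f, ] <- xf
      res <- sqrt(sum((Kff %*% xf - rhs)^2))
      nrm <- sqrt(sum(rhs^2))
      if (nrm > 0 && res / nrm > cfg$linear_tolerance) {
        stop(sprintf("lifting solve did not converge: residual %.2e", res / nrm))
      }
      out
    }
  )
}

#' Harmonic lifting of a wall displacement into the volume
#'
#' Solves, component-wise, the stiffened scalar diffusion problem with the
#' given Dirichlet data on the wall and homogeneous natural conditions on
#' the PV/MV disks; wall values are imposed strongly (reproduced exactly).
#'
#' @param geom a `chamber_geometry`.
#' @param boundary_disp matrix (n_wall x 3) of wall displacements (m), rows
#'   ordered as [wall_vertices()].
#' @param cfg a `lifting_config`.
#' @return matrix (n_vertices x 3) of volumetric displacement.
#' @export
harmonic_lifting <- function(geom, boundary_disp, cfg = lifting_config()) {
  op <- .lifting_operator(geom, cfg)
  stopifnot(nrow(boundary_disp) == length(op$wall))
  op$solve(as.matrix(boundary_disp))
}

#' Volumetric motion over one period
#'
#' Solves the lifting at the collocation times (by default the frame times
#' of the displacement model) and interpolates the lifted fields in time
#' with the same periodic-spline machinery (interpolating), so the ALE
#' velocity is the exact analytic derivative of the interpolant.
#'
#' @param geom a `chamber_geometry`.
#' @param model a `displacement_model`.
#' @param cfg a `lifting_config`.
#' @param time_grid collocation times within one period; defaults to the
#'   spline knots of the model (the frame times).
#' @return object of class `volumetric_motion` with evaluators
#'   `displacement(t)` and `velocity(t)` over all mesh vertices.
#' @export
volumetric_motion <- function(geom, model, cfg = lifting_config(),
                              time_grid = NULL) {
  stopifnot(inherits(model, "displacement_model"))
  if (is.null(time_grid)) {
    time_grid <- model$spline$knots[-length(model$spline$knots)]
  }
  op <- .lifting_operator(geom, cfg)
  if (!identical(op$wall, model$wall_vertex_ids)) {
    stop("displacement model wall vertices do not match the geometry")
  }
  n <- nrow(geom$vertices)
  nt <- length(time_grid)
  lifted <- matrix(0, nt, 3L * n)
  for (k in seq_len(nt)) {
    G <- eval_displacement_model(model, time_grid[k])
    D <- op$solve(G)
    q <- element_quality(geom$vertices, geom$tets, displacement = D)
    if (min(q) <= 0) {
      stop(sprintf(
        "mesh-validity error: inverted element at t = %.4f s", time_grid[k]
      ))
    }
    lifted[k, ] <- as.vector(D) # column-major: x-block, y-block, z-block
  }
  sp <- periodic_spline_fit(time_grid, lifted, model$period,
    smoothing_weight = 0
  )
  structure(list(
    spline = sp, period = model$period, n_vertices = n,
    collocation_times = time_grid,
    displacement = function(t) {
      matrix(periodic_spline_eval(sp, t), ncol = 3)
    },
    velocity = function(t) {
      matrix(periodic_spline_eval(sp, t, deriv = 1), ncol = 3)
    }
  ), class = "volumetric_motion")
}

# zero-motion stand-in for rigid-domain runs
static_motion <- function(geom, period = Inf) {
  n <- nrow(geom$vertices)
  z <- matrix(0, n, 3)
  structure(list(
    spline = NULL, period = period, n_vertices = n,
    collocation_times = numeric(0),
    displacement = function(t) z,
    velocity = function(t) z
  ), class = "volumetric_motion")
}
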