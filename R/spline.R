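# Periodic cubic smoothing splines in time, fitted jointly to many scalar
# components sharing the same frame times (one basis, one factorization,
# many right-hand sides). The penalty is the integrated squared second
# derivative; smoothing_weight = 0 gives the periodic interpolating spline
# and the default weight is chosen by generalized cross-validation.

# cyclic cubic B-spline design matrix on [knots[1], knots[nk]]
.cyclic_basis <- function(x, knots, derivs = 0) {
  mgcv::cSplineDes(x, knots, ord = 4, derivs = derivs)
}

# curvature penalty S = integral of B'' B''^T by 3-point Gauss-Legendre
# on every inter-knot interval (exact: B'' is piecewise linear)
.cyclic_penalty <- function(knots) {
  gl <- .gauss_legendre(3)
  nb <- length(knots) - 1L
  S <- matrix(0, nb, nb)
  for (i in seq_len(length(knots) - 1L)) {
    a <- knots[i]
    b <- knots[i + 1L]
    if (b - a <= 0) next
    xq <- (a + b) / 2 + (b - a) / 2 * gl$x
    wq <- (b - a) / 2 * gl$w
    B2 <- .cyclic_basis(xq, knots, derivs = 2)
    S <- S + crossprod(B2 * sqrt(wq))
  }
  S
}

#' Fit a periodic smoothing spline to multi-component periodic samples
#'
#' @param times sample times (s), strictly increasing, within one period.
#' @param Y numeric matrix, one row per time, one column per component.
#' @param period the period (s).
#' @param smoothing_weight penalty weight `lambda >= 0`; `NULL` selects it
#'   by generalized cross-validation pooled over components.
#' @return object of class `periodic_spline` with an evaluator for values
#'   and analytic derivatives.
#' @export
periodic_spline_fit <- function(times, Y, period, smoothing_weight = NULL) {
  Y <- as.matrix(Y)
  if (length(times) < 4) stop("insufficient data: need at least 4 frames")
  if (anyDuplicated(times)) stop("duplicate frame times")
  if (is.unsorted(times, strictly = TRUE)) stop("times must be increasing")
  if (max(times) - min(times) >= period) {
    stop("times must lie within one period")
  }
  knots <- c(times, times[1] + period)
  B <- .cyclic_basis(times, knots)
  BtB <- crossprod(B)
  S <- .cyclic_penalty(knots)
  BtY <- crossprod(B, Y)

  pick_gcv <- function() {
    sc <- sum(diag(BtB)) / max(sum(diag(S)), .Machine$double.eps)
    grid <- sc * 10^seq(-8, 2, by = 0.5)
    n <- nrow(B)
    best <- 0
    best_gcv <- Inf
    for (lam in grid) {
      M <- tryCatch(solve(BtB + lam * S, t(B)), error = function(e) NULL)
      if (is.null(M)) next
      H <- B %*% M
      edf <- sum(diag(H))
      if (n - edf < 0.5) next
      R <- Y - H %*% Y
      gcv <- n * sum(R^2) / (n - edf)^2
      if (gcv < best_gcv) {
        best_gcv <- gcv
        best <- lam
      }
    }
    best
  }
  lam <- if (is.null(smoothing_weight)) pick_gcv() else smoothing_weight
  if (lam < 0) stop("smoothing_weight must be >= 0")
  A <- BtB + lam * S
  theta <- solve(A, BtY)
  structure(list(
    knots = knots, period = period, t0 = times[1], theta = theta,
    smoothing_weight = lam
  ), class = "periodic_spline")
}

#' Evaluate a periodic spline (or its analytic time derivative)
#'
#' @param sp a `periodic_spline`.
#' @param t evaluation times (s); wrapped into the period.
#' @param deriv derivative order (0, 1 or 2).
#' @return matrix (length(t) x n_components).
#' @export
periodic_spline_eval <- function(sp, t, deriv = 0) {
  tw <- sp$knots[1] + (t - sp$knots[1]) %% sp$period
  # guard the upper boundary against rounding past the last knot
  tw <- pmin(tw, sp$knots[length(sp$knots)])
  .cyclic_basis(tw, sp$knots, derivs = deriv) %*% sp$theta
}

#' Temporal displacement model of the moving wall
#'
#' Fits one periodic smoothing spline per wall-vertex component to the
#' frame-wise boundary displacements (shared basis and factorization).
#'
#' @param frames a `frame_set`.
#' @param smoothing_weight penalty weight; `NULL` (default) uses GCV, 0
#'   interpolates the frames exactly.
#' @return object of class `displacement_model`.
#' @export
fit_displacement_model <- function(frames, smoothing_weight = NULL) {
  stopifnot(inherits(frames, "frame_set"))
  if (length(frames$frame_times) < 4) {
    stop("insufficient data: need at least 4 frames")
  }
  nw <- length(frames$wall_vertex_ids)
  Y <- do.call(cbind, lapply(1:3, function(c) {
    do.call(rbind, lapply(frames$displacements, function(d) d[, c]))
  })) # n_frames x (3 * nw), component-major blocks
  sp <- periodic_spline_fit(frames$frame_times, Y, frames$period,
    smoothing_weight = smoothing_weight
  )
  structure(list(
    spline = sp, wall_vertex_ids = frames$wall_vertex_ids,
    period = frames$period, n_wall = nw,
    smoothing_weight = sp$smoothing_weight
  ), class = "displacement_model")
}

#' Evaluate the wall displacement model
#'
#' @param model a `displacement_model`.
#' @param t a single time (s).
#' @param deriv 0 for displacement (m), 1 for velocity (m/s).
#' @return matrix (n_wall x 3).
#' @export
eval_displacement_model <- function(model, t, deriv = 0) {
  stopifnot(inherits(model, "displacement_model"), length(t) == 1)
  v <- periodic_spline_eval(model$spline, t, deriv = deriv)
  matrix(v, ncol = 3, dimnames = NULL)
}

#' Boundary ALE velocity (analytic spline derivative)
#'
#' @inheritParams eval_displacement_model
#' @return matrix (n_wall x 3) in m/s.
#' @export
ale_boundary_velocity <- function(model, t) {
  eval_displacement_model(model, t, deriv = 1)
}
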