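# Functional and morphological biomarkers: chamber volumes, stroke volume,
# ejection fraction, transmitral E/A-wave analysis, appendage centerline,
# tortuosity (arc length over chord minus one) and ostium area.

#' Volume extrema over the final period of a trace
#'
#' @param trace a `volume_trace` (period taken from its attribute; the
#'   final full period is analysed).
#' @return list with `v_max`, `v_min`, `sv` (mL) and `ef`.
#' @export
volume_extrema <- function(trace) {
  if (!is.data.frame(trace) || nrow(trace) == 0) stop("empty volume trace")
  per <- attr(trace, "period")
  tt <- trace$time
  vv <- trace$volume
  if (!is.null(per) && is.finite(per)) {
    keep <- tt >= max(tt) - per - 1e-12
    vv <- vv[keep]
  }
  v_max <- max(vv)
  v_min <- min(vv)
  sv <- v_max - v_min
  list(v_max = v_max, v_min = v_min, sv = sv,
       ef = if (v_max > 0) sv / v_max else 0)
}

# strict local maxima with topographic prominence above `min_prom`
.prominent_peaks <- function(x, min_prom) {
  n <- length(x)
  if (n < 3) return(integer(0))
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
  keep <- logical(length(cand))
  for (ci in seq_along(cand)) {
    i <- cand[ci]
    # lowest point between the peak and the nearest higher ground each side
    left <- x[seq_len(i - 1)]
    hi_l <- which(left > x[i])
    min_l <- min(x[(if (length(hi_l)) max(hi_l) else 1):(i - 1)])
    right <- x[(i + 1):n]
    hi_r <- which(right > x[i])
    min_r <- min(x[(i + 1):(if (length(hi_r)) i + min(hi_r) else n)])
    prom <- x[i] - max(min_l, min_r)
    keep[ci] <- prom >= min_prom
  }
  cand[keep]
}

#' E/A-wave analysis of a transmitral flowrate trace
#'
#' Restricted to the valve-open interval of the final period, detects the
#' prominent local maxima of the outflow (prominence at least 5% of the
#' peak outflow): the first is the E-wave peak, the last the A-wave peak.
#'
#' @param q_mv data.frame with columns `time` (s) and `q` (mL/s, positive
#'   out of the chamber).
#' @param schedule data.frame (`time`, `state`) from [mv_schedule()].
#' @param period heartbeat period (s).
#' @param min_prominence_frac prominence threshold as a fraction of the
#'   maximum outflow.
#' @return list with `e_peak`, `a_peak` (mL/s), `ea_ratio`, `e_time`,
#'   `a_time` (s, within one period).
#' @export
ea_analysis <- function(q_mv, schedule, period,
                        min_prominence_frac = 0.05) {
  stopifnot(all(c("time", "q") %in% names(q_mv)))
  bc <- boundary_spec(mv_schedule = schedule)
  tt <- q_mv$time
  keep <- tt > max(tt) - period + 1e-12
  tt <- tt[keep]
  qq <- q_mv$q[keep]
  open <- vapply(tt, function(t) .mv_open(bc, t, period), logical(1))
  if (!any(open)) stop("wave-detection error: valve never open in trace")
  to <- tt[open]
  qo <- qq[open]
  ord <- order(to %% period)
  to <- to[ord]
  qo <- qo[ord]
  pk <- .prominent_peaks(qo, min_prominence_frac * max(qo))
  if (length(pk) < 2) {
    stop(sprintf(
      "wave-detection error: found %d prominent outflow peak(s), need 2",
      length(pk)
    ))
  }
  e_i <- pk[1]
  a_i <- pk[length(pk)]
  list(
    e_peak = qo[e_i], a_peak = qo[a_i], ea_ratio = qo[e_i] / qo[a_i],
    e_time = to[e_i] %% period, a_time = to[a_i] %% period
  )
}

#' Centerline tortuosity
#'
#' \eqn{\tau = \ell/d - 1} with \eqn{\ell} the polyline arc length and `d`
#' the Euclidean distance of the endpoints.
#'
#' @param cl a `centerline` (ordered n x 3 matrix of points, n >= 2).
#' @return dimensionless tortuosity (>= 0 up to discretization).
#' @export
tortuosity <- function(cl) {
  cl <- unclass(as.matrix(cl))
  if (nrow(cl) < 2) stop("centerline needs at least 2 points")
  seg <- diff(cl)
  ell <- sum(sqrt(rowSums(seg^2)))
  d <- sqrt(sum((cl[nrow(cl), ] - cl[1, ])^2))
  if (d <= .Machine$double.eps) {
    stop("degenerate geometry: coincident centerline endpoints")
  }
  ell / d - 1
}

#' Appendage centerline
#'
#' Interior path from the ostium-ring centroid to the appendage tip: the
#' tip is the appendage wall vertex farthest (by intra-appendage graph
#' distance) from the ostium; the path is the shortest interior path with
#' edge weights length / wall-distance (pulling it onto the medial axis),
#' resampled to `n_points` equal-arc points.
#'
#' @param geom a `chamber_geometry` with appendage metadata.
#' @param displacement optional current mesh displacement (n x 3).
#' @param n_points points on the returned polyline.
#' @return a `centerline` (n_points x 3 matrix).
#' @export
laa_centerline <- function(geom, displacement = NULL, n_points = 50) {
  if (!length(geom$laa_cells) || !length(geom$ostium_ring)) {
    stop("tagging error: geometry has no appendage (laa_cells/ostium_ring)")
  }
  verts <- geom$vertices
  if (!is.null(displacement)) verts <- verts + displacement
  cells <- geom$tets[geom$laa_cells, , drop = FALSE]
  vids <- sort(unique(as.vector(cells)))
  local <- match(seq_len(nrow(verts)), vids) # global -> local

  # unique edges of the appendage tets
  ep <- rbind(
    cells[, c(1, 2)], cells[, c(1, 3)], cells[, c(1, 4)],
    cells[, c(2, 3)], cells[, c(2, 4)], cells[, c(3, 4)]
  )
  ep <- unique(cbind(pmin(ep[, 1], ep[, 2]), pmax(ep[, 1], ep[, 2])))
  len <- sqrt(rowSums((verts[ep[, 1], , drop = FALSE] -
    verts[ep[, 2], , drop = FALSE])^2))

  wf <- geom$boundary_facets[
    geom$boundary_tag == geom$tag_legend[["WALL"]], , drop = FALSE
  ]
  dwall <- .point_tri_dist_cpp(verts[vids, , drop = FALSE], verts, wf)
  dmap <- rep(0, nrow(verts))
  dmap[vids] <- dwall
  floor_d <- 0.05 * max(dwall)
  wgt <- len / pmax((dmap[ep[, 1]] + dmap[ep[, 2]]) / 2, floor_d)

  g <- igraph::graph_from_edgelist(
    cbind(local[ep[, 1]], local[ep[, 2]]),
    directed = FALSE
  )
  ring_c <- colMeans(verts[geom$ostium_ring, , drop = FALSE])
  d2 <- rowSums(sweep(verts[vids, , drop = FALSE], 2, ring_c)^2)
  start <- which.min(d2)

  # tip: appendage wall vertex farthest from the ostium ring (multi-source
  # geometric graph distance), i.e. the apex of the pouch
  wall_local <- which(vids %in% geom$laa_wall_vertices)
  if (!length(wall_local)) wall_local <- seq_along(vids)
  ring_local <- stats::na.omit(match(geom$ostium_ring, vids))
  src <- if (length(ring_local)) as.integer(ring_local) else start
  dring <- igraph::distances(g, v = src, weights = len)
  dmin <- apply(dring, 2, min)
  tip <- wall_local[which.max(dmin[wall_local])]

  path <- igraph::shortest_paths(g, from = start, to = tip,
                                 weights = wgt)$vpath[[1]]
  pts <- verts[vids[as.integer(path)], , drop = FALSE]
  pts <- rbind(ring_c, pts)
  # note: no smoothing pass -- averaging systematically cuts corners and
  # shortens curved centerlines, biasing the tortuosity low; the residual
  # grid zigzag inflates lengths by only a few percent at desk resolution
  # drop zero-length segments, then resample to equal arc length
  seg <- sqrt(rowSums(diff(pts)^2))
  pts <- pts[c(TRUE, seg > 0), , drop = FALSE]
  seg <- seg[seg > 0]
  s <- c(0, cumsum(seg))
  if (s[length(s)] <= 0) stop("degenerate geometry: zero-length centerline")
  su <- seq(0, s[length(s)], length.out = n_points)
  out <- sapply(1:3, function(c) stats::approx(s, pts[, c], xout = su)$y)
  structure(out, class = c("centerline", class(out)))
}

#' Ostium area
#'
#' Area of the ostium-ring polygon projected onto its least-squares plane.
#'
#' @param geom a `chamber_geometry`.
#' @param displacement optional current mesh displacement (n x 3).
#' @return area in mm^2.
#' @export
ostium_area <- function(geom, displacement = NULL) {
  ring <- geom$ostium_ring
  if (length(ring) < 3) stop("topology error: ostium ring not closed")
  verts <- geom$vertices
  if (!is.null(displacement)) verts <- verts + displacement
  p <- verts[ring, , drop = FALSE]
  ctr <- colMeans(p)
  pc <- sweep(p, 2, ctr)
  sv <- svd(pc)
  uv <- pc %*% sv$v[, 1:2] # in-plane coordinates
  x <- uv[, 1]; y <- uv[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2 * 1e6 # m^2 -> mm^2
}

#' Functional summary of one case
#'
#' Collects the volume-derived metrics, E/A analysis and the appendage
#' morphology evaluated at the minimum-volume configuration (valve
#' closure). When the volume trace is degenerate (no stroke), the E/A
#' fields are returned as NA.
#'
#' @param trace a `volume_trace`.
#' @param q_mv data.frame (`time`, `q`) of transmitral flowrate, or NULL.
#' @param schedule valve schedule data.frame, or NULL.
#' @param geom a `chamber_geometry`, or NULL to skip morphology.
#' @param motion optional `volumetric_motion` (for the minimum-volume
#'   configuration).
#' @param bpm heart rate (1/min).
#' @return object of class `functional_summary` (named list).
#' @export
functional_summary <- function(trace, q_mv = NULL, schedule = NULL,
                               geom = NULL, motion = NULL, bpm) {
  per <- attr(trace, "period")
  ve <- volume_extrema(trace)
  ea <- list(e_peak = NA_real_, a_peak = NA_real_, ea_ratio = NA_real_,
             e_time = NA_real_, a_time = NA_real_)
  degenerate <- ve$sv <= 1e-9 * ve$v_max
  if (!degenerate && !is.null(q_mv) && !is.null(schedule)) {
    ea <- ea_analysis(q_mv, schedule, per)
  }
  oa <- NA_real_
  tort <- NA_real_
  if (!is.null(geom) && length(geom$ostium_ring)) {
    t_min <- trace$time[which.min(trace$volume)]
    d_min <- if (!is.null(motion)) motion$displacement(t_min) else NULL
    oa <- ostium_area(geom, d_min)
    tort <- tortuosity(laa_centerline(geom, d_min))
  }
  structure(list(
    v_max = ve$v_max, v_min = ve$v_min, sv = ve$sv, ef = ve$ef,
    bpm = bpm, period = 60 / bpm,
    ostium_area = oa, tortuosity = tort,
    e_peak = ea$e_peak, a_peak = ea$a_peak, ea_ratio = ea$ea_ratio,
    e_time = ea$e_time, a_time = ea$a_time
  ), class = "functional_summary")
}

#' @export
print.functional_summary <- function(x, ...) {
  cat(sprintf(
    paste0(
      "functional summary: Vmax %.1f mL, Vmin %.1f mL, SV %.1f mL, ",
      "EF %.2f, %.1f bpm (T = %.2f s)\n"
    ),
    x$v_max, x$v_min, x$sv, x$ef, x$bpm, x$period
  ))
  if (is.finite(x$ea_ratio)) {
    cat(sprintf("  E %.1f mL/s, A %.1f mL/s, EA ratio %.2f\n",
                x$e_peak, x$a_peak, x$ea_ratio))
  }
  if (is.finite(x$ostium_area)) {
    cat(sprintf("  ostium area %.1f mm^2, tortuosity %.3f\n",
                x$ostium_area, x$tortuosity))
  }
  invisible(x)
}
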