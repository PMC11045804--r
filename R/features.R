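# Hemodynamic biomarkers from flow histories. All features are computed
# from the phase-averaged velocity: stasis from the speed threshold, wall
# shear statistics (TAWSS, OSI, RRT, ECAP) from the tangential viscous
# traction, kinetic energy and enstrophy as plain volume integrals of the
# printed formulas (no density factor), and phase-gated vorticity medians.

#' Phase-averaged velocity over one period
#'
#' Discards the first `n_discard` beats (initial transient) and averages
#' the remaining `n_average` beats vertex-wise at matching phase.
#'
#' @param history a `flow_history`.
#' @param n_discard beats dropped from the start (clinical default 2).
#' @param n_average beats averaged (clinical default 8); `NULL` = all
#'   remaining.
#' @return object of class `phase_averaged_flow`: snapshot list `U`,
#'   `phase_times` within one period, `period`, counts.
#' @export
phase_average <- function(history, n_discard = 2, n_average = NULL) {
  m <- history$snapshots_per_beat
  b_tot <- history$n_beats
  if (is.null(n_average)) n_average <- b_tot - n_discard
  if (n_discard < 0 || n_average < 1 || n_discard + n_average > b_tot) {
    stop(sprintf(
      "insufficient beats: have %d, asked to discard %d and average %d",
      b_tot, n_discard, n_average
    ))
  }
  beats <- n_discard + seq_len(n_average)
  U <- lapply(seq_len(m), function(k) {
    acc <- 0
    for (b in beats) acc <- acc + history$U[[(b - 1L) * m + k]]
    acc / length(beats)
  })
  structure(list(
    U = U, phase_times = history$times[seq_len(m)], period = history$period,
    n_discarded = n_discard, n_averaged = n_average
  ), class = "phase_averaged_flow")
}

#' Flow stasis field
#'
#' Fraction of the period each vertex's phase-averaged speed stays at or
#' below `threshold` (0.1 m/s by default), by snapshot counting with the
#' uniform time stride.
#'
#' @param pa a `phase_averaged_flow`.
#' @param threshold m/s; must be positive.
#' @return numeric vector in [0, 1], one value per vertex.
#' @export
flow_stasis <- function(pa, threshold = 0.1) {
  if (threshold <= 0) stop("threshold must be > 0")
  m <- length(pa$U)
  acc <- 0
  for (k in seq_len(m)) {
    spd <- sqrt(rowSums(pa$U[[k]]^2))
    acc <- acc + (spd <= threshold)
  }
  acc / m
}

# element gradients of a nodal vector field, recovered to vertices with
# volume weights; returns list of three 3x3-gradient column blocks
.vertex_gradient <- function(verts, tets, field) {
  eg <- .elem_gradients_cpp(verts, tets, field)
  G <- eg$grad # ne x 9: (du1/dx, du1/dy, du1/dz, du2/dx, ...)
  vol <- abs(eg$vol)
  n <- nrow(verts)
  out <- matrix(0, n, ncol(G))
  idx <- as.vector(tets)
  wacc <- rowsum(rep(vol, 4L), idx, reorder = TRUE)
  vids <- as.integer(rownames(wacc))
  wsum <- as.numeric(wacc)
  gacc <- rowsum(G[rep(seq_len(nrow(G)), 4L), , drop = FALSE] * rep(vol, 4L),
                 idx, reorder = TRUE)
  out[vids, ] <- as.matrix(gacc) / wsum
  out
}

# outward unit vertex normals of the wall (area-weighted facet average)
.wall_vertex_normals <- function(verts, wall_facets, wall_ids) {
  fg <- facet_geometry(verts, wall_facets)
  n <- matrix(0, nrow(verts), 3)
  for (a in 1:3) {
    acc <- rowsum(fg$normal * fg$area, wall_facets[, a], reorder = TRUE)
    ids <- as.integer(rownames(acc))
    n[ids, ] <- n[ids, ] + acc
  }
  nn <- sqrt(rowSums(n^2))
  nz <- nn > 0
  n[nz, ] <- n[nz, ] / nn[nz]
  n[wall_ids, , drop = FALSE]
}

#' Wall-shear-stress history over the phase-averaged beat
#'
#' At each phase the velocity gradient is evaluated element-wise on the
#' configuration of that phase, recovered to vertices, and the viscous
#' traction `tau n` is projected onto the wall tangent plane; values are
#' attached to the reference wall vertices.
#'
#' @param pa a `phase_averaged_flow`.
#' @param geom a `chamber_geometry`.
#' @param motion optional `volumetric_motion` (NULL = static mesh).
#' @param mu dynamic viscosity (kg/(m s)).
#' @return object of class `wss_history`: list `W` of (n_wall x 3) Pa
#'   matrices, `wall_vertex_ids`, `phase_times`, `period`.
#' @export
wss_history <- function(pa, geom, motion = NULL,
                        mu = fluid_properties()$dynamic_viscosity) {
  wall_ids <- wall_vertices(geom)
  wall_f <- geom$boundary_facets[
    geom$boundary_tag == geom$tag_legend[["WALL"]], , drop = FALSE
  ]
  m <- length(pa$U)
  W <- vector("list", m)
  for (k in seq_len(m)) {
    verts <- geom$vertices
    if (!is.null(motion)) verts <- verts + motion$displacement(pa$phase_times[k])
    Gv <- .vertex_gradient(verts, geom$tets, pa$U[[k]])
    nrm <- .wall_vertex_normals(verts, wall_f, wall_ids)
    Gw <- Gv[wall_ids, , drop = FALSE]
    # traction t = mu (G + G^T) n at wall vertices
    tr <- matrix(0, length(wall_ids), 3)
    for (a in 1:3) {
      for (b in 1:3) {
        gab <- Gw[, 3L * (a - 1L) + b] # d u_a / d x_b
        gba <- Gw[, 3L * (b - 1L) + a]
        tr[, a] <- tr[, a] + mu * (gab + gba) * nrm[, b]
      }
    }
    tn <- rowSums(tr * nrm)
    W[[k]] <- tr - tn * nrm
  }
  structure(list(
    W = W, wall_vertex_ids = wall_ids, phase_times = pa$phase_times,
    period = pa$period
  ), class = "wss_history")
}

#' Wall feature field: TAWSS, OSI, RRT, ECAP
#'
#' Uniform-stride time averages over the phase-averaged beat. At vertices
#' with vanishing average shear magnitude OSI is set to 0 and RRT/ECAP are
#' flagged NA; RRT is also flagged NA where OSI reaches 1/2 (unbounded
#' residence time), and such sentinels are excluded from medians.
#'
#' @param wss a `wss_history`.
#' @return data.frame with columns `vertex`, `tawss` (Pa), `osi`,
#'   `rrt` (1/Pa), `ecap` (1/Pa).
#' @export
wall_features <- function(wss) {
  m <- length(wss$W)
  mag <- 0
  mvec <- 0
  for (k in seq_len(m)) {
    mag <- mag + sqrt(rowSums(wss$W[[k]]^2))
    mvec <- mvec + wss$W[[k]]
  }
  tawss <- mag / m
  mean_vec_norm <- sqrt(rowSums((mvec / m)^2))
  osi <- rep(0, length(tawss))
  pos <- tawss > 0
  osi[pos] <- 0.5 * (1 - mean_vec_norm[pos] / tawss[pos])
  osi <- pmin(pmax(osi, 0), 0.5)
  denom <- (1 - 2 * osi) * tawss
  rrt <- ifelse(pos & denom > .Machine$double.eps^0.5 * max(tawss), 1 / denom,
                NA_real_)
  ecap <- ifelse(pos, osi / tawss, NA_real_)
  data.frame(vertex = wss$wall_vertex_ids, tawss = tawss, osi = osi,
             rrt = rrt, ecap = ecap)
}

# exact integral of |u|^2 for a P1 field: sum_e vol/20 (|sum u_a|^2 + sum |u_a|^2)
.integral_sq <- function(verts, tets, field) {
  vol <- abs(tet_volumes(verts, tets))
  s <- field[tets[, 1], ] + field[tets[, 2], ] + field[tets[, 3], ] +
    field[tets[, 4], ]
  q <- rowSums(field[tets[, 1], ]^2) + rowSums(field[tets[, 2], ]^2) +
    rowSums(field[tets[, 3], ]^2) + rowSums(field[tets[, 4], ]^2)
  sum(vol / 20 * (rowSums(s^2) + q))
}

# vertex-recovered vorticity of a nodal velocity field
.vorticity <- function(verts, tets, u) {
  Gv <- .vertex_gradient(verts, tets, u)
  # curl: (du3/dy - du2/dz, du1/dz - du3/dx, du2/dx - du1/dy)
  cbind(
    Gv[, 8] - Gv[, 6],
    Gv[, 3] - Gv[, 7],
    Gv[, 4] - Gv[, 2]
  )
}

#' Kinetic-energy and enstrophy traces of the phase-averaged beat
#'
#' \eqn{E_k = (1/2)\int |u|^2} and \eqn{S = (1/2)\int |\omega|^2} as
#' printed (no density factor), integrated on the reference configuration;
#' the vorticity is the element-wise curl recovered to vertices on the
#' configuration of each phase.
#'
#' @param pa a `phase_averaged_flow`.
#' @param geom a `chamber_geometry`.
#' @param motion optional `volumetric_motion` for the per-phase gradients.
#' @return data.frame with `time`, `kinetic_energy` (m^5/s^2), `enstrophy`
#'   (m^3/s^2).
#' @export
global_traces <- function(pa, geom, motion = NULL) {
  m <- length(pa$U)
  ek <- numeric(m)
  s <- numeric(m)
  vol0 <- abs(tet_volumes(geom$vertices, geom$tets))
  for (k in seq_len(m)) {
    u <- pa$U[[k]]
    ek[k] <- 0.5 * .integral_sq(geom$vertices, geom$tets, u)
    verts <- geom$vertices
    if (!is.null(motion)) verts <- verts + motion$displacement(pa$phase_times[k])
    w <- .vorticity(verts, geom$tets, u)
    s[k] <- 0.5 * .integral_sq(geom$vertices, geom$tets, w)
  }
  data.frame(time = pa$phase_times, kinetic_energy = ek, enstrophy = s)
}

#' Vorticity-magnitude medians at the three cardiac phases
#'
#' Median of |omega| at the E-wave peak, A-wave peak and systolic filling
#' (midpoint of the valve-closed interval), over the whole chamber (all
#' vertices) and the appendage (appendage wall vertices).
#'
#' @param pa a `phase_averaged_flow`.
#' @param geom a `chamber_geometry`.
#' @param motion optional `volumetric_motion`.
#' @param e_time,a_time,systolic_time phase times (s) within one period.
#' @return data.frame with columns `region`, `phase`, `median_vorticity`.
#' @export
vorticity_phase_medians <- function(pa, geom, motion = NULL,
                                    e_time, a_time, systolic_time) {
  times <- c(e = e_time, a = a_time, s = systolic_time)
  if (any(!is.finite(times))) {
    stop("wave-detection error: missing phase times")
  }
  ph <- pa$phase_times %% pa$period
  rows <- list()
  for (nm in names(times)) {
    tw <- times[[nm]] %% pa$period
    k <- which.min(pmin(abs(ph - tw), pa$period - abs(ph - tw)))
    verts <- geom$vertices
    if (!is.null(motion)) verts <- verts + motion$displacement(pa$phase_times[k])
    wmag <- sqrt(rowSums(.vorticity(verts, geom$tets, pa$U[[k]])^2))
    rows[[length(rows) + 1L]] <- data.frame(
      region = "LA", phase = nm, median_vorticity = stats::median(wmag)
    )
    if (length(geom$laa_wall_vertices)) {
      rows[[length(rows) + 1L]] <- data.frame(
        region = "LAA", phase = nm,
        median_vorticity = stats::median(wmag[geom$laa_wall_vertices])
      )
    }
  }
  do.call(rbind, rows)
}

#' Region-wise feature medians
#'
#' Unweighted medians over region vertices: wall vertices for the wall
#' features, volume vertices for flow stasis. LA = whole chamber; LAA =
#' appendage (wall subset / appendage-cell vertices). NA sentinels
#' (unbounded RRT) are excluded and counted.
#'
#' @param geom a `chamber_geometry`.
#' @param wall_field data.frame from [wall_features()].
#' @param fs numeric flow-stasis field over all vertices.
#' @param vort optional data.frame from [vorticity_phase_medians()].
#' @return data.frame, one row per region, columns `region`, `fs`,
#'   `tawss`, `osi`, `rrt`, `ecap` (+ `vort_e`, `vort_a`, `vort_s`),
#'   `n_rrt_excluded`.
#' @export
region_medians <- function(geom, wall_field, fs, vort = NULL) {
  med <- function(x) stats::median(x, na.rm = TRUE)
  regions <- list(LA = list(
    wall = seq_len(nrow(wall_field)),
    vol = seq_len(nrow(geom$vertices))
  ))
  if (length(geom$laa_wall_vertices)) {
    laa_vol <- sort(unique(as.vector(
      geom$tets[geom$laa_cells, , drop = FALSE]
    )))
    regions$LAA <- list(
      wall = which(wall_field$vertex %in% geom$laa_wall_vertices),
      vol = laa_vol
    )
  }
  rows <- lapply(names(regions), function(rn) {
    r <- regions[[rn]]
    if (length(r$wall) == 0 || length(r$vol) == 0) {
      stop(sprintf("tagging error: empty region %s", rn))
    }
    out <- data.frame(
      region = rn,
      fs = med(fs[r$vol]),
      tawss = med(wall_field$tawss[r$wall]),
      osi = med(wall_field$osi[r$wall]),
      rrt = med(wall_field$rrt[r$wall]),
      ecap = med(wall_field$ecap[r$wall]),
      n_rrt_excluded = sum(is.na(wall_field$rrt[r$wall]))
    )
    out
  })
  out <- do.call(rbind, rows)
  if (!is.null(vort)) {
    for (ph in c("e", "a", "s")) {
      col <- paste0("vort_", ph)
      out[[col]] <- NA_real_
      for (i in seq_len(nrow(out))) {
        hit <- vort$region == out$region[i] & vort$phase == ph
        if (any(hit)) out[[col]][i] <- vort$median_vorticity[hit][1]
      }
    }
  }
  out
}
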