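# Stabilized P1-P1 finite-element solver for the incompressible
# Navier-Stokes equations in ALE form on the moving chamber. Implicit Euler
# in time with semi-implicit convection (relative velocity frozen from the
# previous step), SUPG/PSPG/grad-div stabilization, traction boundary
# conditions with backflow stabilization on the open PV/MV disks, and
# strong Dirichlet u = u_ALE on the wall (and the MV disk while closed).
# Each step solves one monolithic sparse system by direct LU.

MMHG_PA <- 133.322

#' Fluid properties of blood
#' @param density kg/m^3; default 1.06e3.
#' @param dynamic_viscosity kg/(m s); default 3.5e-3.
#' @return object of class `fluid_properties`.
#' @export
fluid_properties <- function(density = 1.06e3, dynamic_viscosity = 3.5e-3) {
  if (density <= 0 || dynamic_viscosity <= 0) {
    stop("density and viscosity must be positive")
  }
  structure(list(density = density, dynamic_viscosity = dynamic_viscosity),
            class = "fluid_properties")
}

#' Boundary specification
#'
#' Constant pulmonary-vein pressure (always a traction condition), a
#' ventricular pressure applied at the mitral disk while the valve is open,
#' a valve schedule (alternating open/closed transitions over one period),
#' and the backflow-stabilization coefficient for all traction boundaries.
#'
#' @param p_in PV pressure (Pa); default 10 mmHg.
#' @param p_out MV pressure when open (Pa); default 5 mmHg.
#' @param mv_schedule data.frame with columns `time` (s) and `state`
#'   ("open"/"closed"), alternating, within one period.
#' @param backflow_coefficient dimensionless penalty scale (default 1).
#' @return object of class `boundary_spec`.
#' @export
boundary_spec <- function(p_in = 10 * MMHG_PA, p_out = 5 * MMHG_PA,
                          mv_schedule = data.frame(time = 0, state = "open"),
                          backflow_coefficient = 1) {
  stopifnot(is.data.frame(mv_schedule),
            all(c("time", "state") %in% names(mv_schedule)))
  mv_schedule <- mv_schedule[order(mv_schedule$time), , drop = FALSE]
  st <- as.character(mv_schedule$state)
  if (!all(st %in% c("open", "closed"))) stop("states must be open/closed")
  if (any(st[-1] == st[-length(st)])) {
    stop("schedule states must alternate")
  }
  structure(list(p_in = p_in, p_out = p_out, mv_schedule = mv_schedule,
                 backflow_coefficient = backflow_coefficient),
            class = "boundary_spec")
}

#' Solver configuration
#'
#' Desk-scale defaults: dt = 2 ms and 3 beats (the clinical-resolution
#' values 0.5 ms / 10 beats remain admissible). Stabilization constants
#' enter the element time scale
#' `tau = ((ct/dt)^2 + (cc |w|/h)^2 + (cv nu/h^2)^2)^(-1/2)` and the
#' grad-div viscosity `grad_div * (nu + |w| h / 2)`.
#'
#' @param dt time step (s).
#' @param n_beats number of heartbeats simulated.
#' @param snapshots_per_beat velocity/pressure snapshots kept per beat.
#' @param linear_tolerance accepted relative residual of each linear solve.
#' @param stab named numeric vector with `ct`, `cc`, `cv`, `grad_div`.
#' @return object of class `solver_config`.
#' @export
solver_config <- function(dt = 2e-3, n_beats = 3, snapshots_per_beat = 40,
                          linear_tolerance = 1e-8,
                          stab = c(ct = 2, cc = 2, cv = 12, grad_div = 1)) {
  if (dt <= 0) stop("dt must be > 0")
  if (n_beats < 1) stop("n_beats must be >= 1")
  structure(list(dt = dt, n_beats = as.integer(n_beats),
                 snapshots_per_beat = as.integer(snapshots_per_beat),
                 linear_tolerance = linear_tolerance, stab = stab),
            class = "solver_config")
}

#' Mitral-valve schedule from a volume trace
#'
#' The valve opens at the volume maximum (emptying begins) and closes at
#' the minimum (filling begins); extrema are located on the spline-smoothed
#' periodic trace.
#'
#' @param trace a `volume_trace`.
#' @return data.frame with columns `time`, `state` suitable for
#'   [boundary_spec()].
#' @export
mv_schedule <- function(trace) {
  stopifnot(inherits(trace, "volume_trace"))
  per <- attr(trace, "period")
  f <- .trace_fun(trace)
  tt <- seq(0, per, length.out = 4001)[-4001]
  vv <- f(tt)
  if (max(vv) - min(vv) < 1e-9 * max(abs(vv))) {
    stop("schedule error: volume trace has no extrema (constant)")
  }
  refine <- function(t0, maximize) {
    h <- per / 4000
    o <- stats::optimize(function(t) f(t),
      interval = c(t0 - 2 * h, t0 + 2 * h), maximum = maximize
    )
    if (maximize) o$maximum else o$minimum
  }
  t_open <- refine(tt[which.max(vv)], TRUE) %% per
  t_close <- refine(tt[which.min(vv)], FALSE) %% per
  if (abs(t_open - t_close) < 1e-9) {
    stop("schedule error: volume trace extrema coincide")
  }
  sched <- data.frame(
    time = c(t_open, t_close), state = c("open", "closed")
  )
  sched[order(sched$time), , drop = FALSE]
}

# valve state at (wrapped) time t
.mv_open <- function(bc, t, period) {
  s <- bc$mv_schedule
  if (nrow(s) == 1L) return(s$state[1] == "open")
  tw <- t %% period
  idx <- findInterval(tw + 1e-12, s$time)
  st <- if (idx == 0L) s$state[nrow(s)] else s$state[idx]
  st == "open"
}

#' Initial flow state (fluid at rest)
#' @param geom a `chamber_geometry`.
#' @param time initial time (s).
#' @return object of class `flow_state`.
#' @export
flow_state <- function(geom, time = 0) {
  n <- nrow(geom$vertices)
  structure(list(time = time, u = matrix(0, n, 3), p = rep(0, n),
                 d = matrix(0, n, 3)), class = "flow_state")
}

# precomputed step context shared across all steps of a run
.step_context <- function(geom, fluid, bc, cfg) {
  tl <- geom$tag_legend
  pv_tags <- tl[c("PV1", "PV2", "PV3", "PV4")]
  pv_f <- which(geom$boundary_tag %in% pv_tags)
  mv_f <- which(geom$boundary_tag == tl[["MV"]])
  wall <- wall_vertices(geom)
  mv_verts <- sort(unique(as.vector(
    geom$boundary_facets[mv_f, , drop = FALSE]
  )))
  list(
    geom = geom, fluid = fluid, bc = bc, cfg = cfg,
    n = nrow(geom$vertices), wall = wall, mv_verts = mv_verts,
    pv_facets = geom$boundary_facets[pv_f, , drop = FALSE],
    mv_facets = geom$boundary_facets[mv_f, , drop = FALSE]
  )
}

# facet-integral contributions of one traction boundary group: traction
# rhs -p n and implicit backflow penalty on the relative normal inflow
.neumann_terms <- function(verts, facets, p_bc, wrel, rho, bf_coef, n) {
  if (nrow(facets) == 0) {
    return(list(i = integer(0), j = integer(0), x = numeric(0),
                rhs_i = integer(0), rhs_x = numeric(0)))
  }
  fg <- facet_geometry(verts, facets)
  # rhs: -p * int(phi_i n) = -p * area/3 * n per facet vertex
  ri <- integer(0); rx <- numeric(0)
  for (c in 1:3) {
    for (a in 1:3) {
      ri <- c(ri, (c - 1L) * n + facets[, a])
      rx <- c(rx, -p_bc * fg$area / 3 * fg$normal[, c])
    }
  }
  # backflow: rho/2 * (w . n)_- penalty, facet-consistent mass matrix
  wf <- (wrel[facets[, 1], ] + wrel[facets[, 2], ] + wrel[facets[, 3], ]) / 3
  wn <- rowSums(wf * fg$normal)
  coef <- bf_coef * rho / 2 * pmax(-wn, 0)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  act <- which(coef > 0)
  if (length(act)) {
    fa <- facets[act, , drop = FALSE]
    ca <- coef[act] * fg$area[act]
    for (a in 1:3) {
      for (b in 1:3) {
        m <- ca / 12 * (if (a == b) 2 else 1)
        for (c in 1:3) {
          ii <- c(ii, (c - 1L) * n + fa[, a])
          jj <- c(jj, (c - 1L) * n + fa[, b])
          xx <- c(xx, m)
        }
      }
    }
  }
  list(i = ii, j = jj, x = xx, rhs_i = ri, rhs_x = rx)
}

# one implicit-Euler step on the configuration at t1; Dirichlet dofs are
# condensed out of the linear system (strong imposition)
.step_core <- function(ctx, state, t1, d1, uale1) {
  geom <- ctx$geom; cfg <- ctx$cfg; fluid <- ctx$fluid; bc <- ctx$bc
  n <- ctx$n
  verts1 <- geom$vertices + d1
  if (min(tet_volumes(verts1, geom$tets)) <= 0) {
    stop(sprintf("mesh error: inverted element at t = %.4f s", t1))
  }
  mv_open <- .mv_open(bc, t1, if (is.null(ctx$period)) Inf else ctx$period)
  has_neumann <- nrow(ctx$pv_facets) > 0 ||
    (mv_open && nrow(ctx$mv_facets) > 0)

  dir_v <- if (mv_open) ctx$wall else sort(union(ctx$wall, ctx$mv_verts))
  is_dir <- logical(4L * n)
  is_dir[c(dir_v, n + dir_v, 2L * n + dir_v)] <- TRUE
  # pressure gauge: with no traction boundary the pressure is defined up
  # to a constant; pin one dof and report the mean-zero representative
  pin_p <- !has_neumann
  if (pin_p) is_dir[3L * n + 1L] <- TRUE
  dirval <- numeric(4L * n)
  dirval[c(dir_v, n + dir_v, 2L * n + dir_v)] <- as.vector(
    uale1[dir_v, , drop = FALSE]
  )

  st <- cfg$stab
  tr <- .asm_ns_step_cpp(
    verts1, geom$tets, state$u, uale1,
    fluid$density, fluid$dynamic_viscosity, cfg$dt,
    st[["ct"]], st[["cc"]], st[["cv"]], st[["grad_div"]],
    as.integer(is_dir), dirval
  )
  rhs <- tr$rhs
  ti <- tr$i; tj <- tr$j; tx <- tr$x

  add_rhs <- function(rhs, idx, val) {
    # accumulate duplicated indices (plain indexed assignment would not)
    acc <- rowsum(val, idx, reorder = TRUE)
    ids <- as.integer(rownames(acc))
    rhs[ids] <- rhs[ids] + as.numeric(acc)
    rhs
  }
  wrel <- state$u - uale1
  groups <- list(list(ctx$pv_facets, bc$p_in))
  if (mv_open) groups <- c(groups, list(list(ctx$mv_facets, bc$p_out)))
  for (grp in groups) {
    neu <- .neumann_terms(verts1, grp[[1]], grp[[2]], wrel,
                          fluid$density, bc$backflow_coefficient, n)
    if (length(neu$rhs_i)) {
      f <- !is_dir[neu$rhs_i]
      rhs <- add_rhs(rhs, neu$rhs_i[f], neu$rhs_x[f])
    }
    if (length(neu$i)) {
      rowfree <- !is_dir[neu$i]
      coldir <- is_dir[neu$j]
      mv2rhs <- rowfree & coldir
      if (any(mv2rhs)) {
        rhs <- add_rhs(rhs, neu$i[mv2rhs],
                       -neu$x[mv2rhs] * dirval[neu$j[mv2rhs]])
      }
      keep <- rowfree & !coldir
      ti <- c(ti, neu$i[keep]); tj <- c(tj, neu$j[keep])
      tx <- c(tx, neu$x[keep])
    }
  }

  free <- which(!is_dir)
  map <- integer(4L * n)
  map[free] <- seq_along(free)
  A <- Matrix::sparseMatrix(i = map[ti], j = map[tj], x = tx,
                            dims = c(length(free), length(free)))
  bf <- rhs[free]
  xf <- as.numeric(Matrix::solve(Matrix::lu(A, order = 1L), bf))
  res <- sqrt(sum((as.numeric(A %*% xf) - bf)^2))
  nrm <- max(sqrt(sum(bf^2)), .Machine$double.eps)
  if (res / nrm > cfg$linear_tolerance) {
    stop(sprintf("solver error: linear residual %.2e at t = %.4f s",
                 res / nrm, t1))
  }
  sol <- dirval
  sol[free] <- xf
  u <- matrix(sol[seq_len(3L * n)], n, 3)
  p <- sol[3L * n + seq_len(n)]
  if (pin_p) p <- p - mean(p)
  structure(list(time = t1, u = u, p = p, d = d1), class = "flow_state")
}

#' Advance the flow by one time step
#'
#' @param state a `flow_state` at time t.
#' @param geom the `chamber_geometry` (reference configuration).
#' @param motion a `volumetric_motion` (use [static_motion()] via
#'   `motion = NULL` for a rigid domain).
#' @param fluid a `fluid_properties`.
#' @param bc a `boundary_spec`.
#' @param cfg a `solver_config`.
#' @return the `flow_state` at time t + dt.
#' @export
advance <- function(state, geom, motion = NULL, fluid = fluid_properties(),
                    bc = boundary_spec(), cfg = solver_config()) {
  if (is.null(motion)) motion <- static_motion(geom)
  ctx <- .step_context(geom, fluid, bc, cfg)
  ctx$period <- motion$period
  t1 <- state$time + cfg$dt
  .step_core(ctx, state, t1, motion$displacement(t1), motion$velocity(t1))
}

#' Run a multi-beat ALE flow simulation
#'
#' Starts from rest, advances with implicit Euler over `n_beats` periods
#' (dt is snapped so an integer number of steps fits one period), records a
#' per-step scalar trace (volume, valve and vein flowrates, net relative
#' outflow) and keeps uniformly strided velocity/pressure snapshots; the
#' cycle-to-cycle L2 velocity difference between consecutive beats is
#' reported for periodicity monitoring.
#'
#' @inheritParams advance
#' @return object of class `flow_history`.
#' @export
run_flow <- function(geom, motion, fluid = fluid_properties(),
                     bc = boundary_spec(), cfg = solver_config()) {
  period <- motion$period
  if (!is.finite(period)) stop("run_flow needs a periodic motion")
  nsb <- max(2L, as.integer(round(period / cfg$dt)))
  dt <- period / nsb
  cfg$dt <- dt
  divs <- which(nsb %% seq_len(nsb) == 0L)
  snaps <- max(divs[divs <= cfg$snapshots_per_beat])
  stride <- nsb %/% snaps

  ctx <- .step_context(geom, fluid, bc, cfg)
  ctx$period <- period
  state <- flow_state(geom)
  n_steps <- nsb * cfg$n_beats
  tl <- geom$tag_legend
  pv_tags <- c("PV1", "PV2", "PV3", "PV4")

  trace <- data.frame(
    time = numeric(n_steps), V_mL = NA_real_, Q_MV_mL_s = NA_real_,
    Q_PV_mL_s = NA_real_, net_out_mL_s = NA_real_
  )
  U <- vector("list", snaps * cfg$n_beats)
  P <- vector("list", snaps * cfg$n_beats)
  snap_times <- numeric(snaps * cfg$n_beats)
  isnap <- 0L

  # evaluate the motion splines for all step times in one basis call
  step_times <- seq_len(n_steps) * dt
  D_all <- NULL
  if (!is.null(motion$spline)) {
    D_all <- periodic_spline_eval(motion$spline, step_times)
    V_all <- periodic_spline_eval(motion$spline, step_times, deriv = 1)
  }
  nv <- nrow(geom$vertices)
  for (k in seq_len(n_steps)) {
    t1 <- step_times[k]
    if (is.null(D_all)) {
      d1 <- motion$displacement(t1)
      uale1 <- motion$velocity(t1)
    } else {
      d1 <- matrix(D_all[k, ], nv, 3)
      uale1 <- matrix(V_all[k, ], nv, 3)
    }
    state <- .step_core(ctx, state, t1, d1, uale1)

    out_mv <- .region_flux_out(state$u, geom, "MV", d1, uale1)
    out_pv <- sum(vapply(pv_tags, function(tg) {
      .region_flux_out(state$u, geom, tg, d1, uale1)
    }, numeric(1)))
    trace$time[k] <- t1
    trace$V_mL[k] <- enclosed_volume(geom$vertices, geom$boundary_facets, d1)
    trace$Q_MV_mL_s[k] <- out_mv
    trace$Q_PV_mL_s[k] <- -out_pv
    trace$net_out_mL_s[k] <- out_mv + out_pv

    if (k %% stride == 0L) {
      isnap <- isnap + 1L
      U[[isnap]] <- state$u
      P[[isnap]] <- state$p
      snap_times[isnap] <- t1
    }
  }

  cyc <- rep(NA_real_, cfg$n_beats)
  for (b in seq_len(cfg$n_beats)[-1]) {
    cur <- do.call(rbind, U[(b - 1L) * snaps + seq_len(snaps)])
    prev <- do.call(rbind, U[(b - 2L) * snaps + seq_len(snaps)])
    cyc[b] <- sqrt(sum((cur - prev)^2)) / max(sqrt(sum(cur^2)),
                                              .Machine$double.eps)
  }

  structure(list(
    times = snap_times, U = U, P = P, trace = trace,
    period = period, dt = dt, n_beats = cfg$n_beats,
    snapshots_per_beat = snaps, cycle_diff = cyc,
    geom = geom, motion = motion, fluid = fluid, bc = bc, cfg = cfg
  ), class = "flow_history")
}

# raw outward relative flux (mL/s) through a tagged region
.region_flux_out <- function(u, geom, tag, displacement = NULL,
                             u_ale = NULL) {
  tl <- geom$tag_legend
  if (!tag %in% names(tl)) stop(sprintf("unknown region tag '%s'", tag))
  f <- geom$boundary_facets[geom$boundary_tag == tl[[tag]], , drop = FALSE]
  if (nrow(f) == 0) stop(sprintf("unknown region tag '%s' (no facets)", tag))
  verts <- geom$vertices
  if (!is.null(displacement)) verts <- verts + displacement
  if (is.null(u_ale)) u_ale <- 0 * u
  rel <- u - u_ale
  fg <- facet_geometry(verts, f)
  rf <- (rel[f[, 1], ] + rel[f[, 2], ] + rel[f[, 3], ]) / 3
  sum(rowSums(rf * fg$normal) * fg$area) * 1e6
}

#' Flowrate through a tagged open boundary section
#'
#' Integrates the relative flux `(u - u_ALE) . n` over the tagged facets on
#' the current configuration. Sign convention: positive means out of the
#' chamber through the MV and into the chamber through a PV.
#'
#' @param u nodal velocity (n x 3, m/s).
#' @param geom a `chamber_geometry`.
#' @param tag region tag name ("MV", "PV1", ...).
#' @param displacement optional current mesh displacement (n x 3).
#' @param u_ale optional nodal ALE velocity (n x 3).
#' @return flowrate in mL/s.
#' @export
section_flowrate <- function(u, geom, tag, displacement = NULL,
                             u_ale = NULL) {
  q <- .region_flux_out(u, geom, tag, displacement, u_ale)
  if (startsWith(tag, "PV")) -q else q
}

#' Mass-balance audit of a run
#'
#' On a moving incompressible domain the net relative outflow through the
#' open sections must equal -dV/dt; reports the worst deviation relative to
#' the peak MV flowrate.
#'
#' @param history a `flow_history`.
#' @return list with `max_error_mL_s`, `peak_q_mL_s`, `ratio` and the
#'   per-step data.frame.
#' @export
mass_balance <- function(history) {
  tr <- history$trace
  nst <- nrow(tr)
  dvdt <- rep(NA_real_, nst)
  dt <- history$dt
  dvdt[2:(nst - 1)] <- (tr$V_mL[3:nst] - tr$V_mL[1:(nst - 2)]) / (2 * dt)
  err <- tr$net_out_mL_s + dvdt
  peak <- max(abs(tr$Q_MV_mL_s), na.rm = TRUE)
  ok <- is.finite(err)
  list(
    max_error_mL_s = max(abs(err[ok])),
    peak_q_mL_s = peak,
    ratio = max(abs(err[ok])) / peak,
    detail = data.frame(time = tr$time, error_mL_s = err)
  )
}
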