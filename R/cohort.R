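# Phenotype-parameterized synthetic cohort: stroke cases carry smaller
# volumes, lower stroke volume and higher heart rate than controls, while
# ejection fraction is drawn from the same range in both groups so that it
# cannot separate them by construction (mirroring the clinical finding that
# EF is not discriminative).

#' Phenotype parameters for one synthetic case
#'
#' @param group "control" or "stroke".
#' @param v_max,v_min maximum and minimum chamber volume over the beat (mL).
#' @param bpm heart rate (1/min); the period is 60/bpm seconds.
#' @param n_frames number of imaging frames per beat (25, 30 or 40).
#' @param e_fraction share of the emptied volume carried by the early
#'   (E-wave) phase, in (0, 1).
#' @param seed per-case random seed.
#' @return object of class `phenotype_params`.
#' @export
phenotype_params <- function(group = c("control", "stroke"),
                             v_max = 110, v_min = 75, bpm = 55,
                             n_frames = 30, e_fraction = 0.55,
                             seed = 1L) {
  group <- match.arg(group)
  if (!is.finite(v_max) || !is.finite(v_min) || v_min <= 0 || v_max <= 0) {
    stop("volumes must be positive")
  }
  if (v_min > v_max) stop("v_min must not exceed v_max")
  if (bpm <= 0) stop("bpm must be positive")
  if (!n_frames %in% c(25L, 30L, 40L)) {
    stop("n_frames must be one of 25, 30, 40")
  }
  if (e_fraction <= 0 || e_fraction >= 1) stop("e_fraction must be in (0,1)")
  structure(list(
    group = group, v_max = v_max, v_min = v_min, bpm = bpm,
    period = 60 / bpm, n_frames = as.integer(n_frames),
    e_fraction = e_fraction, seed = as.integer(seed)
  ), class = "phenotype_params")
}

# imaging protocols acquire more frames at slow heart rates
.frames_for_bpm <- function(bpm) {
  if (bpm < 55) 40L else if (bpm < 65) 30L else 25L
}

#' Sample a synthetic cohort of phenotypes
#'
#' Controls draw maximum volumes in 90-140 mL and heart rates in
#' 50.3-57.7 bpm; stroke cases draw 50-90 mL and 51.5-76 bpm (the observed
#' clinical BPM ranges of the two groups). Ejection fraction is uniform in
#' 0.25-0.45 for both groups, so the EF ranges overlap by design. Each case
#' owns an independent random substream derived from `(seed, index)`.
#'
#' @param n_control,n_stroke case counts (>= 0).
#' @param seed cohort seed.
#' @return list of `phenotype_params`.
#' @export
sample_cohort <- function(n_control, n_stroke, seed = 1L) {
  if (n_control < 0 || n_stroke < 0) stop("case counts must be >= 0")
  groups <- c(rep("control", n_control), rep("stroke", n_stroke))
  lapply(seq_along(groups), function(i) {
    case_seed <- (as.integer(seed) + 7919L * i) %% 2147483647L
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(case_seed)
    g <- groups[i]
    if (g == "control") {
      v_max <- stats::runif(1, 90, 140)
      bpm <- stats::runif(1, 50.3, 57.7)
    } else {
      v_max <- stats::runif(1, 50, 90)
      bpm <- stats::runif(1, 51.5, 76.0)
    }
    ef <- stats::runif(1, 0.25, 0.45)
    efr <- stats::runif(1, 0.50, 0.65)
    phenotype_params(
      group = g, v_max = v_max, v_min = v_max * (1 - ef), bpm = bpm,
      n_frames = .frames_for_bpm(bpm), e_fraction = efr, seed = case_seed
    )
  })
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# wrapped-Gaussian bump CDF on [0, period]: integral from 0 to t of a
# Gaussian of sd `s` centered at `t0`, wrapped over adjacent periods
.wrapped_cdf <- function(t, t0, s, period) {
  out <- 0
  for (k in -1:1) {
    out <- out + stats::pnorm((t - t0 + k * period) / s) -
      stats::pnorm((-t0 + k * period) / s)
  }
  out
}

#' Volume waveform evaluator for a phenotype
#'
#' Returns a function `V(t)` (mL, smooth and exactly periodic) built from
#' wrapped-Gaussian flow bumps: an E-wave decay and an A-wave contraction
#' during emptying, separated by a diastasis plateau, and a single filling
#' bump; the E share of the emptied volume equals `e_fraction`, the maximum
#' is `v_max` at t = 0 (valve opening) and the minimum `v_min` near 45% of
#' the period (valve closure).
#'
#' @param p a `phenotype_params`.
#' @return function of time (s), vectorized.
#' @export
volume_waveform_fun <- function(p) {
  stopifnot(inherits(p, "phenotype_params"))
  T_hb <- p$period
  sv <- p$v_max - p$v_min
  ef <- p$e_fraction
  force(sv); force(ef)
  # bump centers/widths (fractions of the period) keep every Gaussian tail
  # below ~3e-4 of its mass at the period boundaries and at the extrema,
  # so max/min track v_max/v_min to well under 0.1%
  function(t) {
    tw <- t %% T_hb
    p$v_max - sv * (
      ef * .wrapped_cdf(tw, 0.14 * T_hb, 0.040 * T_hb, T_hb) +
        (1 - ef) * .wrapped_cdf(tw, 0.37 * T_hb, 0.040 * T_hb, T_hb) -
        .wrapped_cdf(tw, 0.72 * T_hb, 0.055 * T_hb, T_hb)
    )
  }
}

#' Sampled volume trace over one period
#'
#' @param p a `phenotype_params`.
#' @param n_samples number of samples over `[0, period]` (inclusive).
#' @return object of class `volume_trace`: data.frame with `time` (s) and
#'   `volume` (mL), with the period stored as an attribute.
#' @export
volume_waveform <- function(p, n_samples = 400) {
  if (p$v_min > p$v_max) stop("v_min must not exceed v_max")
  f <- volume_waveform_fun(p)
  tt <- seq(0, p$period, length.out = n_samples)
  structure(
    data.frame(time = tt, volume = f(tt)),
    period = p$period, class = c("volume_trace", "data.frame")
  )
}

#' Volume trace from explicit samples
#' @param time,volume numeric vectors (s, mL).
#' @param period the period in seconds.
#' @return a `volume_trace`.
#' @export
volume_trace <- function(time, volume, period = max(time)) {
  stopifnot(length(time) == length(volume), all(volume > 0))
  structure(data.frame(time = time, volume = volume),
    period = period, class = c("volume_trace", "data.frame")
  )
}

# periodic spline interpolant of a volume_trace
.trace_fun <- function(trace) {
  per <- attr(trace, "period")
  tt <- trace$time
  vv <- trace$volume
  if (abs(tt[length(tt)] - tt[1] - per) < 1e-12 * per) {
    tt <- tt[-length(tt)]
    vv <- vv[-length(vv)]
  }
  f <- stats::splinefun(c(tt, tt[1] + per), c(vv, vv[1]), method = "periodic")
  function(t) f(t %% per)
}

#' Frame-wise boundary displacements matching a volume trace
#'
#' Emulates the dynamic meshes recovered from imaging: at each of the
#' phenotype's frame times the wall vertices are displaced along a smooth
#' radial mode about the chamber centroid (inlet/outlet rims pinned, motion
#' tapered to zero near them), with the mode amplitude solved per frame so
#' the enclosed volume of the displaced surface matches the trace. The
#' reference configuration is the first frame, whose displacement is
#' identically zero; the reference mesh volume must therefore match
#' `trace(0)` (use [scale_geometry_to_volume()]).
#'
#' @param geom a `chamber_geometry` whose volume matches `trace(0)` within 1%.
#' @param trace a `volume_trace`.
#' @param p the `phenotype_params` (supplies frame count and period).
#' @return object of class `frame_set`: list with `frame_times`, `period`,
#'   `wall_vertex_ids`, and `displacements` (one n_wall x 3 matrix per frame).
#' @export
frames_from_waveform <- function(geom, trace, p) {
  stopifnot(inherits(geom, "chamber_geometry"),
            inherits(trace, "volume_trace"),
            inherits(p, "phenotype_params"))
  per <- p$period
  n_f <- p$n_frames
  tf <- (seq_len(n_f) - 1) * per / n_f
  vfun <- .trace_fun(trace)
  targets <- vfun(tf)

  v_ref <- enclosed_volume(geom)
  if (abs(v_ref - targets[1]) / targets[1] > 0.01) {
    stop(sprintf(paste0(
      "reference mesh volume (%.1f mL) does not match the trace at t=0 ",
      "(%.1f mL); rescale the geometry first"
    ), v_ref, targets[1]))
  }

  wv <- wall_vertices(geom)
  taper <- .rim_taper(geom, wv)
  ctr <- colMeans(geom$vertices)
  radial <- sweep(geom$vertices[wv, , drop = FALSE], 2, ctr, `-`)
  mode <- radial * taper # per-wall-vertex displacement for unit amplitude

  vol_at <- function(g) {
    d <- matrix(0, nrow(geom$vertices), 3)
    d[wv, ] <- g * mode
    enclosed_volume(geom$vertices, geom$boundary_facets, d)
  }
  g_lo <- -0.45
  g_hi <- 0.8
  v_lo <- vol_at(g_lo)
  v_hi <- vol_at(g_hi)

  disp <- vector("list", n_f)
  for (i in seq_len(n_f)) {
    if (i == 1L || abs(targets[i] - v_ref) < 1e-9 * v_ref) {
      disp[[i]] <- matrix(0, length(wv), 3)
      next
    }
    if (targets[i] < v_lo || targets[i] > v_hi) {
      stop(sprintf(paste0(
        "infeasible frame volume %.1f mL at t=%.3f s: achievable range ",
        "with pinned rims is [%.1f, %.1f] mL"
      ), targets[i], tf[i], v_lo, v_hi))
    }
    g <- stats::uniroot(function(x) vol_at(x) - targets[i],
      interval = c(g_lo, g_hi), tol = 1e-12
    )$root
    disp[[i]] <- g * mode
  }

  fs <- structure(list(
    frame_times = tf, period = per, wall_vertex_ids = wv,
    displacements = disp, phenotype = p
  ), class = "frame_set")
  # every displaced surface must remain a valid closed oriented surface
  for (i in seq_len(n_f)) {
    d <- matrix(0, nrow(geom$vertices), 3)
    d[wv, ] <- disp[[i]]
    check_surface(geom$vertices + d, geom$boundary_facets)
  }
  fs
}

# smooth taper in [0,1]: zero on and near the PV/MV caps, one elsewhere
.rim_taper <- function(geom, wv) {
  dirs <- geom$vertices[wv, , drop = FALSE]
  dirs <- dirs / sqrt(rowSums(dirs^2))
  g <- geom$params
  w <- rep(1, length(wv))
  smoothstep <- function(u) {
    u <- pmin(1, pmax(0, u))
    u * u * (3 - 2 * u)
  }
  caps <- if (inherits(g, "geometry_params")) {
    pv <- .pv_axes()
    c(lapply(1:4, function(k) {
      list(axis = pv[k, ], half = .cap_half_angle(g, pv[k, ], g$pv_radius))
    }), list(list(axis = .mv_axis(),
                  half = .cap_half_angle(g, .mv_axis(), g$mv_radius))))
  } else {
    list() # fixtures: no caps to protect
  }
  for (cap in caps) {
    ang <- .angles_to_axis(dirs, cap$axis)
    w <- w * smoothstep((ang - cap$half) / (0.6 * cap$half))
  }
  w
}

#' Analytic centerline fixtures for the tortuosity operator
#'
#' @param kind "straight", "semicircle" or "helix".
#' @param scale segment length / circle radius / helix radius (m).
#' @param n_points number of polyline points (>= 2).
#' @param pitch helix pitch per turn (m); only used for `kind = "helix"`.
#' @return a `centerline` (ordered n x 3 coordinate matrix).
#' @export
centerline_fixture <- function(kind = c("straight", "semicircle", "helix"),
                               scale = 0.02, n_points = 200,
                               pitch = 0.3 * scale) {
  kind <- match.arg(kind)
  if (n_points < 2) stop("n_points must be >= 2")
  s <- seq(0, 1, length.out = n_points)
  pts <- switch(kind,
    straight = cbind(s * scale, 0, 0),
    semicircle = cbind(scale * cos(pi * s), scale * sin(pi * s), 0),
    helix = cbind(scale * cos(2 * pi * s), scale * sin(2 * pi * s), s * pitch)
  )
  structure(pts, class = c("centerline", class(pts)))
}

#' @export
print.phenotype_params <- function(x, ...) {
  cat(sprintf(
    "phenotype [%s]: Vmax %.1f mL, Vmin %.1f mL (SV %.1f, EF %.2f), %.1f bpm (T = %.2f s), %d frames\n",
    x$group, x$v_max, x$v_min, x$v_max - x$v_min,
    (x$v_max - x$v_min) / x$v_max, x$bpm, x$period, x$n_frames
  ))
  invisible(x)
}
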