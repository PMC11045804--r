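# Shared fixtures, built once per test run. Heavier artifacts (solver runs)
# are cached lazily so individual test files stay fast.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

default_chamber <- function() {
  fixture("chamber", function() {
    build_reference_mesh(geometry_params(target_edge_length = 0.006))
  })
}

# moving-chamber 3-beat run at coarse desk settings; used by the
# mass-balance and feature tests (built once, ~1 min)
chamber_run <- function() {
  fixture("chamber_run", function() {
    p <- phenotype_params("control",
      v_max = 110, v_min = 72, bpm = 55,
      n_frames = 30, e_fraction = 0.55
    )
    geom <- scale_geometry_to_volume(
      build_reference_mesh(geometry_params(target_edge_length = 0.0065)),
      p$v_max
    )
    trace <- volume_waveform(p)
    frames <- frames_from_waveform(geom, trace, p)
    model <- fit_displacement_model(frames, smoothing_weight = 0)
    motion <- volumetric_motion(geom, model)
    sched <- mv_schedule(trace)
    history <- run_flow(
      geom, motion, fluid_properties(),
      boundary_spec(mv_schedule = sched),
      solver_config(dt = 5e-3, n_beats = 3)
    )
    list(
      phenotype = p, geom = geom, trace = trace, frames = frames,
      model = model, motion = motion, sched = sched, history = history
    )
  })
}

# steady Poiseuille solution in a straight tube (pseudo-time stepping with
# a large implicit step acts as a Picard iteration)
poiseuille_run <- function(n_cross = 8) {
  fixture(paste0("poiseuille_", n_cross), function() {
    R <- 0.004
    L <- 0.032
    dp <- 0.1
    tube <- tube_mesh("straight", L, R,
      n_cross = n_cross, n_axial = 8,
      end_tags = c("PV1", "MV")
    )
    bc <- boundary_spec(
      p_in = dp, p_out = 0,
      mv_schedule = data.frame(time = 0, state = "open")
    )
    cfg <- solver_config(dt = 0.5)
    st <- flow_state(tube)
    for (k in 1:10) {
      st <- advance(st, tube, NULL, fluid_properties(), bc, cfg)
    }
    u_max <- dp * R^2 / (4 * fluid_properties()$dynamic_viscosity * L)
    list(tube = tube, state = st, R = R, L = L, dp = dp, u_max = u_max)
  })
}

# wrap a single velocity snapshot as a phase-averaged flow
snapshot_flow <- function(u, times = 0, period = 1) {
  U <- if (is.list(u)) u else list(u)
  structure(
    list(
      U = U, phase_times = times, period = period,
      n_discarded = 0, n_averaged = 1
    ),
    class = "phase_averaged_flow"
  )
}

# synthetic wall-shear history from a list of (n_wall x 3) matrices
wss_fixture <- function(W, period = 1) {
  m <- length(W)
  structure(
    list(
      W = W, wall_vertex_ids = seq_len(nrow(W[[1]])),
      phase_times = period * (seq_len(m) - 0.5) / m, period = period
    ),
    class = "wss_history"
  )
}
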