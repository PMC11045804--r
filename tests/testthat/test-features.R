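# hemodynamic features: phase averaging, stasis, WSS statistics, energy

test_that("phase averaging is exact on periodic histories and single beats", {
  n <- 20
  m <- 5
  set.seed(1)
  beat <- lapply(seq_len(m), function(k) matrix(rnorm(3 * n), n, 3))
  hist <- structure(list(
    U = c(beat, beat, beat), times = (1:(3 * m)) * 0.01,
    snapshots_per_beat = m, n_beats = 3, period = m * 0.01
  ), class = "flow_history")
  pa <- phase_average(hist, n_discard = 1)
  for (k in seq_len(m)) {
    expect_equal(pa$U[[k]], beat[[k]], tolerance = 1e-12)
  }
  pa1 <- phase_average(hist, n_discard = 2, n_average = 1)
  for (k in seq_len(m)) expect_identical(pa1$U[[k]], beat[[k]])
  expect_error(phase_average(hist, n_discard = 3), "insufficient")
})

test_that("phase averaging cancels iid noise like 1/sqrt(n) (Monte Carlo)", {
  n <- 50
  m <- 4
  sigma <- 0.1
  resid <- numeric(50)
  for (r in 1:50) {
    set.seed(r)
    beat <- lapply(seq_len(m), function(k) matrix(0, n, 3))
    noisy <- lapply(seq_len(8 * m), function(i) {
      matrix(rnorm(3 * n, sd = sigma), n, 3)
    })
    hist <- structure(list(
      U = noisy, snapshots_per_beat = m, n_beats = 8, period = 1
    ), class = "flow_history")
    pa <- phase_average(hist, n_discard = 0, n_average = 8)
    resid[r] <- sqrt(mean(vapply(pa$U, function(u) mean(u^2), numeric(1))))
  }
  expect_lt(abs(mean(resid) - sigma / sqrt(8)) / (sigma / sqrt(8)), 0.2)
})

test_that("flow stasis closed forms and threshold monotonicity", {
  n <- 10
  zero <- snapshot_flow(lapply(1:4, function(k) matrix(0, n, 3)),
                        times = (1:4) / 4)
  expect_equal(flow_stasis(zero, 0.1), rep(1, n))

  fast <- snapshot_flow(lapply(1:4, function(k) {
    matrix(rep(c(0.2, 0, 0), each = n), n, 3)
  }), times = (1:4) / 4)
  expect_equal(flow_stasis(fast, 0.1), rep(0, n))

  # 30% of the period slow, 70% fast -> fs = 0.30
  m <- 10
  mixed <- snapshot_flow(lapply(seq_len(m), function(k) {
    spd <- if (k <= 3) 0.05 else 0.2
    matrix(rep(c(spd, 0, 0), each = n), n, 3)
  }), times = (1:m) / m)
  expect_equal(flow_stasis(mixed, 0.1), rep(0.3, n))

  # monotone in the threshold
  set.seed(2)
  rnd <- snapshot_flow(lapply(1:6, function(k) matrix(rnorm(3 * n, sd = 0.1), n, 3)),
                       times = (1:6) / 6)
  f1 <- flow_stasis(rnd, 0.05)
  f2 <- flow_stasis(rnd, 0.15)
  expect_true(all(f2 >= f1))
  expect_error(flow_stasis(rnd, 0), "threshold")
})

test_that("wall feature identities: constant, reversing, 3:1 duty cycle", {
  nw <- 7
  w <- 0.8
  const <- wss_fixture(lapply(1:8, function(k) {
    matrix(rep(c(w, 0, 0), each = nw), nw, 3)
  }))
  f <- wall_features(const)
  expect_equal(f$tawss, rep(w, nw), tolerance = 1e-12)
  expect_equal(f$osi, rep(0, nw), tolerance = 1e-12)
  expect_equal(f$rrt, rep(1 / w, nw), tolerance = 1e-12)
  expect_equal(f$ecap, rep(0, nw), tolerance = 1e-12)

  # half-period reversal: OSI = 1/2, RRT flagged divergent
  rev <- wss_fixture(lapply(1:8, function(k) {
    s <- if (k <= 4) w else -w
    matrix(rep(c(s, 0, 0), each = nw), nw, 3)
  }))
  fr <- wall_features(rev)
  expect_equal(fr$osi, rep(0.5, nw), tolerance = 1e-10)
  expect_true(all(is.na(fr$rrt)))

  # 3:1 duty cycle: OSI = 1/4, TAWSS = w, RRT = 2/w
  duty <- wss_fixture(lapply(1:8, function(k) {
    s <- if (k <= 6) w else -w
    matrix(rep(c(s, 0, 0), each = nw), nw, 3)
  }))
  fd <- wall_features(duty)
  expect_equal(fd$osi, rep(0.25, nw), tolerance = 1e-10)
  expect_equal(fd$tawss, rep(w, nw), tolerance = 1e-12)
  expect_equal(fd$rrt, rep(2 / w, nw), tolerance = 0.01)
  # identities RRT (1 - 2 OSI) TAWSS = 1 and ECAP TAWSS = OSI
  expect_equal(fd$rrt * (1 - 2 * fd$osi) * fd$tawss, rep(1, nw),
               tolerance = 1e-10)
  expect_equal(fd$ecap * fd$tawss, fd$osi, tolerance = 1e-12)
})

test_that("OSI stays in [0, 1/2] for random shear histories", {
  set.seed(9)
  for (rep in 1:20) {
    W <- lapply(1:6, function(k) matrix(rnorm(30), 10, 3))
    f <- wall_features(wss_fixture(W))
    expect_true(all(f$osi >= 0 & f$osi <= 0.5))
  }
})

test_that("kinetic energy and enstrophy closed forms", {
  b <- ball_mesh(0.01, 4)
  vol <- sum(abs(tet_volumes(b$vertices, b$tets)))
  # uniform velocity: Ek = |U|^2 V / 2, S ~ 0
  U <- c(0.3, -0.1, 0.2)
  u_uni <- matrix(rep(U, each = nrow(b$vertices)), ncol = 3)
  gt <- global_traces(snapshot_flow(u_uni), b)
  ek_ref <- 0.5 * sum(U^2) * vol
  expect_lt(abs(gt$kinetic_energy - ek_ref) / ek_ref, 1e-6)
  expect_lt(gt$enstrophy, 1e-6 * sum(U^2) * vol / 0.01^2)

  # rigid rotation: |omega| = 2|Omega| everywhere, S = 2 |Omega|^2 V
  Om <- c(0, 0, 12)
  u_rot <- cbind(-Om[3] * b$vertices[, 2], Om[3] * b$vertices[, 1], 0)
  gt2 <- global_traces(snapshot_flow(u_rot), b)
  s_ref <- 2 * sum(Om^2) * vol
  expect_lt(abs(gt2$enstrophy - s_ref) / s_ref, 0.05)
  # zero flow
  gt0 <- global_traces(snapshot_flow(0 * u_rot), b)
  expect_equal(gt0$kinetic_energy, 0)
  expect_equal(gt0$enstrophy, 0)
})

test_that("vorticity phase medians: zero flow, rigid rotation, region masks", {
  geom <- default_chamber()
  n <- nrow(geom$vertices)
  zero <- snapshot_flow(lapply(1:4, function(k) matrix(0, n, 3)),
                        times = (1:4) / 4)
  vm <- vorticity_phase_medians(zero, geom, NULL,
                                e_time = 0.25, a_time = 0.5,
                                systolic_time = 0.9)
  expect_true(all(vm$median_vorticity == 0))

  Om <- 8
  rot <- snapshot_flow(lapply(1:4, function(k) {
    cbind(-Om * geom$vertices[, 2], Om * geom$vertices[, 1], 0)
  }), times = (1:4) / 4)
  vm2 <- vorticity_phase_medians(rot, geom, NULL, 0.25, 0.5, 0.9)
  expect_lt(max(abs(vm2$median_vorticity - 2 * Om)) / (2 * Om), 0.05)
  expect_setequal(unique(vm2$region), c("LA", "LAA"))

  expect_error(
    vorticity_phase_medians(zero, geom, NULL, NA_real_, 0.5, 0.9),
    "wave-detection"
  )
})

test_that("region medians: constants, brute-force check, permutation invariance", {
  geom <- default_chamber()
  n <- nrow(geom$vertices)
  wv <- wall_vertices(geom)
  wf <- data.frame(vertex = wv, tawss = 1.5, osi = 0.1,
                   rrt = 2, ecap = 0.05)
  fs <- rep(0.25, n)
  med <- region_medians(geom, wf, fs)
  expect_equal(med$fs, rep(0.25, 2))
  expect_equal(med$tawss, rep(1.5, 2))

  # LAA mask: a field that is 1 on the appendage and 0 elsewhere
  laa_vol <- sort(unique(as.vector(geom$tets[geom$laa_cells, ])))
  fs2 <- rep(0, n)
  fs2[laa_vol] <- 1
  med2 <- region_medians(geom, wf, fs2)
  expect_equal(med2$fs[med2$region == "LAA"], 1)

  # median matches a sort-based oracle and is permutation invariant
  set.seed(5)
  wf3 <- wf
  wf3$tawss <- rep(c(1, 2, 3, 4, 5), length.out = nrow(wf))
  srt <- sort(wf3$tawss)
  nsrt <- length(srt)
  oracle <- if (nsrt %% 2 == 1) srt[(nsrt + 1) / 2] else {
    (srt[nsrt / 2] + srt[nsrt / 2 + 1]) / 2
  }
  m3 <- region_medians(geom, wf3, fs)
  expect_equal(m3$tawss[m3$region == "LA"], oracle)
  wf4 <- wf3[sample(nrow(wf3)), ]
  m4 <- region_medians(geom, wf4, fs)
  expect_equal(m3$tawss[1], m4$tawss[1])
})
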