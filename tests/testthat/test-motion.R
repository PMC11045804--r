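# wall distance, stiffened harmonic lifting, volumetric motion

test_that("wall distance is exact on wall, positive inside, ~radial in a ball", {
  b <- ball_mesh(0.01, 4)
  d <- wall_distance_field(b)
  expect_true(all(d >= 0))
  wv <- wall_vertices(b)
  expect_lt(max(d[wv]), 1e-14)
  interior <- setdiff(seq_len(nrow(b$vertices)), wv)
  rho <- sqrt(rowSums(b$vertices[interior, ]^2))
  edge <- 0.01 / 4
  expect_lt(max(abs(d[interior] - (0.01 - rho))), edge)

  nowall <- b
  nowall$boundary_tag[] <- REGION_TAGS[["MV"]]
  expect_error(wall_distance_field(nowall), "WALL")
})

test_that("lifting reproduces rigid translation exactly (constants in kernel)", {
  geom <- default_chamber()
  wv <- wall_vertices(geom)
  cvec <- c(1e-3, -2e-3, 0.5e-3)
  G <- matrix(rep(cvec, each = length(wv)), length(wv), 3)
  D <- harmonic_lifting(geom, G)
  for (c in 1:3) {
    expect_lt(max(abs(D[, c] - cvec[c])), 1e-8 * max(abs(cvec)))
  }
  # wall values imposed strongly
  expect_identical(D[wv, ], G)
})

test_that("beta = 0 lifting solves the 1D Laplace profile on a box", {
  bx <- box_mesh(c(0.01, 0.01, 0.01), 4)
  # treat x = 0 and x = L as "wall": retag facets by centroid
  fg <- lahemo:::facet_geometry(bx$vertices, bx$boundary_facets)
  tag <- rep(REGION_TAGS[["MV"]], nrow(bx$boundary_facets))
  tag[abs(fg$centroid[, 1]) < 1e-12] <- REGION_TAGS[["WALL"]]
  tag[abs(fg$centroid[, 1] - 0.01) < 1e-12] <- REGION_TAGS[["WALL"]]
  bx$boundary_tag <- as.integer(tag)
  wv <- wall_vertices(bx)
  G <- matrix(0, length(wv), 3)
  G[, 1] <- bx$vertices[wv, 1] / 0.01 # 0 on x=0 face, 1 on x=L face
  D <- harmonic_lifting(bx, G, lifting_config(beta = 0))
  expect_lt(max(abs(D[, 1] - bx$vertices[, 1] / 0.01)), 1e-6)
  expect_lt(max(abs(D[, 2:3])), 1e-9)
})

test_that("discrete maximum principle surrogate holds for beta = 0", {
  geom <- default_chamber()
  wv <- wall_vertices(geom)
  set.seed(3)
  G <- matrix(runif(3 * length(wv), -1e-3, 2e-3), length(wv), 3)
  D <- harmonic_lifting(geom, G, lifting_config(beta = 0))
  for (c in 1:3) {
    rng <- range(G[, c])
    eps <- 1e-8 * diff(rng)
    expect_gte(min(D[, c]), rng[1] - eps)
    expect_lte(max(D[, c]), rng[2] + eps)
  }
})

test_that("stiffening (beta = 2) does not worsen near-wall element quality", {
  run <- chamber_run()
  geom <- run$geom
  wv <- wall_vertices(geom)
  # strong contraction mode from the generator at the volume minimum
  i_min <- which.min(run$trace$volume)
  fr <- frames_from_waveform(geom, run$trace, run$phenotype)
  i_fr <- which.min(vapply(seq_along(fr$frame_times), function(i) {
    abs(fr$frame_times[i] - run$trace$time[i_min])
  }, numeric(1)))
  G <- fr$displacements[[i_fr]]
  qmin <- sapply(c(0, 1, 2), function(b) {
    D <- harmonic_lifting(geom, G, lifting_config(beta = b))
    min(element_quality(geom$vertices, geom$tets, displacement = D))
  })
  expect_gte(qmin[3], qmin[1] - 1e-12)
  # quality degradation is monotone non-increasing in beta on this fixture
  expect_gte(qmin[2], qmin[1] - 1e-12)
})

test_that("volumetric motion is zero for zero boundary motion and tracks volume", {
  run <- chamber_run()
  geom <- run$geom
  wv <- wall_vertices(geom)
  zero_fr <- structure(list(
    frame_times = run$frames$frame_times, period = run$frames$period,
    wall_vertex_ids = wv,
    displacements = lapply(run$frames$displacements, function(d) d * 0)
  ), class = "frame_set")
  m0 <- fit_displacement_model(zero_fr, smoothing_weight = 0)
  mo0 <- volumetric_motion(geom, m0)
  expect_lt(max(abs(mo0$displacement(0.123))), 1e-12)
  expect_lt(max(abs(mo0$velocity(0.456))), 1e-10)

  # chamber volume follows the trace within 1.5% over the period
  f <- volume_waveform_fun(run$phenotype)
  tt <- seq(0, run$phenotype$period, length.out = 29)
  errs <- vapply(tt, function(t) {
    v <- enclosed_volume(geom$vertices, geom$boundary_facets,
                         run$motion$displacement(t))
    abs(v - f(t)) / f(t)
  }, numeric(1))
  expect_lt(max(errs), 0.015)

  # element validity at all collocation times
  for (t in run$motion$collocation_times) {
    q <- element_quality(geom$vertices, geom$tets,
                         displacement = run$motion$displacement(t))
    expect_gt(min(q), 0)
  }
})
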