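# functional metrics: volumes, E/A analysis, tortuosity, centerline, ostium

test_that("volume_extrema reproduces analytic extrema and identities", {
  tt <- seq(0, 1, length.out = 1001)
  tr <- volume_trace(tt, 100 + 20 * cos(2 * pi * tt), period = 1)
  ex <- volume_extrema(tr)
  expect_equal(ex$v_max, 120, tolerance = 1e-6)
  expect_equal(ex$v_min, 80, tolerance = 1e-6)
  expect_equal(ex$sv, 40, tolerance = 1e-5)
  expect_equal(ex$ef, 1 / 3, tolerance = 1e-6)
  expect_error(volume_extrema(data.frame()), "empty")
})

test_that("ea_analysis detects constructed two-Gaussian peaks", {
  T_hb <- 1
  tt <- seq(0, T_hb, length.out = 2001)
  q <- 400 * exp(-((tt - 0.15) / 0.04)^2 / 2) +
    320 * exp(-((tt - 0.38) / 0.04)^2 / 2)
  sched <- data.frame(time = c(0, 0.5), state = c("open", "closed"))
  ea <- ea_analysis(data.frame(time = tt, q = q), sched, T_hb)
  expect_lt(abs(ea$e_peak - 400) / 400, 0.01)
  expect_lt(abs(ea$a_peak - 320) / 320, 0.01)
  expect_lt(abs(ea$ea_ratio - 1.25) / 1.25, 0.01)

  # symmetric equal bumps give ratio 1
  qs <- 400 * (exp(-((tt - 0.15) / 0.04)^2 / 2) +
                 exp(-((tt - 0.35) / 0.04)^2 / 2))
  eas <- ea_analysis(data.frame(time = tt, q = qs), sched, T_hb)
  expect_equal(eas$ea_ratio, 1, tolerance = 1e-6)

  # a single bump is a detection error, not a guess
  q1 <- 400 * exp(-((tt - 0.25) / 0.05)^2 / 2)
  expect_error(ea_analysis(data.frame(time = tt, q = q1), sched, T_hb),
               "wave-detection")
})

test_that("tortuosity closed forms and isometry/scale invariance", {
  expect_equal(tortuosity(centerline_fixture("straight", 0.05, 100)), 0,
               tolerance = 1e-12)
  semi <- centerline_fixture("semicircle", 0.03, 200)
  expect_lt(abs(tortuosity(semi) - (pi / 2 - 1)), 1e-3)
  # rigid rotation + translation leaves tau unchanged
  th <- 0.7
  Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- sweep(unclass(semi) %*% t(Rz), 2, c(1, -2, 3), `+`)
  expect_equal(tortuosity(moved), tortuosity(semi), tolerance = 1e-12)
  # scale invariance
  expect_equal(tortuosity(unclass(semi) * 17), tortuosity(semi),
               tolerance = 1e-12)
  expect_error(tortuosity(rbind(c(0, 0, 0), c(0, 0, 0))), "degenerate")
})

test_that("laa_centerline recovers straight and bent tube axes", {
  L <- 0.04
  r <- 0.004
  st <- tube_mesh("straight", L, r, n_cross = 4, n_axial = 12,
                  closed_end = TRUE)
  cl <- laa_centerline(st)
  len <- sum(sqrt(rowSums(diff(unclass(cl))^2)))
  expect_lt(abs(len - L) / L, 0.05)
  expect_lt(tortuosity(cl), 0.02)
  # endpoints: start near the ostium centroid, end on the far wall
  ring_c <- colMeans(st$vertices[st$ostium_ring, ])
  expect_lt(sqrt(sum((cl[1, ] - ring_c)^2)), L / 10)

  qt <- tube_mesh("quarter_torus", L, r, n_cross = 4, n_axial = 14,
                  closed_end = TRUE)
  tau <- tortuosity(laa_centerline(qt))
  ref <- pi / (2 * sqrt(2)) - 1 # quarter circle: arc pi*R/2, chord R*sqrt(2)
  expect_lt(abs(tau - ref) / ref, 0.15)

  expect_error(laa_centerline(box_mesh()), "tagging")
})

test_that("ostium_area matches a planar disk and obeys the scaling law", {
  # synthetic ring: planar circle of radius r with 64 vertices
  r <- 0.008
  th <- 2 * pi * (seq_len(64) - 1) / 64
  verts <- cbind(r * cos(th), r * sin(th), 0.002)
  g <- list(
    vertices = verts, ostium_ring = seq_len(64),
    tag_legend = REGION_TAGS
  )
  class(g) <- "chamber_geometry"
  a <- ostium_area(g)
  expect_lt(abs(a - pi * r^2 * 1e6) / (pi * r^2 * 1e6), 0.01)
  g2 <- g
  g2$vertices <- 2 * g2$vertices
  expect_equal(ostium_area(g2), 4 * a, tolerance = 1e-12)
  # mild out-of-plane warp changes the projected area by < 2%
  g3 <- g
  g3$vertices[, 3] <- g3$vertices[, 3] + 0.01 * r * sin(3 * th)
  expect_lt(abs(ostium_area(g3) - pi * r^2 * 1e6) / (pi * r^2 * 1e6), 0.02)
})

test_that("functional_summary populates identities (periods per printed BPM)", {
  p <- phenotype_params("control", v_max = 100, v_min = 70, bpm = 57.1)
  tr <- volume_waveform(p)
  fs <- functional_summary(tr, bpm = p$bpm)
  expect_equal(round(fs$period, 2), 1.05)
  expect_equal(fs$sv, fs$v_max - fs$v_min)
  expect_equal(fs$ef, fs$sv / fs$v_max)
  fs2 <- functional_summary(tr, bpm = 67)
  expect_equal(round(fs2$period, 2), 0.90)
  # degenerate case: EA fields absent
  p0 <- phenotype_params("control", v_max = 100, v_min = 100, bpm = 60)
  f0 <- functional_summary(volume_waveform(p0), bpm = 60)
  expect_equal(f0$sv, 0, tolerance = 1e-9)
  expect_true(is.na(f0$ea_ratio))
})
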