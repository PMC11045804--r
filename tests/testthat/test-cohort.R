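# phenotype sampling, volume waveforms, frame generation

test_that("sample_cohort respects counts, seeds and clinical BPM ranges", {
  expect_identical(sample_cohort(0, 0, 1), list())
  expect_error(sample_cohort(-1, 0, 1), "counts")

  co <- sample_cohort(4, 4, 7)
  expect_length(co, 8)
  bpm_c <- sapply(co[1:4], `[[`, "bpm")
  bpm_s <- sapply(co[5:8], `[[`, "bpm")
  expect_true(all(bpm_c >= 50.3 & bpm_c <= 57.7))
  expect_true(all(bpm_s >= 51.5 & bpm_s <= 76.0))
  expect_true(all(sapply(co, `[[`, "n_frames") %in% c(25L, 30L, 40L)))

  co2 <- sample_cohort(4, 4, 7)
  expect_identical(co, co2)
  co3 <- sample_cohort(4, 4, 8)
  expect_false(identical(co, co3))
})

test_that("cohort-level contracts: volumes, SV, BPM ordering and EF overlap", {
  co <- sample_cohort(5, 5, 3)
  g <- sapply(co, `[[`, "group")
  sv <- sapply(co, function(p) p$v_max - p$v_min)
  bpm <- sapply(co, `[[`, "bpm")
  ef <- sv / sapply(co, `[[`, "v_max")
  expect_lt(median(sv[g == "stroke"]), median(sv[g == "control"]))
  expect_gt(median(bpm[g == "stroke"]), median(bpm[g == "control"]))
  # EF intervals intersect by construction
  expect_lt(max(min(ef[g == "stroke"]), min(ef[g == "control"])),
            min(max(ef[g == "stroke"]), max(ef[g == "control"])))
})

test_that("volume waveform hits extrema, is periodic and biphasic", {
  p <- phenotype_params("control", v_max = 110, v_min = 72, bpm = 55,
                        n_frames = 30, e_fraction = 0.55)
  f <- volume_waveform_fun(p)
  tt <- seq(0, p$period, length.out = 5000)
  V <- f(tt)
  expect_lt(abs(max(V) - 110) / 110, 1e-3)
  expect_lt(abs(min(V) - 72) / 72, 1e-3)
  expect_equal(f(0.3), f(0.3 + 5 * p$period), tolerance = 1e-12)
  # emptying flow has exactly the E and A peaks
  q <- -diff(V) / diff(tt)[1]
  pk <- lahemo:::.prominent_peaks(q, 0.05 * max(q))
  expect_length(pk, 2)
  # E share of the emptied volume ~ e_fraction: integrate up to diastasis
  t_dia <- tt[which.min(abs(tt - 0.26 * p$period))]
  e_emptied <- 110 - f(t_dia)
  expect_lt(abs(e_emptied / (110 - 72) - 0.55), 0.02)
  # fundamental theorem: emptied volume equals v_max - v_min
  i_min <- which.min(V)
  expect_lt(abs(sum(q[1:(i_min - 1)]) * diff(tt)[1] - (110 - 72)) / 38, 1e-3)

  expect_error(phenotype_params(v_max = 70, v_min = 80), "v_min")
})

test_that("degenerate constant phenotype yields zero stroke downstream", {
  p <- phenotype_params("control", v_max = 100, v_min = 100, bpm = 60)
  tr <- volume_waveform(p)
  ex <- volume_extrema(tr)
  expect_equal(ex$sv, 0, tolerance = 1e-9)
  expect_equal(ex$ef, 0, tolerance = 1e-9)
})

test_that("frames_from_waveform matches targets and keeps surfaces valid", {
  p <- phenotype_params("control", v_max = 110, v_min = 72, bpm = 55,
                        n_frames = 25)
  geom <- scale_geometry_to_volume(default_chamber(), p$v_max)
  tr <- volume_waveform(p)
  fr <- frames_from_waveform(geom, tr, p)
  expect_length(fr$frame_times, 25L)
  expect_true(all(fr$displacements[[1]] == 0))

  f <- volume_waveform_fun(p)
  errs <- vapply(seq_along(fr$frame_times), function(i) {
    d <- matrix(0, nrow(geom$vertices), 3)
    d[fr$wall_vertex_ids, ] <- fr$displacements[[i]]
    v <- enclosed_volume(geom$vertices, geom$boundary_facets, d)
    abs(v - f(fr$frame_times[i])) / f(fr$frame_times[i])
  }, numeric(1))
  expect_lt(max(errs), 0.01)

  # constant trace equal to the reference volume: identity motion
  p0 <- phenotype_params("control", v_max = 110, v_min = 110, bpm = 55,
                         n_frames = 25)
  fr0 <- frames_from_waveform(geom, volume_waveform(p0), p0)
  expect_true(all(vapply(fr0$displacements,
                         function(d) all(d == 0), logical(1))))

  # mismatched reference volume is rejected
  expect_error(frames_from_waveform(default_chamber(), tr, p), "rescale")
})

test_that("centerline fixtures have the analytic shapes", {
  expect_equal(tortuosity(centerline_fixture("straight", 0.02, 50)), 0,
               tolerance = 1e-12)
  expect_lt(
    abs(tortuosity(centerline_fixture("semicircle", 0.02, 200)) -
          (pi / 2 - 1)), 1e-3
  )
  hx <- centerline_fixture("helix", 0.01, 500, pitch = 0.003)
  len <- sum(sqrt(rowSums(diff(unclass(hx))^2)))
  ref <- sqrt((2 * pi * 0.01)^2 + 0.003^2)
  expect_lt(abs(len - ref) / ref, 0.005)
  expect_error(centerline_fixture("spiral"), "arg")
  expect_error(centerline_fixture("straight", n_points = 1), "n_points")
})
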