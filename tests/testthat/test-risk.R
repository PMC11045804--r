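# cohort table assembly and penalized logistic separation

make_table <- function(x, y, groups, ids = NULL) {
  if (is.null(ids)) ids <- paste0("P", seq_along(x))
  structure(
    data.frame(id = ids, group = groups, xcol = x, ycol = y,
               stringsAsFactors = FALSE),
    class = c("cohort_table", "data.frame")
  )
}

test_that("assemble_cohort_table builds the schema and rejects duplicates", {
  empty <- assemble_cohort_table(list())
  expect_identical(nrow(empty), 0L)
  expect_true(all(c("id", "group") %in% names(empty)))

  cases <- lapply(1:8, function(i) {
    list(
      id = paste0(if (i <= 4) "C" else "S", i),
      group = if (i <= 4) "control" else "stroke",
      functional = list(v_max = 100 + i, sv = 30 + i, ef = 0.3, bpm = 60),
      medians_la = list(fs = 0.3, tawss = 0.2),
      medians_laa = list(fs = 0.5, tawss = 0.1)
    )
  })
  tb <- assemble_cohort_table(cases)
  expect_identical(nrow(tb), 8L)
  expect_true(all(c("la_fs", "laa_fs", "la_tawss", "v_max") %in% names(tb)))

  cases[[2]]$id <- cases[[1]]$id
  expect_error(assemble_cohort_table(cases), "duplicate")
})

test_that("cohort table round-trips through CSV to 12 significant digits", {
  tb <- make_table(c(pi, exp(1), sqrt(2), 1 / 3), rep(1.23456789012345, 4),
                   c("control", "control", "stroke", "stroke"))
  path <- tempfile(fileext = ".csv")
  write_cohort_table(tb, path)
  tb2 <- read_cohort_table(path)
  expect_lt(max(abs(tb2$xcol - tb$xcol) / abs(tb$xcol)), 1e-12)
  expect_identical(tb2$group, tb$group)
})

test_that("fit_separation: separable clouds, XOR, and degenerate input", {
  set.seed(11)
  # two clouds split by x = 0 (any y): separated, verified by sign oracle
  x <- c(rnorm(4, -2, 0.3), rnorm(4, 2, 0.3))
  y <- rnorm(8)
  g <- rep(c("control", "stroke"), each = 4)
  tb <- make_table(x, y, g)
  fit <- fit_separation(tb, "xcol", "ycol")
  expect_true(fit$separated)
  expect_length(fit$misclassified_ids, 0)
  # brute force: the boundary line must put every point on its own side
  side <- sign(fit$boundary[["c0"]] + fit$boundary[["cx"]] * x +
                 fit$boundary[["cy"]] * y)
  expect_true(all(side[g == "stroke"] == side[g == "stroke"][1]))
  expect_true(all(side[g == "control"] == -side[g == "stroke"][1]))

  # XOR arrangement: not separable, exactly 2 misclassified by any line
  xq <- c(-1, 1, -1, 1)
  yq <- c(-1, -1, 1, 1)
  gq <- c("control", "stroke", "stroke", "control")
  fq <- fit_separation(make_table(xq, yq, gq), "xcol", "ycol")
  expect_false(fq$separated)
  expect_length(fq$misclassified_ids, 2)

  expect_error(fit_separation(make_table(x, y, rep("stroke", 8)),
                              "xcol", "ycol"), "degenerate")
  expect_error(fit_separation(make_table(c(x[-1], NA), y, g),
                              "xcol", "ycol"), "non-finite")
})

test_that("constant y with separating x reduces to a vertical boundary", {
  x <- c(-3, -2, -1.5, -1, 1, 1.5, 2, 3)
  tb <- make_table(x, rep(5, 8), rep(c("control", "stroke"), each = 4))
  fit <- fit_separation(tb, "xcol", "ycol")
  expect_true(fit$separated)
  expect_equal(fit$boundary[["cy"]], 0)
})

test_that("separation flag is invariant under affine covariate rescaling", {
  set.seed(13)
  x <- c(rnorm(4, -1), rnorm(4, 1))
  y <- rnorm(8, sd = 2)
  g <- rep(c("control", "stroke"), each = 4)
  f1 <- fit_separation(make_table(x, y, g), "xcol", "ycol")
  f2 <- fit_separation(make_table(100 * x + 7, -0.01 * y + 3, g),
                       "xcol", "ycol")
  expect_identical(f1$separated, f2$separated)
  expect_identical(f1$misclassified_ids, f2$misclassified_ids)
})

test_that("shrinking the penalty never un-separates a separable pair", {
  set.seed(17)
  x <- c(rnorm(4, -2, 0.2), rnorm(4, 2, 0.2))
  y <- rnorm(8)
  tb <- make_table(x, y, rep(c("control", "stroke"), each = 4))
  for (lam in c(1e-2, 1e-4, 1e-6, 1e-8)) {
    expect_true(fit_separation(tb, "xcol", "ycol", lam)$separated)
  }
})

test_that("noise features do not beat label-permuted fits on average", {
  set.seed(19)
  n <- 8
  g <- rep(c("control", "stroke"), 4) # interleaved labels
  sep_true <- sep_perm <- 0
  for (r in 1:200) {
    x <- rnorm(n)
    y <- rnorm(n)
    tb <- make_table(x, y, g)
    sep_true <- sep_true + fit_separation(tb, "xcol", "ycol")$separated
    gp <- sample(g)
    sep_perm <- sep_perm + fit_separation(make_table(x, y, gp),
                                          "xcol", "ycol")$separated
  }
  # pure-noise separation rate should not exceed the permuted baseline
  # by more than Monte-Carlo slack
  expect_lt(sep_true / 200, sep_perm / 200 + 0.1)
})

test_that("normalize_features appends ratio columns and flags zero denominators", {
  tb <- make_table(1:4, 5:8, c("control", "control", "stroke", "stroke"))
  tb$la_fs <- c(0.5, 0.4, 0.6, 0.7)
  tb$sv <- c(40, 20, 1, 0)
  out <- normalize_features(tb, "sv", feature_names = "la_fs")
  expect_equal(out$la_fs_over_sv[1], 0.0125)
  expect_true(is.na(out$la_fs_over_sv[4]))
  expect_identical(out$la_fs, tb$la_fs) # originals untouched
  # denominator of ones reproduces the feature
  tb$ones <- 1
  out2 <- normalize_features(tb, "ones", feature_names = "la_fs")
  expect_identical(out2$la_fs_over_ones, tb$la_fs)
})
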