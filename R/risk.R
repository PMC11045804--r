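# Merging hemodynamic medians with functional metrics: per-pair penalized
# logistic regression (binomial likelihood) on standardized covariates.
# With 4+4 cases complete separation is the norm, which makes the
# unpenalized likelihood divergent; a small L2 ridge on the slopes keeps
# the fit finite while preserving the boundary location in the separable
# limit. "Correlation" between a feature and a metric is operationalized
# as complete separation of the cases by the probability-1/2 line.

#' Assemble the per-case cohort table
#'
#' @param cases list of per-case records: each a list with `id`, `group`
#'   ("control"/"stroke"), `functional` (named list/vector), and optional
#'   `medians_la`, `medians_laa` (named lists; prefixed `la_`/`laa_`).
#' @return object of class `cohort_table` (a data.frame, one row per case).
#' @export
assemble_cohort_table <- function(cases) {
  if (length(cases) == 0) {
    return(structure(
      data.frame(id = character(0), group = character(0)),
      class = c("cohort_table", "data.frame")
    ))
  }
  ids <- vapply(cases, function(x) as.character(x$id), character(1))
  if (anyDuplicated(ids)) stop("duplicate case ids")
  rows <- lapply(cases, function(x) {
    stopifnot(x$group %in% c("control", "stroke"))
    rec <- c(
      as.list(x$functional),
      if (!is.null(x$medians_la)) {
        stats::setNames(as.list(x$medians_la),
                        paste0("la_", names(x$medians_la)))
      },
      if (!is.null(x$medians_laa)) {
        stats::setNames(as.list(x$medians_laa),
                        paste0("laa_", names(x$medians_laa)))
      }
    )
    rec <- rec[vapply(rec, function(v) is.numeric(v) && length(v) == 1,
                      logical(1))]
    cbind(data.frame(id = as.character(x$id), group = x$group,
                     stringsAsFactors = FALSE),
          as.data.frame(rec))
  })
  cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (m in setdiff(cols, names(r))) r[[m]] <- NA_real_
    r[cols]
  })
  structure(do.call(rbind, rows), class = c("cohort_table", "data.frame"))
}

#' Write / read a cohort table as CSV
#' @param table a `cohort_table`.
#' @param path file path.
#' @return the path (write) or a `cohort_table` (read).
#' @export
write_cohort_table <- function(table, path) {
  tf <- as.data.frame(table)
  num <- vapply(tf, is.numeric, logical(1))
  for (c in which(num)) tf[[c]] <- sprintf("%.15g", tf[[c]])
  utils::write.csv(tf, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = NA)
  for (c in setdiff(names(df), c("id", "group"))) {
    df[[c]] <- as.numeric(df[[c]])
  }
  structure(df, class = c("cohort_table", "data.frame"))
}

# penalized logistic fit by damped Newton / IRLS on standardized covariates
.logistic_ridge <- function(X, y, lambda, tol = 1e-8, max_iter = 200) {
  p <- ncol(X)
  pen <- diag(c(0, rep(1, p - 1)), p) # intercept unpenalized
  beta <- rep(0, p)
  for (it in seq_len(max_iter)) {
    eta <- as.numeric(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    grad <- as.numeric(crossprod(X, y - mu)) - 2 * lambda * (pen %*% beta)
    if (sqrt(sum(grad^2)) < tol) break
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X * w, X) + 2 * lambda * pen
    step <- solve(H, grad)
    # crude damping for the separable limit
    s <- 1
    obj <- function(b) {
      e <- as.numeric(X %*% b)
      -sum(y * e - log1p(exp(e))) + lambda * sum((pen %*% b) * b)
    }
    f0 <- obj(beta)
    while (s > 1e-4 && obj(beta + s * step) > f0) s <- s / 2
    beta <- beta + s * as.numeric(step)
  }
  list(beta = beta, grad_norm = sqrt(sum(grad^2)), iterations = it)
}

#' Fit the per-pair logistic separation
#'
#' Fits `group ~ x + y` (stroke = 1) by maximum L2-penalized binomial
#' likelihood on standardized covariates and reports whether the
#' probability-1/2 line places every case on its own group's side.
#'
#' @param table a `cohort_table`.
#' @param x_name,y_name column names (functional metric, hemodynamic
#'   median).
#' @param penalty_weight ridge weight on the standardized slopes.
#' @return object of class `separation_result`: coefficients (standardized
#'   space), `separated`, `misclassified_ids`, and `boundary` (coefficients
#'   `c0 + cx x + cy y = 0` in original units).
#' @export
fit_separation <- function(table, x_name, y_name, penalty_weight = 1e-4) {
  df <- as.data.frame(table)
  if (!all(c(x_name, y_name) %in% names(df))) {
    stop(sprintf("unknown columns '%s'/'%s'", x_name, y_name))
  }
  y <- as.integer(df$group == "stroke")
  if (length(unique(y)) < 2) {
    stop("degenerate data: both groups must be present")
  }
  xv <- df[[x_name]]
  yv <- df[[y_name]]
  if (any(!is.finite(xv)) || any(!is.finite(yv))) {
    stop("non-finite covariates")
  }
  std <- function(v) {
    s <- stats::sd(v)
    if (s < .Machine$double.eps) list(z = rep(0, length(v)), m = mean(v), s = 0)
    else list(z = (v - mean(v)) / s, m = mean(v), s = s)
  }
  sx <- std(xv)
  sy <- std(yv)
  X <- cbind(1, sx$z, sy$z)
  fit <- .logistic_ridge(X, y, penalty_weight)
  beta <- fit$beta
  prob <- 1 / (1 + exp(-as.numeric(X %*% beta)))
  pred <- prob > 0.5
  mis <- df$id[pred != (y == 1L)]
  # boundary in original units: b0 + b1 (x-mx)/sxv + b2 (y-my)/syv = 0
  cx <- if (sx$s > 0) beta[2] / sx$s else 0
  cy <- if (sy$s > 0) beta[3] / sy$s else 0
  c0 <- beta[1] - cx * sx$m - cy * sy$m
  structure(list(
    x_name = x_name, y_name = y_name,
    coefficients = c(intercept = beta[1], x = beta[2], y = beta[3]),
    penalty_weight = penalty_weight,
    separated = length(mis) == 0,
    misclassified_ids = as.character(mis),
    boundary = c(c0 = c0, cx = cx, cy = cy),
    grad_norm = fit$grad_norm
  ), class = "separation_result")
}

#' Separation matrix over all feature-metric pairs
#'
#' One [fit_separation()] per (hemodynamic median, functional metric)
#' pair, per region. LA metrics: v_max, v_min, sv, ef, bpm; the LAA adds
#' its own volumes plus tortuosity and ostium area.
#'
#' @param table a `cohort_table`.
#' @param region "LA" or "LAA".
#' @param penalty_weight ridge weight passed through.
#' @return logical matrix (rows = hemodynamic medians, columns =
#'   functional metrics) with the per-pair results as attribute `fits`.
#' @export
correlation_matrix <- function(table, region = c("LA", "LAA"),
                               penalty_weight = 1e-4) {
  region <- match.arg(region)
  pre <- if (region == "LA") "la_" else "laa_"
  feat <- paste0(pre, c("fs", "tawss", "osi", "rrt", "ecap",
                        "vort_e", "vort_a", "vort_s"))
  metr <- if (region == "LA") {
    c("v_max", "v_min", "sv", "ef", "bpm")
  } else {
    c("laa_v_max", "laa_v_min", "laa_sv", "laa_ef", "bpm",
      "tortuosity", "ostium_area")
  }
  df <- as.data.frame(table)
  feat <- feat[feat %in% names(df)]
  metr <- metr[metr %in% names(df)]
  out <- matrix(NA, length(feat), length(metr),
                dimnames = list(feat, metr))
  fits <- list()
  for (f in feat) {
    for (m in metr) {
      fit <- fit_separation(table, m, f, penalty_weight)
      out[f, m] <- fit$separated
      fits[[paste(f, m, sep = "|")]] <- fit
    }
  }
  attr(out, "fits") <- fits
  out
}

#' Ratio-normalized feature columns
#'
#' Appends `feature_over_denominator` columns (feature medians divided by
#' one functional metric); rows with a zero denominator are flagged NA.
#'
#' @param table a `cohort_table`.
#' @param denominator_name functional column used as denominator.
#' @param feature_names feature-median columns to normalize (default: all
#'   `la_`/`laa_` medians present).
#' @return the extended `cohort_table`.
#' @export
normalize_features <- function(table, denominator_name,
                               feature_names = NULL) {
  df <- as.data.frame(table)
  if (!denominator_name %in% names(df)) {
    stop(sprintf("unknown denominator '%s'", denominator_name))
  }
  if (is.null(feature_names)) {
    feature_names <- grep("^(la|laa)_(fs|tawss|osi|rrt|ecap|vort_[eas])$",
                          names(df), value = TRUE)
  }
  den <- df[[denominator_name]]
  for (f in feature_names) {
    col <- paste0(f, "_over_", denominator_name)
    df[[col]] <- ifelse(den == 0, NA_real_, df[[f]] / den)
  }
  structure(df, class = c("cohort_table", "data.frame"))
}

#' @export
print.separation_result <- function(x, ...) {
  cat(sprintf(
    "separation %s vs %s: %s (misclassified: %s)\n",
    x$y_name, x$x_name,
    if (x$separated) "SEPARATED" else "not separated",
    if (length(x$misclassified_ids)) {
      paste(x$misclassified_ids, collapse = ", ")
    } else "none"
  ))
  invisible(x)
}
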