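#' Least-squares regression through the origin
#'
#' Fits `y = slope * x` with no intercept: `slope = sum(xy) / sum(x^2)`. The
#' coefficient of determination uses the uncentered total sum of squares,
#' `R^2 = 1 - sum((y - yhat)^2) / sum(y^2)`, the standard definition for
#' no-intercept fits (a centered R^2 can be negative there). The origin
#' constraint is the physically right one for thickness and extent: both must
#' vanish with the hematoma.
#'
#' @param x Measured values.
#' @param y Predicted values (same length).
#' @return A list `(slope, r_squared, n)` of class `rto_fit`.
#' @examples
#' regression_through_origin(1:5, 2 * (1:5))  # slope 2, R^2 = 1
#' @export
regression_through_origin <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 2) stop("need at least 2 complete pairs")
  sxx <- sum(x^2)
  if (sxx == 0) stop("slope through the origin is undefined: all x are zero")
  slope <- sum(x * y) / sxx
  rss <- sum((y - slope * x)^2)
  tss <- sum(y^2)
  r2 <- if (tss == 0) 1 else 1 - rss / tss
  structure(list(slope = slope, r_squared = r2, n = length(x)), class = "rto_fit")
}

#' @export
print.rto_fit <- function(x, ...) {
  cat(sprintf(
    "Regression through the origin: slope = %.4f (R^2 = %.4f), n = %d\n",
    x$slope, x$r_squared, x$n
  ))
  invisible(x)
}

#' Paired comparison of measured and predicted values
#'
#' Two-sided paired t-test on the differences plus the absolute-difference
#' summary (mean, min-max range) used to report agreement. A degenerate pair
#' set (zero variance of differences with a nonzero mean) is flagged rather
#' than producing an infinite statistic.
#'
#' @param x,y Paired vectors of equal length, `n >= 2`.
#' @return A one-row tibble: `n`, `t`, `p_value`, `mean_abs_diff`,
#'   `min_abs_diff`, `max_abs_diff`, `degenerate`.
#' @export
paired_comparison <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 2) stop("need at least 2 complete pairs")
  d <- x - y
  degenerate <- stats::sd(d) == 0
  if (degenerate && all(d == 0)) {
    tt <- list(statistic = 0, p.value = 1)
  } else if (degenerate) {
    tt <- list(statistic = NA_real_, p.value = NA_real_)
  } else {
    tt <- stats::t.test(x, y, paired = TRUE)
  }
  tibble::tibble(
    n = length(x),
    t = unname(tt$statistic),
    p_value = tt$p.value,
    mean_abs_diff = mean(abs(d)),
    min_abs_diff = min(abs(d)),
    max_abs_diff = max(abs(d)),
    degenerate = degenerate
  )
}

#' Validate the geometric model against a measurement table
#'
#' Runs the full validation performed for the model: for each requested
#' latitude model (native, landmark-corrected) the per-case predictions of
#' axial half-thickness `b` and cranial-caudal half-extent `c` are computed
#' from the measured half-length and z-landmarks alone, then compared to the
#' manually measured `b_mm` and `c_mm` by regression through the origin,
#' paired t-tests and absolute differences. Cases with unresolvable
#' geometry are dropped with a count.
#'
#' @param data A measurement table (see [read_measurements()]); phantom
#'   cohorts from [generate_cohort()] work directly.
#' @param r Model sphere radius, mm.
#' @param models Character vector among `"native"`, `"landmark"`.
#' @param landmark_radius Passed to [edh_predict()].
#' @return An `edh_validation` object with [generics::tidy()] and
#'   [generics::glance()] methods; `tidy()` gives one row per target (`b`,
#'   `c`) and model with slope, uncentered R^2, paired-t results and
#'   absolute-difference summaries.
#' @export
edh_validate <- function(data, r = 80, models = c("native", "landmark"),
                         landmark_radius = "model") {
  models <- match.arg(models, c("native", "landmark"), several.ok = TRUE)
  check_measurements(data)
  preds <- purrr::map(models, function(mod) {
    edh_predict(data, r = r, model = mod, landmark_radius = landmark_radius)
  })
  names(preds) <- models
  rows <- purrr::map(models, function(mod) {
    p <- preds[[mod]]
    ok <- is.finite(p$b_pred_mm)
    purrr::map(c(b = "b", c = "c"), function(target) {
      measured <- if (target == "b") p$b_mm[ok] else p$c_mm[ok]
      predicted <- if (target == "b") p$b_pred_mm[ok] else p$c_pred_mm[ok]
      fit <- regression_through_origin(measured, predicted)
      cmp <- paired_comparison(measured, predicted)
      dplyr::bind_cols(
        tibble::tibble(
          target = target, model = mod,
          slope = fit$slope, r_squared = fit$r_squared
        ),
        cmp
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  structure(
    list(
      summary = rows,
      predictions = preds,
      n_input = nrow(data),
      n_dropped = nrow(data) - sum(is.finite(preds[[1]]$b_pred_mm)),
      r = r
    ),
    class = "edh_validation"
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname edh_validate
#' @param x An `edh_validation` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.edh_validation <- function(x, ...) {
  x$summary
}

#' @rdname edh_validate
#' @exportS3Method generics::glance
glance.edh_validation <- function(x, ...) {
  tibble::tibble(
    n_cases = x$n_input,
    n_dropped = x$n_dropped,
    r_mm = x$r,
    min_slope = min(x$summary$slope),
    max_slope = max(x$summary$slope),
    min_r_squared = min(x$summary$r_squared)
  )
}

#' @rdname edh_validate
#' @export
print.edh_validation <- function(x, ...) {
  cat(sprintf(
    "EDH model validation on %d case(s) (%d dropped), r = %g mm\n",
    x$n_input, x$n_dropped, x$r
  ))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf(
      "  %s (%s): slope %.4f (R^2 %.4f); |diff| mean %.2f mm, range %.2f-%.2f mm; paired t p = %.3f\n",
      s$target[i], s$model[i], s$slope[i], s$r_squared[i],
      s$mean_abs_diff[i], s$min_abs_diff[i], s$max_abs_diff[i], s$p_value[i]
    ))
  }
  invisible(x)
}
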