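#' Summarise within-group change
#'
#' Descriptive statistics for the target change within one anchor-change
#' group: sample mean and SD (n - 1 denominator), median (midpoint of the
#' middle two for even n), the t-based 95% confidence interval
#' `mean +/- t(0.975, n-1) * SD / sqrt(n)`, the standardized response mean
#' (SRM = mean change / SD of change, undefined at SD 0 or n 1) and the
#' standardized effect size (SES = mean change / SD of the baseline scores
#' of the full analysis set).
#'
#' @param changes Numeric vector of within-patient changes (n >= 1).
#' @param baseline_sd SD of baseline scores used as the SES denominator
#'   (optional).
#' @param conf_level Confidence level for the interval.
#' @return A one-row tibble: `n`, `mean`, `sd`, `median`, `ci_low`,
#'   `ci_high`, `srm`, `ses`.
#' @export
#' @examples
#' summarize_group(c(-4, -8, -12), baseline_sd = 6.4)
summarize_group <- function(changes, baseline_sd = NULL, conf_level = 0.95) {
  changes <- changes[!is.na(changes)]
  n <- length(changes)
  if (n == 0L) rlang::abort("cannot summarise an empty change vector")
  m <- mean(changes)
  s <- if (n > 1) stats::sd(changes) else NA_real_
  med <- stats::median(changes)
  if (n > 1) {
    half <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1) * s / sqrt(n)
    ci <- c(m - half, m + half)
  } else {
    ci <- c(NA_real_, NA_real_)
  }
  srm <- if (!is.na(s) && s > 0) m / s else NA_real_
  ses <- if (!is.null(baseline_sd) && !is.na(baseline_sd) && baseline_sd > 0) {
    m / baseline_sd
  } else {
    NA_real_
  }
  tibble::tibble(
    n = n, mean = m, sd = s, median = med,
    ci_low = ci[1], ci_high = ci[2], srm = srm, ses = ses
  )
}

#' Summarise every anchor-change group
#'
#' Applies [summarize_group()] to each category of a grouped change table.
#'
#' @param grouped Output of [group_by_anchor_change()].
#' @param baseline_sd SES denominator: SD of the target's baseline scores
#'   over the full analysis set.
#' @inheritParams summarize_group
#' @return A tibble, one row per category, with the group label, size flag
#'   and all [summarize_group()] columns.
#' @export
summarize_groups <- function(grouped, baseline_sd = NULL, conf_level = 0.95) {
  grouped |>
    dplyr::group_by(.data$anchor, .data$category) |>
    dplyr::reframe(
      small_group = .data$small_group[1],
      summarize_group(.data$qlds_change, baseline_sd, conf_level)
    )
}

#' Ordinary least squares of target change on anchor change
#'
#' Fits `target_change ~ anchor_change` by OLS (via [stats::lm()]), keeping
#' the pieces needed for the regression-projection threshold: intercept,
#' slope, their p-values and the complete-case n. Supports [tidy()] and
#' [glance()].
#'
#' @param anchor_changes,target_changes Numeric vectors (pairwise-complete
#'   n >= 3; the anchor must vary).
#' @return An object of class `mct_lm`.
#' @export
#' @examples
#' fit <- fit_change_regression(c(0, 5, 10, 20), c(-8, -9, -10, -13))
#' tidy(fit)
fit_change_regression <- function(anchor_changes, target_changes) {
  stopifnot(length(anchor_changes) == length(target_changes))
  keep <- stats::complete.cases(anchor_changes, target_changes)
  x <- anchor_changes[keep]; y <- target_changes[keep]
  n <- length(x)
  if (n < 3) rlang::abort("regression needs at least 3 complete pairs")
  if (stats::sd(x) == 0) rlang::abort("degenerate design: anchor change has zero variance")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  co <- sm$coefficients
  structure(list(
    intercept = unname(co[1, 1]),
    slope = unname(co[2, 1]),
    se = unname(co[, 2]),
    p_values = c(intercept = unname(co[1, 4]), slope = unname(co[2, 4])),
    n = n,
    r_squared = sm$r.squared,
    sigma = sm$sigma,
    lm = fit
  ), class = "mct_lm")
}

#' @export
print.mct_lm <- function(x, ...) {
  cat(sprintf(
    "OLS of target change on anchor change (n = %d)\n  intercept %.4f (p = %.3g)\n  slope     %.4f (p = %.3g)\n",
    x$n, x$intercept, x$p_values["intercept"], x$slope, x$p_values["slope"]
  ))
  invisible(x)
}

#' @rdname fit_change_regression
#' @param x An `mct_lm` object.
#' @param ... Unused.
#' @method tidy mct_lm
#' @export
tidy.mct_lm <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "anchor_change"),
    estimate = c(x$intercept, x$slope),
    std_error = unname(x$se),
    p_value = unname(x$p_values)
  )
}

#' @rdname fit_change_regression
#' @method glance mct_lm
#' @export
glance.mct_lm <- function(x, ...) {
  tibble::tibble(n = x$n, r_squared = x$r_squared, sigma = x$sigma)
}

# a single threshold candidate with provenance
.mct_candidate <- function(source, value, n = NA_integer_,
                           anchor = NA_character_, criteria = NA_character_) {
  stopifnot(is.finite(value))
  tibble::tibble(
    source = source, anchor = anchor, criteria = criteria,
    value = value, n = as.integer(n)
  )
}

#' Regression-projection threshold candidate
#'
#' Projects the anchor's own external meaningful-change threshold through
#' the fitted regression: `value = intercept + slope * anchor_mct`. Full
#' precision coefficients are always used when a fit is supplied; printed
#' (rounded) coefficients may be supplied directly for worked examples.
#'
#' @param fit An `mct_lm` from [fit_change_regression()], or a numeric
#'   intercept.
#' @param anchor_mct The anchor's external threshold, expressed in the
#'   anchor's improvement direction (e.g. +7 for EQ-VAS).
#' @param slope Required when `fit` is given as a numeric intercept.
#' @param anchor Provenance label.
#' @return A one-row candidate tibble (`source = "regression_projection"`).
#' @export
#' @examples
#' project_regression_mct(-7.84, 7, slope = -0.26)
project_regression_mct <- function(fit, anchor_mct, slope = NULL,
                                   anchor = NA_character_) {
  if (inherits(fit, "mct_lm")) {
    b0 <- fit$intercept; b1 <- fit$slope; n <- fit$n
  } else {
    stopifnot(is.numeric(fit), !is.null(slope))
    b0 <- fit; b1 <- slope; n <- NA_integer_
  }
  .mct_candidate("regression_projection", b0 + b1 * anchor_mct,
                 n = n, anchor = anchor)
}

#' Half-SD distribution-based threshold candidate
#'
#' The distribution-based threshold: one half of the standard deviation of
#' the target change, signed in the improvement direction.
#'
#' @param sd_of_change SD of the target change scores (>= 0).
#' @param improvement_sign -1 when improvement is a decrease (QLDS), +1
#'   otherwise.
#' @param n Number of patients behind the SD (provenance).
#' @return A one-row candidate tibble (`source = "half_sd"`).
#' @export
#' @examples
#' half_sd_mct(11.26)
half_sd_mct <- function(sd_of_change, improvement_sign = -1, n = NA_integer_) {
  stopifnot(sd_of_change >= 0, improvement_sign %in% c(-1, 1))
  .mct_candidate("half_sd", improvement_sign * sd_of_change / 2, n = n,
                 anchor = "distribution")
}

#' Anchor-mean threshold candidate
#'
#' Wraps a one-category (or one-point) improvement group mean as a
#' candidate.
#'
#' @param summary_row A one-row tibble from [summarize_groups()] (the
#'   category-1 row).
#' @param anchor,criteria Provenance labels.
#' @return A one-row candidate tibble (`source = "anchor_mean"`).
#' @export
anchor_mean_mct <- function(summary_row, anchor, criteria = NA_character_) {
  stopifnot(nrow(summary_row) == 1)
  .mct_candidate("anchor_mean", summary_row$mean, n = summary_row$n,
                 anchor = anchor, criteria = criteria)
}

#' Triangulate candidate thresholds into a recommendation
#'
#' Pools threshold candidates from the anchor-based and distribution-based
#' routes: reports their mean, median (midpoint of the central two for even
#' counts) and range, and recommends an integer threshold equal to the
#' median's magnitude rounded half-away-from-zero, reported with the
#' improvement sign.
#'
#' @param candidates A candidate tibble (rows from [anchor_mean_mct()],
#'   [project_regression_mct()], [half_sd_mct()]), or a bare numeric vector
#'   of candidate values.
#' @param include Optional predicate (function of the candidate tibble
#'   returning a logical vector) filtering which candidates enter the pool.
#' @return An object of class `mct_triangulation` with elements
#'   `candidates`, `mean`, `median`, `range`, `recommended`. Supports
#'   [tidy()] and [glance()].
#' @export
#' @examples
#' triangulate(c(-8.22, -8.30, -8.20, -9.69))
triangulate <- function(candidates, include = NULL) {
  if (is.numeric(candidates)) {
    candidates <- tibble::tibble(
      source = "candidate", anchor = NA_character_, criteria = NA_character_,
      value = as.numeric(candidates), n = NA_integer_
    )
  }
  stopifnot(is.data.frame(candidates), "value" %in% names(candidates))
  if (!is.null(include)) candidates <- candidates[include(candidates), , drop = FALSE]
  v <- candidates$value
  if (!length(v)) rlang::abort("no candidates left to triangulate")
  med <- stats::median(v)
  sign_dir <- if (med < 0) -1 else 1
  rec <- as.integer(floor(abs(med) + 0.5))  # half-away-from-zero on |median|
  structure(list(
    candidates = tibble::as_tibble(candidates),
    mean = mean(v),
    median = med,
    range = c(min(v), max(v)),
    recommended = sign_dir * rec
  ), class = "mct_triangulation")
}

#' @export
print.mct_triangulation <- function(x, ...) {
  cat(sprintf(
    "Triangulation of %d candidate threshold(s)\n  mean %.3f, median %.3f, range [%.3f, %.3f]\n  recommended integer MCT: %d-point %s\n",
    nrow(x$candidates), x$mean, x$median, x$range[1], x$range[2],
    abs(x$recommended), if (x$recommended < 0) "improvement (decrease)" else "improvement (increase)"
  ))
  invisible(x)
}

#' @rdname triangulate
#' @param x An `mct_triangulation` object.
#' @param ... Unused.
#' @method tidy mct_triangulation
#' @export
tidy.mct_triangulation <- function(x, ...) {
  x$candidates
}

#' @rdname triangulate
#' @method glance mct_triangulation
#' @export
glance.mct_triangulation <- function(x, ...) {
  tibble::tibble(
    n_candidates = nrow(x$candidates),
    mean = x$mean, median = x$median,
    min = x$range[1], max = x$range[2],
    recommended = x$recommended
  )
}
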