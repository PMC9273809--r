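#' Compute within-patient change scores
#'
#' Joins each patient's baseline and endpoint rows and derives, per
#' instrument, the signed raw change (endpoint minus baseline: negative
#' QLDS/MADRS change is improvement, positive EQ-VAS change is improvement)
#' together with the improvement-signed anchor keys used for grouping:
#' MADRS severity-category change (baseline severity index minus endpoint
#' index, under each of the three criteria) and CGI point change (baseline
#' minus endpoint). A change is present only when both visits carry the
#' relevant score (complete case per instrument); patients lacking either
#' visit row entirely are dropped and counted in the `dropped` attribute.
#'
#' @param data A visit-record tibble (see [read_visit_csv()] for the
#'   schema), or the baseline records if `endpoint_data` is supplied.
#' @param endpoint_data Optional separate endpoint records.
#' @param baseline,endpoint Visit labels identifying the two visits.
#' @param criteria Character vector of MADRS severity criteria to band by.
#' @return A tibble, one row per patient present at both visits, with
#'   columns `patient_id`, `arm`, per-instrument `<instrument>_baseline`
#'   and `<instrument>_change`, `madrs_cat_change_<criteria>` and
#'   `cgi_*_point_change`. Attribute `dropped` is a tibble counting
#'   patients excluded for a missing visit row.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 20), seed = 2)
#' changes <- compute_changes(cohort)
#' dplyr::glimpse(changes)
compute_changes <- function(data, endpoint_data = NULL,
                            baseline = "baseline", endpoint = "endpoint",
                            criteria = c("criteria_1", "criteria_2", "criteria_3")) {
  if (!is.null(endpoint_data)) {
    data <- dplyr::bind_rows(
      dplyr::mutate(data, visit = baseline),
      dplyr::mutate(endpoint_data, visit = endpoint)
    )
  }
  stopifnot(is.data.frame(data), all(c("patient_id", "visit") %in% names(data)))
  dup <- data |>
    dplyr::filter(.data$visit %in% c(baseline, endpoint)) |>
    dplyr::count(.data$patient_id, .data$visit) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    rlang::abort(c(
      "duplicate (patient, visit) rows:",
      sprintf("%s / %s (%d rows)", dup$patient_id, dup$visit, dup$n)
    ))
  }
  instruments <- intersect(instrument_ranges()$instrument, names(data))
  b <- dplyr::filter(data, .data$visit == baseline)
  e <- dplyr::filter(data, .data$visit == endpoint)
  merged <- dplyr::inner_join(b, e, by = "patient_id", suffix = c("_baseline", "_endpoint"))

  n_b_only <- sum(!b$patient_id %in% e$patient_id)
  n_e_only <- sum(!e$patient_id %in% b$patient_id)
  dropped <- tibble::tibble(
    reason = c("missing endpoint row", "missing baseline row"),
    n = c(n_b_only, n_e_only)
  )

  out <- tibble::tibble(patient_id = merged$patient_id)
  if ("arm_baseline" %in% names(merged)) out$arm <- merged$arm_baseline
  for (ins in instruments) {
    bb <- merged[[paste0(ins, "_baseline")]]
    ee <- merged[[paste0(ins, "_endpoint")]]
    out[[paste0(ins, "_baseline")]] <- bb
    out[[paste0(ins, "_change")]] <- ee - bb
  }
  if ("madrs_total" %in% instruments) {
    for (cr in criteria) {
      bands <- severity_criteria(cr)
      bsev <- categorize_madrs(merged$madrs_total_baseline, bands)$severity
      esev <- categorize_madrs(merged$madrs_total_endpoint, bands)$severity
      out[[paste0("madrs_cat_change_", cr)]] <- bsev - esev
    }
  }
  for (cg in intersect(c("cgi_ss_r", "cgi_sr_i"), instruments)) {
    out[[paste0(cg, "_point_change")]] <-
      merged[[paste0(cg, "_baseline")]] - merged[[paste0(cg, "_endpoint")]]
  }
  attr(out, "dropped") <- dropped
  out
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Computes Spearman's rho on average (mid) ranks after pairwise-complete
#' filtering, with the p-value from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#' An exact permutation p-value (full enumeration of all `n!` rank
#' orderings) is available for `n <= 8`.
#'
#' @param x,y Numeric vectors of equal length.
#' @param method `"t"` (default) or `"permutation"`.
#' @return A one-row tibble with `rho`, `p_value`, `n`.
#' @export
#' @examples
#' spearman_rho(1:10, (1:10)^3)
spearman_rho <- function(x, y, method = c("t", "permutation")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) rlang::abort("spearman_rho needs at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    rlang::abort("correlation undefined: zero variance in x or y")
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (method == "t") {
    if (abs(rho) >= 1 - 1e-15) {
      p <- 0
    } else {
      tval <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tval), df = n - 2)
    }
  } else {
    if (n > 8) rlang::abort("exact permutation p-value only for n <= 8")
    perms <- .permutations(n)
    stat <- abs(apply(perms, 1, function(pp) stats::cor(rx, ry[pp])))
    p <- mean(stat >= abs(rho) - 1e-12)
  }
  tibble::tibble(rho = rho, p_value = p, n = n)
}

# all permutations of 1..n as a matrix (n! rows); fine for n <= 8
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Describe an anchor
#'
#' An anchor is an external criterion whose categorical change defines
#' "meaningfully changed" groups for calibrating QLDS change. Three kinds
#' are supported: `severity_categorical` (MADRS banded by a severity
#' criteria scheme), `ordinal_point` (CGI scales, 1-point steps), and
#' `continuous` (EQ-VAS, which contributes through a regression projection
#' at its own published meaningful-change threshold rather than through
#' grouping).
#'
#' @param instrument One of the instruments of [instrument_ranges()]
#'   (except `qlds_total`, the target).
#' @param anchor_type `"severity_categorical"`, `"ordinal_point"` or
#'   `"continuous"`.
#' @param criteria Severity criteria name, required for
#'   `severity_categorical`.
#' @param threshold Qualification threshold on `|rho|` (default 0.40).
#' @param anchor_mct The anchor's own external meaningful-change threshold,
#'   required for (and only for) `continuous` anchors; e.g. 7 points for
#'   EQ-VAS.
#' @return A list of class `anchor_spec`.
#' @export
anchor_spec <- function(instrument,
                        anchor_type = c("severity_categorical", "ordinal_point",
                                        "continuous"),
                        criteria = NULL, threshold = 0.40, anchor_mct = NULL) {
  anchor_type <- match.arg(anchor_type)
  stopifnot(instrument %in% instrument_ranges()$instrument, instrument != "qlds_total")
  if (threshold <= 0) rlang::abort("qualification threshold must be > 0")
  if (anchor_type == "severity_categorical" && is.null(criteria)) {
    rlang::abort("severity_categorical anchors need a criteria name")
  }
  if (anchor_type == "continuous" && is.null(anchor_mct)) {
    rlang::abort("continuous anchors need their own external anchor_mct")
  }
  if (anchor_type != "continuous" && !is.null(anchor_mct)) {
    rlang::abort("anchor_mct is only meaningful for continuous anchors")
  }
  structure(list(
    instrument = instrument, anchor_type = anchor_type, criteria = criteria,
    threshold = threshold, anchor_mct = anchor_mct
  ), class = "anchor_spec")
}

#' The default anchor set
#'
#' MADRS severity-category change under each of the three criteria (primary
#' anchor), the two CGI global impressions as 1-point ordinal anchors, and
#' EQ-VAS as a continuous anchor with its published 7-point individual
#' meaningful-change threshold.
#'
#' @param threshold Qualification threshold on `|rho|`.
#' @param eq_vas_mct EQ-VAS external meaningful-change threshold (points of
#'   improvement).
#' @return A list of [anchor_spec()] objects.
#' @export
default_anchor_specs <- function(threshold = 0.40, eq_vas_mct = 7) {
  c(
    lapply(c("criteria_1", "criteria_2", "criteria_3"), function(cr) {
      anchor_spec("madrs_total", "severity_categorical", criteria = cr,
                  threshold = threshold)
    }),
    list(
      anchor_spec("cgi_ss_r", "ordinal_point", threshold = threshold),
      anchor_spec("cgi_sr_i", "ordinal_point", threshold = threshold),
      anchor_spec("eq_vas", "continuous", threshold = threshold,
                  anchor_mct = eq_vas_mct)
    )
  )
}

# label like "madrs_total (criteria_1)" / "eq_vas"
.anchor_label <- function(spec) {
  if (is.null(spec$criteria)) spec$instrument
  else paste0(spec$instrument, " (", spec$criteria, ")")
}

# column of `changes` holding the grouping key for a categorical/ordinal anchor
.anchor_group_col <- function(spec) {
  switch(spec$anchor_type,
    severity_categorical = paste0("madrs_cat_change_", spec$criteria),
    ordinal_point = paste0(spec$instrument, "_point_change"),
    rlang::abort("continuous anchors are not grouped")
  )
}

#' Qualify a single anchor from its observed correlation
#'
#' An anchor qualifies when the magnitude of its Spearman correlation with
#' the target change reaches the threshold; the sign only encodes the
#' instruments' scoring directions (e.g. EQ-VAS qualifies at rho = -0.53).
#'
#' @param rho Observed Spearman correlation, in `[-1, 1]`.
#' @param spec An [anchor_spec()].
#' @return A one-row tibble: `anchor`, `instrument`, `criteria`, `rho`,
#'   `threshold`, `qualified`.
#' @export
#' @examples
#' qualify_anchor(-0.53, anchor_spec("eq_vas", "continuous", anchor_mct = 7))
qualify_anchor <- function(rho, spec) {
  stopifnot(inherits(spec, "anchor_spec"), rho >= -1, rho <= 1)
  tibble::tibble(
    anchor = .anchor_label(spec),
    instrument = spec$instrument,
    criteria = spec$criteria %||% NA_character_,
    rho = rho,
    threshold = spec$threshold,
    qualified = abs(rho) >= spec$threshold
  )
}

#' Qualify all anchors against observed change scores
#'
#' For every anchor, computes the Spearman correlation between the QLDS raw
#' change and the anchor instrument's raw change (endpoint minus baseline,
#' pairwise-complete per anchor) and applies the `|rho| >=` threshold rule.
#'
#' @param changes A change table from [compute_changes()].
#' @param specs A list of [anchor_spec()]s.
#' @return A tibble with one row per anchor: `anchor`, `instrument`,
#'   `criteria`, `rho`, `p_value`, `n`, `threshold`, `qualified`.
#' @export
qualify_anchors <- function(changes, specs = default_anchor_specs()) {
  purrr::map_dfr(specs, function(spec) {
    x <- changes[[paste0(spec$instrument, "_change")]]
    y <- changes$qlds_total_change
    ct <- spearman_rho(x, y)
    out <- qualify_anchor(ct$rho, spec)
    out$p_value <- ct$p_value
    out$n <- ct$n
    dplyr::relocate(out, "p_value", "n", .after = "rho")
  })
}

#' Group target changes by anchor-change category
#'
#' Splits the QLDS change scores into groups keyed by the exact integer
#' anchor change (positive = improvement: +1 is "improved one category /
#' point"). Grouping is complete-case for the (anchor, target) pair. Groups
#' with fewer than `min_n` patients are flagged, echoing the caution that
#' small anchor groups make the group mean unstable.
#'
#' @param changes A change table from [compute_changes()].
#' @param spec A categorical or ordinal [anchor_spec()].
#' @param min_n Flag groups smaller than this (default 25).
#' @param cumulative If `TRUE`, improvement groups are cumulative
#'   ("improved by at least k") instead of exact ("improved exactly k").
#'   Default exact, matching per-group means reporting.
#' @param force Proceed even though the anchor was not shown to qualify
#'   (grouping itself never checks rho; set `force = FALSE` to require a
#'   `qualified` attribute set by the pipeline).
#' @return A tibble with columns `anchor`, `category`, `patient_id`,
#'   `qlds_change`, `small_group`; one row per patient per group.
#' @export
group_by_anchor_change <- function(changes, spec, min_n = 25,
                                   cumulative = FALSE, force = TRUE) {
  stopifnot(inherits(spec, "anchor_spec"))
  if (nrow(changes) == 0L) rlang::abort("empty change table")
  col <- .anchor_group_col(spec)
  if (!col %in% names(changes)) {
    rlang::abort(paste0("change table lacks anchor column ", col))
  }
  keep <- !is.na(changes[[col]]) & !is.na(changes$qlds_total_change)
  df <- tibble::tibble(
    anchor = .anchor_label(spec),
    category = as.integer(changes[[col]][keep]),
    patient_id = changes$patient_id[keep],
    qlds_change = changes$qlds_total_change[keep]
  )
  if (nrow(df) == 0L) rlang::abort("no complete (anchor, target) pairs to group")
  if (cumulative) {
    pos <- sort(unique(df$category[df$category > 0]))
    cum <- purrr::map_dfr(pos, function(k) {
      dplyr::mutate(dplyr::filter(df, .data$category >= k), category = k)
    })
    df <- dplyr::bind_rows(dplyr::filter(df, .data$category <= 0), cum)
  }
  df <- df |>
    dplyr::group_by(.data$category) |>
    dplyr::mutate(small_group = dplyr::n() < min_n) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$category, .data$patient_id)
  df
}
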