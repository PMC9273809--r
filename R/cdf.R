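#' Empirical CDF step points of a change vector
#'
#' The right-continuous empirical distribution function as a table of step
#' points: one row per distinct value, with the cumulative proportion of
#' observations at or below it. Duplicated values collapse into one step of
#' combined mass; the last proportion is exactly 1.
#'
#' @param changes Numeric vector (n >= 1 after dropping `NA`).
#' @param group Optional group label stored alongside the steps.
#' @return A tibble with columns `group`, `value`, `proportion`, `n`.
#' @export
#' @examples
#' empirical_cdf(c(-10, -5, -5, 0))
empirical_cdf <- function(changes, group = NA_character_) {
  changes <- changes[!is.na(changes)]
  n <- length(changes)
  if (n == 0L) rlang::abort("cannot build an ECDF from an empty vector")
  v <- sort(unique(changes))
  counts <- tabulate(match(changes, v), nbins = length(v))
  tibble::tibble(
    group = group,
    value = v,
    proportion = cumsum(counts) / n,
    n = n
  )
}

# two-sample KS distance: max over pooled values of |F1 - F2|
.ks_distance <- function(a, b) {
  a <- sort(a[!is.na(a)]); b <- sort(b[!is.na(b)])
  stopifnot(length(a) > 0, length(b) > 0)
  pooled <- sort(unique(c(a, b)))
  Fa <- findInterval(pooled, a) / length(a)
  Fb <- findInterval(pooled, b) / length(b)
  max(abs(Fa - Fb))
}

#' Stratified ECDF curves with separation diagnostics
#'
#' Builds one empirical CDF per anchor-change category and quantifies the
#' visual "separation" between adjacent categories with the two-sample
#' Kolmogorov–Smirnov distance (the maximum vertical gap between the two
#' step curves). The KS summary is this package's operationalisation of
#' curve separation; identical groups give 0, groups with disjoint supports
#' give 1.
#'
#' @param grouped Output of [group_by_anchor_change()] (needs >= 2
#'   non-empty categories).
#' @return A list with `curves` (stacked [empirical_cdf()] tables keyed by
#'   `category`) and `separation` (tibble of adjacent category pairs with
#'   `ks_distance` and the two group sizes).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 120), seed = 5)
#' ch <- compute_changes(cohort)
#' g <- group_by_anchor_change(ch, default_anchor_specs()[[1]])
#' stratified_cdfs(g)$separation
stratified_cdfs <- function(grouped) {
  cats <- sort(unique(grouped$category))
  if (length(cats) < 2) rlang::abort("need at least 2 non-empty categories")
  by_cat <- split(grouped$qlds_change, grouped$category)
  curves <- purrr::map_dfr(names(by_cat), function(k) {
    cv <- empirical_cdf(by_cat[[k]], group = k)
    cv$category <- as.integer(k)
    dplyr::relocate(cv, "category")
  })
  pairs <- tibble::tibble(cat_a = cats[-length(cats)], cat_b = cats[-1])
  separation <- pairs |>
    dplyr::mutate(
      n_a = vapply(.data$cat_a, function(k) length(by_cat[[as.character(k)]]), integer(1)),
      n_b = vapply(.data$cat_b, function(k) length(by_cat[[as.character(k)]]), integer(1)),
      ks_distance = purrr::map2_dbl(.data$cat_a, .data$cat_b, function(i, j) {
        .ks_distance(by_cat[[as.character(i)]], by_cat[[as.character(j)]])
      })
    )
  list(curves = dplyr::select(curves, -"group"), separation = separation)
}
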