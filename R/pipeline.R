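#' Run the full threshold-estimation pipeline
#'
#' Executes the complete analysis on a two-visit visit-record table:
#' validate records, compute change scores, qualify anchors by Spearman
#' correlation magnitude, summarise target change within every
#' anchor-change group, fit the continuous-anchor regression and project
#' its external threshold, add the half-SD distribution candidate, and
#' triangulate the default candidate set (one-category / one-point
#' improvement mean of every qualified categorical anchor, regression
#' projection of every qualified continuous anchor, and the half-SD value)
#' into a recommended integer threshold. Stratified ECDF curves with
#' adjacent-category KS separation are produced for every categorical
#' anchor. If no anchor qualifies the pipeline completes with a warning and
#' a half-SD-only candidate set.
#'
#' @param data A visit-record tibble or a path to a visit CSV.
#' @param specs Anchors to evaluate, as a list of [anchor_spec()]s.
#' @param min_n Small-group flag threshold for [group_by_anchor_change()].
#' @param conf_level Confidence level for group summaries.
#' @param include_half_sd Include the distribution-based candidate?
#' @param seed Recorded in the run log (the analysis itself is
#'   deterministic).
#' @return An object of class `mct_report`: a list with `qualification`,
#'   `group_summaries`, `regressions` (list of `mct_lm`), `candidates`,
#'   `triangulation`, `cdf` (per categorical anchor: curves + separation),
#'   `log`.
#' @export
#' @examples
#' report <- run_pipeline(generate_cohort(cohort_config(n_patients = 150), seed = 9))
#' report$triangulation
run_pipeline <- function(data, specs = default_anchor_specs(), min_n = 25,
                         conf_level = 0.95, include_half_sd = TRUE, seed = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
    })
  }
  warnings_log <- character()
  note <- function(msg) {
    warnings_log <<- c(warnings_log, msg)
    rlang::warn(msg)
  }

  if (is.character(data)) data <- stage("read", read_visit_csv(data))
  stage("validate", validate_visit_records(data))
  changes <- stage("changes", compute_changes(data))
  dropped <- attr(changes, "dropped")

  qualification <- stage("qualify", qualify_anchors(changes, specs))
  if (!any(qualification$qualified)) {
    note("no anchor reached the correlation threshold; candidate set is distribution-based only")
  }

  baseline_sd <- stats::sd(changes$qlds_total_baseline, na.rm = TRUE)
  group_summaries <- list(); cdf <- list(); regressions <- list()
  candidates <- list()

  for (spec in specs) {
    lab <- .anchor_label(spec)
    qrow <- qualification[qualification$anchor == lab, ]
    if (spec$anchor_type == "continuous") {
      if (!qrow$qualified) next
      fit <- stage(paste0("regression ", lab), {
        fit_change_regression(
          changes[[paste0(spec$instrument, "_change")]],
          changes$qlds_total_change
        )
      })
      regressions[[lab]] <- fit
      candidates[[paste0(lab, "_projection")]] <-
        project_regression_mct(fit, spec$anchor_mct, anchor = lab)
    } else {
      grouped <- stage(paste0("group ", lab), {
        group_by_anchor_change(changes, spec, min_n = min_n)
      })
      gs <- stage(paste0("summarise ", lab), {
        summarize_groups(grouped, baseline_sd = baseline_sd, conf_level = conf_level)
      })
      group_summaries[[lab]] <- gs
      if (length(unique(grouped$category)) >= 2) {
        cdf[[lab]] <- stage(paste0("cdf ", lab), stratified_cdfs(grouped))
      }
      if (qrow$qualified) {
        one <- gs[gs$category == 1L, ]
        if (nrow(one) == 1) {
          if (one$small_group) {
            note(paste0("one-category improvement group for ", lab,
                        " has n = ", one$n, " < ", min_n))
          }
          candidates[[paste0(lab, "_mean")]] <-
            anchor_mean_mct(one, anchor = lab,
                            criteria = spec$criteria %||% NA_character_)
        } else {
          note(paste0("no one-category improvement group for ", lab,
                      "; anchor contributes no mean candidate"))
        }
      }
    }
  }

  if (include_half_sd) {
    sd_change <- stats::sd(changes$qlds_total_change, na.rm = TRUE)
    candidates[["half_sd"]] <- half_sd_mct(
      sd_change, improvement_sign = -1,
      n = sum(!is.na(changes$qlds_total_change))
    )
  }
  candidates <- dplyr::bind_rows(candidates)
  triangulation <- stage("triangulate", triangulate(candidates))

  structure(list(
    qualification = qualification,
    group_summaries = dplyr::bind_rows(group_summaries),
    regressions = regressions,
    candidates = candidates,
    triangulation = triangulation,
    cdf = cdf,
    log = list(
      n_input_rows = nrow(data),
      n_patients_analyzed = nrow(changes),
      dropped = dropped,
      baseline_sd = baseline_sd,
      seed = seed,
      warnings = warnings_log,
      package_version = as.character(utils::packageVersion("qldsmct"))
    )
  ), class = "mct_report")
}

#' @export
print.mct_report <- function(x, ...) {
  cat("Meaningful change threshold report\n")
  cat(sprintf("  %d patients analysed (%d input rows)\n",
              x$log$n_patients_analyzed, x$log$n_input_rows))
  cat(sprintf("  anchors qualified: %d of %d\n",
              sum(x$qualification$qualified), nrow(x$qualification)))
  print(x$triangulation)
  invisible(x)
}

#' Write a report bundle to disk
#'
#' Writes `qualification.csv`, `group_summaries.csv`, `mct_candidates.csv`,
#' `cdf_curves.csv`, `cdf_separation.csv`, `triangulation.json` and
#' `run_log.json` under `dir`. All outputs are plain text and fully
#' determined by the report object, so identical inputs reproduce
#' byte-identical files.
#'
#' @param report An `mct_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "mct_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  wr <- function(df, name) {
    p <- file.path(dir, name)
    readr::write_csv(df, p, na = "")
    paths <<- c(paths, p)
  }
  wr(report$qualification, "qualification.csv")
  wr(report$group_summaries, "group_summaries.csv")
  wr(report$candidates, "mct_candidates.csv")
  if (length(report$cdf)) {
    curves <- purrr::imap_dfr(report$cdf, function(x, nm) {
      dplyr::mutate(x$curves, anchor = nm, .before = 1)
    })
    sep <- purrr::imap_dfr(report$cdf, function(x, nm) {
      dplyr::mutate(x$separation, anchor = nm, .before = 1)
    })
    wr(curves, "cdf_curves.csv")
    wr(sep, "cdf_separation.csv")
  }
  tri <- report$triangulation
  p <- file.path(dir, "triangulation.json")
  jsonlite::write_json(list(
    mean = tri$mean, median = tri$median,
    min = tri$range[1], max = tri$range[2],
    recommended = tri$recommended,
    candidates = tri$candidates
  ), p, auto_unbox = TRUE, digits = NA, na = "null")
  paths <- c(paths, p)
  p <- file.path(dir, "run_log.json")
  jsonlite::write_json(report$log, p, auto_unbox = TRUE, digits = NA, na = "null")
  paths <- c(paths, p)
  invisible(paths)
}
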