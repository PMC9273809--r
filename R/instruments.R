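#' Instrument score ranges
#'
#' The five instruments handled by the package, with their integer score
#' ranges and the direction that corresponds to clinical improvement.
#'
#' * **QLDS** — Quality of Life in Depression Scale; 34 binary items, total
#'   0 (good quality of life) to 34 (very poor). Improvement = decrease.
#' * **MADRS** — Montgomery–Åsberg Depression Rating Scale; 10 clinician
#'   items scored 0–6, total 0–60. Improvement = decrease.
#' * **CGI-SS-r** — Clinical Global Impression of Severity of Suicidality
#'   (revised); single 7-point rating 0–6. Improvement = decrease.
#' * **CGI-SR-I** — Clinical Global Impression of Imminent Suicide Risk;
#'   single 7-point rating 0–6. Improvement = decrease.
#' * **EQ-VAS** — EuroQol visual analogue health rating, 0 (worst health)
#'   to 100 (best). Improvement = increase.
#'
#' @return A tibble with columns `instrument`, `min`, `max`,
#'   `improvement_sign` (-1 if lower scores are better, +1 if higher).
#' @export
#' @examples
#' instrument_ranges()
instrument_ranges <- function() {
  tibble::tibble(
    instrument = c("qlds_total", "madrs_total", "cgi_ss_r", "cgi_sr_i", "eq_vas"),
    min = c(0L, 0L, 0L, 0L, 0L),
    max = c(34L, 60L, 6L, 6L, 100L),
    improvement_sign = c(-1, -1, -1, -1, 1)
  )
}

# internal lookup used by validators and the simulator
.range_of <- function(instrument) {
  r <- instrument_ranges()
  i <- match(instrument, r$instrument)
  if (anyNA(i)) rlang::abort(paste0("unknown instrument: ", instrument))
  list(min = r$min[i], max = r$max[i])
}

#' Score the QLDS from its 34 binary items
#'
#' The QLDS total is the count of "true" responses over its 34 items, so the
#' score runs from 0 (good quality of life) to 34 (very poor quality of
#' life). Items may be given as logicals, as 0/1 integers, or as the strings
#' `"true"` / `"not true"` (case-insensitive).
#'
#' @param items A vector of exactly 34 binary item responses, or a data
#'   frame / matrix with 34 columns (one row per respondent).
#' @return An integer total per respondent (a scalar for a single vector of
#'   items).
#' @export
#' @examples
#' score_qlds(rep(0, 34))
#' score_qlds(c(rep("true", 12), rep("not true", 22)))
score_qlds <- function(items) {
  if (is.data.frame(items) || is.matrix(items)) {
    m <- as.matrix(items)
    if (ncol(m) != 34L) {
      rlang::abort(paste0("QLDS needs exactly 34 items, got ", ncol(m), " columns"))
    }
    return(vapply(seq_len(nrow(m)), function(i) score_qlds(m[i, ]), integer(1)))
  }
  if (length(items) != 34L) {
    rlang::abort(paste0("QLDS needs exactly 34 items, got ", length(items)))
  }
  vals <- .as_binary_item(items)
  bad <- which(is.na(vals))
  if (length(bad)) {
    rlang::abort(paste0(
      "non-binary or missing QLDS item response at item ",
      paste(bad, collapse = ", "),
      " (expected true/not true, 0/1, or TRUE/FALSE)"
    ))
  }
  as.integer(sum(vals))
}

.as_binary_item <- function(x) {
  if (is.logical(x)) return(as.integer(x))
  if (is.numeric(x)) {
    out <- as.integer(x)
    out[!(x %in% c(0, 1))] <- NA_integer_
    return(out)
  }
  lx <- tolower(trimws(as.character(x)))
  out <- rep(NA_integer_, length(x))
  out[lx %in% c("true", "t", "1", "yes")] <- 1L
  out[lx %in% c("not true", "not_true", "false", "f", "0", "no")] <- 0L
  out
}

#' MADRS severity criteria
#'
#' Three published cut-off schemes that band the MADRS total (0–60) into four
#' ordered depression severity levels. There is no consensus banding in the
#' literature, so analyses are run under all three and compared:
#'
#' * `criteria_1`: none 0–12, slight 13–21, moderate 22–28, severe 29–60
#' * `criteria_2`: none 0–6, slight 7–19, moderate 20–34, severe 35–60
#' * `criteria_3`: none 0–12, slight 13–17, moderate 18–34, severe 35–60
#'
#' Bands are closed integer intervals (the MADRS total is integer-valued, so
#' "> 28–60" is stored as 29–60). Each band carries an ordinal `severity`
#' index: 0 = no depression up to 3 = severe depression; the index is fixed
#' while the label text may be customised via `labels`.
#'
#' @param name One of `"criteria_1"`, `"criteria_2"`, `"criteria_3"`.
#' @param labels Optional character vector of 4 band labels (mildest first).
#' @return A tibble with columns `criteria`, `label`, `severity`, `lower`,
#'   `upper`, one row per band in increasing severity order.
#' @export
#' @examples
#' severity_criteria("criteria_1")
severity_criteria <- function(name = c("criteria_1", "criteria_2", "criteria_3"),
                              labels = NULL) {
  name <- match.arg(name)
  cuts <- switch(name,
    criteria_1 = list(lower = c(0L, 13L, 22L, 29L), upper = c(12L, 21L, 28L, 60L)),
    criteria_2 = list(lower = c(0L, 7L, 20L, 35L), upper = c(6L, 19L, 34L, 60L)),
    criteria_3 = list(lower = c(0L, 13L, 18L, 35L), upper = c(12L, 17L, 34L, 60L))
  )
  labels <- labels %||%
    c("no depression", "slight depression", "moderate depression", "severe depression")
  stopifnot(length(labels) == 4L)
  out <- tibble::tibble(
    criteria = name,
    label = labels,
    severity = 0:3,
    lower = cuts$lower,
    upper = cuts$upper
  )
  .validate_criteria(out)
  out
}

#' All three MADRS severity criteria stacked in one table
#'
#' @inheritParams severity_criteria
#' @return A tibble of 12 bands (3 criteria x 4 levels).
#' @export
all_severity_criteria <- function(labels = NULL) {
  dplyr::bind_rows(lapply(
    c("criteria_1", "criteria_2", "criteria_3"),
    severity_criteria,
    labels = labels
  ))
}

# a criteria table must partition 0..60 with strictly increasing severity
.validate_criteria <- function(bands) {
  stopifnot(all(c("label", "severity", "lower", "upper") %in% names(bands)))
  o <- order(bands$lower)
  b <- bands[o, ]
  if (b$lower[1] != 0L || b$upper[nrow(b)] != 60L) {
    rlang::abort("severity bands must start at 0 and end at 60")
  }
  if (nrow(b) > 1 && any(b$lower[-1] != b$upper[-nrow(b)] + 1L)) {
    rlang::abort("severity bands must be contiguous and non-overlapping over 0-60")
  }
  if (any(b$lower > b$upper)) rlang::abort("severity band with lower > upper")
  if (any(diff(b$severity) <= 0)) {
    rlang::abort("severity index must strictly increase with band order")
  }
  invisible(bands)
}

#' Map MADRS totals to severity bands
#'
#' Assigns each MADRS total score to its unique severity band under the given
#' cut-off scheme.
#'
#' @param score Integer vector of MADRS totals (0–60); `NA` allowed and
#'   propagated.
#' @param criteria A criteria name (`"criteria_1"`, `"criteria_2"`,
#'   `"criteria_3"`) or a bands tibble as returned by [severity_criteria()].
#' @return A tibble with columns `score`, `label`, `severity` (ordinal index
#'   0 = no depression ... 3 = severe).
#' @export
#' @examples
#' categorize_madrs(c(41, 17, 0))
categorize_madrs <- function(score, criteria = "criteria_1") {
  bands <- if (is.character(criteria)) severity_criteria(criteria) else {
    .validate_criteria(criteria)
    tibble::as_tibble(criteria)
  }
  ok <- is.na(score) | (score >= 0 & score <= 60 & score == round(score))
  if (!all(ok)) {
    rlang::abort(paste0(
      "MADRS score out of range 0-60 (or non-integer): ",
      paste(utils::head(score[!ok], 5), collapse = ", ")
    ))
  }
  idx <- vapply(score, function(s) {
    if (is.na(s)) return(NA_integer_)
    which(s >= bands$lower & s <= bands$upper)
  }, integer(1))
  tibble::tibble(
    score = score,
    label = bands$label[idx],
    severity = bands$severity[idx]
  )
}

# vector severity index, used heavily by change construction
.madrs_severity <- function(score, bands) {
  findInterval(score, c(bands$lower, 61L), rightmost.closed = FALSE) - 1L
}

#' Check visit records against instrument ranges
#'
#' Scans a visit-record table and reports every out-of-range score and every
#' duplicated (patient, visit) pair without stopping at the first problem.
#' Missing scores are allowed: completeness is resolved per analysis
#' downstream (complete-case), never by imputation here.
#'
#' @param data A data frame with columns `patient_id`, `visit`, and any of
#'   `qlds_total`, `madrs_total`, `cgi_ss_r`, `cgi_sr_i`, `eq_vas` (extra
#'   columns such as `arm` are ignored).
#' @return A tibble of problems with columns `row`, `patient_id`, `field`,
#'   `value`, `allowed`, `problem`; zero rows when the table is clean.
#' @seealso [validate_visit_records()] which errors on any problem.
#' @export
check_visit_records <- function(data) {
  stopifnot(is.data.frame(data))
  need <- c("patient_id", "visit")
  if (!all(need %in% names(data))) {
    rlang::abort(paste0(
      "visit records need columns: ", paste(setdiff(need, names(data)), collapse = ", ")
    ))
  }
  ranges <- instrument_ranges()
  probs <- list()
  for (k in seq_len(nrow(ranges))) {
    f <- ranges$instrument[k]
    if (!f %in% names(data)) next
    v <- data[[f]]
    bad <- which(!is.na(v) & (v < ranges$min[k] | v > ranges$max[k] | v != round(v)))
    if (length(bad)) {
      probs[[f]] <- tibble::tibble(
        row = bad,
        patient_id = as.character(data$patient_id[bad]),
        field = f,
        value = as.numeric(v[bad]),
        allowed = sprintf("integer %d-%d", ranges$min[k], ranges$max[k]),
        problem = "out of range"
      )
    }
  }
  key <- paste(data$patient_id, data$visit, sep = "\r")
  dup <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
  if (length(dup)) {
    probs[["dup"]] <- tibble::tibble(
      row = dup,
      patient_id = as.character(data$patient_id[dup]),
      field = "patient_id/visit",
      value = NA_real_,
      allowed = "unique (patient_id, visit)",
      problem = "duplicate visit row"
    )
  }
  if (!length(probs)) {
    return(tibble::tibble(
      row = integer(), patient_id = character(), field = character(),
      value = numeric(), allowed = character(), problem = character()
    ))
  }
  dplyr::arrange(dplyr::bind_rows(probs), .data$row)
}

#' Validate visit records, erroring on any problem
#'
#' Runs [check_visit_records()] and aborts with a readable report naming each
#' offending field, value and allowed range if anything fails; otherwise
#' returns the data invisibly so the call can sit inside a pipe.
#'
#' @inheritParams check_visit_records
#' @return `data`, invisibly, when valid.
#' @export
validate_visit_records <- function(data) {
  probs <- check_visit_records(data)
  if (nrow(probs)) {
    msgs <- sprintf(
      "row %d (%s): %s = %s, allowed %s [%s]",
      probs$row, probs$patient_id, probs$field,
      ifelse(is.na(probs$value), "-", format(probs$value)),
      probs$allowed, probs$problem
    )
    rlang::abort(c("invalid visit records:", utils::head(msgs, 20)))
  }
  invisible(data)
}
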