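#' Read a visit-record table from CSV
#'
#' Expects the header
#' `patient_id,arm,visit,qlds_total,madrs_total,cgi_ss_r,cgi_sr_i,eq_vas`;
#' empty cells are missing scores. The file may additionally carry the 34
#' QLDS item columns `qlds_item_01 .. qlds_item_34` with values in \{0, 1\};
#' when present and `score_items = TRUE`, rows whose `qlds_total` is empty
#' get it filled from the items (rows with a partial item set are left
#' missing rather than prorated, and reported via a message).
#'
#' @param path Path to a CSV file.
#' @param score_items Fill missing `qlds_total` from complete item columns?
#' @param validate Run [validate_visit_records()] on the result?
#' @return A tibble of visit records.
#' @export
read_visit_csv <- function(path, score_items = TRUE, validate = TRUE) {
  spec <- readr::cols(
    patient_id = readr::col_character(),
    arm = readr::col_character(),
    visit = readr::col_character(),
    .default = readr::col_double()
  )
  data <- readr::read_csv(path, col_types = spec, na = c("", "NA"))
  need <- c("patient_id", "arm", "visit", "qlds_total", "madrs_total",
            "cgi_ss_r", "cgi_sr_i", "eq_vas")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    rlang::abort(paste0("visit CSV missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  item_cols <- sprintf("qlds_item_%02d", 1:34)
  if (score_items && all(item_cols %in% names(data))) {
    items <- as.matrix(data[item_cols])
    complete <- rowSums(!is.na(items)) == 34L
    fill <- which(is.na(data$qlds_total) & complete)
    if (length(fill)) data$qlds_total[fill] <- score_qlds(items[fill, , drop = FALSE])
    partial <- which(is.na(data$qlds_total) & !complete & rowSums(!is.na(items)) > 0L)
    if (length(partial)) {
      rlang::inform(paste0(
        length(partial), " row(s) have a partial QLDS item set; totals left missing (no prorating)"
      ))
    }
  }
  if (validate) validate_visit_records(data)
  data
}

#' Write a visit-record table to CSV
#'
#' @param data A visit-record tibble.
#' @param path Output path.
#' @return `data`, invisibly.
#' @export
write_visit_csv <- function(data, path) {
  readr::write_csv(data, path, na = "")
  invisible(data)
}
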