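# run code under a private RNG stream, restoring the caller's state
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

#' Configuration for a synthetic two-visit cohort
#'
#' Defines the marginal and correlation structure of a simulated two-visit
#' (baseline / endpoint) trial cohort across the five instruments. Latent
#' Gaussian baselines receive a latent multivariate-normal change vector with
#' the requested correlation matrix; each instrument is then rounded to
#' integers and clipped to its range (CGI scales: a latent continuous
#' severity discretised into 7 levels at configurable cut points). Rounding
#' and clipping slightly attenuate the realised rank correlations relative to
#' the latent targets.
#'
#' Defaults emulate a 4-week, two-visit esketamine trial population of
#' depressed patients with acute suicidal ideation: QLDS baseline mean 27.24
#' (SD 6.40) with mean change -12.46 (SD 11.26); MADRS 41.1 (6.07), change
#' -23.2 (13.03); EQ-VAS 42.0 (24.44), change +20.7 (25.15); CGI baselines
#' matching the published frequency tables (CGI-SS-r 3.78 (1.09), CGI-SR-I
#' 3.61 (1.25)); latent change correlations 0.66 (QLDS-MADRS), 0.43 / 0.44
#' (QLDS-CGI), -0.53 (QLDS-EQ-VAS).
#'
#' @param n_patients Number of patients (two rows each in the output).
#' @param seed Default seed used by [generate_cohort()] when none is given.
#' @param baseline_mean,baseline_sd Named numeric vectors over
#'   `qlds_total`, `madrs_total`, `cgi_ss_r`, `cgi_sr_i`, `eq_vas`.
#' @param change_mean,change_sd Same structure, for endpoint minus baseline
#'   latent changes.
#' @param change_cor 5x5 correlation matrix of the latent changes, in the
#'   instrument order above. Must be symmetric, unit-diagonal, positive
#'   semi-definite.
#' @param missing_rate Fraction of patients whose endpoint scores are
#'   blanked, in `[0, 1)`.
#' @param arms Character vector of arm labels cycled over patients.
#' @param cgi_cut_points Increasing cut points discretising the latent CGI
#'   severity into levels 0..6 (defaults to midpoints, i.e. rounding).
#' @return A list of class `cohort_config`.
#' @export
#' @examples
#' cfg <- cohort_config(n_patients = 50)
#' generate_cohort(cfg, seed = 1)
cohort_config <- function(n_patients = 224,
                          seed = 1234,
                          baseline_mean = c(qlds_total = 27.24, madrs_total = 41.1,
                                            cgi_ss_r = 3.78, cgi_sr_i = 3.61,
                                            eq_vas = 42.0),
                          baseline_sd = c(qlds_total = 6.40, madrs_total = 6.07,
                                          cgi_ss_r = 1.09, cgi_sr_i = 1.25,
                                          eq_vas = 24.44),
                          change_mean = c(qlds_total = -12.46, madrs_total = -23.2,
                                          cgi_ss_r = -2.0, cgi_sr_i = -2.0,
                                          eq_vas = 20.7),
                          change_sd = c(qlds_total = 11.26, madrs_total = 13.03,
                                        cgi_ss_r = 1.6, cgi_sr_i = 1.6,
                                        eq_vas = 25.15),
                          change_cor = default_change_cor(),
                          missing_rate = 0,
                          arms = c("active", "control"),
                          cgi_cut_points = seq(0.5, 5.5, by = 1)) {
  instruments <- instrument_ranges()$instrument
  for (nm in c("baseline_mean", "baseline_sd", "change_mean", "change_sd")) {
    v <- get(nm)
    if (!all(instruments %in% names(v))) {
      rlang::abort(paste0(nm, " must be named over: ", paste(instruments, collapse = ", ")))
    }
  }
  if (any(baseline_sd < 0) || any(change_sd < 0)) {
    rlang::abort("standard deviations must be >= 0")
  }
  .validate_cor(change_cor)
  if (length(missing_rate) != 1 || missing_rate < 0 || missing_rate >= 1) {
    rlang::abort("missing_rate must lie in [0, 1)")
  }
  if (n_patients < 0 || n_patients != round(n_patients)) {
    rlang::abort("n_patients must be a non-negative integer")
  }
  if (any(diff(cgi_cut_points) <= 0) || length(cgi_cut_points) != 6) {
    rlang::abort("cgi_cut_points must be 6 strictly increasing values")
  }
  structure(list(
    n_patients = as.integer(n_patients), seed = seed,
    baseline_mean = baseline_mean[instruments], baseline_sd = baseline_sd[instruments],
    change_mean = change_mean[instruments], change_sd = change_sd[instruments],
    change_cor = change_cor, missing_rate = missing_rate, arms = arms,
    cgi_cut_points = cgi_cut_points
  ), class = "cohort_config")
}

#' Default latent change correlation matrix
#'
#' QLDS-anchor entries use the published change-score correlation magnitudes
#' (0.66 MADRS, 0.43 CGI-SS-r, 0.44 CGI-SR-I, -0.53 EQ-VAS); the
#' anchor-anchor entries, which are not published, are plausible moderate
#' values chosen to keep the matrix positive definite.
#'
#' @return A 5x5 correlation matrix over the instruments of
#'   [instrument_ranges()].
#' @export
default_change_cor <- function() {
  instruments <- instrument_ranges()$instrument
  R <- matrix(c(
    1.00, 0.66, 0.43, 0.44, -0.53,
    0.66, 1.00, 0.50, 0.50, -0.50,
    0.43, 0.50, 1.00, 0.60, -0.35,
    0.44, 0.50, 0.60, 1.00, -0.35,
    -0.53, -0.50, -0.35, -0.35, 1.00
  ), 5, 5, dimnames = list(instruments, instruments))
  R
}

.validate_cor <- function(R) {
  if (!is.matrix(R) || nrow(R) != 5 || ncol(R) != 5) {
    rlang::abort("change_cor must be a 5x5 matrix")
  }
  if (max(abs(R - t(R))) > 1e-8) rlang::abort("change_cor must be symmetric")
  if (max(abs(diag(R) - 1)) > 1e-8) rlang::abort("change_cor must have unit diagonal")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    rlang::abort("change_cor is not positive semi-definite")
  }
  invisible(R)
}

#' Read a cohort configuration from YAML or JSON
#'
#' Top-level keys mirror the arguments of [cohort_config()]; `change_cor`
#' may be given as a list of 5 rows. Missing keys keep their defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `cohort_config` object.
#' @export
read_cohort_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  args <- raw[intersect(names(raw), names(formals(cohort_config)))]
  for (nm in c("baseline_mean", "baseline_sd", "change_mean", "change_sd")) {
    if (!is.null(args[[nm]])) args[[nm]] <- unlist(args[[nm]])
  }
  if (!is.null(args$change_cor)) {
    m <- args$change_cor
    if (is.list(m)) m <- do.call(rbind, lapply(m, unlist))
    instruments <- instrument_ranges()$instrument
    dimnames(m) <- list(instruments, instruments)
    args$change_cor <- m
  }
  do.call(cohort_config, args)
}

.empty_cohort <- function() {
  tibble::tibble(
    patient_id = character(), arm = character(), visit = character(),
    qlds_total = integer(), madrs_total = integer(),
    cgi_ss_r = integer(), cgi_sr_i = integer(), eq_vas = integer()
  )
}

# round/clip a latent score onto its instrument's integer scale;
# CGI scales go through the configured cut points instead of plain rounding
.discretise <- function(latent, instrument, cuts) {
  rng <- .range_of(instrument)
  if (instrument %in% c("cgi_ss_r", "cgi_sr_i")) {
    out <- findInterval(latent, cuts)
  } else {
    out <- round(latent)
  }
  as.integer(pmin(pmax(out, rng$min), rng$max))
}

#' Generate a synthetic two-visit cohort
#'
#' Draws independent latent Gaussian baselines per instrument, adds a latent
#' multivariate-normal change vector with the configured correlation matrix,
#' then discretises both visits onto the instruments' integer scales. The
#' same seed always yields the identical table.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A tibble of visit records, two rows (baseline, endpoint) per
#'   patient, with columns `patient_id`, `arm`, `visit`, `qlds_total`,
#'   `madrs_total`, `cgi_ss_r`, `cgi_sr_i`, `eq_vas`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 10), seed = 7)
#' dplyr::count(cohort, visit)
generate_cohort <- function(config = cohort_config(), seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_patients
  if (n == 0L) return(.empty_cohort())
  instruments <- instrument_ranges()$instrument
  .with_seed(seed, {
    base_lat <- vapply(instruments, function(ins) {
      rnorm(n, config$baseline_mean[[ins]], config$baseline_sd[[ins]])
    }, numeric(n))
    base_lat <- matrix(base_lat, nrow = n,
                       dimnames = list(NULL, instruments))
    D <- diag(config$change_sd[instruments])
    Sigma <- D %*% config$change_cor %*% D
    chg_lat <- MASS::mvrnorm(n, mu = config$change_mean[instruments], Sigma = Sigma)
    chg_lat <- matrix(chg_lat, nrow = n, dimnames = list(NULL, instruments))
    end_lat <- base_lat + chg_lat

    ids <- sprintf("P%05d", seq_len(n))
    arms <- rep_len(config$arms, n)
    mk <- function(lat, visit) {
      cols <- lapply(instruments, function(ins) {
        .discretise(lat[, ins], ins, config$cgi_cut_points)
      })
      names(cols) <- instruments
      tibble::tibble(patient_id = ids, arm = arms, visit = visit, !!!cols)
    }
    out <- dplyr::bind_rows(mk(base_lat, "baseline"), mk(end_lat, "endpoint"))
    out <- dplyr::arrange(out, .data$patient_id, .data$visit)
    if (config$missing_rate > 0) {
      out <- inject_missingness(out, config$missing_rate, seed = NULL)
    }
    out
  })
}

#' Blank endpoint scores at random
#'
#' Marks a random subset of patients as missing at the endpoint visit:
#' every instrument score in their endpoint row is set to `NA`. Baseline
#' rows are never touched. With `seed = NULL` the current RNG stream is
#' used (so the call is reproducible inside [generate_cohort()]).
#'
#' @param records A visit-record tibble.
#' @param rate Fraction of patients to blank, in `[0, 1)`. Each patient is
#'   blanked independently with probability `rate`.
#' @param seed Optional integer seed.
#' @return The records with blanked endpoint rows.
#' @export
inject_missingness <- function(records, rate, seed = NULL) {
  if (length(rate) != 1 || is.na(rate) || rate < 0 || rate >= 1) {
    rlang::abort("rate must lie in [0, 1)")
  }
  if (rate == 0 || nrow(records) == 0L) return(records)
  .with_seed(seed, {
    is_end <- records$visit == "endpoint"
    ids <- unique(records$patient_id[is_end])
    drop <- ids[runif(length(ids)) < rate]
    hit <- is_end & records$patient_id %in% drop
    for (ins in intersect(instrument_ranges()$instrument, names(records))) {
      records[[ins]][hit] <- NA_integer_
    }
    records
  })
}

#' Generate a cohort with known anchor-group composition
#'
#' A purpose-built generator for validating the anchor-based estimators: each
#' patient is assigned a true MADRS category improvement (0, 1, 2 or 3
#' severity bands under `criteria`), the MADRS visits are drawn uniformly
#' inside bands consistent with that assignment (baseline always in the
#' severe band, as in an acutely ill trial population), and the QLDS change
#' is drawn from a normal with the group's true mean. Scores are rounded and
#' clipped to their instrument ranges, which perturbs the realised group
#' means slightly near the scale floor/ceiling. Other instruments are left
#' missing. The true assignment is attached as attribute `true_category`.
#'
#' @param n Number of patients.
#' @param category_probs Probabilities over category improvements 0..3.
#' @param qlds_change_mean Named numeric over categories `"0"`..`"3"`: true
#'   mean QLDS change per group (improvement negative).
#' @param qlds_change_sd True within-group SD of QLDS change.
#' @param qlds_baseline_mean,qlds_baseline_sd QLDS baseline marginal.
#' @param criteria Severity criteria name used for the MADRS bands.
#' @param seed Integer seed.
#' @return A visit-record tibble (two rows per patient) with attribute
#'   `true_category` (integer vector, one per patient).
#' @export
#' @examples
#' coh <- generate_anchored_cohort(100, seed = 3)
#' table(attr(coh, "true_category"))
generate_anchored_cohort <- function(n,
                                     category_probs = c(0.25, 0.35, 0.25, 0.15),
                                     qlds_change_mean = c("0" = 0, "1" = -8,
                                                          "2" = -15, "3" = -20),
                                     qlds_change_sd = 9,
                                     qlds_baseline_mean = 27.24,
                                     qlds_baseline_sd = 6.40,
                                     criteria = "criteria_1",
                                     seed = NULL) {
  stopifnot(length(category_probs) == 4, all(category_probs >= 0))
  bands <- severity_criteria(criteria)
  .with_seed(seed, {
    k <- sample(0:3, n, replace = TRUE, prob = category_probs)
    # baseline in the severe band; endpoint k bands lower
    b_band <- rep(4L, n)
    e_band <- b_band - k
    runif_band <- function(i) {
      lo <- bands$lower[i]; hi <- bands$upper[i]
      lo + floor(runif(length(i)) * (hi - lo + 1L))
    }
    madrs_b <- runif_band(b_band)
    madrs_e <- runif_band(e_band)
    qlds_b <- pmin(pmax(round(rnorm(n, qlds_baseline_mean, qlds_baseline_sd)), 0L), 34L)
    qlds_chg <- round(rnorm(n, qlds_change_mean[as.character(k)], qlds_change_sd))
    qlds_e <- pmin(pmax(qlds_b + qlds_chg, 0L), 34L)
    ids <- sprintf("P%05d", seq_len(n))
    mk <- function(visit, q, m) {
      tibble::tibble(
        patient_id = ids, arm = "pooled", visit = visit,
        qlds_total = as.integer(q), madrs_total = as.integer(m),
        cgi_ss_r = NA_integer_, cgi_sr_i = NA_integer_, eq_vas = NA_integer_
      )
    }
    out <- dplyr::arrange(
      dplyr::bind_rows(mk("baseline", qlds_b, madrs_b), mk("endpoint", qlds_e, madrs_e)),
      .data$patient_id, .data$visit
    )
    attr(out, "true_category") <- k
    out
  })
}

#' The packaged demonstration cohort
#'
#' A fixed synthetic cohort of 224 patients generated from the default
#' [cohort_config()] with its documented default seed (1234). Used in the
#' examples, the vignette and the end-to-end tests.
#'
#' @return A visit-record tibble.
#' @export
demo_cohort <- function() {
  generate_cohort(cohort_config())
}
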