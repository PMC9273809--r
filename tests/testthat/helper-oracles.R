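# Independent oracles and tiny fixture builders used across the suite.

# brute-force average ranks: for each value, 1 + number smaller + half the
# number of other tied values (no call to rank())
oracle_ranks <- function(x) {
  vapply(seq_along(x), function(i) {
    1 + sum(x < x[i]) + (sum(x == x[i]) - 1) / 2
  }, numeric(1))
}

# Pearson on oracle ranks via explicit sums
oracle_spearman <- function(x, y) {
  rx <- oracle_ranks(x); ry <- oracle_ranks(y)
  n <- length(x)
  sx <- sum(rx); sy <- sum(ry)
  num <- n * sum(rx * ry) - sx * sy
  den <- sqrt(n * sum(rx^2) - sx^2) * sqrt(n * sum(ry^2) - sy^2)
  num / den
}

# two-sample KS distance by scanning every pooled value
oracle_ks <- function(a, b) {
  pooled <- c(a, b)
  max(vapply(pooled, function(t) {
    abs(mean(a <= t) - mean(b <= t))
  }, numeric(1)))
}

# a minimal valid two-visit table
make_visits <- function(qlds_b, qlds_e, madrs_b = NULL, madrs_e = NULL,
                        cgi_ss_b = NULL, cgi_ss_e = NULL,
                        eq_b = NULL, eq_e = NULL) {
  n <- length(qlds_b)
  fill <- function(x) if (is.null(x)) rep(NA_integer_, n) else as.integer(x)
  ids <- sprintf("P%03d", seq_len(n))
  dplyr::bind_rows(
    tibble::tibble(patient_id = ids, arm = "a", visit = "baseline",
                   qlds_total = as.integer(qlds_b), madrs_total = fill(madrs_b),
                   cgi_ss_r = fill(cgi_ss_b), cgi_sr_i = NA_integer_,
                   eq_vas = fill(eq_b)),
    tibble::tibble(patient_id = ids, arm = "a", visit = "endpoint",
                   qlds_total = as.integer(qlds_e), madrs_total = fill(madrs_e),
                   cgi_ss_r = fill(cgi_ss_e), cgi_sr_i = NA_integer_,
                   eq_vas = fill(eq_e))
  )
}
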