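test_that("change scores carry the documented sign conventions", {
  d <- make_visits(qlds_b = 27, qlds_e = 15, madrs_b = 41, madrs_e = 17,
                   eq_b = 40, eq_e = 60)
  ch <- compute_changes(d)
  expect_equal(ch$qlds_total_change, -12)        # improvement is negative
  expect_equal(ch$madrs_total_change, -24)
  expect_equal(ch$eq_vas_change, 20)             # improvement is positive
  # 41 is severe (3) and 17 slight (1) under criteria 1: two categories up
  expect_equal(ch$madrs_cat_change_criteria_1, 2L)
  # under criteria 2 (severe > 34, slight 7-19): 3 -> 1 as well
  expect_equal(ch$madrs_cat_change_criteria_2, 2L)
})

test_that("patients lacking a visit are excluded and counted", {
  d <- make_visits(qlds_b = c(10, 20, 30), qlds_e = c(5, 8, 28))
  d <- d[-5, ]  # drop endpoint row of the second patient
  ch <- compute_changes(d)
  expect_equal(nrow(ch), 2L)
  dropped <- attr(ch, "dropped")
  expect_equal(dropped$n[dropped$reason == "missing endpoint row"], 1)
})

test_that("duplicate visit rows abort with the offending patients listed", {
  d <- make_visits(qlds_b = c(10, 20), qlds_e = c(5, 8))
  expect_error(compute_changes(dplyr::bind_rows(d, d[1, ])), "P001")
})

test_that("CGI point change is baseline minus endpoint", {
  d <- make_visits(qlds_b = 20, qlds_e = 10, cgi_ss_b = 5, cgi_ss_e = 3)
  ch <- compute_changes(d)
  expect_equal(ch$cgi_ss_r_point_change, 2L)
})

test_that("spearman_rho hits the concordance bounds", {
  expect_equal(spearman_rho(1:8, (1:8)^2)$rho, 1.0)
  expect_equal(spearman_rho(1:8, -(1:8)^3)$rho, -1.0)
  expect_equal(spearman_rho(1:8, (1:8)^2)$p_value, 0)
})

test_that("spearman_rho matches the brute-force rank-then-Pearson oracle", {
  x <- c(1, 2, 2, 4); y <- c(10, 9, 7, 5)
  expect_equal(spearman_rho(x, y)$rho, oracle_spearman(x, y), tolerance = 1e-12)
  set.seed(101)
  for (i in 1:200) {
    n <- sample(4:12, 1)
    a <- sample(0:5, n, replace = TRUE)   # heavy ties
    b <- sample(0:5, n, replace = TRUE)
    if (sd(a) == 0 || sd(b) == 0) next
    expect_equal(spearman_rho(a, b)$rho, oracle_spearman(a, b), tolerance = 1e-12)
  }
})

test_that("spearman_rho is invariant under strictly monotone transforms", {
  set.seed(7)
  for (i in 1:25) {
    x <- rnorm(15); y <- rnorm(15)
    r0 <- spearman_rho(x, y)$rho
    expect_equal(spearman_rho(exp(x), y)$rho, r0, tolerance = 1e-12)
    expect_equal(spearman_rho(x, y^3)$rho, r0, tolerance = 1e-12)
    expect_equal(spearman_rho(-x, y)$rho, -r0, tolerance = 1e-12)
  }
})

test_that("spearman_rho p-value uses the t approximation on n - 2 df", {
  set.seed(12)
  x <- rnorm(30); y <- x + rnorm(30, sd = 2)
  out <- spearman_rho(x, y)
  tval <- out$rho * sqrt((out$n - 2) / (1 - out$rho^2))
  expect_equal(out$p_value, 2 * pt(-abs(tval), out$n - 2), tolerance = 1e-12)
})

test_that("exact permutation p is available for tiny samples", {
  out <- spearman_rho(1:5, c(2, 4, 6, 8, 10), method = "permutation")
  # only the identity and the full reversal reach |rho| = 1
  expect_equal(out$p_value, 2 / factorial(5), tolerance = 1e-12)
  expect_error(spearman_rho(1:9, 9:1, method = "permutation"), "n <= 8")
})

test_that("degenerate correlation inputs are refused", {
  expect_error(spearman_rho(1:2, 2:1), "at least 3")
  expect_error(spearman_rho(c(1, 1, 1), 1:3), "zero variance")
  expect_error(spearman_rho(c(1, NA, 2), c(3, 4, NA)), "at least 3")
})

test_that("anchors qualify on correlation magnitude, not sign", {
  spec <- anchor_spec("madrs_total", "severity_categorical", criteria = "criteria_1")
  expect_true(qualify_anchor(0.66, spec)$qualified)
  expect_false(qualify_anchor(0.39, spec)$qualified)
  vas <- anchor_spec("eq_vas", "continuous", anchor_mct = 7)
  expect_true(qualify_anchor(-0.53, vas)$qualified)
  expect_true(qualify_anchor(0.40, spec)$qualified)  # threshold is inclusive
})

test_that("anchor specs enforce their own contracts", {
  expect_error(anchor_spec("madrs_total", "severity_categorical"), "criteria")
  expect_error(anchor_spec("eq_vas", "continuous"), "anchor_mct")
  expect_error(anchor_spec("cgi_ss_r", "ordinal_point", anchor_mct = 7), "only")
  expect_error(anchor_spec("qlds_total", "ordinal_point"))
  expect_error(anchor_spec("madrs_total", "severity_categorical",
                           criteria = "criteria_1", threshold = 0), "> 0")
})

test_that("qualification over a change table records rho, p and n per anchor", {
  coh <- generate_cohort(cohort_config(n_patients = 200), seed = 3)
  q <- qualify_anchors(compute_changes(coh))
  expect_equal(nrow(q), 6L)
  expect_true(all(q$n == 200))
  expect_true(all(abs(q$rho) <= 1))
  expect_true(q$qualified[q$anchor == "madrs_total (criteria_1)"])
})

test_that("anchor grouping keys exact integer improvements", {
  d <- make_visits(qlds_b = c(20, 25, 30), qlds_e = c(15, 20, 28),
                   madrs_b = c(41, 41, 41), madrs_e = c(17, 41, 30))
  ch <- compute_changes(d)
  spec <- anchor_spec("madrs_total", "severity_categorical", criteria = "criteria_1")
  g <- group_by_anchor_change(ch, spec, min_n = 2)
  # 41 -> 17 improves two categories; 41 -> 41 none; 41 -> 30 stays severe
  expect_equal(sort(unique(g$category)), c(0L, 2L))
  expect_equal(sum(g$category == 0), 2L)
  expect_equal(nrow(g), nrow(ch))  # group sizes sum to complete cases
  expect_true(all(g$small_group[g$category == 2]))
})

test_that("a cohort with no anchor movement forms a single zero group", {
  d <- make_visits(qlds_b = c(20, 25), qlds_e = c(15, 22),
                   madrs_b = c(41, 35), madrs_e = c(40, 33))
  g <- group_by_anchor_change(
    compute_changes(d),
    anchor_spec("madrs_total", "severity_categorical", criteria = "criteria_1")
  )
  expect_identical(unique(g$category), 0L)
  expect_equal(nrow(g), 2L)
})

test_that("cumulative grouping pools at-least-k improvements", {
  d <- make_visits(qlds_b = rep(20, 4), qlds_e = rep(10, 4),
                   madrs_b = rep(41, 4), madrs_e = c(41, 25, 17, 5))
  spec <- anchor_spec("madrs_total", "severity_categorical", criteria = "criteria_1")
  g <- group_by_anchor_change(compute_changes(d), spec, cumulative = TRUE)
  sizes <- dplyr::count(g, category)
  expect_equal(sizes$n[sizes$category == 1], 3L)  # improved >= 1
  expect_equal(sizes$n[sizes$category == 2], 2L)
  expect_equal(sizes$n[sizes$category == 3], 1L)
})

test_that("category construction responds to the criteria banding", {
  # 20 -> 13: criteria_1 keeps both in 'slight'; criteria_2 moves
  # moderate -> slight; criteria_3 moves moderate -> slight as well
  d <- make_visits(qlds_b = 20, qlds_e = 10, madrs_b = 20, madrs_e = 13)
  ch <- compute_changes(d)
  expect_equal(ch$madrs_cat_change_criteria_1, 0L)
  expect_equal(ch$madrs_cat_change_criteria_2, 1L)
  expect_equal(ch$madrs_cat_change_criteria_3, 1L)
})

test_that("empty change tables cannot be grouped", {
  d <- make_visits(qlds_b = 10, qlds_e = 5)
  ch <- compute_changes(d)
  spec <- anchor_spec("madrs_total", "severity_categorical", criteria = "criteria_1")
  expect_error(group_by_anchor_change(ch[0, ], spec), "empty")
  expect_error(group_by_anchor_change(ch, spec), "no complete")
})
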