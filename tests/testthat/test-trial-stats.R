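test_that("grading table validates counts and sums group sizes", {
  tab <- riker_agitation_table()
  expect_equal(tab$grades, 3:7)
  expect_equal(unname(tab$group_sizes), c(30, 30))
  expect_error(grading_table(c(3, 3), list(A = c(1, 1))), "strictly increasing")
  expect_error(grading_table(3:4, list(A = c(-1, 2))), "non-negative")
  expect_error(grading_table(3:4, list(c(1, 2))), "named list")
})

test_that("agitation incidence truncates to whole percent at the grade-5 cut", {
  tab <- riker_agitation_table()
  expect_identical(agitation_incidence(tab, "A"), 16L)   # 5/30 -> 16.67 -> 16
  expect_identical(agitation_incidence(tab, "B"), 76L)   # 23/30 -> 76.67 -> 76
  # nobody at or above the cut
  none <- grading_table(3:7, list(A = c(10, 20, 0, 0, 0)))
  expect_identical(agitation_incidence(none, "A"), 0L)
  # monotone non-increasing in the threshold
  incs <- vapply(3:7, function(th) agitation_incidence(tab, "B", th), integer(1))
  expect_true(all(diff(incs) <= 0))
  expect_error(agitation_incidence(tab, "C"), "unknown group")
  expect_error(agitation_incidence(tab, "A", 8), "table grades")
})

test_that("2x2 chi-squared matches the closed form and stats::chisq.test", {
  # agitated / not agitated per group, from the grading counts
  res <- chi_square_2x2(5, 23, 25, 7)
  expect_equal(res$statistic, 21.69643, tolerance = 1e-6)
  expect_lt(res$p_value, 0.001)
  # cross-check against the independent implementation (no correction)
  ref <- stats::chisq.test(rbind(c(5, 23), c(25, 7)), correct = FALSE)
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
  # Yates variant
  resy <- chi_square_2x2(5, 23, 25, 7, correct = TRUE)
  refy <- stats::chisq.test(rbind(c(5, 23), c(25, 7)), correct = TRUE)
  expect_equal(resy$statistic, unname(refy$statistic), tolerance = 1e-12)
  # equals the squared two-proportion z statistic
  p1 <- 5 / 30; p2 <- 23 / 30; pp <- 28 / 60
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / 30 + 1 / 30))
  expect_equal(res$statistic, z^2, tolerance = 1e-12)
  # symmetry under transposing rows and columns
  expect_equal(chi_square_2x2(5, 25, 23, 7)$statistic, res$statistic)
  expect_equal(chi_square_2x2(10, 10, 10, 10)$statistic, 0)
  expect_error(chi_square_2x2(0, 0, 5, 5), "margin is zero")
  expect_error(chi_square_2x2(-1, 2, 3, 4), "non-negative")
})

test_that("summary-statistic t tests match closed forms and stats::t.test", {
  s1 <- group_summary(10, 2, 20)
  expect_equal(two_sample_t(s1, s1)$t, 0)
  expect_equal(two_sample_t(s1, s1)$p_value, 1)
  # published heart-rate summaries immediately after awakening
  res <- two_sample_t(group_summary(100, 5.5, 30), group_summary(112, 6.8, 30))
  expect_equal(res$t, -7.515183, tolerance = 1e-6)
  expect_equal(res$df, 58)
  expect_lt(res$p_value, 0.001)
  # doubling both n with the same means/sds scales |t| by sqrt(2)
  res2 <- two_sample_t(group_summary(100, 5.5, 60), group_summary(112, 6.8, 60))
  expect_equal(res2$t, res$t * sqrt(2), tolerance = 1e-12)
  # cross-check both variants against stats::t.test on data constructed to
  # have exactly the given means and SDs
  make_data <- function(mean, sd, n) {
    x <- scale(rnorm(n))   # exact mean 0, sd 1
    as.numeric(x * sd + mean)
  }
  set.seed(16)
  x <- make_data(5, 1.3, 12); y <- make_data(6.1, 2.2, 17)
  gx <- group_summary(5, 1.3, 12); gy <- group_summary(6.1, 2.2, 17)
  refp <- stats::t.test(x, y, var.equal = TRUE)
  refw <- stats::t.test(x, y)
  gotp <- two_sample_t(gx, gy, "pooled")
  gotw <- two_sample_t(gx, gy, "welch")
  expect_equal(gotp$t, unname(refp$statistic), tolerance = 1e-10)
  expect_equal(gotp$p_value, refp$p.value, tolerance = 1e-10)
  expect_equal(gotw$t, unname(refw$statistic), tolerance = 1e-10)
  expect_equal(gotw$df, unname(refw$parameter), tolerance = 1e-10)
  expect_equal(gotw$p_value, refw$p.value, tolerance = 1e-10)
  # Welch df never exceeds the pooled df
  expect_lte(gotw$df, gx$n + gy$n - 2)
  expect_error(two_sample_t(group_summary(1, 0, 5), group_summary(2, 0, 5)),
               "undefined")
})
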