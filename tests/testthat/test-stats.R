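# trial statistics: risk differences, chi-square, rank tests, logistic
# subgroups, sample size

test_that("risk differences reproduce printed trial arithmetic", {
  # IV fluids within 2 days: 927/1123 vs 670/1085
  rd <- risk_difference_ci(927, 1123, 670, 1085)
  expect_equal(round(rd$difference, 1), 20.8)
  expect_equal(round(rd$ci_low, 1), 17.1)
  expect_equal(round(rd$ci_high, 1), 24.4)
  expect_lt(rd$p_value, 0.001)
  # death within 7 days: 134/1123 vs 112/1085
  rd2 <- risk_difference_ci(134, 1123, 112, 1085)
  expect_equal(round(rd2$difference, 1), 1.6)
  expect_equal(round(rd2$ci_low, 1), -1.0)
  expect_equal(round(rd2$ci_high, 1), 4.2)
})

test_that("identical proportions give zero difference, symmetric CI", {
  rd <- risk_difference_ci(50, 100, 100, 200)
  expect_equal(rd$difference, 0)
  expect_equal(rd$ci_low, -rd$ci_high)
  expect_true(rd$ci_low <= rd$difference && rd$difference <= rd$ci_high)
  expect_error(risk_difference_ci(1, 0, 1, 10), "positive")
  # Newcombe interval stays inside [-100, 100] even at extreme proportions
  rdn <- risk_difference_ci(10, 10, 0, 10, method = "newcombe")
  expect_lte(rdn$ci_high, 100)
  expect_gte(rdn$ci_low, -100)
})

test_that("Wald CI width shrinks like 1/sqrt(n) at fixed proportions", {
  w <- vapply(c(1, 4, 16), function(m) {
    rd <- risk_difference_ci(30 * m, 100 * m, 20 * m, 100 * m)
    rd$ci_high - rd$ci_low
  }, numeric(1))
  expect_equal(w[1] / w[2], 2, tolerance = 1e-6)
  expect_equal(w[2] / w[3], 2, tolerance = 1e-6)
})

test_that("chi-square matches the direct sum((O-E)^2/E) formula", {
  expect_equal(chi_square(50, 100, 100, 200)$statistic, 0)
  expect_equal(chi_square(50, 100, 100, 200)$p_value, 1)
  expect_lt(chi_square(927, 1123, 670, 1085)$p_value, 0.001)
  set.seed(88)
  for (rep in 1:50) {
    na <- sample(5:40, 1); nb <- sample(5:40, 1)
    ea <- sample(1:(na - 1), 1); eb <- sample(1:(nb - 1), 1)
    got <- suppressWarnings(chi_square(ea, na, eb, nb))
    O <- matrix(c(ea, na - ea, eb, nb - eb), 2, byrow = TRUE)
    E <- outer(rowSums(O), colSums(O)) / sum(O)
    expect_equal(got$statistic, sum((O - E)^2 / E), tolerance = 1e-10)
    expect_equal(got$p_value, pchisq(sum((O - E)^2 / E), 1, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
  expect_warning(chi_square(0, 30, 1, 30), "expected")
})

test_that("Mann-Whitney handles identity, separation, and ties", {
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p_value, 1, tolerance = 0.05)
  sep <- mann_whitney(c(10, 11, 12, 13), c(1, 2, 3))
  expect_equal(sep$U, 4 * 3)
  expect_equal(mann_whitney(rep(2, 4), rep(2, 5), method = "normal")$p_value, 1)
  # large-sample path agrees with the tie-corrected normal approximation in
  # wilcox.test (independent implementation)
  set.seed(91)
  x <- sample(seq(0, 5, 0.5), 60, replace = TRUE)
  y <- sample(seq(0.5, 6, 0.5), 55, replace = TRUE)
  got <- mann_whitney(x, y, method = "normal")
  ref <- wilcox.test(x, y, exact = FALSE, correct = FALSE)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  expect_equal(got$U, unname(ref$statistic))
})

test_that("exact Mann-Whitney matches the null Wilcoxon distribution", {
  # tie-free small samples: enumeration must reproduce pwilcox tail sums
  set.seed(92)
  for (rep in 1:30) {
    nx <- sample(1:5, 1); ny <- sample(1:5, 1)
    vals <- sample(1:100, nx + ny)  # distinct -> tie-free
    x <- vals[1:nx]; y <- vals[-(1:nx)]
    got <- mann_whitney(x, y, method = "exact")
    U <- got$U; mu <- nx * ny / 2; d <- abs(U - mu)
    p_ref <- pwilcox(mu - d, nx, ny) +
      pwilcox(mu + d - 1, nx, ny, lower.tail = FALSE)
    expect_equal(got$p_value, min(p_ref, 1), tolerance = 1e-9)
  }
})

test_that("Hodges-Lehmann estimates a pure shift and matches brute force", {
  x <- c(1.2, 3.4, 2.2, 5.0, 4.1)
  expect_equal(hodges_lehmann(x, x + 2.5)$estimate, 2.5)
  expect_equal(hodges_lehmann(x, x)$estimate, 0)
  set.seed(93)
  for (rep in 1:20) {
    a <- rnorm(sample(4:9, 1)); b <- rnorm(sample(4:9, 1), mean = 0.5)
    hl <- hodges_lehmann(a, b)
    expect_equal(hl$estimate, median(outer(b, a, "-")), tolerance = 1e-9)
    expect_true(hl$ci_low <= hl$estimate && hl$estimate <= hl$ci_high)
  }
  expect_error(hodges_lehmann(numeric(0), 1:3), "nonempty")
})

test_that("logistic subgroup OR equals the 2x2 cross-product ratio", {
  set.seed(94)
  arm <- rep(0:1, each = 300)
  outcome <- rbinom(600, 1, ifelse(arm == 1, 0.4, 0.25))
  fit <- logistic_subgroup(outcome, arm, subgroup = rep("all", 600))
  a <- sum(outcome == 1 & arm == 1); b <- sum(outcome == 0 & arm == 1)
  c_ <- sum(outcome == 1 & arm == 0); d <- sum(outcome == 0 & arm == 0)
  expect_equal(fit$per_level$or, (a * d) / (b * c_), tolerance = 1e-6)
  expect_false(fit$per_level$separation)
})

test_that("interaction p is near-null without effect modification", {
  set.seed(95)
  n <- 4000
  arm <- rbinom(n, 1, 0.5)
  sg <- sample(c("icu", "ward"), n, replace = TRUE)
  outcome <- rbinom(n, 1, plogis(-1 + 0.5 * arm))  # same effect in both
  fit <- logistic_subgroup(outcome, arm, sg)
  expect_identical(nrow(fit$per_level), 2L)
  expect_gt(fit$interaction_p, 0.001)
  expect_true(all(fit$per_level$ci_low < fit$per_level$or &
                    fit$per_level$or < fit$per_level$ci_high))
  expect_error(logistic_subgroup(outcome, rep(1, n), sg), "both arms")
})

test_that("separation is flagged with an unbounded interval", {
  outcome <- c(rep(0, 20), rep(1, 20))
  arm <- outcome  # perfect separation
  sg <- rep("all", 40)
  fit <- suppressWarnings(logistic_subgroup(outcome, arm, sg))
  expect_true(fit$per_level$separation)
  expect_identical(fit$per_level$ci_high, Inf)
})

test_that("sample size reproduces the trial's planning numbers", {
  ss <- sample_size(sd = 13.4, mean_control = 19.0, mean_treat = 17.1,
                    alpha = 0.05, power = 0.90, attrition = 0.30)
  expect_lte(ss$n_per_group, 1050)
  expect_gte(ss$n_per_group, 1000)   # the normal approximation, ~1046
  expect_identical(ss$n_total_inflated, 3000)
  expect_identical(inflate_for_attrition(2 * 1050, 0.30), 3000)
  # close to the t-based reference computation
  ref <- power.t.test(delta = 1.9, sd = 13.4, power = 0.9)$n
  expect_lt(abs(ss$n_per_group - ref), 5)
  # inverse-square law in the detectable difference
  ss2 <- sample_size(13.4, 19.0, 19.0 - 2 * 1.9)
  expect_equal(ss2$n_per_group / ss$n_per_group, 0.25, tolerance = 0.01)
  expect_error(sample_size(13.4, 19, 19), "differ")
})

test_that("incidence per 100 admissions matches the printed rate", {
  expect_equal(incidence_per_100(2208, 158152), 1.4)
  expect_equal(incidence_per_100(0, 500), 0)
  expect_equal(incidence_per_100(500, 500), 100)
  expect_error(incidence_per_100(1, 0), "positive")
})
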