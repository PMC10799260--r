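# Statistical machinery of the trial: two-proportion risk differences with
# Wald confidence intervals, Pearson chi-square, Mann-Whitney with exact
# small-sample p-values, Hodges-Lehmann shift estimates, univariate logistic
# subgroup analysis with interaction, and the power-based sample size.

#' Per-arm event counts for a 2x2 comparison
#'
#' @param events_a,n_a events and denominator in group A (the alert arm in
#'   the trial's tables).
#' @param events_b,n_b events and denominator in group B (usual care).
#' @return An object of class `contingency_counts`.
#' @export
contingency_counts <- function(events_a, n_a, events_b, n_b) {
  if (n_a <= 0 || n_b <= 0) stop("denominators must be positive", call. = FALSE)
  if (events_a < 0 || events_a > n_a || events_b < 0 || events_b > n_b) {
    stop("event counts must lie in [0, n]", call. = FALSE)
  }
  structure(list(events_a = events_a, n_a = n_a,
                 events_b = events_b, n_b = n_b),
            class = "contingency_counts")
}

.as_counts <- function(c_or_ea, n_a, events_b, n_b) {
  if (inherits(c_or_ea, "contingency_counts")) c_or_ea
  else contingency_counts(c_or_ea, n_a, events_b, n_b)
}

#' Risk difference in percentage points with Wald confidence interval
#'
#' `difference = 100 * (events_a/n_a - events_b/n_b)`, with the Wald interval
#' `difference +/- z * sqrt(pa(1-pa)/n_a + pb(1-pb)/n_b)` and a p-value from
#' the Pearson chi-square test (no continuity correction). The Newcombe
#' score-based interval is available as an alternative.
#'
#' @param c a [contingency_counts()] object, or `events_a` when the four
#'   counts are given positionally.
#' @param n_a,events_b,n_b remaining counts when given positionally.
#' @param level confidence level (default 0.95).
#' @param method `"wald"` (default) or `"newcombe"`.
#' @return An object of class `difference_estimate` with fields `difference`,
#'   `ci_low`, `ci_high` (percentage points) and `p_value`.
#' @examples
#' risk_difference_ci(927, 1123, 670, 1085)  # 20.8 (17.1 to 24.4)
#' @export
risk_difference_ci <- function(c, n_a = NULL, events_b = NULL, n_b = NULL,
                               level = 0.95, method = c("wald", "newcombe")) {
  method <- match.arg(method)
  cc <- .as_counts(c, n_a, events_b, n_b)
  pa <- cc$events_a / cc$n_a
  pb <- cc$events_b / cc$n_b
  diff <- pa - pb
  z <- stats::qnorm((1 + level) / 2)
  if (method == "wald") {
    se <- sqrt(pa * (1 - pa) / cc$n_a + pb * (1 - pb) / cc$n_b)
    lo <- diff - z * se
    hi <- diff + z * se
  } else {
    # Newcombe hybrid score (MOVER): combine Wilson limits for each proportion
    wilson <- function(x, n) {
      p <- x / n
      den <- 1 + z^2 / n
      ctr <- (p + z^2 / (2 * n)) / den
      hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
      c(ctr - hw, ctr + hw)
    }
    wa <- wilson(cc$events_a, cc$n_a)
    wb <- wilson(cc$events_b, cc$n_b)
    lo <- diff - sqrt((pa - wa[1])^2 + (wb[2] - pb)^2)
    hi <- diff + sqrt((wa[2] - pa)^2 + (pb - wb[1])^2)
  }
  p <- chi_square(cc)$p_value
  structure(
    list(difference = 100 * diff, ci_low = 100 * lo, ci_high = 100 * hi,
         p_value = p, level = level, method = method),
    class = "difference_estimate"
  )
}

#' @export
print.difference_estimate <- function(x, ...) {
  cat(sprintf("%.1f (%.1f to %.1f), p = %s\n", x$difference, x$ci_low,
              x$ci_high, format.pval(x$p_value, digits = 2, eps = 1e-3)))
  invisible(x)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Pearson statistic without continuity correction, 1 degree of freedom.
#' Warns when an expected cell count falls below 1 (validity of the
#' approximation).
#'
#' @inheritParams risk_difference_ci
#' @return A list with `statistic`, `p_value` and `df`.
#' @export
chi_square <- function(c, n_a = NULL, events_b = NULL, n_b = NULL) {
  cc <- .as_counts(c, n_a, events_b, n_b)
  tab <- matrix(c(cc$events_a, cc$n_a - cc$events_a,
                  cc$events_b, cc$n_b - cc$events_b), nrow = 2, byrow = TRUE)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 1)) {
    warning("expected cell count below 1; chi-square approximation unreliable",
            call. = FALSE)
  }
  if (any(colSums(tab) == 0)) {
    return(list(statistic = 0, p_value = 1, df = 1L))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p_value = unname(ct$p.value), df = 1L)
}

# Mann-Whitney U for x relative to y: number of (x_i, y_j) pairs with
# x_i > y_j, counting ties as 1/2
.mw_u <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Mann-Whitney rank-sum test
#'
#' Two-sided comparison of two independent samples. With `method = "auto"`
#' (the default) the exact permutation distribution of U is enumerated when
#' the number of group splits is small (`choose(n1+n2, n1) <= max_exact`);
#' otherwise the normal approximation with the tie-corrected variance is
#' used. The exact path handles ties through midranks.
#'
#' @param x,y numeric samples (nonempty).
#' @param method `"auto"`, `"exact"` or `"normal"`.
#' @param max_exact enumeration budget for the exact path (default 20000
#'   splits).
#' @return A list with `U` (pairs where `x` exceeds `y`, ties counted half),
#'   `p_value` and `method_used`.
#' @export
mann_whitney <- function(x, y, method = c("auto", "exact", "normal"),
                         max_exact = 20000) {
  method <- match.arg(method)
  if (!length(x) || !length(y)) stop("both samples must be nonempty", call. = FALSE)
  nx <- length(x); ny <- length(y); N <- nx + ny
  U <- .mw_u(x, y)
  mu <- nx * ny / 2
  if (method == "auto") {
    method <- if (choose(N, nx) <= max_exact) "exact" else "normal"
  }
  if (method == "exact") {
    pooled <- rank(c(x, y))  # midranks; enumeration respects ties
    splits <- utils::combn(N, nx)
    us <- colSums(matrix(pooled[splits], nrow = nx)) - nx * (nx + 1) / 2
    p <- mean(abs(us - mu) >= abs(U - mu) - 1e-9)
  } else {
    pooled <- c(x, y)
    tie_sizes <- table(pooled)
    sigma2 <- nx * ny / 12 *
      ((N + 1) - sum(tie_sizes^3 - tie_sizes) / (N * (N - 1)))
    if (sigma2 <= 0) {
      p <- 1  # all values identical across both samples
    } else {
      z <- (U - mu) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
  }
  list(U = U, p_value = min(p, 1), method_used = method)
}

#' Hodges-Lehmann shift estimate with confidence interval
#'
#' Estimates the location shift of `y` relative to `x` as the median of all
#' pairwise differences `y_j - x_i`; the confidence interval is obtained by
#' inverting the rank-sum test (via [stats::wilcox.test()]).
#'
#' @param x reference sample (e.g. usual care).
#' @param y comparison sample (e.g. alert arm); a positive estimate means `y`
#'   is shifted upward.
#' @param level confidence level (default 0.95).
#' @return A list with `estimate`, `ci_low`, `ci_high` and `level`.
#' @export
hodges_lehmann <- function(x, y, level = 0.95) {
  if (!length(x) || !length(y)) stop("both samples must be nonempty", call. = FALSE)
  est <- stats::median(outer(y, x, "-"))
  wt <- suppressWarnings(
    stats::wilcox.test(y, x, conf.int = TRUE, conf.level = level,
                       exact = FALSE, correct = FALSE)
  )
  list(estimate = est,
       ci_low = wt$conf.int[1], ci_high = wt$conf.int[2], level = level)
}

#' Univariate logistic subgroup analysis with interaction
#'
#' For each level of a subgroup variable, fits `outcome ~ arm` by univariate
#' binary logistic regression and reports the odds ratio of the treated arm
#' with a Wald confidence interval. The interaction p-value comes from the
#' `arm x subgroup` product term of the joint fit. Complete or quasi-complete
#' separation is flagged and the affected interval reported as unbounded.
#'
#' @param outcome logical/0-1 outcome per patient.
#' @param arm logical/0-1 treatment indicator (1 = alert).
#' @param subgroup factor or vector defining the subgroup levels; both arms
#'   must be present in every level.
#' @param level confidence level (default 0.95).
#' @return A list with `per_level` (data frame: `level`, `n`, `or`, `ci_low`,
#'   `ci_high`, `p_value`, `separation`) and `interaction_p`.
#' @export
logistic_subgroup <- function(outcome, arm, subgroup, level = 0.95) {
  outcome <- as.integer(outcome)
  arm <- as.integer(arm)
  subgroup <- as.factor(subgroup)
  if (any(tapply(arm, subgroup, function(a) length(unique(a))) < 2)) {
    stop("both arms must be present in every subgroup level", call. = FALSE)
  }
  z <- stats::qnorm((1 + level) / 2)
  per <- do.call(rbind, lapply(levels(subgroup), function(lv) {
    idx <- subgroup == lv
    fit <- stats::glm(outcome[idx] ~ arm[idx], family = stats::binomial())
    sm <- summary(fit)$coefficients
    beta <- sm[2, 1]; se <- sm[2, 2]; pv <- sm[2, 4]
    sep <- !fit$converged || abs(beta) > 15 || se > 100
    data.frame(level = lv, n = sum(idx), or = exp(beta),
               ci_low = if (sep) 0 else exp(beta - z * se),
               ci_high = if (sep) Inf else exp(beta + z * se),
               p_value = pv, separation = sep, stringsAsFactors = FALSE)
  }))
  interaction_p <- if (nlevels(subgroup) < 2L) NA_real_ else {
    inter <- stats::glm(outcome ~ arm * subgroup, family = stats::binomial())
    smi <- summary(inter)$coefficients
    iterms <- grep("^arm:", rownames(smi))
    if (length(iterms) == 1L) smi[iterms, 4] else {
      # multi-level subgroup: likelihood-ratio test of all product terms
      red <- stats::glm(outcome ~ arm + subgroup, family = stats::binomial())
      stats::pchisq(red$deviance - inter$deviance,
                    df = length(iterms), lower.tail = FALSE)
    }
  }
  list(per_level = per, interaction_p = interaction_p)
}

#' Sample size for a two-group comparison of means
#'
#' Normal-approximation sample size
#' `n = ceiling(2 * sd^2 * (z_{1-alpha/2} + z_{power})^2 / delta^2)` per
#' group, with the enrolment total inflated for anticipated attrition and
#' rounded up to a planning granularity.
#'
#' @param sd common standard deviation of the outcome.
#' @param mean_control,mean_treat assumed group means; their absolute
#'   difference is the detectable effect.
#' @param alpha two-sided significance level (default 0.05).
#' @param power target power (default 0.90).
#' @param attrition anticipated fraction without evaluable follow-up
#'   (default 0.30).
#' @param granularity rounding granularity for the inflated total
#'   (default 100).
#' @return A list with `n_per_group`, `n_total` (2n) and `n_total_inflated`.
#' @examples
#' sample_size(13.4, 19.0, 17.1)  # 1046 per group, 3000 after inflation
#' @export
sample_size <- function(sd, mean_control, mean_treat, alpha = 0.05,
                        power = 0.90, attrition = 0.30, granularity = 100) {
  stopifnot(sd > 0, power > 0, power < 1, attrition >= 0, attrition < 1)
  delta <- abs(mean_control - mean_treat)
  if (delta == 0) stop("group means must differ", call. = FALSE)
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  n <- ceiling(2 * sd^2 * z^2 / delta^2)
  list(n_per_group = n, n_total = 2 * n,
       n_total_inflated = inflate_for_attrition(2 * n, attrition, granularity))
}

#' Inflate an enrolment total for attrition
#'
#' @param n_total evaluable sample size required.
#' @param attrition anticipated attrition fraction in `[0, 1)`.
#' @param granularity rounding granularity (default 100).
#' @return `n_total / (1 - attrition)` rounded up to the granularity.
#' @export
inflate_for_attrition <- function(n_total, attrition, granularity = 100) {
  stopifnot(attrition >= 0, attrition < 1, granularity >= 1)
  ceiling(n_total / (1 - attrition) / granularity) * granularity
}

#' AKI incidence per 100 admissions
#'
#' @param cases number of AKI episodes.
#' @param admissions number of admissions (must be positive).
#' @return `100 * cases / admissions`, reported to one decimal.
#' @examples
#' incidence_per_100(2208, 158152)
#' @export
incidence_per_100 <- function(cases, admissions) {
  if (admissions <= 0) stop("admissions must be positive", call. = FALSE)
  round(100 * cases / admissions, 1)
}
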