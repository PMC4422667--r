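#' Carrier counts for a two-group burden comparison
#'
#' The unit of burden is the carrier (person), not the allele: a case or
#' control counts once however many qualifying variants they carry.
#'
#' @param case_carriers,case_n Carriers and total among cases.
#' @param control_carriers,control_n Carriers and total among controls.
#' @return A list of class `CohortCounts`.
#' @examples
#' cohort_counts(9, 448, 1, 1588)
#' @export
cohort_counts <- function(case_carriers, case_n, control_carriers,
                          control_n) {
  v <- vapply(list(case_carriers, case_n, control_carriers, control_n),
              function(x) as.integer(x)[1L], integer(1L))
  if (anyNA(v) || any(v < 0L))
    fv_stop("all counts must be non-negative integers",
            "famvar_validation_error")
  if (v[2L] == 0L || v[4L] == 0L)
    fv_stop("case_n and control_n must be positive",
            "famvar_validation_error")
  if (v[1L] > v[2L] || v[3L] > v[4L])
    fv_stop("carriers cannot exceed the group size",
            "famvar_validation_error")
  structure(list(case_carriers = v[1L], case_n = v[2L],
                 control_carriers = v[3L], control_n = v[4L]),
            class = "CohortCounts")
}

#' Two-sided Fisher exact test on a 2x2 carrier table
#'
#' Exact conditional test of association for the table
#' (carriers / non-carriers) x (cases / controls), computed from first
#' principles. Conditional on the margins, the case-carrier count is
#' hypergeometric; the two-sided p-value follows the method of small
#' p-values: the sum of the probabilities of every table with the same
#' margins whose point probability does not exceed that of the observed
#' table (a relative tolerance of 1e-7 guards ties against floating-point
#' noise). Point probabilities are evaluated in log space via
#' [lchoose()], so large cohorts pose no overflow problem.
#'
#' @param counts A [cohort_counts()] object.
#' @return The two-sided p-value, in `(0, 1]`. Degenerate margins (no
#'   carriers at all, or everyone a carrier) make every table certain:
#'   the function returns 1 with a warning.
#' @examples
#' fisher_exact_two_sided(cohort_counts(9, 448, 1, 1588))  # 9.14e-06
#' @export
fisher_exact_two_sided <- function(counts) {
  stopifnot(inherits(counts, "CohortCounts"))
  m <- counts$case_n
  n <- counts$control_n
  k <- counts$case_carriers + counts$control_carriers
  if (k == 0L || k == m + n) {
    fv_warn("degenerate margins (carrier column all zero or all full); p = 1",
            "famvar_degenerate_warning")
    return(1)
  }
  support <- max(0L, k - n):min(m, k)
  logp <- lchoose(m, support) + lchoose(n, k - support) -
    lchoose(m + n, k)
  log_obs <- logp[support == counts$case_carriers]
  p <- sum(exp(logp[logp <= log_obs + log1p(1e-7)]))
  min(p, 1)
}

#' Carrier frequency among cases
#'
#' @param counts A [cohort_counts()] object.
#' @return `100 * case_carriers / case_n`, as a percentage rounded to one
#'   decimal (the precision carrier tables report).
#' @examples
#' carrier_frequency(cohort_counts(9, 448, 1, 1588))  # 2.0
#' @export
carrier_frequency <- function(counts) {
  stopifnot(inherits(counts, "CohortCounts"))
  round(100 * counts$case_carriers / counts$case_n, 1L)
}

#' Odds ratio for a 2x2 carrier table
#'
#' Cross-product odds ratio with a Wald confidence interval on the log
#' scale. With `haldane = TRUE`, 0.5 is added to every cell whenever any
#' cell is zero (Haldane–Anscombe correction); otherwise a zero cell
#' yields an infinite, zero or undefined ratio, flagged via `finite`.
#'
#' @param counts A [cohort_counts()] object.
#' @param haldane Apply the +0.5 correction when a cell is zero.
#' @param conf_level Confidence level for the Wald interval.
#' @return A list with `or`, `ci_lower`, `ci_upper`, `finite`.
#' @export
odds_ratio <- function(counts, haldane = FALSE, conf_level = 0.95) {
  stopifnot(inherits(counts, "CohortCounts"))
  a <- counts$case_carriers
  b <- counts$case_n - a
  c <- counts$control_carriers
  d <- counts$control_n - c
  cells <- c(a, b, c, d)
  if (haldane && any(cells == 0L)) cells <- cells + 0.5
  a <- cells[1L]; b <- cells[2L]; c <- cells[3L]; d <- cells[4L]
  or <- (a * d) / (b * c)
  finite <- is.finite(or) && or > 0
  se <- if (all(cells > 0)) sqrt(1 / a + 1 / b + 1 / c + 1 / d) else NA_real_
  z <- qnorm(1 - (1 - conf_level) / 2)
  list(or = or,
       ci_lower = if (finite && !is.na(se)) exp(log(or) - z * se) else NA_real_,
       ci_upper = if (finite && !is.na(se)) exp(log(or) + z * se) else NA_real_,
       finite = finite)
}

#' Welch two-sample t-test (unequal variances)
#'
#' Unpaired two-tailed comparison of two groups of measurements with the
#' Welch statistic and Satterthwaite degrees of freedom, the convention
#' used for replicate assay readouts and age-at-diagnosis comparisons.
#'
#' @param group_a,group_b Numeric vectors, each with at least two values.
#' @return A list with `t`, `df`, `p` (two-sided).
#' @examples
#' welch_t_test(c(1, 2, 3), c(4, 5, 6.5))
#' @export
welch_t_test <- function(group_a, group_b) {
  a <- as.numeric(group_a[!is.na(group_a)])
  b <- as.numeric(group_b[!is.na(group_b)])
  if (length(a) < 2L || length(b) < 2L)
    fv_stop("each group needs at least two non-missing values",
            "famvar_domain_error")
  va <- stats::var(a)
  vb <- stats::var(b)
  if (va == 0 && vb == 0)
    fv_stop("both groups have zero variance; the Welch statistic is undefined",
            "famvar_domain_error")
  na <- length(a)
  nb <- length(b)
  sa <- va / na
  sb <- vb / nb
  t <- (mean(a) - mean(b)) / sqrt(sa + sb)
  df <- (sa + sb)^2 / (sa^2 / (na - 1) + sb^2 / (nb - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}
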