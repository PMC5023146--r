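#' Pearson correlation with two-sided p-value
#'
#' Sample Pearson r with the usual t transform on n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3, finite.
#' @return list with \code{r}, \code{p}, \code{n}.
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("pearson_corr needs equal-length vectors, n >= 3")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("pearson_corr needs finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined-correlation: zero variance")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Unpaired two-sample t-test
#'
#' Equal-variance Student test by default (Welch behind \code{welch = TRUE}).
#' If both groups have zero variance the exact-equality shortcut applies:
#' p = 1 when the means agree, p = 0 otherwise.
#'
#' @param a,b numeric vectors, each length >= 2.
#' @param welch use the Welch (unequal-variance) form.
#' @return list with \code{t}, \code{p}, \code{means}, \code{sds}.
#' @export
unpaired_ttest <- function(a, b, welch = FALSE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  ms <- c(mean(a), mean(b)); ss <- c(stats::sd(a), stats::sd(b))
  if (all(ss == 0)) {
    eq <- isTRUE(all.equal(ms[1], ms[2]))
    return(list(t = if (eq) 0 else Inf * sign(ms[1] - ms[2]),
                p = if (eq) 1 else 0, means = ms, sds = ss))
  }
  tt <- stats::t.test(a, b, var.equal = !welch)
  list(t = unname(tt$statistic), p = tt$p.value, means = ms, sds = ss)
}

#' Paired t-test
#'
#' Two-sided one-sample t on the pairwise differences. Zero-variance
#' differences take the exact-equality shortcut (flagged): p = 1 when all
#' differences are zero, p = 0 for a constant non-zero shift.
#'
#' @param a,b numeric vectors of equal length (pairs).
#' @return list with \code{t}, \code{p}, \code{mean_diff},
#'   \code{degenerate} flag.
#' @export
paired_ttest <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  if (stats::sd(d) < 1e-12 * max(abs(d), 1)) {
    zero <- isTRUE(all.equal(mean(d), 0))
    return(list(t = if (zero) NA_real_ else Inf * sign(mean(d)),
                p = if (zero) 1 else 0, mean_diff = mean(d),
                degenerate = TRUE))
  }
  tt <- stats::t.test(d)
  list(t = unname(tt$statistic), p = tt$p.value, mean_diff = mean(d),
       degenerate = FALSE)
}

#' Random-intercept linear mixed model for paired, clustered comparisons
#'
#' Fits \code{value ~ condition + (1 | patient)} by REML (profiled restricted
#' likelihood over the variance ratio) and reports the fixed condition effect
#' with its Wald p-value. Fits on the variance boundary (between-patient
#' variance estimated 0) are returned with \code{singular = TRUE}; the fixed
#' effect then coincides with the pooled comparison.
#'
#' @param values numeric response (e.g. slice-level wall stress).
#' @param patient patient/cluster identifier.
#' @param condition two-level condition label (e.g. model variant).
#' @return list with \code{estimate}, \code{se}, \code{t}, \code{p} (Wald),
#'   \code{singular}.
#' @export
lme_random_intercept <- function(values, patient, condition) {
  patient <- factor(patient)
  condition <- factor(condition)
  if (nlevels(patient) < 2) stop("need >= 2 patients")
  if (nlevels(condition) != 2) stop("condition must have exactly 2 levels")
  d <- data.frame(y = values, patient = patient, condition = condition)
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(y ~ condition + (1 | patient), data = d, REML = TRUE)))
  co <- summary(fit)$coefficients
  est <- co[2, "Estimate"]; se <- co[2, "Std. Error"]
  tv <- est / se
  list(estimate = unname(est), se = unname(se), t = unname(tv),
       p = 2 * stats::pnorm(-abs(tv)),
       singular = lme4::isSingular(fit, tol = 1e-5))
}

#' Group summary with percent difference
#'
#' Mean and SD of a cohort field per outcome group, the percent difference
#' \code{(mean2 - mean1)/mean1 * 100}, and the unpaired Student t-test
#' p-value. Shapiro-Wilk normality p-values per group are attached for
#' inspection (reported, never gating).
#'
#' @param cohort data.frame with a \code{group} column (values 1/2).
#' @param field column name to summarize.
#' @param welch use the Welch test variant.
#' @return list: \code{mean1}, \code{sd1}, \code{mean2}, \code{sd2},
#'   \code{percent_diff}, \code{p}, \code{normality_p} (length-2).
#' @export
group_summary <- function(cohort, field, welch = FALSE) {
  stopifnot("group" %in% names(cohort), field %in% names(cohort))
  a <- cohort[[field]][cohort$group == 1]
  b <- cohort[[field]][cohort$group == 2]
  tt <- unpaired_ttest(a, b, welch = welch)
  shap <- function(x) if (length(unique(x)) > 3)
    stats::shapiro.test(x)$p.value else NA_real_
  list(mean1 = mean(a), sd1 = stats::sd(a),
       mean2 = mean(b), sd2 = stats::sd(b),
       percent_diff = (mean(b) - mean(a)) / mean(a) * 100,
       p = tt$p, normality_p = c(shap(a), shap(b)))
}
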