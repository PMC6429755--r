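#' Pooled-variance two-sample t test
#'
#' Student's t test with pooled variance and `df = n1 + n2 - 2`, computable
#' either from raw vectors or from (mean, SD, n) summaries. The sign
#' convention is group 1 minus group 2; passing the healthy-control group
#' first reproduces the convention in which a larger IBS mean yields a
#' negative t.
#'
#' @param x,y Raw value vectors (alternative to the summary interface).
#' @param mean_x,sd_x,n_x,mean_y,sd_y,n_y Group summaries.
#' @param welch If `TRUE`, use the Welch (unequal-variance) statistic with
#'   Satterthwaite degrees of freedom instead.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `mean_diff`.
#' @export
#' @examples
#' pooled_t_test(mean_x = 24.4, sd_x = 7.1, n_x = 21,
#'               mean_y = 21.2, sd_y = 7.8, n_y = 65)
pooled_t_test <- function(x = NULL, y = NULL,
                          mean_x = NULL, sd_x = NULL, n_x = NULL,
                          mean_y = NULL, sd_y = NULL, n_y = NULL,
                          welch = FALSE) {
  if (!is.null(x) || !is.null(y)) {
    stopifnot(!is.null(x), !is.null(y))
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    mean_x <- mean(x); sd_x <- sd(x); n_x <- length(x)
    mean_y <- mean(y); sd_y <- sd(y); n_y <- length(y)
  }
  if (n_x < 2 || n_y < 2) abort("both groups need at least 2 observations")
  if (welch) {
    se2x <- sd_x^2 / n_x; se2y <- sd_y^2 / n_y
    se <- sqrt(se2x + se2y)
    if (se == 0) abort("zero variance in both groups: t test undefined")
    df <- (se2x + se2y)^2 / (se2x^2 / (n_x - 1) + se2y^2 / (n_y - 1))
  } else {
    sp2 <- ((n_x - 1) * sd_x^2 + (n_y - 1) * sd_y^2) / (n_x + n_y - 2)
    if (sp2 == 0) abort("zero pooled variance: t test undefined")
    se <- sqrt(sp2) * sqrt(1 / n_x + 1 / n_y)
    df <- n_x + n_y - 2
  }
  tstat <- (mean_x - mean_y) / se
  tibble(statistic = tstat, df = df, p_value = 2 * pt(-abs(tstat), df),
         mean_diff = mean_x - mean_y)
}

#' IBS symptom-severity classification
#'
#' Classifies IBS-SSS scores using the validated cut-offs: below 175 mild,
#' 175 to 300 (inclusive) moderate, above 300 severe.
#'
#' @param score Numeric vector of non-negative IBS-SSS scores.
#' @return A factor with levels `mild`, `moderate`, `severe`.
#' @export
#' @examples
#' classify_severity(c(100, 175, 300, 301))
classify_severity <- function(score) {
  if (any(score < 0, na.rm = TRUE)) abort("IBS-SSS scores must be non-negative")
  cls <- ifelse(score < 175, "mild", ifelse(score <= 300, "moderate", "severe"))
  factor(cls, levels = c("mild", "moderate", "severe"))
}

#' Power of the two-sided correlation test
#'
#' @param r True correlation.
#' @param n Sample size.
#' @param alpha Two-sided significance level.
#' @param method `"fisher-z"`: normal approximation on the Fisher transform
#'   with the second-order mean correction `r / (2(n - 1))`, evaluated at the
#'   exact critical value of the t-based test; `"noncentral-t"`: noncentral-t
#'   power model with `ncp = r * sqrt(n) / sqrt(1 - r^2)`.
#' @return Probability of rejecting the zero-correlation null.
#' @export
#' @examples
#' correlation_power(0.34, 65)
correlation_power <- function(r, n, alpha = 0.05,
                              method = c("fisher-z", "noncentral-t")) {
  method <- match.arg(method)
  stopifnot(n >= 5, alpha > 0, alpha < 1)
  tcrit <- qt(1 - alpha / 2, n - 2)
  if (method == "fisher-z") {
    rcrit <- tcrit / sqrt(tcrit^2 + n - 2)
    mu <- atanh(r) + r / (2 * (n - 1))
    s <- 1 / sqrt(n - 3)
    pnorm((mu - atanh(rcrit)) / s) + pnorm((-mu - atanh(rcrit)) / s)
  } else {
    ncp <- r * sqrt(n) / sqrt(1 - r^2)
    pt(tcrit, n - 2, ncp, lower.tail = FALSE) + pt(-tcrit, n - 2, ncp)
  }
}

#' Minimal detectable correlation at a given power
#'
#' The smallest correlation whose two-sided test at level `alpha` attains the
#' requested power at sample size `n` — the sensitivity of a study design.
#' Monotone decreasing in `n`.
#'
#' @inheritParams correlation_power
#' @param power Target power in (0, 1) (default 0.80).
#' @return The minimal detectable `r`.
#' @export
#' @examples
#' min_detectable_r(65)
#' min_detectable_r(21)
min_detectable_r <- function(n, alpha = 0.05, power = 0.80,
                             method = c("fisher-z", "noncentral-t")) {
  method <- match.arg(method)
  stopifnot(n >= 5, alpha > 0, alpha < 1, power > 0, power < 1)
  f <- function(r) correlation_power(r, n, alpha, method) - power
  hi <- 1 - 1e-9
  if (f(hi) < 0) abort("requested power unattainable at this sample size")
  uniroot(f, c(1e-9, hi), tol = 1e-10)$root
}

#' Variance explained by a correlation
#'
#' Returns `r^2`, with the conventional effect-size thresholds (small 0.10,
#' medium 0.30, large 0.50 — i.e. 1%, 9%, 25% variance explained) attached
#' as an attribute; [effect_size_label()] applies them.
#'
#' @param r Correlation(s) with `|r| <= 1`.
#' @return `r^2`, with a `thresholds` attribute.
#' @export
#' @examples
#' variance_explained(0.5)
#' effect_size_label(c(0.05, 0.2, 0.4, 0.6))
variance_explained <- function(r) {
  if (any(abs(r) > 1, na.rm = TRUE)) abort("|r| must be at most 1")
  structure(r^2, thresholds = c(small = 0.10, medium = 0.30, large = 0.50))
}

#' @rdname variance_explained
#' @export
effect_size_label <- function(r) {
  a <- abs(r)
  cut(a, breaks = c(-Inf, 0.10, 0.30, 0.50, Inf), right = FALSE,
      labels = c("negligible", "small", "medium", "large"))
}

#' Group comparison report for a cohort
#'
#' Produces a Table-2-style summary: per variable, group means, SDs and
#' sample sizes plus the pooled two-sample t test (HC minus IBS).
#'
#' @param table A [cohort_table()].
#' @param variables Variables to summarise; defaults to age plus the
#'   phenotype block.
#' @param welch Use Welch's t instead of the pooled test.
#' @return A tibble: `variable`, `mean_hc`, `sd_hc`, `n_hc`, `mean_ibs`,
#'   `sd_ibs`, `n_ibs`, `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' sim <- simulate_cohort(simulation_config(seed = 2))
#' cohort_report(sim$cohort)
cohort_report <- function(table, variables = NULL, welch = FALSE) {
  blocks <- var_blocks(table)
  variables <- variables %||% c("age", names(blocks)[blocks == "phenotype"])
  rows <- lapply(variables, function(v) {
    x <- table[[v]][table$group == "HC"]
    y <- table[[v]][table$group == "IBS"]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    tt <- pooled_t_test(x = x, y = y, welch = welch)
    tibble(variable = v,
           mean_hc = mean(x), sd_hc = sd(x), n_hc = length(x),
           mean_ibs = mean(y), sd_ibs = sd(y), n_ibs = length(y),
           statistic = tt$statistic, df = tt$df, p_value = tt$p_value)
  })
  list_rbind(rows)
}
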