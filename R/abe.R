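#' Crossover ANOVA on a ln-transformed response
#'
#' Fixed-effects linear model for the 2x2x2 crossover with sequence, subject
#' (nested within sequence), period and treatment effects. Subjects with only
#' one period are excluded with a warning. For complete data the fit reduces
#' to the classical paired contrast: the least-squares mean difference
#' (test - reference) is half the difference of the sequence-wise mean period
#' differences, the mean square error is half the pooled within-sequence
#' variance of the period differences, and `df = n - 2`. `method = "lm"`
#' fits the full fixed-effects model by least squares instead; both paths
#' give identical answers on complete data.
#'
#' @param data Tibble with columns `subject_id`, `sequence` (`"TR"`/`"RT"`),
#'   `period` (1/2), `treatment` (`"T"`/`"R"`) and the response named by
#'   `response` (default `ln_cmax`), one row per subject x period.
#' @param response Name of the response column.
#' @param method `"closed"` (default, complete data) or `"lm"`.
#' @return List with `lsm_diff` (log scale, T - R), `se_diff`, `mse`, `df`
#'   and `n_subjects`.
#' @export
fit_crossover_anova <- function(data, response = "ln_cmax",
                                method = c("closed", "lm")) {
  method <- match.arg(method)
  data <- as_tibble(data)
  data$.y <- data[[response]]
  complete <- data %>%
    group_by(.data$subject_id) %>%
    filter(n() == 2, n_distinct(.data$treatment) == 2,
           n_distinct(.data$period) == 2) %>%
    ungroup()
  dropped <- n_distinct(data$subject_id) - n_distinct(complete$subject_id)
  if (dropped > 0)
    warn(sprintf("%d subject(s) without both periods excluded", dropped))
  n <- n_distinct(complete$subject_id)
  if (n < 3) abort("fewer than 3 complete subjects: ANOVA not estimable")
  if (n_distinct(complete$sequence) < 2)
    abort("both sequences must be present")

  if (method == "lm") {
    fit <- lm(.y ~ sequence + factor(subject_id) + factor(period) + treatment,
              data = complete %>%
                mutate(treatment = factor(.data$treatment,
                                          levels = c("R", "T"))))
    s <- summary(fit)
    co <- s$coefficients["treatmentT", ]
    return(list(lsm_diff = unname(co["Estimate"]),
                se_diff = unname(co["Std. Error"]),
                mse = s$sigma^2, df = fit$df.residual, n_subjects = n))
  }

  d <- complete %>%
    tidyr::pivot_wider(id_cols = c("subject_id", "sequence"),
                       names_from = "period", values_from = ".y",
                       names_prefix = "p") %>%
    mutate(d = .data$p2 - .data$p1)
  by_seq <- d %>%
    group_by(.data$sequence) %>%
    summarise(m = mean(.data$d), ss = sum((.data$d - mean(.data$d))^2),
              k = n(), .groups = "drop")
  m <- setNames(by_seq$m, by_seq$sequence)
  k <- setNames(by_seq$k, by_seq$sequence)
  df <- n - 2
  s2d <- sum(by_seq$ss) / df           # variance of period differences
  mse <- s2d / 2                        # intra-subject (residual) variance
  lsm_diff <- (m[["RT"]] - m[["TR"]]) / 2
  se_diff <- sqrt(s2d / 4 * (1 / k[["TR"]] + 1 / k[["RT"]]))
  list(lsm_diff = lsm_diff, se_diff = se_diff, mse = mse, df = df,
       n_subjects = n)
}

#' Geometric mean ratio and its confidence interval
#'
#' Back-transforms a log-scale least-squares mean difference into the
#' test-to-reference geometric mean ratio (GMR, %) with its two-sided
#' `100 * (1 - 2 * alpha)`% confidence interval
#' `exp(lsm_diff -/+ t(1 - alpha, df) * se_diff) * 100`.
#'
#' @param lsm_diff,se_diff,df Output of [fit_crossover_anova()].
#' @param alpha One-sided significance level (0.05 gives the 90% CI).
#' @return Named list `gmr`, `ci_lower`, `ci_upper`, in percent.
#' @export
gmr_ci <- function(lsm_diff, se_diff, df, alpha = 0.05) {
  stopifnot(df >= 1, se_diff >= 0)
  tcrit <- qt(1 - alpha, df)
  list(gmr = 100 * exp(lsm_diff),
       ci_lower = 100 * exp(lsm_diff - tcrit * se_diff),
       ci_upper = 100 * exp(lsm_diff + tcrit * se_diff))
}

#' Regulatory average-bioequivalence decision
#'
#' TRUE iff the confidence interval lies entirely within the acceptance
#' interval (bounds inclusive), by default \[80.00, 125.00\]%.
#'
#' @param ci_lower,ci_upper CI bounds, percent.
#' @param limits Acceptance interval, percent.
#' @return Logical.
#' @export
abe_decision <- function(ci_lower, ci_upper, limits = c(80, 125)) {
  ci_lower >= limits[1] & ci_upper <= limits[2]
}

#' GMR centrality decision
#'
#' TRUE iff the point estimate of the GMR lies within the tighter centrality
#' range, by default \[90.00, 111.11\]% (bounds inclusive).
#'
#' @param gmr GMR point estimate, percent.
#' @param limits Centrality range, percent.
#' @return Logical.
#' @export
centrality_decision <- function(gmr, limits = c(90, 111.11)) {
  gmr >= limits[1] & gmr <= limits[2]
}

#' Intra-subject CV from the ANOVA mean square error
#'
#' `ISCV% = 100 * sqrt(exp(mse) - 1)`, the exact log-normal relation between
#' the residual variance of the ln-scale crossover ANOVA and the
#' intra-subject coefficient of variation.
#'
#' @param mse Residual mean square on the log scale.
#' @return ISCV, percent.
#' @export
#' @examples
#' iscv_from_mse(log(1.09))  # 30
iscv_from_mse <- function(mse) {
  stopifnot(mse >= 0)
  100 * sqrt(exp(mse) - 1)
}

#' Average bioequivalence analysis of ln(Cmax)
#'
#' Runs the crossover ANOVA on ln(Cmax), forms the GMR and its 90% CI
#' (Schuirmann's two one-sided t-tests at one-sided `alpha`), estimates the
#' intra-subject CV, and applies both the average-bioequivalence decision
#' (CI within `limits`) and the GMR-centrality decision (point estimate
#' within `centrality_limits`).
#'
#' @param data An NCA table from [nca()] (or any tibble with `subject_id`,
#'   `sequence`, `period`, `treatment`, `ln_cmax`), or a raw `be_trial`,
#'   which is passed through [nca()] first.
#' @param alpha One-sided significance level.
#' @param limits Regulatory acceptance interval, percent.
#' @param centrality_limits Centrality range, percent.
#' @param method ANOVA path, see [fit_crossover_anova()].
#' @return Object of class `be_abe`; see [tidy.be_abe()].
#' @export
#' @examples
#' trial <- simulate_trial(pk_model(iov_cv = 20, varying = "V"),
#'                         crossover_design(12), seed = 7)
#' res <- abe(trial)
#' tidy(res)
abe <- function(data, alpha = 0.05, limits = c(80, 125),
                centrality_limits = c(90, 111.11), method = "closed") {
  if (inherits(data, "be_trial") || "conc_ug_l" %in% names(data))
    data <- nca(data)
  fit <- fit_crossover_anova(data, method = method)
  ci <- gmr_ci(fit$lsm_diff, fit$se_diff, fit$df, alpha)
  structure(
    list(gmr = ci$gmr, ci_lower = ci$ci_lower, ci_upper = ci$ci_upper,
         lsm_diff = fit$lsm_diff, se_diff = fit$se_diff,
         mse = fit$mse, df = fit$df, iscv = iscv_from_mse(fit$mse),
         n_subjects = fit$n_subjects, alpha = alpha, limits = limits,
         centrality_limits = centrality_limits,
         decision_abe = abe_decision(ci$ci_lower, ci$ci_upper, limits),
         decision_centrality = centrality_decision(ci$gmr,
                                                   centrality_limits)),
    class = "be_abe"
  )
}

#' @export
print.be_abe <- function(x, ...) {
  cat("<be_abe> average bioequivalence on ln(Cmax)\n")
  cat(sprintf("  GMR %.2f%%  %.0f%% CI [%.2f, %.2f]%%  (n = %d, df = %d)\n",
              x$gmr, 100 * (1 - 2 * x$alpha), x$ci_lower, x$ci_upper,
              x$n_subjects, x$df))
  cat(sprintf("  ISCV %.1f%%  |  ABE within [%.2f, %.2f]%%: %s\n",
              x$iscv, x$limits[1], x$limits[2],
              ifelse(x$decision_abe, "bioequivalent", "not shown")))
  cat(sprintf("  centrality within [%.2f, %.2f]%%: %s\n",
              x$centrality_limits[1], x$centrality_limits[2],
              ifelse(x$decision_centrality, "yes", "no")))
  invisible(x)
}
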