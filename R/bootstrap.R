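#' Power-based resample size for the bootstrap
#'
#' The bootstrap resamples are sized by the exact TOST sample size at the
#' trial's estimated intra-subject CV, assuming a true GMR of 0.90, 80%
#' power and one-sided alpha 0.05. The result is forced even (balanced
#' sequences) with a minimum of 4; no cap is applied even when it exceeds
#' the original trial size, since sampling with replacement permits it.
#'
#' @param iscv Estimated intra-subject CV, percent.
#' @param gmr0 Assumed true ratio for sizing.
#' @param target_power Required power.
#' @param alpha One-sided significance level for sizing.
#' @return Even integer resample size.
#' @export
bootstrap_resample_size <- function(iscv, gmr0 = 0.90, target_power = 0.80,
                                    alpha = 0.05) {
  stopifnot(iscv >= 0)
  n <- tost_sample_size(cv = iscv, gmr = gmr0, alpha = alpha,
                        target_power = target_power)
  max(4L, n + n %% 2L)
}

# Draw resample_n/2 subject ids (with replacement) from each sequence's pool.
draw_resample_ids <- function(pool_tr, pool_rt, resample_n) {
  list(tr = sample(pool_tr, resample_n / 2, replace = TRUE),
       rt = sample(pool_rt, resample_n / 2, replace = TRUE))
}

#' Sequence-balanced subject resampling of a trial
#'
#' Draws `resample_n / 2` subjects with replacement from each sequence's
#' subject pool; each drawn subject contributes both of their periods. Drawn
#' subjects are relabeled as distinct pseudo-subjects so a subject drawn
#' twice enters the fixed-effects ANOVA as two independent subject levels
#' (keeping the design full rank).
#'
#' @param trial Long-format trial tibble ([simulate_trial()]).
#' @param resample_n Total subjects in the resample; an odd value is
#'   incremented by one with a warning.
#' @param seed Optional integer seed.
#' @return A trial tibble with pseudo `subject_id`s 1..`resample_n`.
#' @export
resample_trial <- function(trial, resample_n, seed = NULL) {
  if (resample_n %% 2 != 0) {
    warn("odd resample_n incremented to the next even value")
    resample_n <- resample_n + 1
  }
  subj <- distinct(as_tibble(trial), .data$subject_id, .data$sequence)
  pool_tr <- subj$subject_id[subj$sequence == "TR"]
  pool_rt <- subj$subject_id[subj$sequence == "RT"]
  if (!length(pool_tr) || !length(pool_rt))
    abort("both sequences must be populated")
  with_seed(seed, {
    ids <- draw_resample_ids(pool_tr, pool_rt, resample_n)
    drawn <- c(ids$tr, ids$rt)
    purrr::imap_dfr(drawn, function(id, new_id) {
      as_tibble(trial) %>%
        filter(.data$subject_id == id) %>%
        mutate(subject_id = new_id)
    })
  })
}

#' Bootstrap bioequivalence analysis
#'
#' Non-parametric bioequivalence decision: the original trial's ANOVA yields
#' the estimated ISCV, from which the resample size is derived via exact
#' TOST power at an assumed GMR of 0.90 ([bootstrap_resample_size()]). Then
#' `b` sequence-balanced subject resamples are drawn with replacement, the
#' crossover ANOVA GMR is recomputed on each, and the 95% confidence bounds
#' are the empirical `alpha` and `1 - alpha` percentiles (linear
#' interpolation between order statistics, `quantile type 7`) of the `b`
#' resample GMRs. Bioequivalence is concluded when that percentile interval
#' lies within `limits`. The bootstrap standard error of the GMR is also
#' reported (but plays no part in the decision).
#'
#' Resampling operates on the per-subject NCA table (equivalent to
#' resampling the raw concentration records, since the NCA summary is
#' per-subject) for speed.
#'
#' @param trial Long-format trial tibble, or an [nca()] table.
#' @param b Number of bootstrap resamples.
#' @param alpha Percentile tail probability per side (0.025 gives 95%
#'   bounds).
#' @param seed Optional integer seed.
#' @param limits Acceptance interval, percent.
#' @param gmr0,target_power,size_alpha Resample sizing assumptions, see
#'   [bootstrap_resample_size()].
#' @return Object of class `be_boot` with the resample GMRs, percentile CI
#'   and decision; see [tidy.be_boot()].
#' @export
#' @examples
#' trial <- simulate_trial(pk_model(iov_cv = 20, varying = "V"),
#'                         crossover_design(12), seed = 3)
#' res <- bootstrap_be(trial, seed = 4)
#' glance(res)
bootstrap_be <- function(trial, b = 100, alpha = 0.025, seed = NULL,
                         limits = c(80, 125), gmr0 = 0.90,
                         target_power = 0.80, size_alpha = 0.05) {
  tbl <- if ("conc_ug_l" %in% names(trial)) nca(trial) else as_tibble(trial)
  orig <- abe(tbl)
  resample_n <- bootstrap_resample_size(orig$iscv, gmr0, target_power,
                                        size_alpha)
  # wide per-subject table: one row per subject with both periods' ln(Cmax)
  wide <- tbl %>%
    tidyr::pivot_wider(id_cols = c("subject_id", "sequence"),
                       names_from = "period", values_from = "ln_cmax",
                       names_prefix = "p") %>%
    mutate(d = .data$p2 - .data$p1)
  d_tr <- wide$d[wide$sequence == "TR"]
  d_rt <- wide$d[wide$sequence == "RT"]
  if (!length(d_tr) || !length(d_rt))
    abort("both sequences must be populated")
  half <- resample_n / 2
  gmrs <- with_seed(seed, {
    vapply(seq_len(b), function(i) {
      dt <- sample(d_tr, half, replace = TRUE)
      dr <- sample(d_rt, half, replace = TRUE)
      100 * exp((mean(dr) - mean(dt)) / 2)
    }, numeric(1))
  })
  ci <- unname(quantile(gmrs, c(alpha, 1 - alpha), type = 7))
  structure(
    list(resample_n = resample_n, b = b, gmrs = gmrs,
         ci_lower = ci[1], ci_upper = ci[2],
         se_gmr = sd(gmrs), alpha = alpha, limits = limits,
         iscv = orig$iscv, gmr_original = orig$gmr,
         decision = ci[1] >= limits[1] && ci[2] <= limits[2]),
    class = "be_boot"
  )
}

#' @export
print.be_boot <- function(x, ...) {
  cat("<be_boot> bootstrap bioequivalence\n")
  cat(sprintf(
    "  %d resamples of %d subjects (ISCV %.1f%%), GMR %.2f%%\n",
    x$b, x$resample_n, x$iscv, x$gmr_original))
  cat(sprintf("  percentile %.0f%% CI [%.2f, %.2f]%% -> %s\n",
              100 * (1 - 2 * x$alpha), x$ci_lower, x$ci_upper,
              ifelse(x$decision, "bioequivalent", "not shown")))
  invisible(x)
}
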