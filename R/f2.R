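#' Mean concentration-time profile of a treatment
#'
#' Per-time arithmetic or geometric mean concentration across all subjects
#' receiving the treatment, pooling both sequences. The geometric mean is
#' `exp(mean(log))`, defined as 0 whenever any contributing value is 0 (under
#' this simulator that happens only at the pre-dose sample).
#'
#' @param trial Long-format trial tibble.
#' @param treatment `"T"` or `"R"`.
#' @param mean_type `"geometric"` or `"arithmetic"`.
#' @return Tibble with `time_h` and `conc` (ug/L), plus attributes
#'   `treatment` and `mean_type`.
#' @export
mean_profile <- function(trial, treatment,
                         mean_type = c("geometric", "arithmetic")) {
  mean_type <- match.arg(mean_type)
  sub <- as_tibble(trial) %>% filter(.data$treatment == !!treatment)
  if (n_distinct(sub$subject_id) < 2)
    abort("need at least 2 subjects with the treatment")
  counts <- sub %>% dplyr::count(.data$subject_id)
  if (n_distinct(counts$n) != 1)
    abort("subjects have unequal sampling grids")
  out <- sub %>%
    group_by(.data$time_h) %>%
    summarise(conc = if (mean_type == "arithmetic") mean(.data$conc_ug_l)
              else if (any(.data$conc_ug_l == 0)) 0
              else exp(mean(log(.data$conc_ug_l))),
              .groups = "drop") %>%
    arrange(.data$time_h)
  attr(out, "treatment") <- treatment
  attr(out, "mean_type") <- mean_type
  out
}

#' Normalize mean profiles to the reference mean Cmax
#'
#' The reference mean profile's maximum (`CmaxR`, earliest time on ties
#' giving `tmaxR`) sets the scale: both profiles become
#' `100 * mean_conc / CmaxR` and are truncated to grid points with
#' `0 <= t <= tmaxR` inclusive, so the comparison covers only the absorption
#' phase up to the reference peak.
#'
#' @param ref,test Mean profiles from [mean_profile()], on the same grid.
#' @param include_t0 Keep the t = 0 point (where both normalized values are
#'   0) in the retained vector. Default TRUE.
#' @return List with `times`, `ref_norm`, `test_norm` (percent of CmaxR),
#'   `tmax_ref` (h), `cmax_ref` (ug/L) and `n_points`.
#' @export
normalize_to_reference_cmax <- function(ref, test, include_t0 = TRUE) {
  stopifnot(identical(ref$time_h, test$time_h))
  cmax_ref <- max(ref$conc)
  if (cmax_ref <= 0) abort("all-zero reference mean profile")
  tmax_ref <- ref$time_h[which.max(ref$conc)]
  keep <- ref$time_h <= tmax_ref
  if (!include_t0) keep <- keep & ref$time_h > 0
  list(times = ref$time_h[keep],
       ref_norm = 100 * ref$conc[keep] / cmax_ref,
       test_norm = 100 * test$conc[keep] / cmax_ref,
       tmax_ref = tmax_ref, cmax_ref = cmax_ref,
       n_points = sum(keep))
}

#' f2 similarity factor
#'
#' `f2 = 50 * log10( 100 * (1 + mean((R - T)^2))^(-1/2) )` over paired
#' normalized profile values: 100 when the profiles coincide, decreasing as
#' the mean squared point difference grows (a constant 10-point difference
#' gives ~50, 15 points ~41, 20 points ~35).
#'
#' @param ref_norm,test_norm Equal-length numeric vectors (percent scale).
#' @return The f2 value.
#' @export
#' @examples
#' f2_statistic(rep(100, 5), rep(90, 5))  # 49.89
f2_statistic <- function(ref_norm, test_norm) {
  if (length(ref_norm) != length(test_norm))
    abort("profiles must have equal length")
  stopifnot(length(ref_norm) >= 1)
  msd <- mean((ref_norm - test_norm)^2)
  50 * log10(100 / sqrt(1 + msd))
}

#' f2 cut-off decision
#'
#' TRUE iff `f2 >= cutoff`. The cut-offs 35, 41 and 50 correspond to maximum
#' mean profile differences of 20, 15 and 10 percent respectively.
#'
#' @param f2 The f2 value.
#' @param cutoff Decision threshold.
#' @return Logical.
#' @export
f2_decision <- function(f2, cutoff = 35) f2 >= cutoff

#' f2 similarity analysis of a trial
#'
#' The profile-similarity bioequivalence decision: builds the test and
#' reference mean concentration-time profiles (arithmetic or geometric
#' mean), normalizes both to the reference mean profile's Cmax, truncates at
#' the reference mean tmax, computes the f2 similarity factor over the
#' retained points (t = 0 included by default) and compares it to the
#' cut-off.
#'
#' @param trial Long-format trial tibble.
#' @param mean_type `"geometric"` or `"arithmetic"`.
#' @param cutoff Decision threshold (35, 41 or 50 in practice).
#' @param include_t0 Include the pre-dose point, see
#'   [normalize_to_reference_cmax()].
#' @return Object of class `be_f2`; see [tidy.be_f2()].
#' @export
#' @examples
#' trial <- simulate_trial(pk_model(), crossover_design(12), seed = 5)
#' f2_be(trial, mean_type = "geometric", cutoff = 35)
f2_be <- function(trial, mean_type = c("geometric", "arithmetic"),
                  cutoff = 35, include_t0 = TRUE) {
  mean_type <- match.arg(mean_type)
  ref <- mean_profile(trial, "R", mean_type)
  test <- mean_profile(trial, "T", mean_type)
  nz <- normalize_to_reference_cmax(ref, test, include_t0 = include_t0)
  f2 <- f2_statistic(nz$ref_norm, nz$test_norm)
  structure(
    list(f2 = f2, cutoff = cutoff, decision = f2_decision(f2, cutoff),
         n_points = nz$n_points, tmax_ref = nz$tmax_ref,
         cmax_ref = nz$cmax_ref, mean_type = mean_type,
         times = nz$times, ref_norm = nz$ref_norm,
         test_norm = nz$test_norm),
    class = "be_f2"
  )
}

#' @export
print.be_f2 <- function(x, ...) {
  cat(sprintf("<be_f2> %s-mean f2 similarity\n", x$mean_type))
  cat(sprintf(
    "  f2 = %.2f over %d points up to reference tmax %.2f h (cut-off %g)\n",
    x$f2, x$n_points, x$tmax_ref, x$cutoff))
  cat(sprintf("  decision: %s\n",
              ifelse(x$decision, "similar (bioequivalent)", "not similar")))
  invisible(x)
}
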