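#' Peak concentration and its time
#'
#' Cmax is the maximum observed concentration; tmax the earliest sampling
#' time at which it is attained (ties broken to the earliest time).
#'
#' @param times Sampling times, h.
#' @param conc Observed concentrations, ug/L.
#' @return Named list with `cmax` (ug/L) and `tmax` (h).
#' @export
#' @examples
#' cmax_tmax(c(0, 1, 2), c(0, 10, 10))  # tie -> tmax = 1
cmax_tmax <- function(times, conc) {
  stopifnot(length(times) == length(conc), length(conc) >= 2)
  if (all(conc <= 0)) abort("all-zero profile: no quantifiable peak")
  i <- which.max(conc)
  list(cmax = conc[i], tmax = times[i])
}

#' Area under the curve to the last sampling time
#'
#' Linear-up/log-down trapezoidal rule: segments where the concentration
#' rises (or either endpoint is zero) use the linear trapezoid
#' `(C1 + C2)/2 * dt`; declining segments with both concentrations positive
#' use the logarithmic trapezoid `(C1 - C2) * dt / ln(C1/C2)`, which is exact
#' for a mono-exponential decline. `method = "linear"` forces the plain
#' trapezoid everywhere.
#'
#' @param times Strictly increasing sampling times starting at 0, h.
#' @param conc Concentrations, ug/L (>= 0).
#' @param method `"linuplogdown"` (default) or `"linear"`.
#' @return AUC from time 0 to the last sampling time, ug.h/L.
#' @export
#' @examples
#' auc_last(c(0, 1, 2), c(0, 10, 10))   # 15
#' auc_last(c(0, 1), c(10, 5))          # 5/log(2)
auc_last <- function(times, conc, method = c("linuplogdown", "linear")) {
  method <- match.arg(method)
  stopifnot(length(times) == length(conc))
  if (any(conc < 0)) abort("negative concentration")
  if (times[1] != 0 || any(diff(times) <= 0))
    abort("times must be strictly increasing and start at 0")
  c1 <- conc[-length(conc)]
  c2 <- conc[-1]
  dt <- diff(times)
  lin <- (c1 + c2) / 2 * dt
  if (method == "linear") return(sum(lin))
  logdown <- c1 > c2 & c2 > 0
  seg <- lin
  seg[logdown] <- (c1[logdown] - c2[logdown]) * dt[logdown] /
    log(c1[logdown] / c2[logdown])
  sum(seg)
}

#' Non-compartmental summary of a trial
#'
#' Computes Cmax, tmax and AUC to the last sampling time for every
#' subject x period concentration-time profile of a long-format trial.
#'
#' @param trial Trial tibble with columns `subject_id`, `sequence`, `period`,
#'   `treatment`, `time_h`, `conc_ug_l` ([simulate_trial()] or
#'   [read_trial_csv()]).
#' @param auc_method Passed to [auc_last()].
#' @return Tibble with one row per subject x period: design labels plus
#'   `cmax`, `tmax`, `auc_last` and `ln_cmax`.
#' @export
#' @examples
#' trial <- simulate_trial(pk_model(), crossover_design(12), seed = 1)
#' nca(trial)
nca <- function(trial, auc_method = "linuplogdown") {
  trial %>%
    as_tibble() %>%
    group_by(.data$subject_id, .data$sequence, .data$period,
             .data$treatment) %>%
    arrange(.data$time_h, .by_group = TRUE) %>%
    summarise(
      cmax = max(.data$conc_ug_l),
      tmax = .data$time_h[which.max(.data$conc_ug_l)],
      auc_last = auc_last(.data$time_h, .data$conc_ug_l,
                          method = auc_method),
      .groups = "drop"
    ) %>%
    mutate(ln_cmax = log(.data$cmax))
}
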