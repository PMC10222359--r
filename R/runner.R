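#' Default variability scenario grid
#'
#' The six IIV/IOV levels applied separately to each structural parameter:
#' a shared baseline (no variability) plus 30/0, 30/10, 30/20, 30/30 and
#' 0/45 percent IIV/IOV on each of ka, V and ke — 16 scenario rows in all.
#'
#' @return Tibble with columns `parameter`, `iiv`, `iov`.
#' @export
default_scenarios <- function() {
  levels <- tibble(iiv = c(30, 30, 30, 30, 0), iov = c(0, 10, 20, 30, 45))
  bind_rows(
    tibble(parameter = "none", iiv = 0, iov = 0),
    tidyr::crossing(parameter = c("ka", "V", "ke"), levels)
  )
}

#' Experiment plan for the full simulation study
#'
#' Describes the complete grid: variability scenarios x truth groups (test
#' ka multiplier 1.0 = truly bioequivalent, 0.3 = truly bioinequivalent) x
#' sample sizes x replicate trials, the decision methods to apply, and the
#' master seed from which every trial's sub-seed is derived (so cells can be
#' run in any order with identical results). The default plan is the full
#' study: 2 truth groups x 16 scenarios x 10 sample sizes x 100 replicates
#' = 32,000 trials.
#'
#' @param scenarios Scenario tibble ([default_scenarios()]).
#' @param truth_multipliers Test ka multipliers defining the truth groups.
#' @param n_grid Even sample sizes.
#' @param reps Trials per cell.
#' @param methods Decision methods, subset of `"abe"`, `"centrality"`,
#'   `"bootstrap"`, `"f2_amean"`, `"f2_gmean"`.
#' @param cutoffs f2 cut-offs to evaluate.
#' @param residual_cv Residual error, percent.
#' @param master_seed Integer master seed.
#' @return Object of class `be_plan`.
#' @export
experiment_plan <- function(scenarios = default_scenarios(),
                            truth_multipliers = c(1.0, 0.3),
                            n_grid = seq(12, 30, by = 2), reps = 100,
                            methods = c("abe", "centrality", "bootstrap",
                                        "f2_amean", "f2_gmean"),
                            cutoffs = c(35, 41, 50), residual_cv = 10,
                            master_seed = 20230507) {
  stopifnot(nrow(scenarios) >= 1, reps >= 1, all(n_grid %% 2 == 0))
  methods <- match.arg(methods, several.ok = TRUE)
  structure(
    list(scenarios = scenarios, truth_multipliers = truth_multipliers,
         n_grid = n_grid, reps = reps, methods = methods,
         cutoffs = cutoffs, residual_cv = residual_cv,
         master_seed = as.integer(master_seed)),
    class = "be_plan"
  )
}

#' @export
print.be_plan <- function(x, ...) {
  cells <- nrow(x$scenarios) * length(x$truth_multipliers) * length(x$n_grid)
  cat(sprintf(
    "<be_plan> %d cells x %d reps = %d trials; methods: %s; seed %d\n",
    cells, x$reps, cells * x$reps, paste(x$methods, collapse = ", "),
    x$master_seed))
  invisible(x)
}

param_code <- function(parameter) {
  match(parameter, c("none", "ka", "V", "ke"))
}

#' Run one experiment cell
#'
#' Simulates `reps` trials for one scenario x truth group x sample size
#' combination (each trial from a deterministic sub-seed of `master_seed`),
#' computes the Cmax NCA once per trial, and applies the requested decision
#' methods. Bioequivalence is evaluated on Cmax only.
#'
#' @param parameter Varying parameter: `"none"`, `"ka"`, `"V"` or `"ke"`.
#' @param iiv,iov Variability levels, percent.
#' @param multiplier Test ka multiplier (1 = truly bioequivalent).
#' @param n Total subjects.
#' @param reps Number of replicate trials.
#' @param methods,cutoffs,residual_cv,master_seed See [experiment_plan()].
#' @return Tibble with one row per trial x method (x cutoff for f2):
#'   scenario labels, `truth`, `n`, `rep`, `method`, `cutoff`, the method's
#'   `statistic` (GMR in percent, or the f2 value) and logical `decision`.
#' @export
run_cell <- function(parameter, iiv, iov, multiplier, n, reps = 100,
                     methods = c("abe", "centrality", "bootstrap",
                                 "f2_amean", "f2_gmean"),
                     cutoffs = c(35, 41, 50), residual_cv = 10,
                     master_seed = 20230507) {
  model <- pk_model(iiv_cv = iiv, iov_cv = iov, residual_cv = residual_cv,
                    varying = if (parameter == "none") "none" else parameter,
                    test_ka_multiplier = multiplier)
  design <- crossover_design(n)
  truth <- multiplier == 1
  purrr::map_dfr(seq_len(reps), function(r) {
    seed <- derive_seed(master_seed, param_code(parameter), iiv, iov,
                        round(100 * multiplier), n, r)
    trial <- simulate_trial(model, design, seed = seed)
    tbl <- nca(trial)
    rows <- list()
    if (any(c("abe", "centrality") %in% methods)) {
      a <- abe(tbl)
      if ("abe" %in% methods)
        rows$abe <- tibble(method = "abe", cutoff = NA_real_,
                           statistic = a$gmr, decision = a$decision_abe)
      if ("centrality" %in% methods)
        rows$cent <- tibble(method = "centrality", cutoff = NA_real_,
                            statistic = a$gmr,
                            decision = a$decision_centrality)
    }
    if ("bootstrap" %in% methods) {
      bt <- bootstrap_be(tbl, seed = derive_seed(seed, 1))
      rows$boot <- tibble(method = "bootstrap", cutoff = NA_real_,
                          statistic = bt$gmr_original,
                          decision = bt$decision)
    }
    for (m in intersect(c("f2_amean", "f2_gmean"), methods)) {
      mt <- if (m == "f2_amean") "arithmetic" else "geometric"
      fr <- f2_be(trial, mean_type = mt, cutoff = min(cutoffs))
      rows[[m]] <- tibble(method = m, cutoff = cutoffs,
                          statistic = fr$f2,
                          decision = fr$f2 >= cutoffs)
    }
    bind_rows(rows) %>%
      mutate(parameter = parameter, iiv = iiv, iov = iov, truth = truth,
             n = n, rep = r, .before = 1)
  })
}

#' Run a full experiment plan
#'
#' Executes [run_cell()] for every scenario x truth group x sample size of
#' the plan and binds the per-trial decisions.
#'
#' @param plan An [experiment_plan()].
#' @param progress Print one line per cell to standard error.
#' @return Long decisions tibble (see [run_cell()]).
#' @export
run_experiment <- function(plan, progress = FALSE) {
  stopifnot(inherits(plan, "be_plan"))
  cells <- tidyr::crossing(plan$scenarios,
                           multiplier = plan$truth_multipliers,
                           n = plan$n_grid)
  purrr::pmap_dfr(cells, function(parameter, iiv, iov, multiplier, n) {
    if (progress)
      message(sprintf("cell: %s IIV %g IOV %g mult %g n %d",
                      parameter, iiv, iov, multiplier, n))
    run_cell(parameter, iiv, iov, multiplier, n, reps = plan$reps,
             methods = plan$methods, cutoffs = plan$cutoffs,
             residual_cv = plan$residual_cv,
             master_seed = plan$master_seed)
  })
}

#' Summarize experiment decisions into performance statistics
#'
#' For every scenario x sample size x method (x cutoff), cross-tabulates the
#' decisions of the two truth groups into a confusion matrix and derives the
#' performance statistics ([confusion_stats()]). Cells missing one truth
#' group are skipped with a warning.
#'
#' @param decisions Output of [run_experiment()] or [run_cell()] (both truth
#'   groups bound together).
#' @return Tibble with one row per scenario x n x method x cutoff: counts
#'   plus the eight statistics in percent.
#' @export
summarize_experiment <- function(decisions) {
  grouped <- decisions %>%
    group_by(.data$parameter, .data$iiv, .data$iov, .data$n, .data$method,
             .data$cutoff)
  bad <- grouped %>%
    summarise(ok = n_distinct(.data$truth) == 2, .groups = "drop") %>%
    filter(!.data$ok)
  if (nrow(bad) > 0)
    warn(sprintf("%d cell(s) missing a truth group were skipped", nrow(bad)))
  grouped %>%
    summarise(
      ok = n_distinct(.data$truth) == 2,
      confusion_stats(confusion_counts(.data$truth, .data$decision)),
      .groups = "drop") %>%
    filter(.data$ok) %>%
    select(-"ok")
}

#' Format a low-high range for summary tables
#'
#' @param lo,hi Statistics at the smallest and largest sample size.
#' @param digits Significant digits.
#' @return Character, `"lo-hi"` (en dash) or a single value when equal.
#' @export
format_range <- function(lo, hi, digits = 3) {
  f <- function(x) formatC(signif(x, digits), format = "fg")
  ifelse(f(lo) == f(hi), f(lo), paste0(f(lo), "–", f(hi)))
}

#' Range-formatted summary table over the sample-size grid
#'
#' Mirrors the conventional reporting layout: for each scenario x method (x cutoff), each
#' statistic is shown as the `min(n_grid)`-to-`max(n_grid)` range.
#'
#' @param summary Output of [summarize_experiment()].
#' @param digits Significant digits for formatting.
#' @return Tibble of formatted ranges.
#' @export
summarize_ranges <- function(summary, digits = 3) {
  stats <- c("sensitivity", "specificity", "precision", "npv",
             "accuracy", "f1", "mcc", "kappa")
  lohi <- summary %>%
    filter(.data$n %in% range(.data$n)) %>%
    arrange(.data$n)
  lohi %>%
    group_by(.data$parameter, .data$iiv, .data$iov, .data$method,
             .data$cutoff) %>%
    summarise(dplyr::across(dplyr::all_of(stats),
                            ~ format_range(dplyr::first(.x),
                                           dplyr::last(.x), digits)),
              .groups = "drop")
}

#' Smallest sample size reaching a target empirical sensitivity
#'
#' Scans the sample-size grid of a summarized experiment for the first n at
#' which a method's empirical sensitivity reaches the target; when the grid
#' never reaches it, returns the sentinel `">max"` (e.g. `">30"`).
#'
#' @param summary Output of [summarize_experiment()].
#' @param method Method name (and `cutoff` for the f2 methods).
#' @param parameter,iiv,iov Scenario selector.
#' @param cutoff f2 cut-off selector (ignored otherwise).
#' @param target Target sensitivity, percent.
#' @return Character: the sample size, or the `">max"` sentinel.
#' @export
empirical_sample_size <- function(summary, method, parameter, iiv, iov,
                                  cutoff = NA, target = 80) {
  rows <- summary %>%
    filter(.data$method == !!method, .data$parameter == !!parameter,
           .data$iiv == !!iiv, .data$iov == !!iov,
           (is.na(cutoff) & is.na(.data$cutoff)) |
             (!is.na(cutoff) & .data$cutoff %in% cutoff)) %>%
    arrange(.data$n)
  if (nrow(rows) == 0) abort("no matching cells in the summary")
  hit <- rows$n[rows$sensitivity >= target]
  if (length(hit)) as.character(hit[1]) else paste0(">", max(rows$n))
}
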