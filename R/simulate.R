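# Seeded RNG helper: run code under a local seed without disturbing the
# caller's RNG stream. A NULL seed uses the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed from a master seed and integer keys, kept below
# 2^31 so it is a valid set.seed() argument. Order-dependent LCG hash.
derive_seed <- function(master_seed, ...) {
  m <- 2147483629
  x <- (abs(as.numeric(master_seed)) + 1) %% m
  for (k in c(...)) {
    x <- (x * 69069 + abs(as.numeric(k)) * 7919 + 1) %% m
  }
  as.integer(x)
}

#' Balanced block-wise randomization of sequences
#'
#' Assigns subjects to the two crossover sequences (TR, RT) in blocks of two:
#' each consecutive pair of subjects receives one TR and one RT assignment in
#' random within-block order, so allocation is exactly balanced for any even
#' `n_subjects`.
#'
#' @param n_subjects Even number of subjects.
#' @param seed Optional integer seed for reproducible assignment.
#' @return Tibble with columns `subject_id` and `sequence` (`"TR"`/`"RT"`).
#' @export
#' @examples
#' randomize_sequences(12, seed = 1)
randomize_sequences <- function(n_subjects, seed = NULL) {
  if (n_subjects %% 2 != 0) abort("n_subjects must be even")
  with_seed(seed, {
    blocks <- replicate(n_subjects / 2, sample(c("TR", "RT")))
    tibble(subject_id = seq_len(n_subjects), sequence = as.vector(blocks))
  })
}

treatment_for <- function(sequence, period) {
  ifelse(substr(sequence, period, period) == "T", "T", "R")
}

#' Draw individual pharmacokinetic parameters
#'
#' Realizes per-subject, per-occasion parameters from the population model.
#' For the varying parameter P, the realized value is
#' `P_mean * exp(eta_i + kappa_ij)` with `eta_i ~ N(0, omega^2)` drawn once
#' per subject and `kappa_ij ~ N(0, gamma^2)` redrawn per occasion (period);
#' all other parameters stay at their population means, and bioavailability
#' never varies. For the test treatment the mean ka is first multiplied by
#' `test_ka_multiplier`.
#'
#' @param model A [pk_model()].
#' @param design A [crossover_design()].
#' @param assignment Sequence assignment as returned by
#'   [randomize_sequences()]; generated internally when `NULL`.
#' @param seed Optional integer seed.
#' @return Tibble with one row per subject x period: `subject_id`,
#'   `sequence`, `period`, `treatment`, and realized `ka`, `v`, `ke`, `f`.
#' @export
draw_individual_parameters <- function(model, design, assignment = NULL,
                                       seed = NULL) {
  stopifnot(inherits(model, "pk_model"), inherits(design, "crossover_design"))
  with_seed(seed, {
    if (is.null(assignment))
      assignment <- randomize_sequences(design$n_subjects)
    n <- nrow(assignment)
    omega <- model$iiv_cv / 100
    gamma <- model$iov_cv / 100
    eta <- rnorm(n, 0, omega)
    kappa <- matrix(rnorm(2 * n, 0, gamma), nrow = n) # columns = periods
    out <- tidyr::crossing(assignment, period = 1:2) %>%
      arrange(.data$subject_id, .data$period) %>%
      mutate(
        treatment = treatment_for(.data$sequence, .data$period),
        ka = model$ka *
          ifelse(.data$treatment == "T", model$test_ka_multiplier, 1),
        v = model$v, ke = model$ke, f = model$f
      )
    if (model$varying != "none") {
      re <- exp(eta[out$subject_id] +
                  kappa[cbind(out$subject_id, out$period)])
      col <- c(ka = "ka", V = "v", ke = "ke")[[model$varying]]
      out[[col]] <- out[[col]] * re
    }
    out
  })
}

#' Noise-free concentration-time profile (Bateman equation)
#'
#' Closed-form solution of the one-compartment model with first-order
#' absorption and elimination:
#' `C(t) = F * dose * 1000 * ka / (V * (ka - ke)) * (exp(-ke t) - exp(-ka t))`
#' in ug/L for a dose in mg and V in L. When `ka == ke` (within a relative
#' tolerance) the analytic limit `F * dose * 1000 * ka * t * exp(-ka t) / V`
#' is used instead of dividing by zero.
#'
#' @param times Sampling times, h (>= 0).
#' @param ka,v,ke,f Individual parameter values.
#' @param dose Dose, mg.
#' @return Numeric vector of concentrations, ug/L; exactly 0 at `t = 0`.
#' @export
#' @examples
#' predict_concentration(be_sampling_times(), ka = 1.22, v = 58.8, ke = 0.15,
#'                       f = 0.9, dose = 50)
predict_concentration <- function(times, ka, v, ke, f, dose) {
  stopifnot(all(times >= 0), ka > 0, v > 0, ke > 0)
  scale <- f * dose * 1000 / v  # mg -> ug
  if (abs(ka - ke) < 1e-10 * ka) {
    conc <- scale * ka * times * exp(-ka * times)
  } else {
    conc <- scale * ka / (ka - ke) * (exp(-ke * times) - exp(-ka * times))
  }
  conc[times == 0] <- 0
  pmax(conc, 0)
}

#' Apply multiplicative log-normal residual error
#'
#' Observed concentrations are `Y = C * exp(eps)` with
#' `eps ~ N(0, (residual_cv/100)^2)` drawn independently per sample. Zero
#' (pre-dose) concentrations remain exactly zero: the error model is
#' multiplicative.
#'
#' @param conc Noise-free concentrations, ug/L (>= 0).
#' @param residual_cv Residual error, percent.
#' @param seed Optional integer seed.
#' @return Noisy concentrations, ug/L.
#' @export
apply_residual_error <- function(conc, residual_cv, seed = NULL) {
  stopifnot(all(conc >= 0), residual_cv >= 0)
  if (residual_cv == 0) return(conc)
  with_seed(seed, {
    out <- conc * exp(rnorm(length(conc), 0, residual_cv / 100))
    out[conc == 0] <- 0
    out
  })
}

#' Simulate one 2x2x2 crossover bioequivalence trial
#'
#' Composes sequence randomization, individual parameter realization, the
#' closed-form concentration model and the residual error model into a
#' long-format trial dataset: one row per subject x period x sampling time.
#' There is no carryover between periods.
#'
#' @param model A [pk_model()].
#' @param design A [crossover_design()].
#' @param seed Optional integer seed; the whole trial is reproducible from it.
#' @return A tibble of class `be_trial` with columns `subject_id`, `sequence`,
#'   `period`, `treatment`, `time_h`, `conc_ug_l` and attributes `truth`
#'   (`"bioequivalent"` or `"bioinequivalent"`, from the ka multiplier),
#'   `seed`, `model` and `design`.
#' @export
#' @examples
#' trial <- simulate_trial(pk_model(), crossover_design(12), seed = 42)
#' dplyr::count(trial, treatment)
simulate_trial <- function(model, design = crossover_design(), seed = NULL) {
  stopifnot(inherits(model, "pk_model"), inherits(design, "crossover_design"))
  with_seed(seed, {
    assignment <- randomize_sequences(design$n_subjects)
    params <- draw_individual_parameters(model, design, assignment)
    times <- design$sampling_times
    recs <- params %>%
      mutate(profile = purrr::pmap(
        list(.data$ka, .data$v, .data$ke, .data$f),
        function(ka, v, ke, f) {
          conc <- predict_concentration(times, ka, v, ke, f, model$dose)
          tibble(time_h = times,
                 conc_ug_l = apply_residual_error(conc, model$residual_cv))
        })) %>%
      select("subject_id", "sequence", "period", "treatment", "profile") %>%
      tidyr::unnest("profile")
    structure(
      recs,
      truth = if (model$test_ka_multiplier == 1) "bioequivalent"
              else "bioinequivalent",
      seed = seed, model = model, design = design,
      class = c("be_trial", class(recs))
    )
  })
}

#' Truth label of a simulated trial
#'
#' @param trial A `be_trial` as returned by [simulate_trial()].
#' @return `"bioequivalent"` or `"bioinequivalent"`.
#' @export
trial_truth <- function(trial) attr(trial, "truth")

#' Write / read a trial as long-format CSV
#'
#' Columns `subject_id`, `sequence`, `period`, `treatment`, `time_h`,
#' `conc_ug_l`, with a header and `.` decimal separator, so externally
#' collected concentration data can be analysed with the same functions.
#'
#' @param trial Trial tibble (at least the six standard columns).
#' @param path File path.
#' @return `read_trial_csv()` returns a tibble; `write_trial_csv()` returns
#'   `path` invisibly.
#' @export
write_trial_csv <- function(trial, path) {
  cols <- c("subject_id", "sequence", "period", "treatment",
            "time_h", "conc_ug_l")
  write.csv(as.data.frame(trial)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "sequence", "period", "treatment",
            "time_h", "conc_ug_l")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort(paste("missing columns:", paste(miss, collapse = ", ")))
  as_tibble(df)
}
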