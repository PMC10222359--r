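#' Default 20-point plasma sampling schedule
#'
#' The fixed sampling grid used throughout the simulator: a pre-dose sample at
#' time 0 and 19 post-dose samples out to 24 h, dense around the expected
#' absorption peak (note there is no 1.25 h sample).
#'
#' @return Numeric vector of 20 strictly increasing times in hours, starting
#'   at 0.
#' @export
#' @examples
#' be_sampling_times()
be_sampling_times <- function() {
  c(0, 0.25, 0.50, 0.75, 1.00, 1.50, 1.75, 2.00, 2.25, 2.50,
    2.75, 3.00, 3.25, 3.50, 3.75, 4.00, 6.00, 8.00, 12.00, 24.00)
}

#' Population pharmacokinetic model specification
#'
#' Describes the one-compartment first-order absorption/elimination model
#' used to simulate plasma concentration-time profiles, together with the
#' statistical model: log-normal inter-individual (IIV) and inter-occasion
#' (IOV) random effects applied to exactly one structural parameter at a
#' time, and a multiplicative log-normal residual error on each observed
#' concentration. A covariate effect on the test product's absorption rate
#' constant (`test_ka_multiplier`) encodes true bioinequivalence: 1 gives a
#' truly bioequivalent test product, 0.3 a truly bioinequivalent one.
#'
#' Variability convention: the stated percentages are used directly as the
#' standard deviations of the log-scale random effects, i.e. omega = iiv_cv /
#' 100, gamma = iov_cv / 100 and sigma = residual_cv / 100.
#'
#' @param ka Typical absorption rate constant, 1/h.
#' @param v Typical apparent volume of distribution, L.
#' @param ke Typical elimination rate constant, 1/h.
#' @param f Absolute bioavailability, fraction in (0, 1]. No variability is
#'   ever applied to `f`.
#' @param dose Administered single oral dose, mg.
#' @param iiv_cv Inter-individual variability, percent.
#' @param iov_cv Inter-occasion variability, percent.
#' @param residual_cv Residual (experimental) error, percent.
#' @param varying Which parameter carries the IIV/IOV random effects: one of
#'   `"none"`, `"ka"`, `"V"`, `"ke"`.
#' @param test_ka_multiplier Multiplier on the test product's mean ka.
#' @return An object of class `pk_model`.
#' @export
#' @examples
#' pk_model()                               # baseline, truly bioequivalent
#' pk_model(iov_cv = 45, varying = "V")     # high inter-occasion variability
#' pk_model(test_ka_multiplier = 0.3)       # truly bioinequivalent test
pk_model <- function(ka = 1.22, v = 58.8, ke = 0.15, f = 0.9, dose = 50,
                     iiv_cv = 0, iov_cv = 0, residual_cv = 10,
                     varying = c("none", "ka", "V", "ke"),
                     test_ka_multiplier = 1) {
  varying <- match.arg(varying)
  stopifnot(ka > 0, v > 0, ke > 0, dose > 0, f > 0, f <= 1,
            test_ka_multiplier > 0)
  if (iiv_cv < 0 || iov_cv < 0 || residual_cv < 0)
    abort("variability CVs must be >= 0")
  structure(
    list(ka = ka, v = v, ke = ke, f = f, dose = dose,
         iiv_cv = iiv_cv, iov_cv = iov_cv, residual_cv = residual_cv,
         varying = varying, test_ka_multiplier = test_ka_multiplier),
    class = "pk_model"
  )
}

#' @export
print.pk_model <- function(x, ...) {
  cat("<pk_model> one-compartment, first-order absorption/elimination\n")
  cat(sprintf("  ka %.3g 1/h, V %.3g L, ke %.3g 1/h, F %.2g, dose %.3g mg\n",
              x$ka, x$v, x$ke, x$f, x$dose))
  cat(sprintf("  IIV %g%% / IOV %g%% on '%s'; residual CV %g%%\n",
              x$iiv_cv, x$iov_cv, x$varying, x$residual_cv))
  cat(sprintf("  test ka multiplier %g (%s)\n", x$test_ka_multiplier,
              if (x$test_ka_multiplier == 1) "truly bioequivalent"
              else "truly bioinequivalent"))
  invisible(x)
}

#' 2x2x2 crossover trial design
#'
#' Two sequences (TR: test then reference; RT: reference then test), two
#' treatments, two periods, equal allocation of an even number of subjects.
#' The washout is stored as metadata only: the simulation model carries no
#' carryover, sequence or period effects.
#'
#' @param n_subjects Even total number of subjects (>= 4).
#' @param sampling_times Strictly increasing sampling grid starting at 0.
#' @param washout_days Washout between periods, days (metadata).
#' @return An object of class `crossover_design`.
#' @export
crossover_design <- function(n_subjects = 12,
                             sampling_times = be_sampling_times(),
                             washout_days = 7) {
  if (n_subjects < 4 || n_subjects %% 2 != 0)
    abort("n_subjects must be an even number >= 4")
  if (sampling_times[1] != 0 || any(diff(sampling_times) <= 0))
    abort("sampling_times must be strictly increasing and start at 0")
  structure(
    list(n_subjects = as.integer(n_subjects),
         sampling_times = as.numeric(sampling_times),
         washout_days = washout_days,
         sequences = c("TR", "RT")),
    class = "crossover_design"
  )
}

#' @export
print.crossover_design <- function(x, ...) {
  cat(sprintf(
    "<crossover_design> 2x2x2, %d subjects, %d samples/profile, washout %g d\n",
    x$n_subjects, length(x$sampling_times), x$washout_days))
  invisible(x)
}

#' Read a scenario configuration file
#'
#' Reads a declarative key-value description of a simulation scenario and
#' returns the corresponding model and design. YAML files (`.yaml`/`.yml`)
#' are parsed with the yaml package; otherwise lines of `key = value` (or
#' `key: value`) pairs are accepted. Recognised keys are the arguments of
#' [pk_model()] and [crossover_design()] (`sampling_times` may be a
#' comma-separated list).
#'
#' @param path Path to the configuration file.
#' @return List with elements `model` (`pk_model`) and `design`
#'   (`crossover_design`).
#' @export
read_scenario <- function(path) {
  if (grepl("\\.ya?ml$", path) && requireNamespace("yaml", quietly = TRUE)) {
    kv <- yaml::read_yaml(path)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    parts <- strsplit(lines, "[=:]", fixed = FALSE)
    kv <- lapply(parts, function(p) trimws(paste(p[-1], collapse = ":")))
    names(kv) <- vapply(parts, function(p) trimws(p[1]), "")
    kv <- lapply(kv, function(v) {
      num <- suppressWarnings(as.numeric(strsplit(v, ",")[[1]]))
      if (anyNA(num)) v else num
    })
  }
  marg <- intersect(names(kv), names(formals(pk_model)))
  darg <- intersect(names(kv), names(formals(crossover_design)))
  list(model = do.call(pk_model, kv[marg]),
       design = do.call(crossover_design, kv[darg]))
}
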