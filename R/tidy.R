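#' Tidy an average-bioequivalence result
#'
#' @param x A `be_abe` object from [abe()].
#' @param ... Unused.
#' @return One-row tibble with the GMR, CI bounds, ANOVA quantities, ISCV
#'   and both decisions.
#' @export
tidy.be_abe <- function(x, ...) {
  tibble(gmr = x$gmr, ci_lower = x$ci_lower, ci_upper = x$ci_upper,
         lsm_diff = x$lsm_diff, se_diff = x$se_diff, mse = x$mse,
         df = x$df, iscv = x$iscv, n_subjects = x$n_subjects,
         decision_abe = x$decision_abe,
         decision_centrality = x$decision_centrality)
}

#' @rdname tidy.be_abe
#' @export
glance.be_abe <- function(x, ...) tidy.be_abe(x, ...)

#' Tidy a bootstrap bioequivalence result
#'
#' `tidy()` returns the per-resample GMRs; `glance()` the one-row summary.
#'
#' @param x A `be_boot` object from [bootstrap_be()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.be_boot <- function(x, ...) {
  tibble(resample = seq_along(x$gmrs), gmr = x$gmrs)
}

#' @rdname tidy.be_boot
#' @export
glance.be_boot <- function(x, ...) {
  tibble(gmr_original = x$gmr_original, iscv = x$iscv,
         resample_n = x$resample_n, b = x$b,
         ci_lower = x$ci_lower, ci_upper = x$ci_upper, se_gmr = x$se_gmr,
         decision = x$decision)
}

#' Tidy an f2 similarity result
#'
#' `tidy()` returns the retained normalized profile points; `glance()` the
#' one-row summary.
#'
#' @param x A `be_f2` object from [f2_be()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.be_f2 <- function(x, ...) {
  tibble(time_h = x$times, ref_norm = x$ref_norm, test_norm = x$test_norm)
}

#' @rdname tidy.be_f2
#' @export
glance.be_f2 <- function(x, ...) {
  tibble(f2 = x$f2, cutoff = x$cutoff, decision = x$decision,
         n_points = x$n_points, tmax_ref = x$tmax_ref,
         cmax_ref = x$cmax_ref, mean_type = x$mean_type)
}

#' Plot a simulated trial's concentration-time profiles
#'
#' Spaghetti plot of individual profiles, faceted by treatment.
#'
#' @param object A `be_trial` tibble from [simulate_trial()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.be_trial <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$time_h, .data$conc_ug_l,
                               group = .data$subject_id)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::facet_wrap(~treatment,
                        labeller = ggplot2::as_labeller(
                          c(R = "Reference", T = "Test"))) +
    ggplot2::labs(x = "Time (h)", y = "Concentration (µg/L)") +
    ggplot2::theme_minimal()
}

#' Plot the normalized mean profiles behind an f2 result
#'
#' @param object A `be_f2` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.be_f2 <- function(object, ...) {
  df <- tidy.be_f2(object) %>%
    tidyr::pivot_longer(c("ref_norm", "test_norm"),
                        names_to = "product", values_to = "norm") %>%
    mutate(product = ifelse(.data$product == "ref_norm",
                            "Reference", "Test"))
  ggplot2::ggplot(df, ggplot2::aes(.data$time_h, .data$norm,
                                   colour = .data$product)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "Time (h)", y = "% of reference mean Cmax",
                  colour = NULL,
                  subtitle = sprintf("f2 = %.1f (cut-off %g)",
                                     object$f2, object$cutoff)) +
    ggplot2::theme_minimal()
}

#' Sensitivity (or any statistic) versus sample size
#'
#' Operating-characteristic plot of a summarized experiment: one line per
#' method across the sample-size grid, faceted by scenario.
#'
#' @param summary Output of [summarize_experiment()].
#' @param statistic Column to plot (default `"sensitivity"`).
#' @return A ggplot.
#' @export
plot_operating_characteristics <- function(summary,
                                           statistic = "sensitivity") {
  df <- summary %>%
    mutate(method_label = ifelse(is.na(.data$cutoff), .data$method,
                                 paste0(.data$method, "(", .data$cutoff,
                                        ")")),
           scenario = paste0(.data$parameter, " ", .data$iiv, "/",
                             .data$iov))
  ggplot2::ggplot(df, ggplot2::aes(.data$n, .data[[statistic]],
                                   colour = .data$method_label)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~scenario) +
    ggplot2::labs(x = "Number of subjects", y = paste0(statistic, " (%)"),
                  colour = "method") +
    ggplot2::theme_minimal()
}
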