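#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an MS3 decision table into one row per target
#'
#' @param x an `ms3_decisions` tibble.
#' @param ... unused.
#' @return tibble: `scan_id`, `target_mz`, `target_charge`, `doublet_rank`,
#'   `second_peptide_mass`.
#' @method tidy ms3_decisions
#' @export
tidy.ms3_decisions <- function(x, ...) tidy_targets(x)

#' One-row summary of an MS3 decision table
#'
#' @param x an `ms3_decisions` tibble.
#' @param ... unused.
#' @return tibble: `n_scans`, `n_triggered`, `trigger_rate`,
#'   `mean_targets_per_scan`.
#' @method glance ms3_decisions
#' @export
glance.ms3_decisions <- function(x, ...) {
  tibble::tibble(
    n_scans = nrow(x),
    n_triggered = sum(x$trigger),
    trigger_rate = if (nrow(x)) mean(x$trigger) else NA_real_,
    mean_targets_per_scan = if (nrow(x)) mean(x$n_targets) else NA_real_
  )
}

#' Tidy an evaluation report
#'
#' @param x an `xl_evaluation` object.
#' @param ... unused.
#' @return tibble with one row per metric (`metric`, `estimate`, `ci_lo`,
#'   `ci_hi`), including the per-class MS3-per-MS2 rates.
#' @method tidy xl_evaluation
#' @export
tidy.xl_evaluation <- function(x, ...) {
  ci <- function(name) x$confidence_intervals[[name]] %||% c(NA_real_, NA_real_)
  metrics <- tibble::tibble(
    metric = c("frac_one_doublet", "frac_both_doublets",
               "frac_correctly_triggered"),
    estimate = c(x$frac_one_doublet, x$frac_both_doublets,
                 x$frac_correctly_triggered),
    ci_lo = c(ci("frac_one_doublet")[1], ci("frac_both_doublets")[1],
              ci("frac_correctly_triggered")[1]),
    ci_hi = c(ci("frac_one_doublet")[2], ci("frac_both_doublets")[2],
              ci("frac_correctly_triggered")[2])
  )
  rates <- tibble::tibble(
    metric = paste0("ms3_per_ms2_", x$rates$class),
    estimate = x$rates$rate, ci_lo = x$rates$ci_lo, ci_hi = x$rates$ci_hi
  )
  dplyr::bind_rows(metrics, rates)
}

#' One-row summary of an evaluation report
#'
#' @param x an `xl_evaluation` object.
#' @param ... unused.
#' @return one-row tibble.
#' @method glance xl_evaluation
#' @export
glance.xl_evaluation <- function(x, ...) {
  tibble::tibble(
    n_csms = x$n_csms,
    frac_one_doublet = x$frac_one_doublet,
    frac_both_doublets = x$frac_both_doublets,
    frac_correctly_triggered = x$frac_correctly_triggered
  )
}

#' Plot the distribution of MS3 targets per MS2 scan
#'
#' @param object an `ms3_decisions` tibble.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot ms3_decisions
#' @export
autoplot.ms3_decisions <- function(object, ...) {
  df <- tibble::tibble(n_targets = object$n_targets)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_targets)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "MS3 targets per MS2 scan", y = "scans") +
    ggplot2::theme_minimal()
}

#' Plot per-class MS3-per-MS2 rates with confidence intervals
#'
#' @param object an `xl_evaluation` object.
#' @param ... unused.
#' @return a ggplot; the dashed line marks the ideal of two MS3 scans per
#'   cross-link.
#' @method autoplot xl_evaluation
#' @export
autoplot.xl_evaluation <- function(object, ...) {
  ggplot2::ggplot(object$rates,
                  ggplot2::aes(x = .data$class, y = .data$rate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
                           width = 0.2) +
    ggplot2::geom_hline(yintercept = 2, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "MS3 targets per MS2 scan") +
    ggplot2::theme_minimal()
}

#' Plot a tolerance sweep
#'
#' Recovery of planted doublets and brute-force spurious matches against the
#' matching tolerance, on free y scales.
#'
#' @param object an `xl_sweep` tibble from [sweep_tolerance()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot xl_sweep
#' @export
autoplot.xl_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("tol_ppm", "recovery", "spurious")],
    cols = c("recovery", "spurious"),
    names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$tol_ppm, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "matching tolerance (ppm)", y = NULL) +
    ggplot2::theme_minimal()
}
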