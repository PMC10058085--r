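#' Tidy an FFR network solution
#'
#' @param x an `ffr_solution` from [solve_network()].
#' @param ... unused.
#' @return tibble of nodal pressures (`node`, `pressure` in mmHg).
#' @export
tidy.ffr_solution <- function(x, ...) x$pressures

#' @rdname tidy.ffr_solution
#' @export
glance.ffr_solution <- function(x, ...) {
  tibble(inlet_pressure = x$inlet_pressure, inlet_flow = x$inlet_flow,
         iterations = x$convergence$iterations,
         residual = x$convergence$residual,
         converged = x$convergence$converged)
}

#' Tidy a diagnostic evaluation
#'
#' @param x an `ffr_diagnostics` from [evaluate_cohort()].
#' @param ... unused.
#' @return long tibble of metrics with exact 95% CIs.
#' @export
tidy.ffr_diagnostics <- function(x, ...) x$metrics

#' @rdname tidy.ffr_diagnostics
#' @export
glance.ffr_diagnostics <- function(x, ...) {
  tibble(
    n_vessels = nrow(x$records),
    prevalence = mean(x$records$invasive_ffr <= x$thresholds["reference"]),
    auc = if (is.null(x$roc)) NA_real_ else x$roc$auc,
    auc_se = if (is.null(x$roc)) NA_real_ else sqrt(x$roc$var),
    pearson_r = if (is.null(x$pearson)) NA_real_ else x$pearson$r,
    mean_diff = if (is.null(x$bland_altman)) NA_real_ else x$bland_altman$mean_diff,
    loa_lower = if (is.null(x$bland_altman)) NA_real_ else x$bland_altman$lower,
    loa_upper = if (is.null(x$bland_altman)) NA_real_ else x$bland_altman$upper
  )
}

#' @export
tidy.ctp_bland_altman <- function(x, ...) x$data

#' @export
glance.ctp_bland_altman <- function(x, ...) {
  tibble(mean_diff = x$mean_diff, lower = x$lower, upper = x$upper,
         sd_diff = x$sd_diff)
}

#' @export
glance.ctp_roc <- function(x, ...) {
  tibble(auc = x$auc, var = x$var, se = sqrt(x$var),
         n_pos = x$n_pos, n_neg = x$n_neg)
}
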