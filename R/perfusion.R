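#' Renkin-Crone parameters
#'
#' Constants of the Renkin-Crone relation between the tracer transfer constant
#' K1 and myocardial blood flow (MBF),
#' \deqn{K_1 = \left(1 - a\, e^{-b/\mathrm{MBF}}\right)\,\mathrm{MBF},}
#' with `a` the maximal extraction shortfall (dimensionless) and `b` a
#' permeability-surface term (mL min^-1 g^-1). `tissue_density` converts
#' per-gram flows to the per-mL values consumed by the territory flow
#' integral.
#'
#' @param a dimensionless, in (0, 1). Default 0.904.
#' @param b mL min^-1 g^-1, positive. Default 1.203.
#' @param tissue_density g mL^-1. Default 1.05.
#' @return a list of class `renkin_crone_params`.
#' @export
renkin_crone_params <- function(a = 0.904, b = 1.203, tissue_density = 1.05) {
  stopifnot(is.numeric(a), length(a) == 1, a > 0, a < 1)
  stopifnot(is.numeric(b), length(b) == 1, b > 0)
  stopifnot(is.numeric(tissue_density), length(tissue_density) == 1, tissue_density > 0)
  structure(list(a = a, b = b, tissue_density = tissue_density),
            class = "renkin_crone_params")
}

#' Convert MBF to the tracer transfer constant K1
#'
#' Applies the Renkin-Crone extraction relation. The function is strictly
#' increasing in MBF (its derivative is bounded below by `1 - a > 0`) and
#' `K1/MBF` falls from 1 at low flow to `1 - a` at high flow, reflecting
#' incomplete first-pass tracer extraction at hyperemia.
#'
#' @param mbf myocardial blood flow, mL min^-1 g^-1; positive, vectorized.
#' @param params a [renkin_crone_params()] object.
#' @return K1 in mL min^-1 g^-1, same length as `mbf`.
#' @export
k1_from_mbf <- function(mbf, params = renkin_crone_params()) {
  if (!is.numeric(mbf) || any(!is.finite(mbf)) || any(mbf <= 0)) {
    abort("`mbf` must be finite and > 0.", class = "ctpffr_domain_error")
  }
  (1 - params$a * exp(-params$b / mbf)) * mbf
}

#' Invert the Renkin-Crone relation: MBF from K1
#'
#' Recovers the unique MBF with `k1_from_mbf(mbf) == k1` by bracketed
#' root-finding. Because `K1/MBF` lies in `(1 - a, 1)`, the root is bracketed
#' by `[k1, k1 / (1 - a)]`; monotonicity makes the root unique.
#'
#' @param k1 transfer constant, mL min^-1 g^-1; positive, vectorized.
#' @param params a [renkin_crone_params()] object.
#' @param tol relative tolerance of the returned MBF. Default 1e-10.
#' @return MBF in mL min^-1 g^-1, same length as `k1`.
#' @export
mbf_from_k1 <- function(k1, params = renkin_crone_params(), tol = 1e-10) {
  if (!is.numeric(k1) || any(!is.finite(k1)) || any(k1 <= 0)) {
    abort("`k1` must be finite and > 0.", class = "ctpffr_domain_error")
  }
  vapply(k1, function(k) {
    upper <- k / (1 - params$a)
    f <- function(m) k1_from_mbf(m, params) - k
    # widen the lower end marginally: f(k1) < 0 analytically, but guard
    # against rounding at tiny k1 where K1 ~ MBF
    root <- uniroot(f, lower = k * (1 - 1e-9), upper = upper * (1 + 1e-9),
                    tol = tol * k, maxiter = 1000, check.conv = TRUE)
    root$root
  }, numeric(1))
}

#' Piecewise-linear coupling between FFR and relative hyperemic flow
#'
#' The synthetic generator reduces a territory's hyperemic MBF in proportion
#' to the ischemic burden of its feeding outlet: territories distal to a
#' non-significant lesion (FFR > 0.80) perfuse normally, and below the 0.80
#' threshold relative flow falls linearly as FFR/0.80.
#'
#' @param ffr fractional flow reserve in (0, 1]; vectorized.
#' @return relative flow multiplier in (0, 1].
#' @export
ffr_flow_coupling <- function(ffr) {
  stopifnot(is.numeric(ffr), all(ffr > 0), all(ffr <= 1))
  ifelse(ffr > 0.8, 1, ffr / 0.8)
}
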