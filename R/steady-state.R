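#' Actin-activated steady-state ATPase curve
#'
#' @param actin F-actin concentrations (uM), at least 4 for fitting.
#' @param rate Turnover rates (s^-1 per myosin head), `>= 0`.
#' @param buffer Free-text buffer annotation.
#' @param truth Optional generating ground truth.
#' @return An `atpase_curve` data.frame.
#' @export
atpase_curve <- function(actin, rate, buffer = "", truth = NULL) {
  if (length(actin) != length(rate)) stop("actin and rate lengths differ")
  if (any(actin < 0)) stop("negative actin concentration")
  if (any(rate < 0)) stop("negative turnover rate")
  structure(data.frame(actin = actin, rate = rate),
            class = c("atpase_curve", "data.frame"),
            buffer = buffer, truth = truth)
}

#' Michaelis-Menten fit of an actin-activated ATPase curve
#'
#' Least-squares fit of `v([A]) = kcat * [A] / (Kapp + [A])`. The catalytic
#' efficiency `kcat / Kapp` (uM^-1 s^-1) measures how well F-actin activates
#' the motor at sub-saturating concentrations.
#'
#' @param curve An [atpase_curve()] with >= 4 concentrations.
#' @param subtract_basal If `TRUE` and a 0 uM point is present, its rate is
#'   subtracted from all points before fitting (off by default; whether
#'   published kcat values are basal-subtracted is generally not stated).
#' @return List with `kcat` (s^-1), `Kapp` (uM), `efficiency` (kcat/Kapp,
#'   uM^-1 s^-1), standard errors, and the underlying fit. If the data do not
#'   approach saturation a warning is issued and estimates are returned with
#'   wide confidence intervals.
#' @export
fit_michaelis <- function(curve, subtract_basal = FALSE) {
  if (nrow(curve) < 4) stop("need at least 4 actin concentrations")
  a <- curve$actin
  v <- curve$rate
  if (subtract_basal && any(a == 0)) {
    v <- v - v[a == 0][1]
  }
  keep <- a > 0 | !subtract_basal
  a <- a[keep]; v <- v[keep]
  kcat0 <- max(v) * 1.2
  K0 <- a[which.min(abs(v - kcat0 / 2))]
  if (!is.finite(K0) || K0 <= 0) K0 <- stats::median(a[a > 0])
  m <- minpack.lm::nlsLM(v ~ kcat * a / (K + a),
                         data = data.frame(a = a, v = v),
                         start = list(kcat = kcat0, K = K0),
                         lower = c(kcat = 0, K = 0))
  cf <- stats::coef(m)
  se <- summary(m)$coefficients[, "Std. Error"]
  if (max(a) < cf[["K"]]) {
    warning("no saturation in data: max [actin] below fitted Kapp;",
            " estimates have wide confidence intervals")
  }
  list(kcat = cf[["kcat"]], Kapp = cf[["K"]],
       efficiency = cf[["kcat"]] / cf[["K"]],
       se_kcat = unname(se["kcat"]), se_Kapp = unname(se["K"]), fit = m)
}

#' Evaluate the Michaelis-Menten envelope
#'
#' @param kcat,Kapp Michaelis-Menten parameters (s^-1, uM).
#' @param actin F-actin concentration(s), uM.
#' @return Turnover rate(s), s^-1; monotone increasing in `actin`, bounded by
#'   `kcat`.
#' @export
michaelis_rate <- function(kcat, Kapp, actin) {
  kcat * actin / (Kapp + actin)
}
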