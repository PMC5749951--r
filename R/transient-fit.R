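#' @importFrom minpack.lm nlsLM nls.lm.control
NULL

#' Fit exponential phases to a stopped-flow trace
#'
#' Nonlinear least-squares fit of
#' `signal(t) = offset + sum_i amplitude_i * exp(-k_i * t)`
#' with one or two phases, the standard extraction of observed rates from
#' stopped-flow transients. Start values come from the tail-estimated offset
#' and a log-linear regression of the offset-subtracted signal; on failure or
#' a non-positive fitted rate the fit restarts from rates perturbed by 0.1x
#' and 10x.
#'
#' Reporting rules: phases are ordered by descending `k_obs`; a phase whose
#' absolute amplitude is below `3 *` the residual standard deviation, or
#' which relaxes by less than one e-fold within the fitting window (and is
#' therefore degenerate with the offset), is kept in the output but flagged
#' as not reported; if the two rates of a double-exponential fit converge
#' (ratio < 1.5) the phases are merged into a single-exponential refit,
#' flagged accordingly.
#'
#' @param trace A `signal_trace` (or data.frame with `time`, `signal`).
#' @param n_phases 1 or 2.
#' @param window Optional `c(t0, t1)` fitting window (s); at least 10 samples
#'   must remain.
#' @return An `exp_fit` object: `phases` data.frame (`amplitude`, `k_obs`,
#'   `se_k`, `reported`), `offset`, `residual_sd`, `converged`, `merged`.
#' @export
fit_exponential <- function(trace, n_phases = 1, window = NULL) {
  if (!n_phases %in% c(1L, 2L)) stop("n_phases must be 1 or 2")
  t <- trace$time
  y <- trace$signal
  if (!is.null(window)) {
    keep <- t >= window[1] & t <= window[2]
    t <- t[keep]; y <- y[keep]
  }
  if (length(t) < 10) stop("need at least 10 samples in the fitting window")
  t0 <- t[1]
  ts <- t - t0  # shift so amplitudes refer to the window start

  start <- exp_start_values(ts, y, n_phases)
  fit <- exp_try_fit(ts, y, n_phases, start)
  if (is.null(fit$model)) {
    return(structure(list(phases = NULL, offset = NA_real_,
                          residual_sd = NA_real_, converged = FALSE,
                          merged = FALSE, diagnostics = fit$diagnostics),
                     class = "exp_fit"))
  }
  cf <- stats::coef(fit$model)
  merged <- FALSE
  if (n_phases == 2) {
    ks <- sort(c(cf[["k1"]], cf[["k2"]]), decreasing = TRUE)
    if (ks[1] / ks[2] < 1.5) {  # indistinguishable phases: merge
      merged <- TRUE
      n_phases <- 1L
      start <- exp_start_values(ts, y, 1L)
      fit <- exp_try_fit(ts, y, 1L, start)
      cf <- stats::coef(fit$model)
    }
  }
  res_sd <- stats::sd(stats::residuals(fit$model))
  se <- tryCatch(summary(fit$model)$coefficients[, "Std. Error"],
                 error = function(e) NULL)
  ph <- if (n_phases == 1) {
    data.frame(amplitude = cf[["a1"]], k_obs = cf[["k1"]],
               se_k = if (!is.null(se)) se[["k1"]] else NA_real_)
  } else {
    data.frame(amplitude = c(cf[["a1"]], cf[["a2"]]),
               k_obs = c(cf[["k1"]], cf[["k2"]]),
               se_k = if (!is.null(se)) c(se[["k1"]], se[["k2"]])
                      else c(NA_real_, NA_real_))
  }
  ph <- ph[order(-ph$k_obs), , drop = FALSE]
  rownames(ph) <- NULL
  # report a phase only if its amplitude clears 3x the residual noise and it
  # relaxes by at least one e-fold inside the window (slower phases are
  # degenerate with the offset and cannot be resolved)
  ph$reported <- abs(ph$amplitude) >= 3 * res_sd &
    ph$k_obs * (ts[length(ts)] - ts[1]) >= 1
  structure(list(phases = ph, offset = cf[["c0"]], residual_sd = res_sd,
                 converged = TRUE, merged = merged, diagnostics = NULL),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Exponential fit: NOT converged\n")
    return(invisible(x))
  }
  cat("Exponential fit:", nrow(x$phases), "phase(s), offset =",
      signif(x$offset, 6), "\n")
  print(transform(x$phases, amplitude = signif(amplitude, 6),
                  k_obs = signif(k_obs, 6)), row.names = FALSE)
  if (x$merged) cat("(two starting phases merged: rate ratio < 1.5)\n")
  invisible(x)
}

# Start values by curve peeling: offset from the signal tail, slow phase from
# a log-linear fit of the tail-subtracted signal, fast phase from the early
# residual.
exp_start_values <- function(ts, y, n_phases) {
  n <- length(ts)
  tail_idx <- seq.int(max(1L, n - max(5L, n %/% 10L)), n)
  c0 <- mean(y[tail_idx])
  z <- y - c0
  a_tot <- z[1]
  if (abs(a_tot) < .Machine$double.eps) a_tot <- max(abs(z), 1e-12)
  usable <- which(abs(z) > 0.05 * abs(a_tot))
  usable <- usable[seq_len(max(2L, length(usable) - 2L))]
  k0 <- if (length(usable) >= 2) {
    lf <- stats::lm(log(abs(z[usable])) ~ ts[usable])
    max(-stats::coef(lf)[[2]], 1e-6)
  } else {
    1 / max(ts[n], 1e-9)
  }
  if (n_phases == 1) {
    list(a1 = a_tot, k1 = k0, c0 = c0)
  } else {
    # slow phase from the second half, fast from the early residual
    half <- ts > stats::median(ts)
    k_slow <- k0
    if (sum(half & abs(z) > 1e-3 * abs(a_tot)) >= 3) {
      idx <- which(half & abs(z) > 1e-3 * abs(a_tot))
      lf <- stats::lm(log(abs(z[idx])) ~ ts[idx])
      k_slow <- max(-stats::coef(lf)[[2]], 1e-6)
    }
    list(a1 = a_tot / 2, k1 = max(k_slow * 10, k0 * 5),
         a2 = a_tot / 2, k2 = k_slow, c0 = c0)
  }
}

exp_try_fit <- function(ts, y, n_phases, start) {
  form <- if (n_phases == 1) {
    y ~ c0 + a1 * exp(-k1 * ts)
  } else {
    y ~ c0 + a1 * exp(-k1 * ts) + a2 * exp(-k2 * ts)
  }
  dat <- data.frame(ts = ts, y = y)
  lower <- rep(-Inf, length(start))
  names(lower) <- names(start)
  lower[grep("^k", names(lower))] <- 1e-9
  attempts <- list(start)
  for (f in c(0.1, 10)) {
    s <- start
    for (kn in grep("^k", names(s), value = TRUE)) s[[kn]] <- s[[kn]] * f
    attempts <- c(attempts, list(s))
  }
  diagnostics <- character(0)
  for (s in attempts) {
    m <- tryCatch(
      minpack.lm::nlsLM(form, data = dat, start = s,
                        lower = lower[names(s)],
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e)
    if (!inherits(m, "error")) {
      ks <- stats::coef(m)[grep("^k", names(stats::coef(m)))]
      if (all(ks > 0)) return(list(model = m, diagnostics = NULL))
      diagnostics <- c(diagnostics, "non-positive rate; restarted")
    } else {
      diagnostics <- c(diagnostics, conditionMessage(m))
    }
  }
  list(model = NULL, diagnostics = diagnostics)
}

#' Observed-rate concentration series
#'
#' @param concentration Ligand concentrations (uM), distinct and `>= 0`.
#' @param k_obs Observed rates (s^-1).
#' @param ligand Label of the varied ligand.
#' @param sd Optional per-point uncertainties.
#' @param truth Optional generating ground truth (named list).
#' @return A `kobs_series` data.frame.
#' @export
kobs_series <- function(concentration, k_obs, ligand = "ligand", sd = NULL,
                        truth = NULL) {
  if (length(concentration) != length(k_obs)) {
    stop("concentration and k_obs lengths differ")
  }
  if (anyDuplicated(concentration)) stop("concentrations must be distinct")
  if (any(concentration < 0)) stop("concentrations must be >= 0")
  df <- data.frame(concentration = concentration, k_obs = k_obs)
  if (!is.null(sd)) df$sd <- sd
  structure(df[order(df$concentration), , drop = FALSE],
            class = c("kobs_series", "data.frame"),
            ligand = ligand, truth = truth)
}

#' Linear secondary fit of an observed-rate series
#'
#' Ordinary least squares of `k_obs = slope * [ligand] + intercept` in the
#' sub-saturating regime: the slope estimates the second-order binding
#' constant, the y-intercept the dissociation rate (the standard route to
#' k-D from a mant-ADP concentration series).
#'
#' @param series A [kobs_series()] with at least 2 distinct concentrations.
#' @return List with `slope` (uM^-1 s^-1), `intercept` (s^-1), standard
#'   errors `se_slope`, `se_intercept`, and the underlying `lm` fit.
#' @export
fit_kobs_linear <- function(series) {
  if (length(unique(series$concentration)) < 2) {
    stop("need at least 2 distinct concentrations for a linear fit")
  }
  m <- stats::lm(k_obs ~ concentration, data = series)
  cf <- stats::coef(m)
  # noiseless series are legitimate here; the perfect-fit warning is moot
  se <- suppressWarnings(summary(m))$coefficients[, "Std. Error"]
  list(slope = unname(cf["concentration"]), intercept = unname(cf["(Intercept)"]),
       se_slope = unname(se["concentration"]),
       se_intercept = unname(se["(Intercept)"]), fit = m)
}

#' Hyperbolic secondary fit of an observed-rate series
#'
#' Fits `k_obs = k_max * [S] / (K_half + [S])`, the saturation behaviour of a
#' rapid-equilibrium binding step followed by a rate-limiting isomerization;
#' the initial slope `k_max / K_half` estimates the effective second-order
#' constant.
#'
#' @param series A [kobs_series()] with at least 4 points; a warning is issued
#'   if the sampled concentrations do not reach `K_half` (saturation not
#'   approached; estimates are still returned, with wide confidence
#'   intervals).
#' @return List with `k_max` (s^-1), `K_half` (uM), standard errors, the
#'   implied `second_order` slope (uM^-1 s^-1) and the underlying fit.
#' @export
fit_kobs_hyperbolic <- function(series) {
  if (nrow(series) < 4) stop("need at least 4 points for a hyperbolic fit")
  s <- series$concentration
  k <- series$k_obs
  kmax0 <- max(k) * 1.2
  K0 <- s[which.min(abs(k - kmax0 / 2))]
  if (!is.finite(K0) || K0 <= 0) K0 <- stats::median(s[s > 0])
  m <- minpack.lm::nlsLM(k ~ kmax * s / (K + s),
                         data = data.frame(s = s, k = k),
                         start = list(kmax = kmax0, K = K0),
                         lower = c(kmax = 0, K = 0))
  cf <- stats::coef(m)
  se <- summary(m)$coefficients[, "Std. Error"]
  if (max(s) < cf[["K"]]) {
    warning("saturation not approached: max concentration below fitted K_half;",
            " estimates have wide confidence intervals")
  }
  list(k_max = cf[["kmax"]], K_half = cf[["K"]],
       se_k_max = unname(se["kmax"]), se_K_half = unname(se["K"]),
       second_order = cf[["kmax"]] / cf[["K"]], fit = m)
}
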