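#' Rate and equilibrium constants of one myosin construct
#'
#' A `rate_constants` object collects every elementary rate constant of the
#' myosin / actomyosin ATPase cycle for a single motor construct, in the
#' conventional notation of transient kinetics: plain-face constants describe
#' actin-detached transitions, bold-face ("acto") constants the corresponding
#' actin-attached transitions. Units are fixed: second-order constants in
#' uM^-1 s^-1, first-order constants in s^-1, concentrations in uM.
#'
#' Equilibrium constants (K_D, K_AD, K_A, K_DA, ...) are never stored; they
#' are derived by [equilibrium_constants()] so that the stored set stays
#' internally consistent.
#'
#' @param construct_label Character name of the construct (unique within a run).
#' @param k1k2_myosin Effective second-order ATP binding to myosin
#'   (K1*k+2, uM^-1 s^-1).
#' @param k3_plus_kminus3 Sum of forward and reverse ATP hydrolysis rates on
#'   myosin (s^-1).
#' @param inv_K05 1/K0.5 of the tryptophan ATP concentration dependence (uM).
#' @param k_pi_basal Basal (actin-free) phosphate release rate (s^-1).
#' @param k_pi_actin_max Maximal actin-activated product flux, identified with
#'   the steady-state kcat (s^-1).
#' @param kD_on,kD_off ADP binding to / release from myosin
#'   (uM^-1 s^-1, s^-1).
#' @param k1k2_acto Effective second-order ATP binding to actomyosin
#'   (uM^-1 s^-1).
#' @param k2_acto Maximal ATP-induced actomyosin dissociation rate
#'   (isomerization k+2, s^-1).
#' @param inv_K1_acto 1/K1 of the ATP collision equilibrium on actomyosin (uM).
#' @param kAD_on,kAD_off ADP binding to / release from actomyosin
#'   (uM^-1 s^-1, s^-1).
#' @param kA_on,kA_off Actin binding to / release from nucleotide-free myosin
#'   (uM^-1 s^-1, s^-1).
#' @param kDA_on,kDA_off Actin binding to / release from myosin.ADP
#'   (uM^-1 s^-1, s^-1).
#' @param kcat,Kapp Steady-state actin-activated ATPase parameters
#'   (s^-1, uM).
#' @param hydrolysis_Keq Equilibrium constant of the on-myosin hydrolysis step
#'   (dimensionless, forward/reverse; the experiments constrain only the sum
#'   k+3 + k-3, so the split is a documented default favouring M.ADP.Pi).
#' @param detach_rate Actin detachment rate of the AM.ATP collision state
#'   (s^-1); fast by default so the ATP-induced dissociation hyperbola is
#'   rate-limited by the isomerization.
#' @param kPiA_on,kPiA_off Weak-binding attachment of M.ADP.Pi to actin
#'   (uM^-1 s^-1, s^-1); unprinted, documented defaults.
#' @param measurements Optional data.frame of individual printed measurements
#'   (columns `parameter`, `signal`, `value`, `error`); used by derived-constant
#'   precedence rules when a constant was measured with several signals.
#'
#' @return An object of class `rate_constants` (a named list).
#' @seealso [nm2c_constants()], [build_network()], [equilibrium_constants()]
#' @export
rate_constants <- function(construct_label,
                           k1k2_myosin = NA_real_,
                           k3_plus_kminus3 = NA_real_,
                           inv_K05 = NA_real_,
                           k_pi_basal = 0.02,
                           k_pi_actin_max = NA_real_,
                           kD_on = NA_real_,
                           kD_off = NA_real_,
                           k1k2_acto = NA_real_,
                           k2_acto = NA_real_,
                           inv_K1_acto = NA_real_,
                           kAD_on = NA_real_,
                           kAD_off = NA_real_,
                           kA_on = NA_real_,
                           kA_off = NA_real_,
                           kDA_on = NA_real_,
                           kDA_off = NA_real_,
                           kcat = NA_real_,
                           Kapp = NA_real_,
                           hydrolysis_Keq = 10,
                           detach_rate = 1e4,
                           kPiA_on = 0.01,
                           kPiA_off = 1,
                           measurements = NULL) {
  stopifnot(is.character(construct_label), length(construct_label) == 1L)
  rc <- list(
    construct_label = construct_label,
    k1k2_myosin = k1k2_myosin, k3_plus_kminus3 = k3_plus_kminus3,
    inv_K05 = inv_K05, k_pi_basal = k_pi_basal,
    k_pi_actin_max = k_pi_actin_max,
    kD_on = kD_on, kD_off = kD_off,
    k1k2_acto = k1k2_acto, k2_acto = k2_acto, inv_K1_acto = inv_K1_acto,
    kAD_on = kAD_on, kAD_off = kAD_off,
    kA_on = kA_on, kA_off = kA_off,
    kDA_on = kDA_on, kDA_off = kDA_off,
    kcat = kcat, Kapp = Kapp,
    hydrolysis_Keq = hydrolysis_Keq, detach_rate = detach_rate,
    kPiA_on = kPiA_on, kPiA_off = kPiA_off
  )
  num <- rc[setdiff(names(rc), "construct_label")]
  bad <- names(num)[vapply(num, function(x) is.finite(x) && x < 0, logical(1))]
  if (length(bad)) {
    stop("negative rate constant(s): ", paste(bad, collapse = ", "))
  }
  rc$measurements <- measurements
  structure(rc, class = "rate_constants")
}

#' @export
print.rate_constants <- function(x, ...) {
  cat("Rate constant set:", x$construct_label, "\n")
  flds <- setdiff(names(x), c("construct_label", "measurements"))
  vals <- unlist(x[flds])
  df <- data.frame(constant = flds, value = unname(vals))
  print(df, row.names = FALSE)
  if (!is.null(x$measurements)) {
    cat("(", nrow(x$measurements), "individual measurements attached )\n")
  }
  invisible(x)
}

# Printed steady-state and transient-state measurements for the three
# characterized constructs (wild-type NM2C and the converter-hub charge
# mutants R788K, R788E).  `signal` records the reporter; `method` separates
# repeated measurements of one constant (slope/intercept of a concentration
# series vs a chasing experiment).  Ranges printed as "~a-b" are stored as
# midpoints with the range kept in `note`.
measured_table <- function(construct) {
  rows <- function(parameter, signal, method, NM2C, R788K, R788E, note = "") {
    data.frame(parameter = parameter, signal = signal, method = method,
               NM2C = NM2C, R788K = R788K, R788E = R788E, note = note,
               stringsAsFactors = FALSE)
  }
  tab <- rbind(
    rows("kcat", "nadh_atpase", "steady_state", 0.37, 0.26, 0.20),
    rows("Kapp", "nadh_atpase", "steady_state", 129.4, 110.5, 45.9),
    rows("k1k2_myosin", "tryptophan", "slope", 0.39, 0.18, NA),
    rows("k1k2_myosin", "mant_fluorescence", "slope", 0.48, 0.22, 0.09),
    rows("inv_K05", "tryptophan", "hyperbolic", 46.23, 158.03, NA),
    rows("k3_plus_kminus3", "tryptophan", "hyperbolic", 24.2, 37.31, NA),
    rows("k1k2_acto", "pyrene_actin", "slope", 1.86, 1.03, 2.11),
    rows("k1k2_acto", "mant_fluorescence", "slope", 1.64, 0.73, 1.37),
    rows("inv_K1_acto", "pyrene_actin", "hyperbolic", 318, 826, 380),
    rows("k2_acto", "pyrene_actin", "hyperbolic", 643.06, 767.43, 579.27),
    rows("kD_on", "mant_fluorescence", "slope", 0.39, 0.21, 0.12),
    rows("kD_off", "mant_fluorescence", "intercept", 0.94, 0.58, 0.06),
    rows("kD_off", "mant_fluorescence", "chase", 0.39, 0.51, 0.05),
    rows("kD_off", "tryptophan", "chase", 0.47, 0.24, NA),
    rows("kAD_on", "mant_fluorescence", "slope", 2.54, NA, 0.03),
    rows("kAD_off", "mant_fluorescence", "slope_series", 0.65, NA, 0.09),
    rows("kAD_off", "light_scattering", "chase", 0.39, 0.42, 0.15),
    rows("kAD_off", "mant_fluorescence", "chase", 0.68, 0.59, 0.19),
    rows("kAD_off", "pyrene_actin", "chase", 0.48, 0.46, 0.14),
    rows("K_AD_printed", "calculation", "printed", 0.29, NA, 2.68),
    rows("kA_on", "light_scattering", "slope", 2.49, 1.65, 0.66),
    rows("kA_off", "pyrene_actin", "dissociation", 0.15, 0.055, 0.031,
         note = "R788K printed as ~0.04-0.07; midpoint stored"),
    rows("kDA_on", "light_scattering", "slope", 0.53, 2.53, 0.21),
    rows("kDA_off", "pyrene_actin", "dissociation", 0.004, 0.0885, 0.002,
         note = "R788K printed as ~0.067-0.11; midpoint stored")
  )
  data.frame(parameter = tab$parameter, signal = tab$signal,
             method = tab$method, value = tab[[construct]],
             note = tab$note, stringsAsFactors = FALSE)
}

#' Built-in rate constant sets for NM2C and its converter-hub mutants
#'
#' Returns the measured kinetic parameter set of wild-type human nonmuscle
#' myosin-2C (`"NM2C"`) or of the converter charge mutants `"R788K"` and
#' `"R788E"`, assembled from the published steady-state and transient-state
#' measurements. Where a constant was measured with several reporters, the
#' value used for simulation is resolved by a fixed precedence (mant signals
#' for nucleotide steps, pyrene-actin for the ATP-induced dissociation
#' hyperbola, the y-intercept of the mant-ADP series for k-D); every
#' individual measurement stays available in `$measurements`.
#'
#' Unprinted constants (hydrolysis split, basal Pi release, weak-binding
#' attachment) take the documented package defaults of [rate_constants()].
#' The hydrolysis equilibration rate of R788E was not experimentally
#' accessible; it defaults to the wild-type value.
#'
#' @param construct One of `"NM2C"`, `"R788K"`, `"R788E"`.
#' @return A [rate_constants()] object with the measurement table attached.
#' @export
nm2c_constants <- function(construct = c("NM2C", "R788K", "R788E")) {
  construct <- match.arg(construct)
  m <- measured_table(construct)
  pick <- function(parameter, signal = NULL, method = NULL, default = NA_real_) {
    sel <- m$parameter == parameter
    if (!is.null(signal)) sel <- sel & m$signal == signal
    if (!is.null(method)) sel <- sel & m$method == method
    v <- m$value[sel]
    v <- v[is.finite(v)]
    if (!length(v)) default else v[[1L]]
  }
  k3 <- pick("k3_plus_kminus3")
  if (!is.finite(k3)) k3 <- 24.2  # wild-type default; not accessible for R788E
  rate_constants(
    construct_label = construct,
    k1k2_myosin = pick("k1k2_myosin", "mant_fluorescence"),
    k3_plus_kminus3 = k3,
    inv_K05 = pick("inv_K05"),
    k_pi_actin_max = pick("kcat"),
    kD_on = pick("kD_on"),
    kD_off = pick("kD_off", "mant_fluorescence", "intercept"),
    k1k2_acto = pick("k1k2_acto", "pyrene_actin"),
    k2_acto = pick("k2_acto"),
    inv_K1_acto = pick("inv_K1_acto"),
    kAD_on = pick("kAD_on"),
    kAD_off = pick("kAD_off", "mant_fluorescence", "chase"),
    kA_on = pick("kA_on"),
    kA_off = pick("kA_off"),
    kDA_on = pick("kDA_on"),
    kDA_off = pick("kDA_off"),
    kcat = pick("kcat"),
    Kapp = pick("Kapp"),
    measurements = m
  )
}

#' Look up an individual measurement of a kinetic constant
#'
#' @param rates A [rate_constants()] object with a measurement table.
#' @param parameter Constant name (e.g. `"kAD_off"`).
#' @param signal,method Optional reporter / extraction-method filters.
#' @return The measured value (numeric scalar), or `NA` if absent.
#' @export
measurement <- function(rates, parameter, signal = NULL, method = NULL) {
  m <- rates$measurements
  if (is.null(m)) return(NA_real_)
  sel <- m$parameter == parameter
  if (!is.null(signal)) sel <- sel & m$signal == signal
  if (!is.null(method)) sel <- sel & m$method == method
  v <- m$value[sel]
  v <- v[is.finite(v)]
  if (!length(v)) NA_real_ else v[[1L]]
}
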