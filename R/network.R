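#' @importFrom deSolve lsoda
NULL

# Species of the cycle. Myosin-containing states first, then free ligand
# pools. "A" is the free F-actin site pool.
MYOSIN_SPECIES <- c("M", "M.ATP", "M.ADP.Pi", "M.ADP",
                    "AM", "AM.ATP", "AM.ADP.Pi", "AM.ADP")
ACTO_SPECIES <- c("AM", "AM.ATP", "AM.ADP.Pi", "AM.ADP")
LIGAND_SPECIES <- c("ATP", "ADP", "Pi", "A")
ALL_SPECIES <- c(MYOSIN_SPECIES, LIGAND_SPECIES)

reaction <- function(name, stoich, k, law = "mass_action",
                     drivers = NULL, sat_species = NULL, sat_K = NULL) {
  list(name = name, stoich = stoich, k = k, law = law,
       drivers = drivers, sat_species = sat_species, sat_K = sat_K)
}

#' Build the actomyosin ATPase reaction network
#'
#' Assembles the mass-action reaction list of the eight-state myosin /
#' actomyosin ATPase cycle from a [rate_constants()] set. Actin-detached
#' transitions are governed by the plain-face constants, actin-attached
#' transitions by the bold-face ("acto") constants.
#'
#' Two steps are treated as effective rather than fully elementary, following
#' how the constants are measured:
#' \itemize{
#'   \item ATP binding to myosin is one second-order step with rate
#'     `k1k2_myosin * [ATP]` (the collision equilibrium and isomerization are
#'     not separable without the hyperbolic tryptophan dependence).
#'   \item ATP binding to actomyosin is a rapid-equilibrium collision followed
#'     by isomerization, so the per-AM rate is the saturating hyperbola
#'     `k2_acto * [ATP] / (inv_K1_acto + [ATP])`; the AM.ATP collision state
#'     then detaches from actin at the fast `detach_rate`.
#'   \item Phosphate release from M.ADP.Pi carries an actin-concentration
#'     dependent rate `k_pi_basal + (k_pi_actin_max - k_pi_basal) * [A] /
#'     (Kapp + [A])`, which reproduces the Michaelis-Menten steady-state
#'     envelope without explicit weak-binding isomerization microstates.
#' }
#'
#' Missing (`NA`) constants give a zero flux for the corresponding edge, with
#' the exceptions handled by [rate_constants()] defaults.
#'
#' @param rates A [rate_constants()] object; all constants must be `>= 0`.
#' @return An object of class `reaction_network`: list of reactions, species
#'   roster and the generating constants.
#' @export
build_network <- function(rates) {
  if (!inherits(rates, "rate_constants")) {
    stop("`rates` must be a rate_constants object")
  }
  num_fields <- setdiff(names(rates), c("construct_label", "measurements"))
  for (f in num_fields) {
    v <- rates[[f]]
    if (is.finite(v) && v < 0) stop("negative rate constant: ", f)
  }
  k <- function(x) if (is.finite(rates[[x]])) rates[[x]] else 0
  # hydrolysis split: k3f + k3r = k3_plus_kminus3, k3f/k3r = hydrolysis_Keq
  Keq <- if (is.finite(rates$hydrolysis_Keq)) rates$hydrolysis_Keq else 10
  k3sum <- k("k3_plus_kminus3")
  k3f <- k3sum * Keq / (1 + Keq)
  k3r <- k3sum / (1 + Keq)

  st <- function(...) {
    v <- c(...)
    out <- stats::setNames(numeric(length(ALL_SPECIES)), ALL_SPECIES)
    out[names(v)] <- v
    out
  }
  reactions <- list(
    reaction("atp_binding_myosin",
             st(M = -1, ATP = -1, M.ATP = +1), k("k1k2_myosin"),
             drivers = c("M", "ATP")),
    reaction("hydrolysis_fwd", st(M.ATP = -1, M.ADP.Pi = +1), k3f,
             drivers = "M.ATP"),
    reaction("hydrolysis_rev", st(M.ADP.Pi = -1, M.ATP = +1), k3r,
             drivers = "M.ADP.Pi"),
    reaction("pi_release",
             st(M.ADP.Pi = -1, M.ADP = +1, Pi = +1),
             k("k_pi_basal"), law = "actin_activated",
             drivers = "M.ADP.Pi",
             sat_species = "A",
             sat_K = if (is.finite(rates$Kapp)) rates$Kapp else NA_real_),
    reaction("adp_release_myosin", st(M.ADP = -1, M = +1, ADP = +1),
             k("kD_off"), drivers = "M.ADP"),
    reaction("adp_binding_myosin", st(M = -1, ADP = -1, M.ADP = +1),
             k("kD_on"), drivers = c("M", "ADP")),
    reaction("atp_binding_acto",
             st(AM = -1, ATP = -1, AM.ATP = +1),
             k("k2_acto"), law = "saturating",
             drivers = "AM", sat_species = "ATP",
             sat_K = if (is.finite(rates$inv_K1_acto)) rates$inv_K1_acto else 0),
    reaction("atp_induced_detachment",
             st(AM.ATP = -1, M.ATP = +1, A = +1),
             k("detach_rate"), drivers = "AM.ATP"),
    reaction("adp_release_acto", st(AM.ADP = -1, AM = +1, ADP = +1),
             k("kAD_off"), drivers = "AM.ADP"),
    reaction("adp_binding_acto", st(AM = -1, ADP = -1, AM.ADP = +1),
             k("kAD_on"), drivers = c("AM", "ADP")),
    reaction("actin_binding_rigor", st(M = -1, A = -1, AM = +1),
             k("kA_on"), drivers = c("M", "A")),
    reaction("actin_release_rigor", st(AM = -1, M = +1, A = +1),
             k("kA_off"), drivers = "AM"),
    reaction("actin_binding_adp", st(M.ADP = -1, A = -1, AM.ADP = +1),
             k("kDA_on"), drivers = c("M.ADP", "A")),
    reaction("actin_release_adp", st(AM.ADP = -1, M.ADP = +1, A = +1),
             k("kDA_off"), drivers = "AM.ADP"),
    reaction("actin_binding_weak", st(M.ADP.Pi = -1, A = -1, AM.ADP.Pi = +1),
             k("kPiA_on"), drivers = c("M.ADP.Pi", "A")),
    reaction("actin_release_weak", st(AM.ADP.Pi = -1, M.ADP.Pi = +1, A = +1),
             k("kPiA_off"), drivers = "AM.ADP.Pi"),
    reaction("pi_release_attached",
             st(AM.ADP.Pi = -1, AM.ADP = +1, Pi = +1),
             if (is.finite(rates$k_pi_actin_max)) rates$k_pi_actin_max
             else k("k_pi_basal"),
             drivers = "AM.ADP.Pi")
  )
  structure(list(reactions = reactions, species = ALL_SPECIES, rates = rates),
            class = "reaction_network")
}

#' @export
print.reaction_network <- function(x, ...) {
  cat("Actomyosin cycle network (", x$rates$construct_label, "): ",
      length(x$reactions), " reactions, ", length(x$species), " species\n",
      sep = "")
  for (r in x$reactions) {
    cons <- names(r$stoich)[r$stoich < 0]
    prod <- names(r$stoich)[r$stoich > 0]
    cat(sprintf("  %-24s %s -> %s  (k = %g%s)\n", r$name,
                paste(cons, collapse = " + "), paste(prod, collapse = " + "),
                r$k, if (r$law != "mass_action") paste0(", ", r$law) else ""))
  }
  invisible(x)
}

#' Audit the instantaneous reaction fluxes of a network
#'
#' @param network A [build_network()] result.
#' @param state Named concentration vector (uM) over the network species.
#' @return Named numeric vector of per-reaction fluxes (uM/s).
#' @export
reaction_fluxes <- function(network, state) {
  y <- stats::setNames(numeric(length(network$species)), network$species)
  y[names(state)] <- state
  rates <- network$rates
  vapply(network$reactions, function(r) flux_of(r, y, rates), numeric(1)) |>
    stats::setNames(vapply(network$reactions, `[[`, "", "name"))
}

# single source of truth for flux evaluation (also used by the ODE right side)
flux_of <- function(r, y, rates) {
  if (r$law == "mass_action") {
    r$k * prod(y[r$drivers])
  } else if (r$law == "saturating") {
    s <- y[[r$sat_species]]
    denom <- r$sat_K + s
    if (denom <= 0) 0 else r$k * s / denom * prod(y[r$drivers])
  } else if (r$law == "actin_activated") {
    a <- y[["A"]] + sum(y[ACTO_SPECIES])  # total actin sites seen by the head
    kb <- r$k
    kmax <- if (is.finite(rates$k_pi_actin_max)) rates$k_pi_actin_max else kb
    Kapp <- r$sat_K
    keff <- if (is.finite(Kapp) && Kapp + a > 0) {
      kb + (kmax - kb) * a / (Kapp + a)
    } else {
      kb
    }
    keff * prod(y[r$drivers])
  } else {
    stop("unknown rate law: ", r$law)
  }
}

#' Experimental mixing conditions
#'
#' Initial concentrations and mixing metadata for a simulated stopped-flow or
#' steady-state experiment.
#'
#' @param myosin,actin,atp,adp,pi Initial concentrations (uM). `actin` counts
#'   F-actin sites.
#' @param clamp_ligands Pseudo-first-order clamping of free ligand pools:
#'   `TRUE` holds all pools (ATP, ADP, Pi, A) constant, `FALSE` none, or a
#'   character vector naming the pools in excess (e.g. `"ATP"` for an
#'   ATP-chase over stoichiometric actin).
#' @param dead_time Instrument mixing dead time (s); simulated signal before
#'   this time is discarded by the trace generators.
#' @param start_state Initial partitioning of the myosin: `"detached"` (all
#'   free M), `"rigor"` (pre-equilibrated AM complex, as in ATP-induced
#'   dissociation experiments), `"rigor_adp"` (AM.ADP, as in actomyosin ADP
#'   chase experiments) or `"myosin_adp"` (M.ADP, the myosin-branch chase).
#' @return An object of class `ligand_conditions`.
#' @export
ligand_conditions <- function(myosin, actin = 0, atp = 0, adp = 0, pi = 0,
                              clamp_ligands = FALSE, dead_time = 0.0015,
                              start_state = c("detached", "rigor",
                                              "rigor_adp", "myosin_adp")) {
  start_state <- match.arg(start_state)
  if (is.character(clamp_ligands)) {
    bad <- setdiff(clamp_ligands, LIGAND_SPECIES)
    if (length(bad)) stop("unknown ligand pool(s): ", paste(bad, collapse = ", "))
  }
  conc <- c(myosin = myosin, actin = actin, atp = atp, adp = adp, pi = pi)
  if (any(!is.finite(conc)) || any(conc < 0)) {
    stop("concentrations must be finite and >= 0")
  }
  if (!is.finite(dead_time) || dead_time < 0) stop("dead_time must be >= 0")
  structure(list(myosin = myosin, actin = actin, atp = atp, adp = adp,
                 pi = pi, clamp_ligands = clamp_ligands,
                 dead_time = dead_time, start_state = start_state),
            class = "ligand_conditions")
}

initial_state <- function(conditions) {
  y <- stats::setNames(numeric(length(ALL_SPECIES)), ALL_SPECIES)
  y["ATP"] <- conditions$atp
  y["ADP"] <- conditions$adp
  y["Pi"] <- conditions$pi
  m <- conditions$myosin
  a <- conditions$actin
  if (conditions$start_state == "detached") {
    y["M"] <- m
    y["A"] <- a
  } else if (conditions$start_state == "myosin_adp") {
    y["M.ADP"] <- m
    y["A"] <- a
  } else {
    bound <- min(m, a)
    slot <- if (conditions$start_state == "rigor") "AM" else "AM.ADP"
    y[slot] <- bound
    y["M"] <- m - bound
    y["A"] <- a - bound
  }
  y
}

#' Integrate the cycle to a state-occupancy trajectory
#'
#' Integrates the mass-action ODEs of a [build_network()] reaction network
#' with a stiff-capable solver (`deSolve::lsoda`, absolute tolerance 1e-10 uM,
#' relative 1e-8) and returns species occupancies on the requested time grid.
#'
#' Conservation of total myosin (and, without ligand clamping, total actin) is
#' checked to 1e-6 relative tolerance; violations or solver failures raise an
#' error rather than returning clipped output.
#'
#' @param network A `reaction_network`.
#' @param conditions A [ligand_conditions()] object.
#' @param times Strictly increasing time grid starting at 0 (s).
#' @param atol,rtol Integrator tolerances.
#' @return An `occupancy_trajectory`: data.frame with `time` and one column
#'   per species, with the conditions attached as attributes.
#' @export
simulate_cycle <- function(network, conditions, times,
                           atol = 1e-10, rtol = 1e-8) {
  stopifnot(inherits(network, "reaction_network"),
            inherits(conditions, "ligand_conditions"))
  if (length(times) < 2 || times[1] != 0 || any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing and start at 0")
  }
  if (conditions$myosin <= 0) {
    stop("zero myosin: nothing to simulate")
  }
  y0 <- initial_state(conditions)
  clamped_pools <- if (isTRUE(conditions$clamp_ligands)) LIGAND_SPECIES
                   else if (is.character(conditions$clamp_ligands))
                     conditions$clamp_ligands
                   else character(0)
  reactions <- network$reactions
  rates <- network$rates
  nsp <- length(ALL_SPECIES)
  deriv <- function(t, y, parms) {
    names(y) <- ALL_SPECIES
    dy <- stats::setNames(numeric(nsp), ALL_SPECIES)
    for (r in reactions) {
      f <- flux_of(r, y, rates)
      if (f != 0) dy <- dy + r$stoich * f
    }
    if (length(clamped_pools)) dy[clamped_pools] <- 0
    list(dy)
  }
  sol <- try(deSolve::lsoda(y0, times, deriv, parms = NULL,
                            atol = atol, rtol = rtol), silent = TRUE)
  if (inherits(sol, "try-error")) {
    stop("ODE integration failed: ", attr(sol, "condition")$message)
  }
  diagn <- attributes(sol)$istate
  if (nrow(sol) < length(times)) {
    stop("ODE integrator stopped early at t = ", max(sol[, "time"]),
         " s (istate = ", diagn[1], "); tolerances not met")
  }
  traj <- as.data.frame(sol)
  # occupancy sanity: no species meaningfully negative
  occ <- as.matrix(traj[, ALL_SPECIES])
  if (min(occ) < -1e-9) {
    stop("negative occupancy beyond tolerance: min = ", min(occ))
  }
  # conservation diagnostics
  mt <- rowSums(traj[, MYOSIN_SPECIES])
  m0 <- conditions$myosin
  if (max(abs(mt - m0)) > 1e-6 * max(m0, 1e-12)) {
    stop("myosin mass conservation violated: max drift ",
         max(abs(mt - m0)))
  }
  if (!"A" %in% clamped_pools && conditions$actin > 0) {
    at <- traj$A + rowSums(traj[, ACTO_SPECIES])
    if (max(abs(at - conditions$actin)) > 1e-6 * conditions$actin) {
      stop("actin mass conservation violated")
    }
  }
  structure(traj, class = c("occupancy_trajectory", "data.frame"),
            conditions = conditions, construct = rates$construct_label)
}

#' Write a trajectory as delimited text
#'
#' @param traj An `occupancy_trajectory`.
#' @param path Output file; tab-separated with a header row.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.table(as.data.frame(traj), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
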