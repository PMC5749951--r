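# Synthetic-data generators. Every generator embeds its ground truth in the
# output metadata so downstream fits can be checked without external data.

#' Noise specification for synthetic traces
#'
#' @param sd Gaussian standard deviation; in signal units, or as a fraction
#'   of the clean-signal amplitude when `fraction = TRUE`.
#' @param seed Integer RNG seed; identical spec + seed gives bit-identical
#'   output.
#' @param dead_time Instrument dead time (s): samples before this time are
#'   discarded.
#' @param fraction Interpret `sd` as a fraction of amplitude.
#' @return A `noise_spec`.
#' @export
noise_spec <- function(sd = 0, seed = 1L, dead_time = 0.0015,
                       fraction = FALSE) {
  if (!is.finite(sd) || sd < 0) stop("sd must be >= 0")
  if (!is.finite(dead_time) || dead_time < 0) stop("dead_time must be >= 0")
  structure(list(sd = sd, seed = as.integer(seed), dead_time = dead_time,
                 fraction = fraction), class = "noise_spec")
}

# evaluate code with a local RNG state so generators never disturb the
# caller's random stream
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a noisy stopped-flow transient with known ground truth
#'
#' Simulates the cycle ([build_network()] + [simulate_cycle()]), projects the
#' requested observable, adds iid Gaussian noise and discards the dead-time
#' samples. The generating rate set, conditions and noise parameters are
#' embedded in the trace's `truth` attribute.
#'
#' @param rates A [rate_constants()] object.
#' @param conditions A [ligand_conditions()] object.
#' @param observable Observable kind or an [observable_model()].
#' @param noise A [noise_spec()].
#' @param times Time grid (s) starting at 0.
#' @return A `signal_trace` (dead-time samples removed).
#' @export
generate_transient <- function(rates, conditions, observable,
                               noise = noise_spec(), times) {
  model <- if (inherits(observable, "observable_model")) observable
           else observable_model(observable)
  net <- build_network(rates)
  traj <- simulate_cycle(net, conditions, times)
  trace <- project_signal(traj, model)
  clean <- trace$signal
  sd_abs <- if (noise$fraction) noise$sd * diff(range(clean)) else noise$sd
  if (sd_abs > 0) {
    trace$signal <- clean +
      with_seed(noise$seed, stats::rnorm(length(clean), 0, sd_abs))
  }
  keep <- trace$time >= max(noise$dead_time, conditions$dead_time)
  out <- signal_trace(trace$time[keep], trace$signal[keep],
                      observable = model$kind, conditions = conditions,
                      truth = list(construct = rates$construct_label,
                                   noise_sd = sd_abs, seed = noise$seed,
                                   dead_time = noise$dead_time))
  attr(out, "clean") <- clean[keep]
  out
}

# conditions and time grids for the standard concentration-series experiments
series_design <- function(kind, conc, rates) {
  switch(kind,
    mant_atp_binding = {
      k_true <- rates$k1k2_myosin * conc
      list(conditions = ligand_conditions(myosin = 0.5, atp = conc,
                                          clamp_ligands = TRUE),
           observable = "mant_fluorescence", k_true = k_true)
    },
    mant_adp_binding = {
      k_true <- rates$kD_on * conc + rates$kD_off
      list(conditions = ligand_conditions(myosin = 0.5, adp = conc,
                                          clamp_ligands = TRUE),
           observable = "mant_fluorescence", k_true = k_true)
    },
    pyrene_atp_dissociation = {
      k_true <- rates$k2_acto * conc / (rates$inv_K1_acto + conc)
      list(conditions = ligand_conditions(myosin = 0.25, actin = 0.25,
                                          atp = conc, clamp_ligands = "ATP",
                                          start_state = "rigor"),
           observable = "pyrene_actin", k_true = k_true)
    },
    stop("unknown series kind: ", kind)
  )
}

#' Generate an observed-rate concentration series
#'
#' Emulates a full concentration-dependence experiment: for each ligand
#' concentration one transient is simulated through the cycle, projected,
#' noised and fit with a single exponential; the fitted `k_obs` values are
#' assembled into a [kobs_series()] with the generating truth attached.
#'
#' Supported experiment kinds: `"mant_atp_binding"` (ATP binding to myosin,
#' expected `k_obs = K1k+2 * [ATP]`), `"mant_adp_binding"` (ADP binding,
#' `k_obs = k+D * [ADP] + k-D`), `"pyrene_atp_dissociation"` (ATP-induced
#' actomyosin dissociation, `k_obs = k+2 [ATP]/(1/K1 + [ATP])`).
#'
#' @param rates A [rate_constants()] object.
#' @param kind Experiment kind (see above).
#' @param concentrations Ligand concentrations (uM); must be non-empty.
#' @param noise A [noise_spec()]; `sd` is interpreted per trace (fraction of
#'   amplitude if `fraction = TRUE`).
#' @param replicates Independent shots per concentration; the reported
#'   `k_obs` is their mean, mirroring the averaging of repeated stopped-flow
#'   pushes.
#' @param n_points Samples per transient.
#' @return A [kobs_series()]; truth carries the generating constants.
#' @export
generate_series <- function(rates, kind, concentrations,
                            noise = noise_spec(), replicates = 1,
                            n_points = 200) {
  if (!length(concentrations)) stop("empty concentration list")
  if (any(concentrations <= 0)) stop("concentrations must be > 0")
  if (replicates < 1) stop("replicates must be >= 1")
  kobs <- numeric(length(concentrations))
  for (i in seq_along(concentrations)) {
    des <- series_design(kind, concentrations[i], rates)
    k_exp <- des$k_true
    tmax <- 5 / k_exp
    times <- seq(0, tmax, length.out = n_points)
    reps <- vapply(seq_len(replicates), function(r) {
      ns <- noise_spec(noise$sd,
                       noise$seed + i + 1000L * (r - 1L),
                       noise$dead_time, noise$fraction)
      tr <- generate_transient(rates, des$conditions, des$observable, ns,
                               times)
      fit <- fit_exponential(tr, n_phases = 1)
      if (!fit$converged) stop("exponential fit failed at concentration ",
                               concentrations[i])
      fit$phases$k_obs[1]
    }, numeric(1))
    kobs[i] <- mean(reps)
  }
  kobs_series(concentrations, kobs, ligand = kind,
              truth = list(construct = rates$construct_label, kind = kind,
                           k_true = vapply(concentrations, function(cc)
                             series_design(kind, cc, rates)$k_true,
                             numeric(1))))
}

#' Generate a steady-state ATPase activation curve
#'
#' Michaelis-Menten envelope `v([A]) = kcat [A] / (Kapp + [A])` plus iid
#' Gaussian noise.
#'
#' @param kcat,Kapp Generating parameters (s^-1, uM).
#' @param actin_grid F-actin concentrations (uM), `>= 0`.
#' @param noise A [noise_spec()] (`sd` in rate units, or fraction of kcat if
#'   `fraction = TRUE`).
#' @return An [atpase_curve()]; truth records `kcat`, `Kapp`.
#' @export
generate_atpase_curve <- function(kcat, Kapp, actin_grid,
                                  noise = noise_spec()) {
  if (any(actin_grid < 0)) stop("negative actin concentration in grid")
  v <- michaelis_rate(kcat, Kapp, actin_grid)
  sd_abs <- if (noise$fraction) noise$sd * kcat else noise$sd
  if (sd_abs > 0) {
    v <- pmax(v + with_seed(noise$seed,
                            stats::rnorm(length(v), 0, sd_abs)), 0)
  }
  atpase_curve(actin_grid, v,
               truth = list(kcat = kcat, Kapp = Kapp, noise_sd = sd_abs))
}

#' Generate a chase-style release transient
#'
#' Displacement of bound labeled nucleotide by excess unlabeled ATP: the
#' simulation starts with the actomyosin.ADP complex, the ATP chase removes
#' AM as it forms, and the labeled-nucleotide signal decays at the
#' actin-activated ADP release rate k-AD (or at k-D for the myosin branch
#' with `acto = FALSE`).
#'
#' @param rates A [rate_constants()] object.
#' @param acto Chase from actomyosin (`TRUE`) or myosin (`FALSE`).
#' @param chase_atp Chasing ATP concentration (uM), clamped.
#' @param noise A [noise_spec()].
#' @param n_points Samples.
#' @return A `signal_trace`; truth records the expected release rate.
#' @export
generate_chase <- function(rates, acto = TRUE, chase_atp = 1000,
                           noise = noise_spec(), n_points = 300) {
  k_rel <- if (acto) rates$kAD_off else rates$kD_off
  conditions <- if (acto) {
    ligand_conditions(myosin = 0.5, actin = 0.5, atp = chase_atp,
                      clamp_ligands = c("ATP", "ADP"),
                      start_state = "rigor_adp")
  } else {
    # myosin.ADP decays by k-D; rebinding suppressed by the clamped ATP chase
    # acting as a trap for free myosin, and by the zero-clamped ADP pool
    ligand_conditions(myosin = 0.5, atp = chase_atp, adp = 0,
                      clamp_ligands = c("ATP", "ADP"),
                      start_state = "myosin_adp")
  }
  # only the pre-loaded (labeled) ADP states fluoresce; the unlabeled chase
  # nucleotide that replaces them is dark.  The species pool does not carry
  # labels, so phosphate release is zeroed for the chase: ADP regenerated
  # from the hydrolyzed chase ATP would be dark in the experiment and must
  # not repopulate the (labeled) ADP states; the labeled decay path is
  # unaffected, and the chase is a single-displacement measurement anyway.
  labeled <- observable_model("custom",
                              weights = c(AM.ADP = 1, M.ADP = 1))
  rates_chase <- rates
  rates_chase$k_pi_basal <- 0
  rates_chase$k_pi_actin_max <- 0
  times <- seq(0, 5 / k_rel, length.out = n_points)
  tr <- generate_transient(rates_chase, conditions, labeled, noise, times)
  attr(tr, "truth")$k_release <- k_rel
  tr
}

# ---- structural synthesis -------------------------------------------------

#' Build an ideal polypeptide backbone from internal coordinates
#'
#' Places backbone N/CA/C atoms sequentially (natural extension reference
#' frame) using standard bond lengths (C-N 1.329, N-CA 1.458, CA-C 1.525
#' Angstrom) and angles, with the supplied phi/psi/omega torsions. An ideal
#' alpha-helix is `phi = -57`, `psi = -47`; a fully extended chain is
#' `phi = psi = 180`.
#'
#' @param n_res Number of residues (>= 2).
#' @param phi,psi,omega Backbone torsions in degrees (recycled per residue).
#' @param chain Chain id.
#' @return A `structure_model` with N, CA, C atoms per residue.
#' @export
build_backbone <- function(n_res, phi = -57, psi = -47, omega = 180,
                           chain = "A") {
  stopifnot(n_res >= 2)
  phi <- rep_len(phi, n_res); psi <- rep_len(psi, n_res)
  omega <- rep_len(omega, n_res)
  b_CN <- 1.329; b_NCA <- 1.458; b_CAC <- 1.525
  a_CNCA <- 121.7; a_NCAC <- 111.2; a_CACN <- 116.2
  # seed residue: N at origin, CA on x, C in the xy-plane at the N-CA-C angle
  coords <- list(N = c(0, 0, 0), CA = c(b_NCA, 0, 0))
  coords$C <- coords$CA + b_CAC * c(-cos(a_NCAC * pi / 180),
                                    sin(a_NCAC * pi / 180), 0)
  atoms <- data.frame(name = c("N", "CA", "C"), resno = 1,
                      x = c(coords$N[1], coords$CA[1], coords$C[1]),
                      y = c(coords$N[2], coords$CA[2], coords$C[2]),
                      z = c(coords$N[3], coords$CA[3], coords$C[3]))
  prev <- list(A = coords$N, B = coords$CA, C = coords$C)
  for (r in 2:n_res) {
    N <- nerf_place(prev$A, prev$B, prev$C, b_CN, a_CACN, psi[r - 1])
    CA <- nerf_place(prev$B, prev$C, N, b_NCA, a_CNCA, omega[r - 1])
    C <- nerf_place(prev$C, N, CA, b_CAC, a_NCAC, phi[r])
    atoms <- rbind(atoms, data.frame(
      name = c("N", "CA", "C"), resno = r,
      x = c(N[1], CA[1], C[1]), y = c(N[2], CA[2], C[2]),
      z = c(N[3], CA[3], C[3])))
    prev <- list(A = N, B = CA, C = C)
  }
  atoms$chain <- chain
  atoms$resname <- "ALA"
  structure_model(atoms)
}

# Natural-extension (NeRF) placement: position D given A-B-C, the B-C-D bond
# length, the B-C-D..., i.e. bond (C-D), angle (B-C-D) and torsion (A-B-C-D).
nerf_place <- function(A, B, C, bond, angle_deg, torsion_deg) {
  ang <- angle_deg * pi / 180
  tor <- -torsion_deg * pi / 180  # sign chosen so the measured IUPAC dihedral equals the request
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  n <- cross3(B - A, bc); n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Generate a coordinate trajectory with planted properties
#'
#' Produces `n_frames` frames from a template model realizing requested
#' ground-truth features exactly:
#' \itemize{
#'   \item `rotation`: the selected domain rotates rigidly about a
#'     reproducible random axis through its centroid, linearly interpolated
#'     from 0 degrees (frame 1) to `degrees` (last frame); core atoms stay
#'     fixed, so [domain_rotation()] between first and last frame recovers
#'     the plant.
#'   \item `hbond`: one donor/acceptor atom pair is placed at
#'     `bonded_distance` in exactly `round(fraction * n_frames)` randomly
#'     chosen frames and at `unbonded_distance` otherwise, so
#'     [hbond_population()] recovers the planted occupancy exactly.
#' }
#' Optional iid Gaussian jitter is applied to atoms not involved in any
#' plant.
#'
#' @param template A `structure_model`.
#' @param n_frames Number of frames (>= 1).
#' @param rotation `NULL` or `list(selection=, degrees=)`.
#' @param hbond `NULL` or `list(donor=, acceptor=, fraction=,
#'   bonded_distance=2.8, unbonded_distance=4.5)`.
#' @param jitter_sd Gaussian jitter (Angstrom) on unplanted atoms.
#' @param seed RNG seed (axis choice, frame assignment, jitter).
#' @return A `coord_trajectory`; planted truth in attribute `truth`.
#' @export
generate_trajectory <- function(template, n_frames, rotation = NULL,
                                hbond = NULL, jitter_sd = 0, seed = 1L) {
  stopifnot(inherits(template, "structure_model"))
  if (n_frames < 1) stop("n_frames must be >= 1")
  na <- nrow(template$atoms)
  base <- coords_of(template)
  planted_idx <- integer(0)
  rot_idx <- NULL
  if (!is.null(rotation)) {
    rot_idx <- select_atoms(template, rotation$selection)
    if (length(rot_idx) < 3) stop("rotation selection needs >= 3 atoms")
    planted_idx <- c(planted_idx, rot_idx)
  }
  hb_idx <- NULL
  if (!is.null(hbond)) {
    di <- select_atoms(template, hbond$donor)
    ai <- select_atoms(template, hbond$acceptor)
    if (length(di) != 1 || length(ai) != 1) {
      stop("hbond plant requires exactly one donor and one acceptor atom")
    }
    if (hbond$fraction < 0 || hbond$fraction > 1) {
      stop("hbond fraction must be in [0, 1]")
    }
    if (!is.null(rot_idx) && any(c(di, ai) %in% rot_idx)) {
      stop("inconsistent plants: hbond atoms inside the rotation selection")
    }
    hb_idx <- c(donor = di, acceptor = ai)
    if (is.null(hbond$bonded_distance)) hbond$bonded_distance <- 2.8
    if (is.null(hbond$unbonded_distance)) hbond$unbonded_distance <- 4.5
    planted_idx <- c(planted_idx, di, ai)
  }
  with_seed(seed, {
    axis <- stats::rnorm(3)
    axis <- axis / sqrt(sum(axis^2))
    bonded_frames <- if (!is.null(hbond)) {
      k <- round(hbond$fraction * n_frames)
      sort(sample.int(n_frames, k))
    } else integer(0)
    xyz <- matrix(NA_real_, n_frames, 3 * na)
    for (f in seq_len(n_frames)) {
      fr <- base
      if (!is.null(rot_idx)) {
        theta <- if (n_frames == 1) rotation$degrees
                 else rotation$degrees * (f - 1) / (n_frames - 1)
        R <- rotation_about_axis(axis, theta)
        ctr <- colMeans(base[rot_idx, , drop = FALSE])
        fr[rot_idx, ] <- sweep(
          sweep(base[rot_idx, , drop = FALSE], 2, ctr) %*% t(R), 2, ctr, "+")
      }
      if (!is.null(hb_idx)) {
        d <- if (f %in% bonded_frames) hbond$bonded_distance
             else hbond$unbonded_distance
        dirv <- fr[hb_idx["acceptor"], ] - fr[hb_idx["donor"], ]
        nv <- sqrt(sum(dirv^2))
        if (nv < 1e-9) dirv <- c(1, 0, 0) else dirv <- dirv / nv
        fr[hb_idx["acceptor"], ] <- fr[hb_idx["donor"], ] + d * dirv
      }
      if (jitter_sd > 0) {
        free <- setdiff(seq_len(na), planted_idx)
        if (length(free)) {
          fr[free, ] <- fr[free, ] +
            matrix(stats::rnorm(3 * length(free), 0, jitter_sd),
                   ncol = 3)
        }
      }
      xyz[f, ] <- as.vector(t(fr))
    }
    out <- coord_trajectory(template$atoms, xyz)
    attr(out, "truth") <- list(
      rotation_degrees = if (!is.null(rotation)) rotation$degrees else NULL,
      rotation_axis = if (!is.null(rotation)) axis else NULL,
      hbond_fraction = if (!is.null(hbond)) length(bonded_frames) / n_frames
                       else NULL,
      seed = seed)
    out
  })
}
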