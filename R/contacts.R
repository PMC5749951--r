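# Distance-based interaction readouts: hydrogen-bond occupancies over
# trajectories, per-residue contact profiles, and the inscribed-sphere
# estimate of active-site pocket volume.

#' Hydrogen-bond detection criteria
#'
#' @param distance_cutoff Donor-acceptor heavy-atom distance cutoff
#'   (Angstrom), in (2, 5). The default 3.5 A, with no angle term, suits
#'   crystal structures that lack hydrogens.
#' @param angle_cutoff Optional donor-H-acceptor angle cutoff in degrees for
#'   trajectories with explicit hydrogens (`NULL` disables the angle term).
#' @return An `hbond_criteria` list.
#' @export
hbond_criteria <- function(distance_cutoff = 3.5, angle_cutoff = NULL) {
  if (!is.finite(distance_cutoff) ||
      distance_cutoff <= 2 || distance_cutoff >= 5) {
    stop("distance_cutoff must be in (2, 5) Angstrom")
  }
  structure(list(distance_cutoff = distance_cutoff,
                 angle_cutoff = angle_cutoff),
            class = "hbond_criteria")
}

element_of <- function(name) {
  # element from the atom name: first alphabetic character
  sub("^[0-9]*([A-Za-z]).*$", "\\1", name)
}

#' Hydrogen-bond population over a trajectory
#'
#' Fraction of frames in which any selected donor-acceptor heavy-atom pair
#' satisfies the distance criterion — the standard occupancy readout for an
#' interaction along an MD trajectory. A per-pair breakdown (fraction of
#' frames per donor/acceptor pair) is attached.
#'
#' @param traj A `coord_trajectory`.
#' @param donor_sel,acceptor_sel Non-empty atom selections
#'   (see [select_atoms()]).
#' @param criteria An [hbond_criteria()].
#' @return Numeric fraction in `[0, 1]` with attribute `per_pair`
#'   (data.frame `donor`, `acceptor`, `fraction`).
#' @export
hbond_population <- function(traj, donor_sel, acceptor_sel,
                             criteria = hbond_criteria()) {
  stopifnot(inherits(traj, "coord_trajectory"))
  id <- select_atoms(traj, donor_sel)
  ia <- select_atoms(traj, acceptor_sel)
  if (!length(id)) stop("empty donor selection")
  if (!length(ia)) stop("empty acceptor selection")
  nf <- n_frames(traj)
  cutoff2 <- criteria$distance_cutoff^2
  pair_hits <- matrix(0L, nrow = length(id), ncol = length(ia))
  any_hit <- logical(nf)
  for (f in seq_len(nf)) {
    m <- matrix(traj$xyz[f, ], ncol = 3, byrow = TRUE)
    D <- m[id, , drop = FALSE]
    A <- m[ia, , drop = FALSE]
    d2 <- outer(rowSums(D^2), rowSums(A^2), "+") - 2 * D %*% t(A)
    hit <- d2 <= cutoff2
    pair_hits <- pair_hits + hit
    any_hit[f] <- any(hit)
  }
  lab <- function(i) paste0(traj$atoms$chain[i], ":", traj$atoms$resno[i],
                            "@", traj$atoms$name[i])
  per_pair <- data.frame(
    donor = rep(lab(id), times = length(ia)),
    acceptor = rep(lab(ia), each = length(id)),
    fraction = as.vector(pair_hits) / nf
  )
  structure(mean(any_hit), per_pair = per_pair, class = "hbond_population")
}

#' @export
print.hbond_population <- function(x, ...) {
  cat("H-bond population:", format(unclass(as.numeric(x)), digits = 4), "\n")
  pp <- attr(x, "per_pair")
  pp <- pp[pp$fraction > 0, , drop = FALSE]
  if (nrow(pp)) {
    cat("per-pair fractions:\n")
    print(pp[order(-pp$fraction), ], row.names = FALSE)
  }
  invisible(x)
}

#' Contact profile of a residue
#'
#' Lists every inter-residue atom pair within a cutoff of the query residue,
#' classified as `hbond` when both partners are donor/acceptor heavy atoms
#' (N or O) within the hydrogen-bond cutoff, otherwise `vdW`. Sorted by
#' distance — the interaction-profile readout used to characterize a hub
#' residue's coordination.
#'
#' @param model A `structure_model`.
#' @param residue Selection resolving to the query residue's atoms (e.g.
#'   `"A:788"`).
#' @param cutoff Contact distance cutoff in Angstrom (default 4.0; van der
#'   Waals contacts are conventionally counted up to ~4.8-5).
#' @param hbond_cutoff Donor-acceptor cutoff for the `hbond` class.
#' @return data.frame with `atom` (query atom), `partner`, `partner_resno`,
#'   `distance`, `class`, sorted by distance.
#' @export
contact_profile <- function(model, residue, cutoff = 4.0, hbond_cutoff = 3.5) {
  iq <- select_atoms(model, residue)
  if (!length(iq)) stop("residue not found: ", residue)
  a <- model$atoms
  qres <- unique(paste(a$chain[iq], a$resno[iq]))
  other <- setdiff(which(!(paste(a$chain, a$resno) %in% qres)), iq)
  if (!length(other)) {
    return(data.frame(atom = character(0), partner = character(0),
                      partner_resno = integer(0), distance = numeric(0),
                      class = character(0)))
  }
  Q <- coords_of(model, iq)
  O <- coords_of(model, other)
  d2 <- outer(rowSums(Q^2), rowSums(O^2), "+") - 2 * Q %*% t(O)
  hits <- which(d2 <= cutoff^2, arr.ind = TRUE)
  if (!nrow(hits)) {
    return(data.frame(atom = character(0), partner = character(0),
                      partner_resno = integer(0), distance = numeric(0),
                      class = character(0)))
  }
  qi <- iq[hits[, 1]]
  oi <- other[hits[, 2]]
  dist <- sqrt(pmax(d2[hits], 0))
  el_q <- element_of(a$name[qi])
  el_o <- element_of(a$name[oi])
  cls <- ifelse(el_q %in% c("N", "O") & el_o %in% c("N", "O") &
                  dist <= hbond_cutoff, "hbond", "vdW")
  out <- data.frame(
    atom = paste0(a$resname[qi], a$resno[qi], "@", a$name[qi]),
    partner = paste0(a$resname[oi], a$resno[oi], "@", a$name[oi]),
    partner_resno = a$resno[oi],
    distance = dist, class = cls, stringsAsFactors = FALSE
  )
  out <- out[order(out$distance), ]
  rownames(out) <- NULL
  out
}

#' Inscribed-sphere estimate of a binding-pocket volume
#'
#' Describes the accessible volume around a site center by the largest sphere
#' that fits before touching the protein: radius = (distance from the
#' centroid of the center selection to the nearest non-selected protein heavy
#' atom) - probe, floored at 0; volume = 4/3 pi r^3. This inscribed-sphere
#' reading reproduces the published active-site sphere volumes (697 and
#' 3054 Angstrom^3 correspond to radii of 5.50 and 9.0 Angstrom).
#'
#' @param model A `structure_model` containing protein atoms.
#' @param center_sel Non-empty selection defining the site center.
#' @param probe Probe radius subtracted from the center-to-atom distance
#'   (Angstrom).
#' @return List with `radius` (Angstrom) and `volume` (Angstrom^3).
#' @export
pocket_sphere_volume <- function(model, center_sel, probe = 0) {
  ic <- select_atoms(model, center_sel)
  if (!length(ic)) stop("empty center selection")
  a <- model$atoms
  prot <- setdiff(which(a$record == "ATOM" & element_of(a$name) != "H"), ic)
  if (!length(prot)) stop("no protein atoms outside the center selection")
  ctr <- colMeans(coords_of(model, ic))
  P <- coords_of(model, prot)
  d <- sqrt(rowSums(sweep(P, 2, ctr)^2))
  r <- max(min(d) - probe, 0)
  list(radius = r, volume = 4 / 3 * pi * r^3)
}
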