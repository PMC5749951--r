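# Rigid-body and internal-coordinate geometry on structure models.

#' Optimal rigid superposition of two models
#'
#' Least-squares (Kabsch) superposition of `mobile` onto `target` over a
#' selection, returning the minimized RMSD and the proper rotation
#' (determinant +1) plus translation. Atoms are paired 1:1 by
#' (chain, residue number, atom name); unmatched selected residues raise an
#' error listing them.
#'
#' @param mobile,target `structure_model`s.
#' @param selection Selection (see [select_atoms()]) applied to both models;
#'   default all C-alpha atoms.
#' @return List with `rmsd` (Angstrom), `rotation` (3x3), `translation`
#'   (length-3), `n_atoms`, and `transformed` (the whole mobile model moved
#'   into the target frame).
#' @export
superpose <- function(mobile, target, selection = "@CA") {
  im <- select_atoms(mobile, selection)
  it <- select_atoms(target, selection)
  keym <- paste(mobile$atoms$chain[im], mobile$atoms$resno[im],
                mobile$atoms$name[im])
  keyt <- paste(target$atoms$chain[it], target$atoms$resno[it],
                target$atoms$name[it])
  common <- intersect(keym, keyt)
  un <- c(setdiff(keym, keyt), setdiff(keyt, keym))
  if (length(un)) {
    stop("selection does not map 1:1; unmatched atoms: ",
         paste(utils::head(un, 5), collapse = ", "),
         if (length(un) > 5) " ..." else "")
  }
  if (length(common) < 3) stop("need at least 3 paired atoms")
  P <- coords_of(mobile, im[match(common, keym)])
  Q <- coords_of(target, it[match(common, keyt)])
  if (collinear(P)) stop("selected atoms are collinear; superposition is degenerate")
  k <- kabsch(P, Q)
  moved <- sweep(coords_of(mobile) , 2, k$centroid_P) %*% k$R
  moved <- sweep(moved, 2, k$centroid_Q, "+")
  tm <- mobile
  tm$atoms$x <- moved[, 1]; tm$atoms$y <- moved[, 2]; tm$atoms$z <- moved[, 3]
  Pm <- sweep(sweep(P, 2, k$centroid_P) %*% k$R, 2, k$centroid_Q, "+")
  rmsd <- sqrt(mean(rowSums((Pm - Q)^2)))
  list(rmsd = rmsd, rotation = k$R,
       translation = as.numeric(k$centroid_Q - k$centroid_P %*% k$R),
       n_atoms = length(common), transformed = tm)
}

# Kabsch algorithm: optimal proper rotation mapping centered P onto centered Q.
kabsch <- function(P, Q) {
  cP <- colMeans(P); cQ <- colMeans(Q)
  Pc <- sweep(P, 2, cP); Qc <- sweep(Q, 2, cQ)
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  list(R = R, centroid_P = cP, centroid_Q = cQ)
}

collinear <- function(X, tol = 1e-8) {
  Xc <- sweep(X, 2, colMeans(X))
  s <- svd(Xc)$d
  s[2] <= tol * max(s[1], 1)
}

#' Root-mean-square deviation without refitting
#'
#' @param A,B Coordinate matrices (n x 3) in the same frame.
#' @return RMSD in Angstrom.
#' @export
rmsd_raw <- function(A, B) {
  stopifnot(all(dim(A) == dim(B)))
  sqrt(mean(rowSums((A - B)^2)))
}

#' Planar angle at a C-alpha triple
#'
#' The angle at the vertex residue `j` subtended by the C-alpha atoms of
#' residues `i` and `k` — the standard relay-helix kink readout (e.g. the
#' S489/M510/E521 triple, which fluctuates around 145 degrees in the kinked
#' pre-powerstroke helix and straightens towards 150 degrees).
#'
#' @param model A `structure_model`.
#' @param residues Length-3 vector of residue numbers `(i, j, k)`, vertex in
#'   the middle.
#' @param chain Chain id (default first chain).
#' @return Angle in degrees, in `[0, 180]`.
#' @export
ca_angle <- function(model, residues, chain = NULL) {
  stopifnot(length(residues) == 3)
  if (is.null(chain)) chain <- model$atoms$chain[1]
  get_ca <- function(r) {
    i <- which(model$atoms$chain == chain & model$atoms$resno == r &
                 model$atoms$name == "CA")
    if (!length(i)) stop("missing CA for residue ", r, " in chain ", chain)
    coords_of(model, i[1])[1, ]
  }
  p <- get_ca(residues[1]); v <- get_ca(residues[2]); q <- get_ca(residues[3])
  angle_at(p, v, q)
}

angle_at <- function(p, v, q) {
  u1 <- p - v; u2 <- q - v
  ct <- sum(u1 * u2) / sqrt(sum(u1^2) * sum(u2^2))
  ct <- min(1, max(-1, ct))
  acos(ct) * 180 / pi
}

# Signed dihedral of four points, IUPAC convention, range (-180, 180].
dihedral4 <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  m1 <- cross3(n1, b2 / sqrt(sum(b2^2)))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Backbone phi/psi dihedrals of a chain
#'
#' Computes phi (C_{i-1}, N_i, CA_i, C_i) and psi (N_i, CA_i, C_i, N_{i+1})
#' for every residue of a chain, IUPAC sign convention, range (-180, 180].
#' The first residue has undefined phi and the last undefined psi; dihedrals
#' spanning a chain break (peptide C-N distance above `break_cutoff`) are
#' `NA`.
#'
#' @param model A `structure_model` with backbone N/CA/C atoms.
#' @param chain Chain id (default first chain).
#' @param break_cutoff Maximum C-N bond length treated as contiguous
#'   (Angstrom).
#' @return data.frame with `resno`, `phi`, `psi` (degrees).
#' @export
backbone_dihedrals <- function(model, chain = NULL, break_cutoff = 2.0) {
  a <- model$atoms
  if (is.null(chain)) chain <- a$chain[1]
  a <- a[a$chain == chain & a$name %in% c("N", "CA", "C"), ]
  resnos <- sort(unique(a$resno))
  getc <- function(r, nm) {
    i <- which(a$resno == r & a$name == nm)
    if (!length(i)) return(NULL)
    as.numeric(a[i[1], c("x", "y", "z")])
  }
  out <- data.frame(resno = resnos, phi = NA_real_, psi = NA_real_)
  for (j in seq_along(resnos)) {
    r <- resnos[j]
    N <- getc(r, "N"); CA <- getc(r, "CA"); C <- getc(r, "C")
    if (is.null(N) || is.null(CA) || is.null(C)) next
    if (j > 1) {
      Cprev <- getc(resnos[j - 1], "C")
      if (!is.null(Cprev) && sqrt(sum((N - Cprev)^2)) <= break_cutoff) {
        out$phi[j] <- dihedral4(Cprev, N, CA, C)
      }
    }
    if (j < length(resnos)) {
      Nnext <- getc(resnos[j + 1], "N")
      if (!is.null(Nnext) && sqrt(sum((Nnext - C)^2)) <= break_cutoff) {
        out$psi[j] <- dihedral4(N, CA, C, Nnext)
      }
    }
  }
  out
}

#' Rigid rotation of a domain between two frames
#'
#' Superposes `frameB` onto `frameA` over a fixed core selection, then fits
#' the residual rigid transform of the domain selection and reports its
#' axis-angle rotation magnitude in degrees — the standard readout for e.g.
#' the converter rotation that directs lever-arm motion.
#'
#' @param frameA,frameB `structure_model`s sharing the relevant atoms.
#' @param core_sel Selection held fixed (reference frame).
#' @param domain_sel Selection whose rotation is measured.
#' @return Rotation magnitude in degrees, in `[0, 180]`; the rotation axis is
#'   attached as attribute `axis`.
#' @export
domain_rotation <- function(frameA, frameB, core_sel, domain_sel) {
  sup <- superpose(frameB, frameA, core_sel)
  moved <- sup$transformed
  ia <- select_atoms(frameA, domain_sel)
  ib <- select_atoms(moved, domain_sel)
  keya <- paste(frameA$atoms$chain[ia], frameA$atoms$resno[ia],
                frameA$atoms$name[ia])
  keyb <- paste(moved$atoms$chain[ib], moved$atoms$resno[ib],
                moved$atoms$name[ib])
  common <- intersect(keya, keyb)
  if (length(common) < 3) stop("domain selection too small to fit a rotation")
  P <- coords_of(moved, ib[match(common, keyb)])
  Q <- coords_of(frameA, ia[match(common, keya)])
  if (collinear(P) || collinear(Q)) {
    stop("degenerate (collinear) domain selection")
  }
  R <- kabsch(P, Q)$R
  tr <- sum(diag(R))
  ct <- min(1, max(-1, (tr - 1) / 2))
  ang <- acos(ct) * 180 / pi
  # rotation axis (undefined at 0 and 180 degrees)
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  nax <- sqrt(sum(ax^2))
  structure(ang, axis = if (nax > 1e-12) ax / nax else c(NA, NA, NA))
}

# Rotation matrix about a unit axis by an angle in degrees (Rodrigues).
rotation_about_axis <- function(axis, degrees) {
  axis <- axis / sqrt(sum(axis^2))
  th <- degrees * pi / 180
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}
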