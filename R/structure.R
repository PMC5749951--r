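#' Construct a structure model from an atom table
#'
#' A `structure_model` is a flat atom table: one row per atom with PDB-style
#' fields. Coordinates are in Angstrom; residue numbers follow the file
#' verbatim (author numbering, no renumbering).
#'
#' @param atoms data.frame with columns `serial`, `name` (atom name),
#'   `resname`, `resno`, `chain`, `alt`, `x`, `y`, `z`, `occupancy`, `b`,
#'   `record` ("ATOM"/"HETATM"). Missing metadata columns are filled with
#'   defaults.
#' @param model_id Integer model identifier.
#' @return A `structure_model`.
#' @export
structure_model <- function(atoms, model_id = 1L) {
  need <- c("name", "resno", "x", "y", "z")
  miss <- setdiff(need, colnames(atoms))
  if (length(miss)) stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  n <- nrow(atoms)
  if (n == 0) stop("empty model: no atoms")
  if (is.null(atoms$serial)) atoms$serial <- seq_len(n)
  if (is.null(atoms$resname)) atoms$resname <- "GLY"
  if (is.null(atoms$chain)) atoms$chain <- "A"
  if (is.null(atoms$alt)) atoms$alt <- ""
  if (is.null(atoms$occupancy)) atoms$occupancy <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  if (is.null(atoms$record)) atoms$record <- "ATOM"
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (any(!is.finite(xyz))) stop("non-finite coordinates")
  key <- paste(atoms$chain, atoms$resno, atoms$name, atoms$alt)
  if (anyDuplicated(key)) {
    stop("duplicate (chain, residue, atom, altloc) entries: ",
         key[duplicated(key)][1])
  }
  structure(list(atoms = atoms, model_id = model_id),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atoms
  cat("Structure model:", nrow(a), "atoms,",
      length(unique(paste(a$chain, a$resno))), "residues, chains:",
      paste(unique(a$chain), collapse = " "), "\n")
  invisible(x)
}

#' Multi-frame coordinate trajectory
#'
#' Frames share a single atom roster; only coordinates vary. Stands in for MD
#' snapshots or multi-MODEL PDB entries.
#'
#' @param atoms Atom table as in [structure_model()] (coordinates of frame 1).
#' @param xyz Numeric matrix, one row per frame, `3 * n_atoms` columns
#'   (x1,y1,z1,x2,...).
#' @param times Optional frame time labels (arbitrary units).
#' @return A `coord_trajectory`.
#' @export
coord_trajectory <- function(atoms, xyz, times = NULL) {
  model <- structure_model(atoms)
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3 * nrow(model$atoms)) {
    stop("xyz must have 3 * n_atoms columns")
  }
  if (nrow(xyz) < 1) stop("trajectory needs at least one frame")
  if (is.null(times)) times <- seq_len(nrow(xyz))
  structure(list(atoms = model$atoms, xyz = xyz, times = times),
            class = "coord_trajectory")
}

#' @export
print.coord_trajectory <- function(x, ...) {
  cat("Coordinate trajectory:", nrow(x$xyz), "frames x",
      nrow(x$atoms), "atoms\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `coord_trajectory`.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' Extract one frame of a trajectory as a structure model
#' @param traj A `coord_trajectory`.
#' @param i Frame index.
#' @export
frame_model <- function(traj, i) {
  if (i < 1 || i > n_frames(traj)) stop("frame index out of range")
  a <- traj$atoms
  m <- matrix(traj$xyz[i, ], ncol = 3, byrow = TRUE)
  a$x <- m[, 1]; a$y <- m[, 2]; a$z <- m[, 3]
  structure_model(a, model_id = i)
}

#' Read a PDB file into a structure model or trajectory
#'
#' Parses fixed-width ATOM/HETATM/MODEL records (via `bio3d::read.pdb` behind
#' this surface) after validating the record layout; a malformed fixed-width
#' line is reported with its line number. Alternate locations are resolved by
#' keeping the highest-occupancy conformer (ties broken towards altloc "A").
#' Files with several MODEL blocks return a [coord_trajectory()]; the frame
#' rosters of a multi-model file are identical by PDB construction and are
#' verified on load.
#'
#' @param path Path to a PDB file.
#' @param multi If `TRUE` (default) multi-MODEL files yield a trajectory; if
#'   `FALSE` only the first MODEL is kept.
#' @return A `structure_model` or `coord_trajectory`.
#' @export
read_structure <- function(path, multi = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) stop("no ATOM/HETATM records in ", path)
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54) {
      stop("malformed fixed-width record at line ", i, ": too short")
    }
    coords <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))
    if (any(is.na(suppressWarnings(as.numeric(coords))))) {
      stop("malformed fixed-width record at line ", i,
           ": non-numeric coordinate field")
    }
  }
  pdb <- bio3d::read.pdb(path, multi = multi, verbose = FALSE)
  a <- pdb$atom
  atoms <- data.frame(
    serial = a$eleno, name = a$elety, resname = a$resid,
    resno = a$resno, chain = ifelse(is.na(a$chain), "A", a$chain),
    alt = ifelse(is.na(a$alt), "", a$alt),
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, a$o), b = ifelse(is.na(a$b), 0, a$b),
    record = a$type, stringsAsFactors = FALSE
  )
  # altloc policy: highest occupancy wins, ties -> "A" (then alphabetical)
  key <- paste(atoms$chain, atoms$resno, atoms$name)
  keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(idx) {
    if (length(idx) == 1) return(idx)
    sub <- atoms[idx, ]
    best <- order(-sub$occupancy, sub$alt != "A", sub$alt)[1]
    idx[best]
  }), use.names = FALSE)
  keep <- sort(keep)
  atoms <- atoms[keep, ]
  rownames(atoms) <- NULL
  xyz <- pdb$xyz
  nmod <- if (is.matrix(xyz)) nrow(xyz) else 1L
  if (multi && nmod > 1) {
    cols <- as.vector(rbind(3 * keep - 2, 3 * keep - 1, 3 * keep))
    coord_trajectory(atoms, xyz[, cols, drop = FALSE])
  } else {
    structure_model(atoms)
  }
}

#' Select atoms with a compact selection syntax
#'
#' Selections are strings `"chain:resnum[-resnum][@atomname]"`; each component
#' is optional: `"A"` (whole chain), `"A:480-530"` (residue range),
#' `"A:489@CA"` (one named atom), `"@CA"` (all C-alpha), `":50-60"` (range in
#' any chain). A character vector unions its elements.
#'
#' @param model A `structure_model` (or `coord_trajectory`, whose roster is
#'   used).
#' @param sel Selection string(s), or an integer vector of atom indices
#'   (returned unchanged after range checking).
#' @return Sorted integer atom indices.
#' @export
select_atoms <- function(model, sel) {
  atoms <- if (inherits(model, "coord_trajectory")) model$atoms else model$atoms
  if (is.numeric(sel)) {
    sel <- as.integer(sel)
    if (any(sel < 1 | sel > nrow(atoms))) stop("atom index out of range")
    return(sort(unique(sel)))
  }
  idx <- integer(0)
  for (s in sel) {
    rest <- s
    atom_name <- NULL
    if (grepl("@", rest, fixed = TRUE)) {
      parts <- strsplit(rest, "@", fixed = TRUE)[[1]]
      rest <- parts[1]
      atom_name <- parts[2]
    }
    chain <- NULL
    resrange <- NULL
    if (grepl(":", rest, fixed = TRUE)) {
      parts <- strsplit(rest, ":", fixed = TRUE)[[1]]
      if (nzchar(parts[1])) chain <- parts[1]
      if (length(parts) > 1 && nzchar(parts[2])) resrange <- parts[2]
    } else if (nzchar(rest)) {
      chain <- rest
    }
    m <- rep(TRUE, nrow(atoms))
    if (!is.null(chain)) m <- m & atoms$chain == chain
    if (!is.null(resrange)) {
      rr <- strsplit(resrange, "-", fixed = TRUE)[[1]]
      lo <- as.integer(rr[1])
      hi <- if (length(rr) > 1) as.integer(rr[2]) else lo
      if (is.na(lo) || is.na(hi)) stop("bad residue range in selection: ", s)
      m <- m & atoms$resno >= lo & atoms$resno <= hi
    }
    if (!is.null(atom_name)) m <- m & atoms$name == atom_name
    idx <- c(idx, which(m))
  }
  sort(unique(idx))
}

coords_of <- function(model, idx = seq_len(nrow(model$atoms))) {
  as.matrix(model$atoms[idx, c("x", "y", "z")])
}

#' Write a structure model or trajectory as PDB text
#'
#' Minimal fixed-width writer for synthetic models; trajectories are written
#' as MODEL/ENDMDL blocks.
#'
#' @param x A `structure_model` or `coord_trajectory`.
#' @param path Output path.
#' @export
write_pdb <- function(x, path) {
  fmt_atom <- function(a) {
    nm <- a$name
    # atom-name column convention: 1-3 character names start in column 14
    nm_fmt <- ifelse(nchar(nm) >= 4, sprintf("%-4s", nm),
                     sprintf(" %-3s", nm))
    sprintf("%-6s%5d %s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
            a$record, a$serial, nm_fmt, substr(a$alt, 1, 1), a$resname,
            a$chain, a$resno, a$x, a$y, a$z, a$occupancy, a$b)
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(x, "structure_model")) {
    writeLines(fmt_atom(x$atoms), con)
    writeLines("END", con)
  } else if (inherits(x, "coord_trajectory")) {
    for (i in seq_len(n_frames(x))) {
      writeLines(sprintf("MODEL     %4d", i), con)
      writeLines(fmt_atom(frame_model(x, i)$atoms), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  } else {
    stop("x must be a structure_model or coord_trajectory")
  }
  invisible(path)
}
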