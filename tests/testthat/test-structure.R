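fixture <- function(name) {
  system.file("extdata", name, package = "myokin", mustWork = TRUE)
}

test_that("minimal PDB files parse with exact coordinates", {
  m <- read_structure(fixture("synthetic_minimal.pdb"))
  expect_s3_class(m, "structure_model")
  expect_equal(nrow(m$atoms), 2L)
  expect_equal(m$atoms$x, c(11.104, 12.560), tolerance = 1e-3)
  expect_equal(m$atoms$name, c("N", "CA"))
  expect_equal(m$atoms$resno, c(1L, 1L))
})

test_that("altloc resolution keeps the highest occupancy, ties go to A", {
  m <- read_structure(fixture("synthetic_altloc.pdb"))
  ca <- m$atoms[m$atoms$name == "CA", ]
  expect_equal(nrow(ca), 1L)
  expect_equal(ca$alt, "A")          # 0.6 beats 0.4
  expect_equal(ca$x, 1.458, tolerance = 1e-3)
  og <- m$atoms[m$atoms$name == "OG", ]
  expect_equal(nrow(og), 1L)
  expect_equal(og$alt, "A")          # 0.5/0.5 tie broken towards A
})

test_that("multi-MODEL files yield a trajectory with one shared roster", {
  traj <- read_structure(fixture("synthetic_models.pdb"))
  expect_s3_class(traj, "coord_trajectory")
  expect_equal(n_frames(traj), 3L)
  expect_equal(nrow(traj$atoms), 3L)
  # planted rigid 1 A x-shift between consecutive frames
  f1 <- frame_model(traj, 1); f3 <- frame_model(traj, 3)
  expect_equal(f3$atoms$x - f1$atoms$x, rep(2, 3), tolerance = 1e-3)
  expect_equal(f3$atoms$y, f1$atoms$y, tolerance = 1e-3)
})

test_that("malformed fixed-width records are reported with their line number", {
  bad <- tempfile(fileext = ".pdb")
  on.exit(unlink(bad))
  writeLines(c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00",
    "ATOM      2  CA  ALA A   1      12.xyz   6.071  -6.351  1.00  0.00"
  ), bad)
  expect_error(read_structure(bad), "line 2")
  writeLines("ATOM      1  N", bad)
  expect_error(read_structure(bad), "line 1")
  empty <- tempfile(fileext = ".pdb")
  on.exit(unlink(empty), add = TRUE)
  writeLines("END", empty)
  expect_error(read_structure(empty), "no ATOM")
})

test_that("PDB write/read round-trips models and trajectories", {
  m <- random_hetero_model(40, seed = 9)
  p <- tempfile(fileext = ".pdb")
  on.exit(unlink(p))
  write_pdb(m, p)
  back <- read_structure(p)
  expect_equal(coords_of_model(back), coords_of_model(m), tolerance = 1e-3)
  traj <- generate_trajectory(m, n_frames = 4,
                              rotation = list(selection = "A:1-5",
                                              degrees = 30), seed = 2)
  write_pdb(traj, p)
  back2 <- read_structure(p)
  expect_equal(n_frames(back2), 4L)
  expect_equal(back2$xyz, traj$xyz, tolerance = 1e-3)
})

test_that("the selection grammar resolves chains, ranges and atom names", {
  m <- structure_model(data.frame(
    name = c("N", "CA", "C", "CA", "CA"),
    resno = c(1, 1, 1, 2, 7),
    chain = c("A", "A", "A", "A", "B"),
    x = 1:5, y = 0, z = 0))
  expect_equal(select_atoms(m, "A"), 1:4)
  expect_equal(select_atoms(m, "@CA"), c(2L, 4L, 5L))
  expect_equal(select_atoms(m, "A:1@CA"), 2L)
  expect_equal(select_atoms(m, "A:1-2@CA"), c(2L, 4L))
  expect_equal(select_atoms(m, ":7"), 5L)
  expect_equal(select_atoms(m, c("A:2", "B")), c(4L, 5L))
  expect_error(select_atoms(m, 99), "out of range")
})

test_that("superposition matches the quaternion oracle on random clouds", {
  for (n in c(4, 10, 50, 500)) {
    mob <- random_cloud_model(n, seed = n)
    tgt <- random_cloud_model(n, seed = n + 1000)
    sup <- superpose(mob, tgt, "@CA")
    expect_equal(sup$rmsd, horn_rmsd(coords_of_model(mob),
                                     coords_of_model(tgt)),
                 tolerance = 1e-9)
    expect_equal(det(sup$rotation), 1, tolerance = 1e-9)
  }
})

test_that("superposition is exact under rigid motion and zero for identity", {
  m <- random_cloud_model(30, seed = 5)
  expect_equal(superpose(m, m)$rmsd, 0, tolerance = 1e-9)
  moved <- apply_rigid(m, seed = 7)
  expect_equal(superpose(moved, m)$rmsd, 0, tolerance = 1e-8)
})

test_that("fitting on a selection never does worse on it than a global fit", {
  set.seed(11)
  m <- random_cloud_model(60, seed = 21)
  pert <- m
  pert$atoms$x <- pert$atoms$x + rnorm(60, 0, 1)
  pert$atoms$y <- pert$atoms$y + rnorm(60, 0, 1)
  sel <- "A:1-20@CA"
  global <- superpose(pert, m, "@CA")
  idx <- select_atoms(m, sel)
  rmsd_sel_after_global <- rmsd_raw(coords_of_model(global$transformed)[idx, ],
                                    coords_of_model(m)[idx, ])
  direct <- superpose(pert, m, sel)
  expect_lte(direct$rmsd, rmsd_sel_after_global + 1e-12)
})

test_that("unmatched selections are reported by atom", {
  a <- random_cloud_model(5, seed = 1)
  b <- random_cloud_model(4, seed = 2)
  expect_error(superpose(a, b, "@CA"), "unmatched")
  tiny <- random_cloud_model(2, seed = 3)
  expect_error(superpose(tiny, tiny, "@CA"), "at least 3")
})

test_that("C-alpha angles: collinear, orthogonal and planted-kink cases", {
  line <- structure_model(data.frame(name = "CA", resno = 1:3, chain = "A",
                                     x = c(0, 1, 2), y = 0, z = 0))
  expect_equal(ca_angle(line, c(1, 2, 3)), 180, tolerance = 1e-9)
  ortho <- structure_model(data.frame(name = "CA", resno = 1:3, chain = "A",
                                      x = c(1, 0, 0), y = c(0, 0, 1), z = 0))
  expect_equal(ca_angle(ortho, c(1, 2, 3)), 90, tolerance = 1e-9)
  # kinked helix stand-in: arms of a 145-degree bend at the vertex residue,
  # the pre-powerstroke relay-helix angle regime
  th <- 145 * pi / 180
  kink <- structure_model(data.frame(
    name = "CA", resno = c(489, 510, 521), chain = "A",
    x = c(10, 0, 10 * cos(th)), y = c(0, 0, 10 * sin(th)), z = 0))
  expect_equal(ca_angle(kink, c(489, 510, 521)), 145, tolerance = 0.1)
  expect_error(ca_angle(kink, c(1, 2, 3)), "missing CA")
  # rigid-motion invariance
  moved <- apply_rigid(kink, seed = 4)
  expect_equal(ca_angle(moved, c(489, 510, 521)), 145, tolerance = 1e-6)
})

test_that("backbone dihedrals follow the IUPAC convention and handle breaks", {
  ext <- build_backbone(6, phi = 180, psi = 180)
  d <- backbone_dihedrals(ext)
  expect_true(is.na(d$phi[1]))            # first residue: no preceding C
  expect_true(is.na(d$psi[nrow(d)]))      # last residue: no following N
  mid <- 2:5
  expect_equal(abs(d$phi[mid]), rep(180, 4), tolerance = 1e-6)
  expect_equal(abs(d$psi[mid]), rep(180, 4), tolerance = 1e-6)
  helix <- build_backbone(8, phi = -57, psi = -47)
  dh <- backbone_dihedrals(helix)
  expect_equal(dh$phi[2:7], rep(-57, 6), tolerance = 2)
  expect_equal(dh$psi[2:7], rep(-47, 6), tolerance = 2)
  # dihedrals are invariant under global rigid motion
  dh2 <- backbone_dihedrals(apply_rigid(helix, seed = 8))
  expect_equal(dh2$phi[2:7], dh$phi[2:7], tolerance = 1e-6)
  # a chain break makes the spanning dihedrals undefined
  broken <- helix
  shift <- broken$atoms$resno >= 5
  broken$atoms$x[shift] <- broken$atoms$x[shift] + 50
  db <- backbone_dihedrals(broken)
  expect_true(is.na(db$phi[db$resno == 5]))
  expect_true(is.na(db$psi[db$resno == 4]))
})
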