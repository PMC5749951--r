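test_that("hydrogen-bond criteria are validated", {
  expect_error(hbond_criteria(1.5), "2, 5")
  expect_error(hbond_criteria(6), "2, 5")
  expect_equal(hbond_criteria()$distance_cutoff, 3.5)
})

test_that("fixed-distance pairs give populations of exactly 1 and 0", {
  atoms <- data.frame(name = c("N", "O"), resno = c(1, 2), chain = "A",
                      x = c(0, 2.8), y = 0, z = 0)
  close_traj <- coord_trajectory(atoms,
                                 matrix(rep(c(0, 0, 0, 2.8, 0, 0), 20),
                                        nrow = 20, byrow = TRUE))
  expect_equal(as.numeric(hbond_population(close_traj, "A:1@N", "A:2@O")), 1)
  far <- coord_trajectory(atoms,
                          matrix(rep(c(0, 0, 0, 4.5, 0, 0), 20),
                                 nrow = 20, byrow = TRUE))
  expect_equal(as.numeric(hbond_population(far, "A:1@N", "A:2@O")), 0)
  expect_error(hbond_population(far, "A:9@N", "A:2@O"), "empty donor")
})

test_that("a planted 55% occupancy over 1000 frames is recovered exactly", {
  template <- structure_model(data.frame(
    name = c("N", "O", "CA", "CA"), resno = c(1, 2, 3, 4), chain = "A",
    x = c(0, 4.5, 10, 12), y = 0, z = 0))
  traj <- generate_trajectory(template, n_frames = 1000,
                              hbond = list(donor = "A:1@N",
                                           acceptor = "A:2@O",
                                           fraction = 0.55), seed = 31)
  pop <- hbond_population(traj, "A:1@N", "A:2@O")
  expect_equal(as.numeric(pop), 0.55, tolerance = 1e-12)
  pp <- attr(pop, "per_pair")
  expect_equal(pp$fraction[pp$donor == "A:1@N" & pp$acceptor == "A:2@O"],
               0.55)
})

test_that("population equals the frame-averaged boolean oracle", {
  m <- random_hetero_model(30, seed = 12, spread = 6)
  traj <- generate_trajectory(m, n_frames = 50, jitter_sd = 0.8, seed = 13)
  di <- select_atoms(m, "@N")
  ai <- select_atoms(m, "@O")
  got <- as.numeric(hbond_population(traj, "@N", "@O"))
  expect_equal(got, brute_hbond_population(traj, di, ai, 3.5),
               tolerance = 1e-12)
})

test_that("contact profiles find, class and sort interactions", {
  two <- structure_model(data.frame(
    name = c("CB", "CG"), resno = c(1, 2), chain = "A",
    x = c(0, 3.0), y = 0, z = 0))
  cp <- contact_profile(two, "A:1", cutoff = 3.5)
  expect_equal(nrow(cp), 1L)
  expect_equal(cp$distance, 3.0, tolerance = 1e-9)
  expect_equal(cp$class, "vdW")  # carbon pair is never an H-bond
  # guanidinium nitrogen 2.8 A from a backbone carbonyl oxygen: H-bond class
  arg <- structure_model(data.frame(
    name = c("NH1", "NH2", "O", "C"), resno = c(788, 788, 730, 730),
    chain = "A",
    x = c(0, 1, 2.8, 3.8), y = c(0, 1.5, 0, 0.8), z = 0))
  cp2 <- contact_profile(arg, "A:788", cutoff = 4.0)
  hb <- cp2[cp2$class == "hbond", ]
  expect_true(any(abs(hb$distance - 2.8) < 1e-9 & hb$partner_resno == 730))
  expect_true(all(diff(cp2$distance) >= 0))
  expect_error(contact_profile(arg, "A:999"), "not found")
})

test_that("contact scan agrees with a brute-force all-pairs oracle", {
  m <- random_hetero_model(500, seed = 77)
  idx <- select_atoms(m, "A:3")
  cp <- contact_profile(m, "A:3", cutoff = 4.0)
  ref <- brute_contacts(m, idx, 4.0)
  expect_equal(nrow(cp), nrow(ref))
  expect_equal(cp$distance, ref$d, tolerance = 1e-9)
  # invariant under global rigid motion
  cp2 <- contact_profile(apply_rigid(m, seed = 5), "A:3", cutoff = 4.0)
  expect_equal(cp2$distance, cp$distance, tolerance = 1e-6)
})

test_that("domain rotation recovers planted angles and rejects degeneracy", {
  set.seed(99)
  n_core <- 30; n_dom <- 12
  atoms <- data.frame(
    name = "CA", resno = 1:(n_core + n_dom), chain = "A",
    x = runif(n_core + n_dom, -10, 10),
    y = runif(n_core + n_dom, -10, 10),
    z = runif(n_core + n_dom, -10, 10))
  m <- structure_model(atoms)
  core <- paste0("A:1-", n_core)
  dom <- paste0("A:", n_core + 1, "-", n_core + n_dom)
  expect_equal(as.numeric(domain_rotation(m, m, core, dom)), 0,
               tolerance = 1e-6)
  traj27 <- generate_trajectory(m, n_frames = 5,
                                rotation = list(selection = dom,
                                                degrees = 27), seed = 41)
  got <- domain_rotation(frame_model(traj27, 1), frame_model(traj27, 5),
                         core, dom)
  expect_equal(as.numeric(got), 27, tolerance = 0.1)
  traj180 <- generate_trajectory(m, n_frames = 2,
                                 rotation = list(selection = dom,
                                                 degrees = 180), seed = 43)
  expect_equal(as.numeric(domain_rotation(frame_model(traj180, 1),
                                          frame_model(traj180, 2),
                                          core, dom)), 180, tolerance = 0.1)
  # rigid-motion invariance: moving frame B wholesale changes nothing
  fb <- apply_rigid(frame_model(traj27, 5), seed = 6)
  expect_equal(as.numeric(domain_rotation(frame_model(traj27, 1), fb,
                                          core, dom)), 27, tolerance = 0.1)
  line <- structure_model(data.frame(name = "CA", resno = 101:105,
                                     chain = "A", x = 1:5, y = 0, z = 0))
  both <- structure_model(rbind(m$atoms, line$atoms))
  expect_error(domain_rotation(both, both, core, "A:101-105"), "collinear")
})

test_that("inscribed-sphere volumes reproduce the published active-site spheres", {
  wide <- shell_model(9.0)
  v <- pocket_sphere_volume(wide, "A:0@ZN")
  expect_equal(v$radius, 9.0, tolerance = 1e-9)
  expect_equal(v$volume, 3053.6, tolerance = 0.1)   # printed as 3054
  narrow <- shell_model(5.50)
  v2 <- pocket_sphere_volume(narrow, "A:0@ZN")
  expect_equal(v2$volume, 696.9, tolerance = 0.1)   # printed as 697
  expect_equal(v$volume / v2$volume, 4.3, tolerance = 0.02)  # the printed 4.3-fold jump
  # probe subtraction and the coincident-atom floor
  vp <- pocket_sphere_volume(wide, "A:0@ZN", probe = 1.4)
  expect_equal(vp$radius, 7.6, tolerance = 1e-9)
  coincident <- structure_model(data.frame(
    name = c("ZN", "CA"), resno = c(0, 1), chain = "A",
    x = 0, y = 0, z = 0))
  v0 <- pocket_sphere_volume(coincident, "A:0@ZN")
  expect_equal(v0$radius, 0)
  expect_equal(v0$volume, 0)
  expect_error(pocket_sphere_volume(coincident, "A:9@ZN"), "empty center")
})
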