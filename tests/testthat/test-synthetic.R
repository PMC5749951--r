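test_that("identical seed and spec give bit-identical traces", {
  rc <- nm2c_constants("NM2C")
  cond <- ligand_conditions(myosin = 0.5, atp = 10, clamp_ligands = TRUE)
  times <- seq(0, 1, length.out = 200)
  a <- generate_transient(rc, cond, "mant_fluorescence",
                          noise_spec(0.01, seed = 5), times)
  b <- generate_transient(rc, cond, "mant_fluorescence",
                          noise_spec(0.01, seed = 5), times)
  expect_identical(a$signal, b$signal)
  c2 <- generate_transient(rc, cond, "mant_fluorescence",
                           noise_spec(0.01, seed = 6), times)
  expect_false(identical(a$signal, c2$signal))
})

test_that("zero noise returns exactly the projected model curve", {
  rc <- nm2c_constants("NM2C")
  cond <- ligand_conditions(myosin = 0.5, atp = 10, clamp_ligands = TRUE)
  times <- seq(0, 1, length.out = 200)
  tr <- generate_transient(rc, cond, "mant_fluorescence", noise_spec(0), times)
  net <- build_network(rc)
  ref <- project_signal(simulate_cycle(net, cond, times),
                        observable_model("mant_fluorescence"))
  keep <- ref$time >= 0.0015  # dead-time truncation
  expect_identical(tr$signal, ref$signal[keep])
  expect_gte(min(tr$time), 0.0015)
})

test_that("the realized noise has the requested standard deviation", {
  rc <- rate_constants("flatline")  # null network: flat clean signal
  cond <- ligand_conditions(myosin = 1, atp = 0)
  times <- seq(0, 10, length.out = 10000)
  tr <- generate_transient(rc, cond, "mant_fluorescence",
                          noise_spec(0.01, seed = 8), times)
  resid <- tr$signal - 0  # clean curve is identically zero
  expect_lt(abs(sd(resid) - 0.0100), 2e-4)
})

test_that("noise does not perturb the caller's RNG stream", {
  set.seed(123)
  before <- rnorm(1)
  set.seed(123)
  rc <- nm2c_constants("NM2C")
  cond <- ligand_conditions(myosin = 0.5, atp = 10, clamp_ligands = TRUE)
  generate_transient(rc, cond, "mant_fluorescence", noise_spec(0.01, 5),
                     seq(0, 1, length.out = 50))
  expect_identical(rnorm(1), before)
})

test_that("series round-trips recover the generating constants within 5%", {
  rc <- nm2c_constants("NM2C")
  s <- generate_series(rc, "mant_adp_binding", c(1, 2, 5, 8, 12, 16, 20),
                       noise = noise_spec(0.01, seed = 11, fraction = TRUE))
  lf <- fit_kobs_linear(s)
  expect_lt(abs(lf$slope - 0.39) / 0.39, 0.05)
  expect_lt(abs(lf$intercept - 0.94) / 0.94, 0.05)
  s2 <- generate_series(rc, "mant_atp_binding", c(2, 5, 10, 15, 20, 30),
                        noise = noise_spec(0.01, seed = 7, fraction = TRUE))
  lf2 <- fit_kobs_linear(s2)
  expect_lt(abs(lf2$slope - 0.48) / 0.48, 0.05)
})

test_that("hyperbolic tryptophan-style series recover the hydrolysis saturation", {
  # generator truth k_max = 24.2 s^-1, K_half = 46.23 uM
  conc <- c(5, 10, 20, 40, 80, 160, 320, 400)
  k <- 24.2 * conc / (46.23 + conc)
  set.seed(15)
  s <- kobs_series(conc, k * (1 + rnorm(length(k), 0, 0.01)))
  hf <- fit_kobs_hyperbolic(s)
  expect_lt(abs(hf$k_max - 24.2) / 24.2, 0.05)
  expect_lt(abs(hf$K_half - 46.23) / 46.23, 0.10)
})

test_that("ATPase curve generation honours the half-saturation identity", {
  curve <- generate_atpase_curve(0.37, 129.4, c(0, 64.7, 129.4, 258.8, 500),
                                 noise_spec(0))
  expect_equal(curve$rate[curve$actin == 129.4], 0.37 / 2, tolerance = 1e-12)
  expect_equal(curve$rate[curve$actin == 0], 0)
  fit <- fit_michaelis(curve)
  expect_equal(fit$kcat, 0.37, tolerance = 1e-6)
  expect_error(generate_atpase_curve(0.37, 129.4, c(-5, 10)), "negative")
})

test_that("chase transients decay at the release rate for every construct", {
  for (cc in c("NM2C", "R788K", "R788E")) {
    rc <- nm2c_constants(cc)
    ch <- generate_chase(rc, acto = TRUE,
                         noise = noise_spec(0.01, seed = 3, fraction = TRUE))
    f <- fit_exponential(ch, 1)
    expect_lt(abs(f$phases$k_obs[1] - rc$kAD_off) / rc$kAD_off, 0.05)
  }
})

test_that("trajectory plants are validated and realized exactly", {
  m <- random_hetero_model(24, seed = 19)
  donor <- select_atoms(m, "@N")[1]
  acceptor <- select_atoms(m, "@O")[1]
  expect_error(generate_trajectory(m, 0), "n_frames")
  expect_error(generate_trajectory(m, 10,
                                   hbond = list(donor = donor,
                                                acceptor = acceptor,
                                                fraction = 1.5)),
               "fraction")
  # a donor inside the rotating domain would break the planted distance
  expect_error(generate_trajectory(
    m, 10,
    rotation = list(selection = "A:1-6", degrees = 20),
    hbond = list(donor = donor, acceptor = acceptor, fraction = 0.5)),
    "inconsistent")
  tr <- generate_trajectory(m, n_frames = 5,
                            rotation = list(selection = "A:4-6",
                                            degrees = 27), seed = 23)
  expect_equal(attr(tr, "truth")$rotation_degrees, 27)
  expect_identical(
    generate_trajectory(m, 5, rotation = list(selection = "A:4-6",
                                              degrees = 27), seed = 23)$xyz,
    tr$xyz)
})

test_that("ideal backbones are built with the requested internal coordinates", {
  helix <- build_backbone(6, phi = -57, psi = -47)
  a <- helix$atoms
  # bond lengths of the generated chain match the construction constants
  ca1 <- as.numeric(a[a$resno == 1 & a$name == "CA", c("x", "y", "z")])
  n1 <- as.numeric(a[a$resno == 1 & a$name == "N", c("x", "y", "z")])
  c1 <- as.numeric(a[a$resno == 1 & a$name == "C", c("x", "y", "z")])
  n2 <- as.numeric(a[a$resno == 2 & a$name == "N", c("x", "y", "z")])
  expect_equal(sqrt(sum((ca1 - n1)^2)), 1.458, tolerance = 1e-9)
  expect_equal(sqrt(sum((c1 - ca1)^2)), 1.525, tolerance = 1e-9)
  expect_equal(sqrt(sum((n2 - c1)^2)), 1.329, tolerance = 1e-9)
  expect_error(build_backbone(1), "n_res")
})
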