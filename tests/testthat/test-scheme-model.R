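test_that("rate constant sets validate inputs and resolve measurements", {
  expect_error(rate_constants("x", kD_on = -1), "kD_on")
  rc <- nm2c_constants("NM2C")
  expect_equal(rc$k1k2_myosin, 0.48)
  expect_equal(rc$kAD_off, 0.68)  # chase-derived, the simulation value
  expect_equal(measurement(rc, "kD_off", "mant_fluorescence", "intercept"),
               0.94)
  expect_equal(measurement(rc, "kAD_off", "light_scattering", "chase"), 0.39)
  # tryptophan-reported constants are not accessible for R788E
  r788e <- nm2c_constants("R788E")
  expect_true(is.na(measurement(r788e, "inv_K05", "tryptophan")))
  expect_true(is.na(r788e$inv_K05))
  labs <- vapply(c("NM2C", "R788K", "R788E"),
                 function(cc) nm2c_constants(cc)$construct_label, "")
  expect_false(anyDuplicated(labs) > 0)
})

test_that("an all-zero rate set gives a null network with constant occupancies", {
  rc <- rate_constants("null", k_pi_basal = 0, detach_rate = 0, kPiA_on = 0,
                       kPiA_off = 0)
  net <- build_network(rc)
  state <- c(M = 1, AM = 1, ATP = 100, A = 5)
  expect_true(all(reaction_fluxes(net, state) == 0))
  cond <- ligand_conditions(myosin = 1, actin = 5, atp = 100)
  traj <- simulate_cycle(net, cond, seq(0, 10, length.out = 20))
  for (sp in c("M", "M.ATP", "AM", "A", "ATP")) {
    expect_equal(diff(range(traj[[sp]])), 0)
  }
})

test_that("acto-branch ATP-induced dissociation saturates at k+2", {
  net <- build_network(nm2c_constants("NM2C"))
  # per-AM flux at overwhelming ATP approaches the isomerization limit
  fx <- reaction_fluxes(net, c(AM = 1, ATP = 1e9))
  expect_equal(unname(fx["atp_binding_acto"]), 643.06, tolerance = 1e-6)
  # hyperbolic form at finite ATP
  fx2 <- reaction_fluxes(net, c(AM = 1, ATP = 318))
  expect_equal(unname(fx2["atp_binding_acto"]), 643.06 * 318 / (318 + 318),
               tolerance = 1e-12)
})

test_that("deleting an edge by zeroing its constant removes its flux", {
  rc <- nm2c_constants("NM2C")
  rc$kAD_on <- 0
  net <- build_network(rc)
  fx <- reaction_fluxes(net, c(AM = 1, ADP = 50))
  expect_identical(unname(fx["adp_binding_acto"]), 0)
  # the release direction is untouched
  fx2 <- reaction_fluxes(net, c(AM.ADP = 1))
  expect_gt(unname(fx2["adp_release_acto"]), 0)
})

test_that("pseudo-first-order ATP binding matches the analytic exponential", {
  rc <- rate_constants("two", k1k2_myosin = 0.48, k_pi_basal = 0)
  net <- build_network(rc)
  cond <- ligand_conditions(myosin = 1, atp = 50, clamp_ligands = TRUE)
  traj <- simulate_cycle(net, cond, seq(0, 0.3, length.out = 150))
  ref <- exp(-0.48 * 50 * traj$time)
  expect_lt(max(abs(traj$M - ref) / pmax(ref, 1e-12)), 1e-6)
})

test_that("pseudo-first-order relaxations are mono-exponential within 1%", {
  rc <- nm2c_constants("NM2C")
  net <- build_network(rc)
  # ADP binding relaxation: k_obs = k+D [ADP] + k-D, ligand 10x over myosin
  adp <- 10
  cond <- ligand_conditions(myosin = 0.5, adp = adp, clamp_ligands = TRUE)
  k_true <- rc$kD_on * adp + rc$kD_off
  traj <- simulate_cycle(net, cond, seq(0, 5 / k_true, length.out = 200))
  fit <- fit_exponential(project_signal(traj, observable_model("mant_fluorescence")))
  expect_lt(abs(fit$phases$k_obs[1] - k_true) / k_true, 0.01)
})

test_that("myosin and actin totals are conserved to 1e-6 relative", {
  rc <- nm2c_constants("NM2C")
  net <- build_network(rc)
  cond <- ligand_conditions(myosin = 0.5, actin = 2, atp = 10)
  traj <- simulate_cycle(net, cond, seq(0, 60, length.out = 200))
  myosin_tot <- rowSums(traj[, c("M", "M.ATP", "M.ADP.Pi", "M.ADP",
                                 "AM", "AM.ATP", "AM.ADP.Pi", "AM.ADP")])
  actin_tot <- traj$A + rowSums(traj[, c("AM", "AM.ATP", "AM.ADP.Pi",
                                         "AM.ADP")])
  expect_lt(max(abs(myosin_tot - 0.5)) / 0.5, 1e-6)
  expect_lt(max(abs(actin_tot - 2)) / 2, 1e-6)
  expect_gt(min(as.matrix(traj[, -1])), -1e-9)
})

test_that("halving integrator tolerances leaves the solution unchanged to 1e-5", {
  rc <- nm2c_constants("NM2C")
  net <- build_network(rc)
  cond <- ligand_conditions(myosin = 0.5, actin = 2, atp = 10)
  times <- seq(0, 30, length.out = 100)
  a <- simulate_cycle(net, cond, times)
  b <- simulate_cycle(net, cond, times, atol = 5e-11, rtol = 5e-9)
  sc <- max(abs(as.matrix(a[, -1])))
  expect_lt(max(abs(as.matrix(a[, -1]) - as.matrix(b[, -1]))) / sc, 1e-5)
})

test_that("sub-stoichiometric mant-ATP turnover is triphasic: rise, plateau, decay", {
  rc <- nm2c_constants("NM2C")
  net <- build_network(rc)
  cond <- ligand_conditions(myosin = 0.5, atp = 0.375)  # no clamping
  traj <- simulate_cycle(net, cond, nm2c_full_times(300, 600))
  sig <- project_signal(traj, observable_model("mant_fluorescence"))
  y <- sig$signal
  t <- sig$time
  imax <- which.max(y)
  expect_gt(t[imax], 1)                # interior maximum, not at the edges
  expect_lt(t[imax], 200)
  # a large part of the sub-stoichiometric mant-ATP accumulates in bound
  # states; the slow basal product release drains the pool while the slow
  # second-order binding is still completing, capping the plateau height
  expect_gt(max(y), 0.7 * 0.375)
  # plateau: around the maximum the signal changes slowly relative to rise
  rise_rate <- max(diff(y[t < t[imax]]) / diff(t[t < t[imax]]))
  win <- which(t > t[imax] * 0.9 & t < t[imax] * 1.1)
  plateau_rate <- max(abs(diff(y[win]) / diff(t[win])))
  expect_lt(plateau_rate, 0.05 * rise_rate)
  # slow final decay towards release of hydrolysis products
  expect_lt(y[length(y)], 0.8 * max(y))
  expect_gt(y[length(y)], 0)
})

test_that("thermodynamic-box diagnostic: consistent sets close exactly, the measured set within 1.3x", {
  # self-consistent set: choose rates so K_AD/K_D == K_DA/K_A by construction
  rc <- rate_constants("consistent",
                       kD_on = 1, kD_off = 2,      # K_D  = 2
                       kAD_on = 1, kAD_off = 1,    # K_AD = 1 -> coupling 0.5
                       kA_on = 2, kA_off = 1,      # K_A  = 0.5
                       kDA_on = 4, kDA_off = 1)    # K_DA = 0.25 -> 0.5
  db <- detailed_balance_check(rc)
  expect_equal(db$box_ratio, 1, tolerance = 1e-12)
  db2 <- detailed_balance_check(nm2c_constants("NM2C"))
  expect_equal(db2$thermo_coupling, 0.11, tolerance = 0.05)
  expect_equal(db2$actin_affinity_coupling, 0.13, tolerance = 0.05)
  expect_lt(max(db2$box_ratio, 1 / db2$box_ratio), 1.3)
})

test_that("degenerate inputs are rejected with explicit errors", {
  net <- build_network(nm2c_constants("NM2C"))
  expect_error(simulate_cycle(net, ligand_conditions(myosin = 0, atp = 10),
                              seq(0, 1, 0.1)), "zero myosin")
  expect_error(simulate_cycle(net, ligand_conditions(myosin = 1),
                              c(0.5, 1)), "start at 0")
  expect_error(simulate_cycle(net, ligand_conditions(myosin = 1),
                              c(0, 1, 1)), "increasing")
  expect_error(ligand_conditions(myosin = -1), "concentrations")
  expect_error(ligand_conditions(myosin = 1, clamp_ligands = "XTP"),
               "unknown ligand")
})
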