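# 1:1 binding-model fits, assay simulators and the selectivity matrix.

test_that("steady-state fit inverts its own forward model exactly", {
  ts <- simulate_assay("spr_steady", list(KD = 18e-6, Rmax = 50),
                       list(top = 90e-6, dilution = 3, n_points = 8),
                       cv = 0, seed = 1)
  f <- fit_steady_state(ts)
  expect_true(f$converged)
  expect_equal(unname(f$parameters["KD"]), 18e-6, tolerance = 1e-8)
  expect_equal(unname(f$parameters["Rmax"]), 50, tolerance = 1e-8)
  expect_lt(f$residual_norm / 50, 1e-8)

  # closed form: the response at C = KD is half of Rmax
  at_kd <- simulate_assay("spr_steady", list(KD = 18e-6, Rmax = 50),
                          list(concentrations = 18e-6), cv = 0, seed = 1)
  expect_equal(at_kd$response, 25)
})

test_that("a response linear in concentration is flagged non-converged", {
  # KD far above the range: R ~ (Rmax/KD) * C, no curvature
  C <- c(1, 2, 4, 8, 16) * 1e-6
  ts <- titration_series(C, 1e4 * C, kind = "spr_steady")
  f <- fit_steady_state(ts)
  expect_false(f$converged)
  expect_true("no_curvature" %in% f$flags)
})

test_that("global kinetic fit recovers rate constants from noiseless traces", {
  des <- list(time = seq(0, 600, by = 2),
              concentrations = c(2e-6, 6e-6, 18e-6, 54e-6), t_assoc = 300)
  sg <- simulate_assay("spr_kinetic", list(ka = 1e5, kd = 1e-2, Rmax = 80),
                       des, cv = 0, seed = 1)
  f <- fit_kinetic_1to1(sg)
  expect_true(f$converged)
  expect_equal(unname(f$parameters["ka"]), 1e5, tolerance = 0.01)
  expect_equal(unname(f$parameters["kd"]), 1e-2, tolerance = 0.01)
  expect_equal(unname(f$parameters["KD"]),
               unname(f$parameters["kd"] / f$parameters["ka"]))

  # association plateau at C equals C*Rmax/(C+KD)
  C <- 18e-6; KD <- 1e-7
  plateau <- sg$traces[which.min(abs(sg$time - 300)), 3]
  expect_equal(plateau, C * 80 / (C + KD), tolerance = 1e-3)

  # dissociation half-life ln(2)/kd on the simulated trace
  r300 <- sg$traces[sg$time == 300, 1]
  r_half <- sg$traces[which.min(abs(sg$time - (300 + log(2) / 1e-2))), 1]
  expect_equal(r_half / r300, 0.5, tolerance = 0.01)
})

test_that("a dissociation window with no decay is flagged", {
  des <- list(time = seq(0, 120, by = 1),
              concentrations = c(5e-6, 20e-6), t_assoc = 60)
  sg <- simulate_assay("spr_kinetic", list(ka = 1e5, kd = 5e-5, Rmax = 60),
                       des, cv = 0, seed = 2)
  f <- fit_kinetic_1to1(sg)
  expect_true("no_observable_decay" %in% f$flags)
})

test_that("Boltzmann melt fit recovers Tm and its midpoint property", {
  d <- simulate_assay("dsf", list(Tm = 52, slope = 2, Fmin = 100, Fmax = 1000),
                      list(temperatures = seq(25, 85)), cv = 0, seed = 1)
  f <- fit_boltzmann_tm(d$temperature, d$fluorescence)
  expect_true(f$converged)
  expect_equal(unname(f$parameters["Tm"]), 52, tolerance = 1e-6)

  # F(Tm) is the plateau midpoint
  fmid <- 100 + (1000 - 100) / 2
  at_tm <- d$fluorescence[d$temperature == 52]
  expect_equal(at_tm, fmid)

  flat <- fit_boltzmann_tm(seq(25, 85), rep(500, 61))
  expect_false(flat$converged)
})

test_that("FP displacement fit recovers the inflection and flags flat curves", {
  doses <- 1e-4 / 3^(11:0)
  fp <- simulate_assay("fp", list(Kdisp = 1e-6, hill = 1, top = 200,
                                  bottom = 50),
                       list(concentrations = doses), cv = 0, seed = 1)
  f <- fit_fp_displacement(fp)
  expect_true(f$converged)
  expect_equal(unname(f$parameters["Kdisp"]), 1e-6, tolerance = 1e-6)

  # response at the inflection sits midway between the plateaus
  at_k <- simulate_assay("fp", list(Kdisp = 1e-6, hill = 1, top = 200,
                                    bottom = 50),
                         list(concentrations = 1e-6), cv = 0, seed = 1)
  expect_equal(at_k$response, 125)

  flat <- titration_series(doses, rep(200, 12), kind = "fp")
  ff <- fit_fp_displacement(flat)
  expect_false(ff$converged)
  expect_true("non_displacing" %in% ff$flags)
})

test_that("noisy parameter recovery stays within stated error bands", {
  # steady state at 2% noise: median KD error below 10%
  kd_err <- vapply(1:40, function(s) {
    ts <- simulate_assay("spr_steady", list(KD = 18e-6, Rmax = 50),
                         list(top = 90e-6, dilution = 3, n_points = 8),
                         cv = 0.02, seed = s)
    f <- fit_steady_state(ts)
    abs(f$parameters[["KD"]] - 18e-6) / 18e-6
  }, numeric(1))
  expect_lte(stats::median(kd_err), 0.10)

  # melt at 1% noise, 1 degree sampling: Tm within 0.2 degrees C
  tm_err <- vapply(1:40, function(s) {
    d <- simulate_assay("dsf", list(Tm = 52, slope = 2, Fmin = 100,
                                    Fmax = 1000),
                        list(temperatures = seq(25, 85)), cv = 0.01, seed = s)
    abs(fit_boltzmann_tm(d$temperature, d$fluorescence)$parameters[["Tm"]] - 52)
  }, numeric(1))
  expect_lte(stats::median(tm_err), 0.2)
})

test_that("steady-state KD agrees with kinetic kd/ka on shared truth", {
  ka <- 1e5; kd <- 1.8e-3; rmax <- 60        # KD = 18 uM
  KD <- kd / ka
  des <- list(time = seq(0, 900, by = 3),
              concentrations = KD * c(0.25, 1, 4, 16), t_assoc = 600)
  sgf <- fit_kinetic_1to1(simulate_assay("spr_kinetic",
                                         list(ka = ka, kd = kd, Rmax = rmax),
                                         des, cv = 0.02, seed = 5))
  ssf <- fit_steady_state(simulate_assay("spr_steady",
                                         list(KD = KD, Rmax = rmax),
                                         list(top = 16 * KD, dilution = 2,
                                              n_points = 8),
                                         cv = 0.02, seed = 6))
  expect_equal(unname(ssf$parameters["KD"]), unname(sgf$parameters["KD"]),
               tolerance = 0.05)
})

test_that("assay simulation is deterministic and exact at zero noise", {
  a <- simulate_assay("fp", list(Kdisp = 2e-6, hill = 1.2, top = 180,
                                 bottom = 40),
                      list(concentrations = 1e-4 / 2^(0:9)), cv = 0.03,
                      seed = 77)
  b <- simulate_assay("fp", list(Kdisp = 2e-6, hill = 1.2, top = 180,
                                 bottom = 40),
                      list(concentrations = 1e-4 / 2^(0:9)), cv = 0.03,
                      seed = 77)
  expect_identical(a, b)

  clean <- simulate_assay("spr_steady", list(KD = 1e-6, Rmax = 10),
                          list(concentrations = c(1e-7, 1e-6, 1e-5)),
                          cv = 0, seed = 1)
  expect_equal(clean$response, 10 * clean$concentration /
                 (clean$concentration + 1e-6))
})

test_that("selectivity matrix normalizes, averages and clamps", {
  panel <- data.frame(
    compound = rep(c("cpd1", "cpd2"), each = 6),
    protein = rep(rep(c("P1", "P2"), each = 3), 2),
    replicate = rep(1:3, 4),
    response = c(40, 50, 60,   0, 0, 0,     90, 100, 110,  10, 12, 14))
  rmax <- data.frame(compound = rep(c("cpd1", "cpd2"), each = 2),
                     protein = rep(c("P1", "P2"), 2),
                     rmax_theoretical = c(100, 100, 50, NA))
  m <- selectivity_matrix(panel, rmax)
  expect_equal(m["cpd1", "P1"], 50)       # mean(40,50,60)/100 * 100
  expect_equal(m["cpd1", "P2"], 0)
  expect_equal(m["cpd2", "P1"], 120)      # 200% clamps at 120
  expect_true(attr(m, "over_range")["cpd2", "P1"])
  expect_true(is.na(m["cpd2", "P2"]))     # missing Rmax -> not computable

  # replicate order cannot matter (up to row/column ordering)
  m2 <- selectivity_matrix(panel[sample(nrow(panel)), ], rmax)
  expect_equal(m2[rownames(m), colnames(m)], unclass(m)[, ],
               ignore_attr = TRUE)
})

test_that("theoretical Rmax scales surface capacity by the mass ratio", {
  # 5000 RU of a 50 kDa protein binding a 500 Da compound -> 50 RU
  expect_equal(theoretical_rmax(5000, 500, 50000), 50)
})
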