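test_that("noise-free organoid trajectories follow the growth/death model", {
  cl <- cloneParams(growth_rate = log(2) / 24)
  # no drug: exponential doubling
  tr <- organoidTrajectory(cl, conc = 0, times = c(0, 24), A0 = 1000)
  expect_equal(tr$bf_area, c(1000, 2000))
  expect_equal(tr$green_area, c(0, 0))

  # saturating dose with death rate >> k: fully green by the last timepoint
  cl2 <- cloneParams(ec50 = 10, max_death_rate = 0.1)
  tr2 <- organoidTrajectory(cl2, conc = 1e5, times = seq(0, 120, 24),
                            A0 = 1000)
  expect_gt(tr2$green_area[6L] / tr2$bf_area[6L], 0.999)

  # zero invasion propensity: invasive area identically 0
  tr3 <- organoidTrajectory(cloneParams(invasion_propensity = 0), conc = 400,
                            times = seq(0, 120, 24), induction = 2)
  expect_true(all(tr3$inv_area == 0))

  # invasion switched on only by propensity x induction > 0
  cl4 <- cloneParams(invasion_propensity = 0.5)
  tr4 <- organoidTrajectory(cl4, conc = 400, times = seq(0, 120, 24),
                            induction = 1.5)
  expect_true(all(tr4$inv_area[-1L] > 0))
  expect_true(all(tr4$inv_green_area <= tr4$inv_area))

  expect_error(organoidTrajectory(cl, conc = -1, times = c(0, 24)),
               class = "orgscreen_config_error")
  expect_error(organoidTrajectory(cl, conc = 0, times = c(24, 0)),
               class = "orgscreen_config_error")
})

test_that("simulated plates are byte-identical under a fixed seed", {
  cfg <- simConfig(organoidsPerWell = 15, seed = 42L)
  s1 <- simulatePlate(cfg)
  s2 <- simulatePlate(cfg)
  expect_identical(measurements(s1$screen), measurements(s2$screen))
  expect_identical(s1$truth, s2$truth)
  s3 <- simulatePlate(simConfig(organoidsPerWell = 15, seed = 43L))
  expect_false(identical(measurements(s1$screen), measurements(s3$screen)))
})

test_that("simulated screens satisfy the container invariants", {
  sim <- simulatePlate(simConfig(organoidsPerWell = 15, seed = 7L))
  m <- measurements(sim$screen)
  expect_true(all(m$green_area <= m$bf_area))
  expect_true(all(m$inv_green_area <= m$inv_area))
  expect_true(all(m$bf_area >= 0))
  expect_s4_class(sim$screen, "OrganoidScreen")
  expect_equal(nrow(validateDataset(sim$screen)), 0L)
})

test_that("staurosporine wells reach complete kill by the final timepoint", {
  sim <- simulatePlate(simConfig(organoidsPerWell = 25, seed = 11L))
  m <- measurements(sim$screen)
  l <- plateLayout(sim$screen)
  pos <- unique(l$well[l$role == "positive_control"])
  for (w in pos) {
    mw <- m[m$well == w & m$time_h == max(m$time_h), ]
    expect_gte(sum(mw$green_area) / sum(mw$bf_area), 0.95)
  }
})

test_that("vehicle wells score NDR 1 on a noise-free plate", {
  sim <- simulatePlate(simConfig(organoidsPerWell = 10, noiseSd = 0,
                                 seed = 2L))
  wm <- wellMetrics(sim$screen)
  veh <- wm$ndr[wm$role == "negative_control"]
  expect_true(all(abs(veh - 1) < 1e-6))
})

test_that("ground-truth death fractions agree with emitted green/bf within noise", {
  cfg <- simConfig(organoidsPerWell = 20, seed = 9L, noiseSd = 0.05)
  sim <- simulatePlate(cfg)
  m <- measurements(sim$screen)
  d <- sim$truth$death
  merged <- merge(m, d, by = c("plate_id", "well", "organoid_id", "time_h"))
  obs_fa <- merged$green_area / merged$bf_area
  # two independent lognormal factors: fa/true ratio has log-sd sqrt(2)*0.05
  resid <- log(obs_fa[merged$true_death_fraction > 0.01] /
                 merged$true_death_fraction[merged$true_death_fraction > 0.01])
  expect_lt(stats::quantile(abs(resid), 0.99), 4 * sqrt(2) * cfg@noiseSd)
})

test_that("expected final area is non-increasing in dose for death-dominant clones", {
  cl <- cloneParams(ec50 = 200, max_death_rate = 0.05)
  concs <- c(1, 10, 100, 1000, 10000)
  finals <- vapply(concs, function(cc) {
    tr <- organoidTrajectory(cl, conc = cc, times = seq(0, 120, 24),
                             A0 = 1000)
    tr$bf_area[6L]
  }, numeric(1))
  expect_true(all(diff(finals) <= 0))
})

test_that("a planted resistant fraction is recovered by fraction-affected counting", {
  cfg <- simConfig(
    clones = rbind(
      cloneParams(fraction = 0.7, ec50 = 100, max_death_rate = 0.045),
      cloneParams(fraction = 0.3, ec50 = 5e4, max_death_rate = 0.002)),
    regimens = data.frame(regimen = "gem-pac", concentration = 10000,
                          invasion_induction = 0),
    organoidsPerWell = 200, seed = 21L
  )
  sim <- simulatePlate(cfg)
  st <- organoidStates(sim$screen)
  trt <- st[st$role == "treatment" & st$time_h == 120, ]
  expect_equal(mean(trt$fa < 0.15), 0.3, tolerance = 0.1 / 0.3)
})

test_that("stock scenarios carry the intended ground-truth classes", {
  scens <- defaultScenarios(seed = 1L, organoidsPerWell = 5)
  expect_named(scens, c("cytotoxic_responder", "cytostatic_responder",
                        "heterogeneous", "invasion_inducer"))
  for (nm in names(scens)) expect_s4_class(scens[[nm]], "SimConfig")

  top <- function(sim) {
    w <- sim$truth$wells[sim$truth$wells$role == "treatment", ]
    w[w$concentration == max(w$concentration), ]
  }
  tox <- top(simulatePlate(scens$cytotoxic_responder))
  expect_true(all(tox$expected_class == "cytotoxic"))
  expect_true(all(tox$expected_ndr < -0.5))
  stat <- top(simulatePlate(scens$cytostatic_responder))
  expect_true(all(stat$expected_class == "cytostatic"))
  expect_true(all(stat$expected_cell_death < 40))

  inv <- scens$invasion_inducer@regimens
  expect_true(all(inv$invasion_induction[inv$regimen == "paclitaxel"] > 0))
  expect_true(all(inv$invasion_induction[inv$regimen != "paclitaxel"] == 0))
})

test_that("invalid simulator configurations are rejected", {
  expect_error(simConfig(clones = cloneParams(fraction = 0.5)), "sum to 1")
  expect_error(cloneParams(ec50 = -1), class = "orgscreen_config_error")
  expect_error(simConfig(times = c(24, 0)), "ascending")
  expect_error(simConfig(noiseSd = -0.1), "noiseSd")
})
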