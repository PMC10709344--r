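test_that("well signal and fold change follow the signal definition", {
  m <- rbind(
    makeMeasurements(wells = "A01", times = 0, organoids = 2L,
                     bf = 500, green = 50),
    makeMeasurements(wells = "A01", times = 24, organoids = 2L,
                     bf = 1000, green = 200)
  )
  ws <- wellSignal(m, "A01")
  expect_equal(ws$signal, c(900, 1600))
  expect_equal(ws$fold_change, c(1, 1600 / 900))
  expect_equal(ws$fold_change[2L], 1.778, tolerance = 1e-3)

  # fully green final timepoint: signal and fold collapse to 0
  m2 <- rbind(
    makeMeasurements(wells = "A01", times = 0, bf = 500, green = 0),
    makeMeasurements(wells = "A01", times = 24, bf = 500, green = 500)
  )
  ws2 <- wellSignal(m2, "A01")
  expect_equal(ws2$signal[2L], 0)
  expect_equal(ws2$fold_change[2L], 0)

  expect_error(wellSignal(makeMeasurements(times = 0), "A01"),
               "single timepoint", class = "orgscreen_data_error")
  m3 <- makeMeasurements(bf = 100, green = 100)
  expect_error(wellSignal(m3, "A01"), class = "orgscreen_degenerate_well")
})

test_that("percent viability maps the anchors to 100/0 and is affine", {
  expect_equal(percentViability(4, 4, 0.25), 100)
  expect_equal(percentViability(0.25, 4, 0.25), 0)
  expect_equal(percentViability((4 + 0.25) / 2, 4, 0.25), 50)
  expect_error(percentViability(1, 2, 2), class = "orgscreen_anchor_error")
  # vehicle-only fallback
  expect_equal(percentViability(2, 4), 50)
  # affine: order by viability equals order by fold change
  f <- runif(20, 0.1, 5)
  expect_identical(order(percentViability(f, 4, 0.25)), order(f))
})

test_that("GR metric hits its closed-form anchors", {
  expect_equal(grMetric(4, 4), 1)
  expect_equal(grMetric(1, 4), 0)
  expect_equal(grMetric(1.5, 2), 0.5)
  expect_error(grMetric(1.5, 0.9), class = "orgscreen_slow_growth")
  expect_error(grMetric(-1, 4), class = "orgscreen_metric_error")
})

test_that("NDR metric reproduces the printed anchor scale", {
  expect_identical(ndrMetric(0.25, 4, 0.25), -1)       # complete killing
  expect_identical(ndrMetric(1, 4, 0.25), 0)           # growth inhibition
  expect_equal(ndrMetric(2, 4, 0.25), (sqrt(2) - 1) / (1 - 0.5))
  expect_equal(ndrMetric(2, 4, 0.25), 0.8284, tolerance = 1e-4)
  expect_error(ndrMetric(1, 0.8, 0.25), class = "orgscreen_slow_growth")
})

test_that("NDR anchors are exact for arbitrary valid controls", {
  set.seed(1)
  for (i in 1:50) {
    f_neg <- runif(1, 1.05, 30)
    f_pos <- runif(1, 1e-6, 0.9)
    expect_equal(ndrMetric(f_pos, f_neg, f_pos), -1)
    expect_equal(ndrMetric(1, f_neg, f_pos), 0)
    # GR and NDR always share a sign
    f_trt <- runif(1, 0.01, f_neg * 1.5)
    expect_equal(sign(ndrMetric(f_trt, f_neg, f_pos)),
                 sign(grMetric(f_trt, f_neg)))
  }
})

test_that("NDR approaches GR as the positive control dies completely", {
  f_neg <- 4; f_trt <- 2
  gr <- grMetric(f_trt, f_neg)
  expect_equal(ndrMetric(f_trt, f_neg, 2^-40), gr, tolerance = 1e-5)
  expect_identical(ndrMetric(f_trt, f_neg, 0), gr)
})

test_that("dose-response AUC is a span-normalized trapezoid over log10 dose", {
  conc <- c(1, 10, 100, 1000)
  expect_equal(doseResponseAUC(conc, rep(1, 4)), 1)
  expect_equal(doseResponseAUC(conc, rep(0, 4)), 0)
  # linear from 1 to -1 in log10 c integrates to 0
  expect_equal(doseResponseAUC(conc, seq(1, -1, length.out = 4)), 0)
  expect_error(doseResponseAUC(c(10, 1), c(0, 0)),
               class = "orgscreen_metric_error")
  expect_error(doseResponseAUC(c(1, 1), c(0, 0)),
               class = "orgscreen_metric_error")
  expect_error(doseResponseAUC(c(0, 1), c(0, 0)),
               class = "orgscreen_metric_error")
})

test_that("AUC ratio contrasts combination and alternative regimens", {
  expect_equal(aucRatio(0.5, 0.5), 1)
  expect_equal(aucRatio(0.4, 0.8), 0.5)
  expect_error(aucRatio(0.4, 0), class = "orgscreen_metric_error")
})

test_that("response signatures are classified by the NDR x cell-death rules", {
  expect_equal(classifySignature(-0.7, 60)$label, "cytotoxic")
  expect_equal(classifySignature(-0.1, 55)$label, "mixed")
  expect_equal(classifySignature(0.2, 10)$label, "cytostatic")
  expect_equal(classifySignature(-0.7, 10)$label, "indeterminate")
  # rule set is total on a grid
  grid <- expand.grid(ndr = seq(-1.5, 1.5, 0.25), cd = seq(0, 100, 10))
  labs <- classifySignature(grid$ndr, grid$cd)$label
  expect_true(all(labs %in% c("cytotoxic", "mixed", "cytostatic",
                              "indeterminate")))
})

test_that("whole-screen well metrics anchor on the plate controls", {
  scr <- makeToyScreen()
  wm <- wellMetrics(scr)
  # positive controls fully dead at the endpoint: NDR coincides with GR
  expect_equal(wm$ndr[wm$well == "A01"], 1)
  expect_equal(wm$ndr[wm$well == "A03"], -1)
  expect_equal(wm$ndr[wm$well == "A05"], sqrt(2) - 1)
  expect_equal(wm$ndr[wm$well == "A06"], 0)
  expect_equal(wm$viability[wm$well == "A06"], 25)
  expect_equal(wm$cell_death[wm$well == "A03"], 100)
  # kinetic variant returns one row per requested timepoint
  wmk <- wellMetrics(scr, timepoints = c(24, 48))
  expect_equal(sort(unique(wmk$time_h)), c(24, 48))
})

test_that("NDR decreases with the simulated death rate at fixed growth", {
  ndr_at <- function(death) {
    cfg <- simConfig(clones = cloneParams(ec50 = 100,
                                          max_death_rate = death),
                     regimens = data.frame(regimen = "d",
                                           concentration = 1e4,
                                           invasion_induction = 0),
                     organoidsPerWell = 10, noiseSd = 0, seed = 5L)
    sim <- simulatePlate(cfg)
    wm <- wellMetrics(sim$screen)
    mean(wm$ndr[wm$role == "treatment"])
  }
  ndrs <- vapply(c(0, 0.005, 0.02, 0.05), ndr_at, numeric(1))
  expect_true(all(diff(ndrs) < 0))
})

test_that("noisy vehicle-like treatment wells score NDR 1 within noise", {
  cfg <- simConfig(clones = cloneParams(ec50 = 1e9),  # drug-inert clone
                   regimens = data.frame(regimen = "inert",
                                         concentration = 400,
                                         invasion_induction = 0),
                   organoidsPerWell = 100, noiseSd = 0.05, seed = 13L)
  sim <- simulatePlate(cfg)
  wm <- wellMetrics(sim$screen)
  trt <- wm$ndr[wm$role == "treatment"]
  # noise sd propagated through the fold-change ratio is a few percent
  expect_true(all(abs(trt - 1) < 3 * 0.05))
})

test_that("per-regimen dose-response profiles average replicates and integrate", {
  sim <- simulatePlate(simConfig(organoidsPerWell = 20, noiseSd = 0,
                                 seed = 3L))
  dr <- doseResponse(sim$screen)
  expect_equal(nrow(dr$profile), 5L)
  expect_equal(nrow(dr$auc), 1L)
  exp_ndr <- sim$truth$wells$expected_ndr[sim$truth$wells$role == "treatment"]
  expect_equal(dr$profile$ndr, unique(exp_ndr), tolerance = 1e-6)
  expect_equal(dr$auc$auc,
               doseResponseAUC(dr$profile$concentration, dr$profile$ndr))
})
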