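## Seeded generative model of a 384-well organoid screen with ground truth.
##
## Two-compartment phenomenology per organoid: live area grows exponentially
## at the clone growth rate, drug exposure inhibits growth and adds a death
## rate, both Hill functions of concentration; the dead-reporter overlap
## accumulates as a saturating function of cumulative death. Invasion is an
## annulus-area process switched on by clone propensity x regimen induction.

#' Define one clone of the simulated organoid population
#'
#' @param fraction mixture fraction in the seeded population.
#' @param growth_rate exponential growth rate k (per hour); log(2)/24 gives
#'   daily doubling.
#' @param ec50 drug concentration (nM, anchor compound) of half-maximal
#'   effect.
#' @param hill Hill coefficient of the concentration-effect curve.
#' @param max_death_rate death rate (per hour) at saturating drug.
#' @param invasion_propensity unitless >= 0; 0 means the clone never
#'   invades.
#' @return one-row data.frame of clone parameters.
#' @export
cloneParams <- function(fraction = 1, growth_rate = log(2) / 24,
                        ec50 = 400, hill = 2, max_death_rate = 0.04,
                        invasion_propensity = 0) {
  if (any(c(fraction, growth_rate, ec50, hill, max_death_rate,
            invasion_propensity) < 0)) {
    .orgscreenError("clone parameters must be non-negative",
                    "orgscreen_config_error")
  }
  data.frame(fraction = fraction, growth_rate = growth_rate, ec50 = ec50,
             hill = hill, max_death_rate = max_death_rate,
             invasion_propensity = invasion_propensity)
}

#' Build a simulator configuration
#'
#' Defaults follow the screen design the package targets: two technical
#' replicate wells per condition, ~200 organoids seeded per well (Poisson),
#' imaging every 24 h for 5 days, a five-point log-spaced dose series
#' bracketing the clinically relevant 400 nM gemcitabine anchor (dosed at a
#' fixed 5:1 gemcitabine:paclitaxel molar ratio, so the anchor compound
#' concentration indexes the whole regimen), staurosporine positive
#' controls, and 5% multiplicative log-normal measurement noise.
#'
#' @param clones data.frame of clone parameters, rows from [cloneParams()];
#'   fractions must sum to 1.
#' @param regimens data.frame with columns `regimen`, `concentration` (nM),
#'   `invasion_induction` (>= 0 multiplier on clone invasion propensity).
#' @param nReplicates technical replicate wells per condition.
#' @param organoidsPerWell mean seeded organoids per well.
#' @param times imaging times (hours), ascending from 0.
#' @param meanInitialArea median initial organoid area (um^2).
#' @param areaSdLog log-sd of initial organoid area.
#' @param noiseSd log-sd of multiplicative measurement noise (per channel).
#' @param posControlDeathRate per-hour death rate in staurosporine wells;
#'   the default models the rapid complete kill expected of 2 uM
#'   staurosporine.
#' @param seed integer RNG seed.
#' @return a validated [SimConfig-class].
#' @export
simConfig <- function(clones = cloneParams(),
                      regimens = data.frame(
                        regimen = "gem-pac",
                        concentration = c(16, 80, 400, 2000, 10000),
                        invasion_induction = 0),
                      nReplicates = 2L, organoidsPerWell = 200,
                      times = seq(0, 120, by = 24),
                      meanInitialArea = 5000, areaSdLog = 0.4,
                      noiseSd = 0.05, posControlDeathRate = 0.6,
                      seed = 1L) {
  new("SimConfig",
      nReplicates = as.integer(nReplicates),
      organoidsPerWell = organoidsPerWell, times = as.numeric(times),
      clones = clones, regimens = regimens,
      meanInitialArea = meanInitialArea, areaSdLog = areaSdLog,
      noiseSd = noiseSd, posControlDeathRate = posControlDeathRate,
      seed = as.integer(seed))
}

#' @noRd
.hill <- function(conc, ec50, hill) {
  if (conc <= 0) return(0)
  conc^hill / (conc^hill + ec50^hill)
}

#' Simulate one organoid's measured trajectory
#'
#' Noise-free dynamics: live-area growth `dA/dt = (k (1 - e(d)) - delta(d)) A`
#' with growth-inhibition effect `e(d)` and death rate `delta(d)` both Hill
#' functions of concentration; the dead-reporter overlap is
#' `green = bf * (1 - exp(-delta t))`, i.e. a saturating function of
#' cumulative death. Invasive-annulus area grows linearly in time when
#' `invasion_propensity * induction > 0` and its dead overlap follows the
#' same death saturation. Multiplicative log-normal noise is applied last,
#' per channel and timepoint; overlap channels are nested measurements on
#' the same mask, so their noise factor acts on the overlap ratio of the
#' noisy mask area and the result is clipped to that mask.
#'
#' @param clone one-row data.frame from [cloneParams()].
#' @param conc drug concentration (nM, anchor compound); 0 for vehicle.
#' @param times hours, ascending from 0.
#' @param induction regimen invasion-induction multiplier (>= 0).
#' @param A0 initial organoid area (um^2).
#' @param noiseSd log-sd of multiplicative noise; 0 for noise-free.
#' @param growthInhibition optional override of `e(d)` in [0, 1].
#' @param deathRate optional override of `delta(d)` (per hour), e.g. for
#'   staurosporine wells.
#' @return data.frame per timepoint: `time_h`, `bf_area`, `green_area`,
#'   `inv_area`, `inv_green_area`, `brightness`, `texture`,
#'   `true_death_fraction`.
#' @examples
#' # daily doubling, no drug: area doubles by 24 h
#' organoidTrajectory(cloneParams(), conc = 0, times = c(0, 24), A0 = 1000)
#' @export
organoidTrajectory <- function(clone, conc, times, induction = 0,
                               A0 = 5000, noiseSd = 0,
                               growthInhibition = NULL, deathRate = NULL) {
  if (is.unsorted(times, strictly = TRUE) || times[1L] != 0) {
    .orgscreenError("times must be strictly ascending starting at 0",
                    "orgscreen_config_error")
  }
  if (conc < 0 || induction < 0 || A0 <= 0 || noiseSd < 0) {
    .orgscreenError("negative simulation parameters",
                    "orgscreen_config_error")
  }
  H <- .hill(conc, clone$ec50, clone$hill)
  e <- if (is.null(growthInhibition)) H else growthInhibition
  delta <- if (is.null(deathRate)) clone$max_death_rate * H else deathRate
  k <- clone$growth_rate
  bf <- A0 * exp((k * (1 - e) - delta) * times)
  death_frac <- -expm1(-delta * times)
  green <- bf * death_frac
  phi <- clone$invasion_propensity * induction * H
  tmax <- max(times)
  inv <- A0 * phi * times / tmax
  inv_green <- inv * death_frac
  brightness <- 100 * (1 + 0.5 * death_frac)
  texture <- 100 * (1 + 0.8 * death_frac + 0.6 * pmin(phi, 1))
  if (noiseSd > 0) {
    nt <- length(times)
    eps <- matrix(rlnorm(6L * nt, 0, noiseSd), nt, 6L)
    bf <- bf * eps[, 1L]
    # overlap areas are nested measurements on the same mask: their noise
    # acts on the overlap ratio of the (noisy) mask, then clips to it
    green <- pmin(bf * death_frac * eps[, 2L], bf)
    inv <- inv * eps[, 3L]
    inv_green <- pmin(inv * death_frac * eps[, 4L], inv)
    brightness <- brightness * eps[, 5L]
    texture <- texture * eps[, 6L]
  }
  data.frame(time_h = times, bf_area = bf, green_area = green,
             inv_area = inv, inv_green_area = inv_green,
             brightness = brightness, texture = texture,
             true_death_fraction = death_frac)
}

#' @noRd
.wellName <- function(i) {
  sprintf("%s%02d", LETTERS[((i - 1L) %/% 24L) + 1L], ((i - 1L) %% 24L) + 1L)
}

#' Simulate a complete screening plate with ground truth
#'
#' Lays out vehicle (negative-control) and staurosporine (positive-control)
#' wells plus one treatment well per regimen x concentration x replicate,
#' seeds each with a Poisson number of organoids drawn from the clone
#' mixture, simulates every organoid under the growth/death/invasion model
#' of [organoidTrajectory()] (vectorized per well), and returns the emitted
#' measurement table alongside the generating truth.
#'
#' Reproducible: the same configuration (including seed) yields identical
#' tables.
#'
#' @param cfg a [SimConfig-class] from [simConfig()].
#' @return list with elements:
#'   \describe{
#'     \item{screen}{an [OrganoidScreen-class] (measurements + layout).}
#'     \item{truth}{list of `organoids` (per-organoid clone label, true
#'       growth/death rates, invasive flag), `death` (per organoid and
#'       timepoint true death fraction) and `wells` (per-well condition,
#'       expected noise-free NDR and expected response-signature class).}
#'   }
#' @export
simulatePlate <- function(cfg) {
  validObject(cfg)
  set.seed(cfg@seed)
  regs <- cfg@regimens
  wells <- data.frame(
    role = c(rep("negative_control", cfg@nReplicates),
             rep("positive_control", cfg@nReplicates),
             rep("treatment", nrow(regs) * cfg@nReplicates)),
    regimen = c(rep("vehicle", cfg@nReplicates),
                rep("staurosporine", cfg@nReplicates),
                rep(regs$regimen, each = cfg@nReplicates)),
    concentration = c(rep(NA_real_, 2L * cfg@nReplicates),
                      rep(regs$concentration, each = cfg@nReplicates)),
    invasion_induction = c(rep(0, 2L * cfg@nReplicates),
                           rep(regs$invasion_induction,
                               each = cfg@nReplicates)),
    replicate_id = c(rep(seq_len(cfg@nReplicates), 2L),
                     rep(seq_len(cfg@nReplicates), times = nrow(regs))),
    stringsAsFactors = FALSE
  )
  wells$well <- vapply(seq_len(nrow(wells)), .wellName, character(1))
  wells$plate_id <- "SIMPLATE"

  meas <- vector("list", nrow(wells))
  org_truth <- vector("list", nrow(wells))
  death_truth <- vector("list", nrow(wells))
  times <- cfg@times
  nt <- length(times)
  tmax <- max(times)
  for (i in seq_len(nrow(wells))) {
    w <- wells[i, ]
    n_org <- max(1L, rpois(1L, cfg@organoidsPerWell))
    clone_idx <- sample.int(nrow(cfg@clones), n_org, replace = TRUE,
                            prob = cfg@clones$fraction)
    A0 <- rlnorm(n_org, log(cfg@meanInitialArea), cfg@areaSdLog)
    cl <- cfg@clones[clone_idx, ]
    # per-organoid effect parameters, vectorized over the whole well
    if (w$role == "positive_control") {
      e <- rep(1, n_org)
      delta <- rep(cfg@posControlDeathRate, n_org)
      phi <- rep(0, n_org)
    } else if (w$role == "negative_control") {
      e <- rep(0, n_org)
      delta <- rep(0, n_org)
      phi <- rep(0, n_org)
    } else {
      H <- w$concentration^cl$hill /
        (w$concentration^cl$hill + cl$ec50^cl$hill)
      e <- H
      delta <- cl$max_death_rate * H
      phi <- cl$invasion_propensity * w$invasion_induction * H
    }
    bf <- A0 * exp(outer(cl$growth_rate * (1 - e) - delta, times))
    df <- -expm1(-outer(delta, times))
    inv <- (A0 * phi) %o% (times / tmax)
    brightness <- 100 * (1 + 0.5 * df)
    texture <- 100 * (1 + 0.8 * df + 0.6 * pmin(phi, 1))
    if (cfg@noiseSd > 0) {
      eps <- array(rlnorm(n_org * nt * 6L, 0, cfg@noiseSd),
                   dim = c(n_org, nt, 6L))
      bf <- bf * eps[, , 1L]
      green <- pmin(bf * df * eps[, , 2L], bf)
      inv <- inv * eps[, , 3L]
      inv_green <- pmin(inv * df * eps[, , 4L], inv)
      brightness <- brightness * eps[, , 5L]
      texture <- texture * eps[, , 6L]
    } else {
      green <- bf * df
      inv_green <- inv * df
    }
    meas[[i]] <- data.frame(
      plate_id = w$plate_id, well = w$well,
      time_h = rep(times, each = n_org),
      organoid_id = rep(seq_len(n_org), nt),
      bf_area = as.vector(bf), green_area = as.vector(green),
      inv_area = as.vector(inv), inv_green_area = as.vector(inv_green),
      brightness = as.vector(brightness), texture = as.vector(texture),
      stringsAsFactors = FALSE
    )
    org_truth[[i]] <- data.frame(
      plate_id = w$plate_id, well = w$well, organoid_id = seq_len(n_org),
      clone = clone_idx, true_growth_rate = cl$growth_rate,
      true_death_rate = delta, invasion_strength = phi,
      invasive_flag = phi > 0, initial_area = A0,
      stringsAsFactors = FALSE
    )
    death_truth[[i]] <- data.frame(
      plate_id = w$plate_id, well = w$well,
      organoid_id = rep(seq_len(n_org), nt),
      time_h = rep(times, each = n_org),
      true_death_fraction = as.vector(df)
    )
  }
  m <- do.call(rbind, meas)
  m <- m[.MEASUREMENT_COLS]
  rownames(m) <- NULL

  layout <- data.frame(
    plate_id = wells$plate_id, well = wells$well, role = wells$role,
    compound = ifelse(wells$role == "treatment", wells$regimen,
                      ifelse(wells$role == "positive_control",
                             "staurosporine", "vehicle")),
    concentration = ifelse(wells$role == "positive_control", 2000,
                           wells$concentration),
    replicate_id = wells$replicate_id,
    patient_id = "SIM01", regimen = wells$regimen,
    stringsAsFactors = FALSE
  )
  wells_truth <- cbind(
    wells[c("plate_id", "well", "role", "regimen", "concentration",
            "replicate_id")],
    .expectedWellOutcome(cfg, wells)
  )
  screen <- OrganoidScreen(m, layout)
  list(screen = screen,
       truth = list(organoids = do.call(rbind, org_truth),
                    death = do.call(rbind, death_truth),
                    wells = wells_truth))
}

# noise-free expected NDR and signature class per well, from the population
# mixture in closed form (per-clone exponential signal decay)
#' @noRd
.expectedWellOutcome <- function(cfg, wells) {
  tmax <- max(cfg@times)
  cl <- cfg@clones
  pop_FG <- function(role, conc) {
    if (role == "positive_control") {
      e <- rep(1, nrow(cl)); delta <- rep(cfg@posControlDeathRate, nrow(cl))
    } else if (role == "negative_control") {
      e <- rep(0, nrow(cl)); delta <- rep(0, nrow(cl))
    } else {
      H <- vapply(seq_len(nrow(cl)),
                  function(i) .hill(conc, cl$ec50[i], cl$hill[i]), numeric(1))
      e <- H; delta <- cl$max_death_rate * H
    }
    bf <- sum(cl$fraction * exp((cl$growth_rate * (1 - e) - delta) * tmax))
    green <- sum(cl$fraction *
                   exp((cl$growth_rate * (1 - e) - delta) * tmax) *
                   (-expm1(-delta * tmax)))
    c(F = (bf - green) / 1, cell_death = 100 * green / bf)
  }
  Fneg <- pop_FG("negative_control", 0)[["F"]]
  Fpos <- pop_FG("positive_control", 0)[["F"]]
  out <- data.frame(expected_ndr = NA_real_,
                    expected_class = NA_character_,
                    expected_cell_death = NA_real_)[rep(1L, nrow(wells)), ]
  for (i in seq_len(nrow(wells))) {
    fg <- pop_FG(wells$role[i], wells$concentration[i])
    ndr <- ndrMetric(fg[["F"]], Fneg, Fpos)
    out$expected_ndr[i] <- ndr
    out$expected_cell_death[i] <- fg[["cell_death"]]
    out$expected_class[i] <- classifySignature(ndr, fg[["cell_death"]])$label
  }
  rownames(out) <- NULL
  out
}

#' Stock simulation scenarios
#'
#' Four named configurations spanning the response taxonomy the analysis is
#' designed to resolve:
#' \describe{
#'   \item{cytotoxic_responder}{drug kills at clinical concentrations; deep
#'     negative NDR with high cell death.}
#'   \item{cytostatic_responder}{drug arrests growth without killing; NDR
#'     near 0, minimal cell death.}
#'   \item{heterogeneous}{70% sensitive + 30% drug-resistant subclone; the
#'     resistant fraction survives saturating dose.}
#'   \item{invasion_inducer}{paclitaxel-like arm carrying a positive
#'     invasion-induction factor next to a non-inducing gemcitabine-like
#'     arm.}
#' }
#'
#' @param seed seed planted into every returned configuration.
#' @param organoidsPerWell mean seeded organoids per well (default the
#'   screen-standard 200).
#' @return named list of [SimConfig-class] objects.
#' @export
defaultScenarios <- function(seed = 1L, organoidsPerWell = 200) {
  doses <- c(16, 80, 400, 2000, 10000)
  list(
    cytotoxic_responder = simConfig(
      clones = cloneParams(ec50 = 100, max_death_rate = 0.045),
      regimens = data.frame(regimen = "gem-pac", concentration = doses,
                            invasion_induction = 0),
      organoidsPerWell = organoidsPerWell, seed = seed),
    cytostatic_responder = simConfig(
      clones = cloneParams(ec50 = 100, max_death_rate = 0),
      regimens = data.frame(regimen = "gem-pac", concentration = doses,
                            invasion_induction = 0),
      organoidsPerWell = organoidsPerWell, seed = seed),
    heterogeneous = simConfig(
      clones = rbind(
        cloneParams(fraction = 0.7, ec50 = 100, max_death_rate = 0.045),
        cloneParams(fraction = 0.3, ec50 = 5e4, max_death_rate = 0.002)),
      regimens = data.frame(regimen = "gem-pac", concentration = doses,
                            invasion_induction = 0),
      organoidsPerWell = organoidsPerWell, seed = seed),
    invasion_inducer = simConfig(
      clones = cloneParams(ec50 = 400, max_death_rate = 0.01,
                           invasion_propensity = 0.8),
      regimens = data.frame(
        regimen = c(rep("paclitaxel", 3L), rep("gemcitabine", 3L)),
        concentration = rep(c(80, 400, 2000), 2L),
        invasion_induction = rep(c(1.5, 0), each = 3L)),
      organoidsPerWell = organoidsPerWell, seed = seed)
  )
}
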