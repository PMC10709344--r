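# programmatic fixtures: tiny measurement/layout tables built in code

makeMeasurements <- function(wells = c("A01", "A02"),
                             times = c(0, 24),
                             organoids = 2L,
                             bf = 1000, green = 100,
                             inv = 0, inv_green = 0,
                             plate = "P1") {
  grid <- expand.grid(well = wells, organoid_id = seq_len(organoids),
                      time_h = times, stringsAsFactors = FALSE)
  data.frame(
    plate_id = plate, well = grid$well, time_h = grid$time_h,
    organoid_id = grid$organoid_id,
    bf_area = bf, green_area = green,
    inv_area = inv, inv_green_area = inv_green,
    brightness = 100, texture = 100,
    stringsAsFactors = FALSE
  )
}

makeLayout <- function(plate = "P1") {
  data.frame(
    plate_id = plate,
    well = c("A01", "A02", "A03", "A04", "A05", "A06"),
    role = c("negative_control", "negative_control",
             "positive_control", "positive_control",
             "treatment", "treatment"),
    compound = c("vehicle", "vehicle", "staurosporine", "staurosporine",
                 "gem-pac", "gem-pac"),
    concentration = c(NA, NA, 2000, 2000, 400, 400),
    replicate_id = c(1L, 2L, 1L, 2L, 1L, 2L),
    patient_id = "PT1", regimen = c("vehicle", "vehicle", "staurosporine",
                                    "staurosporine", "gem-pac", "gem-pac"),
    stringsAsFactors = FALSE
  )
}

# small noise-free plate used by several well-metric tests: vehicle wells
# grow 4x, staurosporine wells end fully green (signal fold change 0)
makeToyScreen <- function() {
  times <- c(0, 24, 48)
  rows <- list()
  addWell <- function(bf, green, well) {
    for (tt in seq_along(times)) {
      rows[[length(rows) + 1L]] <<- data.frame(
        plate_id = "P1", well = well, time_h = times[tt],
        organoid_id = 1:2, bf_area = bf[tt], green_area = green[tt],
        inv_area = 0, inv_green_area = 0, brightness = 100, texture = 100,
        stringsAsFactors = FALSE
      )
    }
  }
  addWell(c(500, 1000, 2000), c(0, 0, 0), "A01")    # vehicle: F = 4
  addWell(c(500, 1000, 2000), c(0, 0, 0), "A02")
  addWell(c(500, 500, 500), c(0, 375, 500), "A03")  # kill: F = 0.25, 0
  addWell(c(500, 500, 500), c(0, 375, 500), "A04")
  addWell(c(500, 750, 1000), c(0, 0, 0), "A05")     # F = 2
  addWell(c(500, 500, 500), c(0, 0, 0), "A06")      # stasis: F = 1
  OrganoidScreen(do.call(rbind, rows), makeLayout())
}

# independent brute-force Spearman enumeration (expand.grid-based; separate
# algorithm from the package's recursive generator)
bruteSpearmanP <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  rho_obs <- cor(rx, ry)
  grid <- do.call(expand.grid, rep(list(seq_len(n)), n))
  perms <- as.matrix(grid[apply(grid, 1L, function(r) !anyDuplicated(r)), ])
  rho_null <- apply(perms, 1L, function(p) cor(seq_len(n), p))
  mean(abs(rho_null) >= abs(rho_obs) - 1e-12)
}

# all spanning trees over C labelled nodes via Prufer sequences
bruteMinSpanningTreeLength <- function(cent) {
  C <- nrow(cent)
  dm <- as.matrix(dist(cent))
  if (C == 2L) return(dm[1L, 2L])
  pruferToEdges <- function(pr) {
    degree <- rep(1L, C)
    for (v in pr) degree[v] <- degree[v] + 1L
    edges <- matrix(0L, C - 1L, 2L)
    ptr <- 1L
    pr2 <- pr
    for (i in seq_along(pr2)) {
      leaf <- min(which(degree == 1L))
      edges[i, ] <- c(leaf, pr2[i])
      degree[leaf] <- 0L
      degree[pr2[i]] <- degree[pr2[i]] - 1L
    }
    rest <- which(degree == 1L)
    edges[C - 1L, ] <- rest
    edges
  }
  seqs <- as.matrix(do.call(expand.grid, rep(list(seq_len(C)), C - 2L)))
  best <- Inf
  for (i in seq_len(nrow(seqs))) {
    ed <- pruferToEdges(as.integer(seqs[i, ]))
    best <- min(best, sum(dm[ed]))
  }
  best
}
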