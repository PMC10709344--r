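# three collinear clusters at x = 0, 1, 2 with a few points each
collinearSetup <- function() {
  labels <- rep(1:3, each = 4L)
  offs <- c(-0.01, 0.01)
  coords <- cbind(rep(c(0, 1, 2), each = 4L) + rep(offs, 6L),
                  rep(c(-0.01, 0.01), each = 2L, times = 3L))
  list(labels = labels, coords = coords)
}

test_that("the centroid MST of collinear clusters is the path graph", {
  s <- collinearSetup()
  model <- centroidMST(s$labels, s$coords)
  ed <- mstEdges(model)
  expect_equal(nrow(ed), 2L)
  pairs <- apply(ed[c("from", "to")], 1L, function(r) paste(sort(r),
                                                            collapse = "-"))
  expect_setequal(pairs, c("1-2", "2-3"))
})

test_that("designated terminals are forced to be leaves", {
  # cluster 2 sits between 1 and 3 and would be internal in the free MST
  s <- collinearSetup()
  model <- centroidMST(s$labels, s$coords, terminals = 2L)
  ed <- mstEdges(model)
  deg <- table(c(ed$from, ed$to))
  expect_equal(unname(deg[["2"]]), 1L)
  expect_error(centroidMST(s$labels, s$coords, terminals = 1:3),
               class = "orgscreen_data_error")
  expect_error(centroidMST(rep(1L, 4L), s$coords[1:4, ]),
               class = "orgscreen_data_error")
})

test_that("projection clamps to segments and breaks ties by lowest edge id", {
  labels <- rep(1:3, each = 2L)
  cent_pts <- rbind(c(0, 0), c(0, 0), c(1, 0), c(1, 0), c(2, 0), c(2, 0))
  model <- centroidMST(labels, cent_pts)
  # a point exactly on the middle centroid: distance 0
  m1 <- projectToMST(rbind(cent_pts, c(1, 0)), model)
  expect_equal(m1@projections$dist[7L], 0)
  # beyond the leaf at x = 2: clamps to that centroid
  m2 <- projectToMST(rbind(cent_pts, c(3, 0)), model)
  expect_equal(m2@projections$t[7L] %in% c(0, 1), TRUE)
  expect_equal(m2@projections$dist[7L], 1)
  # equidistant from both unit edges: the lower edge id wins
  m3 <- projectToMST(rbind(cent_pts, c(1, 0.5)), model)
  expect_equal(m3@projections$edge_id[7L],
               min(mstEdges(model)$edge_id))
})

test_that("path pseudotime accumulates distance from the root", {
  s <- collinearSetup()
  extra <- rbind(c(0, 0), c(1.5, 0), c(2, 0))  # root, mid-2nd-edge, leaf
  coords <- rbind(s$coords, extra)
  labels <- c(s$labels, 1L, 3L, 3L)
  model <- centroidMST(labels, coords)
  model <- projectToMST(coords, model)
  model <- pseudotimeVectors(model, root = 1L)
  n <- nrow(coords)
  pt <- model@pseudotimePaths
  expect_equal(ncol(pt), 1L)           # path graph: single root-leaf path
  expect_equal(unname(pt[n - 2L, 1L]), 0, tolerance = 0.02)
  expect_equal(unname(pt[n - 1L, 1L]), 1.5, tolerance = 0.05)
  # a point beyond the leaf clamps to the path's full length
  expect_equal(unname(pt[n, 1L]), sum(mstEdges(model)$length),
               tolerance = 1e-9)
  # single path: common pseudotime equals the path vector
  expect_equal(commonPseudotime(model), unname(pt[, 1L]))
})

test_that("pseudotime is monotone along a path", {
  # four collinear clusters plus probe points placed exactly on the path
  # polyline at increasing arc positions
  set.seed(19)
  cluster_x <- rep(c(1, 4, 7, 10), each = 20L)
  anchors <- cbind(cluster_x + runif(80, -0.2, 0.2), rep(0, 80))
  probes_x <- sort(runif(40, 1, 10))
  coords <- rbind(anchors, cbind(probes_x, 0))
  labels <- c(rep(1:4, each = 20L),
              as.integer(cut(probes_x, c(-Inf, 2.5, 5.5, 8.5, Inf))))
  model <- centroidMST(labels, coords)
  model <- projectToMST(coords, model)
  model <- pseudotimeVectors(model, root = 1L)
  probe_pt <- commonPseudotime(model)[81:120]
  expect_true(!is.unsorted(probe_pt, strictly = FALSE))
  # probe pseudotime equals its arc distance from the root centroid
  root_x <- mean(coords[labels == 1L, 1L])
  on_path <- probes_x >= root_x
  expect_equal(probe_pt[on_path], probes_x[on_path] - root_x,
               tolerance = 1e-9)
})

test_that("observations on shared edges agree across paths", {
  # Y-shaped tree: root 1 at origin, branch point 2, leaves 3 and 4
  cent_pts <- rbind(c(0, 0), c(1, 0), c(2, 1), c(2, -1))
  labels <- 1:4
  coords <- rbind(cent_pts, c(0.5, 0))  # on the shared root edge
  labels <- c(labels, 1L)
  model <- centroidMST(labels, coords)
  model <- projectToMST(coords, model)
  model <- pseudotimeVectors(model, root = 1L)
  pt <- model@pseudotimePaths
  expect_equal(ncol(pt), 2L)
  shared <- pt[5L, ]
  expect_equal(unname(shared[1L]), unname(shared[2L]))
  expect_equal(unname(commonPseudotime(model)[5L]), unname(shared[1L]))
  # common pseudotime is defined everywhere
  expect_true(all(is.finite(commonPseudotime(model))))
})

test_that("density along a path reports per-arm mass and shared-bandwidth curves", {
  set.seed(23)
  # arm A concentrated on the path to the terminal, arm B off-path
  cent_pts <- rbind(c(0, 0), c(1, 0), c(2, 1), c(2, -1))
  base_labels <- 1:4
  onpath <- cbind(runif(30, 1.2, 1.9), runif(30, 0.6, 0.95))
  offpath <- cbind(runif(30, 1.2, 1.9), runif(30, -0.95, -0.6))
  coords <- rbind(cent_pts, onpath, offpath)
  labels <- c(base_labels, rep(3L, 30L), rep(4L, 30L))
  arm <- c(rep("x", 4L), rep("A", 30L), rep("B", 30L))
  model <- centroidMST(labels, coords)
  model <- projectToMST(coords, model)
  model <- pseudotimeVectors(model, root = 1L)
  dens <- suppressWarnings(densityAlongPath(model, arm, terminal = 3L))
  mass <- dens$mass
  expect_equal(mass$mass[mass$arm == "A"], 1)
  expect_equal(mass$mass[mass$arm == "B"], 0)
  # two arms with identical pseudotime samples give identical densities
  coords2 <- rbind(cent_pts, onpath, onpath)
  labels2 <- c(base_labels, rep(3L, 60L))
  arm2 <- c(rep("x", 4L), rep("A", 30L), rep("B", 30L))
  model2 <- projectToMST(coords2, centroidMST(labels2, coords2))
  model2 <- pseudotimeVectors(model2, root = 1L)
  dens2 <- suppressWarnings(densityAlongPath(model2, arm2, terminal = 3L))
  dA <- dens2$density[dens2$density$arm == "A", c("x", "y")]
  dB <- dens2$density[dens2$density$arm == "B", c("x", "y")]
  expect_equal(dA$y, dB$y, tolerance = 1e-12)
})
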