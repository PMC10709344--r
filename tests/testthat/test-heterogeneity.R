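makeStates <- function(n_org = 3L, n_t = 6L, seed = 1L) {
  set.seed(seed)
  grid <- expand.grid(organoid_id = seq_len(n_org),
                      time_h = seq(0, by = 24, length.out = n_t))
  data.frame(
    plate_id = "P1", well = "A01", regimen = "r", concentration = 1,
    role = "treatment",
    organoid_id = grid$organoid_id, time_h = grid$time_h,
    bf_area = rlnorm(nrow(grid), 8), inv_area = rlnorm(nrow(grid), 4),
    fa = runif(nrow(grid)), inv_fraction = runif(nrow(grid), 0, 0.5),
    brightness = rnorm(nrow(grid), 100, 5),
    texture = rnorm(nrow(grid), 100, 5)
  )
}

test_that("feature matrix has one standardized row per organoid-timepoint", {
  st <- makeStates(3L, 6L)
  fm <- buildFeatureMatrix(st)
  expect_equal(dim(fm$X), c(18L, 6L))
  expect_equal(unname(colMeans(fm$X)), rep(0, 6), tolerance = 1e-12)
  expect_equal(unname(apply(fm$X, 2, sd)), rep(1, 6), tolerance = 1e-12)
  expect_equal(nrow(fm$meta), 18L)
})

test_that("constant columns and incomplete rows are dropped with notice", {
  st <- makeStates(4L, 5L)
  st$texture <- 7
  expect_warning(fm <- buildFeatureMatrix(st), "texture")
  expect_equal(ncol(fm$X), 5L)

  st2 <- makeStates(4L, 5L)
  st2$brightness[c(2L, 9L)] <- NA
  expect_message(fm2 <- buildFeatureMatrix(st2), "2 row")
  expect_equal(nrow(fm2$X), 18L)
  expect_equal(fm2$dropped_rows, 2L)
})

test_that("permutation PC selection finds planted structure and rejects noise", {
  set.seed(33)
  noise <- matrix(rnorm(500 * 6), 500, 6)
  sel <- selectInformativePCs(scale(noise), n_perm = 200, seed = 2L)
  expect_equal(sel$n_retained, 0L)
  expect_true(all(sel$p_values >= 1 / 201))
  expect_true(all(sel$p_values <= 1))

  z1 <- rnorm(500); z2 <- rnorm(500)
  planted <- cbind(z1, z1, z1, z2, z2, z2) + matrix(rnorm(500 * 6, 0, 0.4),
                                                    500, 6)
  sel2 <- selectInformativePCs(scale(planted), n_perm = 200, seed = 2L)
  expect_equal(sel2$n_retained, 2L)

  expect_error(selectInformativePCs(scale(noise)[1:5, ], n_perm = 200),
               class = "orgscreen_data_error")
  expect_warning(selectInformativePCs(scale(noise), n_perm = 50, seed = 1L),
                 "resolution")
})

test_that("t-SNE applies the square-root perplexity rule and is seeded", {
  set.seed(5)
  X <- matrix(rnorm(500 * 3), 500, 3)
  e1 <- embedTSNE(X, seed = 9L)
  expect_equal(e1$perplexity, floor(sqrt(500)))
  e2 <- embedTSNE(X, seed = 9L)
  expect_identical(e1$coords, e2$coords)
  # an infeasible perplexity is lowered with a warning
  expect_warning(e3 <- embedTSNE(X[1:20, ], seed = 1L, perplexity = 10),
                 "lowered")
  expect_equal(e3$perplexity, floor(19 / 3))
})

test_that("kNN-Louvain recovers well-separated blobs", {
  set.seed(7)
  blob1 <- matrix(rnorm(200 * 2), 200, 2)
  blob2 <- matrix(rnorm(200 * 2, mean = 20), 200, 2)
  coords <- rbind(blob1, blob2)
  # default k (capped at n-1) keeps each blob connected to the other by
  # low-weight edges, so modularity keeps whole blobs together
  cl <- clusterEmbedding(coords, seed = 3L)
  expect_equal(length(cl$labels), 400L)
  # each blob lands in a single community
  expect_equal(length(unique(cl$labels[1:200])), 1L)
  expect_equal(length(unique(cl$labels[201:400])), 1L)
  expect_false(cl$labels[1L] == cl$labels[400L])
  expect_true(all(igraph::E(cl$graph)$weight >= 0 &
                    igraph::E(cl$graph)$weight <= 1))
})

test_that("kNN k is capped at n-1 and duplicates form one community", {
  coords <- matrix(rnorm(10), 5, 2)
  cl <- clusterEmbedding(coords, k = 1000, seed = 1L)
  expect_equal(length(cl$labels), 5L)

  dup <- matrix(1, 6, 2)
  cl2 <- clusterEmbedding(dup, k = 3, seed = 1L)
  expect_equal(length(unique(cl2$labels)), 1L)
})

test_that("the returned partition beats trivial partitions on modularity", {
  set.seed(11)
  coords <- rbind(matrix(rnorm(100 * 2), 100, 2),
                  matrix(rnorm(100 * 2, 8), 100, 2))
  cl <- clusterEmbedding(coords, k = 20, seed = 2L)
  g <- cl$graph
  w <- igraph::E(g)$weight
  m_single <- igraph::modularity(g, rep(1L, 200), weights = w)
  m_singletons <- igraph::modularity(g, seq_len(200), weights = w)
  expect_gte(cl$modularity, m_single)
  expect_gte(cl$modularity, m_singletons)
})

test_that("rank normalization yields average ranks over n in (0,1]", {
  expect_equal(rankNormalize(c(5, 1, 3)), c(1, 1 / 3, 2 / 3))
  expect_equal(rankNormalize(c(2, 2)), c(0.75, 0.75))
  expect_equal(rankNormalize(7), 1)
  expect_error(rankNormalize(numeric()), class = "orgscreen_data_error")
})

test_that("cluster profiles report enrichment relative to overall fractions", {
  st <- makeStates(10L, 2L, seed = 3L)
  fm <- buildFeatureMatrix(st)
  # put all baseline rows in cluster 1, the rest in cluster 2
  labels <- ifelse(fm$meta$time_h == 0, 1L, 2L)
  prof <- clusterProfiles(labels, fm)
  expect_equal(prof$baseline_cluster, 1L)
  expect_equal(prof$enrichment["1", "0"], 2)   # 100% vs 50% overall
  expect_equal(prof$enrichment["1", "24"], 0)

  # uniform mixing: all enrichments 1
  labels2 <- rep(c(1L, 2L), length.out = nrow(fm$X))
  prof2 <- clusterProfiles(labels2, fm)
  expect_equal(unname(as.vector(prof2$enrichment)), rep(1, 4),
               tolerance = 1e-12)

  # size-weighted enrichment averages to 1 per level
  sizes <- table(labels)
  wavg <- colSums(prof$enrichment * as.numeric(sizes)) / sum(sizes)
  expect_equal(unname(wavg), c(1, 1), tolerance = 1e-12)
})
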