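test_that("mutual-nearest matching respects the 20 um cap", {
  m <- matchCellsNuclei(rbind(c(0, 0, 0)), rbind(c(0, 0, 1)))
  expect_equal(m$distance_um, 1)

  # a lone pair at 25 um stays unmatched
  expect_equal(nrow(matchCellsNuclei(rbind(c(0, 0, 0)),
                                     rbind(c(0, 0, 25)))), 0L)
  # 20 um exactly is not under the cap
  expect_equal(nrow(matchCellsNuclei(rbind(c(0, 0, 0)),
                                     rbind(c(0, 0, 20)))), 0L)

  # non-mutual nearest neighbours never pair (brute-force check):
  # c1's nearest nucleus is n1, but n1's nearest cell is c2
  cells <- data.frame(id = 1:2, x = c(0, 3), y = 0, z = 0)
  nucs <- data.frame(id = 1, x = 4, y = 0, z = 0)
  m2 <- matchCellsNuclei(cells, nucs)
  expect_equal(m2$cell_id, 2L)
})

test_that("matching is symmetric in roles and bounded in size", {
  set.seed(181)
  a <- data.frame(id = 1:40, x = runif(40, 0, 100),
                  y = runif(40, 0, 100), z = runif(40, 0, 100))
  b <- data.frame(id = 1:50, x = runif(50, 0, 100),
                  y = runif(50, 0, 100), z = runif(50, 0, 100))
  m1 <- matchCellsNuclei(a, b)
  m2 <- matchCellsNuclei(b, a)
  expect_lte(nrow(m1), 40L)
  expect_equal(nrow(m1), nrow(m2))
  k1 <- paste(m1$cell_id, m1$nucleus_id)
  k2 <- paste(m2$nucleus_id, m2$cell_id)
  expect_setequal(k1, k2)
  # each id appears at most once
  expect_false(anyDuplicated(m1$cell_id) > 0)
  expect_false(anyDuplicated(m1$nucleus_id) > 0)
})

test_that("matching recovers nearly all true pairs at 1 um offsets", {
  set.seed(191)
  sim <- simulateGrowthPlate(syntheticConfig(nClones = 30,
    sizeRange = c(3, 8), plateExtent = c(800, 800, 400)), seed = 191)
  pair <- simulateCellsAndNuclei(sim$clones, offsetSigma = 1, seed = 192)
  m <- matchCellsNuclei(pair$cells, pair$nucleiCoords)
  hits <- mean(m$cell_id == m$nucleus_id)
  expect_gte(nrow(m) / nrow(pair$cells), 0.99)
  expect_gte(hits, 0.99)
})

test_that("random-clone sampling prunes the farthest cells first", {
  # candidates exactly equal to size are returned unchanged
  cells <- data.frame(id = 1:4, x = c(0, 1, 0, 1), y = c(0, 0, 1, 1),
                      z = 50)
  got <- sampleRandomClone(cells, size = 4, radius = 10,
                           center = c(0.5, 0.5, 50), pdHeight = 100)
  expect_equal(sort(got$id), 1:4)

  # far outlier (deliberately given the LARGEST id so an id-based rule
  # would delete a clustered cell instead) is removed first
  cl <- data.frame(id = 1:7,
                   x = c(0, 1, 0, 1, 0.5, 0.2, 9),
                   y = c(0, 0, 1, 1, 0.5, 0.8, 9),
                   z = 50)
  got2 <- sampleRandomClone(cl, size = 6, radius = 30,
                            center = c(0.5, 0.5, 50), pdHeight = 100)
  expect_equal(sort(got2$id), 1:6)

  # empty candidate window signals sampling failure
  expect_null(sampleRandomClone(cells, size = 4, radius = 10,
                                center = c(0, 0, 500), pdHeight = 100))

  # the P-D window is enforced: 15% of the height on either side
  tall <- data.frame(id = 1:3, x = 0, y = 0, z = c(50, 58, 80))
  got3 <- sampleRandomClone(tall, size = 2, radius = 100,
                            center = c(0, 0, 50), pdHeight = 100)
  expect_equal(sort(got3$id), 1:2)

  # pruned sets stay single connected components under doublet analysis
  set.seed(201)
  pool <- data.frame(id = 1:30, x = runif(30, 0, 40),
                     y = runif(30, 0, 40), z = runif(30, 40, 60))
  got4 <- sampleRandomClone(pool, size = 8, radius = 50,
                            center = c(20, 20, 50), pdHeight = 100)
  expect_equal(nrow(got4), 8L)
  d <- identifyDoublets(as.matrix(got4[, c("x", "y", "z")]))
  g <- igraph::graph_from_edgelist(cbind(edges(d)$id_a, edges(d)$id_b),
                                   directed = FALSE)
  expect_equal(igraph::components(g)$no, 1)
})

test_that("elevation correlation is exact in the zero-offset limit", {
  set.seed(211)
  sim <- simulateGrowthPlate(syntheticConfig(nClones = 20,
    sizeRange = c(3, 8), plateExtent = c(600, 600, 400)), seed = 211)
  pair <- simulateCellsAndNuclei(sim$clones, offsetSigma = 0, seed = 212)
  idx <- split(seq_len(nrow(pair$cells)), pair$cells$clone_id)
  res <- elevationCorrelation(idx,
                              pair$cells[, c("x", "y", "z")],
                              pair$nucleiCoords[, c("x", "y", "z")])
  expect_equal(res$r, 1, tolerance = 1e-12)
})

test_that("correlation degrades from near-perfect to near-zero with
           offset size", {
  sim <- simulateGrowthPlate(syntheticConfig(nClones = 200,
    sizeRange = c(3, 8), plateExtent = c(2500, 2500, 1200)), seed = 221)
  idxOf <- function(p) split(seq_len(nrow(p$cells)), p$cells$clone_id)

  # 1 um offsets on 10 um-scale clones: r > 0.9
  p1 <- simulateCellsAndNuclei(sim$clones, offsetSigma = 1, seed = 222)
  r1 <- elevationCorrelation(idxOf(p1), p1$cells[, c("x", "y", "z")],
                             p1$nucleiCoords[, c("x", "y", "z")])$r
  expect_gt(r1, 0.9)

  # 50 um offsets scramble the geometry: r near 0
  p2 <- simulateCellsAndNuclei(sim$clones, offsetSigma = 50, seed = 223)
  r2 <- elevationCorrelation(idxOf(p2), p2$cells[, c("x", "y", "z")],
                             p2$nucleiCoords[, c("x", "y", "z")])$r
  expect_lt(abs(r2), 0.3)

  # zero variance in the clone means is flagged
  stacks <- lapply(1:3, function(i) cbind(0, 0, c(0, 1, 2)) + 100 * i)
  coords <- do.call(rbind, stacks)
  idx <- split(1:9, rep(1:3, each = 3))
  expect_warning(
    res <- elevationCorrelation(idx, coords, coords),
    "zero variance")
  expect_true(is.na(res$r))
})
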