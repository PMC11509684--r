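test_that("elevation angle matches the spherical convention", {
  expect_equal(as.numeric(elevationAngle(c(0, 0, 0), c(0, 0, 2))), 90)
  expect_equal(as.numeric(elevationAngle(c(0, 0, 0), c(3, 4, 0))), 0)
  expect_equal(as.numeric(elevationAngle(c(0, 0, 0), c(1, 0, 1))), 45)
  # spherical radius is half the inter-centroid distance
  expect_equal(attr(elevationAngle(c(0, 0, 0), c(0, 0, 2)), "radius"), 1)
  expect_error(elevationAngle(c(1, 1, 1), c(1, 1, 1)), "degenerate")
})

test_that("elevation calibration is exact on a 1-degree grid", {
  phi <- 0:90
  for (p in phi) {
    d <- c(cos(p * pi / 180), 0, sin(p * pi / 180))
    expect_equal(as.numeric(elevationAngle(c(0, 0, 0), d)), p,
                 tolerance = 1e-9)
  }
})

test_that("elevation angle is invariant to translation, Z-rotation, swap
           and XY-plane reflection", {
  set.seed(71)
  for (i in 1:50) {
    p <- rnorm(3, sd = 10)
    q <- rnorm(3, sd = 10)
    a0 <- as.numeric(elevationAngle(p, q))
    expect_equal(as.numeric(elevationAngle(q, p)), a0)
    t <- rnorm(3, sd = 40)
    expect_equal(as.numeric(elevationAngle(p + t, q + t)), a0,
                 tolerance = 1e-9)
    th <- runif(1, 0, 2 * pi)
    Rz <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0),
                c(0, 0, 1))
    expect_equal(as.numeric(elevationAngle(Rz %*% p, Rz %*% q)), a0,
                 tolerance = 1e-9)
    refl <- c(1, 1, -1)
    expect_equal(as.numeric(elevationAngle(p * refl, q * refl)), a0,
                 tolerance = 1e-9)
  }
})

test_that("rotation classification uses a closed 60-degree lower bound", {
  expect_equal(classifyRotation(90), "complete")
  expect_equal(classifyRotation(59.999), "incomplete")
  expect_equal(classifyRotation(60), "complete")
})

test_that("the seven elevation bins have the stated boundaries", {
  expect_equal(binElevation(14.9), 1L)
  expect_equal(binElevation(80), 7L)
  expect_equal(binElevation(60), 5L)
  expect_equal(binElevation(c(0, 15, 30, 45, 70, 90)),
               c(1L, 2L, 3L, 4L, 6L, 7L))
})

test_that("clone elevation profiles aggregate doublet angles", {
  # perfectly stacked vertical clone: 2 doublets, all complete
  stack <- cloneFromPoints(cbind(0, 0, c(0, 1, 2)))
  prof <- cloneElevationProfiles(stack, identifyDoublets(stack))[["1"]]
  expect_equal(nDoublets(prof), 2L)
  expect_equal(completeFraction(prof), 1)

  # clone in the XY plane: no complete rotations
  flat <- cloneFromPoints(cbind(c(0, 1, 0), c(0, 0, 1), 0))
  pf <- cloneElevationProfiles(flat, identifyDoublets(flat))[["1"]]
  expect_equal(completeFraction(pf), 0)

  # empty profile is flagged as undefined, never zero
  p0 <- elevationProfile(numeric(0))
  expect_equal(nDoublets(p0), 0L)
  expect_true(is.na(completeFraction(p0)))
})

test_that("bin fractions sum to one and counts to nDoublets", {
  set.seed(81)
  for (i in 1:20) {
    ang <- runif(sample(1:200, 1), 0, 90)
    p <- elevationProfile(ang)
    expect_equal(sum(binCounts(p)), length(ang))
    expect_lt(abs(sum(binCounts(p) / nDoublets(p)) - 1), 1e-12)
    expect_equal(completeFraction(p), mean(ang >= 60))
  }
})

test_that("doublet-level mixture sampling recovers the complete fraction", {
  # 40% complete / 60% incomplete mixture, 2000 doublets
  ang <- doubletLevelAngles(2000, 0.4, seed = 91)
  expect_lt(abs(mean(ang >= 60) - 0.40), 0.03)
})

test_that("neighbour sensitivity finds no k effect under the null", {
  # angles independent of geometry: all clones share one mixture
  cfg <- syntheticConfig(nClones = 50, sizeRange = c(8, 15),
                         columnFraction = 0.5, pCompleteColumn = 0.5,
                         pCompleteCluster = 0.5,
                         plateExtent = c(1500, 1500, 800))
  sim <- simulateGrowthPlate(cfg, seed = 101)
  ds <- identifyDoublets(sim$clones)
  sh <- cloneShapeTable(sim$clones)
  classes <- setNames(sh$class, sh$clone_id)
  ns <- neighborSensitivity(sim$clones, ds, classes)
  expect_true(all(ns$tests$p_value > 0.05))
  # k >= max clone size - 1 equals the unrestricted profile
  tabMax <- ns$table[ns$table$k == 10, ]
  full <- doubletElevationTable(sim$clones, ds)
  for (ci in tabMax$clone_id) {
    if (max(cloneSizes(sim$clones)[as.character(ci)]) - 1 <= 10)
      expect_equal(tabMax$complete_fraction[tabMax$clone_id == ci],
                   mean(full$elevation_deg[full$clone_id == ci] >= 60))
  }
  # a set of perfect columns has proportion 1 for all k
  cols <- CloneSet(data.frame(x = rep(c(0, 100), each = 5), y = 0,
                              z = rep(seq(0, 40, 10), 2),
                              clone_id = rep(1:2, each = 5)),
                   canonicalized = TRUE)
  dcol <- identifyDoublets(cols)
  shc <- cloneShapeTable(cols)
  nsc <- neighborSensitivity(cols, dcol,
                             setNames(shc$class, shc$clone_id),
                             kRange = 1:4, lowK = 1:2, highK = 3:4)
  expect_true(all(nsc$table$complete_fraction == 1))
  # missing classes direct the user to classification
  expect_error(neighborSensitivity(cols, dcol, NULL), "class")
})

test_that("long-format profile table is stacked-histogram ready", {
  stack <- cloneFromPoints(cbind(0, 0, c(0, 1, 2)))
  tab <- elevationProfileTable(
    cloneElevationProfiles(stack, identifyDoublets(stack)))
  expect_equal(nrow(tab), 7L)
  expect_equal(sum(tab$count), 2L)
  expect_equal(tab$bin_label[7], "[80,90]")
})
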