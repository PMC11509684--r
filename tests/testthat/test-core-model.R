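test_that("nucleus tables load, group by clone, and round-trip", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(x = c(0, 1, 2), y = 0, z = c(5, 6, 7), clone_id = 1L)
  write.csv(df, path, row.names = FALSE)
  cs <- readNucleusTable(path)
  expect_equal(length(cloneIds(cs)), 1L)
  expect_equal(unname(cloneSizes(cs)), 3L)

  # empty table -> empty clone set
  write.csv(df[0, ], path, row.names = FALSE)
  expect_equal(length(cloneIds(readNucleusTable(path))), 0L)

  # missing mandatory column -> format error
  write.csv(df[, c("x", "y", "clone_id")], path, row.names = FALSE)
  expect_error(readNucleusTable(path), "missing mandatory")

  # non-finite coordinate names the offending row
  bad <- df
  bad$z[2] <- NA
  write.csv(bad, path, row.names = FALSE)
  expect_error(readNucleusTable(path), "row 2")

  # write -> read round-trips membership and centroids
  set.seed(11)
  big <- data.frame(x = rnorm(20), y = rnorm(20), z = rnorm(20),
                    clone_id = rep(1:4, each = 5))
  cs1 <- CloneSet(big, canonicalized = TRUE)
  out <- withr::local_tempfile(fileext = ".csv")
  writeNucleusTable(cs1, out)
  cs2 <- readNucleusTable(out)
  expect_equal(nuclei(cs2)$clone_id, nuclei(cs1)$clone_id)
  expect_equal(as.matrix(nuclei(cs2)[, c("x", "y", "z")]),
               as.matrix(nuclei(cs1)[, c("x", "y", "z")]),
               tolerance = 1e-9)
})

test_that("frame declaration canonicalizes the P-D axis onto +Z", {
  f <- canonicalFrame("-y")
  expect_equal(as.numeric(canonicalize(f, matrix(c(0, 5, 0), 1))),
               c(0, 0, -5))
  f2 <- canonicalFrame("+x")
  expect_equal(as.numeric(canonicalize(f2, matrix(c(3, 0, 0), 1)))[3], 3)
  expect_error(canonicalFrame("+w"))
})

test_that("canonicalization is an isometry for every declared axis", {
  set.seed(4)
  pts <- matrix(rnorm(30, sd = 20), ncol = 3)
  d0 <- dist(pts)
  for (ax in c("+x", "-x", "+y", "-y", "+z", "-z")) {
    dc <- dist(canonicalize(canonicalFrame(ax), pts))
    expect_lt(max(abs(dc - d0)), 1e-9)
  }
})

test_that("label-mask centroids use 0-based voxel positions and counts", {
  mask <- array(0L, dim = c(4, 4, 4))
  mask[1:2, 1:2, 1:2] <- 7L
  rec <- centroidsFromLabelMask(mask, c(1, 1, 1))
  expect_equal(rec$id, 7L)
  expect_equal(unlist(rec[, c("x", "y", "z")], use.names = FALSE),
               c(0.5, 0.5, 0.5))
  expect_equal(rec$volume, 8)

  # empty mask -> empty list
  expect_equal(nrow(centroidsFromLabelMask(array(0L, c(2, 2, 2)), 1)), 0L)

  # two disjoint labels, counts verified by brute force
  mask2 <- array(0L, dim = c(5, 5, 3))
  mask2[1, 1, 1] <- 2L
  mask2[4:5, 4:5, 1:3] <- 9L
  rec2 <- centroidsFromLabelMask(mask2, c(2, 2, 2))
  expect_equal(rec2$id, c(2L, 9L))
  expect_equal(rec2$volume, c(sum(mask2 == 2), sum(mask2 == 9)) * 8)

  expect_error(centroidsFromLabelMask(mask, c(1, -1, 1)), "config error")
})

test_that("label masks round-trip through multi-page TIFF", {
  mask <- array(0L, dim = c(6, 5, 4))
  mask[2:3, 2:4, 2:3] <- 3L
  mask[5, 1, 4] <- 12L
  path <- withr::local_tempfile(fileext = ".tif")
  writeLabelMask(mask, path)
  back <- readLabelMask(path)
  expect_equal(back, mask)
  rec <- centroidsFromLabelMask(path, 1)
  expect_equal(rec$id, c(3L, 12L))
})

test_that("volume filters follow the inclusive 100-1200 / strict >150 rules", {
  cs <- CloneSet(data.frame(x = 1:3, y = 0, z = 0, clone_id = 1L,
                            volume = c(50, 500, 1500)),
                 canonicalized = TRUE)
  out <- applyFilters(cs)
  expect_equal(nuclei(out)$volume, 500)

  # inclusive bounds pass
  cs2 <- CloneSet(data.frame(x = 1:2, y = 0, z = 0, clone_id = 1L,
                             volume = c(100, 1200)),
                  canonicalized = TRUE)
  expect_equal(nrow(nuclei(applyFilters(cs2))), 2L)

  # clone with total volume exactly 150 is removed (strict >)
  cs3 <- CloneSet(data.frame(x = 1:2, y = 0, z = 0, clone_id = c(1L, 2L),
                             volume = c(150, 400)),
                  canonicalized = TRUE)
  expect_equal(cloneIds(applyFilters(cs3)), 2L)

  # idempotence
  once <- applyFilters(cs)
  expect_equal(nuclei(applyFilters(once)), nuclei(once))

  # records lacking volume pass with a warning
  cs4 <- CloneSet(data.frame(x = 1:2, y = 0, z = 0, clone_id = 1L,
                             volume = c(NA, 500)),
                  canonicalized = TRUE)
  expect_warning(out4 <- applyFilters(cs4), "unfiltered")
  expect_equal(nrow(nuclei(out4)), 2L)

  # configurable clone volume cap (clone volume is the post-filter sum)
  expect_equal(length(cloneIds(applyFilters(cs,
    filterSpec(cloneVolumeMax = 400)))), 0L)
  expect_equal(length(cloneIds(applyFilters(cs,
    filterSpec(cloneVolumeMax = 600)))), 1L)
  expect_equal(length(cloneIds(applyFilters(cs2,
    filterSpec(cloneVolumeMax = 1000)))), 0L)
})

test_that("CloneSet validity rejects duplicate ids and bad volumes", {
  expect_error(CloneSet(data.frame(id = c(1, 1), x = 1:2, y = 0, z = 0,
                                   clone_id = 1L), canonicalized = TRUE))
  expect_error(new("CloneSet",
                   nuclei = data.frame(id = 1L, x = 0, y = 0, z = 0,
                                       clone_id = 1L, color = "cfp",
                                       volume = -5, zone = "PZ"),
                   frame = canonicalFrame()))
})
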