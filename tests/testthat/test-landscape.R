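test_that("neighbour-mean imputation fills missing cells as documented", {
  v <- matrix(c(1, 2, 3, 4, NA, 5, 6, 7, 8), 3, 3, byrow = TRUE)
  out <- gridValues(imputeMissingCells(RasterGrid(v)))
  expect_equal(out[2, 2], mean(c(1:8)))
  expect_equal(out[-5], v[-5])  # known cells untouched

  full <- RasterGrid(matrix(runif(9), 3))
  expect_equal(gridValues(imputeMissingCells(full)), gridValues(full))

  v2 <- matrix(c(NA, 2, 4, 6), 2, 2)
  expect_equal(gridValues(imputeMissingCells(RasterGrid(v2)))[1, 1], 4)

  expect_error(imputeMissingCells(RasterGrid(matrix(NA_real_, 2, 2))),
               "empty grid")
})

test_that("imputation matches the sweep oracle and is idempotent", {
  set.seed(42)
  for (rep in 1:8) {
    nr <- sample(3:20, 1); nc <- sample(3:20, 1)
    v <- matrix(runif(nr * nc), nr, nc)
    v[sample(nr * nc, floor(nr * nc * 0.4))] <- NA
    if (all(is.na(v))) v[1] <- 0.5
    g <- imputeMissingCells(RasterGrid(v))
    expect_equal(gridValues(g), oracleImpute(v), tolerance = 1e-12)
    expect_equal(gridValues(imputeMissingCells(g)), gridValues(g))
  }
})

test_that("block resampling replicates cells and preserves block means", {
  g <- RasterGrid(matrix(c(1, 3, 2, 4), 2, 2), cellSize = 1)
  out <- resampleNearest(g, 2)
  expect_equal(dim(gridValues(out)), c(4L, 4L))
  expect_equal(gridValues(out)[1:2, 1:2], matrix(1, 2, 2))
  expect_equal(out@cellSize, 0.5)
  expect_equal(gridValues(resampleNearest(g, 1)), gridValues(g))
  expect_equal(gridValues(resampleNearest(RasterGrid(matrix(7)), 3)),
               matrix(7, 3, 3))
  # multiset of distinct values and per-block means preserved
  set.seed(7)
  v <- matrix(runif(12), 3, 4)
  r <- gridValues(resampleNearest(RasterGrid(v), 3))
  expect_setequal(unique(as.vector(r)), unique(as.vector(v)))
  blockMean <- sapply(1:4, function(c0) sapply(1:3, function(r0)
    mean(r[(3 * r0 - 2):(3 * r0), (3 * c0 - 2):(3 * c0)])))
  expect_equal(blockMean, v, ignore_attr = TRUE)
  expect_error(resampleNearest(g, 0))
  expect_error(resampleNearest(g, 1.5))
})

test_that("zonal statistics match direct computation", {
  g <- RasterGrid(matrix(c(2, 6, 4, 8), 2, 2))
  z <- matrix(c(1, 2, 1, 2), 2, 2)
  expect_equal(zonalStat(g, z, "mean")$value, c(3, 7))
  expect_equal(zonalStat(g, z, "sum")$value, c(6, 14))
  z1 <- matrix(1, 2, 2)
  expect_equal(zonalStat(RasterGrid(matrix(1:4, 2)), z1, "mean")$value, 2.5)
  expect_error(zonalStat(g, z, "mean", zones = c(1, 2, 3)), "zero cells")
  # sum over all zones equals the grid total
  set.seed(3)
  v <- matrix(runif(100), 10)
  zz <- matrix(sample(1:4, 100, TRUE), 10)
  expect_equal(sum(zonalStat(RasterGrid(v), zz, "sum")$value), sum(v))
})

test_that("urban proportion is the population share inside the mask", {
  pop <- RasterGrid(matrix(c(10, 20, 30, 40), 2, 2))
  ones <- RasterGrid(matrix(1, 2, 2))
  zeros <- RasterGrid(matrix(0, 2, 2))
  z <- matrix(c(1, 1, 2, 2), 2, 2)
  expect_equal(urbanProportion(pop, ones, z)$proportion, c(1, 1))
  expect_equal(urbanProportion(pop, zeros, z)$proportion, c(0, 0))
  mask <- RasterGrid(matrix(c(1, 0, 0, 1), 2, 2))
  one <- matrix(1, 2, 2)
  expect_equal(urbanProportion(pop, mask, one)$proportion, (10 + 40) / 100)
  zeroPop <- RasterGrid(matrix(0, 2, 2))
  expect_error(urbanProportion(zeroPop, ones, one), "zero total population")
})

test_that("population-weighted centroids behave under weighting and symmetry", {
  # two cells with centres at x = 0 and x = 2, pops 1 and 3
  pop <- RasterGrid(matrix(c(1, 3), 1, 2), cellSize = 2, xll = -1)
  ctr <- popWeightedCentroid(pop, matrix(1, 1, 2))
  expect_equal(ctr$cx, 1.5)
  # uniform population over a square: geometric centre
  u <- RasterGrid(matrix(1, 4, 4), cellSize = 1)
  ctr2 <- popWeightedCentroid(u, matrix(1, 4, 4))
  expect_equal(c(ctr2$cx, ctr2$cy), c(2, 2))
  # all mass in one cell: that cell's centre
  w <- matrix(0, 3, 3); w[2, 3] <- 5
  ctr3 <- popWeightedCentroid(RasterGrid(w + 1e-300), matrix(1, 3, 3))
  expect_equal(c(ctr3$cx, ctr3$cy), c(2.5, 1.5))
})

test_that("pairwise centroid distances are Euclidean, symmetric, metric", {
  u <- UnitTable(data.frame(id = c("a", "b"), coarse_id = "C1",
                            population = 10, urban_prop = 0.5, gcp_pc = 1,
                            cx = c(0, 3), cy = c(0, 4)))
  d <- pairwiseDistances(u)
  expect_equal(d["a", "b"], 5)
  set.seed(5)
  u2 <- fixtureUnits(8)
  d2 <- pairwiseDistances(u2)
  expect_equal(diag(d2), rep(0, 8), ignore_attr = TRUE)
  expect_equal(d2, t(d2))
  ids <- unitIds(u2)
  for (k in 1:20) {
    ijk <- sample(ids, 3)
    expect_lte(d2[ijk[1], ijk[2]],
               d2[ijk[1], ijk[3]] + d2[ijk[3], ijk[2]] + 1e-12)
  }
})

test_that("contiguity matrices are symmetric 0/1 with validated ids", {
  u <- fixtureUnits(3)
  ids <- unitIds(u)
  A <- buildContiguity(data.frame(id_a = ids[1], id_b = ids[2]), u)
  expect_equal(A[ids[1], ids[2]], 1)
  expect_equal(A[ids[2], ids[1]], 1)
  expect_equal(sum(A), 2)
  expect_equal(sum(buildContiguity(data.frame(id_a = character(),
                                              id_b = character()), u)), 0)
  expect_error(buildContiguity(data.frame(id_a = ids[1], id_b = ids[1]), u),
               "self-pair")
  expect_error(buildContiguity(data.frame(id_a = "nope", id_b = ids[1]), u),
               "unknown unit id")
})

test_that("ASCII grids and delimited tables round-trip through files", {
  v <- matrix(runif(12), 3, 4)
  v[2, 2] <- NA
  g <- RasterGrid(v, cellSize = 0.25, xll = -70, yll = 3)
  path <- withr::local_tempfile(fileext = ".asc")
  writeAsciiGrid(g, path)
  g2 <- readAsciiGrid(path)
  expect_equal(gridValues(g2), gridValues(g), tolerance = 1e-12)
  expect_equal(g2@cellSize, 0.25)
  expect_equal(c(g2@xll, g2@yll), c(-70, 3))

  u <- fixtureUnits(5)
  up <- withr::local_tempfile(fileext = ".tsv")
  writeUnitTable(u, up, header = "fixture")
  u2 <- readUnitTable(up)
  expect_equal(as.data.frame(u2)$id, unitIds(u))
  expect_equal(as.data.frame(u2)$population, as.numeric(populations(u)),
               tolerance = 1e-12)

  ep <- withr::local_tempfile(fileext = ".tsv")
  writeEdgeList(data.frame(id_a = "u01", id_b = "u02"), ep)
  expect_equal(readEdgeList(ep)$id_b, "u02")
})

test_that("unit aggregation pools population and weights attributes", {
  u <- fixtureUnits(6, nCoarse = 2)
  agg <- aggregateUnits(u)
  expect_equal(nUnits(agg), 2)
  df <- as.data.frame(u); da <- as.data.frame(agg)
  expect_equal(sum(da$population), sum(df$population))
  c1 <- df[df$coarse_id == "C1", ]
  expect_equal(da$urban_prop[da$id == "C1"],
               sum(c1$urban_prop * c1$population) / sum(c1$population))
  expect_equal(da$coarse_id, da$id)  # broadest level is its own parent
})
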