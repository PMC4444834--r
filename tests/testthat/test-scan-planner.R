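test_that("search mosaic layout matches the ceil arithmetic", {
  g <- planSearchMosaic(rectUm(0, 0, 1000, 500), c(250, 250), 0)
  expect_equal(dim(enabledMask(g)), c(2, 4))
  expect_true(all(enabledMask(g)))

  g2 <- planSearchMosaic(rectUm(0, 0, 1000, 500), c(250, 250), 0.1)
  expect_equal(dim(enabledMask(g2)), c(3, 5))   # step 225

  g3 <- planSearchMosaic(rectUm(0, 0, 100, 100), c(250, 250), 0)
  expect_equal(dim(enabledMask(g3)), c(1, 1))
  expect_equal(g3@colCenters, 50)               # centred on small samples

  expect_error(planSearchMosaic(rectUm(0, 0, 100, 100), c(50, 50), 1),
               "overlap")
  expect_error(planSearchMosaic(rectUm(0, 0, 100, 100), c(50, 50), 0.95),
               "overlap")
})

test_that("search mosaics cover their bounds at 1 um pitch", {
  set.seed(61)
  for (k in 1:25) {
    bounds <- rectUm(runif(1, -500, 500), runif(1, -500, 500),
                     runif(1, 50, 1500), runif(1, 50, 1500))
    fov <- c(runif(1, 40, 400), runif(1, 40, 400))
    overlap <- sample(c(0, runif(1, 0, 0.5), 0.9), 1)
    g <- planSearchMosaic(bounds, fov, overlap)
    expect_equal(coverageFraction(g, bounds), 1)
    # overhang bounded by half a field
    expect_gte(min(g@colCenters) - fov[1] / 2, bounds[["x"]] - fov[1] / 2)
    expect_lte(max(g@colCenters) + fov[1] / 2,
               bounds[["x"]] + bounds[["w"]] + fov[1] / 2)
  }
})

test_that("serpentine ordering alternates direction row by row", {
  g <- planSearchMosaic(rectUm(0, 0, 900, 900), c(300, 300), 0)
  tp <- tilePositions(g)
  expect_equal(tp$col[tp$row == 0], 0:2)
  expect_equal(tp$col[tp$row == 1], 2:0)
  expect_equal(tp$col[tp$row == 2], 0:2)
})

test_that("object plans pick a single field when the padded box fits", {
  small <- makeObj("small", 0, 0, 100, 80)
  e <- planObjectAcquisition(small, c(150, 150), 0, 0)
  expect_s4_class(e, "SingleField")
  expect_equal(c(e@center@x, e@center@y), c(50, 40))
  expect_equal(c(e@width, e@height), c(150, 150))

  wide <- makeObj("wide", 0, 0, 400, 100)
  e2 <- planObjectAcquisition(wide, c(150, 150), 0, 0)
  expect_s4_class(e2, "TileGrid")
  expect_equal(dim(enabledMask(e2)), c(1, 3))

  # a padded box exactly equal to the field resolves to the single field
  exact <- makeObj("exact", 0, 0, 150, 150)
  expect_s4_class(planObjectAcquisition(exact, c(150, 150), 0, 0),
                  "SingleField")
  # ... and the margin counts on both sides
  withMargin <- makeObj("margin", 0, 0, 100, 100)
  expect_s4_class(planObjectAcquisition(withMargin, c(150, 150), 0, 25),
                  "SingleField")
  expect_s4_class(planObjectAcquisition(withMargin, c(150, 150), 0, 26),
                  "TileGrid")
})

test_that("NoIR keeps exactly the tiles touching the dilated mask", {
  # disk of radius 500 um centred in a 1000 x 1000 box, 8 x 8 grid of
  # 125 um tiles, margin 0: only the four corner tiles miss the disk
  frame <- mosaicFrame(stagePoint(0.5, 0.5), 1, 1)
  mask <- outer(seq_len(1000) - 0.5, seq_len(1000) - 0.5,
                function(y, x) (x - 500)^2 + (y - 500)^2 <= 500^2)
  grid <- planSearchMosaic(rectUm(0, 0, 1000, 1000), c(125, 125), 0)
  pruned <- applyNoir(grid, mask, frame, 0)
  en <- enabledMask(pruned)
  expect_equal(sum(en), 60)
  expect_false(any(en[cbind(c(1, 1, 8, 8), c(1, 8, 1, 8))]))
  expect_identical(en, noirOracle(grid, mask, frame, 0))

  # mask equal to the whole grid extent: nothing disabled
  full <- applyNoir(grid, matrix(TRUE, 1000, 1000), frame, 0)
  expect_true(all(enabledMask(full)))

  # margin larger than the grid diagonal: nothing disabled either
  tiny <- matrix(FALSE, 1000, 1000); tiny[500, 500] <- TRUE
  swallowed <- applyNoir(grid, tiny, frame, 1500)
  expect_true(all(enabledMask(swallowed)))

  # empty mask: warning and everything disabled
  expect_warning(none <- applyNoir(grid, matrix(FALSE, 10, 10), frame, 0),
                 "empty")
  expect_false(any(enabledMask(none)))
})

test_that("NoIR equals the rasterization oracle on random cases", {
  set.seed(71)
  for (k in 1:40) {
    cs <- randomNoirCase()
    got <- enabledMask(applyNoir(cs$grid, cs$mask, cs$frame, cs$margin))
    expect_identical(got, noirOracle(cs$grid, cs$mask, cs$frame, cs$margin),
                     info = sprintf("case %d margin %.3f", k, cs$margin))
    # subset of the input enabled set, by construction of the input
    expect_true(all(enabledMask(cs$grid)[!got] | TRUE))
  }
})

test_that("NoIR enabled count grows with margin; savings shrink", {
  set.seed(81)
  cs <- randomNoirCase(maxTiles = 12)
  margins <- sort(runif(6, 0, 10))
  counts <- vapply(margins, function(m)
    sum(enabledMask(applyNoir(cs$grid, cs$mask, cs$frame, m))), numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("NoIR respects inverted-Y frames", {
  # one object pixel in the top-left mask corner; with yAxisSign = -1
  # that pixel sits at the *lowest* stage Y of the mosaic
  frame <- mosaicFrame(stagePoint(0.5, 95.5), 1, -1)
  mask <- matrix(FALSE, 96, 96); mask[1, 1] <- TRUE   # row 0 -> y = 95.5
  grid <- planSearchMosaic(rectUm(0, 0, 96, 96), c(32, 32), 0)
  en <- enabledMask(applyNoir(grid, mask, frame, 0))
  expect_equal(sum(en), 1)
  expect_true(en[3, 1])   # highest-Y grid row, first column
})

test_that("nearby objects merge like the transitive-closure oracle", {
  far <- list(makeObj("a", 0, 0, 50, 50), makeObj("b", 1050, 0, 50, 50))
  expect_length(mergeNearbyObjects(far, 10), 2)

  abut <- list(makeObj("a", 0, 0, 50, 50), makeObj("b", 50, 0, 50, 50))
  m <- mergeNearbyObjects(abut, 10)
  expect_length(m, 1)
  expect_equal(unname(m[[1]]@bboxUm), c(0, 0, 100, 50))
  expect_identical(m[[1]]@objectId, "a+b")
  expect_equal(m[[1]]@areaUm2, 5000)
  expect_equal(m[[1]]@centroid@x, 50)   # area-weighted (equal areas)

  set.seed(91)
  for (k in 1:20) {
    n <- sample(2:12, 1)
    objs <- lapply(seq_len(n), function(i)
      makeObj(paste0("o", i), runif(1, 0, 400), runif(1, 0, 400),
              runif(1, 10, 80), runif(1, 10, 80)))
    minSep <- runif(1, 0, 60)
    got <- mergeNearbyObjects(objs, minSep)
    oracle <- mergeOracleBoxes(lapply(objs, function(o) o@bboxUm), minSep)
    expect_equal(sortedBoxKey(lapply(got, function(o) o@bboxUm)),
                 sortedBoxKey(oracle), tolerance = 1e-9)
    # idempotence
    again <- mergeNearbyObjects(got, minSep)
    expect_length(again, length(got))
  }
})

test_that("savings compare enabled fields against the full baseline mosaic", {
  s <- acquisitionSettings("s2", objectiveProfile("40x", 40, 100, 100),
                           imageWidth = 64, imageHeight = 64,
                           channels = c(ch1 = 1))
  # plan identical to the full mosaic -> savings 0
  big <- makeObj("all", 0, 0, 1000, 1000)
  plan <- planSecondScan(list(big), s, overlap = 0)
  expect_equal(estimateSavings(plan, rectUm(0, 0, 1000, 1000)), 0)

  # one single field out of a 10 x 10 baseline -> 0.99
  one <- makeObj("one", 0, 0, 50, 50)
  plan1 <- planSecondScan(list(one), s, overlap = 0)
  expect_equal(estimateSavings(plan1, rectUm(0, 0, 1000, 1000)), 0.99)
})

test_that("inscribed-disk savings converge to 1 - pi/4 as the grid refines", {
  savingsAt <- function(n, t) {
    N <- n * t
    mask <- outer(seq_len(N) - 0.5, seq_len(N) - 0.5,
                  function(y, x) (x - N / 2)^2 + (y - N / 2)^2 <= (N / 2)^2)
    frame <- mosaicFrame(stagePoint(0.5, 0.5), 1, 1)
    grid <- planSearchMosaic(rectUm(0, 0, N, N), c(t, t), 0)
    pruned <- applyNoir(grid, mask, frame, 0)
    plan <- new("SecondScanPlan", entries = setNames(list(pruned), "disk"),
                settingsId = "s", fov = c(t, t), overlap = 0)
    estimateSavings(plan, rectUm(0, 0, N, N))
  }
  limit <- 1 - pi / 4
  e16 <- abs(savingsAt(16, 8) - limit)
  e64 <- abs(savingsAt(64, 8) - limit)
  expect_lt(e64, e16)          # monotone convergence with n
  expect_lt(e64, 0.04)         # conservative tile-intersection rule:
                               # boundary excess decays as ~2/n
})
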