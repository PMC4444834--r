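tinyTmaSlide <- function(seed = 3) {
  generateSlide(tmaSpec(nPieces = 4, extent = c(3000, 3000),
                        pieceDiameter = c(150, 450), seed = seed))
}

test_that("the first scan stitches tiles at their nominal geometry", {
  slide <- tinyTmaSlide()
  tpl <- demoTemplate("tma", extent = c(3000, 3000))
  # one-tile sample: mosaic equals the tile
  s1 <- tpl@firstScanSettings             # 2500 um FOV, 512 px
  small <- generateSlide(tmaSpec(nPieces = 1, extent = c(2000, 2000),
                                 pieceDiameter = c(200, 300), seed = 5))
  grid1 <- planSearchMosaic(rectUm(0, 0, 2000, 2000), c(2500, 2500), 0)
  tiles1 <- acquire(small, s1, grid1)
  expect_length(tiles1, 1)
  st1 <- stitchTiles(tiles1)
  expect_identical(st1$image, tiles1[[1]]$image)

  # 4 x 2 grid at zero overlap: stitched size is exactly (4w) x (2h) px
  obj <- objectiveProfile("10x", 10, 500, 500)
  s <- acquisitionSettings("z", obj, imageWidth = 100, imageHeight = 100,
                           channels = c(tissue = 1))   # 5 um pixels
  grid <- planSearchMosaic(rectUm(0, 0, 2000, 1000), c(500, 500), 0)
  expect_equal(dim(enabledMask(grid)), c(2, 4))
  st <- stitchTiles(acquire(slide, s, grid))
  expect_equal(dim(st$image)[1:2], c(200, 400))
})

test_that("stepwise execution equals the one-click play run artifact-for-artifact", {
  slide <- tinyTmaSlide()
  tpl <- demoTemplate("tma", extent = c(3000, 3000))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()

  m1 <- runFirstScan(tpl, slide, outDir = d1)
  m1 <- runAnalysis(m1)
  m1 <- runSecondScan(m1, writeImages = FALSE)

  m2 <- runAll(tpl, slide, outDir = d2, writeImages = FALSE)

  for (art in c("coordinates", "second_scan_job_slide1")) {
    f1 <- manifestArtifacts(m1)[[art]]
    f2 <- manifestArtifacts(m2)[[art]]
    expect_identical(readBin(f1, "raw", file.size(f1)),
                     readBin(f2, "raw", file.size(f2)), info = art)
  }
  expect_equal(manifestSavings(m1), manifestSavings(m2))
  expect_true(all(manifestStatus(m2) == "done"))
})

test_that("steps enforce their order and a failing analysis halts the chain", {
  slide <- tinyTmaSlide()
  tpl <- demoTemplate("tma", extent = c(3000, 3000))
  d <- withr::local_tempdir()
  m <- runFirstScan(tpl, slide, outDir = d)
  expect_error(runSecondScan(m), "step order")

  # an external macro that fails must not let step 3 run
  tplBad <- tpl
  tplBad@macro <- "external"
  tplBad@externalCommand <- "false"
  mb <- runFirstScan(tplBad, slide, outDir = withr::local_tempdir())
  expect_error(mb <- runAnalysis(mb), "macro-contract")
  expect_identical(manifestStatus(mb)[["analysis"]], "pending")
  expect_error(runSecondScan(mb), "step order")
})

test_that("an empty coordinate list warns and acquires nothing", {
  # blank slide: a TMA spec with zero pieces
  blank <- generateSlide(tmaSpec(nPieces = 0, extent = c(3000, 3000),
                                 seed = 7))
  tpl <- demoTemplate("tma", extent = c(3000, 3000))
  d <- withr::local_tempdir()
  m <- runFirstScan(tpl, blank, outDir = d)
  m <- runAnalysis(m)
  expect_equal(nrow(readCoordinates(manifestArtifacts(m)$coordinates)), 0)
  expect_warning(m <- runSecondScan(m), "empty coordinate list")
  expect_identical(manifestStatus(m)[["second_scan"]], "done")
  expect_true(is.na(manifestSavings(m)))
})

test_that("small objects are re-acquired centred, with paracentricity applied", {
  # one ellipse just small enough (with margins) for a single 250 um field
  slide <- generateSlide(tmaSpec(nPieces = 1, extent = c(2000, 2000),
                                 pieceDiameter = c(200, 215),
                                 shapes = "ellipse",
                                 minSeparationUm = 10, seed = 9))
  tpl <- demoTemplate("tma", extent = c(2000, 2000))
  tpl@noirEnabled <- FALSE
  tpl@planMarginUm <- 0
  d <- withr::local_tempdir()
  m <- runAll(tpl, slide, outDir = d, writeImages = FALSE)
  job <- readScanJob(manifestArtifacts(m)$second_scan_job_slide1)
  expect_length(job@items, 1)
  it <- job@items[[1]]
  expect_s4_class(it, "SingleField")
  recs <- readCoordinates(manifestArtifacts(m)$coordinates)
  # the stage request equals the detected centroid plus the objective
  # offset difference (here +4, -3 um)
  expect_equal(it@center@x, recs$x_um[1] + 4, tolerance = 1e-9)
  expect_equal(it@center@y, recs$y_um[1] - 3, tolerance = 1e-9)
  # and the simulated capture lands centred on the object: the brightest
  # region's centroid sits at the image centre
  acq <- m@state$slots$slide1$acquisitions[[1]]
  img <- acq$image[, , 1]
  w <- img > (max(img) + min(img)) / 2
  ctr <- c(mean(col(img)[w]), mean(row(img)[w]))
  px <- dim(img)[1] / 2 + 0.5
  expect_lt(max(abs(ctr - px)), 1.5)   # within ~1 px of centre
})

test_that("NoIR acquires fewer or equal fields and still covers each object", {
  slide <- tinyTmaSlide(seed = 13)
  tpl <- demoTemplate("tma", extent = c(3000, 3000))
  dOn <- withr::local_tempdir(); dOff <- withr::local_tempdir()
  mOn <- runAll(tpl, slide, outDir = dOn, noir = TRUE, writeImages = FALSE)
  mOff <- runAll(tpl, slide, outDir = dOff, noir = FALSE,
                 writeImages = FALSE)
  planOn <- mOn@state$slots$slide1$plan
  planOff <- mOff@state$slots$slide1$plan
  nOn <- sum(vapply(planOn@entries, function(e)
    if (is(e, "SingleField")) 1 else sum(enabledMask(e)), numeric(1)))
  nOff <- sum(vapply(planOff@entries, function(e)
    if (is(e, "SingleField")) 1 else sum(enabledMask(e)), numeric(1)))
  expect_lte(nOn, nOff)
  expect_gte(manifestSavings(mOn), manifestSavings(mOff))
  # both plans fully cover each object's mask
  frame <- mOn@state$slots$slide1$frame
  objs <- mOn@state$slots$slide1$objects
  for (k in seq_along(objs)) {
    expect_true(maskCoveredByEntry(objs[[k]], planOn@entries[[k]], frame))
    expect_true(maskCoveredByEntry(objs[[k]], planOff@entries[[k]], frame))
  }
})

test_that("the reported savings equal a recomputation from the emitted job", {
  slide <- tinyTmaSlide(seed = 15)
  tpl <- demoTemplate("tma", extent = c(3000, 3000))
  m <- runAll(tpl, slide, outDir = withr::local_tempdir(),
              writeImages = FALSE)
  job <- readScanJob(manifestArtifacts(m)$second_scan_job_slide1)
  fov2 <- unname(effectiveFov(tpl@secondScanSettings))
  plan <- new("SecondScanPlan",
              entries = setNames(job@items,
                                 vapply(job@items, function(i) i@id,
                                        character(1))),
              settingsId = job@settings@id, fov = fov2,
              overlap = tpl@secondOverlap)
  expect_equal(manifestSavings(m),
               estimateSavings(plan, rectUm(0, 0, 3000, 3000)))
})

test_that("manual selections drive the second scan through the same pipeline", {
  slide <- tinyTmaSlide(seed = 17)
  tpl <- demoTemplate("tma", extent = c(3000, 3000))
  d <- withr::local_tempdir()
  m <- runFirstScan(tpl, slide, outDir = d)
  gt <- groundTruth(slide)
  recs <- data.frame(object_id = "pick1", x_um = gt$x[1], y_um = gt$y[1],
                     bbox_w_um = 2 * gt$radius[1],
                     bbox_h_um = 2 * gt$radius[1],
                     label = "manual", score = 1)
  m <- runAnalysis(m, macro = "manual", records = recs)
  got <- readCoordinates(manifestArtifacts(m)$coordinates)
  expect_equal(got$object_id, "pick1")
  m <- runSecondScan(m, writeImages = FALSE)
  expect_identical(manifestStatus(m)[["second_scan"]], "done")
})

test_that("manifest JSON records status, artifacts and savings", {
  slide <- tinyTmaSlide(seed = 19)
  tpl <- demoTemplate("tma", extent = c(3000, 3000))
  m <- runAll(tpl, slide, outDir = withr::local_tempdir(),
              writeImages = FALSE)
  p <- withr::local_tempfile(fileext = ".json")
  writeManifest(m, p)
  doc <- jsonlite::fromJSON(p)
  expect_equal(doc$status$second_scan, "done")
  expect_equal(doc$savings, manifestSavings(m), tolerance = 1e-6)
  expect_true("coordinates" %in% names(doc$artifacts))
})
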