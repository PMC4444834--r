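rectImage <- function(nr = 120, nc = 160, rects, bg = 0.05, fg = 0.8) {
  img <- matrix(bg, nr, nc)
  for (r in rects)
    img[r[1]:r[2], r[3]:r[4]] <- fg
  img
}

test_that("tissue detection finds bright components and filters by area", {
  frame <- mosaicFrame(stagePoint(0, 0), 2)
  params <- detectionParams("tissue", thresholdMode = "fixed",
                            thresholdValue = 0.4, smoothingSigma = 0)

  expect_identical(detectTissue(matrix(0.05, 60, 60), frame, params), list())

  # three disjoint rectangles: rows/cols are 1-based matrix indices
  rects <- list(c(11, 30, 11, 40), c(61, 100, 21, 60), c(31, 44, 101, 112))
  img <- rectImage(rects = rects)
  objs <- detectTissue(img, frame, params)
  expect_length(objs, 3)
  # sorted by descending area
  areas <- vapply(objs, function(o) o@areaUm2, numeric(1))
  expect_true(all(diff(areas) <= 0))
  # centroids within 1 px of the true rectangle centres (stage um)
  centres <- lapply(rects, function(r)
    c(mean(r[3:4]) - 1, mean(r[1:2]) - 1) * frame@pixelSize)
  for (o in objs) {
    d <- vapply(centres, function(cc)
      max(abs(c(o@centroid@x, o@centroid@y) - cc)), numeric(1))
    expect_lt(min(d), frame@pixelSize)
  }
  # areas in um^2: smallest rect is 14 x 12 px * 4 um^2/px
  expect_equal(min(areas), 14 * 12 * 4)

  # raising min_area above the smallest rectangle leaves two objects
  params2 <- detectionParams("tissue", thresholdMode = "fixed",
                             thresholdValue = 0.4, smoothingSigma = 0,
                             minArea = 14 * 12 * 4 + 1)
  expect_length(detectTissue(img, frame, params2), 2)
})

test_that("components are 8-connected and border objects are flagged", {
  frame <- mosaicFrame(stagePoint(0, 0), 1)
  params <- detectionParams("ch", thresholdMode = "fixed",
                            thresholdValue = 0.5, smoothingSigma = 0)
  # two 2x2 blocks touching only at one corner: one 8-connected object
  img <- matrix(0, 20, 20)
  img[5:6, 5:6] <- 1
  img[7:8, 7:8] <- 1
  objs <- detectTissue(img, frame, params)
  expect_length(objs, 1)
  expect_false(objs[[1]]@border)

  imgB <- matrix(0, 20, 20)
  imgB[1:3, 9:11] <- 1
  objsB <- detectTissue(imgB, frame, params)
  expect_length(objsB, 1)
  expect_true(objsB[[1]]@border)
})

test_that("detection is equivariant under camera translation", {
  slide <- generateSlide(ctcSpec(nCells = 150, eventFraction = 0.04,
                                 extent = c(500, 500), noiseSd = 0,
                                 seed = 13))
  tpl <- demoTemplate("ctc")
  # both windows contain the whole scene; only the camera is shifted
  r1 <- renderRegion(slide, rectUm(-20, -20, 540, 540), 2)
  r2 <- renderRegion(slide, rectUm(-36, -32, 540, 540), 2)
  e1 <- detectRareEvents(r1$image, r1$frame, tpl@detectionParams,
                         tpl@markerRules)
  e2 <- detectRareEvents(r2$image, r2$frame, tpl@detectionParams,
                         tpl@markerRules)
  expect_equal(length(e1), length(e2))
  expect_gt(length(e1), 0)
  c1 <- sort(vapply(e1, function(o) o@centroid@x, numeric(1)))
  c2 <- sort(vapply(e2, function(o) o@centroid@x, numeric(1)))
  expect_lt(max(abs(c1 - c2)), 2)   # within one 2 um pixel
})

test_that("marker gating implements the CK+/CD45- rule on both branches", {
  # one synthetic cell: bright nucleus, marker intensities set per case
  mkImage <- function(ck, cd45) {
    nr <- 40; nc <- 40
    d <- outer(seq_len(nr) - 20.5, seq_len(nc) - 20.5,
               function(y, x) sqrt(x^2 + y^2))
    nuc <- 0.05 + 0.6 * (d <= 5)
    cyto <- function(a) 0.05 + a * (d <= 9)
    array(c(nuc, cyto(ck), cyto(cd45)), dim = c(nr, nc, 3),
          dimnames = list(NULL, NULL, c("dapi", "ck", "cd45")))
  }
  frame <- mosaicFrame(stagePoint(0, 0), 1)
  nucleus <- detectionParams("dapi", thresholdMode = "fixed",
                             thresholdValue = 0.3, smoothingSigma = 0)
  rules <- list(markerRule("ck", "positive", 0.35),
                markerRule("cd45", "negative", 0.35))

  expect_length(detectRareEvents(mkImage(0.6, 0.1), frame, nucleus, rules), 1)
  # CD45 above the cutoff: leukocyte, excluded
  expect_length(detectRareEvents(mkImage(0.6, 0.6), frame, nucleus, rules), 0)
  # CK below the cutoff: not an event either
  expect_length(detectRareEvents(mkImage(0.1, 0.1), frame, nucleus, rules), 0)

  ev <- detectRareEvents(mkImage(0.6, 0.1), frame, nucleus, rules)[[1]]
  expect_identical(ev@label, "event")
  expect_true(all(c("dapi", "ck", "cd45") %in% names(ev@channelStats)))
  expect_gt(ev@channelStats[["ck"]], 0.35)

  expect_error(detectRareEvents(mkImage(0.6, 0.1), frame, nucleus,
                                list(markerRule("cd8", "positive", 0.2))),
               "cd8")
})

test_that("raising a positive marker threshold never increases event count", {
  slide <- generateSlide(ctcSpec(nCells = 300, extent = c(650, 650),
                                 eventFraction = 0.05, seed = 17))
  r <- renderRegion(slide, rectUm(0, 0, 650, 650), 2, noise = TRUE,
                    noiseSeed = 3)
  nucleus <- demoTemplate("ctc")@detectionParams
  counts <- vapply(seq(0.1, 0.7, by = 0.1), function(thr) {
    length(detectRareEvents(r$image, r$frame, nucleus,
                            list(markerRule("ck", "positive", thr),
                                 markerRule("cd45", "negative", 0.35))))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("noiseless scenes are recovered exactly", {
  slide <- generateSlide(ctcSpec(nCells = 200, extent = c(550, 550),
                                 eventFraction = 0.03, noiseSd = 0,
                                 seed = 19))
  tpl <- demoTemplate("ctc")
  r <- renderRegion(slide, rectUm(0, 0, 550, 550), 2)
  ev <- detectRareEvents(r$image, r$frame, tpl@detectionParams,
                         tpl@markerRules)
  gt <- groundTruth(slide)
  gte <- gt[gt$class == "event", ]
  expect_length(ev, nrow(gte))
  sc <- scoreDetections(ev, gte, tolUm = 2)   # centroid within 1 px (2 um)
  expect_equal(unname(sc), c(nrow(gte), 0, 0))
})

test_that("objects exported through the coordinate contract re-import identically", {
  frame <- mosaicFrame(stagePoint(0, 0), 2)
  params <- detectionParams("tissue", thresholdMode = "fixed",
                            thresholdValue = 0.4, smoothingSigma = 0)
  img <- rectImage(rects = list(c(11, 30, 11, 40), c(61, 100, 21, 60)))
  objs <- detectTissue(img, frame, params)
  p <- withr::local_tempfile(fileext = ".csv")
  writeCoordinates(objectsToRecords(objs), p)
  back <- importManualSelection(readCoordinates(p), frame)
  expect_equal(objectsToRecords(back)[, c("object_id", "x_um", "y_um",
                                          "bbox_w_um", "bbox_h_um")],
               objectsToRecords(objs)[, c("object_id", "x_um", "y_um",
                                          "bbox_w_um", "bbox_h_um")])
  expect_identical(back[[1]]@label, "manual")
})

test_that("the external macro contract accepts, rejects and errors as specified", {
  d <- withr::local_tempdir()
  mosaicPath <- file.path(d, "mosaic.tif")
  tiff::writeTIFF(matrix(0.5, 50, 50), mosaicPath)
  framePath <- file.path(d, "frame.json")
  writeFrame(mosaicFrame(stagePoint(0, 0), 2), framePath, dim = c(50, 50))
  # mosaic spans x,y in [-1, 99] um; one record inside, one outside
  macro <- file.path(d, "macro.R")
  writeLines(c(
    "a <- commandArgs(trailingOnly = TRUE)",
    "out <- a[length(a)]",
    "writeLines(c('object_id,x_um,y_um,bbox_w_um,bbox_h_um,label,score',",
    "  'in1,50,50,10,10,manual,1',",
    "  'out1,500,50,10,10,manual,1'), out)"), macro)
  rscript <- file.path(R.home("bin"), "Rscript")
  expect_message(
    recs <- runExternalMacro(rscript, macro, mosaicPath, framePath,
                             file.path(d, "out.csv")),
    "out1")
  expect_equal(recs$object_id, "in1")
  expect_equal(attr(recs, "rejected")$object_id, "out1")

  failing <- file.path(d, "fail.R")
  writeLines("quit(status = 3)", failing)
  expect_error(runExternalMacro(rscript, failing, mosaicPath, framePath,
                                file.path(d, "out2.csv")),
               "macro-contract error")

  silent <- file.path(d, "silent.R")
  writeLines("invisible(NULL)", silent)
  expect_error(runExternalMacro(rscript, silent, mosaicPath, framePath,
                                file.path(d, "never.csv")),
               "macro-contract error")
})
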