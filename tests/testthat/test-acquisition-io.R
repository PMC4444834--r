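test_that("settings documents round-trip canonically and validate fields", {
  obj <- objectiveProfile("10x", 10, 1500, 1500)
  s <- acquisitionSettings("min", obj, imageWidth = 64, imageHeight = 64,
                           channels = c(dapi = 1))
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  writeSettings(s, p1)
  writeSettings(readSettings(p1), p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))

  # schema violation names the offending field
  doc <- jsonlite::fromJSON(p1, simplifyVector = FALSE)
  doc$image_width <- NULL
  p3 <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(doc, auto_unbox = TRUE), p3)
  expect_error(readSettings(p3), "image_width")

  # unknown schema version
  doc2 <- jsonlite::fromJSON(p1, simplifyVector = FALSE)
  doc2$schema_version <- 99
  writeLines(jsonlite::toJSON(doc2, auto_unbox = TRUE), p3)
  expect_error(readSettings(p3), "version")
})

test_that("randomly generated settings all round-trip field-for-field", {
  set.seed(31)
  for (k in 1:100) {
    s <- randomSettings()
    p <- withr::local_tempfile(fileext = ".json")
    writeSettings(s, p)
    s2 <- readSettings(p)
    expect_identical(s2@id, s@id)
    expect_equal(s2@zoom, s@zoom)
    expect_identical(s2@imageWidth, s@imageWidth)
    expect_identical(s2@imageHeight, s@imageHeight)
    expect_equal(s2@channels, s@channels)
    expect_equal(s2@zStack, s@zStack)
    expect_equal(s2@timeLapse, s@timeLapse)
    expect_equal(s2@objective@fovWidth, s@objective@fovWidth)
    expect_equal(s2@objective@paracentricityDx, s@objective@paracentricityDx)
    # second write is byte-identical (canonical determinism)
    p2 <- withr::local_tempfile(fileext = ".json")
    writeSettings(s2, p2)
    expect_identical(readBin(p, "raw", file.size(p)),
                     readBin(p2, "raw", file.size(p2)))
  }
})

test_that("coordinate CSV keeps order, round-trips, and reports bad lines", {
  p <- withr::local_tempfile(fileext = ".csv")

  writeCoordinates(emptyCoordinates(), p)
  expect_identical(readLines(p), "object_id,x_um,y_um,bbox_w_um,bbox_h_um,label,score")
  expect_equal(nrow(readCoordinates(p)), 0)

  r <- data.frame(object_id = c("a", "b", "c"),
                  x_um = c(1.5, -2.25, 300), y_um = c(0, 10, -40.125),
                  bbox_w_um = c(5, 0, 12), bbox_h_um = c(5, 0, 8),
                  label = c("tissue", "manual", "event"),
                  score = c(0.5, 1, 0.25))
  writeCoordinates(r, p)
  got <- readCoordinates(p)
  expect_equal(got, r)

  writeLines(c("object_id,x_um,y_um,bbox_w_um,bbox_h_um,label,score",
               "a,abc,2,3,4,l,5"), p)
  expect_error(readCoordinates(p), "line 2")

  set.seed(41)
  for (k in 1:30) {
    r <- randomCoordinates()
    writeCoordinates(r, p)
    got <- readCoordinates(p)
    if (nrow(r)) expect_equal(got, r) else expect_equal(nrow(got), 0)
  }
})

test_that("templates save, reload and re-validate their settings references", {
  set.seed(51)
  d <- withr::local_tempdir()
  for (k in 1:20) {
    t <- randomTemplate()
    p <- file.path(d, sprintf("tpl%d.json", k))
    saveTemplate(t, p)
    t2 <- loadTemplate(p)
    expect_identical(t2@macro, t@macro)
    expect_equal(t2@noirMarginUm, t@noirMarginUm)
    expect_equal(t2@firstOverlap, t@firstOverlap)
    expect_equal(t2@minSeparationUm, t@minSeparationUm)
    expect_equal(t2@detectionParams@maxArea, t@detectionParams@maxArea)
    expect_equal(length(t2@markerRules), length(t@markerRules))
    expect_equal(t2@layout@slots, t@layout@slots)
    expect_identical(t2@firstScanSettings@id, t@firstScanSettings@id)
    # canonical: saving the reloaded template is byte-identical
    p2 <- file.path(d, sprintf("tpl%d_b.json", k))
    saveTemplate(t2, p2)
    # settings files are shared names; compare template docs only
    expect_identical(readBin(p, "raw", file.size(p)),
                     readBin(p2, "raw", file.size(p2)))
  }
  # dangling settings reference -> resolution error
  t <- randomTemplate()
  p <- file.path(d, "dangling.json")
  saveTemplate(t, p)
  unlink(file.path(d, t@firstScanPath))
  expect_error(loadTemplate(p), "resolution error")
})

test_that("scan jobs with fields and pruned grids round-trip", {
  s <- randomSettings()
  g <- planSearchMosaic(rectUm(0, 0, 900, 600), c(300, 300), 0.1)
  g@enabled[1, 2] <- FALSE
  job <- scanJob(s, list(singleField(stagePoint(10, 20), 250, 250, "f1"), g),
                 sampleId = "slide1")
  p <- withr::local_tempfile(fileext = ".json")
  writeScanJob(job, p)
  job2 <- readScanJob(p)
  expect_identical(job2@sampleId, "slide1")
  expect_equal(length(job2@items), 2)
  expect_equal(job2@items[[1]]@center@x, 10)
  expect_identical(enabledMask(job2@items[[2]]), enabledMask(g))
  expect_equal(job2@items[[2]]@colCenters, g@colCenters)
  p2 <- withr::local_tempfile(fileext = ".json")
  writeScanJob(job2, p2)
  expect_identical(readBin(p, "raw", file.size(p)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("job validation flags items outside their sample slot", {
  s <- acquisitionSettings("s", objectiveProfile("10x", 10, 500, 500),
                           imageWidth = 64, imageHeight = 64,
                           channels = c(ch1 = 1))
  layout <- slideLayout(1, width = 1000, height = 1000)
  inside <- scanJob(s, list(singleField(stagePoint(500, 500), 50, 50, "ok")))
  expect_length(validateJob(inside, layout), 0)

  outside <- scanJob(s, list(singleField(stagePoint(1001, 500), 50, 50,
                                         "field_out")))
  v <- validateJob(outside, layout)
  expect_length(v, 1)
  expect_match(v, "field_out")

  # five slides in parallel, one job per slot, all valid
  lay5 <- slideLayout(5, width = 2000, height = 1000)
  for (i in 1:5) {
    slot <- lay5@slots[i, ]
    job <- scanJob(s, list(singleField(
      stagePoint(slot$x + slot$w / 2, slot$y + slot$h / 2), 50, 50,
      paste0("f", i))), sampleId = slot$slot_id)
    expect_length(validateJob(job, lay5), 0)
  }
  expect_error(slideLayout(6), "n <= 5")
})

test_that("layout invariants reject overlapping or oversized slide sets", {
  expect_error(sampleLayout(data.frame(
    slot_id = c("a", "b"), x = c(0, 500), y = 0, w = 1000, h = 1000)),
    "overlap")
  expect_silent(sampleLayout(data.frame(
    slot_id = c("a", "b"), x = c(0, 1500), y = 0, w = 1000, h = 1000)))
})
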