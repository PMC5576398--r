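test_that("a noiseless 2.54 mm band renders as exactly 120 px at 1200 dpi", {
  img <- renderPatch(patchRenderSpec(2.54), dpi = 1200)
  px <- pixelMatrix(img)
  perRow <- rowSums(px > 0)
  expect_true(all(perRow == 120L))
  # band is one contiguous run in every row
  expect_true(all(apply(px > 0, 1, function(r)
    max(which(r)) - min(which(r)) + 1L == 120L)))
  expect_equal(measurePatchWidth(img), 2.54, tolerance = 1e-12)
  expect_equal(mmPerPixel(img), 25.4 / 1200)
})

test_that("rendering is deterministic given the seed", {
  spec <- patchRenderSpec(2.5, edgeRoughnessSd = 0.05, speckRate = 0.1,
                          dropoutRate = 0.05, seed = 11L)
  a <- renderPatch(spec, dpi = 300)
  b <- renderPatch(spec, dpi = 300)
  expect_identical(pixelMatrix(a), pixelMatrix(b))
  spec2 <- patchRenderSpec(2.5, edgeRoughnessSd = 0.05, speckRate = 0.1,
                           dropoutRate = 0.05, seed = 12L)
  expect_false(identical(pixelMatrix(a),
                         pixelMatrix(renderPatch(spec2, dpi = 300))))
})

test_that("an all-background image measures zero width", {
  img <- patchImage(matrix(0, 400, 200), dpi = 300)
  expect_equal(measurePatchWidth(img), 0)
})

test_that("bands wider than the canvas are rejected", {
  expect_error(renderPatch(patchRenderSpec(10), canvasWidth = 8),
               "canvas")
})

test_that("rasters shorter than the station span are rejected", {
  img <- renderPatch(patchRenderSpec(2, patchLength = 10), dpi = 300)
  expect_error(measurePatchWidth(img, nStations = 7, spacing = 3),
               "too short")
  expect_gt(measurePatchWidth(img, nStations = 3, spacing = 3), 0)
})

test_that("noiseless render-measure round trips are exact to one pixel", {
  for (w in c(0.9, 1.3, 2.5, 6.7)) {
    img <- renderPatch(patchRenderSpec(w), dpi = 600)
    expect_lt(abs(measurePatchWidth(img) - w), 25.4 / 600 + 1e-12)
  }
})

test_that("measured width grows monotonically with rendered width", {
  widths <- c(0.8, 1.5, 3, 6, 12)
  measured <- vapply(widths, function(w)
    measurePatchWidth(renderPatch(patchRenderSpec(w), dpi = 300)),
    numeric(1))
  expect_true(all(diff(measured) > 0))
})

test_that("specks beyond the search window do not affect the width", {
  img <- renderPatch(patchRenderSpec(2), dpi = 300, canvasWidth = 30)
  base <- measurePatchWidth(img)
  px <- pixelMatrix(img)
  # paint specks in the outermost columns, far outside the +/-5-width
  # search window around the band axis
  px[c(10, 50, 120, 200), c(2, 3, ncol(px) - 2)] <- 1
  expect_equal(measurePatchWidth(patchImage(px, 300)), base)
})

test_that("specks farther than twice the band width from the axis are inert", {
  img <- renderPatch(patchRenderSpec(2.5), dpi = 300, canvasWidth = 30)
  base <- measurePatchWidth(img)
  px <- pixelMatrix(img)
  axisCol <- mean(range(which(px[1, ] > 0)))
  offsetPx <- 2 * 2.5 / (25.4 / 300)  # two band widths from the axis
  px[seq(5, nrow(px), by = 40), round(axisCol + offsetPx)] <- 1
  expect_equal(measurePatchWidth(patchImage(px, 300)), base)
})

test_that("noisy patches are measured within one pixel plus five percent", {
  for (s in 1:10) {
    spec <- patchRenderSpec(2.5, edgeRoughnessSd = 0.05, speckRate = 0.05,
                            dropoutRate = 0.1, seed = 100L + s)
    img <- renderPatch(spec, dpi = 600)
    m <- measurePatchWidth(img)
    expect_lt(abs(m - 2.5), 25.4 / 600 + 0.05 * 2.5)
  }
})

test_that("PNG round trip preserves pixels and resolution", {
  img <- renderPatch(patchRenderSpec(2, edgeRoughnessSd = 0.03,
                                     speckRate = 0.05, seed = 3L),
                     dpi = 300)
  path <- file.path(tempdir(), "patch.png")
  writePatchPng(img, path)
  back <- readPatchPng(path)
  expect_equal(pixelMatrix(back), pixelMatrix(img), tolerance = 1 / 255)
  # dpi is quantised to whole pixels-per-meter in the file metadata
  expect_equal(imageDpi(back), 300, tolerance = 0.01)
  expect_equal(measurePatchWidth(back), measurePatchWidth(img),
               tolerance = 1e-4)
})

test_that("BMP round trip preserves pixels and resolution", {
  img <- renderPatch(patchRenderSpec(2, edgeRoughnessSd = 0.03,
                                     speckRate = 0.05, seed = 3L),
                     dpi = 300)
  path <- file.path(tempdir(), "patch.bmp")
  writePatchBmp(img, path)
  back <- readPatchBmp(path)
  expect_equal(pixelMatrix(back), pixelMatrix(img), tolerance = 1 / 255)
  expect_equal(imageDpi(back), 300, tolerance = 0.01)
  expect_error(readPatchBmp(path <- {
    p <- file.path(tempdir(), "notbmp.bin")
    writeBin(as.raw(1:10), p); p
  }), "not a BMP")
})
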