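#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a PatchImage
#'
#' @param pixels numeric matrix of stain intensities in [0, 1]; rows run
#'   along the cylinder length, columns across the contact width.
#' @param dpi scanner resolution, dots per inch.
#' @return a [PatchImage-class] object.
#' @export
patchImage <- function(pixels, dpi) {
  new("PatchImage", pixels = pixels, dpi = as.numeric(dpi))
}

#' Construct a PatchRenderSpec
#'
#' @param trueWidth nominal stained band width, mm.
#' @param patchLength patch extent along the cylinder length, mm;
#'   default 25 mm, the film square size.
#' @param edgeRoughnessSd SD of per-row Gaussian edge perturbation, mm.
#' @param speckRate expected exterior specks per mm^2 of canvas.
#' @param dropoutRate fraction of interior band pixels left unstained.
#' @param seed RNG seed; the render is deterministic given the seed.
#' @return a [PatchRenderSpec-class] object.
#' @export
patchRenderSpec <- function(trueWidth, patchLength = 25,
                            edgeRoughnessSd = 0, speckRate = 0,
                            dropoutRate = 0, seed = 1L) {
  new("PatchRenderSpec", trueWidth = as.numeric(trueWidth),
      patchLength = as.numeric(patchLength),
      edgeRoughnessSd = as.numeric(edgeRoughnessSd),
      speckRate = as.numeric(speckRate),
      dropoutRate = as.numeric(dropoutRate), seed = as.integer(seed))
}

#' @describeIn patchAccessors scanner resolution, dpi.
#' @export
setMethod("imageDpi", "PatchImage", function(x) x@dpi)

#' @describeIn patchAccessors physical pixel pitch, mm (25.4 / dpi).
#' @export
setMethod("mmPerPixel", "PatchImage", function(x) 25.4 / x@dpi)

#' @describeIn patchAccessors raw intensity matrix.
#' @export
setMethod("pixelMatrix", "PatchImage", function(x) x@pixels)

#' Accessors for PatchImage objects
#'
#' @param x a [PatchImage-class].
#' @name patchAccessors
NULL

setMethod("show", "PatchImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf(
    "PatchImage: %d x %d px at %g dpi (%.3g x %.3g mm), %d stained px\n",
    d[1L], d[2L], object@dpi, d[1L] * 25.4 / object@dpi,
    d[2L] * 25.4 / object@dpi, sum(object@pixels > 0)))
})

setMethod("show", "PatchRenderSpec", function(object) {
  cat(sprintf(paste0(
    "PatchRenderSpec: width %g mm, length %g mm, edge SD %g mm, ",
    "specks %g /mm^2, dropout %g, seed %d\n"),
    object@trueWidth, object@patchLength, object@edgeRoughnessSd,
    object@speckRate, object@dropoutRate, object@seed))
})

#' Render a synthetic contact-patch raster
#'
#' Draws a stained band of nominal width \code{trueWidth} centred in the
#' canvas, then degrades it the way developed film patches look when
#' scanned: each row's two edges are perturbed by independent Gaussian
#' noise (rough edges), a fraction of interior pixels is left unstained
#' (dropout), and small noncontiguous specks are scattered outside the
#' band. Stained pixels have intensity 1, background 0. The render is
#' fully deterministic given \code{spec}'s seed.
#'
#' @param spec a [PatchRenderSpec-class].
#' @param dpi raster resolution, dots per inch; default 1200, the scan
#'   resolution used for real patches.
#' @param canvasWidth canvas extent across the width axis, mm; default
#'   \code{max(6 * trueWidth, trueWidth + 8)} so that exterior specks
#'   and the measurement search window have room. Must exceed
#'   \code{trueWidth}.
#' @param speckClearance minimum distance between a speck centre and the
#'   nominal band edge, mm; keeps specks noncontiguous with the patch.
#' @return a [PatchImage-class].
#' @examples
#' img <- renderPatch(patchRenderSpec(2.54, edgeRoughnessSd = 0.05,
#'                                    speckRate = 0.05, seed = 7))
#' measurePatchWidth(img)
#' @export
renderPatch <- function(spec, dpi = 1200,
                        canvasWidth = max(6 * spec@trueWidth,
                                          spec@trueWidth + 8),
                        speckClearance = 1) {
  validObject(spec)
  stopifnot(length(dpi) == 1L, dpi > 0)
  if (spec@trueWidth >= canvasWidth)
    stop("'trueWidth' (", spec@trueWidth, " mm) must be smaller than the ",
         "canvas width (", canvasWidth, " mm)", call. = FALSE)
  s <- 25.4 / dpi
  nCols <- max(2L, as.integer(round(canvasWidth / s)))
  if (nCols %% 2L == 1L) nCols <- nCols + 1L  # centre on a pixel boundary
  nRows <- max(1L, as.integer(round(spec@patchLength / s)))
  cx <- nCols * s / 2
  centers <- (seq_len(nCols) - 0.5) * s
  half <- spec@trueWidth / 2

  withr::with_seed(spec@seed, {
    px <- matrix(0, nRows, nCols)
    left <- cx - half + stats::rnorm(nRows, 0, spec@edgeRoughnessSd)
    right <- cx + half + stats::rnorm(nRows, 0, spec@edgeRoughnessSd)
    swap <- left > right
    if (any(swap)) {
      tmp <- left[swap]; left[swap] <- right[swap]; right[swap] <- tmp
    }
    for (i in seq_len(nRows))
      px[i, centers > left[i] & centers < right[i]] <- 1
    if (spec@dropoutRate > 0) {
      stained <- which(px == 1)
      drop <- stained[stats::runif(length(stained)) < spec@dropoutRate]
      px[drop] <- 0
    }
    if (spec@speckRate > 0) {
      widthMm <- nCols * s; lengthMm <- nRows * s
      nSpecks <- stats::rpois(1L, spec@speckRate * widthMm * lengthMm)
      # exterior strips on either side of the band, inset by the clearance
      loEdge <- cx - half - speckClearance
      hiEdge <- cx + half + speckClearance
      for (k in seq_len(nSpecks)) {
        if (loEdge <= 0 && hiEdge >= widthMm) break  # no exterior room
        sideWidths <- c(max(loEdge, 0), max(widthMm - hiEdge, 0))
        side <- sample.int(2L, 1L, prob = sideWidths / sum(sideWidths))
        x0 <- if (side == 1L) stats::runif(1L, 0, loEdge)
              else stats::runif(1L, hiEdge, widthMm)
        y0 <- stats::runif(1L, 0, lengthMm)
        r <- stats::runif(1L, 0.5, 1.5) * s
        jj <- which(abs(centers - x0) <= r)
        ii <- which(abs((seq_len(nRows) - 0.5) * s - y0) <= r)
        for (i in ii) {
          hit <- jj[(centers[jj] - x0)^2 +
                    ((i - 0.5) * s - y0)^2 <= r^2]
          px[i, hit] <- 1
        }
      }
    }
    patchImage(px, dpi)
  })
}

#' Measure contact width from a patch image by station averaging
#'
#' Reproduces the scanned-film measurement procedure: the transverse
#' width is read in pixel units at \code{nStations} profile lines spaced
#' \code{spacing} mm apart along the cylinder length (centred on the
#' patch mid-length), the station widths are averaged, and the mean is
#' converted to mm via the raster's dpi.
#'
#' At each station the width is the outer extent — last minus first
#' above-threshold pixel plus one — of the stained band, read within a
#' search window of \code{searchFactor} times the patch's apparent
#' width on either side of the band axis. Stained pixels on a profile
#' are grouped into runs and runs separated by no more than
#' \code{maxGap} are merged, so the unstained gaps that dropout leaves
#' inside a real patch stay interior to the band, while isolated
#' specks — separated from the band by more than \code{maxGap} — form
#' their own groups and cannot inflate the extent. The band at a
#' station is the merged group nearest the axis. Axis and apparent
#' width are first estimated from per-station medians of an unwindowed
#' pass that takes the widest group at each station.
#'
#' @param image a [PatchImage-class].
#' @param nStations number of profile lines; default 7.
#' @param spacing station spacing along the length axis, mm; default 3.
#' @param threshold intensity above which a pixel counts as stained;
#'   default 0.5 (half of full stain).
#' @param searchFactor half-width of the per-station search window, in
#'   multiples of the apparent band width; default 5.
#' @param maxGap widest unstained gap, mm, still treated as interior
#'   to the band; default 0.5.
#' @return average width in mm; 0 if no pixel exceeds the threshold at
#'   any station.
#' @examples
#' img <- renderPatch(patchRenderSpec(2.54))
#' measurePatchWidth(img)  # 2.54
#' @export
measurePatchWidth <- function(image, nStations = 7L, spacing = 3,
                              threshold = 0.5, searchFactor = 5,
                              maxGap = 0.5) {
  stopifnot(is(image, "PatchImage"), nStations >= 1L, spacing > 0,
            threshold > 0, searchFactor > 0, maxGap >= 0)
  px <- image@pixels
  s <- mmPerPixel(image)
  nRows <- nrow(px); nCols <- ncol(px)
  spacingPx <- spacing / s
  span <- (nStations - 1L) * spacingPx
  if (span > nRows - 1L)
    stop(sprintf(paste0(
      "patch is too short for the station span: %d stations %g mm apart ",
      "need %.3g mm but the raster is %.3g mm long"),
      nStations, spacing, span * s + s, nRows * s), call. = FALSE)
  mid <- (nRows + 1) / 2
  rows <- round(mid + (seq_len(nStations) - (nStations + 1) / 2) * spacingPx)
  rows <- pmin(pmax(as.integer(rows), 1L), nRows)
  maxGapPx <- maxGap / s

  # stained runs on one profile, merged across gaps <= maxGap
  groups <- function(row, cols) {
    on <- cols[px[row, cols] > threshold]
    if (length(on) == 0L) return(NULL)
    brk <- which(diff(on) > maxGapPx + 1)
    cbind(on[c(1L, brk + 1L)], on[c(brk, length(on))])
  }
  # pass 1: widest merged group per station gives a robust estimate of
  # the band axis and apparent width (specks are far narrower)
  pass1 <- matrix(NA_real_, nStations, 2L)
  for (k in seq_len(nStations)) {
    g <- groups(rows[k], seq_len(nCols))
    if (!is.null(g))
      pass1[k, ] <- g[which.max(g[, 2L] - g[, 1L]), ]
  }
  hit <- !is.na(pass1[, 1L])
  if (!any(hit)) return(0)
  axis <- stats::median((pass1[hit, 1L] + pass1[hit, 2L]) / 2)
  apparent <- stats::median(pass1[hit, 2L] - pass1[hit, 1L] + 1)
  # pass 2: within the search window, the merged group nearest the
  # axis is the band; its outer extent is the station width
  lo <- max(1L, as.integer(floor(axis - searchFactor * apparent)))
  hi <- min(nCols, as.integer(ceiling(axis + searchFactor * apparent)))
  widths <- numeric(nStations)
  for (k in seq_len(nStations)) {
    g <- groups(rows[k], lo:hi)
    if (is.null(g)) next
    dist <- pmax(g[, 1L] - axis, axis - g[, 2L], 0)
    band <- g[which.min(dist), , drop = TRUE]
    widths[k] <- band[2L] - band[1L] + 1
  }
  mean(widths) * s
}
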