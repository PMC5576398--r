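#' @import methods
NULL

#' Material: linear-elastic solid used in a contact pairing
#'
#' Holds the two elastic constants that enter the Hertzian line-contact
#' formula: Young's modulus \code{E} (GPa) and Poisson's ratio \code{nu}.
#' Construct with [material()]; the built-in registry ([defaultMaterials()])
#' covers steel, UHMWPE, artificial cortical bone and CoCr.
#'
#' @slot name character label, e.g. \code{"steel"}.
#' @slot E Young's modulus in GPa; must be positive.
#' @slot nu Poisson's ratio, dimensionless; must satisfy \code{0 <= nu < 0.5}.
#' @seealso [material()], [defaultMaterials()], [hertzWidth()]
#' @exportClass Material
setClass("Material",
  representation(name = "character", E = "numeric", nu = "numeric"))

setValidity("Material", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (length(object@E) != 1L || !is.finite(object@E) || object@E <= 0)
    msg <- c(msg, "elastic modulus 'E' must be a single positive number (GPa)")
  if (length(object@nu) != 1L || !is.finite(object@nu) ||
      object@nu < 0 || object@nu >= 0.5)
    msg <- c(msg, "Poisson's ratio 'nu' must satisfy 0 <= nu < 0.5")
  if (length(msg)) msg else TRUE
})

#' ContactCase: one cylinder-on-flat loading configuration
#'
#' A frictionless elastic cylinder of diameter \code{Dcyl} pressed onto a
#' flat substrate with compressive force \code{F}, with \code{Lcyl} mm of
#' cylinder length engaged in the contact.
#'
#' @slot F compressive force, N; non-negative.
#' @slot Dcyl cylinder diameter, mm; non-negative.
#' @slot Lcyl engaged cylinder length, mm; strictly positive.
#' @slot cylinder,flat [Material-class] objects for the two bodies.
#' @seealso [contactCase()], [hertzWidth()]
#' @exportClass ContactCase
setClass("ContactCase",
  representation(F = "numeric", Dcyl = "numeric", Lcyl = "numeric",
                 cylinder = "Material", flat = "Material"))

setValidity("ContactCase", function(object) {
  msg <- character()
  for (s in c("F", "Dcyl", "Lcyl")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v))
      msg <- c(msg, sprintf("'%s' must be a single finite number", s))
  }
  if (length(msg) == 0L) {
    if (object@F < 0) msg <- c(msg, "force 'F' must be >= 0")
    if (object@Dcyl < 0) msg <- c(msg, "diameter 'Dcyl' must be >= 0")
    if (object@Lcyl <= 0) msg <- c(msg, "engaged length 'Lcyl' must be > 0")
  }
  if (length(msg)) msg else TRUE
})

#' PowerLawModel: empirical film-measured contact width model
#'
#' The film-measured contact width follows \eqn{W_F = a F^b D^c} with
#' \code{F} in N, \code{D} in mm and \eqn{W_F} in mm. The fitted
#' coefficients for the three experimental pairings (MOM, MOP, MOB) are
#' available from [filmModels()].
#'
#' @slot a prefactor, mm N^-b mm^-c; strictly positive.
#' @slot b force exponent, dimensionless.
#' @slot c diameter exponent, dimensionless.
#' @slot combo pairing label: \code{"MOM"}, \code{"MOP"}, \code{"MOB"} or
#'   a custom label.
#' @seealso [powerLawModel()], [filmModels()], [predictWidth()],
#'   [fitPowerLaw()]
#' @exportClass PowerLawModel
setClass("PowerLawModel",
  representation(a = "numeric", b = "numeric", c = "numeric",
                 combo = "character"))

setValidity("PowerLawModel", function(object) {
  msg <- character()
  if (length(object@a) != 1L || !is.finite(object@a) || object@a <= 0)
    msg <- c(msg, "prefactor 'a' must be a single positive number")
  if (length(object@b) != 1L || !is.finite(object@b))
    msg <- c(msg, "force exponent 'b' must be a single finite number")
  if (length(object@c) != 1L || !is.finite(object@c))
    msg <- c(msg, "diameter exponent 'c' must be a single finite number")
  if (length(object@combo) != 1L || !nzchar(object@combo))
    msg <- c(msg, "'combo' must be a single non-empty label")
  if (length(msg)) msg else TRUE
})

#' FitResult: a fitted power-law width model with goodness of fit
#'
#' Returned by [fitPowerLaw()]. \code{rSquared} is the coefficient of
#' determination computed on the original (mm) scale against the fitted
#' power law; \code{rSquaredLog} is the R-squared of the underlying
#' log-space linear regression, exposed for diagnostics.
#'
#' @slot model the fitted [PowerLawModel-class].
#' @slot rSquared original-scale coefficient of determination (<= 1).
#' @slot rSquaredLog log-scale coefficient of determination (<= 1).
#' @slot n number of records used in the fit.
#' @seealso [fitPowerLaw()]
#' @exportClass FitResult
setClass("FitResult",
  representation(model = "PowerLawModel", rSquared = "numeric",
                 rSquaredLog = "numeric", n = "integer"))

setValidity("FitResult", function(object) {
  msg <- character()
  if (length(object@rSquared) != 1L || object@rSquared > 1 + 1e-12)
    msg <- c(msg, "'rSquared' must be a single number <= 1")
  if (length(object@rSquaredLog) != 1L || object@rSquaredLog > 1 + 1e-12)
    msg <- c(msg, "'rSquaredLog' must be a single number <= 1")
  if (length(object@n) != 1L || object@n < 3L)
    msg <- c(msg, "'n' must be a single count >= 3")
  if (length(msg)) msg else TRUE
})

#' PatchImage: grayscale raster of a film contact patch
#'
#' A scanned (or synthetically rendered) contact patch. Pixel values are
#' stain intensities in [0, 1] with 0 = unstained background. Rows run
#' along the cylinder length axis and columns across the contact width,
#' so each row is one transverse intensity profile. The physical scale is
#' \code{25.4 / dpi} mm per pixel.
#'
#' @slot pixels numeric matrix of intensities in [0, 1]; rows = length
#'   axis, columns = width axis.
#' @slot dpi scanner resolution in dots (pixels) per inch; positive.
#' @seealso [patchImage()], [renderPatch()], [measurePatchWidth()],
#'   [mmPerPixel()]
#' @exportClass PatchImage
setClass("PatchImage",
  representation(pixels = "matrix", dpi = "numeric"))

setValidity("PatchImage", function(object) {
  msg <- character()
  if (!is.numeric(object@pixels) || length(dim(object@pixels)) != 2L)
    msg <- c(msg, "'pixels' must be a numeric matrix")
  else if (any(!is.finite(object@pixels)) ||
           any(object@pixels < 0) || any(object@pixels > 1))
    msg <- c(msg, "pixel intensities must be finite and within [0, 1]")
  if (length(object@dpi) != 1L || !is.finite(object@dpi) || object@dpi <= 0)
    msg <- c(msg, "'dpi' must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' PatchRenderSpec: parameters for rendering a synthetic contact patch
#'
#' Describes the geometry and imperfections of a synthetic film patch:
#' a stained band of nominal width \code{trueWidth} over a patch of
#' length \code{patchLength}, with per-row Gaussian edge perturbation,
#' interior dropout (unstained pixels inside the band) and exterior
#' specks (small noncontiguous stains away from the band), mimicking the
#' rough edges and noncontiguous patches seen on developed film.
#'
#' @slot trueWidth nominal band width, mm; strictly positive.
#' @slot patchLength patch extent along the cylinder length, mm.
#' @slot edgeRoughnessSd standard deviation of the per-row edge
#'   perturbation, mm; >= 0.
#' @slot speckRate expected number of exterior specks per mm^2; >= 0.
#' @slot dropoutRate fraction of interior band pixels left unstained,
#'   in [0, 1).
#' @slot seed integer RNG seed; rendering is deterministic given the seed.
#' @seealso [patchRenderSpec()], [renderPatch()]
#' @exportClass PatchRenderSpec
setClass("PatchRenderSpec",
  representation(trueWidth = "numeric", patchLength = "numeric",
                 edgeRoughnessSd = "numeric", speckRate = "numeric",
                 dropoutRate = "numeric", seed = "integer"))

setValidity("PatchRenderSpec", function(object) {
  msg <- character()
  if (length(object@trueWidth) != 1L || !is.finite(object@trueWidth) ||
      object@trueWidth <= 0)
    msg <- c(msg, "'trueWidth' must be a single positive number (mm)")
  if (length(object@patchLength) != 1L || !is.finite(object@patchLength) ||
      object@patchLength <= 0)
    msg <- c(msg, "'patchLength' must be a single positive number (mm)")
  if (length(object@edgeRoughnessSd) != 1L || object@edgeRoughnessSd < 0)
    msg <- c(msg, "'edgeRoughnessSd' must be >= 0")
  if (length(object@speckRate) != 1L || object@speckRate < 0)
    msg <- c(msg, "'speckRate' must be >= 0")
  if (length(object@dropoutRate) != 1L || object@dropoutRate < 0 ||
      object@dropoutRate >= 1)
    msg <- c(msg, "'dropoutRate' must be in [0, 1)")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "'seed' must be a single integer")
  if (length(msg)) msg else TRUE
})

#' ExperimentDesign: layout of a simulated indentation experiment
#'
#' The factorial design of the indentation study: material pairings x
#' cylinder diameters x compressive forces, each cell replicated, with a
#' per-pairing replicate variability expressed as a coefficient of
#' variation (relative SD of the measured width). The default design
#' ([defaultDesign()]) is 5 diameters x 2 forces x 3 replicates per
#' pairing.
#'
#' @slot combos character vector of pairing labels.
#' @slot diameters cylinder diameters, mm; positive, no duplicates.
#' @slot forces compressive forces, N; positive, no duplicates.
#' @slot replicates replicates per cell; >= 1.
#' @slot cv named numeric vector of per-combo width CVs (fraction of the
#'   mean), one entry per combo; each in [0, 1).
#' @slot seed integer RNG seed for the simulation.
#' @seealso [experimentDesign()], [defaultDesign()],
#'   [simulateIndentationDataset()]
#' @exportClass ExperimentDesign
setClass("ExperimentDesign",
  representation(combos = "character", diameters = "numeric",
                 forces = "numeric", replicates = "integer",
                 cv = "numeric", seed = "integer"))

setValidity("ExperimentDesign", function(object) {
  msg <- character()
  if (length(object@combos) < 1L || anyDuplicated(object@combos))
    msg <- c(msg, "'combos' must be a non-empty vector of unique labels")
  if (length(object@diameters) < 1L || any(object@diameters <= 0) ||
      anyDuplicated(object@diameters))
    msg <- c(msg, "'diameters' must be unique positive values (mm)")
  if (length(object@forces) < 1L || any(object@forces <= 0) ||
      anyDuplicated(object@forces))
    msg <- c(msg, "'forces' must be unique positive values (N)")
  if (length(object@replicates) != 1L || object@replicates < 1L)
    msg <- c(msg, "'replicates' must be a single count >= 1")
  if (is.null(names(object@cv)) || !all(object@combos %in% names(object@cv)))
    msg <- c(msg, "'cv' must be named and cover every combo")
  else if (any(object@cv < 0) || any(object@cv >= 1))
    msg <- c(msg, "each 'cv' must lie in [0, 1)")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "'seed' must be a single integer")
  if (length(msg)) msg else TRUE
})
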