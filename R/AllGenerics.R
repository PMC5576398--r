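#' @include AllClasses.R
NULL

#' Hertzian line-contact width
#'
#' Closed-form true contact width for a frictionless elastic cylinder
#' pressed on a flat substrate (classic Hertzian line contact):
#' \deqn{W_O = \sqrt{\frac{8 F D_{cyl}}{\pi L_{cyl}}
#'   \left[\frac{1-\nu_{cyl}^2}{E_{cyl}} +
#'         \frac{1-\nu_{flat}^2}{E_{flat}}\right]}}
#' Inputs follow the experimental unit convention (F in N, lengths in mm,
#' moduli in GPa); the evaluation converts to SI internally and returns
#' the width in mm.
#'
#' @param case a [ContactCase-class], or the force in N when using the
#'   numeric convenience form.
#' @param ... passed to methods; the numeric method takes \code{Dcyl},
#'   \code{Lcyl} (mm) and \code{cylinder}, \code{flat} materials.
#' @return contact width in mm. Zero force or zero diameter gives 0 by
#'   continuity. A warning is issued when the width exceeds one tenth of
#'   the cylinder diameter, where the Hertzian small-contact assumption
#'   becomes questionable.
#' @examples
#' hertzWidth(contactCase(750, 50.8, 75, "steel", "steel"))
#' hertzWidth(335, Dcyl = 36.5, Lcyl = 13.61,
#'            cylinder = "CoCr", flat = "UHMWPE")
#' @export
setGeneric("hertzWidth", function(case, ...) standardGeneric("hertzWidth"))

#' Predict film-measured contact width from a power-law model
#'
#' Evaluates \eqn{W_F = a F^b D^c} (F in N, D in mm, result in mm).
#'
#' @param model a [PowerLawModel-class] or a combo label such as
#'   \code{"MOM"} (resolved through [filmModels()]).
#' @param F compressive force, N; non-negative (vectorised).
#' @param D cylinder diameter, mm; non-negative (vectorised).
#' @param ... passed to methods.
#' @return predicted width(s) in mm; 0 where \code{F = 0} or \code{D = 0}.
#' @examples
#' predictWidth(filmModel("MOM"), F = 750, D = 50.8)
#' predictWidth("MOP", F = 3000, D = 76.2)
#' @export
setGeneric("predictWidth", function(model, F, D, ...)
  standardGeneric("predictWidth"))

#' @rdname materialAccessors
#' @export
setGeneric("modulus", function(x) standardGeneric("modulus"))

#' @rdname materialAccessors
#' @export
setGeneric("poissonRatio", function(x) standardGeneric("poissonRatio"))

#' @rdname materialAccessors
#' @export
setGeneric("materialName", function(x) standardGeneric("materialName"))

#' @rdname modelAccessors
#' @export
setGeneric("comboLabel", function(x) standardGeneric("comboLabel"))

#' @rdname modelAccessors
#' @export
setGeneric("rSquared", function(x, scale = c("original", "log"))
  standardGeneric("rSquared"))

#' @rdname patchAccessors
#' @export
setGeneric("imageDpi", function(x) standardGeneric("imageDpi"))

#' @rdname patchAccessors
#' @export
setGeneric("mmPerPixel", function(x) standardGeneric("mmPerPixel"))

#' @rdname patchAccessors
#' @export
setGeneric("pixelMatrix", function(x) standardGeneric("pixelMatrix"))
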