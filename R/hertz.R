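#' @include AllClasses.R AllGenerics.R materials.R
NULL

#' Construct a ContactCase
#'
#' @param F compressive force, N (>= 0).
#' @param Dcyl cylinder diameter, mm (>= 0).
#' @param Lcyl engaged cylinder length, mm (> 0).
#' @param cylinder,flat materials of the two bodies: [Material-class]
#'   objects or registry labels (see [getMaterial()]).
#' @return a [ContactCase-class] object.
#' @examples
#' contactCase(750, 50.8, 75, "steel", "steel")
#' @export
contactCase <- function(F, Dcyl, Lcyl, cylinder, flat) {
  new("ContactCase", F = as.numeric(F), Dcyl = as.numeric(Dcyl),
      Lcyl = as.numeric(Lcyl), cylinder = getMaterial(cylinder),
      flat = getMaterial(flat))
}

#' Per-pairing engaged cylinder length
#'
#' In the indentation experiments 75 mm of cylinder length was engaged
#' for metal-on-metal tests and 50 mm for metal-on-polymer and
#' metal-on-bone tests (set by the substrate plate sizes).
#'
#' @param combo pairing label: \code{"MOM"}, \code{"MOP"} or \code{"MOB"}.
#' @return engaged length in mm.
#' @export
defaultEngagedLength <- function(combo) {
  stopifnot(is.character(combo))
  unname(vapply(combo, function(cb) switch(cb,
    MOM = 75, MOP = 50, MOB = 50,
    stop("no default engaged length for combo '", cb, "'", call. = FALSE)),
    numeric(1)))
}

#' Default cylinder/flat materials for a pairing
#'
#' All experimental cylinders were steel; the flat substrate is steel
#' (MOM), UHMWPE (MOP) or artificial cortical bone (MOB).
#'
#' @param combo pairing label: \code{"MOM"}, \code{"MOP"} or \code{"MOB"}.
#' @param registry material registry, see [getMaterial()].
#' @return list with elements \code{cylinder} and \code{flat}.
#' @export
comboMaterials <- function(combo, registry = defaultMaterials()) {
  stopifnot(is.character(combo), length(combo) == 1L)
  flat <- switch(combo, MOM = "steel", MOP = "UHMWPE", MOB = "bone",
    stop("no default materials for combo '", combo, "'", call. = FALSE))
  list(cylinder = getMaterial("steel", registry),
       flat = getMaterial(flat, registry))
}

# Core evaluation in SI units. F [N], D/L [mm] -> m, E [GPa] -> Pa;
# result back to mm. Vectorised over F and D.
.hertzWidthCore <- function(F, D_mm, L_mm, Ecyl_GPa, nuCyl, Eflat_GPa, nuFlat) {
  compliance <- (1 - nuCyl^2) / (Ecyl_GPa * 1e9) +
                (1 - nuFlat^2) / (Eflat_GPa * 1e9)
  w_m <- sqrt(8 * F * (D_mm * 1e-3) / (pi * (L_mm * 1e-3)) * compliance)
  w_m * 1e3
}

#' @rdname hertzWidth
#' @param warnValidity warn when \eqn{W_O > 0.1 D_{cyl}}, outside the
#'   small-contact regime the formula assumes. Default \code{TRUE}.
#' @export
setMethod("hertzWidth", "ContactCase", function(case, warnValidity = TRUE) {
  validObject(case)
  if (case@F == 0 || case@Dcyl == 0) return(0)
  w <- .hertzWidthCore(case@F, case@Dcyl, case@Lcyl,
                       case@cylinder@E, case@cylinder@nu,
                       case@flat@E, case@flat@nu)
  if (isTRUE(warnValidity) && w > 0.1 * case@Dcyl)
    warning(sprintf(paste0(
      "contact width %.3g mm exceeds 10%% of the cylinder diameter ",
      "(%.3g mm); Hertzian small-contact assumption may be violated"),
      w, case@Dcyl), call. = FALSE)
  w
})

#' @rdname hertzWidth
#' @param Dcyl cylinder diameter, mm.
#' @param Lcyl engaged cylinder length, mm.
#' @param cylinder,flat materials or registry labels.
#' @param warnValidity see above.
#' @export
setMethod("hertzWidth", "numeric",
  function(case, Dcyl, Lcyl, cylinder, flat, warnValidity = TRUE) {
    hertzWidth(contactCase(case, Dcyl, Lcyl, cylinder, flat),
               warnValidity = warnValidity)
  })

setMethod("show", "ContactCase", function(object) {
  cat(sprintf(
    "ContactCase: F = %g N, D = %g mm, L = %g mm, %s cylinder on %s flat\n",
    object@F, object@Dcyl, object@Lcyl,
    object@cylinder@name, object@flat@name))
})
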