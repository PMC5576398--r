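#' @include AllClasses.R
NULL

#' Construct a Material
#'
#' @param name material label.
#' @param E Young's modulus, GPa.
#' @param nu Poisson's ratio (0 <= nu < 0.5).
#' @return a [Material-class] object.
#' @examples
#' material("steel", E = 210, nu = 0.31)
#' @export
material <- function(name, E, nu) {
  new("Material", name = as.character(name), E = as.numeric(E),
      nu = as.numeric(nu))
}

#' Built-in material registry
#'
#' The four materials used in the indentation experiments and the knee
#' implant case study: steel (210 GPa, 0.31), ultrahigh-molecular-weight
#' polyethylene (0.9 GPa, 0.4), artificial cortical bone, a glass-filled
#' epoxy bone analogue (16.7 GPa, 0.3), and cobalt-chrome implant alloy,
#' modelled with steel's elastic constants (210 GPa, 0.31).
#'
#' @return named list of [Material-class] objects with entries
#'   \code{steel}, \code{UHMWPE}, \code{bone} and \code{CoCr}.
#' @seealso [getMaterial()], [loadMaterials()]
#' @export
defaultMaterials <- function() {
  list(
    steel  = material("steel", E = 210, nu = 0.31),
    UHMWPE = material("UHMWPE", E = 0.9, nu = 0.4),
    bone   = material("bone", E = 16.7, nu = 0.3),
    CoCr   = material("CoCr", E = 210, nu = 0.31)
  )
}

#' Look up a material by name
#'
#' @param name a material label present in the registry, or an existing
#'   [Material-class] object (returned unchanged).
#' @param registry named list of materials; defaults to
#'   [defaultMaterials()].
#' @return a [Material-class] object.
#' @examples
#' getMaterial("UHMWPE")
#' @export
getMaterial <- function(name, registry = defaultMaterials()) {
  if (is(name, "Material")) return(name)
  stopifnot(is.character(name), length(name) == 1L)
  if (!name %in% names(registry))
    stop("unknown material '", name, "'; registry has: ",
         paste(names(registry), collapse = ", "), call. = FALSE)
  registry[[name]]
}

#' Load a material registry from a YAML config file
#'
#' The file maps material names to elastic constants, e.g.
#' \preformatted{
#' steel:  {E: 210, nu: 0.31}
#' UHMWPE: {E: 0.9, nu: 0.4}
#' }
#' Entries override or extend the built-in registry.
#'
#' @param path path to the YAML file.
#' @param base registry to extend; defaults to [defaultMaterials()].
#' @return named list of [Material-class] objects.
#' @export
loadMaterials <- function(path, base = defaultMaterials()) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg) || is.null(names(cfg)))
    stop("material config must be a named mapping", call. = FALSE)
  for (nm in names(cfg)) {
    entry <- cfg[[nm]]
    if (is.null(entry$E) || is.null(entry$nu))
      stop("material '", nm, "' must provide both 'E' (GPa) and 'nu'",
           call. = FALSE)
    base[[nm]] <- material(nm, E = entry$E, nu = entry$nu)
  }
  base
}

#' @describeIn materialAccessors Young's modulus in GPa.
#' @export
setMethod("modulus", "Material", function(x) x@E)

#' @describeIn materialAccessors Poisson's ratio.
#' @export
setMethod("poissonRatio", "Material", function(x) x@nu)

#' @describeIn materialAccessors material label.
#' @export
setMethod("materialName", "Material", function(x) x@name)

#' Accessors for Material objects
#'
#' @param x a [Material-class].
#' @return \code{modulus}: modulus in GPa; \code{poissonRatio}: the
#'   dimensionless ratio; \code{materialName}: the label.
#' @name materialAccessors
NULL

setMethod("show", "Material", function(object) {
  cat(sprintf("Material '%s': E = %g GPa, nu = %g\n",
              object@name, object@E, object@nu))
})
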