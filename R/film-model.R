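#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a PowerLawModel
#'
#' @param a prefactor (> 0), mm N^-b mm^-c.
#' @param b force exponent.
#' @param c diameter exponent.
#' @param combo pairing label; default \code{"custom"}.
#' @return a [PowerLawModel-class] object.
#' @examples
#' powerLawModel(0.1778, 0.2273, 0.2936, combo = "MOM")
#' @export
powerLawModel <- function(a, b, c, combo = "custom") {
  new("PowerLawModel", a = as.numeric(a), b = as.numeric(b),
      c = as.numeric(c), combo = as.character(combo))
}

#' Fitted film-width models for the experimental pairings
#'
#' The power-law coefficients of the film-measured contact width
#' \eqn{W_F = a F^b D^c} (F in N, D in mm, W in mm) fitted to the
#' indentation experiments:
#' \itemize{
#'   \item MOM (steel on steel): \eqn{W_F = 0.1778 F^{0.2273} D^{0.2936}}
#'   \item MOP (steel on UHMWPE): \eqn{W_F = 0.0449 F^{0.4664} D^{0.4201}}
#'   \item MOB (steel on bone):  \eqn{W_F = 0.1647 F^{0.2397} D^{0.3394}}
#' }
#'
#' @return \code{filmModels()}: named list of [PowerLawModel-class]
#'   objects; \code{filmModel(combo)}: the single model for one pairing.
#' @examples
#' filmModel("MOP")
#' @export
filmModels <- function() {
  list(
    MOM = powerLawModel(0.1778, 0.2273, 0.2936, combo = "MOM"),
    MOP = powerLawModel(0.0449, 0.4664, 0.4201, combo = "MOP"),
    MOB = powerLawModel(0.1647, 0.2397, 0.3394, combo = "MOB")
  )
}

#' @rdname filmModels
#' @param combo pairing label \code{"MOM"}, \code{"MOP"} or \code{"MOB"}.
#' @export
filmModel <- function(combo) {
  models <- filmModels()
  if (!combo %in% names(models))
    stop("no fitted film model for combo '", combo,
         "'; available: ", paste(names(models), collapse = ", "),
         call. = FALSE)
  models[[combo]]
}

#' @rdname predictWidth
#' @export
setMethod("predictWidth", "PowerLawModel", function(model, F, D) {
  validObject(model)
  stopifnot(is.numeric(F), is.numeric(D))
  if (any(F < 0)) stop("force 'F' must be >= 0", call. = FALSE)
  if (any(D < 0)) stop("diameter 'D' must be >= 0", call. = FALSE)
  w <- model@a * F^model@b * D^model@c
  # 0^0 = 1 in R; zero load or zero diameter means no contact patch
  w[F == 0 | D == 0] <- 0
  w
})

#' @rdname predictWidth
#' @export
setMethod("predictWidth", "character", function(model, F, D) {
  predictWidth(filmModel(model), F, D)
})

#' Fit a power-law width model to indentation records
#'
#' Ordinary least squares on the log scale:
#' \eqn{\ln W = \ln a + b \ln F + c \ln D}, the standard line-of-best-fit
#' for power-law data. The reported \code{rSquared} is computed on the
#' original (mm) scale against the back-transformed fit; the log-scale
#' R-squared is kept alongside for diagnostics.
#'
#' @param records data.frame of indentation records with columns
#'   \code{force_N}, \code{diameter_mm}, \code{width_mm} (the schema of
#'   [indentationRecords()]); any \code{combo} column may hold one or
#'   more labels — pass a single-combo subset to fit one pairing.
#' @param combo optional label stored on the fitted model; defaults to
#'   the single combo present in \code{records}, or \code{"custom"}.
#' @return a [FitResult-class].
#' @details At least 3 records spanning at least 2 distinct forces and 2
#'   distinct diameters are required; with a single force (or diameter)
#'   level the corresponding exponent is unidentifiable and the fit
#'   stops with an error naming it. Replicates enter as individual
#'   records, not cell means.
#' @examples
#' recs <- simulateIndentationDataset(
#'   defaultDesign(combos = "MOP", cv = c(MOP = 0), seed = 1))
#' fitPowerLaw(recs)
#' @export
fitPowerLaw <- function(records, combo = NULL) {
  req <- c("force_N", "diameter_mm", "width_mm")
  if (!is.data.frame(records) || !all(req %in% names(records)))
    stop("'records' must be a data.frame with columns ",
         paste(req, collapse = ", "), call. = FALSE)
  F <- records$force_N; D <- records$diameter_mm; W <- records$width_mm
  if (any(!is.finite(F)) || any(!is.finite(D)) || any(!is.finite(W)) ||
      any(F <= 0) || any(D <= 0) || any(W <= 0))
    stop("records must have strictly positive force, diameter and width",
         call. = FALSE)
  if (nrow(records) < 3L)
    stop("need at least 3 records to fit a power law", call. = FALSE)
  if (length(unique(F)) < 2L)
    stop("degenerate design: all forces equal; force exponent 'b' is ",
         "unidentifiable", call. = FALSE)
  if (length(unique(D)) < 2L)
    stop("degenerate design: all diameters equal; diameter exponent 'c' ",
         "is unidentifiable", call. = FALSE)
  if (is.null(combo)) {
    combo <- if ("combo" %in% names(records) &&
                 length(unique(records$combo)) == 1L)
      as.character(records$combo[[1L]]) else "custom"
  }
  fit <- stats::lm(log(W) ~ log(F) + log(D))
  cf <- stats::coef(fit)
  model <- powerLawModel(exp(cf[[1L]]), cf[[2L]], cf[[3L]], combo = combo)
  What <- predictWidth(model, F, D)
  # R^2 = 1 for an exact fit even when the data are constant (SS_tot = 0)
  .r2 <- function(obs, pred) {
    ssRes <- sum((obs - pred)^2)
    ssTot <- sum((obs - mean(obs))^2)
    if (ssTot == 0) {
      if (ssRes <= 1e-12 * max(1, sum(obs^2))) 1 else -Inf
    } else 1 - ssRes / ssTot
  }
  r2 <- .r2(W, What)
  r2log <- .r2(log(W), stats::fitted(fit))
  new("FitResult", model = model, rSquared = r2,
      rSquaredLog = r2log, n = nrow(records))
}

#' Accessors for models and fit results
#'
#' @param x a [PowerLawModel-class] or [FitResult-class].
#' @param scale for \code{rSquared}: \code{"original"} (mm scale,
#'   default) or \code{"log"} (the linear regression's R-squared).
#' @param object,... [coef()][stats::coef] compatibility arguments.
#' @return \code{comboLabel}: the pairing label; \code{rSquared}: the
#'   requested coefficient of determination; \code{coef}: named vector
#'   \code{c(a =, b =, c =)}.
#' @name modelAccessors
NULL

#' @describeIn modelAccessors pairing label of a model.
#' @export
setMethod("comboLabel", "PowerLawModel", function(x) x@combo)

#' @describeIn modelAccessors pairing label of a fit's model.
#' @export
setMethod("comboLabel", "FitResult", function(x) x@model@combo)

#' @describeIn modelAccessors coefficients of a model.
#' @export
setMethod("coef", "PowerLawModel", function(object, ...)
  c(a = object@a, b = object@b, c = object@c))

#' @describeIn modelAccessors coefficients of a fitted model.
#' @export
setMethod("coef", "FitResult", function(object, ...) coef(object@model))

#' @describeIn modelAccessors coefficient of determination of a fit.
#' @export
setMethod("rSquared", "FitResult", function(x, scale = c("original", "log")) {
  switch(match.arg(scale), original = x@rSquared, log = x@rSquaredLog)
})

#' @describeIn modelAccessors the fitted model of a fit result.
#' @param fit a [FitResult-class].
#' @export
fittedModel <- function(fit) {
  stopifnot(is(fit, "FitResult"))
  fit@model
}

setMethod("show", "PowerLawModel", function(object) {
  cat(sprintf("PowerLawModel [%s]: W_F = %.4g * F^%.4g * D^%.4g  (N, mm -> mm)\n",
              object@combo, object@a, object@b, object@c))
})

setMethod("show", "FitResult", function(object) {
  show(object@model)
  cat(sprintf("  n = %d records, R^2 = %.6f (original scale), %.6f (log scale)\n",
              object@n, object@rSquared, object@rSquaredLog))
})

#' Serialize a fit result to JSON
#'
#' @param fit a [FitResult-class].
#' @param path optional file path; when omitted the JSON string is
#'   returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
writeFitJson <- function(fit, path = NULL) {
  stopifnot(is(fit, "FitResult"))
  x <- list(combo = comboLabel(fit), a = fit@model@a, b = fit@model@b,
            c = fit@model@c, r_squared = fit@rSquared,
            r_squared_log = fit@rSquaredLog, n = fit@n)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
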