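#' @include AllClasses.R hertz.R
NULL

#' CondyleCase: knee-implant condyle contact configuration
#'
#' One femoral condyle of a total knee replacement modelled as a CoCr
#' cylinder (sagittal curvature diameter \code{D_S}, width
#' \code{W_CONDYLE}) compressing a flat UHMWPE tibial layer. The
#' film-measured coronal and sagittal contact widths \code{W_FC} and
#' \code{W_FS} come from a film test of the implant. The coronal width
#' is taken as error-free (the condyle is nearly flat coronally, so the
#' film overestimates only the sagittal width):
#' \code{W_C = W_FC = W_CONDYLE}.
#'
#' @param F compressive force, N. Default 335, one condyle's share at
#'   90 degrees of knee flexion.
#' @param D_S sagittal curvature diameter, mm. Default 36.5.
#' @param W_CONDYLE condyle width = engaged cylinder length, mm.
#'   Default 13.61.
#' @param W_FC film-measured coronal width, mm. Default 13.61.
#' @param W_FS film-measured sagittal width, mm. Default 2.35.
#' @param cylinder,flat materials; default CoCr on UHMWPE.
#' @return \code{condyleCase}: a list of validated case inputs.
#' @seealso [condyleAreaError()]
#' @export
condyleCase <- function(F = 335, D_S = 36.5, W_CONDYLE = 13.61,
                        W_FC = 13.61, W_FS = 2.35,
                        cylinder = "CoCr", flat = "UHMWPE") {
  vals <- c(F = F, D_S = D_S, W_CONDYLE = W_CONDYLE, W_FC = W_FC,
            W_FS = W_FS)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all condyle case inputs must be positive finite numbers",
         call. = FALSE)
  list(F = F, D_S = D_S, W_CONDYLE = W_CONDYLE, W_FC = W_FC, W_FS = W_FS,
       cylinder = getMaterial(cylinder), flat = getMaterial(flat))
}

#' Film contact-area percentage error for a knee-implant condyle
#'
#' Computes the true sagittal contact width from Hertzian line-contact
#' theory, forms the true and film-measured contact areas, and reports
#' the film's contact-area percentage error:
#' \deqn{error = \frac{W_{FC} W_{FS} - W_C W_S}{W_C W_S} \times 100}
#' with \eqn{W_C = W_{FC}} (coronal width taken as error-free), so the
#' error reduces to \eqn{100 (W_{FS}/W_S - 1)}.
#'
#' @param case a case from [condyleCase()]; defaults to the Omnifit
#'   Series 7000 condyle at 335 N and 90 degrees flexion.
#' @return list with \code{W_S} (true sagittal width, mm),
#'   \code{true_area} and \code{film_area} (mm^2) and \code{error_pct}.
#' @examples
#' condyleAreaError()  # W_S ~ 1.46 mm, error ~ 61%
#' @export
condyleAreaError <- function(case = condyleCase()) {
  W_S <- hertzWidth(contactCase(case$F, case$D_S, case$W_CONDYLE,
                                case$cylinder, case$flat))
  W_C <- case$W_FC  # coronal width assumed error-free
  trueArea <- W_C * W_S
  filmArea <- case$W_FC * case$W_FS
  list(W_S = W_S, true_area = trueArea, film_area = filmArea,
       error_pct = (filmArea - trueArea) / trueArea * 100)
}
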