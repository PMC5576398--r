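#' @include AllClasses.R hertz.R film-model.R
NULL

# Tested experimental domain; predictions outside it are extrapolations
# of the fitted power laws and are tagged in sweep output.
.TESTED_D_RANGE <- c(1.6, 76.2)
.TESTED_F_RANGE <- c(750, 3000)

#' Film thickness-error ratio
#'
#' The headline error statistic \eqn{W_F / W_O}: the ratio of the
#' film-measured contact width (empirical power law, [predictWidth()])
#' to the true Hertzian width ([hertzWidth()]) for one material pairing
#' at a given force and cylinder diameter. Values above 1 mean the film
#' overestimates the true contact width.
#'
#' Uses the pairing's fitted film model, default materials and default
#' engaged length (75 mm MOM, 50 mm MOP/MOB).
#'
#' @param combo pairing label \code{"MOM"}, \code{"MOP"} or \code{"MOB"}.
#' @param F compressive force, N (> 0); vectorised.
#' @param D cylinder diameter, mm (> 0); vectorised.
#' @return the dimensionless ratio \eqn{W_F / W_O}.
#' @details The ratio is undefined at \code{D = 0} (both widths vanish);
#'   such inputs are rejected. No Hertz-validity warning is raised here:
#'   the ratio is routinely evaluated at small diameters where the width
#'   approaches the diameter, as the underlying sweep figures do.
#' @examples
#' errorRatio("MOM", F = 750, D = 50.8)
#' @export
errorRatio <- function(combo, F, D) {
  stopifnot(is.numeric(F), is.numeric(D))
  if (any(F <= 0)) stop("force 'F' must be > 0", call. = FALSE)
  if (any(D <= 0))
    stop("error ratio is undefined at D = 0 (both widths are 0); ",
         "diameters must be > 0", call. = FALSE)
  model <- filmModel(combo)
  mats <- comboMaterials(combo)
  L <- defaultEngagedLength(combo)
  n <- max(length(F), length(D))
  F <- rep_len(F, n); D <- rep_len(D, n)
  wO <- vapply(seq_len(n), function(i)
    hertzWidth(contactCase(F[i], D[i], L, mats$cylinder, mats$flat),
               warnValidity = FALSE), numeric(1))
  predictWidth(model, F, D) / wO
}

#' Sweep error-ratio curves over diameter and force
#'
#' Computes \eqn{W_O}, \eqn{W_F} and the error ratio \eqn{W_F/W_O} for
#' every (pairing, force) combination over a diameter grid — the full
#' error-characterisation sweep across material pairings.
#'
#' @param combos pairing labels; default all three.
#' @param forces forces in N; default \code{c(750, 3000)}, the 1x and 4x
#'   body-weight levels of the experiments.
#' @param D_grid strictly increasing positive diameters, mm; default
#'   0.5 mm steps over (0, 80] (0 is excluded: the ratio diverges as the
#'   diameter vanishes).
#' @return long-format data.frame with columns \code{combo},
#'   \code{force_N}, \code{diameter_mm}, \code{W_O_mm}, \code{W_F_mm},
#'   \code{ratio} and \code{extrapolated} (TRUE where the grid point
#'   lies outside the tested domain of 1.6–76.2 mm and 750–3000 N).
#' @examples
#' sweep <- sweepErrorCurves(D_grid = c(10, 25.4, 50.8))
#' head(sweep)
#' @export
sweepErrorCurves <- function(combos = c("MOM", "MOP", "MOB"),
                             forces = c(750, 3000),
                             D_grid = seq(0.5, 80, by = 0.5)) {
  stopifnot(is.numeric(forces), is.numeric(D_grid))
  if (any(D_grid <= 0))
    stop("all grid diameters must be > 0", call. = FALSE)
  if (is.unsorted(D_grid, strictly = TRUE))
    stop("'D_grid' must be strictly increasing", call. = FALSE)
  if (any(forces <= 0)) stop("forces must be > 0", call. = FALSE)
  out <- lapply(combos, function(cb) {
    model <- filmModel(cb)
    mats <- comboMaterials(cb)
    L <- defaultEngagedLength(cb)
    do.call(rbind, lapply(forces, function(f) {
      wO <- vapply(D_grid, function(d)
        hertzWidth(contactCase(f, d, L, mats$cylinder, mats$flat),
                   warnValidity = FALSE), numeric(1))
      wF <- predictWidth(model, f, D_grid)
      data.frame(combo = cb, force_N = f, diameter_mm = D_grid,
                 W_O_mm = wO, W_F_mm = wF, ratio = wF / wO,
                 extrapolated =
                   D_grid < .TESTED_D_RANGE[1] | D_grid > .TESTED_D_RANGE[2] |
                   f < .TESTED_F_RANGE[1] | f > .TESTED_F_RANGE[2])
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Plot error-ratio curves
#'
#' One line per (pairing, force) of the error ratio versus cylinder
#' diameter, the standard visual summary of the sweep.
#'
#' @param sweep a data.frame from [sweepErrorCurves()].
#' @return a ggplot object.
#' @export
plotErrorCurves <- function(sweep) {
  stopifnot(all(c("combo", "force_N", "diameter_mm", "ratio") %in%
                names(sweep)))
  ggplot2::ggplot(sweep, ggplot2::aes(
      x = diameter_mm, y = ratio, colour = combo,
      linetype = factor(force_N))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Cylinder diameter (mm)",
                  y = expression(W[F] / W[O]),
                  colour = "Pairing", linetype = "Force (N)") +
    ggplot2::theme_bw()
}
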