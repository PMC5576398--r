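#' @include AllClasses.R film-model.R hertz.R patch-imaging.R
NULL

#' Construct an ExperimentDesign
#'
#' @param combos pairing labels.
#' @param diameters cylinder diameters, mm.
#' @param forces compressive forces, N.
#' @param replicates replicates per (combo, force, diameter) cell.
#' @param cv named per-combo coefficient of variation of the measured
#'   width (fraction of the mean).
#' @param seed RNG seed.
#' @return an [ExperimentDesign-class] object.
#' @export
experimentDesign <- function(combos, diameters, forces, replicates, cv,
                             seed = 1L) {
  new("ExperimentDesign", combos = as.character(combos),
      diameters = as.numeric(diameters), forces = as.numeric(forces),
      replicates = as.integer(replicates), cv = cv,
      seed = as.integer(seed))
}

#' The default indentation experiment design
#'
#' The factorial layout of the indentation study: cylinder diameters of
#' 1.6, 12.7, 25.4, 50.8 and 76.2 mm (1/16 to 3 inch), quasi-static
#' forces of 750 and 3000 N (1x and 4x body weight for a 75 kg person),
#' 3 replicates per cell. Replicate variability of the measured width
#' averaged 9.3\% (MOM), 3.4\% (MOP) and 7.9\% (MOB) of the mean, which
#' the simulator applies as per-combo CVs.
#'
#' @param combos subset of pairings to include; default all three.
#' @param replicates replicates per cell; default 3.
#' @param cv named CVs; default the experimental values above
#'   (restricted to \code{combos}).
#' @param seed RNG seed; default 1.
#' @return an [ExperimentDesign-class] object.
#' @examples
#' defaultDesign("MOP")  # 5 diameters x 2 forces x 3 replicates
#' @export
defaultDesign <- function(combos = c("MOM", "MOP", "MOB"), replicates = 3L,
                          cv = c(MOM = 0.093, MOP = 0.034, MOB = 0.079),
                          seed = 1L) {
  experimentDesign(combos,
                   diameters = c(1.6, 12.7, 25.4, 50.8, 76.2),
                   forces = c(750, 3000), replicates = replicates,
                   cv = cv[combos], seed = seed)
}

#' Load an experiment design from a YAML config file
#'
#' Recognised keys: \code{combos}, \code{diameters}, \code{forces},
#' \code{replicates}, \code{cv} (mapping combo to fraction),
#' \code{seed}. Missing keys fall back to [defaultDesign()] values.
#'
#' @param path path to the YAML file.
#' @return an [ExperimentDesign-class] object.
#' @export
designFromYaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- defaultDesign()
  combos <- if (!is.null(cfg$combos)) as.character(cfg$combos)
            else base@combos
  cv <- if (!is.null(cfg$cv)) unlist(cfg$cv) else base@cv
  experimentDesign(
    combos,
    diameters = if (!is.null(cfg$diameters)) cfg$diameters
                else base@diameters,
    forces = if (!is.null(cfg$forces)) cfg$forces else base@forces,
    replicates = if (!is.null(cfg$replicates)) cfg$replicates
                 else base@replicates,
    cv = cv[combos],
    seed = if (!is.null(cfg$seed)) cfg$seed else base@seed)
}

setMethod("show", "ExperimentDesign", function(object) {
  cat(sprintf(paste0(
    "ExperimentDesign: %d combo(s) x %d force(s) x %d diameter(s) x ",
    "%d replicate(s) = %d records, seed %d\n"),
    length(object@combos), length(object@forces),
    length(object@diameters), object@replicates,
    length(object@combos) * length(object@forces) *
      length(object@diameters) * object@replicates, object@seed))
  cat("  CV: ", paste(sprintf("%s %.1f%%", object@combos,
                              100 * object@cv[object@combos]),
                      collapse = ", "), "\n", sep = "")
})

#' Build a validated indentation-record table
#'
#' The tabular record schema used throughout: one row per measured film
#' width, columns \code{combo}, \code{force_N}, \code{diameter_mm},
#' \code{replicate}, \code{width_mm}.
#'
#' @param combo pairing labels.
#' @param force_N forces, N (> 0).
#' @param diameter_mm diameters, mm (> 0).
#' @param replicate replicate indices.
#' @param width_mm measured widths, mm (> 0).
#' @return a data.frame with the schema above.
#' @export
indentationRecords <- function(combo, force_N, diameter_mm, replicate,
                               width_mm) {
  df <- data.frame(combo = as.character(combo),
                   force_N = as.numeric(force_N),
                   diameter_mm = as.numeric(diameter_mm),
                   replicate = as.integer(replicate),
                   width_mm = as.numeric(width_mm))
  .validateRecords(df)
  df
}

.validateRecords <- function(df) {
  req <- c("combo", "force_N", "diameter_mm", "replicate", "width_mm")
  if (!is.data.frame(df) || !all(req %in% names(df)))
    stop("indentation records need columns ", paste(req, collapse = ", "),
         call. = FALSE)
  num <- df[c("force_N", "diameter_mm", "width_mm")]
  if (any(!vapply(num, is.numeric, logical(1))) ||
      any(!is.finite(as.matrix(num))) || any(as.matrix(num) <= 0))
    stop("force_N, diameter_mm and width_mm must be positive finite ",
         "numbers", call. = FALSE)
  invisible(df)
}

#' Simulate the indentation experiment
#'
#' Generates film-width records for every (combo, force, diameter,
#' replicate) cell of a design. Each width is the combo's power-law
#' prediction perturbed by multiplicative Gaussian noise,
#' \eqn{W = a F^b D^c (1 + \epsilon)} with
#' \eqn{\epsilon \sim N(0, cv)}, truncated to stay positive (at the
#' experimental CVs of at most 9.3\% truncation is never triggered in
#' practice). Deterministic given the design seed.
#'
#' @param design an [ExperimentDesign-class].
#' @param models named list of [PowerLawModel-class] objects covering
#'   every combo in the design; default [filmModels()].
#' @return a data.frame of indentation records (see
#'   [indentationRecords()]) with
#'   \code{nrow = combos x forces x diameters x replicates}.
#' @examples
#' recs <- simulateIndentationDataset(defaultDesign("MOP"))
#' nrow(recs)  # 30: one film square / polymer plate per test
#' @export
simulateIndentationDataset <- function(design, models = filmModels()) {
  validObject(design)
  missing <- setdiff(design@combos, names(models))
  if (length(missing))
    stop("no width model supplied for combo(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  grid <- expand.grid(replicate = seq_len(design@replicates),
                      diameter_mm = design@diameters,
                      force_N = design@forces,
                      combo = design@combos,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("combo", "force_N", "diameter_mm", "replicate")]
  mu <- vapply(seq_len(nrow(grid)), function(i)
    predictWidth(models[[grid$combo[i]]], grid$force_N[i],
                 grid$diameter_mm[i]), numeric(1))
  cvVec <- design@cv[grid$combo]
  eps <- withr::with_seed(design@seed,
                          stats::rnorm(nrow(grid), 0, 1)) * cvVec
  w <- pmax(mu * (1 + eps), .Machine$double.eps)
  out <- cbind(grid, width_mm = w)
  rownames(out) <- NULL
  .validateRecords(out)
  out
}

#' Render a synthetic patch image for every indentation record
#'
#' Pairs each record with a rendered film patch whose nominal band width
#' is the record's measured width. The patch length defaults to the
#' 25 mm film square, capped at the pairing's engaged cylinder length.
#' Records whose width exceeds the film square are tagged
#' \code{clipped = TRUE} (physically the patch would overrun the film)
#' and flagged with a warning.
#'
#' @param records indentation records (see [indentationRecords()]).
#' @param dpi raster resolution; default 1200.
#' @param filmSquare film square side, mm; default 25.
#' @param edgeRoughnessSd,speckRate,dropoutRate render imperfections
#'   passed to [patchRenderSpec()].
#' @param seed base seed; record \code{i} renders with
#'   \code{seed + i}, so the set is byte-identical across runs.
#' @return list with \code{records} (input plus a \code{clipped}
#'   column) and \code{images} (list of [PatchImage-class], one per
#'   record row).
#' @examples
#' recs <- simulateIndentationDataset(
#'   defaultDesign("MOP", cv = c(MOP = 0)))
#' ps <- simulatePatchSet(recs[1:2, ], dpi = 300)
#' measurePatchWidth(ps$images[[1]])
#' @export
simulatePatchSet <- function(records, dpi = 1200, filmSquare = 25,
                             edgeRoughnessSd = 0.05, speckRate = 0.02,
                             dropoutRate = 0.02, seed = 1L) {
  .validateRecords(records)
  clipped <- records$width_mm > filmSquare
  if (any(clipped))
    warning(sum(clipped), " record(s) have widths beyond the ",
            filmSquare, " mm film square and are tagged clipped",
            call. = FALSE)
  lengths <- vapply(as.character(records$combo), function(cb)
    tryCatch(defaultEngagedLength(cb), error = function(e) Inf),
    numeric(1))
  patchLen <- pmin(filmSquare, lengths)
  images <- lapply(seq_len(nrow(records)), function(i) {
    spec <- patchRenderSpec(
      trueWidth = records$width_mm[i], patchLength = patchLen[i],
      edgeRoughnessSd = edgeRoughnessSd, speckRate = speckRate,
      dropoutRate = dropoutRate, seed = as.integer(seed) + i)
    renderPatch(spec, dpi = dpi,
                canvasWidth = max(6 * records$width_mm[i],
                                  records$width_mm[i] + 8))
  })
  records$clipped <- clipped
  list(records = records, images = images)
}
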