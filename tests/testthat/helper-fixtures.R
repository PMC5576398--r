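# Shared fixtures for the test suite. All expected values marked
# "frozen oracle" were computed with an independent SI-unit evaluation
# of the closed-form expressions (outside this package) and frozen here.

# full experimental grid: 5 diameters x 2 forces
experimentalGrid <- function() {
  expand.grid(force_N = c(750, 3000),
              diameter_mm = c(1.6, 12.7, 25.4, 50.8, 76.2),
              KEEP.OUT.ATTRS = FALSE)
}

# noise-free records from one registered film model over the full grid
noiseFreeRecords <- function(combo, replicates = 3L) {
  d <- defaultDesign(combo, replicates = replicates,
                     cv = stats::setNames(0, combo))
  simulateIndentationDataset(d)
}

# frozen oracle values (mm unless stated)
ORACLE <- list(
  hertz_MOM_750_50.8   = 0.10552793916114805,
  hertz_MOP_750_50.8   = 1.3488543427253346,
  hertz_MOB_750_50.8   = 0.33776827954754485,
  hertz_TKR            = 1.464628032015739,   # 335 N, 36.5 mm, 13.61 mm
  film_MOM_750_50.8    = 2.5367330532245456,
  film_MOP_3000_76.2   = 11.603392355463725,
  ratio_MOM_750_50.8   = 24.03849704058741,
  ratio_MOB_750_50.8   = 9.040596083104468,
  ratio_MOP_750_50.8   = 3.8005216009300815,
  tkr_error_full       = 60.45029513505493,   # % with full-precision W_S
  tkr_WS_670           = 2.071296826708474,
  tkr_error_670        = 13.455491733380253
)
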