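test_that("Hertz width matches independent SI-unit evaluations", {
  expect_equal(hertzWidth(contactCase(750, 50.8, 75, "steel", "steel")),
               ORACLE$hertz_MOM_750_50.8, tolerance = 1e-10)
  expect_equal(hertzWidth(contactCase(750, 50.8, 50, "steel", "UHMWPE")),
               ORACLE$hertz_MOP_750_50.8, tolerance = 1e-10)
  expect_equal(hertzWidth(contactCase(750, 50.8, 50, "steel", "bone")),
               ORACLE$hertz_MOB_750_50.8, tolerance = 1e-10)
  expect_equal(hertzWidth(contactCase(335, 36.5, 13.61, "CoCr", "UHMWPE")),
               ORACLE$hertz_TKR, tolerance = 1e-10)
})

test_that("numeric convenience form agrees with the ContactCase method", {
  expect_identical(
    hertzWidth(750, Dcyl = 50.8, Lcyl = 75,
               cylinder = "steel", flat = "steel"),
    hertzWidth(contactCase(750, 50.8, 75, "steel", "steel")))
})

test_that("zero load or zero diameter gives zero width by continuity", {
  expect_identical(hertzWidth(contactCase(0, 50.8, 75, "steel", "steel")), 0)
  expect_identical(hertzWidth(contactCase(750, 0, 75, "steel", "steel")), 0)
})

test_that("invalid contact cases are rejected", {
  expect_error(contactCase(-1, 50.8, 75, "steel", "steel"), "F")
  expect_error(contactCase(750, -2, 75, "steel", "steel"), "Dcyl")
  expect_error(contactCase(750, 50.8, 0, "steel", "steel"), "Lcyl")
  expect_error(contactCase(750, 50.8, -5, "steel", "steel"), "Lcyl")
  expect_error(getMaterial("adamantium"), "unknown material")
})

test_that("width scales as the square root of force and diameter", {
  base <- hertzWidth(contactCase(750, 50.8, 50, "steel", "UHMWPE"))
  expect_equal(hertzWidth(contactCase(3000, 50.8, 50, "steel", "UHMWPE")),
               2 * base, tolerance = 1e-12)
  expect_equal(
    hertzWidth(contactCase(750, 203.2, 50, "steel", "UHMWPE"),
               warnValidity = FALSE),
    2 * base, tolerance = 1e-12)
})

test_that("width is symmetric under swapping cylinder and flat materials", {
  for (pair in list(c("steel", "UHMWPE"), c("steel", "bone"),
                    c("CoCr", "UHMWPE"))) {
    expect_equal(
      hertzWidth(contactCase(750, 25.4, 50, pair[1], pair[2])),
      hertzWidth(contactCase(750, 25.4, 50, pair[2], pair[1])),
      tolerance = 1e-12)
  }
})

test_that("width is monotone in force, diameter and engaged length", {
  wAt <- function(F, D, L)
    hertzWidth(contactCase(F, D, L, "steel", "bone"), warnValidity = FALSE)
  Fs <- c(200, 750, 1500, 3000)
  expect_true(all(diff(vapply(Fs, wAt, numeric(1), D = 25.4, L = 50)) > 0))
  Ds <- c(1.6, 12.7, 25.4, 50.8, 76.2)
  expect_true(all(diff(vapply(Ds, function(d)
    wAt(750, d, 50), numeric(1))) > 0))
  Ls <- c(25, 50, 75, 100)
  expect_true(all(diff(vapply(Ls, function(l)
    wAt(750, 25.4, l), numeric(1))) < 0))
})

test_that("a softer flat substrate widens the contact", {
  w <- function(flat, L) hertzWidth(contactCase(750, 50.8, L, "steel", flat))
  # at the common engaged length the compliance ordering is PE > bone > steel
  expect_true(w("UHMWPE", 50) > w("bone", 50))
  expect_true(w("bone", 50) > w("steel", 50))
})

test_that("widths outside the small-contact regime raise a validity warning", {
  expect_warning(hertzWidth(contactCase(750, 2, 50, "steel", "UHMWPE")),
                 "10%")
  expect_silent(hertzWidth(contactCase(750, 50.8, 50, "steel", "UHMWPE")))
})

test_that("material registry is loadable and overridable from YAML", {
  cfg <- file.path(tempdir(), "materials.yaml")
  writeLines(c("titanium: {E: 110, nu: 0.34}",
               "steel: {E: 200, nu: 0.30}"), cfg)
  reg <- loadMaterials(cfg)
  expect_equal(modulus(reg$titanium), 110)
  expect_equal(poissonRatio(reg$titanium), 0.34)
  expect_equal(modulus(reg$steel), 200)     # override
  expect_equal(modulus(reg$UHMWPE), 0.9)    # inherited default
  expect_error(material("foam", E = 1, nu = 0.6), "nu")
  expect_error(material("void", E = -1, nu = 0.3), "modulus")
})
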