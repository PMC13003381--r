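test_that("condensation arithmetic reproduces the printed formulas", {
  expect_identical(format_formula(build_formula(d_iGDGT0)), "C86H172O6")
  expect_identical(format_formula(build_formula(d_ext_iGTGT0)), "C91H184O6")
  expect_identical(format_formula(build_formula(d_ext_iGDGT0)), "C91H182O6")
  expect_identical(
    format_formula(build_formula(
      lipid_descriptor("GTGT", bridges = 40, pendants = c(25, 25), hexoses = 1)
    )),
    "C102H204O11"
  )
  # each cyclopentane ring removes H2
  expect_identical(
    format_formula(build_formula(
      lipid_descriptor("GDGT", bridges = c(40, 40), rings = 1)
    )),
    "C86H170O6"
  )
  # the GMGT C-C bridge also removes H2
  expect_identical(
    format_formula(build_formula(
      lipid_descriptor("GMGT", bridges = c(40, 40))
    )),
    "C86H170O6"
  )
})

test_that("archaeol formulas follow diether chemistry", {
  expect_identical(format_formula(build_formula(d_AR)), "C43H88O3")
  expect_identical(
    format_formula(build_formula(lipid_descriptor("AR", pendants = c(20, 25)))),
    "C48H98O3"
  )
})

test_that("a GTGT is two hydrogens heavier than the matching GDGT", {
  for (a in c(20L, 25L)) {
    for (b in c(20L, 25L)) {
      gtgt <- build_formula(
        lipid_descriptor("GTGT", bridges = 40, pendants = c(a, b))
      )
      gdgt <- build_formula(
        lipid_descriptor("GDGT", bridges = c(40L, a + b))
      )
      expect_equal(formula_subtract(gtgt, gdgt), c(H = 2L))
    }
  }
})

test_that("structural increments change the formula by the expected units", {
  f0 <- build_formula(d_iGTGT0)
  f1 <- build_formula(d_ext_iGTGT0)
  f2 <- build_formula(d_diext_iGTGT0)
  expect_equal(formula_subtract(f1, f0), parse_formula("C5H10"))
  expect_equal(formula_subtract(f2, f1), parse_formula("C5H10"))
  fg <- build_formula(d_1G_ext_iGTGT0)
  expect_equal(formula_subtract(fg, f1), parse_formula("C6H10O5"))
})

test_that("systematic names follow the field convention", {
  expect_identical(systematic_name(d_1G_ext_iGTGT0), "1G-ext-iGTGT-0")
  expect_identical(systematic_name(d_iGDGT0), "iGDGT-0")
  expect_identical(systematic_name(d_diext_iGDGT0), "di-ext-iGDGT-0")
  expect_identical(
    systematic_name(lipid_descriptor("AR", pendants = c(20, 20), hexoses = 2)),
    "2G-AR"
  )
  expect_identical(
    systematic_name(lipid_descriptor("GDGT", bridges = c(40, 40), rings = 3)),
    "iGDGT-3"
  )
})

test_that("descriptor invariants are enforced", {
  expect_error(lipid_descriptor("GDGT", bridges = c(40, 40, 40)), "requires")
  expect_error(lipid_descriptor("GDGT", bridges = c(40, 42)), "40, 45 or 50")
  expect_error(lipid_descriptor("AR", pendants = c(20, 30)), "20 or 25")
  expect_error(lipid_descriptor("AR", pendants = c(20, 20), rings = 1),
               "rings")
  expect_error(lipid_descriptor("GDGT", bridges = c(40, 40), rings = 9),
               "0\\.\\.8")
  expect_error(lipid_descriptor("GDGT", bridges = c(40, 40), hexoses = 4),
               "hexoses")
})

test_that("library enumeration spans the requested ranges exactly once", {
  ring_series <- enumerate_library(cores = "GDGT", extensions = 0,
                                   rings = 0:4, hexoses = 0)
  expect_identical(nrow(ring_series), 5L)
  expect_setequal(ring_series$name, paste0("iGDGT-", 0:4))

  gtgt <- enumerate_library(cores = "GTGT", extensions = 0:2, rings = 0,
                            hexoses = 0)
  expect_identical(nrow(gtgt), 3L)
  expect_identical(gtgt$formula, c("C86H174O6", "C91H184O6", "C96H194O6"))

  expect_error(enumerate_library(extensions = integer(0)), "non-empty")

  lib <- default_library()
  expect_false(any(duplicated(lib$name)))
  expect_false(is.unsorted(lib$neutral_mass))
  # identical across runs
  expect_identical(dplyr::select(lib, -"descriptor"),
                   dplyr::select(default_library(), -"descriptor"))
  # adduct m/z columns consistent with the formula
  expect_equal(lib$`mz_M+H`, adduct_mz(monoisotopic_mass(lib$formula), "+H"),
               tolerance = 1e-12)
})

test_that("di-extended GDGT is modelled as C40 + C50 and mass-equals the C45+C45 isomer", {
  lib <- default_library()
  expect_identical(
    lib$chains[lib$name == "di-ext-iGDGT-0"], "C40/C50"
  )
  alt <- lipid_descriptor("GDGT", bridges = c(45, 45))
  expect_identical(format_formula(build_formula(alt)),
                   lib$formula[lib$name == "di-ext-iGDGT-0"])
})
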