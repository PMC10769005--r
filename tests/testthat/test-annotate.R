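# Lipid mass chemistry: formulas, monoisotopic masses, adducts, isotopes and
# ppm matching. Expected values are frozen from independent hand sums of the
# monoisotopic atomic masses.

test_that("monoisotopic masses reproduce independent hand sums", {
  expect_identical(monoisotopic_mass("C"), 12)
  # 2 x 1.0078250319 + 15.9949146 = 18.0105647
  expect_equal(monoisotopic_mass("H2O"), 18.0105647, tolerance = 1e-6)
  # 23*12 + 48*1.0078250319 + 14.0030740 + 7*15.9949146 + 30.9737615
  expect_equal(monoisotopic_mass("C23H48NO7P"), 481.3168392, tolerance = 1e-6)
  expect_error(monoisotopic_mass("C2X5"), "unsupported element")
  expect_error(parse_formula(""), "cannot parse")
})

test_that("formula parsing handles multi-letter elements and repeats", {
  f <- parse_formula("C6H5NaCl2C2")
  expect_identical(f[["C"]], 8L)
  expect_identical(f[["Na"]], 1L)
  expect_identical(f[["Cl"]], 2L)
})

test_that("adduct ions reproduce the reported marker and calibrant m/z", {
  lpe <- monoisotopic_mass("C23H48NO7P")
  expect_equal(round(adduct_mz(lpe, "-H"), 3), 480.310)
  lpc <- monoisotopic_mass("C26H48NO7P")
  expect_equal(round(adduct_mz(lpc, "+H"), 3), 518.324)
  expect_equal(round(lipid_mz("PI", 38, 4, "-H"), 4), 885.5499)
  expect_equal(round(lipid_mz("PC", 32, 0, "+Na"), 4), 756.5514)
  expect_equal(round(lipid_mz("PC", 34, 1, "+H"), 4), 760.5851)
  expect_equal(round(lipid_mz("PC", 34, 1, "+Na"), 4), 782.5670)
  # protonation symmetry: [M+H]+ and [M-H]- differ by two proton masses
  expect_equal(adduct_mz(lpe, "+H") - adduct_mz(lpe, "-H"), 2 * 1.00727646,
               tolerance = 1e-9)
  expect_error(adduct_mz(lpe, "+NH4"), "unsupported adduct")
})

test_that("13C isotopologue shifts match the reported isotope pairs", {
  expect_identical(isotope_mz(500, 0), 500)
  expect_equal(round(isotope_mz(adduct_mz(monoisotopic_mass("C26H48NO7P"), "+H"), 1), 3),
               519.327)
  expect_equal(round(isotope_mz(adduct_mz(monoisotopic_mass("C23H48NO7P"), "-H"), 1), 3),
               481.313)
})

test_that("lipid class composition rules give the expected formulas", {
  f <- lipid_class_formula("LPC", 18, 3)
  expect_identical(f[c("C", "H", "N", "O", "P")],
                   c(C = 26L, H = 48L, N = 1L, O = 7L, P = 1L))
  f <- lipid_class_formula("PC", 32, 0)
  expect_identical(f[c("C", "H", "N", "O", "P")],
                   c(C = 40L, H = 80L, N = 1L, O = 8L, P = 1L))
  f <- lipid_class_formula("PI", 38, 4)
  expect_identical(f[c("C", "H", "O", "P")],
                   c(C = 47L, H = 83L, O = 13L, P = 1L))
  expect_false("N" %in% names(lipid_class_formula("PA", 32, 0)))
  expect_error(lipid_class_formula("PC", 0, 20), "negative hydrogen")
  expect_error(lipid_class_formula("TG", 52, 2), "unsupported lipid class")
})

test_that("mass is monotone increasing in chain length at fixed class and DB", {
  for (cls in c("PC", "LPE", "SM", "PI")) {
    masses <- vapply(seq(20, 44, by = 2), function(cc)
      monoisotopic_mass(lipid_class_formula(cls, cc, 1)), numeric(1))
    expect_true(all(diff(masses) > 0), label = cls)
  }
})

test_that("species table expansion emits isotopologues with exact spacing", {
  tab <- expand_species_table(data.frame(name = "LPE(18:0)", class = "LPE",
                                         total_c = 18, total_db = 0,
                                         adduct = "-H", n_isotopes = 3))
  expect_identical(nrow(tab), 3L)
  expect_equal(diff(tab$theoretical_mz), rep(1.0033548, 2), tolerance = 1e-6)
})

test_that("peak annotation matches within tolerance and reports unknowns", {
  species <- expand_species_table(build_default_panel())
  expect_identical(nrow(annotate_peaks(numeric(), species)), 0L)
  hit <- annotate_peaks(480.309, species, tol_ppm = 10)
  expect_identical(hit$name, "LPE(18:0)")
  expect_lt(abs(hit$error_ppm), 2)
  far <- 480.3096 * (1 + 15e-6)
  expect_identical(annotate_peaks(far, species, tol_ppm = 10)$name, "unknown")
  expect_identical(annotate_peaks(far, species, tol_ppm = 20)$name, "LPE(18:0)")
})

test_that("exact ties (isobaric species) resolve deterministically", {
  species <- data.frame(name = c("isomer_b", "isomer_a"), adduct = "-H",
                        n13c = 0L, theoretical_mz = c(500.001, 500.001))
  # equal error: the first row in ascending-m/z order wins, stably
  expect_identical(annotate_peaks(500, species, tol_ppm = 10)$name, "isomer_b")
  expect_identical(annotate_peaks(500, species, tol_ppm = 10)$name,
                   annotate_peaks(500, species, tol_ppm = 10)$name)
  # a strictly nearer neighbour always beats a farther one
  species2 <- data.frame(name = c("near", "far"), adduct = "-H", n13c = 0L,
                         theoretical_mz = c(500.0005, 500.002))
  expect_identical(annotate_peaks(500, species2, tol_ppm = 10)$name, "near")
})

test_that("calibrant table reproduces the recalibration reference ions", {
  tab <- calibrant_table()
  expect_gte(sum(tab$polarity == "positive"), 4)
  expect_gte(sum(tab$polarity == "negative"), 4)
  expect_true(885.5499 %in% round(tab$theoretical_mz, 4))
  expect_true(all(c(756.5514, 760.5851, 782.5670) %in% round(tab$theoretical_mz, 4)))
})
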