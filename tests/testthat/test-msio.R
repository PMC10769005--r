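# imzML/ibd round trips, format validation, ion images and mask IO.

test_that("imzML round trip preserves peaks exactly", {
  ph <- generate_phantom(small_phantom_config())
  path <- file.path(tempdir(), "rt.imzML")
  write_imzml(ph$dataset, path)
  back <- read_imzml(path)
  expect_identical(length(back), length(ph$dataset))
  expect_identical(back$grid_shape, ph$dataset$grid_shape)
  # m/z stored as 64-bit floats: exact; intensities as 32-bit: relative error
  o <- order(back$coords[, 2], back$coords[, 1])
  orig <- order(ph$dataset$coords[, 2], ph$dataset$coords[, 1])
  for (k in sample(length(back), 25)) {
    i <- o[k]; j <- orig[k]
    expect_identical(back$mz[[i]], ph$dataset$mz[[j]])
    expect_equal(back$intensity[[i]], ph$dataset$intensity[[j]],
                 tolerance = 1e-6)
    expect_identical(lengths(back$mz[i]), lengths(ph$dataset$mz[j]))
  }
  file.remove(path, sub("imzML$", "ibd", path))
})

test_that("single-pixel files and polarity metadata survive the round trip", {
  ds <- toy_dataset(list(cbind(400.0, 10)), polarity = "negative")
  path <- file.path(tempdir(), "one.imzML")
  write_imzml(ds, path)
  back <- read_imzml(path)
  expect_identical(length(back), 1L)
  expect_identical(back$mz[[1]], 400.0)
  expect_identical(back$polarity, "negative")
  file.remove(path, sub("imzML$", "ibd", path))
})

test_that("invalid inputs are rejected with clear errors", {
  ds <- toy_dataset(list(cbind(400.0, 10)))
  empty <- ds; empty$mz <- list(); empty$intensity <- list()
  empty$coords <- empty$coords[0, , drop = FALSE]
  expect_error(write_imzml(empty, file.path(tempdir(), "e.imzML")), "no pixels")

  path <- file.path(tempdir(), "orphan.imzML")
  write_imzml(ds, path)
  file.remove(sub("imzML$", "ibd", path))
  expect_error(read_imzml(path), "ibd")
  file.remove(path)

  # continuous-mode declaration is refused
  path2 <- file.path(tempdir(), "cont.imzML")
  write_imzml(ds, path2)
  txt <- readLines(path2)
  txt <- sub("IMS:1000031\" name=\"processed", "IMS:1000030\" name=\"continuous", txt)
  writeLines(txt, path2)
  expect_error(read_imzml(path2), "continuous")
  file.remove(path2, sub("imzML$", "ibd", path2))
})

test_that("unsorted spectra are sorted with intensities co-permuted", {
  ds <- new_ims_dataset(mz = list(c(500, 400, 450)),
                        intensity = list(c(3, 1, 2)),
                        coords = cbind(x = 0L, y = 0L))
  expect_identical(ds$mz[[1]], c(400, 450, 500))
  expect_identical(ds$intensity[[1]], c(1, 2, 3))
  expect_error(new_ims_dataset(mz = list(c(400, 500)), intensity = list(c(1, -2)),
                               coords = cbind(x = 0L, y = 0L)), "negative")
  expect_error(new_ims_dataset(mz = list(400, 500), intensity = list(1, 2),
                               coords = cbind(x = c(0L, 0L), y = c(0L, 0L))),
               "duplicate")
})

test_that("our imzML output is readable by an independent implementation", {
  ph <- generate_phantom(small_phantom_config())
  sub <- new_ims_dataset(mz = ph$dataset$mz[1:20],
                         intensity = ph$dataset$intensity[1:20],
                         coords = ph$dataset$coords[1:20, ],
                         polarity = ph$dataset$polarity,
                         mz_range = ph$dataset$mz_range,
                         grid_shape = ph$dataset$grid_shape)
  path <- file.path(tempdir(), "xcheck.imzML")
  write_imzml(sub, path)
  script <- file.path(tempdir(), "xcheck.py")
  writeLines(c(
    "from pyimzml.ImzMLParser import ImzMLParser",
    sprintf("p = ImzMLParser(r'%s')", path),
    "mz, inten = p.getspectrum(0)",
    "print(len(p.coordinates), len(mz), '%.6f' % mz[0], '%.3f' % sum(inten))"
  ), script)
  out <- suppressWarnings(system2("python", script, stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  expect_true(is.null(status) || status == 0, label = paste(out, collapse = " "))
  parts <- strsplit(tail(out, 1), " ")[[1]]
  expect_identical(as.integer(parts[1]), 20L)
  expect_identical(as.integer(parts[2]), length(sub$mz[[1]]))
  expect_equal(as.numeric(parts[3]), sub$mz[[1]][1], tolerance = 1e-6)
  expect_equal(as.numeric(parts[4]), sum(sub$intensity[[1]]), tolerance = 1e-3)
  file.remove(path, sub("imzML$", "ibd", path), script)
})

test_that("ion images render intensity on the grid with max scaling", {
  ph <- generate_phantom(clean_phantom_config())
  fm <- extract_features(ph$dataset, sort(ph$truth$panel_mz), tol_ppm = 7)
  # deposit-exclusive marker: nonzero only inside the mask
  img <- export_ion_image(fm, ph$truth$true_marker_mz[2])
  expect_identical(dim(img), dim(ph$truth$deposit_mask))
  expect_true(all(img[!ph$truth$deposit_mask] == 0))
  expect_gt(sum(img[ph$truth$deposit_mask]), 0)
  # absent feature errors
  expect_error(export_ion_image(fm, 1999.0), "no feature within")
  # PNG output is written and max-scaled
  p <- file.path(tempdir(), "ion.png")
  export_ion_image(fm, ph$truth$true_marker_mz[2], p)
  expect_true(file.exists(p))
  expect_lte(max(png::readPNG(p)), 1)
  file.remove(p)
})

test_that("label masks survive CSV and PNG round trips", {
  lab <- matrix("unlabeled", 6, 5)
  lab[2, 2] <- "SDD"; lab[3, ] <- "background"
  mask <- new_label_mask(lab)
  for (ext in c("csv", "png")) {
    p <- file.path(tempdir(), paste0("mask.", ext))
    write_label_mask(mask, p)
    back <- read_label_mask(p, grid_shape = c(5L, 6L))
    expect_identical(back$labels, lab)
    file.remove(p)
  }
  expect_identical(mask$counts[["SDD"]], 1L)
  expect_identical(mask$counts[["background"]], 5L)
})
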