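# Dataset containers and standard-format IO: processed-mode imzML/ibd,
# PNG ion images, CSV masks and peak tables.

#' Construct an IMS dataset of centroid spectra
#'
#' @param mz List of numeric m/z vectors, one per pixel (sorted ascending;
#'   unsorted input is sorted with intensities co-permuted).
#' @param intensity List of matching non-negative intensity vectors.
#' @param coords Integer matrix (n x 2) of 0-based pixel coordinates
#'   (x = column, y = row).
#' @param polarity `"positive"` or `"negative"`.
#' @param mz_range Acquisition m/z range `c(min, max)`.
#' @param grid_shape `c(width, height)` in pixels.
#' @param provenance Free-form metadata list.
#' @return Object of class `ims_dataset`.
#' @export
new_ims_dataset <- function(mz, intensity, coords, polarity = "positive",
                            mz_range = NULL, grid_shape = NULL,
                            provenance = list()) {
  stopifnot(length(mz) == length(intensity), nrow(coords) == length(mz))
  polarity <- match.arg(polarity, c("positive", "negative"))
  for (i in seq_along(mz)) {
    if (length(mz[[i]]) != length(intensity[[i]]))
      stop_sddmark("pixel %d: m/z and intensity lengths differ", i)
    if (is.unsorted(mz[[i]], strictly = FALSE)) {
      o <- order(mz[[i]])
      mz[[i]] <- mz[[i]][o]
      intensity[[i]] <- intensity[[i]][o]
    }
    if (any(intensity[[i]] < 0)) stop_sddmark("pixel %d: negative intensity", i)
  }
  if (is.null(grid_shape)) grid_shape <- c(max(coords[, 1]) + 1L, max(coords[, 2]) + 1L)
  if (any(coords[, 1] < 0 | coords[, 1] >= grid_shape[1]) ||
      any(coords[, 2] < 0 | coords[, 2] >= grid_shape[2]))
    stop_sddmark("pixel coordinates outside grid_shape")
  if (anyDuplicated(coords[, 1] + grid_shape[1] * coords[, 2]))
    stop_sddmark("duplicate pixel coordinates")
  if (is.null(mz_range)) {
    rng <- range(unlist(mz, use.names = FALSE), na.rm = TRUE)
    mz_range <- c(floor(rng[1]), ceiling(rng[2]))
  }
  structure(list(mz = mz, intensity = intensity, coords = coords,
                 polarity = polarity, mz_range = mz_range,
                 grid_shape = as.integer(grid_shape), provenance = provenance),
            class = "ims_dataset")
}

#' @export
print.ims_dataset <- function(x, ...) {
  npk <- sum(lengths(x$mz))
  cat(sprintf("<ims_dataset> %d spectra on a %d x %d grid, %s mode\n",
              length(x$mz), x$grid_shape[1], x$grid_shape[2], x$polarity))
  cat(sprintf("  m/z range %g-%g, %d centroid peaks total (mean %.1f/pixel)\n",
              x$mz_range[1], x$mz_range[2], npk, npk / max(1, length(x$mz))))
  invisible(x)
}

#' @export
length.ims_dataset <- function(x) length(x$mz)

.imzml_uuid <- function() {
  bytes <- as.raw(sample.int(256L, 16L, replace = TRUE) - 1L)
  bytes[7] <- as.raw(bitwOr(bitwAnd(as.integer(bytes[7]), 0x0F), 0x40))
  bytes[9] <- as.raw(bitwOr(bitwAnd(as.integer(bytes[9]), 0x3F), 0x80))
  bytes
}

.uuid_string <- function(bytes) {
  hex <- paste(format(bytes), collapse = "")
  paste(substr(hex, 1, 8), substr(hex, 9, 12), substr(hex, 13, 16),
        substr(hex, 17, 20), substr(hex, 21, 32), sep = "-")
}

#' Write a dataset as processed-mode imzML
#'
#' Writes a standards-conformant imzML/ibd pair in processed (centroided)
#' mode: m/z arrays as 64-bit and intensity arrays as 32-bit floats, with
#' external offsets into the binary `.ibd` companion. Pixel positions are
#' converted to the 1-based convention of the format.
#'
#' @param dataset An `ims_dataset`.
#' @param path Output path of the `.imzML` file (the `.ibd` is written
#'   alongside).
#' @return Invisibly, `path`.
#' @export
write_imzml <- function(dataset, path) {
  stopifnot(inherits(dataset, "ims_dataset"))
  if (length(dataset) == 0) stop_sddmark("refusing to write a dataset with no pixels")
  ibd_path <- sub("\\.imzml$", ".ibd", path, ignore.case = TRUE)
  if (identical(ibd_path, path)) ibd_path <- paste0(path, ".ibd")
  # UUID derived from the dataset content: identical datasets produce
  # byte-identical files and the caller's RNG stream is untouched
  uuid <- with_seed(child_seed(sum(lengths(dataset$mz)) %% 1e6 + length(dataset), "uuid"),
                    .imzml_uuid())

  con <- file(ibd_path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(uuid, con)
  offset <- 16
  n <- length(dataset)
  mz_off <- int_off <- numeric(n)
  mz_len <- lengths(dataset$mz)
  for (i in seq_len(n)) {
    mz_off[i] <- offset
    writeBin(as.double(dataset$mz[[i]]), con, size = 8, endian = "little")
    offset <- offset + 8 * mz_len[i]
    int_off[i] <- offset
    writeBin(as.double(dataset$intensity[[i]]), con, size = 4, endian = "little")
    offset <- offset + 4 * mz_len[i]
  }

  pol_cv <- if (dataset$polarity == "positive")
    '<cvParam cvRef="MS" accession="MS:1000130" name="positive scan"/>'
  else
    '<cvParam cvRef="MS" accession="MS:1000129" name="negative scan"/>'
  head <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    '<cvList count="2">',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '<cv id="IMS" fullName="Imaging MS Ontology" URI="https://raw.githubusercontent.com/imzML/imzML/master/imagingMS.obo"/>',
    '</cvList>',
    '<fileDescription><fileContent>',
    '<cvParam cvRef="IMS" accession="IMS:1000031" name="processed"/>',
    sprintf('<cvParam cvRef="IMS" accession="IMS:1000080" name="universally unique identifier" value="{%s}"/>',
            .uuid_string(uuid)),
    '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum"/>',
    '</fileContent></fileDescription>',
    '<referenceableParamGroupList count="2">',
    '<referenceableParamGroup id="mzArray">',
    '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>',
    '</referenceableParamGroup>',
    '<referenceableParamGroup id="intensityArray">',
    '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>',
    '<cvParam cvRef="MS" accession="MS:1000521" name="32-bit float"/>',
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>',
    '</referenceableParamGroup>',
    '</referenceableParamGroupList>',
    '<scanSettingsList count="1"><scanSettings id="scanSettings1">',
    sprintf('<cvParam cvRef="IMS" accession="IMS:1000042" name="max count of pixels x" value="%d"/>',
            dataset$grid_shape[1]),
    sprintf('<cvParam cvRef="IMS" accession="IMS:1000043" name="max count of pixels y" value="%d"/>',
            dataset$grid_shape[2]),
    '</scanSettings></scanSettingsList>',
    '<softwareList count="1"><software id="sddmark" version="0.1.0"/></softwareList>',
    '<instrumentConfigurationList count="1"><instrumentConfiguration id="IC1"/></instrumentConfigurationList>',
    '<dataProcessingList count="1"><dataProcessing id="export">',
    '<processingMethod order="1" softwareRef="sddmark">',
    '<cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML"/>',
    '</processingMethod></dataProcessing></dataProcessingList>',
    sprintf('<run id="run1" defaultInstrumentConfigurationRef="IC1"><spectrumList count="%d" defaultDataProcessingRef="export">', n)
  )
  spec_xml <- vapply(seq_len(n), function(i) {
    paste0(
      sprintf('<spectrum id="spectrum=%d" index="%d" defaultArrayLength="%d">', i, i - 1, mz_len[i]),
      pol_cv,
      '<cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum"/>',
      '<scanList count="1"><scan>',
      sprintf('<cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>',
              dataset$coords[i, 1] + 1L),
      sprintf('<cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/>',
              dataset$coords[i, 2] + 1L),
      '</scan></scanList>',
      '<binaryDataArrayList count="2">',
      '<binaryDataArray encodedLength="0"><referenceableParamGroupRef ref="mzArray"/>',
      sprintf('<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>', mz_len[i]),
      sprintf('<cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>', 8 * mz_len[i]),
      sprintf('<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>', mz_off[i]),
      '<binary/></binaryDataArray>',
      '<binaryDataArray encodedLength="0"><referenceableParamGroupRef ref="intensityArray"/>',
      sprintf('<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>', mz_len[i]),
      sprintf('<cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>', 4 * mz_len[i]),
      sprintf('<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>', int_off[i]),
      '<binary/></binaryDataArray>',
      '</binaryDataArrayList></spectrum>')
  }, character(1))
  tail <- c('</spectrumList></run></mzML>')
  writeLines(c(head, spec_xml, tail), path)
  invisible(path)
}

#' Read a processed-mode imzML dataset
#'
#' Parses the imzML index and reads the external m/z (64-bit) and intensity
#' (32- or 64-bit float) arrays from the paired `.ibd` file. Continuous-mode
#' files are rejected. Unsorted m/z arrays are sorted with intensities
#' co-permuted; 1-based imzML positions are converted to the package's
#' 0-based coordinates.
#'
#' @param path Path to the `.imzML` file.
#' @return An `ims_dataset`.
#' @export
read_imzml <- function(path) {
  ibd_path <- sub("\\.imzml$", ".ibd", path, ignore.case = TRUE)
  if (identical(ibd_path, path)) ibd_path <- paste0(path, ".ibd")
  if (!file.exists(ibd_path))
    stop_sddmark("missing .ibd companion for '%s'", path)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  mode_nodes <- xml2::xml_find_all(doc, "//fileContent/cvParam[@cvRef='IMS']")
  accs <- xml2::xml_attr(mode_nodes, "accession")
  if ("IMS:1000030" %in% accs)
    stop_sddmark("continuous-mode imzML is not supported; only processed (centroided) mode")
  if (!"IMS:1000031" %in% accs)
    stop_sddmark("imzML file does not declare processed mode")

  grp <- xml2::xml_find_all(doc, "//referenceableParamGroup")
  sizes <- c(mzArray = 8L, intensityArray = 4L)
  for (g in grp) {
    id <- xml2::xml_attr(g, "id")
    acc <- xml2::xml_attr(xml2::xml_find_all(g, "cvParam"), "accession")
    if (id %in% names(sizes))
      sizes[[id]] <- if ("MS:1000523" %in% acc) 8L else 4L
  }
  neg <- xml2::xml_find_all(doc, "//cvParam[@accession='MS:1000129']")
  pol <- if (length(neg) > 0) "negative" else "positive"

  spectra <- xml2::xml_find_all(doc, "//spectrum")
  n <- length(spectra)
  if (n == 0) stop_sddmark("imzML file contains no spectra")
  get1 <- function(node, xp) xml2::xml_attr(xml2::xml_find_first(node, xp), "value")
  con <- file(ibd_path, "rb")
  on.exit(close(con), add = TRUE)
  mz_list <- vector("list", n); int_list <- vector("list", n)
  coords <- matrix(0L, nrow = n, ncol = 2, dimnames = list(NULL, c("x", "y")))
  for (i in seq_len(n)) {
    sp <- spectra[[i]]
    coords[i, ] <- c(as.integer(get1(sp, ".//cvParam[@accession='IMS:1000050']")) - 1L,
                     as.integer(get1(sp, ".//cvParam[@accession='IMS:1000051']")) - 1L)
    arrays <- xml2::xml_find_all(sp, ".//binaryDataArray")
    for (arr in arrays) {
      ref <- xml2::xml_attr(xml2::xml_find_first(arr, "referenceableParamGroupRef"), "ref")
      len <- as.integer(get1(arr, "cvParam[@accession='IMS:1000103']"))
      off <- as.numeric(get1(arr, "cvParam[@accession='IMS:1000102']"))
      seek(con, where = off, origin = "start")
      vals <- readBin(con, "double", n = len, size = sizes[[ref]], endian = "little")
      if (ref == "mzArray") mz_list[[i]] <- vals else int_list[[i]] <- vals
    }
  }
  new_ims_dataset(mz = mz_list, intensity = int_list, coords = coords,
                  polarity = pol,
                  provenance = list(source = path))
}

#' Render a feature's ion image
#'
#' Builds the spatial intensity image of one feature column of a
#' [feature_matrix] (nearest feature within `tol_ppm` of the requested m/z)
#' and optionally writes it as a grayscale PNG scaled to the per-image
#' maximum. Pixels absent from the matrix are rendered as background (0).
#'
#' @param matrix A `feature_matrix`.
#' @param feature_mz Requested feature m/z.
#' @param path Optional PNG output path.
#' @param tol_ppm Matching tolerance in ppm (default the matrix's extraction
#'   tolerance).
#' @return Invisibly, the image as a `grid_height x grid_width` matrix.
#' @export
export_ion_image <- function(matrix, feature_mz, path = NULL,
                             tol_ppm = matrix$feature_tol_ppm) {
  stopifnot(inherits(matrix, "feature_matrix"))
  err <- abs(ppm_error(feature_mz, matrix$feature_mz))
  j <- which.min(err)
  if (err[j] > tol_ppm)
    stop_sddmark("no feature within %.1f ppm of m/z %.4f (nearest %.1f ppm away)",
                 tol_ppm, feature_mz, err[j])
  img <- matrix(0, nrow = matrix$grid_shape[2], ncol = matrix$grid_shape[1])
  img[cbind(matrix$pixel_index[, 2] + 1L, matrix$pixel_index[, 1] + 1L)] <-
    matrix$values[, j]
  if (!is.null(path)) {
    mx <- max(img)
    png::writePNG(if (mx > 0) img / mx else img, path)
  }
  invisible(img)
}

#' Read/write label masks as CSV or PNG
#'
#' CSV masks have columns `x,y,label` with 0-based coordinates and labels in
#' `{SDD, background, unlabeled}`. PNG masks use gray levels 255/128/0 for
#' SDD/background/unlabeled.
#'
#' @param mask A `label_mask` (for writing).
#' @param path File path ending in `.csv` or `.png`.
#' @return `read_label_mask()` returns a `label_mask`; `write_label_mask()`
#'   returns `path` invisibly.
#' @export
write_label_mask <- function(mask, path) {
  stopifnot(inherits(mask, "label_mask"))
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- matrix(0, nrow = nrow(mask$labels), ncol = ncol(mask$labels))
    img[mask$labels == "background"] <- 128 / 255
    img[mask$labels == "SDD"] <- 1
    png::writePNG(img, path)
  } else {
    h <- nrow(mask$labels); w <- ncol(mask$labels)
    df <- data.frame(x = rep(0:(w - 1), each = h), y = rep(0:(h - 1), times = w),
                     label = as.vector(mask$labels))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_label_mask
#' @param grid_shape `c(width, height)`; required for CSV masks that omit
#'   unlabeled pixels.
#' @export
read_label_mask <- function(path, grid_shape = NULL) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3) img <- img[, , 1]
    lab <- matrix("unlabeled", nrow = nrow(img), ncol = ncol(img))
    lab[img > 0.75] <- "SDD"
    lab[img > 0.25 & img <= 0.75] <- "background"
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    stopifnot(all(c("x", "y", "label") %in% names(df)))
    if (is.null(grid_shape)) grid_shape <- c(max(df$x) + 1L, max(df$y) + 1L)
    lab <- matrix("unlabeled", nrow = grid_shape[2], ncol = grid_shape[1])
    lab[cbind(df$y + 1L, df$x + 1L)] <- df$label
  }
  new_label_mask(lab, source = "file")
}
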