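# Minimal imzML 1.1 reader/writer (continuous and processed modes, 64-bit
# float arrays, external binary .ibd with a 16-byte UUID header). No R imzML
# package is available in this stack, so the subset of the standard the
# pipeline needs is implemented here and covered by roundtrip tests.

IMZML_ACC <- list(
  continuous = "IMS:1000030", processed = "IMS:1000031",
  uuid = "IMS:1000080", pos_x = "IMS:1000050", pos_y = "IMS:1000051",
  ext_len = "IMS:1000103", ext_enc_len = "IMS:1000104",
  ext_offset = "IMS:1000102",
  mz_array = "MS:1000514", int_array = "MS:1000515",
  neg = "MS:1000129", pos = "MS:1000130"
)

random_uuid_hex <- function() {
  paste(sprintf("%02x", sample.int(256L, 16L, replace = TRUE) - 1L),
        collapse = "")
}

#' Write an MSI dataset as an imzML/ibd pair
#'
#' Continuous mode stores the shared m/z axis once; processed mode stores one
#' m/z array per pixel (used for centroid data, for which the roundtrip is
#' lossless). Both arrays are encoded as little-endian 64-bit floats.
#' Metadata with no imzML representation (molecular class, animal id,
#' post-mortem time) is written to a `<path stem>.meta.json` sidecar.
#'
#' @param dataset an [msi_dataset()].
#' @param path output path ending in `.imzML`; the `.ibd` is written beside it.
#' @return `path`, invisibly.
#' @export
write_imzml <- function(dataset, path) {
  validate_msi_dataset(dataset)
  n <- nrow(dataset$coords)
  if (n == 0L) abort("empty pixel list", "atlasmsi_validation_error")
  continuous <- dataset$mode == "profile"
  ibd_path <- sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)
  if (identical(ibd_path, path)) ibd_path <- paste0(path, ".ibd")

  uuid <- random_uuid_hex()
  con <- tryCatch(file(ibd_path, "wb"),
                  error = function(e) abort(sprintf("cannot write %s", ibd_path),
                                            "atlasmsi_io_error"))
  writeBin(as.raw(strtoi(substring(uuid, seq(1, 31, 2), seq(2, 32, 2)), 16L)),
           con)
  offset <- 16L
  put <- function(x) {
    writeBin(as.numeric(x), con, size = 8, endian = "little")
    start <- offset
    offset <<- offset + 8L * length(x)
    c(start, length(x), 8L * length(x))  # offset, array length, encoded length
  }
  if (continuous) {
    mz_rec <- put(dataset$mz)
    int_recs <- lapply(seq_len(n), function(i) put(dataset$intensities[, i]))
    mz_recs <- rep(list(mz_rec), n)
  } else {
    mz_recs <- vector("list", n); int_recs <- vector("list", n)
    for (i in seq_len(n)) {
      mz_recs[[i]] <- put(dataset$mz[[i]])
      int_recs[[i]] <- put(dataset$intensities[[i]])
    }
  }
  close(con)

  pol_acc <- if (dataset$meta$polarity == "-") IMZML_ACC$neg else IMZML_ACC$pos
  pol_name <- if (dataset$meta$polarity == "-") "negative scan" else "positive scan"
  mode_acc <- if (continuous) IMZML_ACC$continuous else IMZML_ACC$processed
  mode_name <- if (continuous) "continuous" else "processed"

  bda <- function(group, rec) {
    paste0(
      '   <binaryDataArray encodedLength="0">\n',
      sprintf('    <referenceableParamGroupRef ref="%s"/>\n', group),
      sprintf('    <cvParam cvRef="IMS" accession="%s" name="external array length" value="%d"/>\n',
              IMZML_ACC$ext_len, rec[2]),
      sprintf('    <cvParam cvRef="IMS" accession="%s" name="external encoded length" value="%d"/>\n',
              IMZML_ACC$ext_enc_len, rec[3]),
      sprintf('    <cvParam cvRef="IMS" accession="%s" name="external offset" value="%d"/>\n',
              IMZML_ACC$ext_offset, rec[1]),
      '    <binary/>\n   </binaryDataArray>\n')
  }
  spectra <- vapply(seq_len(n), function(i) {
    paste0(
      sprintf(' <spectrum index="%d" id="spectrum=%d" defaultArrayLength="%d">\n',
              i - 1L, i, mz_recs[[i]][2]),
      sprintf('  <cvParam cvRef="MS" accession="%s" name="%s"/>\n', pol_acc, pol_name),
      '  <scanList count="1"><scan>\n',
      sprintf('   <cvParam cvRef="IMS" accession="%s" name="position x" value="%d"/>\n',
              IMZML_ACC$pos_x, dataset$coords[i, 1] + 1L),
      sprintf('   <cvParam cvRef="IMS" accession="%s" name="position y" value="%d"/>\n',
              IMZML_ACC$pos_y, dataset$coords[i, 2] + 1L),
      '  </scan></scanList>\n',
      '  <binaryDataArrayList count="2">\n',
      bda("mzArray", mz_recs[[i]]), bda("intensityArray", int_recs[[i]]),
      '  </binaryDataArrayList>\n </spectrum>\n')
  }, character(1))

  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">\n',
    '<cvList count="2">\n',
    ' <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="http://psidev.info/ms/mzML/psi-ms.obo"/>\n',
    ' <cv id="IMS" fullName="Imaging MS Ontology" URI="http://www.maldi-msi.org/download/imzml/imagingMS.obo"/>\n',
    '</cvList>\n',
    '<fileDescription><fileContent>\n',
    sprintf(' <cvParam cvRef="IMS" accession="%s" name="%s"/>\n', mode_acc, mode_name),
    sprintf(' <cvParam cvRef="IMS" accession="%s" name="universally unique identifier" value="{%s}"/>\n',
            IMZML_ACC$uuid, uuid),
    '</fileContent></fileDescription>\n',
    '<referenceableParamGroupList count="2">\n',
    ' <referenceableParamGroup id="mzArray">\n',
    sprintf('  <cvParam cvRef="MS" accession="%s" name="m/z array" unitName="m/z"/>\n', IMZML_ACC$mz_array),
    '  <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>\n',
    '  <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>\n',
    ' </referenceableParamGroup>\n',
    ' <referenceableParamGroup id="intensityArray">\n',
    sprintf('  <cvParam cvRef="MS" accession="%s" name="intensity array"/>\n', IMZML_ACC$int_array),
    '  <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>\n',
    '  <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>\n',
    ' </referenceableParamGroup>\n',
    '</referenceableParamGroupList>\n',
    '<run id="run1">\n',
    sprintf('<spectrumList count="%d">\n', n),
    paste(spectra, collapse = ""),
    '</spectrumList>\n</run>\n</mzML>\n')
  tryCatch(writeLines(xml, path, sep = ""),
           error = function(e) abort(sprintf("cannot write %s", path),
                                     "atlasmsi_io_error"))

  meta_path <- sub("\\.imzML$", ".meta.json", path, ignore.case = TRUE)
  jsonlite::write_json(dataset$meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an imzML/ibd pair
#'
#' Continuous-mode files yield a profile [msi_dataset()] on a shared m/z grid;
#' processed-mode files yield a centroid dataset. A `<stem>.meta.json`
#' sidecar, when present, supplies metadata that imzML cannot carry; otherwise
#' defaults from `sidecar` (a list) are used.
#'
#' @param path `.imzML` path; the `.ibd` is located beside it.
#' @param sidecar optional list of metadata defaults.
#' @return an [msi_dataset()].
#' @export
read_imzml <- function(path, sidecar = NULL) {
  if (!file.exists(path))
    abort(sprintf("file not found: %s", path), "atlasmsi_io_error")
  ibd_path <- sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)
  if (!file.exists(ibd_path))
    abort(sprintf("ibd file not found: %s", ibd_path), "atlasmsi_io_error")
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) abort(sprintf("corrupt imzML: %s", path),
                                            "atlasmsi_io_error"))
  xml2::xml_ns_strip(doc)

  continuous <- !is.na(xml2::xml_find_first(
    doc, sprintf("//fileContent/cvParam[@accession='%s']", IMZML_ACC$continuous)))

  spectra <- xml2::xml_find_all(doc, "//spectrum")
  if (!length(spectra)) abort("no spectra in imzML", "atlasmsi_io_error")
  grab_num <- function(acc) as.numeric(xml2::xml_attr(xml2::xml_find_first(
    spectra, sprintf(".//cvParam[@accession='%s']", acc)), "value"))
  px <- grab_num(IMZML_ACC$pos_x) - 1
  py <- grab_num(IMZML_ACC$pos_y) - 1

  pol <- vapply(spectra, function(s) {
    if (!is.na(xml2::xml_find_first(s, sprintf("./cvParam[@accession='%s']", IMZML_ACC$neg)))) "-"
    else if (!is.na(xml2::xml_find_first(s, sprintf("./cvParam[@accession='%s']", IMZML_ACC$pos)))) "+"
    else NA_character_
  }, character(1))
  pol <- unique(pol[!is.na(pol)])
  if (length(pol) > 1)
    abort("mixed polarity within one imzML file", "atlasmsi_validation_error")

  arr_info <- function(which_ref) {
    nodes <- xml2::xml_find_all(doc, sprintf(
      "//binaryDataArray[referenceableParamGroupRef/@ref='%s']", which_ref))
    get <- function(acc) as.numeric(xml2::xml_attr(xml2::xml_find_first(
      nodes, sprintf("./cvParam[@accession='%s']", acc)), "value"))
    data.frame(offset = get(IMZML_ACC$ext_offset), len = get(IMZML_ACC$ext_len))
  }
  mz_info <- arr_info("mzArray")
  int_info <- arr_info("intensityArray")
  if (nrow(mz_info) != length(spectra) || nrow(int_info) != length(spectra))
    abort("corrupt imzML: array records do not match spectra", "atlasmsi_io_error")

  con <- file(ibd_path, "rb")
  on.exit(close(con))
  read_arr <- function(offset, len) {
    seek(con, where = offset, origin = "start")
    readBin(con, what = numeric(), n = len, size = 8, endian = "little")
  }

  meta_path <- sub("\\.imzML$", ".meta.json", path, ignore.case = TRUE)
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  meta <- modifyList(as.list(sidecar %||% list()), as.list(meta))
  if (length(pol)) meta$polarity <- pol

  coords <- cbind(x = as.integer(px), y = as.integer(py))
  if (continuous) {
    mz <- read_arr(mz_info$offset[1], mz_info$len[1])
    ints <- matrix(0, nrow = length(mz), ncol = length(spectra))
    for (i in seq_along(spectra))
      ints[, i] <- read_arr(int_info$offset[i], int_info$len[i])
    msi_dataset(coords, mz, ints, meta, mode = "profile")
  } else {
    mzl <- lapply(seq_along(spectra), function(i) read_arr(mz_info$offset[i], mz_info$len[i]))
    intl <- lapply(seq_along(spectra), function(i) read_arr(int_info$offset[i], int_info$len[i]))
    msi_dataset(coords, mzl, intl, meta, mode = "centroid")
  }
}
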