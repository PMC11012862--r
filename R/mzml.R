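# Minimal mzML chromatogram I/O.
#
# No mzML library is available in this R stack, so this is a small,
# self-contained reader/writer for the chromatogramList subset of mzML 1.1:
# 64-bit little-endian float arrays, base64 encoded, optionally zlib
# compressed. It is intentionally not a general mzML implementation
# (no spectra, no indexed wrapper).

.CV <- list(
  time_array = "MS:1000595",
  intensity_array = "MS:1000515",
  float64 = "MS:1000523",
  no_compression = "MS:1000576",
  zlib = "MS:1000574",
  minute = "UO:0000031"
)

.b64_doubles <- function(x, compress) {
  raw <- writeBin(as.numeric(x), raw(), size = 8, endian = "little")
  if (compress) raw <- memCompress(raw, type = "gzip")
  jsonlite::base64_enc(raw)
}

.decode_doubles <- function(txt, compressed) {
  raw <- jsonlite::base64_dec(gsub("\\s", "", txt))
  if (compressed) raw <- memDecompress(raw, type = "gzip")
  readBin(raw, what = "numeric", n = length(raw) / 8, size = 8,
          endian = "little")
}

#' Write chromatograms to an mzML file
#'
#' Writes a chromatogram-list-only mzML 1.1 document (64-bit floats, base64,
#' optional zlib). Time is stored in minutes.
#'
#' @param chroms List of `srm_chromatogram` objects.
#' @param path Output path.
#' @param compress Use zlib compression for the binary arrays.
#' @return `path`, invisibly.
#' @export
write_mzml <- function(chroms, path, compress = FALSE) {
  comp_cv <- if (compress) .CV$zlib else .CV$no_compression
  comp_name <- if (compress) "zlib compression" else "no compression"
  chrom_xml <- vapply(seq_along(chroms), function(i) {
    ch <- chroms[[i]]
    t64 <- .b64_doubles(ch$time, compress)
    i64 <- .b64_doubles(ch$intensity, compress)
    sprintf(paste0(
      '<chromatogram index="%d" id="%s" defaultArrayLength="%d">',
      '<binaryDataArrayList count="2">',
      '<binaryDataArray encodedLength="%d">',
      '<cvParam cvRef="MS" accession="%s" name="64-bit float"/>',
      '<cvParam cvRef="MS" accession="%s" name="%s"/>',
      '<cvParam cvRef="MS" accession="%s" name="time array" unitAccession="%s" unitName="minute"/>',
      '<binary>%s</binary></binaryDataArray>',
      '<binaryDataArray encodedLength="%d">',
      '<cvParam cvRef="MS" accession="%s" name="64-bit float"/>',
      '<cvParam cvRef="MS" accession="%s" name="%s"/>',
      '<cvParam cvRef="MS" accession="%s" name="intensity array"/>',
      '<binary>%s</binary></binaryDataArray>',
      '</binaryDataArrayList></chromatogram>'),
      i - 1L, ch$id, length(ch$time),
      nchar(t64), .CV$float64, comp_cv, comp_name, .CV$time_array,
      .CV$minute, t64,
      nchar(i64), .CV$float64, comp_cv, comp_name, .CV$intensity_array, i64)
  }, "")
  doc <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
    '<run id="run1"><chromatogramList count="', length(chroms),
    '" defaultDataProcessingRef="dp1">',
    paste(chrom_xml, collapse = ""),
    '</chromatogramList></run></mzML>\n')
  writeLines(doc, path)
  invisible(path)
}

#' Read chromatograms from an mzML file
#'
#' Reads the chromatogramList of an mzML document (64-bit float arrays,
#' no compression or zlib).
#'
#' @param path mzML file path.
#' @return A list of `srm_chromatogram` objects.
#' @export
read_mzml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  nodes <- xml2::xml_find_all(doc, ".//chromatogram")
  if (length(nodes) == 0) stop("no chromatograms found in ", path)
  lapply(nodes, function(node) {
    id <- xml2::xml_attr(node, "id")
    arrays <- xml2::xml_find_all(node, ".//binaryDataArray")
    time <- NULL; intensity <- NULL
    for (arr in arrays) {
      acc <- xml2::xml_attr(xml2::xml_find_all(arr, ".//cvParam"),
                            "accession")
      compressed <- .CV$zlib %in% acc
      if (!(.CV$float64 %in% acc)) {
        stop("only 64-bit float arrays are supported")
      }
      vals <- .decode_doubles(xml2::xml_text(
        xml2::xml_find_first(arr, ".//binary")), compressed)
      if (.CV$time_array %in% acc) time <- vals
      if (.CV$intensity_array %in% acc) intensity <- vals
    }
    if (is.null(time) || is.null(intensity)) {
      stop("chromatogram '", id, "' lacks a time or intensity array")
    }
    srm_chromatogram(id, time, intensity)
  })
}
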