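# MS2 diagnostic-peak counting and stripping. Spectra are plain lists so
# the synthetic generator, the mzML reader and the tests share one shape.

#' Construct a spectrum record
#'
#' @param spectrum_id Native identifier string.
#' @param ms_level Integer MS level (1 or 2).
#' @param mz,intensity Parallel numeric peak vectors; stored sorted by m/z.
#' @param precursor_mz Precursor m/z for MS2 spectra, `NA` otherwise.
#' @return A list of class `spectrum`.
#' @export
spectrum_record <- function(spectrum_id, ms_level, mz = numeric(0),
                            intensity = numeric(0), precursor_mz = NA_real_) {
  stopifnot(length(mz) == length(intensity), all(intensity >= 0))
  o <- order(mz)
  structure(list(spectrum_id = as.character(spectrum_id),
                 ms_level = as.integer(ms_level),
                 precursor_mz = precursor_mz,
                 mz = mz[o], intensity = intensity[o]),
            class = "spectrum")
}

.in_any_window <- function(mz, windows) {
  # windows: matrix with columns low, high; closed on both ends
  if (is.null(dim(windows))) windows <- matrix(windows, ncol = 2)
  hit <- rep(FALSE, length(mz))
  for (i in seq_len(nrow(windows)))
    hit <- hit | (mz >= windows[i, 1] & mz <= windows[i, 2])
  hit
}

#' Does an MS2 spectrum carry a diagnostic remnant peak?
#'
#' A spectrum counts as diagnostic when at least one peak lies inside any
#' window and its intensity relative to the base peak is strictly greater
#' than `min_relative_intensity`.
#'
#' @param spectrum A `spectrum` record (must be MS2).
#' @param windows Two-column matrix of closed m/z windows.
#' @param min_relative_intensity Strict relative-intensity threshold.
#' @return Logical flag.
#' @export
has_diagnostic_peak <- function(spectrum, windows, min_relative_intensity = 0.1) {
  stopifnot(inherits(spectrum, "spectrum"))
  if (spectrum$ms_level != 2L) stop("has_diagnostic_peak expects an MS2 spectrum")
  if (length(spectrum$mz) == 0L) return(FALSE)
  base <- max(spectrum$intensity)
  if (base <= 0) return(FALSE)
  hit <- .in_any_window(spectrum$mz, windows)
  any(hit & (spectrum$intensity / base > min_relative_intensity))
}

#' Fraction of MS2 spectra carrying diagnostic peaks
#'
#' @param spectra List of `spectrum` records; MS1 entries are ignored.
#' @inheritParams has_diagnostic_peak
#' @return Fraction in `[0, 1]`.
#' @export
diagnostic_fraction <- function(spectra, windows, min_relative_intensity = 0.1) {
  ms2 <- Filter(function(s) s$ms_level == 2L, spectra)
  if (length(ms2) == 0L) stop("no MS2 spectra")
  mean(vapply(ms2, has_diagnostic_peak, logical(1),
              windows = windows,
              min_relative_intensity = min_relative_intensity))
}

#' Should a dataset be prefiltered before searching?
#'
#' Datasets where more than 30% of MS2 spectra carry remnant fragment
#' peaks are stripped before database searching.
#'
#' @param fraction Diagnostic fraction in `[0, 1]`.
#' @return Logical; strict `> 0.30`.
#' @export
should_prefilter <- function(fraction) {
  stopifnot(fraction >= 0, fraction <= 1)
  fraction > 0.30
}

#' Remove peaks falling in diagnostic windows
#'
#' Removal is by m/z match only (no intensity threshold); windows are
#' closed on both ends. MS1 spectra pass through unchanged, and a spectrum
#' whose every peak is removed is retained with an empty peak list.
#'
#' @param spectrum A `spectrum` record.
#' @param windows Two-column matrix of m/z windows (may have zero rows).
#' @return The filtered `spectrum`.
#' @export
strip_diagnostic_peaks <- function(spectrum, windows) {
  stopifnot(inherits(spectrum, "spectrum"))
  if (spectrum$ms_level != 2L) return(spectrum)
  if (is.null(dim(windows))) windows <- matrix(windows, ncol = 2)
  if (nrow(windows) == 0L || length(spectrum$mz) == 0L) return(spectrum)
  keep <- !.in_any_window(spectrum$mz, windows)
  spectrum$mz <- spectrum$mz[keep]
  spectrum$intensity <- spectrum$intensity[keep]
  spectrum
}

# ---- minimal mzML subset I/O -----------------------------------------------
# Only what the pipeline needs: ms level, precursor m/z and the two binary
# peak arrays (64-bit little-endian doubles, uncompressed). Written files
# round-trip through read_mzml(); foreign cvParams are not preserved.

.b64_doubles <- function(x) jsonlite::base64_enc(writeBin(as.double(x), raw(), size = 8, endian = "little"))
.doubles_b64 <- function(s) {
  if (is.na(s) || !nzchar(s)) return(numeric(0))
  raw <- jsonlite::base64_dec(s)
  readBin(raw, what = "double", n = length(raw) / 8, size = 8, endian = "little")
}

#' Write spectra to a minimal mzML file
#'
#' @param spectra List of `spectrum` records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mzml <- function(spectra, path) {
  doc <- xml2::xml_new_root("mzML",
    xmlns = "http://psi.hupo.org/ms/mzml", version = "1.1.0")
  run <- xml2::xml_add_child(doc, "run", id = "run1")
  sl <- xml2::xml_add_child(run, "spectrumList", count = as.character(length(spectra)))
  for (i in seq_along(spectra)) {
    s <- spectra[[i]]
    sp <- xml2::xml_add_child(sl, "spectrum",
      index = as.character(i - 1L), id = s$spectrum_id,
      defaultArrayLength = as.character(length(s$mz)))
    xml2::xml_add_child(sp, "cvParam", cvRef = "MS", accession = "MS:1000511",
                        name = "ms level", value = as.character(s$ms_level))
    if (s$ms_level == 2L && !is.na(s$precursor_mz)) {
      pl <- xml2::xml_add_child(sp, "precursorList", count = "1")
      pr <- xml2::xml_add_child(pl, "precursor")
      sil <- xml2::xml_add_child(pr, "selectedIonList", count = "1")
      si <- xml2::xml_add_child(sil, "selectedIon")
      xml2::xml_add_child(si, "cvParam", cvRef = "MS", accession = "MS:1000744",
                          name = "selected ion m/z", value = format(s$precursor_mz, digits = 12))
    }
    bal <- xml2::xml_add_child(sp, "binaryDataArrayList", count = "2")
    for (arr in list(c("MS:1000514", "m/z array"), c("MS:1000515", "intensity array"))) {
      ba <- xml2::xml_add_child(bal, "binaryDataArray")
      xml2::xml_add_child(ba, "cvParam", cvRef = "MS", accession = "MS:1000523",
                          name = "64-bit float", value = "")
      xml2::xml_add_child(ba, "cvParam", cvRef = "MS", accession = "MS:1000576",
                          name = "no compression", value = "")
      xml2::xml_add_child(ba, "cvParam", cvRef = "MS", accession = arr[1],
                          name = arr[2], value = "")
      vals <- if (arr[1] == "MS:1000514") s$mz else s$intensity
      xml2::xml_add_child(ba, "binary", .b64_doubles(vals))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read a (minimal) mzML file
#'
#' Parses ms level, precursor m/z and uncompressed 64-bit float peak
#' arrays; zlib-compressed arrays are decompressed with [memDecompress()].
#'
#' @param path Path to an mzML file.
#' @return List of `spectrum` records.
#' @export
read_mzml <- function(path) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "m")
  nodes <- xml2::xml_find_all(doc, ".//m:spectrum", ns)
  lapply(nodes, function(sp) {
    cv <- function(node, acc)
      xml2::xml_attr(xml2::xml_find_first(
        node, sprintf(".//m:cvParam[@accession='%s']", acc), ns), "value")
    level <- as.integer(cv(sp, "MS:1000511"))
    prec <- suppressWarnings(as.numeric(cv(sp, "MS:1000744")))
    arrays <- xml2::xml_find_all(sp, ".//m:binaryDataArray", ns)
    mz <- numeric(0); inten <- numeric(0)
    for (ba in arrays) {
      acc <- xml2::xml_attr(xml2::xml_find_all(ba, ".//m:cvParam", ns), "accession")
      b64 <- xml2::xml_text(xml2::xml_find_first(ba, ".//m:binary", ns))
      raw <- jsonlite::base64_dec(gsub("\\s", "", b64))
      if ("MS:1000574" %in% acc) raw <- memDecompress(raw, type = "gzip")
      vals <- readBin(raw, "double", n = length(raw) / 8, size = 8, endian = "little")
      if ("MS:1000514" %in% acc) mz <- vals
      if ("MS:1000515" %in% acc) inten <- vals
    }
    spectrum_record(xml2::xml_attr(sp, "id"), level, mz, inten,
                    precursor_mz = if (is.na(prec)) NA_real_ else prec)
  })
}

#' Prefilter an mzML file in place of the search engine
#'
#' Computes the pooled diagnostic fraction, and when it exceeds the 30%
#' rule strips the diagnostic windows from every MS2 spectrum.
#'
#' @param spectra List of `spectrum` records (pooled over a dataset's runs).
#' @param windows Diagnostic windows from [diagnostic_windows()].
#' @param min_relative_intensity Counting threshold.
#' @return List with `fraction`, `filtered` flag and `spectra`.
#' @export
prefilter_spectra <- function(spectra, windows, min_relative_intensity = 0.1) {
  frac <- diagnostic_fraction(spectra, windows, min_relative_intensity)
  if (should_prefilter(frac)) {
    spectra <- lapply(spectra, strip_diagnostic_peaks, windows = windows)
    list(fraction = frac, filtered = TRUE, spectra = spectra)
  } else {
    list(fraction = frac, filtered = FALSE, spectra = spectra)
  }
}
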