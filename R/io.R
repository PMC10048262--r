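#' Write / read spectra as wide CSV
#'
#' Wide format: first column `sample_id`, remaining columns one per
#' wavelength channel with the wavelength in nm (2-decimal fixed format)
#' as header. The same dialect is accepted for user-supplied instrument
#' exports.
#'
#' @param spectra a [spectrum_set()].
#' @param path CSV path.
#' @export
write_spectra <- function(spectra, path) {
  stopifnot(inherits(spectra, "spectrum_set"))
  df <- data.table::data.table(sample_id = spectra$sample_ids)
  mat <- data.table::as.data.table(spectra$intensities)
  data.table::setnames(mat, sprintf("%.2f", spectra$wavelengths))
  data.table::fwrite(cbind(df, mat), path)
  invisible(path)
}

#' @rdname write_spectra
#' @return `read_spectra` returns a [spectrum_set()].
#' @export
read_spectra <- function(path) {
  # header = TRUE: an all-numeric wavelength header defeats fread's
  # header auto-detection
  dt <- data.table::fread(path, header = TRUE)
  ids <- as.character(dt[[1]])
  wl <- as.numeric(names(dt)[-1])
  if (anyNA(wl)) stop("non-numeric wavelength headers in ", path)
  spectrum_set(wl, as.matrix(dt[, -1]), ids)
}

#' Write / read a concentration table as CSV
#'
#' Columns: `sample_id`, `group`, `variety`, then `<element>_mgkg` per
#' element.
#'
#' @param concentrations a [generate_design()] table.
#' @param path CSV path.
#' @export
write_concentrations <- function(concentrations, path) {
  data.table::fwrite(as.data.frame(concentrations), path)
  invisible(path)
}

#' @rdname write_concentrations
#' @export
read_concentrations <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  df$sample_id <- as.character(df$sample_id)
  df$group <- factor(df$group, levels = unique(df$group))
  class(df) <- c("concentration_table", "data.frame")
  df
}
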