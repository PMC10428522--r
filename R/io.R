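#' Read a spectrum from a two-column CSV file
#'
#' Expects a header `wavelength_nm,absorbance` (any second-column name is
#' accepted; the first column must be the wavelength grid).
#'
#' @param path CSV file path.
#' @param order derivative order to stamp on the result (default 0).
#' @param label label for the spectrum (default: file name).
#' @return A [new_spectrum()] object.
#' @export
read_spectrum_csv <- function(path, order = 0L, label = basename(path)) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 2L) stop("expected at least two columns", call. = FALSE)
  new_spectrum(df[[1]], df[[2]], order = order, label = label)
}

#' Read several spectra from a wide CSV file
#'
#' First column is the wavelength grid; every further column is one
#' spectrum named by its header.
#'
#' @param path CSV file path.
#' @param order derivative order stamped on every spectrum.
#' @return Named list of spectra.
#' @export
read_spectra_csv <- function(path, order = 0L) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 2L) stop("expected at least two columns", call. = FALSE)
  out <- lapply(names(df)[-1], function(nm) {
    new_spectrum(df[[1]], df[[nm]], order = order, label = nm)
  })
  names(out) <- names(df)[-1]
  out
}

#' Write a spectrum to a two-column CSV file
#'
#' Values are printed with 9 significant digits so a write/read cycle is
#' bit-comparable as text. Masked points are written as empty fields.
#'
#' @param s a spectrum.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(s, path) {
  stopifnot(is_spectrum(s))
  val <- formatC(s$value, digits = 9, format = "g")
  val[s$masked] <- ""
  lines <- c("wavelength_nm,absorbance",
             paste(formatC(s$wavelength, digits = 9, format = "g"),
                   val, sep = ","))
  writeLines(lines, path)
  invisible(path)
}
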