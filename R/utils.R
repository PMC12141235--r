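#' Round half away from zero
#'
#' Commercial rounding used at the reporting boundary: halves round up in
#' magnitude (0.0745 -> 0.075), unlike [base::round()]'s round-half-even.
#' All internal arithmetic stays at full precision; this is applied only
#' when tables are rendered.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(0.0745, 2.5), c(3, 0))
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Locate a packaged example data file
#'
#' @param file File name under the package's `extdata` directory, or `NULL`
#'   to list the available files.
#' @return A file path, or a character vector of file names.
#' @export
#' @examples
#' vegrisk_example()
#' vegrisk_example("province_capitals.csv")
vegrisk_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "vegrisk")))
  }
  system.file("extdata", file, package = "vegrisk", mustWork = TRUE)
}

# lower-case, trim and collapse internal whitespace
squish_name <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x <- gsub("\\s+", " ", x)
  x[!nzchar(x)] <- NA_character_
  x
}
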