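#' Construct a uniformly sampled 1-D spectrum
#'
#' A `spectrum1d` holds an axis (unitless x for synthetic signals, Raman shift
#' in cm^-1 for measured spectra) and an intensity vector on a strictly
#' increasing, uniformly spaced grid.  Every decomposer in the package assumes
#' uniform sampling, so the constructor validates it.
#'
#' @param axis numeric vector of axis positions, strictly increasing and
#'   uniformly spaced (relative tolerance `1e-6`), length >= 8.
#' @param intensity numeric vector of intensities, same length as `axis`.
#'   `NA`/`NaN` values are a hard error: none of the methods can impute.
#' @param label free-text label carried through decompositions and reports.
#' @return An object of class `spectrum1d` with fields `axis`, `intensity`,
#'   `label`, and the grid spacing `dx`.
#' @examples
#' s <- spectrum1d(seq(0, 1, length.out = 16), rnorm(16))
#' s$dx
#' @export
spectrum1d <- function(axis, intensity, label = "") {
  axis <- as.numeric(axis)
  intensity <- as.numeric(intensity)
  if (length(axis) != length(intensity))
    stop_validation("axis and intensity differ in length (",
                    length(axis), " vs ", length(intensity), ")")
  if (length(axis) < 8L)
    stop_validation("spectrum needs at least 8 points, got ", length(axis))
  if (anyNA(axis) || any(!is.finite(axis)))
    stop_validation("axis contains NA/NaN/Inf values")
  if (anyNA(intensity) || any(!is.finite(intensity)))
    stop_validation("intensity contains NA/NaN/Inf values")
  d <- diff(axis)
  if (any(d <= 0))
    stop_validation("axis must be strictly increasing")
  dx <- mean(d)
  if (max(abs(d - dx)) > 1e-6 * abs(dx))
    stop_validation("axis spacing is non-uniform beyond relative tolerance 1e-6")
  structure(
    list(axis = axis, intensity = intensity, label = as.character(label)[1],
         dx = dx),
    class = "spectrum1d"
  )
}

#' @export
print.spectrum1d <- function(x, ...) {
  cat(sprintf("<spectrum1d> %d points, axis [%g, %g], dx = %g%s\n",
              length(x$axis), x$axis[1], x$axis[length(x$axis)], x$dx,
              if (nzchar(x$label)) paste0(", label: ", x$label) else ""))
  invisible(x)
}

#' @export
length.spectrum1d <- function(x) length(x$axis)

is_spectrum1d <- function(x) inherits(x, "spectrum1d")

#' Read a two-column spectrum from delimited text
#'
#' Column 1 is the axis, column 2 the intensity.  Files written with a
#' descending axis (common in Raman exports) are silently reversed to the
#' ascending convention, with a log message.
#'
#' @param path file path.
#' @param delimiter field separator; `","` (default) or `"\t"` etc.
#' @param skip_header skip one leading non-numeric header line.
#' @param label optional label; defaults to the file name.
#' @return a [spectrum1d].
#' @export
read_spectrum <- function(path, delimiter = ",", skip_header = FALSE,
                          label = NULL) {
  if (!file.exists(path)) stop_io("cannot read spectrum: no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  first <- if (skip_header) 2L else 1L
  if (length(lines) < first) stop_validation("file has no data rows: ", path)
  rows <- strsplit(trimws(lines[first:length(lines)]), delimiter, fixed = TRUE)
  ncols <- vapply(rows, length, 1L)
  if (any(ncols < 2L))
    stop_validation("line ", which(ncols < 2L)[1] + first - 1L,
                    " has fewer than 2 columns")
  ax <- suppressWarnings(as.numeric(vapply(rows, `[[`, "", 1L)))
  iy <- suppressWarnings(as.numeric(vapply(rows, `[[`, "", 2L)))
  bad <- which(is.na(ax) | is.na(iy))
  if (length(bad))
    stop_validation("non-numeric value on line ", bad[1] + first - 1L,
                    " of ", path)
  if (length(ax) >= 2L && ax[1] > ax[length(ax)]) {
    message("read_spectrum: descending axis in ", path, "; reversing")
    ax <- rev(ax)
    iy <- rev(iy)
  }
  spectrum1d(ax, iy, label = if (is.null(label)) basename(path) else label)
}

#' Write a spectrum as two-column CSV
#'
#' Values are written with 12 significant digits so read/write round-trips
#' are lossless to well below 1e-10 relative error.
#'
#' @param x a [spectrum1d].
#' @param path output file path.
#' @param delimiter field separator.
#' @param header write an `axis,intensity` header line.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(x, path, delimiter = ",", header = TRUE) {
  stopifnot(is_spectrum1d(x))
  out <- paste(sprintf("%.12g", x$axis), sprintf("%.12g", x$intensity),
               sep = delimiter)
  if (header) out <- c(paste("axis", "intensity", sep = delimiter), out)
  ok <- tryCatch({ writeLines(out, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_io("cannot write spectrum to ", path)
  invisible(path)
}
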