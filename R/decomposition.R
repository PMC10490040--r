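#' Construct a decomposition of a spectrum into modes
#'
#' Container shared by the two decomposers.  `vmd` decompositions carry one
#' center frequency per mode (cycles/sample, ascending); `emd` decompositions
#' carry a residual trend instead.
#'
#' @param method `"vmd"` or `"emd"`.
#' @param modes numeric matrix, one column per mode, `source_len` rows.  For
#'   VMD columns are `u1..uK` (ascending center frequency); for EMD columns
#'   are `imf1..imfK` (descending oscillation frequency).
#' @param center_freq numeric vector of per-mode center frequencies in
#'   cycles/sample, each in `[0, 0.5]`, ascending (VMD only).
#' @param residual numeric residual vector (EMD only).
#' @param dx grid spacing of the source spectrum, used to convert frequencies
#'   to cycles per axis unit.
#' @param params list of solver parameters, carried for provenance.
#' @return object of class `decomposition`.
#' @export
decomposition <- function(method, modes, center_freq = NULL, residual = NULL,
                          dx = 1, params = list()) {
  method <- match.arg(method, c("vmd", "emd"))
  modes <- as.matrix(modes)
  source_len <- nrow(modes)
  if (method == "vmd") {
    if (is.null(center_freq) || length(center_freq) != ncol(modes))
      stop_validation("vmd decomposition needs one center frequency per mode")
    if (any(center_freq < -1e-12 | center_freq > 0.5 + 1e-12))
      stop_validation("center frequencies must lie in [0, 0.5] cycles/sample")
    if (is.unsorted(center_freq))
      stop_validation("center frequencies must be ascending")
    center_freq <- pmin(pmax(center_freq, 0), 0.5)
    residual <- NULL
  } else {
    if (is.null(residual) || length(residual) != source_len)
      stop_validation("emd decomposition needs a residual of source length")
    center_freq <- NULL
  }
  structure(
    list(method = method, modes = modes, center_freq = center_freq,
         residual = residual, source_len = source_len, dx = dx,
         params = params),
    class = "decomposition"
  )
}

#' @export
print.decomposition <- function(x, ...) {
  cat(sprintf("<decomposition> method %s, %d mode(s), %d samples\n",
              x$method, ncol(x$modes), x$source_len))
  if (x$method == "vmd")
    cat("  center freq (cycles/sample):",
        paste(signif(x$center_freq, 4), collapse = ", "), "\n")
  else
    cat("  + residual\n")
  invisible(x)
}

n_modes <- function(d) ncol(d$modes)

mode_colnames <- function(d) {
  if (d$method == "vmd") paste0("u", seq_len(n_modes(d)))
  else paste0("imf", seq_len(n_modes(d)))
}

#' Write a decomposition to CSV plus a JSON sidecar
#'
#' The CSV holds one column per mode (`u1..uK` or `imf1..imfK`, plus
#' `residual` for EMD).  The sidecar `<path>.json` stores method, center
#' frequencies, grid spacing, source length and solver parameters.  Values are
#' written with 12 significant digits and round-trip through
#' [read_decomposition()] to better than 1e-10.
#'
#' @param d a [decomposition].
#' @param path output CSV path; the sidecar goes to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_decomposition <- function(d, path) {
  stopifnot(inherits(d, "decomposition"))
  m <- d$modes
  cols <- mode_colnames(d)
  if (d$method == "emd") {
    m <- cbind(m, d$residual)
    cols <- c(cols, "residual")
  }
  lines <- c(paste(cols, collapse = ","),
             apply(m, 1L, function(r) paste(sprintf("%.12g", r), collapse = ",")))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop_io("cannot write decomposition to ", path)
  sidecar <- list(method = d$method, center_freq = d$center_freq,
                  params = d$params, source_len = d$source_len, dx = d$dx)
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a decomposition written by [write_decomposition()]
#'
#' @param path CSV path; the sidecar is read from `paste0(path, ".json")`.
#' @return a [decomposition].
#' @export
read_decomposition <- function(path) {
  if (!file.exists(path)) stop_io("no such file: ", path)
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path)) stop_io("missing sidecar: ", side_path)
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  tab <- utils::read.csv(path, check.names = FALSE)
  if (identical(side$method, "emd")) {
    res <- tab[["residual"]]
    modes <- as.matrix(tab[, setdiff(names(tab), "residual"), drop = FALSE])
    decomposition("emd", modes, residual = res, dx = side$dx,
                  params = as.list(side$params))
  } else {
    decomposition("vmd", as.matrix(tab), center_freq = side$center_freq,
                  dx = side$dx, params = as.list(side$params))
  }
}

#' Bundle a denoised spectrum with its mode bookkeeping
#'
#' @param denoised a [spectrum1d].
#' @param kept,removed 1-based mode indices kept/removed (empty for the
#'   direct filters).  Together they must partition `1..K` disjointly.
#' @param snr_db Eq.-style SNR in dB versus a clean reference, or `NULL` when
#'   no reference exists (measured spectra).
#' @param method method name.
#' @param params parameter list used.
#' @param diagnostics named list of extra diagnostics (e.g. first-difference
#'   energy for real spectra).
#' @return object of class `denoise_result`.
#' @export
denoise_result <- function(denoised, kept = integer(), removed = integer(),
                           snr_db = NULL, method = "", params = list(),
                           diagnostics = list()) {
  stopifnot(is_spectrum1d(denoised))
  kept <- as.integer(kept); removed <- as.integer(removed)
  if (length(kept) || length(removed)) {
    k <- length(kept) + length(removed)
    if (length(intersect(kept, removed)))
      stop_validation("kept and removed mode sets overlap")
    if (!setequal(union(kept, removed), seq_len(k)))
      stop_validation("kept and removed must partition 1..K")
  }
  structure(
    list(denoised = denoised, kept = kept, removed = removed,
         snr_db = snr_db, method = method, params = params,
         diagnostics = diagnostics),
    class = "denoise_result"
  )
}

#' @export
print.denoise_result <- function(x, ...) {
  cat(sprintf("<denoise_result> method %s%s%s\n", x$method,
              if (length(x$kept)) paste0(", kept modes {",
                                         paste(x$kept, collapse = ","), "}")
              else "",
              if (!is.null(x$snr_db)) sprintf(", SNR %.2f dB", x$snr_db)
              else ""))
  invisible(x)
}
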