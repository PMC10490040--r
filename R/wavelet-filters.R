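## Orthogonal wavelet filter banks.  Scaling (lowpass decomposition) filters
## are the published Daubechies/Symlet coefficients; the other three filters
## follow from the quadrature-mirror relations
##   rec_lo = rev(dec_lo),  dec_hi = (-1)^k * rec_lo,  rec_hi = rev(dec_hi).

.wavelet_dec_lo <- list(
  haar = c(0.70710678118654757, 0.70710678118654757),
  db2 = c(-0.12940952255126037, 0.22414386804201339,
          0.83651630373780794, 0.48296291314453416),
  db4 = c(-0.010597401785069032, 0.032883011666885197, 0.030841381835560764,
          -0.18703481171909309, -0.027983769416859854, 0.63088076792985892,
          0.71484657055291567, 0.23037781330889651),
  sym4 = c(-0.075765714789273325, -0.02963552764599851, 0.49761866763201545,
           0.80373875180591614, 0.29785779560527736, -0.099219543576847216,
           -0.012603967262037833, 0.032223100604042702),
  sym8 = c(-0.0033824159510061256, -0.00054213233179114812,
           0.031695087811492981, 0.0076074873249176054,
           -0.14329423835080971, -0.061273359067658524,
           0.48135965125837221, 0.77718575170052351,
           0.3644418948353314, -0.051945838107709037,
           -0.027219029917056003, 0.049137179673607506,
           0.0038087520138906151, -0.014952258337048231,
           -0.0003029205147213668, 0.0018899503327594609)
)

#' Names of the available discrete wavelets
#' @return character vector.
#' @export
wavelet_names <- function() names(.wavelet_dec_lo)

wavelet_filters <- function(wavelet) {
  dec_lo <- .wavelet_dec_lo[[wavelet]]
  if (is.null(dec_lo))
    stop_validation("unknown wavelet '", wavelet, "'; available: ",
                    paste(wavelet_names(), collapse = ", "))
  rec_lo <- rev(dec_lo)
  dec_hi <- rec_lo * (-1)^seq_along(rec_lo)
  list(dec_lo = dec_lo, dec_hi = dec_hi,
       rec_lo = rec_lo, rec_hi = rev(dec_hi), len = length(dec_lo))
}
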