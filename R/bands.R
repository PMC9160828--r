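#' Canonical EEG frequency bands
#'
#' The five-band partition used throughout the pipeline: delta 0.5-4 Hz,
#' theta 4-7 Hz, alpha 7.5-13 Hz, beta 15-28 Hz, gamma 29-48 Hz. The gaps
#' between the printed band edges (7-7.5, 13-15, 28-29 Hz and everything
#' above 48 Hz) belong to no band and are excluded from every band-limited
#' quantity.
#'
#' @return data.frame with columns `name`, `f_low`, `f_high`
#' @export
#' @examples
#' eeg_bands()
eeg_bands <- function() {
  data.frame(
    name = c("delta", "theta", "alpha", "beta", "gamma"),
    f_low = c(0.5, 4, 7.5, 15, 29),
    f_high = c(4, 7, 13, 28, 48),
    stringsAsFactors = FALSE
  )
}

#' Define a single frequency band
#'
#' @param name band name
#' @param f_low lower edge in Hz, must be > 0
#' @param f_high upper edge in Hz, must exceed `f_low`
#' @return one-row data.frame compatible with [eeg_bands()]
#' @export
band_definition <- function(name, f_low, f_high) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!(f_low > 0 && f_high > f_low)) {
    stop("band edges must satisfy 0 < f_low < f_high", call. = FALSE)
  }
  data.frame(name = name, f_low = f_low, f_high = f_high,
             stringsAsFactors = FALSE)
}

# Resolve a band table against requested names, with a clear error for
# unknown bands.
match_bands <- function(bands, names_wanted) {
  if (is.null(names_wanted)) return(bands)
  missing <- setdiff(names_wanted, bands$name)
  if (length(missing) > 0) {
    stop("unknown band(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  bands[bands$name %in% names_wanted, , drop = FALSE]
}
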