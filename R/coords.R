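#' Coordinate-frame conversions
#'
#' All in-memory objects in this package use 1-based inclusive coordinates
#' (the VCF/GFF3 frame). bedGraph and BEDPE files use 0-based half-open
#' intervals; these helpers own every transform between the two frames so the
#' convention lives in exactly one place.
#'
#' @param start1,end1 1-based inclusive interval bounds.
#' @param start0,end0 0-based half-open interval bounds.
#' @name coords
NULL

#' @rdname coords
#' @return `to_zero_based()` returns a list with `start0` and `end0`.
#' @export
to_zero_based <- function(start1, end1) {
  list(start0 = as.integer(start1) - 1L, end0 = as.integer(end1))
}

#' @rdname coords
#' @return `to_one_based()` returns a list with `start1` and `end1`.
#' @export
to_one_based <- function(start0, end0) {
  list(start1 = as.integer(start0) + 1L, end1 = as.integer(end0))
}
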