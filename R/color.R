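# Colorimetry: mean CIELab per grain and the yellowness index.

#' Mean CIELab color of one grain
#'
#' Converts the grain's pixels from sRGB (D65, 2 degree observer) to CIELab
#' and averages L, a, b over the grain mask.
#'
#' @param image Height x width x 3 array in \[0,1\].
#' @param labels Integer label matrix aligned with `image`.
#' @param grain_id Label of the grain.
#' @return Named numeric vector `c(L, a, b)`.
#' @export
grain_color <- function(image, labels, grain_id) {
  px <- which(labels == grain_id)
  if (length(px) == 0) stop("grain_id ", grain_id, " not found in labels")
  npix <- prod(dim(image)[1:2])
  rgb <- cbind(image[px], image[px + npix], image[px + 2 * npix])
  lab <- grDevices::convertColor(rgb, from = "sRGB", to = "Lab")
  c(L = mean(lab[, 1]), a = mean(lab[, 2]), b = mean(lab[, 3]))
}

#' Yellowness index
#'
#' `YI = 142.86 * b / L`: the CIELab yellowness formula used for film and
#' grain surfaces; positive for yellow-cast, negative for blue-cast
#' surfaces.
#'
#' @param L CIELab lightness, > 0.
#' @param b CIELab yellow-blue coordinate.
#' @return Numeric vector of yellowness indices.
#' @export
yellowness_index <- function(L, b) {
  if (any(L <= 0)) stop("yellowness index undefined for L <= 0")
  142.86 * b / L
}
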