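#' Contrast adjustment by quantile stretching
#'
#' Linearly rescales intensities so that the `lowFraction` quantile maps to
#' 0 and the `1 - highFraction` quantile maps to the top of the
#' representable range, clipping outside. This concentrates the display
#' range on the dominant middle portion of the histogram, saturating the
#' extreme tails.
#'
#' @param img integer intensity matrix.
#' @param lowFraction,highFraction saturated tail fractions; must satisfy
#'   `0 <= lowFraction < 1 - highFraction <= 1`.
#' @param bitDepth pixel bit depth of the image (default 16).
#' @return rescaled integer matrix of the same dimensions. A constant image
#'   (both quantiles equal) is returned unchanged.
#' @export
#' @examples
#' ramp <- matrix(round(seq(0, 65535, length.out = 64)), 8, 8)
#' range(adjustContrast(ramp, 0.05, 0.05))
adjustContrast <- function(img, lowFraction = 0.01, highFraction = 0.01,
                           bitDepth = 16L) {
  stopifnot(is.matrix(img))
  if (lowFraction < 0 || highFraction < 0 ||
      lowFraction >= 1 - highFraction)
    stop("need 0 <= lowFraction < 1 - highFraction <= 1")
  maxv <- 2^bitDepth - 1
  q <- quantile(img, c(lowFraction, 1 - highFraction), names = FALSE)
  if (q[1] == q[2]) return(img)
  out <- (img - q[1]) / (q[2] - q[1]) * maxv
  out <- matrix(pmin(pmax(round(out), 0), maxv), nrow(img), ncol(img))
  storage.mode(out) <- storage.mode(img)
  out
}

#' Unsharp-mask sharpening
#'
#' Adds `amount` times the difference between the image and its Gaussian
#' blur: `clip(img + amount * (img - blur(img, radius)))`. Arithmetic is in
#' floating point; the result is rounded and clipped back to the integer
#' range.
#'
#' @param img integer intensity matrix.
#' @param radius Gaussian sigma of the blur, in pixels (> 0).
#' @param amount strength of the high-frequency boost (>= 0); 0 returns the
#'   input.
#' @param bitDepth pixel bit depth (default 16).
#' @return sharpened integer matrix of the same dimensions.
#' @export
sharpen <- function(img, radius = 1.5, amount = 0.8, bitDepth = 16L) {
  stopifnot(is.matrix(img), radius > 0, amount >= 0)
  if (amount == 0) return(img)
  maxv <- 2^bitDepth - 1
  blur <- as.matrix(EBImage::gblur(img, sigma = radius))
  out <- img + amount * (img - blur)
  out <- matrix(pmin(pmax(round(out), 0), maxv), nrow(img), ncol(img))
  storage.mode(out) <- storage.mode(img)
  out
}

#' Standard preprocessing stage
#'
#' Contrast adjustment followed by unsharp sharpening, the enhancement
#' applied to every image before segmentation.
#'
#' @param img integer intensity matrix.
#' @param lowFraction,highFraction see [adjustContrast()].
#' @param radius,amount see [sharpen()].
#' @param bitDepth pixel bit depth.
#' @return preprocessed integer matrix.
#' @export
preprocessImage <- function(img, lowFraction = 0.01, highFraction = 0.01,
                            radius = 1.5, amount = 0.8, bitDepth = 16L) {
  sharpen(adjustContrast(img, lowFraction, highFraction, bitDepth),
          radius = radius, amount = amount, bitDepth = bitDepth)
}
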