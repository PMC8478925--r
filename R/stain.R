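# Color deconvolution between RGB and the HED stain space.
#
# Under Beer-Lambert absorption a pixel's optical density is a non-negative
# linear mix of the stain OD vectors: OD = conc %*% M, with M the 3x3 stain
# basis. Deconvolution inverts that mix; the forward model renders it.

#' Deconvolve an RGB image into HED stain concentrations
#'
#' Converts each pixel to optical density, `OD_c = -log10((v_c + eps)/255)`,
#' and unmixes it through the inverse stain matrix. `eps` keeps the log
#' finite at pixel value 0 (at the cost of a small bias in very dark
#' pixels); optical densities below zero (pixels brighter than the blank,
#' unphysical) are treated as zero, and negative unmixed concentrations,
#' which arise from quantization noise, are clamped to 0.
#'
#' @param image `H x W x 3` numeric array, values in `[0, 255]`.
#' @param basis a [StainBasis-class]; defaults to the Ruifrok-Johnston
#'   H/E/DAB vectors.
#' @param eps positive offset added to pixel values inside the log.
#' @return `H x W x 3` numeric array of concentrations, channels ordered
#'   H, E, DAB (OD units).
#' @examples
#' img <- array(255, c(2, 2, 3))           # pure white
#' max(rgbToStain(img))                    # zero optical density
#' @export
rgbToStain <- function(image, basis = stainBasis(), eps = 1) {
  assertRGBImage(image)
  stopifnot(is(basis, "StainBasis"), eps > 0)
  m <- stainMatrix(basis)
  minv <- tryCatch(solve(m),
                   error = function(e) stop("singular stain basis",
                                            call. = FALSE))
  d <- dim(image)
  od <- -log10((matrix(image, ncol = 3L) + eps) / 255)
  od[od < 0] <- 0
  conc <- od %*% minv
  conc[conc < 0] <- 0
  array(conc, d)
}

#' Render stain concentrations into an RGB image (Beer-Lambert forward model)
#'
#' `v_c = round(255 * 10^(-(conc . basis)_c))`, clamped to `[0, 255]`. This
#' is the forward model behind the synthetic phantoms and the reference for
#' the differentiable HED loss.
#'
#' @param conc `H x W x 3` numeric array of non-negative concentrations
#'   (channels H, E, DAB).
#' @param basis a [StainBasis-class].
#' @return `H x W x 3` numeric array on the 0-255 scale.
#' @export
stainToRgb <- function(conc, basis = stainBasis()) {
  if (!is.array(conc) || length(dim(conc)) != 3L || dim(conc)[3] != 3L)
    stop("conc must be an H x W x 3 array", call. = FALSE)
  if (anyNA(conc) || min(conc) < 0)
    stop("concentrations must be finite and >= 0", call. = FALSE)
  stopifnot(is(basis, "StainBasis"))
  od <- matrix(conc, ncol = 3L) %*% stainMatrix(basis)
  v <- clamp(round(255 * 10^(-od)), 0, 255)
  array(v, dim(conc))
}

#' Extract one stain channel as an 8-bit raster
#'
#' Maps concentration linearly onto 0-255, saturating at `cMax`:
#' `value = round(255 * min(conc/cMax, 1))`. Higher value means more stain.
#' With the default `cMax = 1` the conventional DAB threshold of 80
#' corresponds to a concentration of about 0.314 OD.
#'
#' @param conc `H x W x 3` concentration array from [rgbToStain()].
#' @param channel `"H"`, `"E"` or `"DAB"`.
#' @param cMax concentration mapped to 255; must be positive.
#' @return `H x W` numeric matrix of 8-bit values.
#' @export
stainChannel8bit <- function(conc, channel = c("H", "E", "DAB"), cMax = 1) {
  channel <- match.arg(channel)
  stopifnot(cMax > 0)
  if (!is.array(conc) || length(dim(conc)) != 3L || dim(conc)[3] != 3L)
    stop("conc must be an H x W x 3 array", call. = FALSE)
  k <- match(channel, c("H", "E", "DAB"))
  matrix(round(255 * pmin(conc[, , k] / cMax, 1)),
         dim(conc)[1], dim(conc)[2])
}

#' Extract a stain channel straight from an RGB raster
#'
#' Convenience wrapper: deconvolve then map one channel to 8 bits. The
#' eosin channel of an H&E image and the DAB channel of a CK image are the
#' substrates of registration and of the tumor mask.
#'
#' @inheritParams rgbToStain
#' @inheritParams stainChannel8bit
#' @return `H x W` numeric matrix of 8-bit values.
#' @export
extractStainChannel <- function(image, channel = c("H", "E", "DAB"),
                                basis = stainBasis(), cMax = 1, eps = 1) {
  stainChannel8bit(rgbToStain(image, basis, eps), match.arg(channel), cMax)
}
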