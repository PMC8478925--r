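# shared low-level helpers: image validation, grayscale, translation,
# downsampling, seeded evaluation

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @noRd
assertRGBImage <- function(img, what = "image") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop(what, " must be an H x W x 3 array", call. = FALSE)
  if (dim(img)[1] < 1L || dim(img)[2] < 1L)
    stop(what, " must be non-empty", call. = FALSE)
  if (anyNA(img) || min(img) < 0 || max(img) > 255)
    stop(what, " values must lie in [0, 255]", call. = FALSE)
  invisible(img)
}

#' Convert an RGB raster to 8-bit grayscale (ITU-R 601 luma)
#'
#' `gray = round(0.299 R + 0.587 G + 0.114 B)`, the luma convention used by
#' both the white-background patch filter and the tissue mask.
#'
#' @param img `H x W x 3` numeric array on the 0-255 scale.
#' @return `H x W` numeric matrix of rounded luma values in `[0, 255]`.
#' @export
rgbToGray <- function(img) {
  assertRGBImage(img)
  round(0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3])
}

#' Translate an image by an integer pixel shift
#'
#' Positive `drow`/`dcol` move content down/right; exposed margins are filled
#' with `fill` (white by default, the background of a brightfield scan).
#'
#' @param img `H x W x 3` array or `H x W` matrix.
#' @param drow,dcol integer shift in pixels.
#' @param fill fill value for exposed margins.
#' @return translated image of identical shape.
#' @export
translateImage <- function(img, drow, dcol, fill = 255) {
  drow <- as.integer(round(drow)); dcol <- as.integer(round(dcol))
  d <- dim(img)
  h <- d[1]; w <- d[2]
  out <- if (length(d) == 3L) array(fill, d) else matrix(fill, h, w)
  if (abs(drow) >= h || abs(dcol) >= w) return(out)
  srcR <- seq_len(h - abs(drow)) + max(0L, -drow)
  srcC <- seq_len(w - abs(dcol)) + max(0L, -dcol)
  dstR <- srcR + drow
  dstC <- srcC + dcol
  if (length(d) == 3L) out[dstR, dstC, ] <- img[srcR, srcC, ]
  else out[dstR, dstC] <- img[srcR, srcC]
  out
}

#' Downsample an image by block averaging
#'
#' Averages `factor x factor` blocks (trailing rows/columns that do not fill
#' a block are dropped), the resampling used before global shift estimation.
#'
#' @param img `H x W x 3` array or `H x W` matrix.
#' @param factor integer downsampling factor, >= 1.
#' @return downsampled image, same type as input.
#' @export
downsampleImage <- function(img, factor) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1L)
  if (factor == 1L) return(img)
  d <- dim(img)
  hf <- d[1] %/% factor; wf <- d[2] %/% factor
  if (hf < 1L || wf < 1L)
    stop("image smaller than one downsampling block", call. = FALSE)
  ds1 <- function(m) {
    m <- m[seq_len(hf * factor), seq_len(wf * factor), drop = FALSE]
    # average rows within blocks, then columns
    m <- array(m, c(factor, hf, wf * factor))
    m <- colMeans(m)                      # hf x (wf*factor)
    m <- array(t(m), c(factor, wf, hf))
    t(colMeans(m))                        # hf x wf
  }
  if (length(d) == 3L) {
    out <- array(0, c(hf, wf, d[3]))
    for (k in seq_len(d[3])) out[, , k] <- ds1(img[, , k])
    out
  } else ds1(img)
}

# run code under a fixed seed without disturbing the caller's RNG stream
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# round half away from zero to `digits` decimals (table formatting convention)
roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Read an RGB raster from PNG or TIFF
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @return `H x W x 3` numeric array on the 0-255 scale.
#' @export
readRaster <- function(path) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported raster format: ", ext, call. = FALSE))
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), c(dim(px), 3L))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]
  round(px * 255)
}

#' Write an RGB raster to PNG or TIFF
#'
#' @param img `H x W x 3` numeric array on the 0-255 scale.
#' @param path destination path ending in .png, .tif or .tiff.
#' @return `path`, invisibly.
#' @export
writeRaster <- function(img, path) {
  assertRGBImage(img)
  ext <- tolower(tools::file_ext(path))
  px <- clamp(img, 0, 255) / 255
  switch(ext,
    png = png::writePNG(px, path),
    tif = ,
    tiff = tiff::writeTIFF(px, path, bits.per.sample = 8L),
    stop("unsupported raster format: ", ext, call. = FALSE))
  invisible(path)
}
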