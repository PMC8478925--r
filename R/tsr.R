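# dTSR scoring: binarize tissue from H&E and tumor from (virtual) CK,
# derive stroma as tissue minus tumor, and apply
# dTSR = 100 * stroma / (tumor + stroma), averaged over hotspots.

#' Tissue mask from an H&E image
#'
#' Tissue is every pixel whose grayscale (ITU-R 601 luma) value is
#' strictly below 200; the bright background of a brightfield scan is
#' excluded.
#'
#' @param heImage `H x W x 3` RGB array.
#' @param threshold grayscale threshold (default 200).
#' @return logical `H x W` mask.
#' @export
tissueMask <- function(heImage, threshold = 200) {
  rgbToGray(heImage) < threshold
}

#' Tumor mask from a (virtual) CK image
#'
#' Tumor is every pixel whose 8-bit DAB channel, obtained by color
#' deconvolution, is strictly above 80: CK-IHC marks epithelial tumor
#' cells with the DAB chromogen.
#'
#' @param ckImage `H x W x 3` RGB array.
#' @param threshold 8-bit DAB threshold (default 80).
#' @param basis stain basis for deconvolution.
#' @param cMax,eps see [extractStainChannel()].
#' @return logical `H x W` mask.
#' @export
tumorMask <- function(ckImage, threshold = 80, basis = stainBasis(),
                      cMax = 1, eps = 1) {
  extractStainChannel(ckImage, "DAB", basis, cMax, eps) > threshold
}

#' Build the tissue/tumor/stroma mask set
#'
#' Tumor is restricted to tissue so that areas are conserved:
#' `stroma = tissue AND NOT tumor`, hence
#' `|tumor| + |stroma| = |tissue|`.
#'
#' @param tissue,tumor logical masks of identical shape.
#' @return list with logical masks `tissue`, `tumor`, `stroma`.
#' @export
maskSet <- function(tissue, tumor) {
  if (!identical(dim(tissue), dim(tumor)))
    stop("masks must have identical shape", call. = FALSE)
  tumorIn <- tumor & tissue
  list(tissue = tissue, tumor = tumorIn, stroma = tissue & !tumorIn)
}

#' Compute the dTSR of one H&E / virtual-CK image pair
#'
#' `dTSR = 100 * stroma_area / (tumor_area + stroma_area)`, with the
#' tumor area counted inside tissue only, so the denominator equals the
#' tissue area.
#'
#' @param heImage,ckImage equal-shape RGB arrays.
#' @param tissueThreshold,dabThreshold binarization thresholds.
#' @param basis,cMax,eps deconvolution settings for the tumor mask.
#' @return list: `dtsr` (percent), `tumor_area`, `stroma_area`,
#'   `tissue_area` (pixels).
#' @export
computeDTSR <- function(heImage, ckImage, tissueThreshold = 200,
                        dabThreshold = 80, basis = stainBasis(),
                        cMax = 1, eps = 1) {
  if (!identical(dim(heImage), dim(ckImage)))
    stop("images must have identical shape", call. = FALSE)
  ms <- maskSet(tissueMask(heImage, tissueThreshold),
                tumorMask(ckImage, dabThreshold, basis, cMax, eps))
  tumorA <- sum(ms$tumor); stromaA <- sum(ms$stroma)
  if (tumorA + stromaA == 0)
    stop("undefined score: no tissue in image", call. = FALSE)
  list(dtsr = 100 * stromaA / (tumorA + stromaA),
       tumor_area = tumorA, stroma_area = stromaA,
       tissue_area = tumorA + stromaA)
}

#' Rasterize a polygon onto a pixel grid
#'
#' Even-odd fill over pixel centers at integer 0-based `(row, col)`
#' coordinates; pixels whose center lies on a polygon edge are included.
#'
#' @param polygon numeric matrix, one vertex per row as `(row, col)`,
#'   at least 3 vertices.
#' @param nrow,ncol extent of the target grid.
#' @param originRow,originCol 0-based grid origin in polygon coordinates.
#' @return logical `nrow x ncol` mask.
#' @export
rasterizePolygon <- function(polygon, nrow, ncol,
                             originRow = 0, originCol = 0) {
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3L)
    stop("polygon needs at least 3 vertices", call. = FALSE)
  pr <- polygon[, 1] - originRow
  pc <- polygon[, 2] - originCol
  n <- length(pr)
  nxt <- c(2:n, 1)
  rows <- 0:(nrow - 1)
  mask <- matrix(FALSE, nrow, ncol)
  cols0 <- 0:(ncol - 1)
  for (e in seq_len(n)) {
    r1 <- pr[e]; c1 <- pc[e]; r2 <- pr[nxt[e]]; c2 <- pc[nxt[e]]
    if (r1 == r2) next                      # horizontal edge: no crossing
    # half-open rule in the row direction
    lo <- pmin(r1, r2); hi <- pmax(r1, r2)
    hit <- rows >= lo & rows < hi
    if (!any(hit)) next
    xc <- c1 + (rows[hit] - r1) * (c2 - c1) / (r2 - r1)
    for (idx in seq_along(xc)) {
      ri <- which(hit)[idx]
      cross <- cols0 < xc[idx]
      mask[ri, ] <- xor(mask[ri, ], cross)
    }
  }
  # include boundary pixels (centers exactly on an edge can be missed by
  # the half-open crossing rule): sample edges densely
  for (e in seq_len(n)) {
    r1 <- pr[e]; c1 <- pc[e]; r2 <- pr[nxt[e]]; c2 <- pc[nxt[e]]
    len <- max(abs(r2 - r1), abs(c2 - c1))
    t <- seq(0, 1, length.out = max(2L, ceiling(len * 4) + 1L))
    rr <- round(r1 + t * (r2 - r1)); cc <- round(c1 + t * (c2 - c1))
    keep <- rr >= 0 & rr < nrow & cc >= 0 & cc < ncol &
      abs(r1 + t * (r2 - r1) - rr) < 1e-9 &
      abs(c1 + t * (c2 - c1) - cc) < 1e-9
    mask[cbind(rr[keep] + 1, cc[keep] + 1)] <- TRUE
  }
  mask
}

#' Validate a hotspot annotation
#'
#' @param hotspots list of polygons; each a numeric matrix of 0-based
#'   level-0 `(row, col)` vertices, >= 3 rows.
#' @return the validated list, invisibly.
#' @export
validateHotspots <- function(hotspots) {
  if (!is.list(hotspots) || length(hotspots) < 1L)
    stop("at least one hotspot polygon is required", call. = FALSE)
  for (p in hotspots) {
    p <- as.matrix(p)
    if (nrow(p) < 3L || ncol(p) != 2L)
      stop("each polygon needs >= 3 (row, col) vertices", call. = FALSE)
    a <- abs(sum(p[, 1] * c(p[-1, 2], p[1, 2]) -
                 p[, 2] * c(p[-1, 1], p[1, 1]))) / 2
    if (a <= 0) stop("polygon with zero area", call. = FALSE)
  }
  invisible(hotspots)
}

#' Score a slide: hotspot-averaged dTSR and dichotomized class
#'
#' For each hotspot polygon the bounding box is cropped from the H&E
#' slide, pixels outside the polygon are set to white background, a
#' virtual CK image is generated (crops are white-padded up to a tile
#' multiple for the generator and cut back), and the crop's dTSR is
#' computed. The slide score is the unweighted mean of the hotspot
#' scores; the class is `dTSR-high` iff the mean is strictly above
#' `cutoff`.
#'
#' @param heWsi `H x W x 3` RGB array of the (level-0) H&E slide.
#' @param model a [VirtualStainModel-class] or a function
#'   `function(heRegion) -> ckRegion` (e.g. the phantom oracle).
#' @param hotspots list of polygons, see [validateHotspots()].
#' @param cutoff dichotomization cut-off in percent (default 65).
#' @param tile generator tile size; defaults to the model's.
#' @param tissueThreshold,dabThreshold,basis,cMax,eps see [computeDTSR()].
#' @return a [TSRScore-class].
#' @export
scoreWSI <- function(heWsi, model, hotspots, cutoff = 65, tile = NULL,
                     tissueThreshold = 200, dabThreshold = 80,
                     basis = stainBasis(), cMax = 1, eps = 1) {
  assertRGBImage(heWsi, "heWsi")
  validateHotspots(hotspots)
  if (is.null(tile))
    tile <- if (is(model, "VirtualStainModel")) model@config$tile else NULL
  h <- dim(heWsi)[1]; w <- dim(heWsi)[2]
  scores <- numeric(0)
  tumorTot <- 0; stromaTot <- 0
  for (poly in hotspots) {
    poly <- as.matrix(poly)
    r0 <- max(0L, floor(min(poly[, 1]))); r1 <- min(h - 1L, ceiling(max(poly[, 1])))
    c0 <- max(0L, floor(min(poly[, 2]))); c1 <- min(w - 1L, ceiling(max(poly[, 2])))
    if (r1 < r0 || c1 < c0) stop("hotspot outside the slide", call. = FALSE)
    crop <- heWsi[(r0 + 1):(r1 + 1), (c0 + 1):(c1 + 1), , drop = FALSE]
    inPoly <- rasterizePolygon(poly, nrow(crop), ncol(crop), r0, c0)
    cropMasked <- crop
    for (k in 1:3) {
      ch <- cropMasked[, , k]; ch[!inPoly] <- 255; cropMasked[, , k] <- ch
    }
    ckCrop <- if (is.function(model) && is.null(tile)) {
      model(cropMasked)
    } else {
      tl <- if (is.null(tile)) 256L else as.integer(tile)
      hp <- ceiling(nrow(cropMasked) / tl) * tl
      wp <- ceiling(ncol(cropMasked) / tl) * tl
      padded <- array(255, c(hp, wp, 3))
      padded[seq_len(nrow(cropMasked)), seq_len(ncol(cropMasked)), ] <-
        cropMasked
      full <- generateAndStitch(padded, model, tl)
      full[seq_len(nrow(cropMasked)), seq_len(ncol(cropMasked)), ,
           drop = FALSE]
    }
    res <- tryCatch(
      computeDTSR(cropMasked, ckCrop, tissueThreshold, dabThreshold,
                  basis, cMax, eps),
      error = function(e) NULL)
    if (is.null(res)) next                   # tissue-empty hotspot
    scores <- c(scores, res$dtsr)
    tumorTot <- tumorTot + res$tumor_area
    stromaTot <- stromaTot + res$stroma_area
  }
  if (length(scores) == 0L)
    stop("undefined score: all hotspots tissue-empty", call. = FALSE)
  m <- mean(scores)
  new("TSRScore", tumorArea = tumorTot, stromaArea = stromaTot,
      dtsr = m,
      tsrClass = if (m > cutoff) "dTSR-high" else "dTSR-low",
      hotspotScores = scores, cutoff = cutoff)
}

#' Read/write hotspot annotations as JSON
#'
#' The JSON format is a list of polygons, each an array of `[row, col]`
#' vertex pairs in 0-based level-0 pixel coordinates.
#'
#' @param path JSON file path.
#' @return `readHotspots()`: a validated list of vertex matrices.
#' @export
readHotspots <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  hotspots <- lapply(raw, function(p) {
    m <- do.call(rbind, lapply(p, function(v) as.numeric(unlist(v))))
    colnames(m) <- c("row", "col")
    m
  })
  validateHotspots(hotspots)
  hotspots
}

#' @rdname readHotspots
#' @param hotspots list of polygon vertex matrices.
#' @export
writeHotspots <- function(hotspots, path) {
  validateHotspots(hotspots)
  jsonlite::write_json(lapply(hotspots, unname), path, digits = NA)
  invisible(path)
}
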