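# Two-step registration of a re-stained H&E/CK slide pair.
#
# The slides come from the same physical section, so the misalignment is a
# rigid integer translation. Both slides are reduced to binarized stain
# channels (eosin for H&E, DAB for CK); the translation maximizing their
# linear cross-correlation, computed via FFT, is the shift estimate. A
# coarse global shift at strong downsampling is refined per local region by
# averaging patch-level shifts after outlier rejection.

# truncated, normalized 2-D Gaussian window of odd side `block`
gaussianWindow <- function(block, sigma = (block - 1) / 6) {
  r <- (block - 1) / 2
  g <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# Gaussian-weighted local mean with replicate boundary, via FFT correlation
localWeightedMean <- function(img, block, sigma = (block - 1) / 6) {
  p <- (block - 1L) %/% 2L
  h <- nrow(img); w <- ncol(img)
  pad <- matrix(0, h + 2L * p, w + 2L * p)
  pad[(p + 1L):(p + h), (p + 1L):(p + w)] <- img
  pad[seq_len(p), ] <- pad[rep(p + 1L, p), ]
  pad[(p + h + 1L):(p + h + 2L * p - p), ] <- pad[rep(p + h, p), ]
  pad[, seq_len(p)] <- pad[, rep(p + 1L, p)]
  pad[, (p + w + 1L):(p + w + p)] <- pad[, rep(p + w, p)]
  n1 <- nrow(pad); n2 <- ncol(pad)
  k <- gaussianWindow(block, sigma)
  kpad <- matrix(0, n1, n2)
  idx1 <- ((-p:p) %% n1) + 1L
  idx2 <- ((-p:p) %% n2) + 1L
  kpad[idx1, idx2] <- k
  cc <- Re(fft(fft(pad) * Conj(fft(kpad)), inverse = TRUE)) / (n1 * n2)
  cc[(p + 1L):(p + h), (p + 1L):(p + w)]
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so diagonal label
# adjacencies are merged afterwards with a small union-find
label8 <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n < 2L) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  a <- lab[-h, -w]; b <- lab[-1, -1]          # down-right diagonal
  c_ <- lab[-1, -w]; d <- lab[-h, -1]         # up-right diagonal
  pairs <- rbind(cbind(as.vector(a), as.vector(b)),
                 cbind(as.vector(c_), as.vector(d)))
  pairs <- pairs[pairs[, 1] > 0L & pairs[, 2] > 0L &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs) == 0L) return(lab)
  pairs <- unique(pairs)
  parent <- seq_len(n)
  findRoot <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(nrow(pairs))) {
    ra <- findRoot(pairs[r, 1]); rb <- findRoot(pairs[r, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  roots <- vapply(seq_len(n), findRoot, integer(1))
  lab[lab > 0L] <- roots[lab[lab > 0L]]
  lab
}

#' Binarize a stain channel for registration
#'
#' Locally adaptive thresholding followed by small-object removal. A pixel
#' is foreground iff its value exceeds the Gaussian-weighted mean of its
#' `blockSize` neighborhood by more than `offset`, which keeps stained
#' structure and rejects both the empty background and flat interiors.
#' Every 8-connected foreground component with area strictly below
#' `minArea` is then removed.
#'
#' @param channel `H x W` numeric matrix (8-bit stain channel).
#' @param blockSize odd neighborhood side length, >= 3 and no larger than
#'   either image dimension.
#' @param offset threshold offset above the local mean.
#' @param minArea components with fewer pixels than this are dropped.
#' @param sigma Gaussian window width; default `(blockSize - 1)/6`.
#' @return logical `H x W` mask.
#' @export
registrationMask <- function(channel, blockSize = 151L, offset = 10,
                             minArea = 200L,
                             sigma = (blockSize - 1) / 6) {
  if (!is.matrix(channel)) stop("channel must be a matrix", call. = FALSE)
  blockSize <- as.integer(blockSize)
  if (blockSize < 3L || blockSize %% 2L == 0L)
    stop("blockSize must be an odd integer >= 3", call. = FALSE)
  if (blockSize > min(dim(channel)))
    stop("image smaller than the threshold block", call. = FALSE)
  if (minArea < 0L) stop("minArea must be >= 0", call. = FALSE)
  lm <- localWeightedMean(channel, blockSize, sigma)
  mask <- channel > lm + offset
  if (minArea > 0L && any(mask)) {
    lab <- label8(mask)
    area <- tabulate(lab[lab > 0L])
    keep <- which(area >= minArea)
    mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  }
  mask
}

#' Integer shift maximizing the linear cross-correlation of two masks
#'
#' Zero-padded (linear, not circular) cross-correlation computed with the
#' FFT. The returned `(drow, dcol)` is the displacement of `maskMov`
#' relative to `maskRef`: translating `maskRef` by it (equivalently,
#' `maskMov` by its negative) maximizes their overlap. Ties are broken by
#' the smallest `(drow, dcol)` in lexicographic order.
#'
#' @param maskRef,maskMov logical or 0/1 matrices of identical shape, each
#'   with at least one foreground pixel.
#' @return a [ShiftVector-class].
#' @export
crossCorrelationShift <- function(maskRef, maskMov) {
  if (!identical(dim(maskRef), dim(maskMov)))
    stop("masks must have identical shape", call. = FALSE)
  a <- maskRef * 1; b <- maskMov * 1
  if (sum(a) < 1 || sum(b) < 1)
    stop("degenerate input: empty mask", call. = FALSE)
  h <- nrow(a); w <- ncol(a)
  p1 <- stats::nextn(2L * h - 1L, c(2, 3, 5))
  p2 <- stats::nextn(2L * w - 1L, c(2, 3, 5))
  A <- matrix(0, p1, p2); A[seq_len(h), seq_len(w)] <- b   # moving mask
  B <- matrix(0, p1, p2); B[seq_len(h), seq_len(w)] <- a   # reference
  cc <- Re(fft(fft(A) * Conj(fft(B)), inverse = TRUE)) / (p1 * p2)
  cc <- round(cc, 6)                        # mask overlaps are integers
  dr <- ifelse(0:(p1 - 1) <= h - 1, 0:(p1 - 1), 0:(p1 - 1) - p1)
  dc <- ifelse(0:(p2 - 1) <= w - 1, 0:(p2 - 1), 0:(p2 - 1) - p2)
  okR <- which(dr >= -(h - 1) & dr <= h - 1)
  okC <- which(dc >= -(w - 1) & dc <= w - 1)
  sub <- cc[okR, okC, drop = FALSE]
  best <- max(sub)
  hits <- which(sub == best, arr.ind = TRUE)
  cand <- cbind(dr[okR[hits[, 1]]], dc[okC[hits[, 2]]])
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  shiftVector(cand[1, 1], cand[1, 2])
}

#' Estimate the global shift between an H&E/CK slide pair
#'
#' Both rasters are block-averaged down by `downsample`, the eosin channel
#' is extracted from the H&E image and the DAB channel from the CK image,
#' both are binarized with [registrationMask()], and the cross-correlation
#' peak gives the coarse shift, multiplied back to level-0 pixels.
#'
#' @param he,ck `H x W x 3` arrays of the H&E and CK slides (level 0).
#' @param downsample integer downsampling factor.
#' @param basis stain basis for deconvolution.
#' @param blockSize,offset,minArea see [registrationMask()]; at strong
#'   downsampling of small phantoms, pass a correspondingly smaller
#'   `blockSize`.
#' @param cMax,eps see [extractStainChannel()].
#' @return a level-0 [ShiftVector-class] (a multiple of `downsample`).
#' @export
estimateGlobalShift <- function(he, ck, downsample = 32L,
                                basis = stainBasis(), blockSize = 151L,
                                offset = 10, minArea = 200L,
                                cMax = 1, eps = 1) {
  assertRGBImage(he, "he"); assertRGBImage(ck, "ck")
  hd <- downsampleImage(he, downsample)
  cd <- downsampleImage(ck, downsample)
  eo <- extractStainChannel(hd, "E", basis, cMax, eps)
  dab <- extractStainChannel(cd, "DAB", basis, cMax, eps)
  mRef <- registrationMask(eo, blockSize, offset, minArea)
  mMov <- registrationMask(dab, blockSize, offset, minArea)
  if (!any(mRef) || !any(mMov))
    stop("degenerate input: all-background slide", call. = FALSE)
  s <- crossCorrelationShift(mRef, mMov)
  shiftVector(s@drow * as.integer(downsample),
              s@dcol * as.integer(downsample))
}

#' Refine registration with per-region local shifts
#'
#' The slide is covered by a grid of `regionSize` regions (edge regions at
#' their natural size). Within each region, the globally aligned CK content
#' is tiled into `patchSize` patches together with the H&E content;
#' near-white H&E patches and patches whose CK content is little-dyed
#' (no DAB to register against) are skipped, each remaining patch
#' contributes a residual shift from [crossCorrelationShift()] on
#' binarized stain channels, patch shifts whose row or column component deviates from the
#' per-region median by more than `madMultiplier` times the median absolute
#' deviation (floored at `madFloor` px) are discarded as outliers, and the
#' region's final shift is the rounded mean of the inliers plus the global
#' shift. Regions with no usable patch inherit the global shift alone.
#'
#' @inheritParams estimateGlobalShift
#' @param globalShift the coarse [ShiftVector-class] from
#'   [estimateGlobalShift()].
#' @param regionSize,patchSize region and patch side lengths in pixels;
#'   `regionSize` must be a positive multiple of `patchSize`.
#' @param madMultiplier,madFloor outlier rule parameters.
#' @param whiteValue,whiteFrac white-background rule forwarded to
#'   [isWhiteBackground()].
#' @param dabThreshold,dyedFrac little-dyed rule forwarded to
#'   [isLittleDyed()].
#' @return a [LocalShiftMap-class].
#' @export
estimateLocalShifts <- function(he, ck, globalShift,
                                regionSize = 10240L, patchSize = 1024L,
                                basis = stainBasis(), blockSize = 151L,
                                offset = 10, minArea = 200L,
                                madMultiplier = 3, madFloor = 2,
                                whiteValue = 220, whiteFrac = 0.95,
                                dabThreshold = 80, dyedFrac = 0.05,
                                cMax = 1, eps = 1) {
  assertRGBImage(he, "he"); assertRGBImage(ck, "ck")
  stopifnot(is(globalShift, "ShiftVector"))
  regionSize <- as.integer(regionSize); patchSize <- as.integer(patchSize)
  if (regionSize < 1L || patchSize < 1L || regionSize %% patchSize != 0L)
    stop("regionSize must be a positive multiple of patchSize",
         call. = FALSE)
  g <- shiftComponents(globalShift)
  # the shift records the CK displacement; its inverse aligns CK onto H&E
  ckAligned <- translateImage(ck, -g["drow"], -g["dcol"])
  h <- dim(he)[1]; w <- dim(he)[2]
  rows <- seq(0L, h - 1L, by = regionSize)
  cols <- seq(0L, w - 1L, by = regionSize)
  out <- vector("list", length(rows) * length(cols))
  i <- 0L
  for (or in rows) for (oc in cols) {
    rh <- min(regionSize, h - or); rw <- min(regionSize, w - oc)
    shifts <- matrix(0, 0, 2)
    nPatch <- 0L
    for (pr in seq(0L, rh - patchSize, by = patchSize)) {
      for (pc in seq(0L, rw - patchSize, by = patchSize)) {
        ri <- (or + pr + 1L):(or + pr + patchSize)
        ci <- (oc + pc + 1L):(oc + pc + patchSize)
        hePatch <- he[ri, ci, , drop = FALSE]
        if (isWhiteBackground(hePatch, whiteValue, whiteFrac)) next
        ckPatch <- ckAligned[ri, ci, , drop = FALSE]
        if (isLittleDyed(ckPatch, dabThreshold, dyedFrac, basis, cMax,
                         eps)) next
        nPatch <- nPatch + 1L
        eo <- extractStainChannel(hePatch, "E", basis, cMax, eps)
        dab <- extractStainChannel(ckPatch, "DAB", basis, cMax, eps)
        mRef <- tryCatch(registrationMask(eo, blockSize, offset, minArea),
                         error = function(e) NULL)
        mMov <- tryCatch(registrationMask(dab, blockSize, offset, minArea),
                         error = function(e) NULL)
        if (is.null(mRef) || is.null(mMov) || !any(mRef) || !any(mMov)) next
        s <- crossCorrelationShift(mRef, mMov)
        shifts <- rbind(shifts, shiftComponents(s))
      }
    }
    i <- i + 1L
    if (nrow(shifts) == 0L) {
      out[[i]] <- data.frame(origin_row = or, origin_col = oc,
                             drow = g[["drow"]], dcol = g[["dcol"]],
                             n_patches = nPatch, n_inliers = 0L)
      next
    }
    medR <- median(shifts[, 1]); medC <- median(shifts[, 2])
    madR <- max(madFloor, median(abs(shifts[, 1] - medR)))
    madC <- max(madFloor, median(abs(shifts[, 2] - medC)))
    inl <- abs(shifts[, 1] - medR) <= madMultiplier * madR &
           abs(shifts[, 2] - medC) <= madMultiplier * madC
    kept <- shifts[inl, , drop = FALSE]
    out[[i]] <- data.frame(
      origin_row = or, origin_col = oc,
      drow = as.integer(round(mean(kept[, 1]))) + g[["drow"]],
      dcol = as.integer(round(mean(kept[, 2]))) + g[["dcol"]],
      n_patches = nPatch, n_inliers = nrow(kept))
  }
  new("LocalShiftMap", shifts = do.call(rbind, out),
      regionSize = regionSize, globalShift = globalShift)
}
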