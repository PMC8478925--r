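# Tiling registered H&E/CK region pairs into training patches and applying
# the two curation filters (white background, little-dyed) plus the
# little-dyed rebalancing.

#' Is an H&E patch white background?
#'
#' TRUE iff strictly more than `frac` of the grayscale (ITU-R 601 luma)
#' pixels are strictly above `value`. Such patches carry no tissue and are
#' removed from training data.
#'
#' @param hePatch `H x W x 3` RGB array.
#' @param value grayscale threshold (default 220).
#' @param frac fraction threshold (default 0.95).
#' @return logical flag.
#' @export
isWhiteBackground <- function(hePatch, value = 220, frac = 0.95) {
  g <- rgbToGray(hePatch)
  mean(g > value) > frac
}

#' Is a CK patch little-dyed?
#'
#' TRUE iff the fraction of pixels whose 8-bit DAB channel value is
#' strictly above `dabThreshold` is strictly below `frac`: the patch shows
#' (almost) no epithelial staining and carries little structural signal for
#' the translator.
#'
#' @param ckPatch `H x W x 3` RGB array.
#' @param dabThreshold 8-bit DAB threshold (default 80).
#' @param frac dyed-area fraction threshold (default 0.05).
#' @param basis stain basis for deconvolution.
#' @param cMax,eps see [extractStainChannel()].
#' @return logical flag.
#' @export
isLittleDyed <- function(ckPatch, dabThreshold = 80, frac = 0.05,
                         basis = stainBasis(), cMax = 1, eps = 1) {
  dab <- extractStainChannel(ckPatch, "DAB", basis, cMax, eps)
  mean(dab > dabThreshold) < frac
}

#' Tile an aligned region pair into patch pairs
#'
#' Non-overlapping `tile x tile` grid from the top-left origin; partial
#' edge tiles are dropped. Each pair carries its 0-based origin and the
#' two curation flags.
#'
#' @param heRegion,ckRegion `H x W x 3` arrays of identical shape, already
#'   aligned via the region's final shift.
#' @param tile tile side length in pixels (default 256).
#' @param origin 0-based (row, col) of the region's top-left corner,
#'   added to tile origins.
#' @param basis,cMax,eps deconvolution settings for the little-dyed flag.
#' @param whiteValue,whiteFrac white-background rule parameters.
#' @param dabThreshold,dyedFrac little-dyed rule parameters.
#' @return list of patch pairs (possibly empty).
#' @export
tilePairs <- function(heRegion, ckRegion, tile = 256L, origin = c(0L, 0L),
                      basis = stainBasis(), whiteValue = 220,
                      whiteFrac = 0.95, dabThreshold = 80, dyedFrac = 0.05,
                      cMax = 1, eps = 1) {
  assertRGBImage(heRegion, "heRegion"); assertRGBImage(ckRegion, "ckRegion")
  if (!identical(dim(heRegion), dim(ckRegion)))
    stop("regions must have identical shape", call. = FALSE)
  tile <- as.integer(tile)
  stopifnot(tile >= 1L)
  h <- dim(heRegion)[1]; w <- dim(heRegion)[2]
  nr <- h %/% tile; nc <- w %/% tile
  if (nr < 1L || nc < 1L) return(list())
  pairs <- vector("list", nr * nc)
  k <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ri <- ((i - 1L) * tile + 1L):(i * tile)
    ci <- ((j - 1L) * tile + 1L):(j * tile)
    hePatch <- heRegion[ri, ci, , drop = FALSE]
    ckPatch <- ckRegion[ri, ci, , drop = FALSE]
    k <- k + 1L
    pairs[[k]] <- list(
      he = hePatch, ck = ckPatch,
      origin = c(row = origin[1] + (i - 1L) * tile,
                 col = origin[2] + (j - 1L) * tile),
      white_background = isWhiteBackground(hePatch, whiteValue, whiteFrac),
      little_dyed = isLittleDyed(ckPatch, dabThreshold, dyedFrac,
                                 basis, cMax, eps))
  }
  pairs
}

#' Assemble a curated training set from patch pairs
#'
#' White-background pairs are removed. Little-dyed pairs are subsampled
#' uniformly without replacement (seeded) so that they make up as close as
#' possible to `littleDyedFraction` of the final set: with `n_inf`
#' informative pairs kept, `k = round(f * n_inf / (1 - f))` little-dyed
#' pairs are retained (capped at availability), since
#' `k / (k + n_inf) = f`. Selection is deterministic under a fixed seed and
#' recorded in the dataset provenance.
#'
#' @param pairs list of patch pairs as produced by [tilePairs()].
#' @param littleDyedFraction target little-dyed share in `[0, 1]`.
#' @param seed RNG seed for the subsampling.
#' @param provenance optional named list merged into the provenance record.
#' @return a [PairedPatchDataset-class].
#' @export
assembleTrainingSet <- function(pairs, littleDyedFraction = 0.10, seed,
                                provenance = list()) {
  stopifnot(littleDyedFraction >= 0, littleDyedFraction <= 1)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  keep <- !vapply(pairs, function(p) isTRUE(p$white_background), logical(1))
  pairs <- pairs[keep]
  dyed <- vapply(pairs, function(p) isTRUE(p$little_dyed), logical(1))
  nInf <- sum(!dyed)
  idxDyed <- which(dyed)
  if (length(idxDyed) > 0L && littleDyedFraction < 1) {
    k <- round(littleDyedFraction * nInf / (1 - littleDyedFraction))
    k <- min(length(idxDyed), k)
    sel <- withSeed(seed, sort(sample(idxDyed, k)))
    pairs <- pairs[sort(c(which(!dyed), sel))]
  }
  new("PairedPatchDataset", pairs = pairs,
      provenance = modifyList(
        list(seed = seed, little_dyed_fraction = littleDyedFraction),
        provenance))
}
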