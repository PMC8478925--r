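# Shared fixture builders and independent oracles used across tests.
# Everything is generated in code under fixed seeds; no files.

# textured disc phantom with asymmetric tumor geometry for registration
discPhantom <- function(canvas = c(1024L, 1024L), noiseSd = 0, seed = 3L) {
  spec <- phantomSpec(
    canvas = canvas, tissueMargin = round(canvas[1] / 16),
    discs = list(
      list(center = round(canvas * c(0.30, 0.40)), radius = round(canvas[1] / 8.5)),
      list(center = round(canvas * c(0.66, 0.59)), radius = round(canvas[1] / 11)),
      list(center = round(canvas * c(0.49, 0.24)), radius = round(canvas[1] / 17))),
    noiseSd = noiseSd, seed = seed)
  renderPhantomPair(spec)
}

# small aligned patch-pair dataset for training smoke tests
phantomDataset <- function(nPairs = 8L, tile = 64L, seed = 4L) {
  spec <- phantomSpec(canvas = c(256L, 256L), tissueMargin = 16L,
                      tumorFraction = 0.5, noiseSd = 3, seed = seed)
  pair <- renderPhantomPair(spec)
  pairs <- tilePairs(pair$he, pair$ck, tile = tile)
  ds <- assembleTrainingSet(pairs, littleDyedFraction = 0.10, seed = seed)
  ds@pairs <- patchPairs(ds)[seq_len(min(nPairs, nPairs(ds)))]
  ds
}

# brute-force Gaussian-weighted local mean with replicate boundary:
# direct spatial accumulation, independent of the FFT path
bruteLocalMean <- function(img, block, sigma = (block - 1) / 6) {
  p <- (block - 1L) %/% 2L
  h <- nrow(img); w <- ncol(img)
  pad <- matrix(0, h + 2L * p, w + 2L * p)
  pad[(p + 1):(p + h), (p + 1):(p + w)] <- img
  pad[1:p, ] <- pad[rep(p + 1, p), ]
  pad[(p + h + 1):(p + h + p), ] <- pad[rep(p + h, p), ]
  pad[, 1:p] <- pad[, rep(p + 1, p)]
  pad[, (p + w + 1):(p + w + p)] <- pad[, rep(p + w, p)]
  g1 <- exp(-(seq(-p, p))^2 / (2 * sigma^2))
  k <- outer(g1, g1); k <- k / sum(k)
  out <- matrix(0, h, w)
  for (di in seq_len(block)) for (dj in seq_len(block)) {
    out <- out + k[di, dj] * pad[(di):(di + h - 1), (dj):(dj + w - 1)]
  }
  out
}

# exhaustive-search shift oracle: displacement of mov relative to ref,
# lexicographic tie-break; O(H^2 W^2), small masks only
bruteShift <- function(ref, mov) {
  h <- nrow(ref); w <- ncol(ref)
  best <- -Inf; bestS <- c(0L, 0L)
  for (dr in -(h - 1):(h - 1)) for (dc in -(w - 1):(w - 1)) {
    refT <- translateImage(ref * 1, dr, dc, fill = 0)
    sc <- sum(refT * mov)
    if (sc > best) { best <- sc; bestS <- c(dr, dc) }
  }
  bestS
}

# exhaustive concordant-pair AUC oracle (half credit for ties)
bruteAuc <- function(scores, truth) {
  pos <- scores[truth == 1]; neg <- scores[truth == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# a flat-colour RGB patch
flatPatch <- function(h, w, rgb) {
  array(rep(rgb, each = h * w), c(h, w, 3))
}

# Table 2 of the study: rows vTSR (low, high), columns dTSR (low, high)
table2Counts <- function() {
  new("ContingencyTable2x2",
      counts = matrix(c(98L, 23L, 30L, 207L), 2, 2,
                      dimnames = list(vTSR = c("vTSR-low", "vTSR-high"),
                                      dTSR = c("dTSR-low", "dTSR-high"))))
}
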