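# Patch tiling and curation: grid geometry, white-background and
# little-dyed filters, little-dyed rebalancing.

test_that("tiling produces the exact non-overlapping grid", {
  he <- array(100, c(512, 512, 3))
  ck <- array(100, c(512, 512, 3))
  pairs <- tilePairs(he, ck, tile = 256)
  expect_length(pairs, 4L)
  origins <- t(sapply(pairs, function(p) unname(p$origin)))
  expect_equal(origins[order(origins[, 1], origins[, 2]), ],
               rbind(c(0, 0), c(0, 256), c(256, 0), c(256, 256)))
  expect_length(tilePairs(array(0, c(500, 500, 3)),
                          array(0, c(500, 500, 3)), 256), 1L)
  expect_length(tilePairs(array(0, c(255, 600, 3)),
                          array(0, c(255, 600, 3)), 256), 0L)
  expect_error(tilePairs(he, array(0, c(256, 256, 3))), "identical")
})

test_that("white-background rule is strict at both thresholds", {
  expect_true(isWhiteBackground(flatPatch(20, 20, c(255, 255, 255))))
  expect_false(isWhiteBackground(flatPatch(20, 20, c(0, 0, 0))))
  # exactly 95.0% of pixels bright: not white background (strict >)
  p <- flatPatch(20, 20, c(255, 255, 255))
  dark <- seq_len(20)                       # 20/400 = 5% dark
  p[cbind(dark, dark, 1)] <- 0; p[cbind(dark, dark, 2)] <- 0
  p[cbind(dark, dark, 3)] <- 0
  expect_false(isWhiteBackground(p))
  # one fewer dark pixel tips the fraction over 95%
  p2 <- flatPatch(20, 20, c(255, 255, 255))
  dark <- seq_len(19)
  p2[cbind(dark, dark, 1)] <- 0; p2[cbind(dark, dark, 2)] <- 0
  p2[cbind(dark, dark, 3)] <- 0
  expect_true(isWhiteBackground(p2))
})

test_that("little-dyed rule counts DAB-positive pixels strictly", {
  expect_true(isLittleDyed(flatPatch(20, 20, c(255, 255, 255))))
  # half the patch rendered at strong DAB: clearly dyed
  conc <- array(0, c(20, 20, 3)); conc[1:10, , 3] <- 0.8
  expect_false(isLittleDyed(stainToRgb(conc)))
  # exactly 5.0% dyed pixels: still little-dyed excluded? strict < 5%
  conc <- array(0, c(20, 20, 3)); conc[1, , 3] <- 0.8   # 20/400 = 5%
  expect_false(isLittleDyed(stainToRgb(conc)))
  conc <- array(0, c(20, 20, 3)); conc[1, 1:19, 3] <- 0.8  # 4.75%
  expect_true(isLittleDyed(stainToRgb(conc)))
})

test_that("little-dyed rebalancing keeps the configured share", {
  mkPair <- function(dyed, i) list(he = array(0, c(2, 2, 3)),
                                   ck = array(0, c(2, 2, 3)),
                                   origin = c(row = i, col = 0),
                                   white_background = FALSE,
                                   little_dyed = dyed)
  pairs <- c(lapply(1:900, function(i) mkPair(FALSE, i)),
             lapply(901:1800, function(i) mkPair(TRUE, i)))
  ds <- assembleTrainingSet(pairs, 0.10, seed = 17)
  expect_equal(nPairs(ds), 1000L)
  nd <- sum(vapply(patchPairs(ds), function(p) p$little_dyed, logical(1)))
  expect_equal(nd, 100L)
  # deterministic under the seed
  ds2 <- assembleTrainingSet(pairs, 0.10, seed = 17)
  expect_identical(patchPairs(ds), patchPairs(ds2))
  ds3 <- assembleTrainingSet(pairs, 0.10, seed = 18)
  expect_false(identical(patchPairs(ds), patchPairs(ds3)))
  # no little-dyed input: unchanged
  inf <- lapply(1:30, function(i) mkPair(FALSE, i))
  expect_equal(nPairs(assembleTrainingSet(inf, 0.10, seed = 1)), 30L)
})

test_that("white-background pairs never reach the dataset", {
  spec <- phantomSpec(canvas = c(192L, 192L), tissueMargin = 48L,
                      tumorFraction = 0.6, noiseSd = 3, seed = 6)
  pair <- renderPhantomPair(spec)
  pairs <- tilePairs(pair$he, pair$ck, tile = 32)
  expect_true(any(vapply(pairs, function(p) p$white_background, logical(1))))
  ds <- assembleTrainingSet(pairs, 0.10, seed = 2)
  expect_false(any(vapply(patchPairs(ds), function(p) p$white_background,
                          logical(1))))
  # share within one pair of the target
  nd <- sum(vapply(patchPairs(ds), function(p) p$little_dyed, logical(1)))
  nInf <- nPairs(ds) - nd
  expect_lte(abs(nd - round(0.10 * nInf / 0.90)), 1)
})

test_that("curation filters are pure functions of pixel content", {
  set.seed(31)
  p <- array(sample(0:255, 32 * 32 * 3, replace = TRUE), c(32, 32, 3))
  expect_identical(isWhiteBackground(p), isWhiteBackground(p))
  expect_identical(isLittleDyed(p), isLittleDyed(p))
})
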