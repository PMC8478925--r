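# Two-step slide registration: adaptive-threshold masks and FFT
# cross-correlation shift estimation.

test_that("adaptive mask matches a brute-force windowed-mean oracle", {
  set.seed(21)
  img <- matrix(10, 64, 64)
  img[23:42, 17:36] <- 200                 # bright 20x20 square
  img <- img + matrix(runif(64 * 64, -1, 1), 64, 64)
  block <- 31L; offset <- 10
  mask <- registrationMask(img, block, offset, minArea = 0L)
  oracle <- img > bruteLocalMean(img, block) + offset
  expect_identical(mask, oracle)
  # the square is foreground, far background is rejected
  expect_true(all(mask[23:42, 17:36]))
  far <- mask; far[8:57, 2:51] <- FALSE    # blank square + halo
  expect_false(any(far))
})

test_that("small-object removal is strict at the area threshold", {
  img <- matrix(0, 160, 260)
  img[31:40, 31:50] <- 255                 # 10 x 20 = 200 px blob
  img[101:110, 181:195] <- 255             # 10 x 15 = 150 px blob
  mask <- registrationMask(img, 31L, 10, minArea = 200L)
  expect_true(all(mask[31:40, 31:50]))     # area 200 kept (strict <)
  expect_false(any(mask[101:110, 181:195]))
  expect_equal(sum(mask), 200L)
})

test_that("mask is shift-equivariant away from borders", {
  set.seed(22)
  img <- matrix(5, 96, 96)
  img[30:45, 40:55] <- 180
  img[60:70, 20:28] <- 140
  m1 <- registrationMask(img, 15L, 10, minArea = 0L)
  m2 <- registrationMask(translateImage(img, 5, 7, fill = 5), 15L, 10,
                         minArea = 0L)
  inner <- 20:76
  expect_identical(m2[inner + 5, inner + 7], m1[inner, inner])
})

test_that("mask rejects invalid parameters", {
  img <- matrix(0, 32, 32)
  expect_error(registrationMask(img, 33L), "smaller")
  expect_error(registrationMask(img, 14L), "odd")
})

test_that("cross-correlation shift matches translation and brute force", {
  set.seed(23)
  base <- matrix(runif(32 * 32) > 0.8, 32, 32)
  expect_equal(unname(shiftComponents(crossCorrelationShift(base, base))),
               c(0L, 0L))
  # content-preserving translation is recovered exactly
  padded <- matrix(FALSE, 64, 64); padded[17:48, 17:48] <- base
  moved <- translateImage(padded, 12, -7, fill = 0) > 0
  expect_equal(unname(shiftComponents(crossCorrelationShift(padded, moved))),
               c(12L, -7L))
  expect_error(crossCorrelationShift(padded, padded & FALSE), "empty")
})

test_that("FFT argmax equals exhaustive search on random masks", {
  set.seed(24)
  for (i in 1:100) {
    a <- matrix(runif(16 * 16) > 0.7, 16, 16)
    b <- matrix(runif(16 * 16) > 0.7, 16, 16)
    if (!any(a) || !any(b)) next
    expect_equal(unname(shiftComponents(crossCorrelationShift(a, b))),
                 bruteShift(a, b))
  }
})

test_that("global shift estimation recovers planted shifts", {
  pair <- discPhantom(c(1024L, 1024L), noiseSd = 0, seed = 3L)
  sh <- makeShiftedPair(pair, shiftVector(64, -96))
  est <- estimateGlobalShift(sh$he, sh$ck, downsample = 32,
                             blockSize = 9L, offset = 10, minArea = 3L)
  expect_equal(unname(shiftComponents(est)), c(64L, -96L))
  expect_equal(unname(shiftComponents(est)) %% 32, c(0, 0))
  # zero-shift pair
  est0 <- estimateGlobalShift(pair$he, pair$ck, downsample = 32,
                              blockSize = 9L, offset = 10, minArea = 3L)
  expect_equal(unname(shiftComponents(est0)), c(0L, 0L))
  # a shift that is not a multiple of the downsample factor is recovered
  # within the quantization bound
  sh70 <- makeShiftedPair(pair, shiftVector(70, 0))
  est70 <- estimateGlobalShift(sh70$he, sh70$ck, downsample = 32,
                               blockSize = 9L, offset = 10, minArea = 3L)
  expect_lte(max(abs(unname(shiftComponents(est70)) - c(70, 0))), 32)
})

test_that("an all-background slide raises a degenerate-input error", {
  white <- array(255, c(256, 256, 3))
  expect_error(estimateGlobalShift(white, white, downsample = 4,
                                   blockSize = 9L, offset = 10,
                                   minArea = 3L),
               "all-background")
})

test_that("local shifts recover a uniform planted shift per region", {
  pair <- discPhantom(c(1024L, 1024L), noiseSd = 0, seed = 3L)
  sh <- makeShiftedPair(pair, shiftVector(64, -96))
  lm <- estimateLocalShifts(sh$he, sh$ck, shiftVector(64, -96),
                            regionSize = 512L, patchSize = 256L,
                            blockSize = 31L, offset = 10, minArea = 30L)
  tab <- shiftTable(lm)
  expect_equal(tab$drow, rep(64L, nrow(tab)))
  expect_equal(tab$dcol, rep(-96L, nrow(tab)))
})

test_that("a corrupted patch is rejected by the MAD rule", {
  pair <- discPhantom(c(1024L, 1024L), noiseSd = 0, seed = 3L)
  sh <- makeShiftedPair(pair, shiftVector(64, -96))
  ckBad <- sh$ck
  set.seed(9)
  ckBad[257:512, 1:256, ] <- sample(0:255, 256 * 256 * 3, replace = TRUE)
  lm <- estimateLocalShifts(sh$he, ckBad, shiftVector(64, -96),
                            regionSize = 512L, patchSize = 256L,
                            blockSize = 31L, offset = 10, minArea = 30L)
  tab <- shiftTable(lm)
  first <- tab[tab$origin_row == 0 & tab$origin_col == 0, ]
  expect_equal(first$drow, 64L)
  expect_equal(first$dcol, -96L)
  expect_lt(first$n_inliers, first$n_patches)
})

test_that("an all-white region falls back to the global shift", {
  he <- array(255, c(128, 128, 3))
  ck <- array(255, c(128, 128, 3))
  lm <- estimateLocalShifts(he, ck, shiftVector(5, -3),
                            regionSize = 128L, patchSize = 64L,
                            blockSize = 15L, offset = 10, minArea = 5L)
  tab <- shiftTable(lm)
  expect_equal(tab$drow, 5L)
  expect_equal(tab$dcol, -3L)
  expect_equal(tab$n_patches, 0L)
  expect_error(
    estimateLocalShifts(he, ck, shiftVector(0, 0), regionSize = 100L,
                        patchSize = 64L, blockSize = 15L),
    "multiple")
})
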