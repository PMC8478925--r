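# Conditional adversarial translator: loss arithmetic, deterministic
# inference, stitching, and training plumbing.

test_that("reconstruction losses vanish for a perfect prediction", {
  set.seed(41)
  y <- array(sample(0:255, 8 * 8 * 3, replace = TRUE), c(8, 8, 3))
  x <- array(sample(0:255, 8 * 8 * 3, replace = TRUE), c(8, 8, 3))
  sr <- array(0.9, c(2, 2, 1)); sf <- array(0.4, c(2, 2, 1))
  lt <- computeLosses(x, y, y, sr, sf)
  expect_equal(lt$l1_rgb, 0)
  expect_equal(lt$l1_hed, 0)
  expect_equal(lt$adv, log(0.9) + log(1 - 0.4), tolerance = 1e-12)
})

test_that("constant offset images give the closed-form RGB L1", {
  x <- flatPatch(8, 8, c(100, 100, 100))
  y <- flatPatch(8, 8, c(120, 130, 140))
  yh <- flatPatch(8, 8, c(110, 120, 130))   # off by 10 everywhere
  lt <- computeLosses(x, y, yh, array(0.5, c(1, 1, 1)),
                      array(0.5, c(1, 1, 1)))
  expect_equal(lt$l1_rgb, 10 / 255, tolerance = 1e-12)
})

test_that("HED L1 matches an independently coded stain-space oracle", {
  minv <- solve(stainMatrix(stainBasis()))
  oracleHed <- function(img, eps = 1) {
    od <- -log10((matrix(img, ncol = 3) + eps) / 255)
    od %*% minv                              # no rounding, no clamping
  }
  set.seed(42)
  for (i in 1:20) {
    x <- array(sample(0:255, 8 * 8 * 3, replace = TRUE), c(8, 8, 3))
    y <- array(sample(0:255, 8 * 8 * 3, replace = TRUE), c(8, 8, 3))
    yh <- array(sample(0:255, 8 * 8 * 3, replace = TRUE), c(8, 8, 3))
    lt <- computeLosses(x, y, yh, array(0.5, c(1, 1, 1)),
                        array(0.5, c(1, 1, 1)))
    expect_equal(lt$l1_hed, mean(abs(oracleHed(y) - oracleHed(yh))),
                 tolerance = 1e-6)
  }
})

test_that("the total loss is linear in lambda1 and lambda2", {
  set.seed(43)
  x <- array(sample(0:255, 8 * 8 * 3, replace = TRUE), c(8, 8, 3))
  y <- array(sample(0:255, 8 * 8 * 3, replace = TRUE), c(8, 8, 3))
  yh <- array(sample(0:255, 8 * 8 * 3, replace = TRUE), c(8, 8, 3))
  sr <- array(0.7, c(2, 2, 1)); sf <- array(0.3, c(2, 2, 1))
  at <- function(l1, l2)
    computeLosses(x, y, yh, sr, sf,
                  trainingConfig(lambda1 = l1, lambda2 = l2))
  base <- at(0, 0)
  expect_equal(base$total, base$adv_generator)   # L1 terms excluded
  l10 <- at(10, 0); l09 <- at(0, 0.9); full <- at(10, 0.9)
  expect_equal(l10$total - base$total, 10 * base$l1_rgb, tolerance = 1e-12)
  expect_equal(l09$total - base$total, 0.9 * base$l1_hed, tolerance = 1e-12)
  expect_equal(full$total,
               base$adv_generator + 10 * full$l1_rgb + 0.9 * full$l1_hed,
               tolerance = 1e-12)
  expect_error(computeLosses(x, y, array(0, c(4, 4, 3)), sr, sf),
               "identical shape")
})

test_that("training config enforces its invariants", {
  expect_error(trainingConfig(lambda1 = -1), ">= 0")
  expect_error(trainingConfig(epochs = 0), "epochs")
  expect_error(trainingConfig(tile = 100, depth = 3), "divisible")
  expect_error(trainingConfig(batch = 4), "batch")
})

test_that("inference is deterministic, shape-preserving and in range", {
  ds <- phantomDataset(2L, tile = 64L)
  cfg <- trainingConfig(tile = 64, depth = 3, nf = 4, ndf = 4,
                        dLayers = 2, epochs = 1, maxSteps = 2, seed = 1)
  m <- trainVirtualStain(ds, cfg)
  he <- patchPairs(ds)[[1]]$he
  out1 <- generatorForward(he, m)
  out2 <- generatorForward(he, m)
  expect_identical(out1, out2)
  expect_equal(dim(out1), dim(he))
  expect_true(all(out1 >= 0 & out1 <= 255))
  # non-square but divisible input is accepted
  wide <- array(128, c(64, 128, 3))
  expect_equal(dim(generatorForward(wide, m)), c(64, 128, 3))
  expect_error(generatorForward(array(128, c(60, 60, 3)), m), "divisible")
})

test_that("training logs one row per epoch and rejects empty data", {
  ds <- phantomDataset(3L, tile = 64L)
  cfg <- trainingConfig(tile = 64, depth = 2, nf = 4, ndf = 4,
                        dLayers = 1, epochs = 2, seed = 1)
  m <- trainVirtualStain(ds, cfg)
  expect_equal(nrow(lossLog(m)), 2L)
  expect_equal(lossLog(m)$epoch, c(1, 2))
  empty <- new("PairedPatchDataset", pairs = list(), provenance = list())
  expect_error(trainVirtualStain(empty, cfg), "empty")
})

test_that("stitching composes generator tiles without blending", {
  ds <- phantomDataset(2L, tile = 64L)
  cfg <- trainingConfig(tile = 64, depth = 2, nf = 4, ndf = 4,
                        dLayers = 1, epochs = 1, maxSteps = 1, seed = 2)
  m <- trainVirtualStain(ds, cfg)
  region <- array(0, c(128, 128, 3))
  set.seed(44)
  region[] <- sample(0:255, length(region), replace = TRUE)
  out <- generateAndStitch(region, m, tile = 64)
  expect_equal(dim(out), dim(region))
  expect_identical(out[1:64, 1:64, ],
                   generatorForward(region[1:64, 1:64, ], m))
  # identity stub reproduces the input over the covered area
  idOut <- generateAndStitch(region, function(p) p, tile = 64)
  expect_equal(idOut[1:128, 1:128, ], region, ignore_attr = TRUE)
  # uncovered margins are white and flagged
  region2 <- array(0, c(150, 130, 3))
  idOut2 <- generateAndStitch(region2, function(p) p, tile = 64)
  expect_equal(attr(idOut2, "uncovered"), list(rows = 22L, cols = 2L))
  expect_true(all(idOut2[129:150, , ] == 255))
  expect_error(generateAndStitch(array(0, c(32, 32, 3)), function(p) p,
                                 tile = 64), "smaller")
})
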