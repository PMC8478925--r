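# dTSR scoring: masks, the stroma-percentage formula, polygon hotspots
# and slide-level dichotomization.

test_that("tissue and tumor masks honor their strict thresholds", {
  expect_false(any(tissueMask(flatPatch(4, 4, c(255, 255, 255)))))
  expect_true(all(tissueMask(flatPatch(4, 4, c(0, 0, 0)))))
  half <- flatPatch(4, 4, c(255, 255, 255)); half[1:2, , ] <- 0
  expect_equal(sum(tissueMask(half)), 8L)
  expect_false(any(tissueMask(flatPatch(4, 4, c(200, 200, 200)))))
  expect_true(all(tissueMask(flatPatch(4, 4, c(199, 199, 199)))))

  expect_false(any(tumorMask(flatPatch(4, 4, c(255, 255, 255)))))
  # uniform DAB at exactly 8-bit 80 is not tumor (strict >)
  conc80 <- array(0, c(4, 4, 3)); conc80[, , 3] <- 80 / 255
  ck80 <- stainToRgb(conc80)
  dab <- extractStainChannel(ck80, "DAB")
  expect_true(all(dab <= 80))
  expect_false(any(tumorMask(ck80)))
})

test_that("a rendered DAB disc is recovered within the edge tolerance", {
  h <- 128; w <- 128
  rc <- outer(0:(h - 1), rep(1, w)); cc <- outer(rep(1, h), 0:(w - 1))
  disc <- (rc - 63)^2 + (cc - 63)^2 <= 40^2
  conc <- array(0, c(h, w, 3))
  conc[, , 3] <- 0.8 * disc                  # 8-bit DAB about 200
  ck <- stainToRgb(conc)
  got <- sum(tumorMask(ck))
  expect_lt(abs(got - sum(disc)) / sum(disc), 0.02)
})

test_that("the dTSR formula and its conservation law hold", {
  he <- flatPatch(10, 10, c(255, 255, 255))
  he[1:10, 1:10, ] <- 255
  # tissue: 100 dark pixels; tumor: 30 of them
  he <- flatPatch(10, 10, c(50, 50, 50))
  conc <- array(0, c(10, 10, 3)); conc[1:3, , 3] <- 0.8
  ck <- stainToRgb(conc)
  res <- computeDTSR(he, ck)
  expect_equal(res$dtsr, 70)
  expect_equal(res$tumor_area + res$stroma_area, res$tissue_area)
  # no tumor -> 100; tumor covering all tissue -> 0
  expect_equal(computeDTSR(he, flatPatch(10, 10, c(255, 255, 255)))$dtsr,
               100)
  concAll <- array(0, c(10, 10, 3)); concAll[, , 3] <- 0.8
  expect_equal(computeDTSR(he, stainToRgb(concAll))$dtsr, 0)
  expect_error(computeDTSR(flatPatch(10, 10, c(255, 255, 255)),
                           flatPatch(10, 10, c(255, 255, 255))),
               "no tissue")
})

test_that("growing the tumor never increases the dTSR", {
  set.seed(51)
  he <- flatPatch(16, 16, c(60, 60, 60))
  prev <- 100
  for (k in seq(0, 16, by = 4)) {
    conc <- array(0, c(16, 16, 3))
    if (k > 0) conc[seq_len(k), , 3] <- 0.8
    d <- computeDTSR(he, stainToRgb(conc))$dtsr
    expect_lte(d, prev)
    prev <- d
  }
})

test_that("polygon rasterization matches a point-in-polygon oracle", {
  # independent even-odd crossing test per pixel center
  pip <- function(r, c, poly) {
    n <- nrow(poly); inside <- FALSE
    j <- n
    for (i in seq_len(n)) {
      ri <- poly[i, 1]; ci <- poly[i, 2]
      rj <- poly[j, 1]; cj <- poly[j, 2]
      if ((ri > r) != (rj > r)) {
        xc <- ci + (r - ri) * (cj - ci) / (rj - ri)
        if (c < xc) inside <- !inside
      }
      j <- i
    }
    inside
  }
  poly <- rbind(c(2.5, 1.5), c(2.5, 17.2), c(14.8, 12.3), c(9.1, 3.7))
  mask <- rasterizePolygon(poly, 20, 20)
  for (r in 0:19) for (c in 0:19) {
    if (mask[r + 1, c + 1] != pip(r, c, poly)) {
      # disagreements may only occur on the boundary, which we include
      onEdge <- FALSE
      n <- nrow(poly)
      for (i in seq_len(n)) {
        a <- poly[i, ]; b <- poly[if (i == n) 1 else i + 1, ]
        d <- abs((b[1] - a[1]) * (c - a[2]) - (b[2] - a[2]) * (r - a[1])) /
          sqrt(sum((b - a)^2))
        within <- r >= min(a[1], b[1]) - 1 & r <= max(a[1], b[1]) + 1 &
          c >= min(a[2], b[2]) - 1 & c <= max(a[2], b[2]) + 1
        if (d < 1e-6 && within) onEdge <- TRUE
      }
      expect_true(onEdge)
    }
  }
  # an axis-aligned rectangle covers exactly its pixel grid incl. borders
  rect <- rbind(c(3, 4), c(3, 10), c(8, 10), c(8, 4))
  m <- rasterizePolygon(rect, 12, 14)
  expect_equal(sum(m), 6L * 7L)
  expect_true(all(m[4:9, 5:11]))
  expect_error(rasterizePolygon(rbind(c(0, 0), c(1, 1)), 4, 4),
               "3 vertices")
})

test_that("phantom slides with oracle CK recover true stroma fractions", {
  oracle <- phantomOracleModel()
  for (frac in c(20, 50, 80)) {
    spec <- phantomSpec(canvas = c(160L, 160L), tissueMargin = 16L,
                        tumorFraction = 1 - frac / 100, noiseSd = 3,
                        seed = 50 + frac)
    pair <- renderPhantomPair(spec)
    hs <- list(rbind(c(16, 16), c(16, 143), c(143, 143), c(143, 16)))
    s <- scoreWSI(pair$he, oracle, hs)
    expect_lt(abs(dtsr(s) - stromaFraction(pair$truth)), 2)
    expect_length(hotspotScores(s), 1L)
    expect_equal(dtsr(s), hotspotScores(s)[1])
  }
})

test_that("the class boundary at the cut-off is strict", {
  # true stroma fraction exactly 65%: tissue 128 rows, tumor band 44.8 ->
  # use 160-row tissue with 56 tumor rows for an exact 65%
  spec <- phantomSpec(canvas = c(192L, 192L), tissueMargin = 16L,
                      tumorFraction = 0.35, noiseSd = 0, seed = 60)
  pair <- renderPhantomPair(spec)
  expect_equal(stromaFraction(pair$truth), 65)
  hs <- list(rbind(c(16, 16), c(16, 175), c(175, 175), c(175, 16)))
  s <- scoreWSI(pair$he, phantomOracleModel(), hs)
  expect_equal(dtsr(s), 65)
  expect_equal(tsrClass(s), "dTSR-low")      # 65 is not > 65
  s2 <- scoreWSI(pair$he, phantomOracleModel(), hs, cutoff = 64.9)
  expect_equal(tsrClass(s2), "dTSR-high")
  expect_error(scoreWSI(pair$he, phantomOracleModel(), list()),
               "hotspot")
})

test_that("hotspot JSON round-trips", {
  hs <- list(rbind(c(1, 2), c(1, 30), c(25, 30), c(25, 2)),
             rbind(c(40.5, 10), c(60, 55.25), c(80, 12)))
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  writeHotspots(hs, path)
  back <- readHotspots(path)
  expect_equal(lapply(back, unname), lapply(hs, unname))
})
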