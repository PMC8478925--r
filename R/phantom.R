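# Synthetic paired pseudo-H&E / pseudo-CK phantoms.
#
# Phantoms are rendered through the package's own Beer-Lambert forward
# model from piecewise-constant stain concentrations over known geometry
# (hard edges, no anti-aliasing, so areas are exact), with seeded additive
# Gaussian noise. They emulate the paired re-stained rasters the pipeline
# consumes, with exact pre-noise truth masks and optionally planted
# integer shifts, so registration, curation, training, scoring and
# evaluation can all be validated without slide data.

#' Default stain concentrations of the phantom renderer
#'
#' Tumor tissue: hematoxylin 0.6 (dense nuclei); stroma: hematoxylin
#' 0.25; eosin 0.5 in both, since eosin contrast in tissue comes from
#' cellular texture rather than a region-level offset; the CK raster
#' carries a diffuse DAB 0.45 over tumor rising to 0.9 at the cell-dot
#' texture, plus a light hematoxylin counterstain 0.15 over all tissue;
#' background is unstained (white). Tumor "cell" dots add hematoxylin
#' 0.2 and eosin 0.3 in the H&E raster. These levels keep the default
#' thresholds (grayscale 200 for tissue, 80 on the 8-bit DAB channel for
#' tumor) comfortably separated on either side.
#'
#' @return named list of concentration levels (OD units).
#' @export
phantomStainLevels <- function() {
  list(tumorH = 0.6, tumorE = 0.5, stromaH = 0.25, stromaE = 0.5,
       ckTumorDAB = 0.9, ckTumorDABBase = 0.45, ckCounterstainH = 0.15,
       dotH = 0.2, dotE = 0.3)
}

#' Specify a phantom slide pair
#'
#' Geometry: tissue is a centered rectangle inset by `tissueMargin`
#' pixels; the tumor is either the top fraction `tumorFraction` of the
#' tissue rows (pixel-exact control of the stroma fraction) or a list of
#' discs, each `list(center = c(row, col), radius = r)` (0-based level-0
#' coordinates), which must lie inside the tissue.
#'
#' @param canvas `c(height, width)` in pixels.
#' @param tissueMargin inset of the tissue rectangle from the canvas edge.
#' @param tumorFraction fraction of tissue that is tumor, in `[0, 1]`
#'   (ignored when `discs` is given).
#' @param discs optional list of tumor discs.
#' @param levels stain levels, see [phantomStainLevels()].
#' @param noiseSd additive Gaussian noise sigma in 8-bit units
#'   (default 3).
#' @param texture if `TRUE` (default), a seeded multi-scale pattern of
#'   "cell" dots is drawn inside the tumor and rendered into both
#'   rasters at identical positions, emulating the shared cellular
#'   texture of a re-stained section that registration keys on. Dots lie
#'   inside tumor, so truth masks are unaffected.
#' @param seed RNG seed for the texture and the noise.
#' @return a validated spec list of class `PhantomSpec`.
#' @export
phantomSpec <- function(canvas = c(512L, 512L), tissueMargin = 32L,
                        tumorFraction = 0.3, discs = NULL,
                        levels = phantomStainLevels(), noiseSd = 3,
                        texture = TRUE, seed = 1L) {
  canvas <- as.integer(canvas)
  stopifnot(length(canvas) == 2L, all(canvas >= 8L),
            tissueMargin >= 0L, noiseSd >= 0,
            tumorFraction >= 0, tumorFraction <= 1)
  if (2L * tissueMargin >= min(canvas))
    stop("tissueMargin leaves no tissue", call. = FALSE)
  structure(list(canvas = canvas, tissueMargin = as.integer(tissueMargin),
                 tumorFraction = tumorFraction, discs = discs,
                 levels = levels, noiseSd = noiseSd,
                 texture = isTRUE(texture), seed = as.integer(seed)),
            class = "PhantomSpec")
}

# seeded multi-scale dot pattern restricted to the tumor mask
phantomDots <- function(spec, tumor) {
  h <- spec$canvas[1]; w <- spec$canvas[2]
  dots <- matrix(FALSE, h, w)
  if (!any(tumor)) return(dots)
  m <- min(h, w)
  rc <- outer(0:(h - 1), rep(1, w))
  cc <- outer(rep(1, h), 0:(w - 1))
  centers <- which(tumor, arr.ind = TRUE) - 1L   # 0-based candidates
  withSeed(spec$seed + 7L, {
    for (oct in c(16L, 32L, 64L)) {
      r <- max(1L, round(m / oct))
      n <- min(nrow(centers), 6L * (oct / 16L)^2)
      pick <- centers[sample(nrow(centers), n), , drop = FALSE]
      for (i in seq_len(nrow(pick)))
        dots <- dots | ((rc - pick[i, 1])^2 + (cc - pick[i, 2])^2 <= r^2)
    }
  })
  dots & tumor
}

phantomMasks <- function(spec) {
  h <- spec$canvas[1]; w <- spec$canvas[2]; m <- spec$tissueMargin
  tissue <- matrix(FALSE, h, w)
  rows <- (m + 1L):(h - m); cols <- (m + 1L):(w - m)
  tissue[rows, cols] <- TRUE
  tumor <- matrix(FALSE, h, w)
  if (!is.null(spec$discs)) {
    rc <- outer(0:(h - 1), rep(1, w))
    cc <- outer(rep(1, h), 0:(w - 1))
    for (d in spec$discs) {
      inside <- (rc - d$center[1])^2 + (cc - d$center[2])^2 <= d$radius^2
      if (any(inside & !tissue))
        stop("tumor disc outside tissue", call. = FALSE)
      tumor <- tumor | inside
    }
  } else if (spec$tumorFraction > 0) {
    k <- round(spec$tumorFraction * length(rows))
    if (k > 0L) tumor[rows[seq_len(k)], cols] <- TRUE
  }
  list(tissue = tissue, tumor = tumor)
}

#' Render a paired pseudo-H&E / pseudo-CK phantom
#'
#' Both rasters are rendered with [stainToRgb()] from the spec's stain
#' levels over the spec's geometry; seeded Gaussian noise is added and
#' clamped to `[0, 255]`. Truth masks record the exact pre-noise
#' geometry.
#'
#' @param spec a [phantomSpec()].
#' @param basis stain basis for rendering.
#' @return list with elements `he`, `ck` (RGB arrays) and `truth`
#'   (a [PhantomTruth-class]).
#' @export
renderPhantomPair <- function(spec, basis = stainBasis()) {
  stopifnot(inherits(spec, "PhantomSpec"))
  g <- phantomMasks(spec)
  h <- spec$canvas[1]; w <- spec$canvas[2]
  lv <- spec$levels
  stroma <- g$tissue & !g$tumor
  dots <- if (spec$texture) phantomDots(spec, g$tumor)
          else matrix(FALSE, h, w)
  heConc <- array(0, c(h, w, 3))
  heConc[, , 1] <- lv$tumorH * g$tumor + lv$stromaH * stroma +
    lv$dotH * dots
  heConc[, , 2] <- lv$tumorE * g$tumor + lv$stromaE * stroma +
    lv$dotE * dots
  ckConc <- array(0, c(h, w, 3))
  ckConc[, , 1] <- lv$ckCounterstainH * g$tissue
  ckConc[, , 3] <- lv$ckTumorDABBase * g$tumor +
    (lv$ckTumorDAB - lv$ckTumorDABBase) * dots
  he <- stainToRgb(heConc, basis)
  ck <- stainToRgb(ckConc, basis)
  if (spec$noiseSd > 0) {
    noise <- withSeed(spec$seed, list(
      he = array(rnorm(length(he), 0, spec$noiseSd), dim(he)),
      ck = array(rnorm(length(ck), 0, spec$noiseSd), dim(ck))))
    he <- clamp(round(he + noise$he), 0, 255)
    ck <- clamp(round(ck + noise$ck), 0, 255)
  }
  ts <- sum(g$tissue)
  truth <- new("PhantomTruth", tumorMask = g$tumor, tissueMask = g$tissue,
               stromaFraction = if (ts > 0) 100 * sum(stroma) / ts else 0,
               plantedShift = shiftVector(0L, 0L))
  list(he = he, ck = ck, truth = truth)
}

#' Plant a known shift into a phantom pair
#'
#' Translates the CK raster by `shift` (white fill at exposed margins)
#' and records the planted truth; registration should recover it.
#'
#' @param pair output of [renderPhantomPair()].
#' @param shift a [ShiftVector-class] with
#'   `|components| < canvas/4` so the pair retains overlap.
#' @return the pair with translated `ck` and updated truth.
#' @export
makeShiftedPair <- function(pair, shift) {
  stopifnot(is(shift, "ShiftVector"))
  s <- shiftComponents(shift)
  d <- dim(pair$ck)
  if (abs(s["drow"]) >= d[1] / 4 || abs(s["dcol"]) >= d[2] / 4)
    stop("shift too large: pair would lose overlap", call. = FALSE)
  pair$ck <- translateImage(pair$ck, s["drow"], s["dcol"], fill = 255)
  pair$truth@plantedShift <- shift
  pair
}

#' Oracle virtual-CK model for phantom slides
#'
#' Phantom CK is a deterministic function of phantom H&E content: tumor
#' tissue carries distinctly denser hematoxylin than stroma, so the
#' oracle deconvolves the H&E input, classifies tissue pixels by their
#' hematoxylin concentration against the midpoint of the tumor/stroma
#' levels, and re-renders the exact CK appearance. Usable wherever a
#' [VirtualStainModel-class] is accepted as a `function(heRegion)`.
#'
#' @param basis stain basis.
#' @param levels stain levels the phantom was rendered with.
#' @param tissueThreshold grayscale tissue threshold.
#' @return `function(heRegion) -> ckRegion`.
#' @export
phantomOracleModel <- function(basis = stainBasis(),
                               levels = phantomStainLevels(),
                               tissueThreshold = 200) {
  midH <- (levels$tumorH + levels$stromaH) / 2
  function(heRegion) {
    conc <- rgbToStain(heRegion, basis)
    tissue <- tissueMask(heRegion, tissueThreshold)
    tumor <- tissue & (conc[, , 1] > midH)
    ckConc <- array(0, dim(heRegion))
    ckConc[, , 1] <- levels$ckCounterstainH * tissue
    ckConc[, , 3] <- levels$ckTumorDAB * tumor
    stainToRgb(ckConc, basis)
  }
}

#' Generate a phantom benchmark of slides with known TSR
#'
#' One phantom per requested stroma fraction (cycled up to `nSlides`),
#' each with a single hotspot polygon covering its tissue rectangle, and
#' a truth table with the true stroma fraction and the true class at the
#' cut-off.
#'
#' @param nSlides number of slides (>= 1).
#' @param stromaFractions true stroma percentages to cycle through.
#' @param canvas,tissueMargin,noiseSd forwarded to [phantomSpec()].
#' @param cutoff classification cut-off in percent (default 65; a slide
#'   is truly high iff its fraction is strictly above it).
#' @param seed base seed; slide i uses `seed + i`.
#' @param basis stain basis.
#' @return list: `slides` (each with `id`, `he`, `ck`, `truth`,
#'   `hotspots`) and `truth` (data.frame `slide_id`, `stroma_fraction`,
#'   `tsr_class`).
#' @export
generateBenchmark <- function(nSlides, stromaFractions,
                              canvas = c(256L, 256L), tissueMargin = 24L,
                              noiseSd = 3, cutoff = 65, seed = 1L,
                              basis = stainBasis()) {
  stopifnot(nSlides >= 1L, length(stromaFractions) >= 1L)
  slides <- vector("list", nSlides)
  rows <- vector("list", nSlides)
  for (i in seq_len(nSlides)) {
    frac <- stromaFractions[((i - 1L) %% length(stromaFractions)) + 1L]
    spec <- phantomSpec(canvas = canvas, tissueMargin = tissueMargin,
                        tumorFraction = 1 - frac / 100,
                        noiseSd = noiseSd, seed = seed + i)
    pair <- renderPhantomPair(spec, basis)
    m <- tissueMargin
    r1 <- canvas[1] - m - 1L; c1 <- canvas[2] - m - 1L
    hotspot <- rbind(c(m, m), c(m, c1), c(r1, c1), c(r1, m))
    trueFrac <- stromaFraction(pair$truth)
    slides[[i]] <- list(id = sprintf("phantom-%02d", i), he = pair$he,
                        ck = pair$ck, truth = pair$truth,
                        hotspots = list(hotspot))
    rows[[i]] <- data.frame(
      slide_id = sprintf("phantom-%02d", i),
      stroma_fraction = trueFrac,
      tsr_class = if (trueFrac > cutoff) "high" else "low")
  }
  list(slides = slides, truth = do.call(rbind, rows))
}
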