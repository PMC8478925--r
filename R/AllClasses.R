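#' StainBasis: optical-density stain vectors for color deconvolution
#'
#' Holds the 3x3 matrix whose rows are the unit optical-density (OD) vectors
#' of hematoxylin, eosin and DAB over the R, G, B channels. Rows must be
#' non-negative, unit Euclidean norm (tolerance 1e-6) and the matrix must be
#' invertible, so RGB absorbance can be unmixed into per-stain
#' concentrations and back.
#'
#' @slot od 3x3 numeric matrix, rows named `H`, `E`, `DAB`, columns
#'   `R`, `G`, `B`.
#' @seealso [stainBasis()], [rgbToStain()], [stainToRgb()]
#' @export
setClass("StainBasis", slots = c(od = "matrix"))

setValidity("StainBasis", function(object) {
  m <- object@od
  if (!is.numeric(m) || !identical(dim(m), c(3L, 3L)))
    return("od must be a numeric 3x3 matrix")
  if (anyNA(m) || any(m < 0))
    return("stain vector components must be finite and >= 0")
  if (any(abs(sqrt(rowSums(m^2)) - 1) > 1e-6))
    return("each stain vector must have unit Euclidean norm (tol 1e-6)")
  if (abs(det(m)) < 1e-8)
    return("stain matrix must be invertible")
  TRUE
})

#' Construct a stain basis
#'
#' With no arguments, returns the Ruifrok-Johnston H/E/DAB optical-density
#' vectors (row-normalized to unit length), the standard basis for
#' brightfield H&E/DAB deconvolution. A custom basis can be given as a 3x3
#' matrix (rows = stains H, E, DAB; columns = R, G, B) or as a row-major
#' 9-number vector, as used in pipeline configuration files.
#'
#' @param m optional 3x3 numeric matrix or length-9 row-major vector.
#' @param normalize if `TRUE` (default), rows are rescaled to unit norm.
#' @return a [StainBasis-class] object.
#' @examples
#' stainBasis()
#' @export
stainBasis <- function(m = NULL, normalize = TRUE) {
  if (is.null(m)) {
    m <- rbind(c(0.65, 0.70, 0.29),
               c(0.07, 0.99, 0.11),
               c(0.27, 0.57, 0.78))
  } else if (is.numeric(m) && length(m) == 9L && is.null(dim(m))) {
    m <- matrix(m, 3, 3, byrow = TRUE)
  }
  m <- as.matrix(m)
  if (normalize) {
    nrm <- sqrt(rowSums(m^2))
    if (any(nrm == 0)) stop("stain vector with zero norm", call. = FALSE)
    m <- m / nrm
  }
  dimnames(m) <- list(c("H", "E", "DAB"), c("R", "G", "B"))
  new("StainBasis", od = m)
}

#' @describeIn stainBasis extract the 3x3 OD matrix.
#' @param x a `StainBasis`.
#' @export
stainMatrix <- function(x) {
  stopifnot(is(x, "StainBasis"))
  x@od
}

setMethod("show", "StainBasis", function(object) {
  cat("StainBasis (rows: stains H/E/DAB; columns: R/G/B optical density)\n")
  print(round(object@od, 4))
})

#' ShiftVector: an integer translation between a slide pair
#'
#' A rigid `(drow, dcol)` pixel translation recording the displacement of
#' CK content relative to its re-stained H&E counterpart (positive = CK
#' sits lower/further right); applying the negative aligns CK onto H&E.
#' Expressed at level-0 resolution unless `levelScale` says otherwise.
#'
#' @slot drow,dcol integer shift components in pixels (row-major order).
#' @slot levelScale integer; pixel size multiplier of the level the shift
#'   was measured at (1 = level 0).
#' @export
setClass("ShiftVector",
         slots = c(drow = "integer", dcol = "integer", levelScale = "integer"),
         prototype = prototype(drow = 0L, dcol = 0L, levelScale = 1L))

setValidity("ShiftVector", function(object) {
  if (length(object@drow) != 1L || length(object@dcol) != 1L ||
      anyNA(c(object@drow, object@dcol)))
    return("drow/dcol must be single finite integers")
  if (length(object@levelScale) != 1L || is.na(object@levelScale) ||
      object@levelScale < 1L)
    return("levelScale must be a positive integer")
  TRUE
})

#' Construct a shift vector
#'
#' @param drow,dcol integer shift components in pixels.
#' @param levelScale pixel-size multiplier of the measurement level.
#' @return a [ShiftVector-class] object.
#' @export
shiftVector <- function(drow = 0L, dcol = 0L, levelScale = 1L) {
  new("ShiftVector", drow = as.integer(round(drow)),
      dcol = as.integer(round(dcol)), levelScale = as.integer(levelScale))
}

#' @describeIn shiftVector shift components as a named integer vector.
#' @param x a `ShiftVector`.
#' @export
shiftComponents <- function(x) {
  stopifnot(is(x, "ShiftVector"))
  c(drow = x@drow, dcol = x@dcol)
}

setMethod("show", "ShiftVector", function(object) {
  cat(sprintf("ShiftVector: (drow = %d, dcol = %d) px, levelScale = %d\n",
              object@drow, object@dcol, object@levelScale))
})

#' LocalShiftMap: per-region final shifts of a registered slide pair
#'
#' One row per non-background local region: the region origin (0-based,
#' level 0) and the final shift (global + mean of inlier patch shifts), with
#' patch/inlier counts for diagnostics.
#'
#' @slot shifts data.frame with columns `origin_row`, `origin_col`, `drow`,
#'   `dcol`, `n_patches`, `n_inliers`.
#' @slot regionSize integer region edge length in pixels.
#' @slot globalShift the [ShiftVector-class] used as coarse alignment.
#' @export
setClass("LocalShiftMap",
         slots = c(shifts = "data.frame", regionSize = "integer",
                   globalShift = "ShiftVector"))

setValidity("LocalShiftMap", function(object) {
  need <- c("origin_row", "origin_col", "drow", "dcol",
            "n_patches", "n_inliers")
  if (!all(need %in% names(object@shifts)))
    return(paste("shifts must have columns:", paste(need, collapse = ", ")))
  if (object@regionSize < 1L) return("regionSize must be positive")
  TRUE
})

#' @rdname LocalShiftMap-class
#' @param x a `LocalShiftMap`.
#' @return `shiftTable()`: the per-region data.frame.
#' @export
shiftTable <- function(x) {
  stopifnot(is(x, "LocalShiftMap"))
  x@shifts
}

#' @rdname LocalShiftMap-class
#' @export
globalShift <- function(x) {
  stopifnot(is(x, "LocalShiftMap"))
  x@globalShift
}

setMethod("show", "LocalShiftMap", function(object) {
  cat(sprintf("LocalShiftMap: %d region(s), region size %d px\n",
              nrow(object@shifts), object@regionSize))
  cat(sprintf("  global shift (%d, %d)\n",
              object@globalShift@drow, object@globalShift@dcol))
  print(head(object@shifts, 5))
  if (nrow(object@shifts) > 5) cat("  ...\n")
})

#' PairedPatchDataset: curated H&E/CK patch pairs for training
#'
#' An ordered list of aligned patch pairs after curation: pairs flagged as
#' white background have been removed, and little-dyed pairs (CK patches
#' with under 5% DAB-positive pixels) have been subsampled to a configured
#' share of the set.
#'
#' @slot pairs list; each element has `he`, `ck` (equal-shape RGB arrays),
#'   `origin` (0-based row/col), `white_background`, `little_dyed` flags.
#' @slot provenance list: slide/registration identifiers, the subsampling
#'   seed and the little-dyed target fraction.
#' @export
setClass("PairedPatchDataset",
         slots = c(pairs = "list", provenance = "list"))

setValidity("PairedPatchDataset", function(object) {
  for (p in object@pairs) {
    if (!all(c("he", "ck", "origin", "white_background", "little_dyed")
             %in% names(p)))
      return("each pair needs he, ck, origin, white_background, little_dyed")
    if (!identical(dim(p$he), dim(p$ck)))
      return("he and ck patches must have identical shape")
    if (isTRUE(p$white_background))
      return("dataset must not contain white-background pairs")
  }
  TRUE
})

#' @rdname PairedPatchDataset-class
#' @param x a `PairedPatchDataset`.
#' @return `patchPairs()`: the list of pairs; `nPairs()`: its length;
#'   `datasetProvenance()`: the provenance list.
#' @export
patchPairs <- function(x) {
  stopifnot(is(x, "PairedPatchDataset"))
  x@pairs
}

#' @rdname PairedPatchDataset-class
#' @export
nPairs <- function(x) length(patchPairs(x))

#' @rdname PairedPatchDataset-class
#' @export
datasetProvenance <- function(x) {
  stopifnot(is(x, "PairedPatchDataset"))
  x@provenance
}

setMethod("show", "PairedPatchDataset", function(object) {
  nd <- sum(vapply(object@pairs, function(p) isTRUE(p$little_dyed), logical(1)))
  cat(sprintf("PairedPatchDataset: %d pair(s), %d little-dyed (%.1f%%)\n",
              length(object@pairs), nd,
              if (length(object@pairs)) 100 * nd / length(object@pairs) else 0))
})

#' VirtualStainModel: a trained H&E-to-CK generator
#'
#' Holds the generator and discriminator parameters of the conditional
#' adversarial translator, the training configuration and the per-epoch
#' loss log. Inference uses the generator only and is deterministic
#' (dropout is absent by design).
#'
#' @slot config training configuration list, see [trainingConfig()].
#' @slot generator,discriminator parameter lists of the two networks.
#' @slot lossLog data.frame with one row per epoch.
#' @export
setClass("VirtualStainModel",
         slots = c(config = "list", generator = "list",
                   discriminator = "list", lossLog = "data.frame"))

#' @rdname VirtualStainModel-class
#' @param x a `VirtualStainModel`.
#' @export
modelConfig <- function(x) {
  stopifnot(is(x, "VirtualStainModel"))
  x@config
}

#' @rdname VirtualStainModel-class
#' @export
lossLog <- function(x) {
  stopifnot(is(x, "VirtualStainModel"))
  x@lossLog
}

setMethod("show", "VirtualStainModel", function(object) {
  cfg <- object@config
  cat(sprintf(
    "VirtualStainModel: tile %d, depth %d, nf %d | lambda1 %.3g, lambda2 %.3g\n",
    cfg$tile, cfg$depth, cfg$nf, cfg$lambda1, cfg$lambda2))
  if (nrow(object@lossLog))
    cat(sprintf("  trained %d epoch(s); final l1_rgb = %.4f\n",
                nrow(object@lossLog),
                object@lossLog$l1_rgb[nrow(object@lossLog)]))
})

#' TSRScore: tumor-stroma ratio of a slide or hotspot set
#'
#' The digital tumor-stroma ratio, `dTSR = 100 * stroma / (tumor + stroma)`
#' in percent, averaged over hotspots, with the dichotomized class at the
#' configured cut-off (`dTSR-high` iff mean dTSR is strictly above it).
#'
#' @slot tumorArea,stromaArea pixel counts summed over hotspots.
#' @slot dtsr mean stroma percentage in `[0, 100]`.
#' @slot tsrClass `"dTSR-low"` or `"dTSR-high"`.
#' @slot hotspotScores per-hotspot dTSR percentages.
#' @slot cutoff dichotomization cut-off in percent.
#' @export
setClass("TSRScore",
         slots = c(tumorArea = "numeric", stromaArea = "numeric",
                   dtsr = "numeric", tsrClass = "character",
                   hotspotScores = "numeric", cutoff = "numeric"))

setValidity("TSRScore", function(object) {
  if (object@dtsr < 0 || object@dtsr > 100)
    return("dtsr must lie in [0, 100]")
  if (!object@tsrClass %in% c("dTSR-low", "dTSR-high"))
    return("tsrClass must be dTSR-low or dTSR-high")
  want <- if (object@dtsr > object@cutoff) "dTSR-high" else "dTSR-low"
  if (object@tsrClass != want)
    return("tsrClass inconsistent with dtsr and cutoff")
  TRUE
})

#' @rdname TSRScore-class
#' @param x a `TSRScore`.
#' @export
dtsr <- function(x) {
  stopifnot(is(x, "TSRScore"))
  x@dtsr
}

#' @rdname TSRScore-class
#' @export
tsrClass <- function(x) {
  stopifnot(is(x, "TSRScore"))
  x@tsrClass
}

#' @rdname TSRScore-class
#' @export
hotspotScores <- function(x) {
  stopifnot(is(x, "TSRScore"))
  x@hotspotScores
}

setMethod("show", "TSRScore", function(object) {
  cat(sprintf("TSRScore: dTSR = %.2f%% -> %s (cut-off %.0f%%)\n",
              object@dtsr, object@tsrClass, object@cutoff))
  cat(sprintf("  hotspots: %s\n",
              paste(sprintf("%.2f", object@hotspotScores), collapse = ", ")))
})

#' ContingencyTable2x2: vTSR vs dTSR cross-tabulation
#'
#' Rows are the pathologists' visual classes (vTSR-low, vTSR-high), columns
#' the pipeline's classes (dTSR-low, dTSR-high).
#'
#' @slot counts 2x2 non-negative integer matrix.
#' @export
setClass("ContingencyTable2x2", slots = c(counts = "matrix"))

setValidity("ContingencyTable2x2", function(object) {
  m <- object@counts
  if (!identical(dim(m), c(2L, 2L)) || anyNA(m) || any(m < 0) ||
      any(m != round(m)))
    return("counts must be a 2x2 matrix of non-negative integers")
  if (sum(m) < 1) return("table must contain at least one observation")
  TRUE
})

#' @rdname ContingencyTable2x2-class
#' @param x a `ContingencyTable2x2`.
#' @export
tableCounts <- function(x) {
  stopifnot(is(x, "ContingencyTable2x2"))
  x@counts
}

setMethod("show", "ContingencyTable2x2", function(object) {
  cat("ContingencyTable2x2 (rows vTSR, columns dTSR)\n")
  print(object@counts)
})

#' PhantomTruth: ground truth of a rendered phantom pair
#'
#' Exact pre-noise geometry of a synthetic slide: tumor and tissue masks,
#' the true stroma fraction and any planted inter-image shift.
#'
#' @slot tumorMask,tissueMask logical matrices, tumor a subset of tissue.
#' @slot stromaFraction true stroma percentage,
#'   `100 * |tissue \ tumor| / |tissue|`.
#' @slot plantedShift the [ShiftVector-class] applied to the CK raster.
#' @export
setClass("PhantomTruth",
         slots = c(tumorMask = "matrix", tissueMask = "matrix",
                   stromaFraction = "numeric", plantedShift = "ShiftVector"))

setValidity("PhantomTruth", function(object) {
  if (!identical(dim(object@tumorMask), dim(object@tissueMask)))
    return("masks must have identical shape")
  if (any(object@tumorMask & !object@tissueMask))
    return("tumor must lie inside tissue")
  ts <- sum(object@tissueMask)
  if (ts > 0) {
    want <- 100 * sum(object@tissueMask & !object@tumorMask) / ts
    if (abs(want - object@stromaFraction) > 1e-8)
      return("stromaFraction inconsistent with masks")
  }
  TRUE
})

#' @rdname PhantomTruth-class
#' @param x a `PhantomTruth`.
#' @export
stromaFraction <- function(x) {
  stopifnot(is(x, "PhantomTruth"))
  x@stromaFraction
}

#' @rdname PhantomTruth-class
#' @export
plantedShift <- function(x) {
  stopifnot(is(x, "PhantomTruth"))
  x@plantedShift
}

setMethod("show", "PhantomTruth", function(object) {
  cat(sprintf(
    "PhantomTruth: %d x %d, tissue %d px, tumor %d px, stroma %.2f%%\n",
    nrow(object@tissueMask), ncol(object@tissueMask),
    sum(object@tissueMask), sum(object@tumorMask), object@stromaFraction))
  cat(sprintf("  planted shift (%d, %d)\n",
              object@plantedShift@drow, object@plantedShift@dcol))
})
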