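# Conditional adversarial H&E -> CK translation (Pix2Pix-style).
#
# The generator is a U-Net with skip connections and no dropout, so
# inference is deterministic; the discriminator is a PatchGAN scoring
# receptive patches of the concatenated (H&E, CK) input. The generator
# objective adds two reconstruction terms to the adversarial loss: an L1
# in RGB (weight lambda1) and an L1 in the HED stain space (weight
# lambda2), the latter computed through a smooth (unrounded, unclamped)
# stain transform so gradients flow.

#' Training configuration for the virtual stainer
#'
#' Defaults follow the published setup: `lambda1 = 10` (RGB L1 weight),
#' `lambda2 = 0.9` (HED L1 weight), batch size 1, fixed learning rate
#' 2e-4, 200 epochs, Adam with `beta1 = 0.5`, `beta2 = 0.999`, weight
#' init N(0, 0.02), 256x256 tiles with a depth-8 U-Net over 64 base
#' filters and a 3-downsampling (70x70 receptive field) PatchGAN. A
#' reduced architecture for CPU-scale experiments is obtained by lowering
#' `tile`, `depth`, `nf`, `ndf` and `dLayers`.
#'
#' @param tile patch side length; must be divisible by `2^depth`.
#' @param depth number of U-Net downsamplings.
#' @param nf,ndf base filter counts of generator and discriminator.
#' @param dLayers number of stride-2 discriminator convolutions.
#' @param lambda1,lambda2 weights of the RGB and HED L1 terms (>= 0).
#' @param lr learning rate; `beta1`, `beta2` the Adam moments.
#' @param epochs training epochs (>= 1); `batch` is fixed at 1.
#' @param maxSteps optional cap on total generator update steps.
#' @param seed RNG seed governing init and epoch shuffling.
#' @param basis [StainBasis-class] used by the HED loss.
#' @param eps offset inside the log of the stain transform.
#' @return a validated configuration list.
#' @export
trainingConfig <- function(tile = 256L, depth = 8L, nf = 64L, ndf = 64L,
                           dLayers = 3L, lambda1 = 10, lambda2 = 0.9,
                           lr = 2e-4, beta1 = 0.5, beta2 = 0.999,
                           epochs = 200L, maxSteps = Inf, seed = 1L,
                           batch = 1L, basis = stainBasis(), eps = 1) {
  cfg <- list(tile = as.integer(tile), depth = as.integer(depth),
              nf = as.integer(nf), ndf = as.integer(ndf),
              dLayers = as.integer(dLayers), lambda1 = lambda1,
              lambda2 = lambda2, lr = lr, beta1 = beta1, beta2 = beta2,
              epochs = as.integer(epochs), maxSteps = maxSteps,
              seed = as.integer(seed), batch = as.integer(batch),
              basis = basis, eps = eps)
  if (cfg$lambda1 < 0 || cfg$lambda2 < 0)
    stop("loss weights must be >= 0", call. = FALSE)
  if (cfg$epochs < 1L) stop("epochs must be >= 1", call. = FALSE)
  if (cfg$tile %% 2L^cfg$depth != 0L)
    stop("tile must be divisible by 2^depth", call. = FALSE)
  if (cfg$batch != 1L) stop("batch size is fixed at 1", call. = FALSE)
  cfg
}

# smooth HED transform of a [0,1]-scaled image: no rounding, no clamping
hedSmooth <- function(v01, minv, eps) {
  d <- dim(v01)
  od <- -log10(matrix(v01, ncol = 3L) + eps / 255)
  array(od %*% minv, d)
}

# gradient of hedSmooth composed with downstream gradient dConc
hedSmoothBackward <- function(dConc, v01, minv, eps) {
  d <- dim(v01)
  dOd <- matrix(dConc, ncol = 3L) %*% t(minv)
  dv <- -dOd / ((matrix(v01, ncol = 3L) + eps / 255) * log(10))
  array(dv, d)
}

#' Loss terms of the conditional adversarial objective
#'
#' Computes, for one (input, target, prediction) triple and the
#' discriminator's patch-score grids, the adversarial value
#' `adv = mean(log D(x,y)) + mean(log(1 - D(x, G(x))))`, the RGB and HED
#' mean-absolute reconstruction terms on the `[0, 1]` pixel scale, and the
#' generator total `adv_generator + lambda1 * l1_rgb + lambda2 * l1_hed`,
#' where `adv_generator = -mean(log D(x, G(x)))` is the non-saturating
#' generator form of the adversarial term.
#'
#' @param x,y,yHat H&E input, real CK and generated CK, equal-shape RGB
#'   arrays on the 0-255 scale.
#' @param discScoresReal,discScoresFake discriminator probability grids
#'   for the real and fake pair (values in (0, 1)).
#' @param config a [trainingConfig()] list (uses `lambda1`, `lambda2`,
#'   `basis`, `eps`).
#' @return a list of class `LossTerms`: `adv`, `adv_generator`, `l1_rgb`,
#'   `l1_hed`, `total`.
#' @export
computeLosses <- function(x, y, yHat, discScoresReal, discScoresFake,
                          config = trainingConfig()) {
  if (!identical(dim(x), dim(y)) || !identical(dim(y), dim(yHat)))
    stop("x, y and yHat must have identical shape", call. = FALSE)
  y01 <- y / 255; yh01 <- yHat / 255
  minv <- solve(stainMatrix(config$basis))
  adv <- mean(log(discScoresReal)) + mean(log(1 - discScoresFake))
  advG <- -mean(log(discScoresFake))
  l1rgb <- mean(abs(y01 - yh01))
  l1hed <- mean(abs(hedSmooth(y01, minv, config$eps) -
                    hedSmooth(yh01, minv, config$eps)))
  structure(list(adv = adv, adv_generator = advG, l1_rgb = l1rgb,
                 l1_hed = l1hed,
                 total = advG + config$lambda1 * l1rgb +
                   config$lambda2 * l1hed),
            class = "LossTerms")
}

#' @export
print.LossTerms <- function(x, ...) {
  cat(sprintf(
    "LossTerms: adv %.4f | advG %.4f | l1_rgb %.4f | l1_hed %.4f | total %.4f\n",
    x$adv, x$adv_generator, x$l1_rgb, x$l1_hed, x$total))
  invisible(x)
}

#' Train the virtual stainer on a curated patch dataset
#'
#' Alternating single-sample updates: the discriminator maximizes the
#' adversarial objective on one real and one generated pair, then the
#' generator minimizes the non-saturating adversarial term plus the
#' weighted L1 terms. Weights are initialized N(0, 0.02) under the
#' configuration seed; pairs are visited in a reshuffled order each epoch.
#'
#' @param dataset a non-empty [PairedPatchDataset-class] whose patches
#'   match `config$tile`.
#' @param config a [trainingConfig()] list.
#' @return a [VirtualStainModel-class] with a per-epoch loss log
#'   (`epoch`, `adv`, `adv_generator`, `l1_rgb`, `l1_hed`, `total`,
#'   `d_loss`, `steps`).
#' @export
trainVirtualStain <- function(dataset, config = trainingConfig()) {
  stopifnot(is(dataset, "PairedPatchDataset"))
  pairs <- patchPairs(dataset)
  if (length(pairs) == 0L) stop("dataset is empty", call. = FALSE)
  for (p in pairs)
    if (any(dim(p$he)[1:2] %% 2L^config$depth != 0L))
      stop("patch size must be divisible by 2^depth", call. = FALSE)
  minv <- solve(stainMatrix(config$basis))
  lam1 <- config$lambda1; lam2 <- config$lambda2

  withSeed(config$seed, {
    G <- initGenerator(config$depth, config$nf)
    D <- initDiscriminator(config$dLayers, config$ndf)
    stG <- adamInit(G); stD <- adamInit(D)
    logRows <- list()
    step <- 0L
    for (ep in seq_len(config$epochs)) {
      if (step >= config$maxSteps) break
      ord <- sample(length(pairs))
      acc <- c(adv = 0, adv_generator = 0, l1_rgb = 0, l1_hed = 0,
               total = 0, d_loss = 0)
      nAcc <- 0L
      for (ix in ord) {
        if (step >= config$maxSteps) break
        step <- step + 1L
        x01 <- pairs[[ix]]$he / 255
        y01 <- pairs[[ix]]$ck / 255
        xN <- 2 * x01 - 1; yN <- 2 * y01 - 1

        gf <- gForward(G, xN)
        yhN <- gf$out
        yh01 <- (yhN + 1) / 2

        # --- discriminator step ---
        fReal <- dForward(D, bindChannels(xN, yN))
        fFake <- dForward(D, bindChannels(xN, yhN))
        dLoss <- bceWithLogits(fReal$logits, 1) +
                 bceWithLogits(fFake$logits, 0)
        gR <- dBackward(D, fReal$caches, bceWithLogitsGrad(fReal$logits, 1))
        gF <- dBackward(D, fFake$caches, bceWithLogitsGrad(fFake$logits, 0))
        dGrads <- sumGrads(gR$grads, gF$grads)
        up <- adamStep(D, dGrads, stD, config$lr, config$beta1, config$beta2)
        D <- up$params; stD <- up$state

        # --- generator step (against the updated discriminator) ---
        fFake2 <- dForward(D, bindChannels(xN, yhN))
        gAdvBack <- dBackward(D, fFake2$caches,
                              bceWithLogitsGrad(fFake2$logits, 1))
        dYhN <- gAdvBack$dInput[, , 4:6, drop = FALSE]
        n <- length(yh01)
        dYh01 <- 2 * dYhN +                      # chain through yh01 -> yhN
          lam1 * sign(yh01 - y01) / n +
          lam2 * hedSmoothBackward(
            sign(hedSmooth(yh01, minv, config$eps) -
                 hedSmooth(y01, minv, config$eps)) / n,
            yh01, minv, config$eps)
        gGrads <- gBackward(G, gf$caches, dYh01 / 2)
        up <- adamStep(G, gGrads, stG, config$lr, config$beta1, config$beta2)
        G <- up$params; stG <- up$state

        lt <- computeLosses(x01 * 255, y01 * 255, yh01 * 255,
                            1 / (1 + exp(-fReal$logits)),
                            1 / (1 + exp(-fFake$logits)), config)
        acc <- acc + c(lt$adv, lt$adv_generator, lt$l1_rgb, lt$l1_hed,
                       lt$total, dLoss)
        nAcc <- nAcc + 1L
      }
      if (nAcc > 0L)
        logRows[[length(logRows) + 1L]] <-
          c(epoch = ep, acc / nAcc, steps = step)
    }
    lossLog <- as.data.frame(do.call(rbind, logRows))
    new("VirtualStainModel", config = config, generator = G,
        discriminator = D, lossLog = lossLog)
  })
}

sumGrads <- function(a, b) {
  if (is.numeric(a)) return(a + b)
  out <- a
  for (nm in seq_along(a)) out[[nm]] <- sumGrads(a[[nm]], b[[nm]])
  out
}

#' Generate a virtual CK patch from an H&E patch
#'
#' Deterministic inference: the generator has no dropout, so two calls
#' with identical input and model state are bit-identical. Input height
#' and width must be divisible by `2^depth`.
#'
#' @param hePatch `H x W x 3` RGB array on the 0-255 scale.
#' @param model a [VirtualStainModel-class].
#' @return generated CK patch, same shape, integer values in `[0, 255]`.
#' @export
generatorForward <- function(hePatch, model) {
  assertRGBImage(hePatch, "hePatch")
  stopifnot(is(model, "VirtualStainModel"))
  depth <- model@config$depth
  if (any(dim(hePatch)[1:2] %% 2L^depth != 0L))
    stop("input size must be divisible by 2^depth", call. = FALSE)
  xN <- 2 * (hePatch / 255) - 1
  out <- gForward(model@generator, xN)$out
  clamp(round(255 * (out + 1) / 2), 0, 255)
}

#' Generate and stitch a virtual CK region
#'
#' Tiles the region from its top-left origin, runs the generator on each
#' tile and places outputs at their origins with no blending. Right/bottom
#' margins not covered by a full tile are filled white and reported in the
#' `"uncovered"` attribute.
#'
#' @param heRegion `H x W x 3` RGB array, at least one tile in each
#'   dimension.
#' @param model a [VirtualStainModel-class], or a function
#'   `function(heTile) -> ckTile` (e.g. an oracle or identity stub).
#' @param tile tile side length; defaults to the model's training tile.
#' @return virtual CK region, same shape as `heRegion`.
#' @export
generateAndStitch <- function(heRegion, model, tile = NULL) {
  assertRGBImage(heRegion, "heRegion")
  if (is.null(tile))
    tile <- if (is(model, "VirtualStainModel")) model@config$tile else 256L
  tile <- as.integer(tile)
  h <- dim(heRegion)[1]; w <- dim(heRegion)[2]
  nr <- h %/% tile; nc <- w %/% tile
  if (nr < 1L || nc < 1L)
    stop("region smaller than one tile", call. = FALSE)
  gen <- if (is.function(model)) model
         else function(p) generatorForward(p, model)
  out <- array(255, dim(heRegion))
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ri <- ((i - 1L) * tile + 1L):(i * tile)
    ci <- ((j - 1L) * tile + 1L):(j * tile)
    out[ri, ci, ] <- gen(heRegion[ri, ci, , drop = FALSE])
  }
  attr(out, "uncovered") <- list(rows = h - nr * tile, cols = w - nc * tile)
  out
}
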