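# Pipeline orchestration: simulate -> register -> tile -> train -> infer
# -> score -> evaluate over a working directory, with a run manifest and
# a serialized copy of the configuration for provenance.

#' Default pipeline configuration
#'
#' All stage parameters with their published defaults: downsample 32,
#' region 10240, patch 1024, adaptive-threshold block 151 with offset 10,
#' minimum object area 200, tile 256, white-background rule 95%/220,
#' little-dyed rule 5%/80 with a 10% target share, lambda1 10, lambda2
#' 0.9, learning rate 2e-4, 200 epochs, batch size 1, tissue threshold
#' 200, DAB threshold 80, and the 65% dTSR cut-off. Overrides (e.g. the
#' reduced scales used for phantom runs) are merged recursively and
#' logged in the manifest.
#'
#' @param path optional YAML (or JSON) configuration file to load.
#' @param overrides named list of overrides merged over the defaults.
#' @return nested configuration list.
#' @export
pipelineConfig <- function(path = NULL, overrides = list()) {
  cfg <- list(
    seed = 1L,
    workdir = ".",
    stain = list(basis = as.vector(t(stainBasis()@od)), c_max = 1, eps = 1),
    simulate = list(n_slides = 4L, stroma_fractions = c(20, 50, 70, 90),
                    canvas = c(256L, 256L), tissue_margin = 24L,
                    noise_sd = 3),
    register = list(downsample = 32L, region = 10240L, patch = 1024L,
                    block = 151L, offset = 10, min_area = 200L),
    tile = list(size = 256L, white_value = 220, white_frac = 0.95,
                dab_threshold = 80, dyed_frac = 0.05,
                little_dyed_fraction = 0.10),
    train = list(tile = 256L, depth = 8L, nf = 64L, ndf = 64L,
                 d_layers = 3L, lambda1 = 10, lambda2 = 0.9, lr = 2e-4,
                 epochs = 200L, max_steps = Inf),
    score = list(tissue_threshold = 200, dab_threshold = 80, cutoff = 65))
  if (!is.null(path)) {
    ext <- tolower(tools::file_ext(path))
    loaded <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
              else jsonlite::read_json(path, simplifyVector = TRUE)
    cfg <- modifyList(cfg, loaded)
  }
  modifyList(cfg, overrides)
}

# deterministic polynomial hash of the serialized configuration
paramHash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                        force = TRUE)
  h <- 0
  for (b in utf8ToInt(as.character(s))) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

pipePaths <- function(cfg) {
  wd <- cfg$workdir
  list(fixtures = file.path(wd, "fixtures"),
       shifts = file.path(wd, "shifts"),
       dataset = file.path(wd, "dataset"),
       model = file.path(wd, "model"),
       virtual = file.path(wd, "virtual_ck"),
       scores = file.path(wd, "scores"),
       manifest = file.path(wd, "run_manifest.json"),
       config = file.path(wd, "pipeline_config.json"))
}

pipeSlideIds <- function(paths) {
  truthCsv <- file.path(paths$fixtures, "truth.csv")
  if (!file.exists(truthCsv))
    stop("missing stage output: fixtures/truth.csv (run 'simulate')",
         call. = FALSE)
  read.csv(truthCsv, stringsAsFactors = FALSE)
}

#' Run the virtual-staining pipeline
#'
#' Executes the requested stages in their canonical order
#' (`simulate`, `register`, `tile`, `train`, `infer`, `score`,
#' `evaluate`) inside `config$workdir`, writing a run manifest that
#' records the parameter hash, seeds, per-stage status and every output
#' file. Stage dependencies are checked: a missing upstream artifact
#' raises an error naming the absent stage output. Rerunning with an
#' identical configuration and inputs reproduces identical outputs for
#' the deterministic stages.
#'
#' @param config a [pipelineConfig()] list.
#' @param stages character vector, subset of the stage names above.
#' @return the manifest list, invisibly.
#' @export
runPipeline <- function(config = pipelineConfig(),
                        stages = c("simulate", "register", "tile")) {
  order <- c("simulate", "register", "tile", "train", "infer", "score",
             "evaluate")
  stages <- order[order %in% stages]
  if (length(stages) == 0L) stop("no known stage requested", call. = FALSE)
  paths <- pipePaths(config)
  dir.create(config$workdir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(config, paths$config, auto_unbox = TRUE,
                       digits = NA, force = TRUE, pretty = TRUE)
  basis <- stainBasis(config$stain$basis)
  manifest <- list(parameter_hash = paramHash(config), seed = config$seed,
                   stages = list())
  for (st in stages) {
    t0 <- Sys.time()
    outputs <- switch(st,
      simulate = stageSimulate(config, paths, basis),
      register = stageRegister(config, paths, basis),
      tile = stageTile(config, paths, basis),
      train = stageTrain(config, paths, basis),
      infer = stageInfer(config, paths),
      score = stageScore(config, paths, basis),
      evaluate = stageEvaluate(config, paths))
    manifest$stages[[st]] <- list(
      status = "completed",
      seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2),
      outputs = outputs)
  }
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

stageSimulate <- function(cfg, paths, basis) {
  dir.create(paths$fixtures, showWarnings = FALSE, recursive = TRUE)
  sm <- cfg$simulate
  bench <- generateBenchmark(sm$n_slides, sm$stroma_fractions,
                             canvas = sm$canvas,
                             tissueMargin = sm$tissue_margin,
                             noiseSd = sm$noise_sd,
                             cutoff = cfg$score$cutoff,
                             seed = cfg$seed, basis = basis)
  outs <- character(0)
  for (sl in bench$slides) {
    heP <- file.path(paths$fixtures, paste0(sl$id, "_he.png"))
    ckP <- file.path(paths$fixtures, paste0(sl$id, "_ck.png"))
    hsP <- file.path(paths$fixtures, paste0(sl$id, "_hotspots.json"))
    writeRaster(sl$he, heP); writeRaster(sl$ck, ckP)
    writeHotspots(sl$hotspots, hsP)
    outs <- c(outs, heP, ckP, hsP)
  }
  truthP <- file.path(paths$fixtures, "truth.csv")
  write.csv(bench$truth, truthP, row.names = FALSE)
  c(outs, truthP)
}

stageRegister <- function(cfg, paths, basis) {
  dir.create(paths$shifts, showWarnings = FALSE, recursive = TRUE)
  rg <- cfg$register
  truth <- pipeSlideIds(paths)
  outs <- character(0)
  for (id in truth$slide_id) {
    he <- readRaster(file.path(paths$fixtures, paste0(id, "_he.png")))
    ck <- readRaster(file.path(paths$fixtures, paste0(id, "_ck.png")))
    gs <- estimateGlobalShift(he, ck, rg$downsample, basis, rg$block,
                              rg$offset, rg$min_area,
                              cfg$stain$c_max, cfg$stain$eps)
    lm <- estimateLocalShifts(he, ck, gs, rg$region, rg$patch, basis,
                              rg$block, rg$offset, rg$min_area,
                              whiteValue = cfg$tile$white_value,
                              whiteFrac = cfg$tile$white_frac,
                              cMax = cfg$stain$c_max, eps = cfg$stain$eps)
    out <- file.path(paths$shifts, paste0(id, "_shifts.json"))
    jsonlite::write_json(
      list(global = as.list(shiftComponents(gs)),
           region_size = lm@regionSize,
           regions = shiftTable(lm)),
      out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    outs <- c(outs, out)
  }
  outs
}

stageTile <- function(cfg, paths, basis) {
  dir.create(paths$dataset, showWarnings = FALSE, recursive = TRUE)
  tl <- cfg$tile
  truth <- pipeSlideIds(paths)
  allPairs <- list()
  for (id in truth$slide_id) {
    shiftP <- file.path(paths$shifts, paste0(id, "_shifts.json"))
    if (!file.exists(shiftP))
      stop("missing stage output: ", shiftP, " (run 'register')",
           call. = FALSE)
    sh <- jsonlite::read_json(shiftP, simplifyVector = TRUE)
    he <- readRaster(file.path(paths$fixtures, paste0(id, "_he.png")))
    ck <- readRaster(file.path(paths$fixtures, paste0(id, "_ck.png")))
    regs <- as.data.frame(sh$regions)
    for (r in seq_len(nrow(regs))) {
      o <- regs[r, ]
      rs <- sh$region_size
      rh <- min(rs, dim(he)[1] - o$origin_row)
      rw <- min(rs, dim(he)[2] - o$origin_col)
      ri <- (o$origin_row + 1):(o$origin_row + rh)
      ci <- (o$origin_col + 1):(o$origin_col + rw)
      ckAl <- translateImage(ck, -o$drow, -o$dcol)
      pairs <- tilePairs(he[ri, ci, , drop = FALSE],
                         ckAl[ri, ci, , drop = FALSE], tl$size,
                         origin = c(o$origin_row, o$origin_col),
                         basis = basis, whiteValue = tl$white_value,
                         whiteFrac = tl$white_frac,
                         dabThreshold = tl$dab_threshold,
                         dyedFrac = tl$dyed_frac,
                         cMax = cfg$stain$c_max, eps = cfg$stain$eps)
      pairs <- lapply(pairs, function(p) { p$slide <- id; p })
      allPairs <- c(allPairs, pairs)
    }
  }
  ds <- assembleTrainingSet(allPairs, tl$little_dyed_fraction,
                            seed = cfg$seed)
  dsP <- file.path(paths$dataset, "dataset.rds")
  saveRDS(ds, dsP)
  man <- do.call(rbind, lapply(patchPairs(ds), function(p)
    data.frame(origin_row = p$origin["row"], origin_col = p$origin["col"],
               little_dyed = p$little_dyed)))
  manP <- file.path(paths$dataset, "manifest.csv")
  write.csv(man, manP, row.names = FALSE)
  c(dsP, manP)
}

stageTrain <- function(cfg, paths, basis) {
  dsP <- file.path(paths$dataset, "dataset.rds")
  if (!file.exists(dsP))
    stop("missing stage output: ", dsP, " (run 'tile')", call. = FALSE)
  ds <- readRDS(dsP)
  tr <- cfg$train
  tc <- trainingConfig(tile = tr$tile, depth = tr$depth, nf = tr$nf,
                       ndf = tr$ndf, dLayers = tr$d_layers,
                       lambda1 = tr$lambda1, lambda2 = tr$lambda2,
                       lr = tr$lr, epochs = tr$epochs,
                       maxSteps = tr$max_steps, seed = cfg$seed,
                       basis = basis, eps = cfg$stain$eps)
  model <- trainVirtualStain(ds, tc)
  dir.create(paths$model, showWarnings = FALSE, recursive = TRUE)
  mP <- file.path(paths$model, "model.rds")
  saveRDS(model, mP)
  lP <- file.path(paths$model, "loss_log.json")
  jsonlite::write_json(lossLog(model), lP, digits = NA, pretty = TRUE)
  c(mP, lP)
}

pipeModel <- function(paths) {
  mP <- file.path(paths$model, "model.rds")
  if (!file.exists(mP))
    stop("missing stage output: ", mP, " (run 'train')", call. = FALSE)
  readRDS(mP)
}

stageInfer <- function(cfg, paths) {
  model <- pipeModel(paths)
  truth <- pipeSlideIds(paths)
  dir.create(paths$virtual, showWarnings = FALSE, recursive = TRUE)
  outs <- character(0)
  for (id in truth$slide_id) {
    he <- readRaster(file.path(paths$fixtures, paste0(id, "_he.png")))
    vck <- generateAndStitch(he, model)
    out <- file.path(paths$virtual, paste0(id, "_virtual_ck.png"))
    writeRaster(vck, out)
    outs <- c(outs, out)
  }
  outs
}

stageScore <- function(cfg, paths, basis) {
  model <- pipeModel(paths)
  truth <- pipeSlideIds(paths)
  sc <- cfg$score
  dir.create(paths$scores, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (id in truth$slide_id) {
    he <- readRaster(file.path(paths$fixtures, paste0(id, "_he.png")))
    hs <- readHotspots(file.path(paths$fixtures,
                                 paste0(id, "_hotspots.json")))
    s <- scoreWSI(he, model, hs, cutoff = sc$cutoff,
                  tissueThreshold = sc$tissue_threshold,
                  dabThreshold = sc$dab_threshold, basis = basis)
    rows[[id]] <- data.frame(slide_id = id, dtsr = dtsr(s),
                             tsr_class = tsrClass(s))
  }
  out <- file.path(paths$scores, "dtsr_scores.csv")
  write.csv(do.call(rbind, rows), out, row.names = FALSE)
  out
}

stageEvaluate <- function(cfg, paths) {
  scoresP <- file.path(paths$scores, "dtsr_scores.csv")
  if (!file.exists(scoresP))
    stop("missing stage output: ", scoresP, " (run 'score')",
         call. = FALSE)
  scores <- read.csv(scoresP, stringsAsFactors = FALSE)
  truth <- pipeSlideIds(paths)
  merged <- merge(scores, truth, by = "slide_id")
  tab <- buildContingency(merged$tsr_class.y,
                          sub("dTSR-", "", merged$tsr_class.x))
  rep <- agreementReport(tab)
  auc <- tryCatch(rocAuc(merged$dtsr, merged$tsr_class.y)$auc,
                  error = function(e) NA_real_)
  out <- file.path(cfg$workdir, "agreement_report.json")
  jsonlite::write_json(
    list(n = rep$n, counts = rep$counts,
         dtsr_marginal_pct = as.list(rep$dtsr_marginal_pct),
         p_o = rep$p_o, kappa = rep$kappa, auc = auc),
    out, auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  out
}
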