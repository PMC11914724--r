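## Single entry point wiring the stages behind subcommands, driven by one
## flat YAML config with a global seed. A thin Rscript wrapper
## (inst/scripts/ecgrisk-cli.R) exposes this from the shell.

.RUN_SECTIONS <- c("seed", "out", "simulate", "render", "digitize",
                   "prep", "train", "evaluate", "roundtrip")

.defaultRunConfig <- function() {
  list(seed = 1L, out = ".",
       simulate = list(nSubjects = 20L, noiseSd = 0.02),
       render = list(grid = TRUE, colour = TRUE, degrade = NULL),
       digitize = list(noGridFallback = FALSE),
       prep = list(asynchronous = FALSE, resolution = c(310L, 868L)),
       train = list(architecture = "residual1d", epochs = 30L, batchSize = 32L,
                    lr = 1e-3, patience = 5L),
       evaluate = list(bootstrap = 200L),
       roundtrip = list(n = 50L, degrade = NULL))
}

.mergeConfig <- function(base, user) {
  for (k in names(user)) {
    if (is.list(base[[k]]) && is.list(user[[k]])) {
      bad <- setdiff(names(user[[k]]), names(base[[k]]))
      .assert(length(bad) == 0, "unknown config key: %s.%s", k, bad[1])
      base[[k]] <- .mergeConfig(base[[k]], user[[k]])
    } else base[[k]] <- user[[k]]
  }
  base
}

#' Load and validate a run configuration
#'
#' @param config path to a YAML file, or a named list; unknown keys are
#'   rejected with an error naming the field.
#' @param seed,out optional overrides.
#' @return the resolved config list.
#' @export
loadRunConfig <- function(config = NULL, seed = NULL, out = NULL) {
  user <- if (is.character(config)) yaml::read_yaml(config) else config %||% list()
  bad <- setdiff(names(user), .RUN_SECTIONS)
  .assert(length(bad) == 0, "unknown config key: %s", bad[1])
  cfg <- .mergeConfig(.defaultRunConfig(), user)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(out)) cfg$out <- out
  cfg
}

.logStage <- function(fmt, ...) message(sprintf(paste0("[ecgrisk] ", fmt), ...))

#' Run a pipeline subcommand
#'
#' Subcommands: `simulate` (cohort CSVs + manifest), `render` (PNG pages
#' + truth sidecars for the simulated cohort), `digitize` (recover
#' signals from rendered PNGs), `prep-signals` / `prep-images` (model
#' inputs), `train` + `evaluate` (survival network on a synthetic
#' cohort, C-index report), `roundtrip` (digitization fidelity
#' benchmark). Every run logs the resolved seed and writes its artifacts
#' under `out`; identical config + seed reproduces identical outputs.
#'
#' @param subcommand one of the above.
#' @param config YAML path or list (see [loadRunConfig()]).
#' @param seed,out overrides for the config's seed and output directory.
#' @return invisibly, a list of the artifacts written.
#' @export
runPipeline <- function(subcommand, config = NULL, seed = NULL, out = NULL) {
  cfg <- loadRunConfig(config, seed, out)
  dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
  .logStage("subcommand '%s', seed %d, out '%s'", subcommand, cfg$seed, cfg$out)
  t0 <- Sys.time()
  grid <- intervalGrid()
  layout <- layoutSpec()
  res <- switch(subcommand,
    simulate = {
      coh <- generateCohort(cohortConfig(nSubjects = cfg$simulate$nSubjects,
                                         seed = cfg$seed,
                                         noiseSd = cfg$simulate$noiseSd), grid)
      dir.create(file.path(cfg$out, "signals"), showWarnings = FALSE)
      paths <- vapply(names(coh$signals), function(id) {
        writeEcgCsv(coh$signals[[id]], file.path(cfg$out, "signals", paste0(id, ".csv")))
      }, character(1))
      mf <- writeManifestCsv(coh$records, file.path(cfg$out, "manifest.csv"))
      .logStage("wrote %d signals + manifest", length(paths))
      list(signals = paths, manifest = mf)
    },
    render = {
      sigDir <- file.path(cfg$out, "signals")
      .assert(dir.exists(sigDir), "run 'simulate' first: %s not found", sigDir)
      style <- renderStyle(grid = cfg$render$grid, colour = cfg$render$colour)
      dir.create(file.path(cfg$out, "pages"), showWarnings = FALSE)
      files <- list.files(sigDir, pattern = "\\.csv$", full.names = TRUE)
      dg <- cfg$render$degrade
      paths <- vapply(files, function(f) {
        page <- renderPaperEcg(readEcgCsv(f), layout, style)
        if (!is.null(dg))
          page <- applyScanDegradation(page, rotation = dg$rotation %||% 0,
                                       blurSd = dg$blurSd %||% 0,
                                       noiseSd = dg$noiseSd %||% 0, seed = cfg$seed)
        writeRenderedPng(page, file.path(cfg$out, "pages",
                                         sub("\\.csv$", ".png", basename(f))))
      }, character(1))
      .logStage("rendered %d pages", length(paths))
      list(pages = paths)
    },
    digitize = {
      pageDir <- file.path(cfg$out, "pages")
      .assert(dir.exists(pageDir), "no pages/ directory under out")
      dir.create(file.path(cfg$out, "digitized"), showWarnings = FALSE)
      files <- list.files(pageDir, pattern = "\\.png$", full.names = TRUE)
      paths <- vapply(files, function(f) {
        page <- readRenderedPng(f, truthPath = NA)  # digitize blind
        dig <- digitizeEcg(page, layout)
        writeDigitizedCsv(dig, file.path(cfg$out, "digitized",
                                         sub("\\.png$", ".csv", basename(f))))
      }, character(1))
      .logStage("digitized %d pages", length(paths))
      list(digitized = paths)
    },
    `prep-signals` = {
      sigDir <- file.path(cfg$out, "signals")
      .assert(dir.exists(sigDir), "no signals/ directory under out")
      dir.create(file.path(cfg$out, "inputs1d"), showWarnings = FALSE)
      files <- list.files(sigDir, pattern = "\\.csv$", full.names = TRUE)
      paths <- vapply(files, function(f) {
        x <- prepareModelInput1D(readEcgCsv(f),
                                 asynchronous = isTRUE(cfg$prep$asynchronous),
                                 layout = layout)
        p <- file.path(cfg$out, "inputs1d", basename(f))
        write.csv(as.data.frame(x), p, row.names = FALSE)
        p
      }, character(1))
      .logStage("prepared %d 1D inputs", length(paths))
      list(inputs = paths)
    },
    `prep-images` = {
      pageDir <- file.path(cfg$out, "pages")
      .assert(dir.exists(pageDir), "no pages/ directory under out")
      ladder <- resolutionLadder()
      files <- list.files(pageDir, pattern = "\\.png$", full.names = TRUE)
      outPaths <- character(0)
      for (r in seq_len(nrow(ladder))) {
        sub <- file.path(cfg$out, sprintf("images_%dx%d", ladder[r, 1], ladder[r, 2]))
        dir.create(sub, showWarnings = FALSE)
        for (f in files) {
          img <- prepareModelInput2D(readRenderedPng(f), target = ladder[r, ],
                                     layout = layout)
          p <- file.path(sub, basename(f))
          png::writePNG(img, p)
          outPaths <- c(outPaths, p)
        }
      }
      .logStage("wrote %d images over %d resolutions", length(outPaths), nrow(ladder))
      list(images = outPaths)
    },
    train = ,
    evaluate = {
      coh <- generateCohort(cohortConfig(nSubjects = cfg$simulate$nSubjects,
                                         seed = cfg$seed,
                                         noiseSd = cfg$simulate$noiseSd), grid)
      inputs <- lapply(coh$signals, prepareModelInput1D)
      X <- .stackInputs(inputs, "residual1d")
      targets <- encodeTargets(coh$records$time, coh$records$event, grid)
      splits <- prepareCohort(coh$records, grid, seed = cfg$seed)
      model <- buildModel(netConfig("residual1d", K = nIntervals(grid),
                                    seed = cfg$seed, lr = cfg$train$lr,
                                    batchSize = cfg$train$batchSize,
                                    epochs = cfg$train$epochs,
                                    patience = cfg$train$patience), grid)
      model <- trainModel(model, X, targets, splits)
      mp <- file.path(cfg$out, "model.rds")
      saveRDS(model, mp)
      jsonlite::write_json(list(config = model@config,
                                grid = intervalBoundaries(grid),
                                history = model@history),
                           file.path(cfg$out, "model.json"), auto_unbox = TRUE)
      .logStage("trained %d epochs (best val %.4f)",
                length(model@history$valLoss), model@history$bestVal)
      artifacts <- list(model = mp)
      if (subcommand == "evaluate") {
        h <- predictHazards(model, .batchSlice(X, splits$test))
        ci <- concordanceIndex(hazardsToSurvival(h)$risk,
                               coh$records$time[splits$test],
                               coh$records$event[splits$test],
                               B = cfg$evaluate$bootstrap, seed = cfg$seed)
        rp <- file.path(cfg$out, "cindex.json")
        jsonlite::write_json(unclass(ci), rp, auto_unbox = TRUE, digits = NA)
        .logStage("test C-index %.4f", ci$estimate)
        artifacts$cindex <- rp
      }
      artifacts
    },
    roundtrip = {
      style <- renderStyle(grid = cfg$render$grid, colour = cfg$render$colour)
      rep <- roundtripBenchmark(n = cfg$roundtrip$n, seed = cfg$seed,
                                layout = layout, style = style,
                                degrade = cfg$roundtrip$degrade)
      rp <- file.path(cfg$out, "roundtrip.json")
      jsonlite::write_json(list(medianR = rep$medianR, meanMae = rep$meanMae,
                                rQuantiles = as.list(rep$rQuantiles),
                                nRecords = rep$nRecords, nFailed = rep$nFailed,
                                seed = rep$seed),
                           rp, auto_unbox = TRUE, digits = NA)
      .logStage("round trip: median r %.4f, MAE %.4f mV", rep$medianR, rep$meanMae)
      list(report = rp)
    },
    .stopf("unknown subcommand '%s'", subcommand))
  .logStage("done in %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
  invisible(res)
}
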