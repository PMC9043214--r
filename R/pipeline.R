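# End-to-end orchestration: calibrate -> extinction estimates -> vole/pollen
# reconstructions -> biomization -> diversity, from one validated config.

pipelineKeys <- c("seed", "out", "curve", "records", "calibrate",
  "extinction", "voletherm", "reconstruct", "biomize", "diversity")

#' Validate a pipeline configuration
#'
#' @param config a named list, or the path of a YAML file holding one.
#' @return the validated config list (defaults filled in).
#' @export
validateConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or YAML path",
    call. = FALSE)
  unknown <- setdiff(names(config), pipelineKeys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
      call. = FALSE)
  if (is.null(config$seed)) stop("config needs an explicit seed",
    call. = FALSE)
  if (is.null(config$out)) stop("config needs an output directory",
    call. = FALSE)
  paths <- c(config$curve$path, config$records$path,
    config$voletherm$counts, config$reconstruct$training,
    config$reconstruct$climate, config$reconstruct$fossil,
    config$biomize$counts, config$biomize$pft, config$biomize$biomes,
    config$diversity$counts)
  missing <- paths[!vapply(paths, file.exists, logical(1))]
  if (length(missing))
    stop("input file(s) not found: ", paste(missing, collapse = ", "),
      call. = FALSE)
  config
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in dependency order (calibration of the
#' dated records, extinction estimates per taxon, vole thermometer, pollen
#' transfer-function reconstruction, biomization, diversity), writing one CSV
#' per stage plus a JSON run manifest (input checksums, settings, seeds,
#' warnings, output checksums) into \code{config$out}. A stage error is
#' recorded in the manifest, its dependants are skipped, the completed
#' stages' outputs remain, and the returned status is nonzero.
#'
#' Identical (config, inputs, seed) give byte-identical outputs.
#'
#' @param config a named list or YAML path (see [validateConfig()]).
#' @return invisibly, a list: \code{status} (0 = all stages ok),
#'   \code{outputs}, \code{errors}, \code{warnings}, \code{manifest}.
#' @export
runPipeline <- function(config) {
  config <- validateConfig(config)
  outdir <- config$out
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  outputs <- character()
  errors <- list()
  warns <- character()
  grab <- function(expr, stage) {
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        errors[[stage]] <<- conditionMessage(e)
        NULL
      }),
      warning = function(w) {
        warns <<- c(warns, paste0(stage, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
  }

  curve <- NULL
  if (!is.null(config$curve))
    curve <- grab(readCalCurve(config$curve$path,
      config$curve$dialect %||% "simple"), "curve")

  records <- NULL
  if (!is.null(config$records))
    records <- grab(readDatedRecords(config$records$path), "records")

  # stage: calibration of every c14 record
  if (!is.null(records) && !is.null(curve) && !is.null(config$calibrate)) {
    tab <- grab(calibrateRecords(records, curve,
      level = config$calibrate$level %||% 0.95,
      gridStep = config$calibrate$gridStep %||% 1), "calibrate")
    if (!is.null(tab)) {
      f <- file.path(outdir, "calibrated.csv")
      write.csv(tab, f, row.names = FALSE)
      outputs <- c(outputs, f)
    }
  }

  # stage: extinction estimates per taxon (GRIWM and/or phase)
  if (!is.null(records) && !is.null(config$extinction)) {
    ext <- config$extinction
    taxa <- ext$taxa %||% unique(filterRecords(records)@taxon)
    methods <- ext$method %||% c("griwm", "phase")
    rows <- list()
    for (tx in taxa) {
      ser <- grab(recordsToSeries(records, tx, curve), "extinction")
      if (is.null(ser)) next
      if ("griwm" %in% methods && length(ser) >= 2) {
        g <- grab(griwm(ser, alpha = ext$alpha %||% 0.05,
          iterations = ext$iterations %||% 10000, seed = seed),
          "extinction")
        if (!is.null(g))
          rows[[paste0(tx, ".griwm")]] <- data.frame(taxon = tx,
            method = "griwm", estimate = g@terminal, lower = g@ciLower,
            upper = g@ciUpper)
      }
      if ("phase" %in% methods) {
        p <- grab(phaseFit(ser,
          iterations = ext$phase$iterations %||% 20000,
          burnin = ext$phase$burnin %||% 2000,
          chains = ext$phase$chains %||% 4, seed = seed), "extinction")
        if (!is.null(p)) {
          be <- boundaryEstimate(p)
          rows[[paste0(tx, ".phase")]] <- data.frame(taxon = tx,
            method = "phase", estimate = be["end", "median"],
            lower = be["end", "lower"], upper = be["end", "upper"])
          if (!p@converged)
            warns <- c(warns, paste0("extinction: phase model for ", tx,
              " has split R-hat > 1.1"))
        }
      }
    }
    if (length(rows)) {
      f <- file.path(outdir, "extinction.csv")
      write.csv(do.call(rbind, rows), f, row.names = FALSE)
      outputs <- c(outputs, f)
    }
  }

  # stage: vole thermometer
  if (!is.null(config$voletherm)) {
    vc <- grab(readCounts(config$voletherm$counts), "voletherm")
    if (!is.null(vc)) {
      tj <- grab(reconstructTJuly(vc, speciesOptima(),
        minCount = config$voletherm$minCount %||% 10), "voletherm")
      if (!is.null(tj)) {
        f <- file.path(outdir, "tjuly.csv")
        write.csv(data.frame(sample = rownames(countMatrix(vc)),
          tjuly = as.numeric(tj), flag = attr(tj, "flag")), f,
          row.names = FALSE)
        outputs <- c(outputs, f)
      }
    }
  }

  # stage: pollen transfer functions (WA-PLS with component selection + MAT)
  if (!is.null(config$reconstruct)) {
    rc <- config$reconstruct
    tr <- grab(readTrainingSet(rc$training, rc$climate, rc$climateVar),
      "reconstruct")
    fossil <- grab(readCounts(rc$fossil), "reconstruct")
    if (!is.null(tr) && !is.null(fossil)) {
      K <- rc$components %||% 5
      cv <- grab(looCrossvalidate(tr$counts, tr$climate, K,
        sqrtTransform = rc$sqrtTransform %||% TRUE), "reconstruct")
      if (!is.null(cv)) {
        comp <- as.integer(selectComponent(cv,
          rc$nRandomizations %||% 999, seed = seed))
        fit <- waplsFit(tr$counts, tr$climate, K,
          sqrtTransform = rc$sqrtTransform %||% TRUE)
        wp <- waplsPredict(fit, fossil, comp)
        mt <- matReconstruct(tr$counts, tr$climate, fossil,
          k = rc$k %||% 6, threshold = rc$threshold %||% Inf)
        f <- file.path(outdir, "reconstruction.csv")
        write.csv(data.frame(sample = wp$sample,
          wapls = wp$estimate, wapls_component = comp,
          mat = mt$estimate, mat_analogues = mt$nAnalogues,
          flag = paste0(wp$flag, mt$flag)), f, row.names = FALSE)
        outputs <- c(outputs, f)
        f2 <- file.path(outdir, "cv_statistics.csv")
        write.csv(cv@stats, f2, row.names = FALSE)
        outputs <- c(outputs, f2)
      }
    }
  }

  # stage: biomization
  if (!is.null(config$biomize)) {
    bz <- config$biomize
    bc <- grab(readCounts(bz$counts), "biomize")
    pft <- grab(readPftMatrix(bz$pft), "biomize")
    bm <- grab(readBiomeMatrix(bz$biomes), "biomize")
    if (!is.null(bc) && !is.null(pft) && !is.null(bm)) {
      tab <- grab(biomize(bc, pft, bm,
        threshold = bz$threshold %||% 0.5,
        apCutoff = bz$apCutoff %||% 70), "biomize")
      if (!is.null(tab)) {
        f <- file.path(outdir, "biomes.csv")
        write.csv(tab, f, row.names = FALSE)
        outputs <- c(outputs, f)
      }
    }
  }

  # stage: diversity
  if (!is.null(config$diversity)) {
    dv <- config$diversity
    dc <- grab(readCounts(dv$counts), "diversity")
    if (!is.null(dc)) {
      tab <- grab(diversitySummary(dc, dv$baseN %||% "auto",
        dv$index %||% "pielou"), "diversity")
      if (!is.null(tab)) {
        f <- file.path(outdir, "diversity.csv")
        write.csv(tab, f, row.names = FALSE)
        outputs <- c(outputs, f)
      }
    }
  }

  manifestPath <- file.path(outdir, "manifest.json")
  man <- writeManifest(manifestPath,
    inputs = Filter(Negate(is.null), list(
      curve = config$curve$path, records = config$records$path,
      voletherm = config$voletherm$counts,
      training = config$reconstruct$training,
      climate = config$reconstruct$climate,
      fossil = config$reconstruct$fossil,
      biomize_counts = config$biomize$counts,
      pft = config$biomize$pft, biomes = config$biomize$biomes,
      diversity = config$diversity$counts)),
    settings = c(config[setdiff(names(config), "out")],
      list(errors = errors)),
    outputs = outputs, warnings = warns)
  invisible(list(status = if (length(errors)) 1L else 0L,
    outputs = outputs, errors = errors, warnings = warns, manifest = man))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
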