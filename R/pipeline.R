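# End-to-end orchestration: sample -> classify -> tissue map -> area
# features -> deep features -> discretize -> merge -> cross-validated
# evaluation, with seeding, provenance and simple content-hash caching.

#' Build a pipeline run configuration
#'
#' A single global `seed` fans out to per-stage seeds through
#' [deriveSeed()], so each stage is independently reproducible.
#'
#' @param cohort a [syntheticCohortConfig()] (synthetic input mode), or
#'   NULL when `maps_dir`/`survival_csv` point at on-disk inputs.
#' @param maps_dir directory of tissue-map CSVs (file input mode).
#' @param survival_csv survival table CSV with columns
#'   patient_id,time,event (file input mode).
#' @param sampling_ratio patch sampling ratio (default 0.05).
#' @param tissues tissue set for deep features (default TUM, LYM, STR,
#'   MUC; BACK is not allowed).
#' @param morph_height,morph_width,connectivity morphology settings.
#' @param band around-tumor band width in patches.
#' @param deep [deepConvSurvConfig()] overrides as a named list.
#' @param classifier `"oracle"` (generator ground truth) or `"train"`.
#' @param max_patches_per_tissue training-set cap per extractor.
#' @param models survival models to evaluate.
#' @param k cross-validation folds.
#' @param nperm permutations for reported cutpoint p-values.
#' @param output_dir where artifacts are written (NULL = none).
#' @param cache reuse cached stage outputs keyed by config hash.
#' @param seed global run seed.
#' @return list of class `runConfig`.
#' @export
runConfig <- function(cohort = syntheticCohortConfig(), maps_dir = NULL,
                      survival_csv = NULL, sampling_ratio = 0.05,
                      tissues = c("TUM", "LYM", "STR", "MUC"),
                      morph_height = 5L, morph_width = 5L,
                      connectivity = 8L, band = 2L, deep = list(),
                      classifier = c("oracle", "train"),
                      max_patches_per_tissue = 300L,
                      models = survModels(), k = 5L, nperm = 1000L,
                      output_dir = NULL, cache = FALSE, seed = 1L) {
  classifier <- match.arg(classifier)
  if (length(tissues) == 0L || "BACK" %in% tissues)
    stop("tissue set must be non-empty and exclude BACK")
  if (!all(tissues %in% tissueClasses())) stop("invalid tissue in tissue set")
  structure(list(cohort = cohort, maps_dir = maps_dir,
                 survival_csv = survival_csv,
                 sampling_ratio = sampling_ratio, tissues = tissues,
                 morph_height = as.integer(morph_height),
                 morph_width = as.integer(morph_width),
                 connectivity = as.integer(connectivity),
                 band = as.integer(band), deep = deep,
                 classifier = classifier,
                 max_patches_per_tissue = as.integer(max_patches_per_tissue),
                 models = models, k = as.integer(k),
                 nperm = as.integer(nperm), output_dir = output_dir,
                 cache = cache, seed = as.integer(seed)),
            class = "runConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [runConfig()] arguments; the `cohort` key
#' holds [syntheticCohortConfig()] arguments.
#'
#' @param path YAML file path.
#' @return list of class `runConfig`.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("validation: config file not found: ", path)
  y <- yaml::read_yaml(path)
  if (!is.null(y$cohort)) y$cohort <- do.call(syntheticCohortConfig, y$cohort)
  do.call(runConfig, y)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s': %s", name, conditionMessage(e)), call. = FALSE)
  })
}

.cacheGet <- function(cfg, key, compute) {
  if (!isTRUE(cfg$cache) || is.null(cfg$output_dir)) return(compute())
  dir <- file.path(cfg$output_dir, "cache")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- file.path(dir, paste0(.configHash(cfg[setdiff(names(cfg),
                    c("output_dir", "cache"))]), "-", key, ".rds"))
  if (file.exists(fp)) return(readRDS(fp))
  val <- compute()
  saveRDS(val, fp)
  val
}

.writeCSVWithHash <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash=", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

# sample patches of one patient and generate their images
.samplePatientPatches <- function(map, cfg, intensity, patientSeed) {
  pos <- samplePatches(map, samplingConfig(cfg$sampling_ratio,
                                           seed = patientSeed))
  lab <- as.matrix(map)[cbind(pos$row, pos$col)]
  keep <- lab != "BACK"
  pos <- pos[keep, , drop = FALSE]
  lab <- lab[keep]
  co <- cfg$cohort
  imgs <- vector("list", length(lab))
  for (i in seq_along(lab)) {
    imgs[[i]] <- generatePatchImages(
      lab[i], 1L, edge = co$patch_pixels,
      seed = deriveSeed(patientSeed, paste0("img:", i)),
      noise_sd = co$texture_noise_sd, intensity = intensity)[[1]]
  }
  data.frame(row = pos$row, col = pos$col, true_class = lab,
             img = I(imgs), stringsAsFactors = FALSE)
}

#' Run the full pipeline
#'
#' Executes the end-to-end chain and returns a run report. All stage
#' errors are re-raised with the stage name; input validation happens
#' before any computation.
#'
#' @param cfg a [runConfig()].
#' @return list with elements `areaFeatures`, `histoFeatures`, `features`
#'   (merged matrix), `cutoffs` (full-cohort cutpoints with permutation
#'   p-values), `cv` (the [crossValidate()] table), `survival`,
#'   `extractors`, and `provenance` (config hash, seed, stage seeds,
#'   problem sizes).
#' @export
runPipeline <- function(cfg) {
  stopifnot(inherits(cfg, "runConfig"))
  # ---- validation (before any compute) ----
  fileMode <- is.null(cfg$cohort)
  if (fileMode) {
    if (is.null(cfg$maps_dir) || !dir.exists(cfg$maps_dir))
      stop("validation: maps_dir does not exist")
    if (is.null(cfg$survival_csv) || !file.exists(cfg$survival_csv))
      stop("validation: survival CSV not found")
  }
  hash <- .configHash(cfg[setdiff(names(cfg), c("output_dir", "cache"))])
  morph <- morphConfig(cfg$morph_height, cfg$morph_width, cfg$connectivity)
  outDir <- cfg$output_dir
  if (!is.null(outDir)) dir.create(outDir, recursive = TRUE,
                                   showWarnings = FALSE)

  # ---- inputs ----
  if (fileMode) {
    surv <- .stage("load", utils::read.csv(cfg$survival_csv,
                                           comment.char = "#"))
    if (!all(c("patient_id", "time", "event") %in% names(surv)))
      stop("validation: survival CSV needs patient_id,time,event")
    files <- list.files(cfg$maps_dir, pattern = "\\.csv$",
                        full.names = TRUE)
    files <- files[vapply(files, function(f)
      startsWith(readLines(f, n = 1L), "# slide_id="), logical(1))]
    maps <- .stage("load", lapply(files, readTissueMapCSV))
    names(maps) <- vapply(maps, slideID, character(1))
    maps <- maps[surv$patient_id]
    lp <- rep(0, nrow(surv))
    cohort <- NULL
  } else {
    cohort <- .cacheGet(cfg, "cohort",
      function() .stage("simulate", generateCohort(cfg$cohort)))
    maps <- tissueMaps(cohort)
    surv <- survivalData(cohort)
    lp <- groundTruth(cohort)$log_hazard
  }
  n <- nrow(surv)

  # ---- area features ----
  area <- .stage("area-features",
    .cacheGet(cfg, "area", function() cohortAreaFeatures(maps, morph,
                                                          cfg$band)))

  # ---- patch sampling + images (synthetic inputs only) ----
  doDeep <- !fileMode
  histo <- NULL; extractors <- list()
  if (doDeep) {
    shade <- if (cfg$cohort$texture_hazard_coef != 0 && sd(lp) > 0) {
      cfg$cohort$texture_hazard_coef * as.numeric(scale(lp))
    } else rep(0, n)
    sampled <- .stage("sample", lapply(seq_len(n), function(i) {
      .samplePatientPatches(maps[[i]], cfg, shade[i],
                            deriveSeed(cfg$seed, paste0("sample:", i)))
    }))
    # ---- classify sampled patches ----
    clf <- .stage("classify", {
      if (cfg$classifier == "oracle") {
        oracleClassifier(maps)
      } else {
        lib <- list(); libLab <- character()
        for (tc in setdiff(tissueClasses(), "BACK")) {
          ims <- generatePatchImages(tc, 60L, edge = cfg$cohort$patch_pixels,
            seed = deriveSeed(cfg$seed, paste0("lib:", tc)),
            noise_sd = cfg$cohort$texture_noise_sd)
          lib <- c(lib, ims)
          libLab <- c(libLab, rep(tc, length(ims)))
        }
        trainPatchClassifier(lib, libLab,
                             seed = deriveSeed(cfg$seed, "classifier"))
      }
    })
    predClass <- .stage("classify", lapply(seq_len(n), function(i) {
      sp <- sampled[[i]]
      if (cfg$classifier == "oracle") sp$true_class
      else classifyPatches(clf, sp$img)$class
    }))

    # ---- deep features ----
    deepCfg <- do.call(deepConvSurvConfig, utils::modifyList(
      list(edge = cfg$cohort$patch_pixels,
           seed = deriveSeed(cfg$seed, "extractor")), cfg$deep))
    histo <- .stage("deep-features", .cacheGet(cfg, "deep", function() {
      blocks <- list()
      nTotal <- vapply(predClass, length, integer(1))  # non-BACK sampled
      for (tt in cfg$tissues) {
        patIdx <- list(); imgs <- list()
        for (i in seq_len(n)) {
          sel <- which(predClass[[i]] == tt)
          if (length(sel)) {
            imgs <- c(imgs, sampled[[i]]$img[sel])
            patIdx <- c(patIdx, list(rep(i, length(sel))))
          }
        }
        pat <- unlist(patIdx)
        if (length(imgs) == 0L) {
          blocks[[tt]] <- matrix(0, n, deepCfg$fcWidth)
          next
        }
        trIdx <- seq_along(imgs)
        if (length(trIdx) > cfg$max_patches_per_tissue) {
          trIdx <- .withSeed(deriveSeed(cfg$seed, paste0("cap:", tt)),
                             sort(sample(trIdx, cfg$max_patches_per_tissue)))
        }
        ext <- trainTissueExtractor(
          imgs[trIdx], surv$time[pat[trIdx]], surv$event[pat[trIdx]],
          cfg = structure(utils::modifyList(unclass(deepCfg),
            list(seed = deriveSeed(cfg$seed, paste0("extractor:", tt)))),
            class = "deepConvSurvConfig"),
          patient_id = surv$patient_id[pat[trIdx]])
        ext@tissue <- tt
        extractors[[tt]] <<- ext
        feats <- patchFeatures(ext, imgs)
        block <- t(vapply(seq_len(n), function(i) {
          sel <- pat == i
          if (nTotal[i] == 0L) return(numeric(deepCfg$fcWidth))
          aggregateTissue(feats[sel, , drop = FALSE], sum(sel), nTotal[i],
                          width = deepCfg$fcWidth)
        }, numeric(deepCfg$fcWidth)))
        blocks[[tt]] <- block
      }
      out <- do.call(cbind, blocks[cfg$tissues])
      colnames(out) <- unlist(lapply(cfg$tissues, function(tt)
        sprintf("%s_%d", tt, seq_len(deepCfg$fcWidth))))
      out
    }))
  }

  # ---- merge + cross-validated evaluation ----
  areaX <- as.matrix(area[, areaFeatureNames()])
  X <- if (is.null(histo)) areaX
       else mergeFeatures(histo, areaX, histoWidth = ncol(histo))
  cv <- .stage("evaluate",
    crossValidate(X, surv, models = cfg$models, k = cfg$k,
                  seed = deriveSeed(cfg$seed, "cv"),
                  discretizeCols = areaFeatureNames()))

  # ---- full-cohort cutpoints for reporting ----
  cutoffs <- .stage("discretize", lapply(areaFeatureNames(), function(fn) {
    tryCatch(maxstatCutoff(area[[fn]], surv$time, surv$event,
                           nperm = cfg$nperm,
                           seed = deriveSeed(cfg$seed, paste0("perm:", fn))),
             error = function(e) NULL)
  }))
  names(cutoffs) <- areaFeatureNames()

  report <- list(areaFeatures = area, histoFeatures = histo, features = X,
                 cutoffs = cutoffs, cv = cv, survival = surv,
                 extractors = extractors,
                 provenance = list(config_hash = hash, seed = cfg$seed,
                                   n_patients = n,
                                   feature_width = ncol(X),
                                   models = cfg$models, k = cfg$k))

  # ---- artifacts ----
  if (!is.null(outDir)) {
    .writeCSVWithHash(area, file.path(outDir, "area_features.csv"), hash)
    .writeCSVWithHash(cbind(patient_id = surv$patient_id, as.data.frame(X)),
                      file.path(outDir, "features.csv"), hash)
    cvOut <- cv; attr(cvOut, "folds") <- NULL; attr(cvOut, "cutoffs") <- NULL
    .writeCSVWithHash(cvOut, file.path(outDir, "cv_results.csv"), hash)
    cutJson <- lapply(cutoffs, function(co) if (is.null(co)) NULL else
      co[c("cutoff", "statistic", "p.value", "n.high", "n.low")])
    jsonlite::write_json(list(config_hash = hash, cutoffs = cutJson),
                         file.path(outDir, "cutoffs.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    for (fn in areaFeatureNames()) {
      co <- cutoffs[[fn]]
      if (is.null(co)) next
      grp <- discretize(area[[fn]], co$cutoff)
      for (gv in unique(grp)) {
        km <- kaplanMeier(surv$time[grp == gv], surv$event[grp == gv])
        .writeCSVWithHash(as.data.frame(km),
          file.path(outDir, sprintf("km_%s_group%d.csv", fn, gv)), hash)
      }
    }
    jsonlite::write_json(report$provenance,
                         file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  report
}
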