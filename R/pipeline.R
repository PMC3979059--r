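## End-to-end orchestration: volumes + YAML/JSON manifest in, per-sample
## morphometry/erosion CSV, group statistics CSV and provenance JSON out.
##
## Stage order per sample: read -> standard Gaussian filter -> fixed
## threshold segmentation -> ROI construction -> morphometry -> erosion
## scores; then group statistics over all samples. A failing sample is
## reported with its id and stage and the run continues. Numeric CSV
## output uses a fixed 10-significant-digit representation so identical
## configurations reproduce identical bytes.

.fmtNum <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 10, format = "g"))
}

.writeCsvFixed <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  for (j in which(num)) df[[j]] <- .fmtNum(df[[j]])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
}

# rbind with column union (missing columns filled with NA)
.rbindFill <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in setdiff(names(b), names(a))) a[[nm]] <- NA
  for (nm in setdiff(names(a), names(b))) b[[nm]] <- NA
  rbind(a, b[names(a)])
}

.loadConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    cfg <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE)
    else yaml::read_yaml(config)
    attr(cfg, "baseDir") <- dirname(normalizePath(config))
    cfg
  } else config
}

.cfgDefaults <- function(cfg) {
  if (is.null(cfg$filter)) cfg$filter <- list(sigma = 0.8, support = 1L)
  if (is.null(cfg$strong_filter))
    cfg$strong_filter <- list(sigma = 2.5, support = 5L)
  if (is.null(cfg$segment)) cfg$segment <- list(threshold = 500)
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$output_dir)) cfg$output_dir <- "results"
  cfg
}

.buildRoi <- function(vol, roi, baseDir) {
  type <- roi$type
  if (identical(type, "slab")) {
    slabRoi(vol, roi$landmark_slice, roi$offset_mm, roi$extent_mm,
            direction = if (is.null(roi$direction)) 1L else roi$direction,
            label = roi$label)
  } else if (identical(type, "joint")) {
    jointRoi(vol, roi$center_slice, roi$n_slices, label = roi$label)
  } else if (identical(type, "mask")) {
    m <- readVolume(file.path(baseDir, roi$mask))
    RoiMask(volData(m), voxelSize(m), label = roi$label)
  } else stop("unknown ROI type: ", type)
}

.measureRoi <- function(raw, filtered, bone, roi, roiDef, cfg) {
  measure <- if (is.null(roiDef$measure)) "joint" else roiDef$measure
  thr <- cfg$segment$threshold
  if (measure == "trabecular") {
    slices <- which(apply(volData(roi), 1, any))
    cortex <- cortexMask(.maskWithin(bone, roi))
    comp <- trabecularMask(cortex, slices = slices, label = roiLabel(roi))
    comp@data <- comp@data & volData(roi)
    morphometry(filtered, bone, comp, threshold = thr,
                kind = "trabecular")
  } else if (measure == "cortical") {
    morphometry(filtered, bone, roi, threshold = thr, kind = "cortical")
  } else if (measure == "erosion") {
    es <- smoothnessEstimator(
      raw, roi,
      standard = filterParams(cfg$filter$sigma, cfg$filter$support),
      strong = filterParams(cfg$strong_filter$sigma,
                            cfg$strong_filter$support),
      seg = segmentationParams(thr))
    data.frame(label = es$label, BV = es$BV, TV = totalVolume(roi),
               BVTV = es$BV / totalVolume(roi), BS = es$BS,
               TbTh = NA_real_, CtTh = NA_real_,
               marrow_volume = NA_real_,
               total_diaphysis_volume = NA_real_,
               BS_over_BV = es$BS_over_BV, BS_smooth = es$BS_smooth,
               smoothness = es$smoothness)
  } else {
    morphometry(filtered, bone, roi, threshold = thr, kind = "joint")
  }
}

#' Run the full analysis pipeline
#'
#' Executes the per-sample stages (read, standard filter, segmentation,
#' ROI construction, morphometry, erosion scores) for every sample in the
#' manifest, then group statistics per (ROI label, measurement), writing
#' \code{morphometry.csv}, \code{stats.csv}, \code{provenance.json} and
#' \code{run.log} to the configured output directory.
#'
#' @param config path to a YAML/JSON manifest (see [writeStudy()] for the
#'   layout) or an equivalent list.
#' @param quiet suppress progress messages.
#' @return Invisibly, a list: \code{results} (per-sample data.frame),
#'   \code{stats}, \code{failed} (per-sample error records), \code{ok},
#'   and output file paths.
#' @export
runPipeline <- function(config, quiet = FALSE) {
  cfg <- .cfgDefaults(.loadConfig(config))
  baseDir <- attr(cfg, "baseDir")
  if (is.null(baseDir)) baseDir <- "."
  outDir <- cfg$output_dir
  if (!grepl("^(/|[A-Za-z]:)", outDir))
    outDir <- file.path(baseDir, outDir)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  logPath <- file.path(outDir, "run.log")
  logCon <- file(logPath, "w")
  on.exit(close(logCon))
  logMsg <- function(level, ...) {
    line <- paste0("[", level, "] ", ...)
    writeLines(line, logCon)
    if (!quiet) message(line)
  }
  fp <- filterParams(cfg$filter$sigma, cfg$filter$support)
  sp <- segmentationParams(cfg$segment$threshold)

  rows <- NULL
  failed <- NULL
  hashes <- list()
  for (s in cfg$samples) {
    stage <- "read"
    res <- tryCatch({
      vpath <- file.path(baseDir, s$volume)
      raw <- readVolume(vpath)
      hashes[[s$id]] <- unname(tools::md5sum(vpath))
      stage <- "filter"
      filtered <- gaussianFilter(raw, fp)
      stage <- "segment"
      bone <- segmentBone(filtered, sp)
      out <- NULL
      for (roiDef in s$rois) {
        stage <- paste0("roi:", roiDef$label)
        roi <- .buildRoi(raw, roiDef, baseDir)
        stage <- paste0("measure:", roiDef$label)
        r <- .measureRoi(raw, filtered, bone, roi, roiDef, cfg)
        r <- cbind(data.frame(sample = s$id, group = s$group), r)
        out <- .rbindFill(out, r)
      }
      out
    }, error = function(e) {
      logMsg("ERROR", "sample ", s$id, " failed at stage '", stage,
             "': ", conditionMessage(e))
      structure(list(sample = s$id, stage = stage,
                     message = conditionMessage(e)), class = "om_fail")
    })
    if (inherits(res, "om_fail")) {
      failed <- c(failed, list(res))
    } else {
      rows <- .rbindFill(rows, res)
      logMsg("INFO", "sample ", s$id, " done (",
             nrow(res), " ROI rows)")
    }
  }
  if (!is.null(rows)) {
    ord <- order(match(rows$sample, vapply(cfg$samples, `[[`, "", "id")),
                 rows$label)
    rows <- rows[ord, ]
  }

  statsRows <- NULL
  if (!is.null(rows) && length(unique(rows$group)) >= 2) {
    measures <- c("BV", "TV", "BVTV", "BS", "TbTh", "CtTh",
                  "marrow_volume", "total_diaphysis_volume",
                  "BS_over_BV", "smoothness")
    for (lab in unique(rows$label)) {
      sub <- rows[rows$label == lab, ]
      for (mv in intersect(measures, names(sub))) {
        vals <- sub[[mv]]
        keep <- !is.na(vals)
        if (!any(keep)) next
        tb <- table(sub$group[keep])
        if (length(tb) < 2 || any(tb < 2)) next
        st <- tryCatch(anovaTukey(vals[keep], sub$group[keep]),
                       error = function(e) NULL)
        if (is.null(st)) next
        pw <- st@pairwise
        statsRows <- rbind(statsRows, data.frame(
          label = lab, measurement = mv, F = st@statistic,
          p = st@pValue,
          pair = paste(pw$groupA, pw$groupB, sep = " vs "),
          p_adj = pw$pAdj, significant = pw$significant))
      }
    }
  }

  resPath <- file.path(outDir, "morphometry.csv")
  if (!is.null(rows)) .writeCsvFixed(rows, resPath)
  statsPath <- file.path(outDir, "stats.csv")
  if (is.null(statsRows))
    statsRows <- data.frame(label = character(), measurement = character(),
                            F = numeric(), p = numeric(),
                            pair = character(), p_adj = numeric(),
                            significant = logical())
  .writeCsvFixed(statsRows, statsPath)

  prov <- list(
    package = "osteomorph",
    version = as.character(packageVersion("osteomorph")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    parameters = list(filter = cfg$filter,
                      strong_filter = cfg$strong_filter,
                      segment = cfg$segment),
    input_hashes = hashes,
    failed_samples = lapply(failed, function(f)
      list(sample = f$sample, stage = f$stage, message = f$message)))
  provPath <- file.path(outDir, "provenance.json")
  jsonlite::write_json(prov, provPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  logMsg("INFO", "run complete: ", length(cfg$samples) - length(failed),
         "/", length(cfg$samples), " samples ok")
  invisible(list(results = rows, stats = statsRows, failed = failed,
                 ok = length(failed) == 0,
                 outputs = list(morphometry = resPath, stats = statsPath,
                                provenance = provPath, log = logPath)))
}

## header-only dimension probe for the geometry checks in validateConfig
.probeDims <- function(path) {
  fmt <- .volFormat(path)
  if (fmt %in% c("mha", "mhd")) {
    con <- file(path, "rb"); on.exit(close(con))
    repeat {
      line <- readLines(con, n = 1L)
      if (!length(line)) return(NULL)
      if (grepl("^DimSize", line))
        return(rev(as.integer(
          strsplit(trimws(sub(".*=", "", line)), "\\s+")[[1]])))
    }
  } else if (fmt == "nrrd") {
    con <- file(path, "rb"); on.exit(close(con))
    repeat {
      line <- readLines(con, n = 1L)
      if (!length(line) || line == "") return(NULL)
      if (grepl("^sizes:", line))
        return(rev(as.integer(
          strsplit(trimws(sub("^sizes:", "", line)), "\\s+")[[1]])))
    }
  } else NULL
}

#' Validate a pipeline configuration without computing
#'
#' Reports missing files, incomplete ROI definitions and out-of-range
#' parameters; slab geometry is probed against the volume header where
#' the format allows it.
#'
#' @param config manifest path or list (as for [runPipeline()]).
#' @return List with \code{ok} (logical), \code{problems} and
#'   \code{warnings} (character vectors).
#' @export
validateConfig <- function(config) {
  cfg <- .cfgDefaults(.loadConfig(config))
  baseDir <- attr(cfg, "baseDir")
  if (is.null(baseDir)) baseDir <- "."
  problems <- character()
  warnings <- character()
  if (cfg$filter$sigma < 0)
    problems <- c(problems, "filter.sigma is negative")
  if (cfg$filter$support < 0)
    problems <- c(problems, "filter.support is negative")
  if (cfg$strong_filter$sigma < 0)
    problems <- c(problems, "strong_filter.sigma is negative")
  if (!is.finite(cfg$segment$threshold))
    problems <- c(problems, "segment.threshold is not finite")
  if (!length(cfg$samples))
    problems <- c(problems, "no samples in manifest")
  for (s in cfg$samples) {
    sid <- if (is.null(s$id)) "<unnamed>" else s$id
    if (is.null(s$volume)) {
      problems <- c(problems, paste0("sample ", sid, ": no volume path"))
      next
    }
    vpath <- file.path(baseDir, s$volume)
    if (!file.exists(vpath)) {
      problems <- c(problems,
                    paste0("sample ", sid, ": missing file ", s$volume))
      next
    }
    dims <- .probeDims(vpath)
    for (roi in s$rois) {
      if (is.null(roi$label))
        problems <- c(problems, paste0("sample ", sid, ": ROI without label"))
      if (identical(roi$type, "slab")) {
        need <- c("landmark_slice", "offset_mm", "extent_mm")
        miss <- need[!need %in% names(roi)]
        if (length(miss)) {
          problems <- c(problems, paste0(
            "sample ", sid, ", ROI ", roi$label, ": missing ",
            paste(miss, collapse = ", ")))
        } else if (!is.null(dims)) {
          rng <- tryCatch(slabToSlices(
            roi$landmark_slice, roi$offset_mm, roi$extent_mm,
            cfg$voxel_size_um %||% 6,
            direction = roi$direction %||% 1L, nSlices = dims[1]),
            error = function(e) conditionMessage(e))
          if (is.character(rng))
            warnings <- c(warnings, paste0(
              "sample ", sid, ", ROI ", roi$label, ": ", rng))
        }
      } else if (identical(roi$type, "joint")) {
        if (is.null(roi$center_slice) || is.null(roi$n_slices))
          problems <- c(problems, paste0(
            "sample ", sid, ", ROI ", roi$label,
            ": missing center_slice/n_slices"))
        else if (!is.null(dims) &&
                 (roi$center_slice - floor(roi$n_slices / 2) < 1 ||
                  roi$center_slice - floor(roi$n_slices / 2) +
                    roi$n_slices - 1 > dims[1]))
          warnings <- c(warnings, paste0(
            "sample ", sid, ", ROI ", roi$label,
            ": joint slab exceeds volume bounds"))
      }
    }
  }
  list(ok = length(problems) == 0, problems = problems,
       warnings = warnings)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
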