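## Volume input/output.
##
## Supported formats: MetaImage (.mha single file, .mhd + .raw pair), NRRD
## (.nrrd, raw encoding), and multipage TIFF (.tif/.tiff) or a directory of
## single-slice TIFFs. MetaImage/NRRD carry the voxel spacing in their
## headers (in mm); TIFF relies on a JSON sidecar written next to the file.
## Densities are stored as IEEE doubles in MetaImage/NRRD (lossless
## round-trip) and as 32-bit floats rescaled to [0, 1] (or 16-bit integers)
## with a declared offset/scale in TIFF. Masks are stored as 8-bit {0, 1}.
##
## Grid convention: the in-memory array is (slice, row, column) with the
## tomogram stack along axis 1; on disk the raw stream is written
## column-fastest, slice-slowest (x y z), the usual MetaImage/NRRD layout.

.volFormat <- function(path) {
  low <- tolower(path)
  if (grepl("\\.mha$", low)) return("mha")
  if (grepl("\\.mhd$", low)) return("mhd")
  if (grepl("\\.nrrd$", low)) return("nrrd")
  if (grepl("\\.tiff?$", low)) return("tiff")
  "tiffdir"
}

.sidecarPath <- function(path, format) {
  if (format == "tiffdir") file.path(path, "volume.json")
  else paste0(path, ".json")
}

.readSidecar <- function(path, format) {
  sp <- .sidecarPath(path, format)
  if (file.exists(sp)) jsonlite::read_json(sp, simplifyVector = TRUE)
  else NULL
}

.writeSidecar <- function(path, format, meta) {
  jsonlite::write_json(meta, .sidecarPath(path, format),
                       auto_unbox = TRUE, digits = NA)
}

## disk (x, y, z) = (col, row, slice) -> memory (slice, row, col)
.diskToMem <- function(v, dimsDisk) {
  a <- array(v, dimsDisk)          # col, row, slice
  aperm(a, c(3, 2, 1))
}
.memToDisk <- function(arr) as.vector(aperm(arr, c(3, 2, 1)))

#' Read a calibrated volume or mask
#'
#' Reads MetaImage (.mha/.mhd), NRRD (.nrrd), multipage TIFF, or a
#' directory of single-slice TIFFs. MetaImage and NRRD spacing metadata
#' (mm) is converted to micrometres and checked for isotropy; TIFF voxel
#' size comes from the JSON sidecar or the \code{voxelSize} argument.
#'
#' @param path file (or TIFF-stack directory) to read.
#' @param voxelSize isotropic voxel size in micrometres; may be omitted
#'   when the format (or sidecar) carries spacing metadata.
#' @param name identifier for the volume; defaults to the file name.
#' @return A \linkS4class{DensityVolume}, or a \linkS4class{BinaryVolume}
#'   when the file holds a binary mask.
#' @seealso [writeVolume()]
#' @export
readVolume <- function(path, voxelSize = NULL, name = NULL) {
  if (!file.exists(path))
    stop("file not found: ", path)
  format <- .volFormat(path)
  meta <- .readSidecar(path, format)
  res <- switch(format,
    mha  = .readMeta(path),
    mhd  = .readMeta(path),
    nrrd = .readNrrd(path),
    tiff = .readTiffStack(path, multipage = TRUE, meta = meta),
    tiffdir = .readTiffStack(path, multipage = FALSE, meta = meta))
  vs <- res$voxelSize
  if (!is.null(meta$voxel_size_um)) vs <- meta$voxel_size_um
  if (!is.null(voxelSize)) vs <- voxelSize
  if (is.null(vs))
    stop("voxel size missing: not in file metadata and not supplied")
  kind <- res$kind
  if (!is.null(meta$kind)) kind <- meta$kind
  if (is.null(name)) {
    name <- if (!is.null(meta$name) && nzchar(meta$name)) meta$name
            else basename(path)
  }
  if (identical(kind, "mask"))
    BinaryVolume(array(res$arr != 0, dim(res$arr)), vs, name = name)
  else
    DensityVolume(res$arr, vs, name = name)
}

#' Write a calibrated volume or mask
#'
#' Writes the format implied by the file extension (.mha, .mhd + .raw,
#' .nrrd, .tif/.tiff multipage) or a directory of single-slice TIFFs, plus
#' a JSON sidecar with the name, voxel size and density units. MetaImage
#' and NRRD store doubles (masks: 8-bit \{0, 1\}) and round-trip losslessly
#' through [readVolume()]; TIFF densities are rescaled to [0, 1] and
#' stored as 32-bit floats (or \code{tiffBits = 16} integers) with the
#' offset/scale declared in the sidecar.
#'
#' @param vol a \linkS4class{DensityVolume} or \linkS4class{BinaryVolume}.
#' @param path destination; parent directory must exist.
#' @param tiffBits 32 (float, default) or 16 (integer) for TIFF densities.
#' @return Invisibly, \code{path}.
#' @export
writeVolume <- function(vol, path, tiffBits = 32L) {
  stopifnot(is(vol, "DensityVolume") || is(vol, "BinaryVolume"))
  format <- .volFormat(path)
  if (format != "tiffdir" && !dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  isMask <- is(vol, "BinaryVolume")
  meta <- list(name = volName(vol), voxel_size_um = voxelSize(vol),
               units = if (isMask) "binary" else "mg HA/cm^3",
               kind = if (isMask) "mask" else "density")
  switch(format,
    mha  = .writeMeta(vol, path, local = TRUE),
    mhd  = .writeMeta(vol, path, local = FALSE),
    nrrd = .writeNrrd(vol, path),
    tiff = { meta <- c(meta, .writeTiffStack(vol, path, multipage = TRUE,
                                             bits = tiffBits)) },
    tiffdir = { meta <- c(meta, .writeTiffStack(vol, path,
                                                multipage = FALSE,
                                                bits = tiffBits)) })
  .writeSidecar(path, format, meta)
  invisible(path)
}

## ---- MetaImage -----------------------------------------------------------

.metaTypes <- c(MET_DOUBLE = "double", MET_FLOAT = "float",
                MET_SHORT = "short", MET_USHORT = "ushort",
                MET_UCHAR = "uchar")

.readRawVals <- function(con, type, n) {
  switch(type,
    double = readBin(con, "double", n, size = 8, endian = "little"),
    float  = readBin(con, "double", n, size = 4, endian = "little"),
    short  = readBin(con, "integer", n, size = 2, signed = TRUE,
                     endian = "little"),
    ushort = readBin(con, "integer", n, size = 2, signed = FALSE,
                     endian = "little"),
    uchar  = as.numeric(readBin(con, "integer", n, size = 1,
                                signed = FALSE)))
}

.checkIsotropic <- function(spacingMm, path) {
  if (max(spacingMm) - min(spacingMm) > 1e-9 * max(spacingMm))
    stop("anisotropic voxel spacing in ", path, " (",
         paste(spacingMm, collapse = " x "),
         " mm); only isotropic volumes are supported")
  spacingMm[1] * 1000
}

.readMeta <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line)) stop("truncated MetaImage header in ", path)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    hdr[[key]] <- trimws(paste(kv[-1], collapse = "="))
    if (key == "ElementDataFile") break
  }
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  spacing <- as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]])
  type <- .metaTypes[[hdr$ElementType]]
  if (is.null(type)) stop("unsupported ElementType: ", hdr$ElementType)
  n <- prod(dims)
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    vals <- .readRawVals(con, type, n)
  } else {
    rawPath <- file.path(dirname(path), hdr$ElementDataFile)
    if (!file.exists(rawPath)) stop("raw data file not found: ", rawPath)
    rcon <- file(rawPath, "rb")
    on.exit(close(rcon), add = TRUE)
    vals <- .readRawVals(rcon, type, n)
  }
  list(arr = .diskToMem(vals, dims),
       voxelSize = .checkIsotropic(spacing, path),
       kind = if (type == "uchar") "mask" else "density")
}

.writeMeta <- function(vol, path, local = TRUE) {
  isMask <- is(vol, "BinaryVolume")
  arr <- volData(vol)
  dims <- rev(dim(arr))   # disk order: col row slice
  sp <- voxelSize(vol) / 1000
  rawName <- if (local) "LOCAL" else
    paste0(sub("\\.mhd$", "", basename(path), ignore.case = TRUE), ".raw")
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           paste("DimSize =", paste(dims, collapse = " ")),
           paste("ElementSpacing =",
                 paste(sprintf("%.15g", rep(sp, 3)), collapse = " ")),
           paste("ElementType =", if (isMask) "MET_UCHAR" else "MET_DOUBLE"),
           paste("ElementDataFile =", rawName))
  v <- .memToDisk(arr)
  con <- file(path, "wb")
  writeLines(hdr, con)
  if (local) {
    .writeRawVals(con, v, isMask)
    close(con)
  } else {
    close(con)
    rcon <- file(file.path(dirname(path), rawName), "wb")
    .writeRawVals(rcon, v, isMask)
    close(rcon)
  }
}

.writeRawVals <- function(con, v, isMask) {
  if (isMask) writeBin(as.integer(v), con, size = 1)
  else writeBin(as.numeric(v), con, size = 8, endian = "little")
}

## ---- NRRD ----------------------------------------------------------------

.nrrdTypes <- c(double = "double", float = "float", short = "short",
                `unsigned short` = "ushort", uchar = "uchar",
                `unsigned char` = "uchar")

.readNrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD", magic)) stop("not an NRRD file: ", path)
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line) || line == "") break
    if (grepl("^#", line)) next
    kv <- strsplit(line, ":", fixed = TRUE)[[1]]
    hdr[[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = ":"))
  }
  if (!identical(hdr$encoding, "raw"))
    stop("unsupported NRRD encoding: ", hdr$encoding)
  dims <- as.integer(strsplit(hdr$sizes, "\\s+")[[1]])
  type <- .nrrdTypes[[hdr$type]]
  if (is.null(type)) stop("unsupported NRRD type: ", hdr$type)
  spacing <- if (!is.null(hdr$spacings))
    as.numeric(strsplit(hdr$spacings, "\\s+")[[1]]) else NULL
  vals <- .readRawVals(con, type, prod(dims))
  list(arr = .diskToMem(vals, dims),
       voxelSize = if (is.null(spacing)) NULL
                   else .checkIsotropic(spacing, path),
       kind = if (type == "uchar") "mask" else "density")
}

.writeNrrd <- function(vol, path) {
  isMask <- is(vol, "BinaryVolume")
  arr <- volData(vol)
  dims <- rev(dim(arr))
  sp <- voxelSize(vol) / 1000
  hdr <- c("NRRD0004",
           paste("type:", if (isMask) "uchar" else "double"),
           "dimension: 3",
           paste("sizes:", paste(dims, collapse = " ")),
           paste("spacings:",
                 paste(sprintf("%.15g", rep(sp, 3)), collapse = " ")),
           "endian: little", "encoding: raw", "")
  con <- file(path, "wb")
  writeLines(hdr, con)
  .writeRawVals(con, .memToDisk(arr), isMask)
  close(con)
}

## ---- TIFF ----------------------------------------------------------------

.readTiffStack <- function(path, multipage, meta) {
  if (multipage) {
    slices <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(slices)) slices <- list(slices)
  } else {
    files <- sort(list.files(path, pattern = "\\.tiff?$", full.names = TRUE,
                             ignore.case = TRUE))
    if (!length(files)) stop("no TIFF slices found in directory: ", path)
    slices <- lapply(files, tiff::readTIFF)
  }
  nr <- nrow(slices[[1]]); nc <- ncol(slices[[1]])
  arr <- array(0, c(length(slices), nr, nc))
  for (k in seq_along(slices)) arr[k, , ] <- slices[[k]]
  scale <- if (!is.null(meta$scale)) meta$scale else 1
  offset <- if (!is.null(meta$offset)) meta$offset else 0
  list(arr = arr * scale + offset, voxelSize = NULL, kind = NULL)
}

.writeTiffStack <- function(vol, path, multipage, bits = 32L) {
  isMask <- is(vol, "BinaryVolume")
  arr <- volData(vol)
  if (isMask) {
    arr <- arr + 0
    offset <- 0; scale <- 1; bits <- 8L
  } else {
    offset <- min(arr)
    scale <- max(arr) - offset
    if (scale == 0) scale <- 1
    arr <- (arr - offset) / scale
  }
  slices <- lapply(seq_len(dim(arr)[1]), function(k) arr[k, , ])
  if (multipage) {
    tiff::writeTIFF(slices, path, bits.per.sample = as.integer(bits),
                    compression = "none", reduce = FALSE)
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    for (k in seq_along(slices))
      tiff::writeTIFF(slices[[k]],
                      file.path(path, sprintf("slice_%05d.tif", k)),
                      bits.per.sample = as.integer(bits),
                      compression = "none", reduce = FALSE)
  }
  list(scale = scale, offset = offset, bits = as.integer(bits))
}
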