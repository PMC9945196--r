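#' Read a density volume from NIfTI or MetaImage
#'
#' NIfTI (.nii / .nii.gz) is read through RNifti; MetaImage (.mha / .mhd +
#' .raw) through a built-in reader for uncompressed files. Header spacings
#' are interpreted as millimetres and converted to micrometres. Only
#' isotropic volumes are accepted.
#'
#' @param path input file.
#' @param units units tag to attach (\code{"HU"} by default).
#' @return a \linkS4class{DensityVolume}.
#' @export
readDensityVolume <- function(path, units = "HU") {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::readNifti(path)
    sp <- RNifti::pixdim(img)
    vals <- array(as.numeric(img), dim(img))
  } else if (grepl("\\.(mha|mhd)$", path, ignore.case = TRUE)) {
    meta <- .readMetaImage(path)
    sp <- meta$spacing
    vals <- meta$values
  } else {
    .stopf("unsupported volume format: %s", path)
  }
  if (length(sp) < 3L || diff(range(sp[1:3])) > 1e-6 * sp[1])
    .stopf("only isotropic volumes are supported (spacings: %s)",
           paste(signif(sp, 6), collapse = ", "))
  DensityVolume(vals, sp[1] * 1000, units)
}

#' Write a density volume to NIfTI or MetaImage
#'
#' @param volume a \linkS4class{DensityVolume}.
#' @param path output file (.nii, .nii.gz, .mha or .mhd).
#' @return the path, invisibly.
#' @export
writeDensityVolume <- function(volume, path) {
  stopifnot(is(volume, "DensityVolume"))
  mm <- spacing(volume) / 1000
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::asNifti(voxelValues(volume))
    RNifti::pixdim(img) <- rep(mm, 3)
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.(mha|mhd)$", path, ignore.case = TRUE)) {
    .writeMetaImage(voxelValues(volume), rep(mm, 3), path)
  } else {
    .stopf("unsupported volume format: %s", path)
  }
  invisible(path)
}

# Minimal MetaImage reader: uncompressed MET_FLOAT/MET_DOUBLE/MET_SHORT/
# MET_UCHAR, local or external raw data.
.readMetaImage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (!length(line)) .stopf("truncated MetaImage header")
    kv <- strsplit(line, "=", fixed = TRUE)[[1L]]
    key <- trimws(kv[1L]); val <- trimws(paste(kv[-1L], collapse = "="))
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  dims <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1L]])
  sp <- if (!is.null(hdr$ElementSpacing))
    as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1L]]) else rep(1, 3)
  type <- hdr$ElementType
  n <- prod(dims)
  reader <- switch(type,
    MET_FLOAT = function(c) readBin(c, "numeric", n, size = 4),
    MET_DOUBLE = function(c) readBin(c, "numeric", n, size = 8),
    MET_SHORT = function(c) readBin(c, "integer", n, size = 2, signed = TRUE),
    MET_UCHAR = function(c) readBin(c, "integer", n, size = 1, signed = FALSE),
    .stopf("unsupported MetaImage element type: %s", type))
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    raw <- reader(con)
  } else {
    rawPath <- file.path(dirname(path), hdr$ElementDataFile)
    con2 <- file(rawPath, "rb")
    on.exit(close(con2), add = TRUE)
    raw <- reader(con2)
  }
  list(values = array(as.numeric(raw), dims), spacing = sp)
}

.writeMetaImage <- function(values, spacingMm, path) {
  d <- dim(values)
  local <- grepl("\\.mha$", path, ignore.case = TRUE)
  dataFile <- if (local) "LOCAL" else
    paste0(sub("\\.mhd$", "", basename(path), ignore.case = TRUE), ".raw")
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           paste("DimSize =", paste(d, collapse = " ")),
           paste("ElementSpacing =", paste(spacingMm, collapse = " ")),
           "ElementType = MET_DOUBLE",
           paste("ElementDataFile =", dataFile))
  if (local) {
    con <- file(path, "wb")
    writeLines(hdr, con)
    writeBin(as.numeric(values), con, size = 8)
    close(con)
  } else {
    writeLines(hdr, path)
    con <- file(file.path(dirname(path), dataFile), "wb")
    writeBin(as.numeric(values), con, size = 8)
    close(con)
  }
  invisible(path)
}

#' Read a calibration table
#'
#' Two-column CSV with a header: HU, density_g_cc.
#'
#' @param path CSV file.
#' @return data.frame with columns \code{HU} and \code{density_g_cc}.
#' @export
readCalibrationTable <- function(path) {
  df <- utils::read.csv(path)
  if (ncol(df) < 2L)
    .stopf("calibration table must have 2 columns (HU, density_g_cc)")
  names(df)[1:2] <- c("HU", "density_g_cc")
  df
}
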