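## File interfaces: float32 WAV with JSON sidecar for recordings, CSV for
## absorption spectra and repeated-measures tables, YAML for the chamber
## and air configuration, PNG for images and masks.

#' Write a recording as a float32 WAV file with a JSON sidecar
#'
#' Minimal RIFF/WAVE writer (IEEE float, mono).  Metadata that WAV cannot
#' carry — the sound-offset time, position label, band, and any synthetic
#' truth — goes into `<file>.json` alongside.
#'
#' @param rec a [Recording-class]
#' @param path output path (`.wav`)
#' @param band optional [Band-class] recorded in the sidecar
#' @param truth optional named list of synthetic truth values for the sidecar
#' @return `path`, invisibly
#' @export
writeWav <- function(rec, path, band = NULL, truth = NULL) {
  stopifnot(is(rec, "Recording"))
  con <- file(path, "wb")
  on.exit(close(con))
  x <- rec@samples
  dataBytes <- length(x) * 4L
  wInt <- function(v, size) writeBin(as.integer(v), con, size = size,
                                     endian = "little")
  writeChar("RIFF", con, eos = NULL); wInt(36L + dataBytes, 4)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); wInt(16L, 4)
  wInt(3L, 2)                       # IEEE float
  wInt(1L, 2)                       # mono
  wInt(round(rec@fs), 4)
  wInt(round(rec@fs) * 4L, 4)       # byte rate
  wInt(4L, 2); wInt(32L, 2)         # block align, bits
  writeChar("data", con, eos = NULL); wInt(dataBytes, 4)
  writeBin(as.numeric(x), con, size = 4, endian = "little")
  side <- list(fs = rec@fs, tau_off = rec@tauOff, position_id = rec@positionId)
  if (!is.null(band))
    side$band <- list(fc = band@fc, fl = band@fl, fh = band@fh)
  if (!is.null(truth)) side$truth <- truth
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a float32 WAV file written by [writeWav()]
#'
#' @param path path to the `.wav` file; the `.json` sidecar is read if
#'   present (for `tauOff` and `positionId`)
#' @return a [Recording-class]
#' @export
readWav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rInt <- function(size, signed = TRUE)
    readBin(con, "integer", size = size, endian = "little", signed = signed)
  if (readChar(con, 4) != "RIFF") stop("not a RIFF file")
  rInt(4)
  if (readChar(con, 4) != "WAVE") stop("not a WAVE file")
  fs <- NULL; fmt <- NULL; bits <- NULL; x <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- rInt(4)
    if (id == "fmt ") {
      fmt <- rInt(2, signed = FALSE); rInt(2)
      fs <- rInt(4); rInt(4); rInt(2)
      bits <- rInt(2)
      if (size > 16) readBin(con, "raw", size - 16)
    } else if (id == "data") {
      if (is.null(fmt)) stop("malformed WAV: data before fmt")
      if (fmt != 3L || bits != 32L)
        stop("only 32-bit float WAV is supported")
      x <- readBin(con, "numeric", n = size / 4, size = 4, endian = "little")
      break
    } else {
      readBin(con, "raw", size)
    }
  }
  if (is.null(x)) stop("no data chunk found")
  tauOff <- 0; posId <- "pos1"
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(side$tau_off)) tauOff <- side$tau_off
    if (!is.null(side$position_id)) posId <- side$position_id
  }
  Recording(x, fs, tauOff, posId)
}

#' Write absorption spectra to CSV
#'
#' Long format with header `subject_id, kind, fc_hz, alpha`.
#'
#' @param spectra list of [AbsorptionSpectrum-class] objects (or one)
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
writeAbsorptionCsv <- function(spectra, path) {
  if (is(spectra, "AbsorptionSpectrum")) spectra <- list(spectra)
  rows <- do.call(rbind, lapply(spectra, function(sp)
    data.frame(subject_id = sp@subjectId, kind = sp@kind,
               fc_hz = vapply(sp@bands, bandCentre, numeric(1)),
               alpha = sp@alpha)))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read absorption spectra from CSV
#'
#' @param path CSV with columns `subject_id, kind, fc_hz, alpha`
#' @param convention band-edge convention passed to [Band()]
#' @return list of [AbsorptionSpectrum-class] objects, one per subject
#' @export
readAbsorptionCsv <- function(path, convention = "base2") {
  df <- utils::read.csv(path)
  lapply(split(df, df$subject_id), function(d) {
    d <- d[order(d$fc_hz), ]
    AbsorptionSpectrum(lapply(d$fc_hz, Band, convention = convention),
                       d$alpha, d$subject_id[1], d$kind[1])
  })
}

#' Read/write a long-format repeated-measures table
#'
#' Header `preparation, group, set_id, fc_hz, alpha`.
#'
#' @param dataset a validated long-format data.frame
#' @param path CSV path
#' @return the dataset (read) or `path` invisibly (write)
#' @export
writeRMDatasetCsv <- function(dataset, path) {
  validateRMDataset(dataset)
  utils::write.csv(dataset, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRMDatasetCsv
#' @export
readRMDatasetCsv <- function(path) {
  validateRMDataset(utils::read.csv(path))
}

#' Read chamber and air configuration from YAML or JSON
#'
#' Expected top-level keys: `chamber` (with `V`, `S`) and optionally `air`
#' (any of the [AirProperties()] arguments).
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file
#' @return list with `chamber` ([ChamberSpec-class]) and `air`
#'   ([AirProperties-class])
#' @export
readChamberConfig <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  if (is.null(cfg$chamber) || is.null(cfg$chamber$V) || is.null(cfg$chamber$S))
    stop("config must provide chamber: {V, S}; missing ",
         if (is.null(cfg$chamber)) "chamber" else
           if (is.null(cfg$chamber$V)) "chamber$V" else "chamber$S")
  air <- do.call(AirProperties, as.list(cfg$air %||% list()))
  list(chamber = ChamberSpec(cfg$chamber$V, cfg$chamber$S), air = air)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a greyscale image (and optionally a mask) as 8-bit PNG
#'
#' @param img numeric matrix on `[0, 1]` (clipped)
#' @param path output `.png` path
#' @return `path`, invisibly
#' @export
writeImagePng <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' Read a PNG or TIFF image as a greyscale intensity matrix
#'
#' Colour images are converted with luminance weights
#' `0.2126 R + 0.7152 G + 0.0722 B`.
#'
#' @param path path to a `.png` or `.tif`/`.tiff` file
#' @return numeric matrix on `[0, 1]`
#' @export
readImageGrey <- function(path) {
  arr <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("package 'tiff' required to read TIFF images")
    tiff::readTIFF(path)
  } else png::readPNG(path)
  if (length(dim(arr)) == 3)
    arr <- 0.2126 * arr[, , 1] + 0.7152 * arr[, , 2] + 0.0722 * arr[, , 3]
  arr
}
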