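#' Construct a raw thermogram object
#'
#' A \code{raw_thermogram} wraps an as-acquired false-color (or grayscale)
#' thermographic image together with its provenance and, when known, its
#' Nuernberger-Mueller stage label.
#'
#' @param pixels numeric array \code{height x width x 3} (RGB) or matrix
#'   \code{height x width} (grayscale), values in \code{[0, 255]}. Stored
#'   row-major with the origin at the top-left corner.
#' @param source_id character scalar identifying the image.
#' @param stage optional stage label in \code{0:3} (\code{NA} if unknown).
#' @return an object of class \code{raw_thermogram}.
#' @seealso \code{\link{read_thermogram}}, \code{\link{extract_roi}}
#' @export
raw_thermogram <- function(pixels, source_id = "unknown", stage = NA) {
  if (!(is.matrix(pixels) || (is.array(pixels) && length(dim(pixels)) == 3L)))
    stop("'pixels' must be a height x width matrix or height x width x 3 array")
  d <- dim(pixels)
  if (length(d) == 3L && d[3] != 3L)
    stop("color thermograms must have exactly 3 channels, got ", d[3])
  if (d[1] < 64L || d[2] < 64L)
    stop("thermogram too small: need at least 64x64 pixels, got ",
         d[1], "x", d[2])
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stop("pixel values must lie in [0, 255] with no missing values")
  stage <- validate_stage(stage, allow_na = TRUE)
  structure(list(pixels = pixels, source_id = as.character(source_id),
                 stage = stage),
            class = "raw_thermogram")
}

#' @export
print.raw_thermogram <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<raw_thermogram> %s: %dx%d, %s, stage %s\n", x$source_id,
              d[1], d[2], if (length(d) == 3L) "RGB" else "grayscale",
              if (is.na(x$stage)) "unknown" else x$stage))
  invisible(x)
}

#' Validate a Nuernberger-Mueller stage label
#'
#' Stages follow the 4-level clinical scale: 0 healthy skin, 1 mild
#' (alterations only on pinching), 2 moderate (orange-peel appearance when
#' standing), 3 severe (evident standing and lying).
#'
#' @param stage value to validate.
#' @param allow_na whether a missing label is acceptable.
#' @return the label as an integer scalar (possibly \code{NA_integer_}).
#' @export
validate_stage <- function(stage, allow_na = FALSE) {
  if (length(stage) != 1L) stop("stage must be a scalar")
  if (is.na(stage)) {
    if (allow_na) return(NA_integer_)
    stop("stage label is missing")
  }
  s <- suppressWarnings(as.integer(stage))
  if (is.na(s) || s != as.numeric(stage) || !(s %in% 0:3))
    stop("invalid stage label '", stage, "': must be one of 0, 1, 2, 3")
  s
}

#' Parse a stage label from a file name
#'
#' The packaged convention encodes the label as the token \code{"_stageK"}
#' (K in 0..3) anywhere in the basename, e.g. \code{"subjA_stage2.png"}.
#'
#' @param path file path or name.
#' @return integer stage or \code{NA_integer_} when no token is present.
#' @export
stage_from_filename <- function(path) {
  m <- regmatches(basename(path),
                  regexpr("_stage([0-3])(?=[._]|$)", basename(path),
                          perl = TRUE))
  if (length(m) == 0L) return(NA_integer_)
  as.integer(sub("_stage", "", m[1]))
}

#' Read a thermographic image from disk
#'
#' Supports 8-bit PNG, TIFF and JPEG rasters. JPEG input is accepted with a
#' warning because lossy compression perturbs the gradient structure the
#' downstream features rely on. If the basename carries a \code{"_stageK"}
#' token the stage label is populated.
#'
#' @param path path to a PNG/TIFF/JPEG file.
#' @return a \code{\link{raw_thermogram}}.
#' @export
read_thermogram <- function(path) {
  if (!file.exists(path)) stop("cannot read thermogram: no such file '",
                               path, "'")
  ext <- tolower(tools::file_ext(path))
  px <- tryCatch(switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    jpg  = ,
    jpeg = {
      warning("JPEG input '", basename(path),
              "': lossy compression may perturb gradient features")
      jpeg::readJPEG(path)
    },
    stop("unsupported raster format '.", ext, "' for '", path, "'")
  ), error = function(e) {
    if (grepl("unsupported raster", conditionMessage(e)))
      stop(conditionMessage(e), call. = FALSE)
    stop("failed to decode '", path, "': ", conditionMessage(e),
         call. = FALSE)
  })
  if (is.list(px)) px <- px[[1]]  # multi-page TIFF: first page
  if (length(dim(px)) == 3L) {
    if (dim(px)[3] >= 3L) px <- px[, , 1:3, drop = FALSE]
    else px <- px[, , 1]  # single-channel stored with a dim of 1
  }
  raw_thermogram(round(px * 255),
                 source_id = tools::file_path_sans_ext(basename(path)),
                 stage = stage_from_filename(path))
}

#' Write a thermogram (or any raster) to disk losslessly
#'
#' @param x a \code{\link{raw_thermogram}}, matrix or 3-channel array with
#'   values in \code{[0, 255]}.
#' @param path output path; extension selects PNG (default) or TIFF.
#' @return \code{path}, invisibly.
#' @export
write_thermogram <- function(x, path) {
  px <- if (inherits(x, "raw_thermogram")) x$pixels else x
  ext <- tolower(tools::file_ext(path))
  img <- px / 255
  if (ext %in% c("tif", "tiff")) tiff::writeTIFF(img, path, bits.per.sample = 8L)
  else if (ext == "png") png::writePNG(img, path)
  else stop("lossless output requires a .png or .tiff extension, got '.",
            ext, "'")
  invisible(path)
}

#' Load a dataset manifest
#'
#' A manifest is a UTF-8 CSV with header \code{path,stage} mapping image
#' files to stage labels; manifest labels take precedence over any label
#' encoded in the file name.
#'
#' @param path CSV file path.
#' @param name manifest name (defaults to the file basename).
#' @return a \code{dataset_manifest}: a data frame with columns \code{path}
#'   (character) and \code{stage} (integer in 0..3), rows in file order.
#' @export
load_manifest <- function(path, name = tools::file_path_sans_ext(basename(path))) {
  if (!file.exists(path)) stop("manifest file not found: '", path, "'")
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!all(c("path", "stage") %in% names(df)))
    stop("manifest must have header columns 'path' and 'stage'")
  dataset_manifest(df$path, df$stage, name = name)
}

#' Construct a dataset manifest in memory
#'
#' @param paths character vector of image paths (must be unique).
#' @param stages stage labels, one per path, each in 0..3.
#' @param name manifest name.
#' @return a \code{dataset_manifest} data frame.
#' @export
dataset_manifest <- function(paths, stages, name = "dataset") {
  if (length(paths) != length(stages))
    stop("'paths' and 'stages' must have equal length")
  stages_int <- suppressWarnings(as.integer(stages))
  bad <- which(is.na(stages_int) | !(stages_int %in% 0:3))
  if (length(bad) > 0L)
    stop("invalid stage label '", stages[bad[1]], "' at manifest row ",
         bad[1], ": must be one of 0, 1, 2, 3")
  dup <- anyDuplicated(paths)
  if (dup > 0L)
    stop("duplicate path in manifest at row ", dup, ": '", paths[dup], "'")
  out <- data.frame(path = as.character(paths), stage = stages_int,
                    stringsAsFactors = FALSE)
  attr(out, "name") <- name
  class(out) <- c("dataset_manifest", "data.frame")
  out
}

#' Per-stage image counts of a manifest
#'
#' @param manifest a \code{dataset_manifest}.
#' @return named integer vector of counts for stages \code{"0".."3"}
#'   (always length 4, zeros for absent stages).
#' @export
manifest_counts <- function(manifest) {
  tab <- table(factor(manifest$stage, levels = 0:3))
  setNames(as.integer(tab), names(tab))
}

#' Write a manifest to CSV
#'
#' @param manifest a \code{dataset_manifest}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  write.csv(as.data.frame(manifest)[, c("path", "stage")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.dataset_manifest <- function(x, ...) {
  cnt <- manifest_counts(x)
  cat(sprintf("<dataset_manifest> '%s': %d images (stage 0: %d, 1: %d, 2: %d, 3: %d)\n",
              attr(x, "name") %||% "dataset", nrow(x),
              cnt[1], cnt[2], cnt[3], cnt[4]))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
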