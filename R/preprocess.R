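#' Preprocessing configuration
#'
#' Parameters of the automatic region-of-interest (ROI) extraction chain.
#' Defaults are conservative and documented; every value can be overridden.
#'
#' @param target_height,target_width output ROI size in pixels (default
#'   210 x 240, the size fed to feature extraction).
#' @param contrast_low,contrast_high percentiles (0-100) for the linear
#'   contrast stretch; values at or below/above them map to 0/1.
#' @param edge_threshold threshold in (0,1) applied to the normalized Sobel
#'   magnitude, or \code{NULL} (default) to use Otsu's method.
#' @param min_component_area connected components smaller than this many
#'   pixels are treated as noise and removed.
#' @param annotation_margin_fraction maximum fraction of each dimension that
#'   annotation removal may excise from any one border.
#' @return a \code{preprocess_config} list.
#' @export
preprocess_config <- function(target_height = 210L, target_width = 240L,
                              contrast_low = 2, contrast_high = 98,
                              edge_threshold = NULL,
                              min_component_area = 64L,
                              annotation_margin_fraction = 0.2) {
  if (target_height <= 0L || target_width <= 0L)
    stop("target dimensions must be positive")
  if (!(contrast_low >= 0 && contrast_low < contrast_high &&
        contrast_high <= 100))
    stop("need 0 <= contrast_low < contrast_high <= 100")
  if (!is.null(edge_threshold) &&
      !(edge_threshold > 0 && edge_threshold < 1))
    stop("edge_threshold must lie in (0, 1)")
  structure(list(target_height = as.integer(target_height),
                 target_width = as.integer(target_width),
                 contrast_low = contrast_low, contrast_high = contrast_high,
                 edge_threshold = edge_threshold,
                 min_component_area = as.integer(min_component_area),
                 annotation_margin_fraction = annotation_margin_fraction),
            class = "preprocess_config")
}

#' Convert a thermogram to a grayscale intensity matrix in [0, 1]
#'
#' RGB input is collapsed with the standard luminance weights
#' (0.299, 0.587, 0.114). Rainbow thermographic palettes are not
#' luminance-monotone in temperature, but the downstream analysis is purely
#' morphological, so luminance is an acceptable and standard reduction.
#'
#' @param x a \code{\link{raw_thermogram}}, matrix, or 3-channel array.
#' @return numeric matrix with values in \code{[0, 1]}.
#' @export
to_grayscale <- function(x) {
  px <- if (inherits(x, "raw_thermogram")) x$pixels else x
  if (length(dim(px)) == 3L)
    px <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
  if (max(px) > 1) px <- px / 255
  .clamp(px)
}

#' Linear percentile contrast stretch
#'
#' Maps values at or below the low percentile to 0 and at or above the high
#' percentile to 1, linearly in between. A constant image (zero dynamic
#' range) is returned unchanged with a warning.
#'
#' @param image grayscale matrix.
#' @param config a \code{\link{preprocess_config}}.
#' @return matrix with values in \code{[0, 1]}; pixel ordering is preserved
#'   wherever not clipped.
#' @export
enhance_contrast <- function(image, config = preprocess_config()) {
  if (!is.matrix(image)) stop("enhance_contrast expects a grayscale matrix")
  q <- quantile(image, c(config$contrast_low, config$contrast_high) / 100,
                names = FALSE)
  if (q[2] <= q[1]) {
    warning("image has zero dynamic range between the contrast percentiles; ",
            "returned unchanged")
    return(image)
  }
  .clamp((image - q[1]) / (q[2] - q[1]))
}

#' Sobel gradient magnitude
#'
#' Convolves the image with the standard 3x3 Sobel kernels and returns
#' \code{sqrt(Gx^2 + Gy^2)} per pixel. Borders are handled by reflection, so
#' a constant image yields an exactly zero response everywhere.
#'
#' @param image grayscale matrix, both dimensions at least 3.
#' @return non-negative matrix of the same size.
#' @export
sobel_edges <- function(image) {
  d <- dim(image)
  if (is.null(d) || min(d) < 3L)
    stop("sobel_edges needs an image of at least 3x3 pixels")
  p <- .pad_reflect(image)
  h <- d[1]; w <- d[2]
  sh <- function(di, dj) p[(2 + di):(h + 1 + di), (2 + dj):(w + 1 + dj)]
  # Gx: derivative across columns (vertical-edge detector), smoothed over rows
  gx <- (sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1))
  gy <- (sh(1, -1) + 2 * sh(1, 0) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1))
  sqrt(gx^2 + gy^2)
}

# reflect-pad a matrix by one pixel on every side
.pad_reflect <- function(m) {
  m2 <- rbind(m[1, , drop = FALSE], m, m[nrow(m), , drop = FALSE])
  cbind(m2[, 1, drop = FALSE], m2, m2[, ncol(m2), drop = FALSE])
}

#' Remove the temperature bar and text annotations
#'
#' Thermograms carry a vertical color-scale bar abutting the left or right
#' border and text strips along the top/bottom. Both are detected by edge-
#' density profiling: a contiguous run of border columns (rows) whose mean
#' Sobel magnitude exceeds 3x the median column (row) density is excised, up
#' to \code{annotation_margin_fraction} of the dimension. When nothing is
#' detected the image is returned unchanged.
#'
#' @param x a \code{\link{raw_thermogram}} or grayscale matrix.
#' @param config a \code{\link{preprocess_config}}.
#' @return grayscale matrix with annotation strips removed; the excised
#'   margins are recorded in attribute \code{"margins"}
#'   (top, bottom, left, right).
#' @export
remove_annotations <- function(x, config = preprocess_config()) {
  g <- to_grayscale(x)
  e <- sobel_edges(g)
  h <- nrow(g); w <- ncol(g)
  cap_c <- floor(config$annotation_margin_fraction * w)
  cap_r <- floor(config$annotation_margin_fraction * h)
  run_len <- function(dens, cap) {
    thr <- 3 * median(dens)
    if (cap < 3L) return(0L)
    # widest border strip (>= 3 px, <= cap) whose mean density clears 3x median
    strip_means <- cumsum(dens[seq_len(cap)]) / seq_len(cap)
    hits <- which(strip_means > thr & seq_len(cap) >= 3L)
    if (length(hits) == 0L) return(0L)
    k <- max(hits)
    while (k > 0L && dens[k] <= thr) k <- k - 1L  # trim quiet trailing cols
    if (k < 3L) return(0L)
    min(k + 2L, cap)  # 2-px pad covers the annotation's smooth outer edge
  }
  left   <- run_len(colMeans(e), cap_c)
  right  <- run_len(rev(colMeans(e)), cap_c)
  top    <- run_len(rowMeans(e), cap_r)
  bottom <- run_len(rev(rowMeans(e)), cap_r)
  out <- g[(top + 1L):(h - bottom), (left + 1L):(w - right), drop = FALSE]
  attr(out, "margins") <- c(top = top, bottom = bottom,
                            left = left, right = right)
  out
}

#' Remove noise from a binary mask
#'
#' Drops 8-connected components smaller than \code{min_component_area}
#' pixels, then applies a morphological closing with a 3x3 box element so
#' that nearby fragments (for example the two edges of a thin outline) merge.
#'
#' @param mask logical or 0/1 matrix.
#' @param config a \code{\link{preprocess_config}}.
#' @return logical matrix.
#' @export
remove_noise <- function(mask, config = preprocess_config()) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  if (!any(m > 0)) return(m > 0)
  lab <- EBImage::bwlabel(m)
  areas <- tabulate(lab)
  keep <- which(areas >= config$min_component_area)
  m <- matrix(as.numeric(lab %in% keep), nrow(m), ncol(m))
  if (any(m > 0))
    m <- as.matrix(EBImage::closing(m, EBImage::makeBrush(3, "box")))
  m > 0
}

#' Automatic region-of-interest extraction
#'
#' Runs the full preprocessing chain on a raw thermogram: grayscale
#' conversion, annotation removal, percentile contrast stretch, Sobel edge
#' detection, thresholding (Otsu by default), noise removal, bounding-box
#' crop around the thigh region(s), bilinear resize to the target size, and
#' rescaling to \code{[0, 1]}. Components of at least half the largest
#' component's area are treated as thighs and their union bounding box is
#' cropped, so both separated and merged thighs are retained.
#'
#' @param raw a \code{\link{raw_thermogram}}.
#' @param config a \code{\link{preprocess_config}}.
#' @param keep_debug if \code{TRUE}, intermediate rasters (grayscale,
#'   contrast, edges, mask, crop box) are attached as attribute
#'   \code{"debug"}.
#' @return a \code{roi_image}: list with \code{pixels} (matrix
#'   \code{target_height x target_width}, values in \code{[0,1]}),
#'   \code{source_id} and \code{stage}.
#' @export
extract_roi <- function(raw, config = preprocess_config(),
                        keep_debug = FALSE) {
  if (!inherits(raw, "raw_thermogram"))
    stop("extract_roi expects a raw_thermogram")
  ga <- remove_annotations(raw, config)
  span <- diff(quantile(ga, c(config$contrast_low, config$contrast_high) /
                          100, names = FALSE))
  if (span < 0.1)
    stop("ROI extraction failed for '", raw$source_id,
         "': no visible warm foreground (thermal contrast spans only ",
         round(span * 100), "% of the intensity range)")
  gc <- enhance_contrast(ga, config)
  e <- sobel_edges(gc)
  emax <- max(e)
  if (emax <= 0)
    stop("ROI extraction failed for '", raw$source_id,
         "': no edges found (flat image)")
  en <- e / emax
  thr <- config$edge_threshold %||% EBImage::otsu(en, range = c(0, 1))
  mask <- remove_noise(en > thr, config)
  if (!any(mask))
    stop("ROI extraction failed for '", raw$source_id,
         "': no foreground component found")
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  areas <- tabulate(lab)
  keep <- which(areas >= 0.5 * max(areas))
  px <- which(matrix(lab %in% keep, nrow(lab), ncol(lab)), arr.ind = TRUE)
  rr <- range(px[, 1]); cc <- range(px[, 2])
  if (diff(rr) + 1L < 16L || diff(cc) + 1L < 16L)
    stop("ROI extraction failed for '", raw$source_id,
         "': degenerate bounding box (", diff(rr) + 1L, "x", diff(cc) + 1L,
         " px)")
  crop <- gc[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE]
  out <- as.matrix(EBImage::resize(crop, w = config$target_height,
                                   h = config$target_width,
                                   filter = "bilinear", antialias = TRUE))
  out <- .clamp(out)
  roi <- structure(list(pixels = out, source_id = raw$source_id,
                        stage = raw$stage),
                   class = "roi_image")
  if (keep_debug)
    attr(roi, "debug") <- list(grayscale = to_grayscale(raw), contrast = gc,
                               edges = e, mask = mask,
                               crop_box = c(row_min = rr[1], row_max = rr[2],
                                            col_min = cc[1], col_max = cc[2]))
  roi
}

#' @export
print.roi_image <- function(x, ...) {
  cat(sprintf("<roi_image> %s: %dx%d grayscale in [%.3f, %.3f], stage %s\n",
              x$source_id, nrow(x$pixels), ncol(x$pixels), min(x$pixels),
              max(x$pixels), if (is.na(x$stage)) "unknown" else x$stage))
  invisible(x)
}

#' Preprocess every image in a manifest
#'
#' @param manifest a \code{dataset_manifest} whose paths are readable images.
#' @param config a \code{\link{preprocess_config}}.
#' @param on_error \code{"stop"} (default) or \code{"skip"} failed images.
#' @return list of \code{roi_image} objects (named by source id).
#' @export
preprocess_manifest <- function(manifest, config = preprocess_config(),
                                on_error = c("stop", "skip")) {
  on_error <- match.arg(on_error)
  rois <- list()
  for (i in seq_len(nrow(manifest))) {
    raw <- read_thermogram(manifest$path[i])
    raw$stage <- manifest$stage[i]  # manifest labels override filename labels
    roi <- if (on_error == "stop") extract_roi(raw, config)
           else tryCatch(extract_roi(raw, config), error = function(e) NULL)
    if (!is.null(roi)) rois[[raw$source_id]] <- roi
  }
  rois
}
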