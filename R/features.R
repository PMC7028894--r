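#' HOG configuration
#'
#' The default configuration (48-pixel cells, 2x2-cell blocks at stride 1,
#' 9 unsigned orientation bins, L2 block normalization) yields exactly 432
#' features on a 210x240 region of interest: floor(210/48) = 4 cell rows and
#' floor(240/48) = 5 cell columns give 3 x 4 overlapping blocks, each
#' contributing 2 x 2 cells x 9 bins.
#'
#' @param cell_size cell side in pixels.
#' @param block_size block side in cells.
#' @param orientations number of unsigned orientation bins over [0, 180).
#' @param block_stride block stride in cells.
#' @param block_norm block normalization; only \code{"L2"} is implemented.
#' @return a \code{hog_config} list.
#' @export
hog_config <- function(cell_size = 48L, block_size = 2L, orientations = 9L,
                       block_stride = 1L, block_norm = "L2") {
  if (cell_size < 1L || block_size < 1L || orientations < 1L ||
      block_stride < 1L)
    stop("hog_config: all sizes must be positive integers")
  if (block_norm != "L2") stop("only L2 block normalization is implemented")
  structure(list(cell_size = as.integer(cell_size),
                 block_size = as.integer(block_size),
                 orientations = as.integer(orientations),
                 block_stride = as.integer(block_stride),
                 block_norm = block_norm),
            class = "hog_config")
}

#' HOG feature-vector length for a given image size
#'
#' \code{D = n_blocks_rows * n_blocks_cols * block_size^2 * orientations},
#' with \code{n_blocks_rows = floor((floor(H/c) - b) / stride) + 1} and the
#' analogous column count.
#'
#' @param height,width image size in pixels.
#' @param config a \code{\link{hog_config}}.
#' @return integer feature count.
#' @export
hog_length <- function(height, width, config = hog_config()) {
  cr <- floor(height / config$cell_size)
  cc <- floor(width / config$cell_size)
  if (cr < config$block_size || cc < config$block_size)
    stop("image too small for HOG: need at least ",
         config$block_size * config$cell_size, "x",
         config$block_size * config$cell_size, " pixels, got ",
         height, "x", width)
  br <- floor((cr - config$block_size) / config$block_stride) + 1L
  bc <- floor((cc - config$block_size) / config$block_stride) + 1L
  as.integer(br * bc * config$block_size^2 * config$orientations)
}

# wrap a numeric vector as a feature_vector
feature_vector <- function(values, method) {
  if (anyNA(values) || any(!is.finite(values)))
    stop("feature vector for method '", method, "' contains non-finite values")
  structure(as.numeric(values), method = method, class = "feature_vector")
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector> method '%s', length %d\n",
              attr(x, "method"), length(x)))
  invisible(x)
}

.roi_pixels <- function(image) {
  if (inherits(image, "roi_image")) image$pixels
  else if (is.matrix(image)) image
  else stop("expected a roi_image or grayscale matrix")
}

#' Histogram of oriented gradients
#'
#' Gradients are computed with centered differences (replicated borders),
#' orientations folded to the unsigned range [0, 180). Each pixel votes its
#' gradient magnitude into the per-cell orientation histogram, split
#' linearly between the two nearest bin centers (with wrap-around). Cells
#' are grouped into overlapping blocks that are L2-normalized independently
#' (an epsilon guard leaves all-zero blocks at zero), and block vectors are
#' concatenated in row-major block order.
#'
#' @param image a \code{roi_image} or grayscale matrix in \code{[0, 1]}.
#' @param config a \code{\link{hog_config}}.
#' @return a \code{feature_vector} of length
#'   \code{hog_length(nrow, ncol, config)}.
#' @export
hog_features <- function(image, config = hog_config()) {
  img <- .roi_pixels(image)
  h <- nrow(img); w <- ncol(img)
  nfeat <- hog_length(h, w, config)  # validates the size
  c_sz <- config$cell_size; b <- config$block_size; s <- config$block_stride
  nb <- config$orientations

  # centered differences, replicate border
  gx <- img[, c(2:w, w)] - img[, c(1, 1:(w - 1))]
  gy <- img[c(2:h, h), ] - img[c(1, 1:(h - 1)), ]
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) %% pi           # unsigned orientation in [0, pi)

  cr <- floor(h / c_sz); cc <- floor(w / c_sz)
  use_r <- seq_len(cr * c_sz); use_c <- seq_len(cc * c_sz)
  mag <- mag[use_r, use_c]; ang <- ang[use_r, use_c]
  ci <- (rep(use_r, times = length(use_c)) - 1L) %/% c_sz  # 0-based cell row
  cj <- (rep(use_c, each = length(use_r)) - 1L) %/% c_sz

  # linear interpolation between the two nearest bin centers, wrap-around
  bw <- pi / nb
  t <- as.vector(ang) / bw - 0.5
  b0 <- floor(t)
  frac <- t - b0
  b0 <- ((b0 %% nb) + nb) %% nb
  b1 <- (b0 + 1L) %% nb
  mv <- as.vector(mag)

  ncell <- cr * cc
  lin0 <- 1L + ci + cj * cr + b0 * ncell
  lin1 <- 1L + ci + cj * cr + b1 * ncell
  sums <- rowsum(c(mv * (1 - frac), mv * frac), group = c(lin0, lin1))
  hist <- numeric(ncell * nb)
  hist[as.integer(rownames(sums))] <- sums[, 1]
  hist <- array(hist, dim = c(cr, cc, nb))

  br <- floor((cr - b) / s) + 1L
  bc <- floor((cc - b) / s) + 1L
  out <- numeric(nfeat)
  eps <- 1e-10
  k <- 0L
  blen <- b * b * nb
  for (bi in seq_len(br)) {
    for (bj in seq_len(bc)) {
      r0 <- (bi - 1L) * s + 1L
      c0 <- (bj - 1L) * s + 1L
      v <- as.vector(hist[r0:(r0 + b - 1L), c0:(c0 + b - 1L), ])
      nrm <- sqrt(sum(v^2) + eps^2)
      if (sum(v^2) > 0) v <- v / nrm else v <- v * 0
      out[(k + 1L):(k + blen)] <- v
      k <- k + blen
    }
  }
  feature_vector(out, "hog")
}

#' Statistical intensity features
#'
#' Eight fixed-order summaries of the grayscale intensity distribution:
#' mean, variance, skewness, kurtosis (excess), median, 10th percentile,
#' 90th percentile, and the Shannon entropy (bits) of the 64-bin intensity
#' histogram. Skewness and kurtosis are defined as 0 for a zero-variance
#' image.
#'
#' @param image a \code{roi_image} or grayscale matrix.
#' @return a \code{feature_vector} of length 8.
#' @export
stat_features <- function(image) {
  x <- as.vector(.roi_pixels(image))
  m <- mean(x); v <- var(x)
  if (v > 0) {
    sk <- e1071::skewness(x, type = 3)
    ku <- e1071::kurtosis(x, type = 3)
  } else sk <- ku <- 0
  q <- quantile(x, c(0.5, 0.1, 0.9), names = FALSE)
  p <- tabulate(pmin(pmax(floor(x * 64) + 1L, 1L), 64L), nbins = 64L)
  p <- p / length(x)
  ent <- -sum(p[p > 0] * log2(p[p > 0]))
  feature_vector(c(m, v, sk, ku, q[1], q[2], q[3], ent), "stat")
}

#' Contour shape features
#'
#' Otsu-binarizes the image, keeps the largest 8-connected component, and
#' returns \code{[perimeter, area, area/perimeter^2, eccentricity,
#' solidity]}. The perimeter is the length of the 0.5-level contour of the
#' Gaussian-smoothed mask, which tracks the true boundary length of both
#' polygonal and curved shapes to within a few percent. Images with an empty
#' foreground yield a zero vector with a warning.
#'
#' @param image a \code{roi_image} or grayscale matrix in \code{[0, 1]}.
#' @return a \code{feature_vector} of length 5.
#' @export
contour_features <- function(image) {
  img <- .roi_pixels(image)
  if (max(img) <= min(img)) {
    warning("contour_features: empty foreground (flat image)")
    return(feature_vector(numeric(5), "cont"))
  }
  thr <- EBImage::otsu(.clamp(img), range = c(0, 1))
  mask <- img > thr
  if (!any(mask)) {
    warning("contour_features: empty foreground after thresholding")
    return(feature_vector(numeric(5), "cont"))
  }
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  areas <- tabulate(lab)
  comp <- matrix(lab == which.max(areas), nrow(lab), ncol(lab))
  area <- sum(comp)
  per <- .mask_perimeter(comp)
  compact <- if (per > 0) area / per^2 else 0
  idx <- which(comp, arr.ind = TRUE)
  ecc <- .mask_eccentricity(idx)
  sol <- .mask_solidity(idx, area)
  feature_vector(c(per, area, compact, ecc, sol), "cont")
}

# boundary length of a binary mask: 0.5-level contour of the smoothed mask
.mask_perimeter <- function(mask) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  sm <- as.matrix(EBImage::gblur(m, sigma = 1.2))
  cl <- contourLines(x = seq_len(nrow(m)), y = seq_len(ncol(m)), z = sm,
                     levels = 0.5)
  if (length(cl) == 0L) return(0)
  sum(vapply(cl, function(p) {
    n <- length(p$x)
    sum(sqrt(diff(p$x)^2 + diff(p$y)^2)) +
      sqrt((p$x[1] - p$x[n])^2 + (p$y[1] - p$y[n])^2)
  }, numeric(1)))
}

# eccentricity of the equivalent ellipse from central second moments
.mask_eccentricity <- function(idx) {
  if (nrow(idx) < 2L) return(0)
  mu <- cov(idx) * (nrow(idx) - 1) / nrow(idx)
  ev <- eigen(mu, symmetric = TRUE, only.values = TRUE)$values
  if (ev[1] <= 0) return(0)
  sqrt(max(0, 1 - ev[2] / ev[1]))
}

# solidity: component area over convex hull area (shoelace on pixel centers)
.mask_solidity <- function(idx, area) {
  if (nrow(idx) < 3L) return(1)
  hull <- chull(idx[, 1], idx[, 2])
  hx <- idx[hull, 1]; hy <- idx[hull, 2]
  n <- length(hull)
  hull_area <- abs(sum(hx * hy[c(2:n, 1)] - hx[c(2:n, 1)] * hy)) / 2
  # pixel-count area includes the half-pixel rim the center hull misses
  hull_area <- hull_area + .mask_perimeter_hull(hx, hy) / 2 + 1
  min(1, area / hull_area)
}

.mask_perimeter_hull <- function(hx, hy) {
  n <- length(hx)
  sum(sqrt((hx - hx[c(2:n, 1)])^2 + (hy - hy[c(2:n, 1)])^2))
}

#' Local binary pattern histogram
#'
#' Basic rotation-invariant uniform LBP with 8 neighbors at radius 1
#' (the integer 8-neighborhood). Each interior pixel is coded by comparing
#' its neighbors to the center (neighbor >= center sets the bit); uniform
#' codes (at most 2 circular 0/1 transitions) are binned by their number of
#' set bits (0..8, where 8 is the "flat" pattern a constant region
#' produces), all non-uniform codes share a tenth bin. The returned 10-bin
#' histogram is normalized to sum to 1.
#'
#' @param image a \code{roi_image} or grayscale matrix.
#' @return a \code{feature_vector} of length 10.
#' @export
lbp_features <- function(image) {
  img <- .roi_pixels(image)
  h <- nrow(img); w <- ncol(img)
  if (h < 3L || w < 3L) stop("lbp_features needs at least a 3x3 image")
  ctr <- img[2:(h - 1), 2:(w - 1)]
  # circular neighbor order
  off <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
              c(1, 1), c(1, 0), c(1, -1), c(0, -1))
  bits <- lapply(off, function(o)
    img[(2 + o[1]):(h - 1 + o[1]), (2 + o[2]):(w - 1 + o[2])] >= ctr)
  nbits <- Reduce(`+`, bits)
  trans <- Reduce(`+`, lapply(seq_along(bits), function(k)
    bits[[k]] != bits[[if (k == length(bits)) 1L else k + 1L]]))
  bin <- ifelse(trans <= 2L, nbits + 1L, 10L)  # 1..9 uniform, 10 non-uniform
  hist <- tabulate(bin, nbins = 10L)
  feature_vector(hist / sum(hist), "lbp")
}

#' Fit a PCA basis on training images
#'
#' Images are flattened column-major to vectors (length 50,400 for the
#' default 210x240 ROI) and mean-centered; the basis holds the top-k
#' principal directions. Fitting accepts the training partition only, so
#' test images can never leak into the basis.
#'
#' @param train_images list of \code{roi_image}s (or matrices), all the same
#'   size.
#' @param k number of components (default 40), must be at most
#'   \code{length(train_images) - 1}.
#' @return a \code{pca_basis} list with \code{center}, \code{rotation}
#'   (p x k) and \code{k}.
#' @export
fit_pca <- function(train_images, k = 40L) {
  n <- length(train_images)
  if (k > n - 1L)
    stop("PCA k = ", k, " exceeds the number of training images minus one (",
         n - 1L, ")")
  X <- do.call(rbind, lapply(train_images,
                             function(im) as.vector(.roi_pixels(im))))
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sv <- svd(Xc, nu = 0, nv = k)
  structure(list(center = ctr, rotation = sv$v[, seq_len(k), drop = FALSE],
                 k = as.integer(k)),
            class = "pca_basis")
}

#' Project an image onto a fitted PCA basis
#'
#' @param image a \code{roi_image} or matrix of the size the basis was fit on.
#' @param basis a \code{\link{fit_pca}} result.
#' @return a \code{feature_vector} of length \code{basis$k}.
#' @export
pca_features <- function(image, basis) {
  x <- as.vector(.roi_pixels(image))
  if (length(x) != length(basis$center))
    stop("image size does not match the PCA basis")
  feature_vector(as.vector((x - basis$center) %*% basis$rotation), "pca")
}

#' Fit per-stage mean-image templates
#'
#' @param train_images list of \code{roi_image}s with stage labels.
#' @return a \code{eucdist_templates} list of 4 mean vectors (NULL, with a
#'   warning, for any stage absent from training).
#' @export
fit_eucdist_templates <- function(train_images) {
  stages <- vapply(train_images, function(im) as.integer(im$stage), 0L)
  tpl <- vector("list", 4L)
  for (s in 0:3) {
    sel <- which(stages == s)
    if (length(sel) == 0L) {
      warning("no training images for stage ", s,
              "; its template distance will be +Inf")
      next
    }
    tpl[[s + 1L]] <- rowMeans(vapply(train_images[sel],
                                     function(im) as.vector(.roi_pixels(im)),
                                     numeric(length(as.vector(
                                       .roi_pixels(train_images[[sel[1]]]))))))
  }
  structure(list(templates = tpl), class = "eucdist_templates")
}

#' Euclidean distances to the four stage templates
#'
#' @param image a \code{roi_image} or matrix.
#' @param templates a \code{\link{fit_eucdist_templates}} result.
#' @return a \code{feature_vector} of length 4 (distance to stages 0..3;
#'   a stage with no template contributes a large finite sentinel equal to
#'   twice the largest observed distance so downstream scaling stays finite).
#' @export
eucdist_features <- function(image, templates) {
  x <- as.vector(.roi_pixels(image))
  d <- vapply(templates$templates, function(t)
    if (is.null(t)) NA_real_ else sqrt(sum((x - t)^2)), numeric(1))
  if (anyNA(d)) {
    mx <- max(d, na.rm = TRUE)
    d[is.na(d)] <- 2 * max(mx, 1)
  }
  feature_vector(d, "eucdist")
}

#' Names of the implemented feature extraction methods
#' @return character vector.
#' @export
feature_methods <- function() c("hog", "lbp", "stat", "cont", "pca", "eucdist")

#' Build a feature extractor
#'
#' An extractor couples a method name with any fitted state (PCA basis,
#' class templates). Stateful methods must be fitted with
#' \code{\link{fit_extractor}} on the training partition before use;
#' stateless methods are ready immediately. This interface is what prevents
#' test-set leakage: fitting only ever sees the training list.
#'
#' @param method one of \code{feature_methods()}.
#' @param hog a \code{\link{hog_config}} used when \code{method = "hog"}.
#' @param pca_k number of PCA components when \code{method = "pca"}.
#' @return a \code{feature_extractor}.
#' @export
feature_extractor <- function(method = feature_methods(),
                              hog = hog_config(), pca_k = 40L) {
  method <- match.arg(method)
  structure(list(method = method, hog = hog, pca_k = as.integer(pca_k),
                 state = NULL,
                 fitted = !(method %in% c("pca", "eucdist"))),
            class = "feature_extractor")
}

#' Fit an extractor's state on training images
#'
#' @param extractor a \code{\link{feature_extractor}}.
#' @param train_images list of training \code{roi_image}s.
#' @return the fitted extractor.
#' @export
fit_extractor <- function(extractor, train_images) {
  if (extractor$method == "pca") {
    k <- min(extractor$pca_k, length(train_images) - 1L)
    extractor$state <- fit_pca(train_images, k = k)
  } else if (extractor$method == "eucdist") {
    extractor$state <- fit_eucdist_templates(train_images)
  }
  extractor$fitted <- TRUE
  extractor
}

#' Extract features from one image with a (fitted) extractor
#'
#' @param extractor a fitted \code{\link{feature_extractor}}.
#' @param image a \code{roi_image}.
#' @return a \code{feature_vector}.
#' @export
extract_features <- function(extractor, image) {
  if (!extractor$fitted)
    stop("extractor '", extractor$method,
         "' must be fitted on training images first (fit_extractor)")
  switch(extractor$method,
         hog = hog_features(image, extractor$hog),
         lbp = lbp_features(image),
         stat = stat_features(image),
         cont = contour_features(image),
         pca = pca_features(image, extractor$state),
         eucdist = eucdist_features(image, extractor$state))
}

#' Extract a feature matrix from a list of images
#'
#' @param extractor a fitted \code{\link{feature_extractor}}.
#' @param images list of \code{roi_image}s.
#' @return numeric matrix, one row per image.
#' @export
feature_matrix <- function(extractor, images) {
  rows <- lapply(images, function(im)
    suppressWarnings(as.numeric(extract_features(extractor, im))))
  do.call(rbind, rows)
}
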