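#' Synthetic thermogram configuration
#'
#' Describes the layout and statistics of simulated 320x240 false-color
#' thermograms: a cool background, two warm thigh-shaped ellipses, a
#' vertical temperature bar with tick marks on one edge, text-like strips
#' along the top and bottom, stage-dependent hot/cold mottling inside the
#' thighs, and i.i.d. Gaussian pixel noise. Mottling is modelled as random
#' Gaussian blobs because advancing cellulite shows as an increasingly
#' inhomogeneous ("orange peel") thermal texture; the per-stage blob count
#' \code{lambda} and amplitude \code{amplitude} are the monotone severity
#' knobs, both zero for healthy skin.
#'
#' @param height,width image size in pixels.
#' @param bar_width temperature-bar width in pixels.
#' @param bar_side \code{"right"} or \code{"left"}.
#' @param text_strip_height height of the top and bottom text strips.
#' @param base_contrast warm-minus-cold intensity contrast (fraction of the
#'   dynamic range).
#' @param lambda mean mottling-blob count per stage 0..3 (non-decreasing,
#'   \code{lambda[1] == 0}).
#' @param amplitude blob amplitude per stage 0..3 as a fraction of the
#'   range (non-decreasing, \code{amplitude[1] == 0}).
#' @param blob_radius range (min, max) of blob radii in pixels.
#' @param noise_sd standard deviation of the additive pixel noise (default
#'   0.01 of the dynamic range, matching the noise floor of a clinical
#'   camera with ~50 mK sensitivity displaying a span of a few kelvin).
#' @param palette \code{"rainbow"} (false color; deliberately not
#'   luminance-monotone, to stress grayscale conversion) or
#'   \code{"grayscale"}.
#' @return a \code{synth_config} list.
#' @export
synth_config <- function(height = 240L, width = 320L, bar_width = 24L,
                         bar_side = c("right", "left"),
                         text_strip_height = 16L, base_contrast = 0.4,
                         lambda = c(0, 6, 14, 26),
                         amplitude = c(0, 0.08, 0.14, 0.22),
                         blob_radius = c(4, 10), noise_sd = 0.01,
                         palette = c("rainbow", "grayscale")) {
  bar_side <- match.arg(bar_side)
  palette <- match.arg(palette)
  if (length(lambda) != 4L || length(amplitude) != 4L)
    stop("lambda and amplitude must have one value per stage 0..3")
  if (any(diff(lambda) < 0) || any(diff(amplitude) < 0))
    stop("lambda and amplitude must be non-decreasing in stage")
  if (lambda[1] != 0 || amplitude[1] != 0)
    stop("healthy skin (stage 0) must be smooth: lambda[1] and amplitude[1] ",
         "must be 0")
  cfg <- structure(list(height = as.integer(height),
                        width = as.integer(width),
                        bar_width = as.integer(bar_width),
                        bar_side = bar_side,
                        text_strip_height = as.integer(text_strip_height),
                        base_contrast = base_contrast, lambda = lambda,
                        amplitude = amplitude, blob_radius = blob_radius,
                        noise_sd = noise_sd, palette = palette),
                   class = "synth_config")
  # thigh geometry: two ellipses in the annotation-free interior
  interior_w <- cfg$width - cfg$bar_width
  cfg$thigh_semi_row <- 0.30 * cfg$height
  cfg$thigh_semi_col <- 0.17 * interior_w
  cfg$thigh_center_row <- 0.52 * cfg$height
  cfg$thigh_center_cols <- c(0.30, 0.68) * interior_w
  if (max(blob_radius) > min(cfg$thigh_semi_row, cfg$thigh_semi_col))
    stop("blob radius exceeds the thigh minor semi-axis")
  cfg
}

# jet-like false-color ramp used by thermal cameras
.thermal_ramp <- local({
  ramp <- NULL
  function() {
    if (is.null(ramp))
      ramp <<- colorRamp(c("#00007F", "#0000FF", "#00FFFF", "#00FF00",
                           "#FFFF00", "#FF0000", "#7F0000"))
    ramp
  }
})

# map a [0,1] scalar field to an RGB array through the configured palette
.apply_palette <- function(field, palette) {
  if (palette == "grayscale") {
    return(array(rep(field, 3L), dim = c(nrow(field), ncol(field), 3L)))
  }
  rgb <- .thermal_ramp()(as.vector(field)) / 255
  array(rgb, dim = c(nrow(field), ncol(field), 3L))
}

#' Generate one synthetic thermogram
#'
#' Builds a scalar pseudo-temperature field (cool background, two smooth
#' warm thighs, Poisson-many hot/cold Gaussian blobs of stage-dependent
#' count and amplitude inside the thigh masks, additive Gaussian noise),
#' maps it through the palette, and composites the temperature bar and
#' text strips. Deterministic given \code{(stage, seed)}. The ground-truth
#' thigh mask is attached as attribute \code{"mask"} so that ROI-extraction
#' recall is measurable.
#'
#' @param stage stage label in 0..3.
#' @param config a \code{\link{synth_config}}.
#' @param seed RNG seed.
#' @return a \code{\link{raw_thermogram}} with attribute \code{"mask"}
#'   (logical height x width matrix).
#' @export
generate_thermogram <- function(stage, config = synth_config(), seed = 1L) {
  stage <- validate_stage(stage)
  set.seed(seed)
  h <- config$height; w <- config$width
  bg <- 0.15
  field <- matrix(bg, h, w)

  # thigh ellipses with a little per-image geometric jitter
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  col_off <- if (config$bar_side == "left") config$bar_width else 0L
  mask <- matrix(FALSE, h, w)
  for (cx in config$thigh_center_cols) {
    jr <- runif(1, 0.95, 1.05); jc <- runif(1, 0.95, 1.05)
    cy <- config$thigh_center_row * runif(1, 0.97, 1.03)
    ccx <- col_off + cx * runif(1, 0.97, 1.03)
    r2 <- ((rows - cy) / (config$thigh_semi_row * jr))^2 +
          ((cols - ccx) / (config$thigh_semi_col * jc))^2
    # plateau with a soft rim so the Sobel step sees a clean thigh outline
    warm <- config$base_contrast * .clamp((1 - r2) / 0.25)
    field <- pmax(field, bg + warm)
    mask <- mask | (r2 <= 1)
  }

  # stage-dependent hot/cold mottling
  lam <- config$lambda[stage + 1L]
  amp <- config$amplitude[stage + 1L]
  n_blob <- if (lam > 0) rpois(1, lam) else 0L
  if (n_blob > 0 && amp > 0) {
    inside <- which(mask, arr.ind = TRUE)
    for (b in seq_len(n_blob)) {
      ctr <- inside[sample.int(nrow(inside), 1L), ]
      r <- runif(1, config$blob_radius[1], config$blob_radius[2])
      sgn <- sample(c(-1, 1), 1L)
      win <- ceiling(3 * r / 2)
      ri <- max(1L, ctr[1] - win):min(h, ctr[1] + win)
      ci <- max(1L, ctr[2] - win):min(w, ctr[2] + win)
      d2 <- outer((ri - ctr[1])^2, (ci - ctr[2])^2, `+`)
      bump <- sgn * amp * exp(-d2 / (2 * (r / 2)^2))
      bump[!mask[ri, ci]] <- 0  # mottling stays inside the thighs
      field[ri, ci] <- field[ri, ci] + bump
    }
  }

  field <- field + matrix(rnorm(h * w, 0, config$noise_sd), h, w)
  field <- .clamp(field)
  rgb <- .apply_palette(field, config$palette)

  # temperature bar: vertical palette ramp with tick marks, speckled tick
  # labels (as printed temperature values render at this resolution) and a
  # dark border, as thermal-camera overlays carry
  bw <- config$bar_width
  bar_cols <- if (config$bar_side == "right") (w - bw + 1L):w else 1L:bw
  ramp_vals <- seq(1, 0, length.out = h)
  bar_rgb <- .apply_palette(matrix(ramp_vals, h, 1L), config$palette)
  for (ch in 1:3) rgb[, bar_cols, ch] <- bar_rgb[, rep(1L, bw), ch]
  ticks <- seq(8L, h - 8L, by = 12L)
  label_cols <- bar_cols[seq_len(max(3L, bw %/% 2L))]
  for (tick in ticks) {
    lab_rows <- (tick + 1L):min(tick + 3L, h)
    glyph <- matrix(sample(c(0, 1), length(lab_rows) * length(label_cols),
                           replace = TRUE),
                    length(lab_rows), length(label_cols))
    for (ch in 1:3) {
      rgb[tick, bar_cols, ch] <- 1      # white tick line
      rgb[lab_rows, label_cols, ch] <- glyph
    }
  }
  inner <- if (config$bar_side == "right") bar_cols[1] else bar_cols[bw]
  for (ch in 1:3)
    rgb[, c(inner, inner + if (config$bar_side == "right") 1L else -1L),
        ch] <- 0                        # dark inner border

  # text strips: dark bands with white glyph-like speckle
  th <- config$text_strip_height
  if (th > 0L) {
    for (strip_rows in list(1L:th, (h - th + 1L):h)) {
      for (ch in 1:3) rgb[strip_rows, , ch] <- 0.05
      n_glyph <- 150L
      gr <- sample(strip_rows[strip_rows > min(strip_rows) &
                                strip_rows < max(strip_rows)],
                   n_glyph, replace = TRUE)
      gc <- sample.int(w - 2L, n_glyph, replace = TRUE) + 1L
      for (ch in 1:3) {
        rgb[cbind(gr, gc, ch)] <- 1
        rgb[cbind(gr, gc + 1L, ch)] <- 1
      }
    }
  }

  out <- raw_thermogram(round(255 * rgb),
                        source_id = sprintf("synth_seed%d_stage%d", seed,
                                            stage),
                        stage = stage)
  attr(out, "mask") <- mask
  out
}

#' Generate a labelled synthetic dataset on disk
#'
#' Writes one PNG per image (named with the \code{"_stageK"} convention), a
#' sidecar ground-truth mask PNG per image, and a \code{manifest.csv}.
#' Deterministic given \code{seed}: image i of stage s uses seed
#' \code{seed + 1000*s + i}.
#'
#' @param counts integer vector of per-stage image counts (stages 0..3).
#' @param config a \code{\link{synth_config}}.
#' @param seed base RNG seed.
#' @param out_dir output directory (created if needed).
#' @param write_masks also write ground-truth mask sidecars.
#' @return the \code{dataset_manifest} (invisibly also written to
#'   \code{out_dir/manifest.csv}).
#' @export
generate_dataset <- function(counts = c(27L, 93L, 61L, 31L),
                             config = synth_config(), seed = 17L,
                             out_dir = tempfile("synth_"),
                             write_masks = FALSE) {
  if (length(counts) != 4L || any(counts < 0))
    stop("counts must be 4 non-negative integers (stages 0..3)")
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory '", out_dir, "'")
  paths <- character(0); stages <- integer(0)
  k <- 0L
  for (s in 0:3) {
    for (i in seq_len(counts[s + 1L])) {
      k <- k + 1L
      img <- generate_thermogram(s, config, seed = seed + 1000L * s + i)
      p <- file.path(out_dir, sprintf("synth_%03d_stage%d.png", k, s))
      write_thermogram(img, p)
      if (write_masks)
        png::writePNG(matrix(as.numeric(attr(img, "mask")),
                             nrow(attr(img, "mask"))),
                      sub("\\.png$", "_mask.png", p))
      paths <- c(paths, p); stages <- c(stages, s)
    }
  }
  manifest <- dataset_manifest(paths, stages, name = basename(out_dir))
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}

#' Generate a synthetic dataset in memory
#'
#' Like \code{\link{generate_dataset}} but returns the
#' \code{raw_thermogram} objects directly without touching the disk.
#'
#' @inheritParams generate_dataset
#' @return list of \code{raw_thermogram}s (stages attached).
#' @export
generate_thermogram_set <- function(counts = c(27L, 93L, 61L, 31L),
                                    config = synth_config(), seed = 17L) {
  out <- list()
  for (s in 0:3)
    for (i in seq_len(counts[s + 1L]))
      out[[length(out) + 1L]] <-
        generate_thermogram(s, config, seed = seed + 1000L * s + i)
  out
}
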