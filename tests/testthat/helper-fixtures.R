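# fixtures built in code; no binary test data ships with the package

# small deterministic grayscale roi_image
make_roi <- function(seed = 1L, h = 210L, w = 240L, stage = NA) {
  set.seed(seed)
  structure(list(pixels = matrix(runif(h * w), h, w),
                 source_id = paste0("fixture", seed), stage = stage),
            class = "roi_image")
}

# binary mask with a filled axis-aligned rectangle
make_rect_mask <- function(h, w, r0, r1, c0, c1) {
  m <- matrix(0, h, w)
  m[r0:r1, c0:c1] <- 1
  m
}

# grayscale image containing a filled disc of the given radius
make_disc_image <- function(r, pad = 20L) {
  n <- 2L * r + 2L * pad + 1L
  ctr <- (n + 1) / 2
  d2 <- outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, `+`)
  matrix(as.numeric(d2 <= r^2), n, n)
}

# tiny labelled feature set: 4 Gaussian clusters in d dimensions
make_cluster_features <- function(counts = c(10L, 10L, 10L, 10L), d = 6L,
                                  sep = 4, seed = 42L) {
  set.seed(seed)
  X <- NULL; labels <- integer(0)
  for (s in 0:3) {
    mu <- rep(0, d); mu[(s %% d) + 1L] <- sep * s
    X <- rbind(X, matrix(rnorm(counts[s + 1L] * d), ncol = d,
                         byrow = TRUE) + rep(mu, each = counts[s + 1L]))
    labels <- c(labels, rep(s, counts[s + 1L]))
  }
  list(X = X, labels = labels)
}

# clinical-style class counts used throughout the evaluation protocol
clinical_counts <- c(27L, 93L, 61L, 31L)

table3_printed <- data.frame(
  stage = 0:3,
  n_test = c(8L, 28L, 18L, 9L),
  tpr = c(0.125, 0.892, 0.555, 0.333),
  tnr = c(0.963, 0.657, 0.800, 0.981),
  f_score = c(0.181, 0.769, 0.540, 0.461)
)

# brute-force Mann-Whitney AUC: fraction of positive/negative pairs ordered
# correctly, ties counted one half — the independent oracle for auc()
mw_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# brute-force HOG dimensionality: literally place cells and slide blocks
count_hog_features <- function(h, w, cell, block, stride, bins) {
  cell_rows <- 0L
  r <- 1L
  while (r + cell - 1L <= h) { cell_rows <- cell_rows + 1L; r <- r + cell }
  cell_cols <- 0L
  c <- 1L
  while (c + cell - 1L <= w) { cell_cols <- cell_cols + 1L; c <- c + cell }
  nfeat <- 0L
  bi <- 1L
  while (bi + block - 1L <= cell_rows) {
    bj <- 1L
    while (bj + block - 1L <= cell_cols) {
      nfeat <- nfeat + block * block * bins
      bj <- bj + stride
    }
    bi <- bi + stride
  }
  nfeat
}
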