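# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's modular-arithmetic / tabulate shortcuts: the GridMask
# oracle paints every drop square explicitly, the confusion oracle loops over
# pixels.

# enumerate drop squares at (dy + a*d, dx + b*d) and paint them zero
oracle_gridmask <- function(r, d, dx, dy, height, width) {
  s <- round((1 - r) * d)
  m <- matrix(1L, height, width)
  if (s > 0) {
    for (a in seq(-1L, ceiling(height / d) + 1L)) {
      for (b in seq(-1L, ceiling(width / d) + 1L)) {
        i0 <- dy + a * d # 0-based top-left of the drop square
        j0 <- dx + b * d
        ii <- intersect(seq(i0, i0 + s - 1L), seq(0L, height - 1L))
        jj <- intersect(seq(j0, j0 + s - 1L), seq(0L, width - 1L))
        if (length(ii) && length(jj)) m[ii + 1L, jj + 1L] <- 0L
      }
    }
  }
  m
}

# per-pixel counting oracle for the confusion counts of class k
oracle_confusion <- function(pred, truth, k) {
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_along(pred)) {
    p <- pred[i] == k
    t <- truth[i] == k
    if (p && t) tp <- tp + 1L
    else if (p && !t) fp <- fp + 1L
    else if (!p && t) fn <- fn + 1L
    else tn <- tn + 1L
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

oracle_metrics <- function(pred, truth, num_classes) {
  iou <- dsc <- numeric(num_classes)
  for (k in seq_len(num_classes) - 1L) {
    cc <- oracle_confusion(pred, truth, k)
    u <- cc["tp"] + cc["fp"] + cc["fn"]
    iou[k + 1L] <- if (u == 0) 1 else cc["tp"] / u
    d2 <- 2 * cc["tp"] + cc["fp"] + cc["fn"]
    dsc[k + 1L] <- if (d2 == 0) 1 else 2 * cc["tp"] / d2
  }
  list(iou = iou, dsc = dsc, mean_iou = mean(iou), mean_dsc = mean(dsc))
}

# tiny in-memory dataset for smoke training tests
tiny_dataset <- function(n = 4, size = 32, seed = 1) {
  generate_scenes(scene_config(height = size, width = size), n, seed = seed)
}

# mild standard-augmentation settings used by the training experiments
study_augment <- function() {
  augment_config(rotation_deg = 15, hflip_prob = 0.5,
                 brightness_delta = 0.1, noise_sd = 0.02)
}
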