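#' Standard augmentation configuration
#'
#' Ranges for the usual joint image/label augmentations applied before
#' GridMask: rotation, flips, scaling, translation, elastic deformation,
#' brightness adjustment, noise injection, and cropping. A transform whose
#' range is degenerate (0, or `c(1, 1)` for scale) is disabled.
#'
#' Geometric transforms use one shared coordinate map for image and label so
#' the pair stays aligned; the image is resampled bilinearly, the label with
#' nearest-neighbour so it stays strictly binary. Photometric transforms
#' (brightness, noise) touch the image only.
#'
#' @param rotation_deg Maximum absolute rotation in degrees; the angle is
#'   drawn uniformly from `[-rotation_deg, rotation_deg]`.
#' @param hflip_prob,vflip_prob Probabilities of horizontal / vertical flips.
#' @param scale_range Length-2 multiplicative zoom range, e.g. `c(0.9, 1.1)`.
#' @param translate_px Maximum absolute translation in pixels along each axis.
#' @param elastic_amplitude Peak displacement of the elastic field in pixels
#'   (0 disables).
#' @param elastic_sigma Gaussian smoothing scale of the elastic displacement
#'   field in pixels.
#' @param brightness_delta Maximum absolute additive intensity shift.
#' @param noise_sd Standard deviation of additive Gaussian pixel noise.
#' @param crop_size Optional length-2 `c(height, width)` of a random crop
#'   taken after the other transforms; `NULL` disables cropping.
#' @return An object of class `augment_config`.
#' @export
augment_config <- function(rotation_deg = 0, hflip_prob = 0, vflip_prob = 0,
                           scale_range = c(1, 1), translate_px = 0,
                           elastic_amplitude = 0, elastic_sigma = 8,
                           brightness_delta = 0, noise_sd = 0,
                           crop_size = NULL) {
  check_scalar_number(rotation_deg, "rotation_deg", lo = 0)
  check_scalar_number(hflip_prob, "hflip_prob", lo = 0, hi = 1)
  check_scalar_number(vflip_prob, "vflip_prob", lo = 0, hi = 1)
  if (length(scale_range) != 2L || any(scale_range <= 0) ||
      scale_range[2] < scale_range[1])
    stop_invalid("scale_range must be two positive numbers, low <= high")
  check_scalar_number(translate_px, "translate_px", lo = 0)
  check_scalar_number(elastic_amplitude, "elastic_amplitude", lo = 0)
  check_scalar_number(elastic_sigma, "elastic_sigma", lo = 0.5)
  check_scalar_number(brightness_delta, "brightness_delta", lo = 0)
  check_scalar_number(noise_sd, "noise_sd", lo = 0)
  if (!is.null(crop_size)) {
    if (length(crop_size) != 2L || any(crop_size < 1))
      stop_invalid("crop_size must be c(height, width), both >= 1")
    crop_size <- as.integer(crop_size)
  }
  structure(list(rotation_deg = rotation_deg, hflip_prob = hflip_prob,
                 vflip_prob = vflip_prob, scale_range = scale_range,
                 translate_px = translate_px,
                 elastic_amplitude = elastic_amplitude,
                 elastic_sigma = elastic_sigma,
                 brightness_delta = brightness_delta, noise_sd = noise_sd,
                 crop_size = crop_size),
            class = "augment_config")
}

# smoothed random displacement field (one component), amplitude-normalised
elastic_field <- function(h, w, amplitude, sigma) {
  sigma <- min(sigma, (min(h, w) - 2) / 7) # smoothing brush must fit the frame
  f <- matrix(runif(h * w, -1, 1), h, w)
  f <- EBImage::gblur(f, sigma = sigma)
  m <- max(abs(f))
  if (m > 0) f <- f / m
  f * amplitude
}

# inverse-map resampling shared by image (bilinear) and label (nearest);
# out-of-bounds sources are filled with 0 (background)
warp_pair <- function(image, label, src_i, src_j) {
  h <- dim(image)[1]; w <- dim(image)[2]; nc <- dim(image)[3]
  # nearest for the label
  ni <- round(src_i); nj <- round(src_j)
  ok <- ni >= 1 & ni <= h & nj >= 1 & nj <= w
  lab <- matrix(0L, h, w)
  lab[ok] <- label[cbind(ni[ok], nj[ok])]
  # bilinear for the image
  i0 <- floor(src_i); j0 <- floor(src_j)
  fi <- src_i - i0; fj <- src_j - j0
  out <- array(0, dim(image))
  corner <- function(ii, jj) {
    inb <- ii >= 1 & ii <= h & jj >= 1 & jj <= w
    idx <- cbind(pmin(pmax(ii, 1L), h), pmin(pmax(jj, 1L), w))
    list(inb = inb, idx = idx)
  }
  c00 <- corner(i0, j0);       c10 <- corner(i0 + 1, j0)
  c01 <- corner(i0, j0 + 1);   c11 <- corner(i0 + 1, j0 + 1)
  w00 <- (1 - fi) * (1 - fj); w10 <- fi * (1 - fj)
  w01 <- (1 - fi) * fj;       w11 <- fi * fj
  for (c in seq_len(nc)) {
    ch <- image[, , c]
    v <- w00 * ifelse(c00$inb, ch[c00$idx], 0) +
         w10 * ifelse(c10$inb, ch[c10$idx], 0) +
         w01 * ifelse(c01$inb, ch[c01$idx], 0) +
         w11 * ifelse(c11$inb, ch[c11$idx], 0)
    out[, , c] <- matrix(v, h, w)
  }
  list(image = out, label = lab)
}

#' Apply the standard augmentation stack to one sample
#'
#' Draws transform parameters from the R random stream and applies, in order:
#' flips (pure index reversal, exact), the composed rotation/scale/translation
#' warp with optional elastic deformation (skipped entirely when all are
#' disabled, so the disabled configuration is the identity), a random crop,
#' then brightness shift and Gaussian noise on the image only. Output
#' intensities are clipped to `[0, 1]`.
#'
#' @param image An `H x W x C` array in `[0, 1]`.
#' @param label An `H x W` binary matrix aligned with `image`.
#' @param config An [augment_config()].
#' @return A list with elements `image` and `label`.
#' @export
apply_standard <- function(image, label, config) {
  check_image(image)
  check_binary_mask(label, "label")
  if (!identical(dim(image)[1:2], dim(label)))
    stop_invalid("label dimensions must equal the image spatial dimensions")
  if (!inherits(config, "augment_config"))
    stop_invalid("config must be an augment_config")
  h <- dim(image)[1]; w <- dim(image)[2]

  if (config$hflip_prob > 0 && runif(1) < config$hflip_prob) {
    image <- image[, w:1, , drop = FALSE]
    label <- label[, w:1, drop = FALSE]
  }
  if (config$vflip_prob > 0 && runif(1) < config$vflip_prob) {
    image <- image[h:1, , , drop = FALSE]
    label <- label[h:1, , drop = FALSE]
  }

  need_warp <- config$rotation_deg > 0 ||
    any(config$scale_range != 1) || config$translate_px > 0 ||
    config$elastic_amplitude > 0
  if (need_warp) {
    theta <- if (config$rotation_deg > 0)
      runif(1, -config$rotation_deg, config$rotation_deg) * pi / 180 else 0
    s <- if (any(config$scale_range != 1))
      runif(1, config$scale_range[1], config$scale_range[2]) else 1
    tx <- if (config$translate_px > 0)
      runif(1, -config$translate_px, config$translate_px) else 0
    ty <- if (config$translate_px > 0)
      runif(1, -config$translate_px, config$translate_px) else 0
    cy <- (h + 1) / 2; cx <- (w + 1) / 2
    ij <- expand.grid(i = seq_len(h), j = seq_len(w))
    dy <- ij$i - cy - ty; dx <- ij$j - cx - tx
    # inverse map: rotate by -theta, scale by 1/s
    src_i <- cy + (cos(theta) * dy + sin(theta) * dx) / s
    src_j <- cx + (-sin(theta) * dy + cos(theta) * dx) / s
    if (config$elastic_amplitude > 0) {
      src_i <- src_i + as.vector(elastic_field(h, w, config$elastic_amplitude,
                                               config$elastic_sigma))
      src_j <- src_j + as.vector(elastic_field(h, w, config$elastic_amplitude,
                                               config$elastic_sigma))
    }
    warped <- warp_pair(image, label, src_i, src_j)
    image <- warped$image
    label <- warped$label
  }

  if (!is.null(config$crop_size)) {
    ch <- min(config$crop_size[1], h); cw <- min(config$crop_size[2], w)
    r0 <- if (h > ch) sample.int(h - ch + 1L, 1L) - 1L else 0L
    c0 <- if (w > cw) sample.int(w - cw + 1L, 1L) - 1L else 0L
    image <- image[r0 + seq_len(ch), c0 + seq_len(cw), , drop = FALSE]
    label <- label[r0 + seq_len(ch), c0 + seq_len(cw), drop = FALSE]
  }

  if (config$brightness_delta > 0)
    image <- image + runif(1, -config$brightness_delta,
                           config$brightness_delta)
  if (config$noise_sd > 0)
    image <- image + array(rnorm(length(image), sd = config$noise_sd),
                           dim(image))
  if (config$brightness_delta > 0 || config$noise_sd > 0)
    image <- pmin(pmax(image, 0), 1)

  storage.mode(label) <- "integer"
  list(image = image, label = label)
}
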