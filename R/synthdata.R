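#' Synthetic surgical-scene configuration
#'
#' Parameters of the synthetic endoscopic frames used to exercise the
#' pipeline without external data: elongated articulated metallic tools
#' entering from the image borders (biased towards the bottom corners, the
#' typical instrument geometry in endoscopic video), over a smoothly textured
#' reddish tissue-like background, with optional tissue-coloured occluders
#' over the tools, specular streaks, and red splash-like blobs. Foreground
#' fractions are small, reproducing the class imbalance that motivates the
#' balanced loss.
#'
#' @param height,width Frame size in pixels.
#' @param n_tools Number of instruments per frame (>= 0).
#' @param tool_width Length-2 range of shaft widths in pixels.
#' @param tool_length Length-2 range of shaft lengths as fractions of
#'   `min(height, width)`.
#' @param bg_texture_scale Gaussian smoothing scale of the background texture
#'   in pixels.
#' @param bg_contrast Amplitude of the background texture in intensity units.
#' @param specular_prob Probability of a specular streak per tool.
#' @param occluder_prob Probability of a tissue-coloured occluder per tool
#'   (drawn on the image only; labels are never edited).
#' @param occluder_size Length-2 range of occluder radii in pixels.
#' @param splash_prob Probability of a red splash blob per frame.
#' @param seed Optional integer seed making a scene fully deterministic.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(height = 64L, width = 64L, n_tools = 2L,
                         tool_width = c(4, 8), tool_length = c(0.4, 0.9),
                         bg_texture_scale = 8, bg_contrast = 0.25,
                         specular_prob = 0.5, occluder_prob = 0.3,
                         occluder_size = c(3, 7), splash_prob = 0.3,
                         seed = NULL) {
  check_scalar_number(height, "height", lo = 8, integer = TRUE)
  check_scalar_number(width, "width", lo = 8, integer = TRUE)
  check_scalar_number(n_tools, "n_tools", lo = 0, integer = TRUE)
  if (length(tool_width) != 2L || any(tool_width < 1) ||
      tool_width[2] > min(height, width) / 2)
    stop_invalid("tool_width range must fit the frame")
  if (length(tool_length) != 2L || any(tool_length <= 0) ||
      any(tool_length > 1.5))
    stop_invalid("tool_length must be fractions of min(height, width)")
  check_scalar_number(bg_texture_scale, "bg_texture_scale", lo = 1)
  check_scalar_number(bg_contrast, "bg_contrast", lo = 0, hi = 1)
  for (p in c("specular_prob", "occluder_prob", "splash_prob"))
    check_scalar_number(get(p), p, lo = 0, hi = 1)
  if (length(occluder_size) != 2L || any(occluder_size < 1))
    stop_invalid("occluder_size must be a positive length-2 range")
  if (!is.null(seed)) check_scalar_number(seed, "seed", integer = TRUE)
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_tools = as.integer(n_tools), tool_width = tool_width,
                 tool_length = tool_length,
                 bg_texture_scale = bg_texture_scale,
                 bg_contrast = bg_contrast, specular_prob = specular_prob,
                 occluder_prob = occluder_prob,
                 occluder_size = occluder_size, splash_prob = splash_prob,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "scene_config")
}

# squared distance from every pixel to segment a--b (2-vectors, (row, col))
segment_dist2 <- function(px, py, a, b) {
  vx <- b[2] - a[2]; vy <- b[1] - a[1]
  l2 <- vx^2 + vy^2
  t <- if (l2 == 0) 0 else
    pmin(pmax(((px - a[2]) * vx + (py - a[1]) * vy) / l2, 0), 1)
  (px - (a[2] + t * vx))^2 + (py - (a[1] + t * vy))^2
}

disc_mask <- function(px, py, centre, radius) {
  (px - centre[2])^2 + (py - centre[1])^2 <= radius^2
}

# smoothed noise matrix scaled to [-1, 1]; the smoothing brush must fit the
# frame, so sigma is capped relative to the short side
texture_field <- function(h, w, sigma) {
  sigma <- min(sigma, (min(h, w) - 2) / 7)
  f <- EBImage::gblur(matrix(runif(h * w, -1, 1), h, w), sigma = sigma)
  m <- max(abs(f))
  if (m > 0) f / m else f
}

#' Generate one synthetic surgical scene
#'
#' Renders the background, tools, occluders and splash blobs described by a
#' [scene_config()] and returns the RGB frame with its binary ground-truth
#' instrument mask. Occluders and splashes are painted on the image only —
#' the label keeps the full tool extent, which is exactly the occlusion
#' robustness the GridMask training targets.
#'
#' @param config A [scene_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return A list with `image` (`H x W x 3` array in `[0, 1]`) and `label`
#'   (`H x W` integer 0/1 matrix).
#' @export
generate_scene <- function(config, seed = NULL) {
  if (!inherits(config, "scene_config"))
    stop_invalid("config must be a scene_config")
  if (is.null(seed)) seed <- config$seed
  if (!is.null(seed)) set.seed(seed)
  h <- config$height; w <- config$width
  py <- matrix(seq_len(h), h, w)
  px <- matrix(seq_len(w), h, w, byrow = TRUE)

  # tissue-like background: reddish base hue modulated by smooth texture
  tex <- texture_field(h, w, config$bg_texture_scale) * config$bg_contrast
  tex2 <- texture_field(h, w, config$bg_texture_scale / 2) *
    config$bg_contrast / 2
  image <- array(0, c(h, w, 3))
  image[, , 1] <- 0.55 + tex + 0.3 * tex2
  image[, , 2] <- 0.27 + 0.6 * tex + 0.2 * tex2
  image[, , 3] <- 0.25 + 0.5 * tex

  label <- matrix(0L, h, w)
  tool_masks <- vector("list", config$n_tools)
  if (config$n_tools > 0) for (t in seq_len(config$n_tools)) {
    # entry point: biased to the bottom corners, else any border point
    if (runif(1) < 0.6) {
      corner <- sample(c(1L, 2L), 1L)
      p0 <- c(h - runif(1, 0, 0.15) * h,
              if (corner == 1L) runif(1, 0, 0.25) * w
              else w - runif(1, 0, 0.25) * w)
    } else {
      side <- sample.int(4L, 1L)
      u <- runif(1)
      p0 <- switch(side, c(1, u * w), c(h, u * w), c(u * h, 1), c(u * h, w))
    }
    centre <- c(h / 2, w / 2)
    ang <- atan2(centre[1] - p0[1], centre[2] - p0[2]) +
      runif(1, -0.35, 0.35)
    len <- runif(1, config$tool_length[1], config$tool_length[2]) * min(h, w)
    width_t <- runif(1, config$tool_width[1], config$tool_width[2])
    p1 <- p0 + len * c(sin(ang), cos(ang))
    # articulated tip: shorter segment bent off the shaft axis
    bend <- ang + sample(c(-1, 1), 1) * runif(1, 0.2, 0.7)
    p2 <- p1 + 0.3 * len * c(sin(bend), cos(bend))
    d2_shaft <- segment_dist2(px, py, p0, p1)
    d2_tip <- segment_dist2(px, py, p1, p2)
    half <- width_t / 2
    tool <- d2_shaft <= half^2 | d2_tip <= (0.8 * half)^2
    tool_masks[[t]] <- tool

    # metallic shading: gray base, darker towards the edge of the shaft
    base_g <- runif(1, 0.55, 0.8)
    d2 <- pmin(d2_shaft, d2_tip / 0.8^2)
    shade <- base_g - 0.25 * sqrt(pmax(d2, 0)) / half
    for (c in 1:3) {
      ch <- image[, , c]
      ch[tool] <- pmin(pmax(shade[tool] * c(1, 1, 1.06)[c], 0), 1)
      image[, , c] <- ch
    }
    if (runif(1) < config$specular_prob) {
      # thin bright streak along the shaft axis
      off <- runif(1, -0.3, 0.3) * half
      n_vec <- c(cos(ang), -sin(ang)) # normal (row, col)
      spec <- segment_dist2(px, py, p0 + off * n_vec, p1 + off * n_vec) <=
        (0.35 * half)^2 & tool
      for (c in 1:3) {
        ch <- image[, , c]
        ch[spec] <- 0.95
        image[, , c] <- ch
      }
    }
    label[tool] <- 1L

    if (runif(1) < config$occluder_prob && any(tool)) {
      idx <- which(tool)
      centre_px <- idx[sample.int(length(idx), 1L)]
      cy <- (centre_px - 1L) %% h + 1L
      cx <- (centre_px - 1L) %/% h + 1L
      r <- runif(1, config$occluder_size[1], config$occluder_size[2])
      occ <- disc_mask(px, py, c(cy, cx), r)
      occ_col <- c(0.6 + runif(1, -0.08, 0.08), 0.3, 0.28)
      for (c in 1:3) {
        ch <- image[, , c]
        ch[occ] <- occ_col[c]
        image[, , c] <- ch
      }
    }
  }

  if (runif(1) < config$splash_prob) {
    centre_s <- c(runif(1, 1, h), runif(1, 1, w))
    r <- runif(1, 0.05, 0.15) * min(h, w)
    blob <- disc_mask(px, py, centre_s, r) &
      (texture_field(h, w, 2) > -0.3)
    col <- c(0.55, 0.06, 0.06)
    for (c in 1:3) {
      ch <- image[, , c]
      ch[blob] <- 0.35 * ch[blob] + 0.65 * col[c]
      image[, , c] <- ch
    }
  }

  image <- pmin(pmax(image, 0), 1)
  list(image = image, label = label)
}

#' Generate a list of scenes in memory
#'
#' Convenience wrapper producing a `seg_dataset` (lists of images and masks)
#' from consecutive seeds `seed, seed + 1, ...`, so any scene can be
#' regenerated in isolation.
#'
#' @param config A [scene_config()].
#' @param n_scenes Number of frames.
#' @param seed Seed of the first scene (default 1).
#' @return A `seg_dataset`: list with `images`, `masks`, `config`.
#' @export
generate_scenes <- function(config, n_scenes, seed = 1L) {
  check_scalar_number(n_scenes, "n_scenes", lo = 1, integer = TRUE)
  scenes <- lapply(seq_len(n_scenes) - 1L,
                   function(i) generate_scene(config, seed = seed + i))
  structure(list(images = lapply(scenes, `[[`, "image"),
                 masks = lapply(scenes, `[[`, "label"),
                 config = config),
            class = "seg_dataset")
}

#' Write a synthetic dataset to disk
#'
#' Writes `images/NNN.png` (8-bit RGB) and `masks/NNN.png` (8-bit grayscale,
#' 0/255) pairs plus a `manifest.json` listing the files and the generating
#' configuration. Regenerating with the same config and seed reproduces the
#' files byte for byte.
#'
#' @param config A [scene_config()].
#' @param n_scenes Number of frames (>= 1).
#' @param out_dir Output directory (created if missing).
#' @param seed Seed of the first scene.
#' @return The manifest, invisibly.
#' @export
generate_dataset <- function(config, n_scenes, out_dir, seed = 1L) {
  ds <- generate_scenes(config, n_scenes, seed = seed)
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE,
             showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  entries <- vector("list", n_scenes)
  for (i in seq_len(n_scenes)) {
    nm <- sprintf("%03d.png", i - 1L)
    png::writePNG(ds$images[[i]], file.path(out_dir, "images", nm))
    png::writePNG(ds$masks[[i]] * 1.0, file.path(out_dir, "masks", nm))
    entries[[i]] <- list(image = file.path("images", nm),
                         mask = file.path("masks", nm))
  }
  manifest <- list(n_scenes = n_scenes, seed = seed,
                   config = unclass(config), files = entries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}

#' Read a dataset written by [generate_dataset()]
#'
#' @param dir Dataset directory containing `images/`, `masks/` and
#'   `manifest.json`.
#' @return A `seg_dataset`.
#' @export
read_dataset <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path)) stop_invalid("no manifest.json under ", dir)
  mf <- jsonlite::read_json(mf_path)
  images <- list(); masks <- list()
  for (e in mf$files) {
    img <- png::readPNG(file.path(dir, e$image))
    m <- png::readPNG(file.path(dir, e$mask))
    if (length(dim(m)) == 3L) m <- m[, , 1]
    masks[[length(masks) + 1L]] <- matrix(as.integer(m > 0.5), nrow(m),
                                          ncol(m))
    images[[length(images) + 1L]] <- img
  }
  structure(list(images = images, masks = masks, config = mf$config),
            class = "seg_dataset")
}

#' Occluded variant of a dataset
#'
#' Adds tissue-coloured discs over each frame until approximately
#' `occlusion_level` of that frame's tool pixels are covered. Labels are left
#' untouched: the model is asked to recover the full tool under occlusion,
#' the robustness property GridMask training is meant to buy.
#'
#' @param dataset A `seg_dataset`.
#' @param occlusion_level Target fraction of tool pixels to cover, in
#'   `[0, 1]`.
#' @param seed Seed for the occluder placement.
#' @return A `seg_dataset` with modified images and identical masks.
#' @export
occluded_variant <- function(dataset, occlusion_level, seed = 1L) {
  check_scalar_number(occlusion_level, "occlusion_level", lo = 0, hi = 1)
  if (occlusion_level == 0) return(dataset)
  set.seed(seed)
  out <- dataset
  for (f in seq_along(dataset$images)) {
    img <- dataset$images[[f]]
    lab <- dataset$masks[[f]]
    tool_idx <- which(lab == 1L)
    if (length(tool_idx) == 0L) next
    h <- nrow(lab); w <- ncol(lab)
    py <- matrix(seq_len(h), h, w)
    px <- matrix(seq_len(w), h, w, byrow = TRUE)
    covered <- matrix(FALSE, h, w)
    target <- occlusion_level * length(tool_idx)
    tries <- 0L
    while (sum(covered[tool_idx]) < target && tries < 200L) {
      centre_px <- tool_idx[sample.int(length(tool_idx), 1L)]
      cy <- (centre_px - 1L) %% h + 1L
      cx <- (centre_px - 1L) %/% h + 1L
      r <- runif(1, 2.5, 5.5)
      occ <- disc_mask(px, py, c(cy, cx), r)
      covered <- covered | occ
      col <- c(0.6 + runif(1, -0.06, 0.06), 0.3, 0.28)
      for (c in 1:3) {
        ch <- img[, , c]
        ch[occ] <- col[c]
        img[, , c] <- ch
      }
      tries <- tries + 1L
    }
    out$images[[f]] <- img
  }
  out
}
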