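#' Segmentation model configuration
#'
#' Describes an encoder-decoder segmentation network. Two variants are
#' provided: `"unet"`, a plain U-Net baseline (3x3 convolutions, dilation 1,
#' concatenation skips), and `"enhanced"`, which deepens the context of the
#' encoder with dilated convolutions, replaces concatenation skips with
#' residual (additive) skips after a 1x1 channel projection, optionally gates
#' the skip/decoder merge with adaptive feature fusion, and uses depthwise
#' separable convolutions to cut parameters.
#'
#' @param variant `"unet"` or `"enhanced"`.
#' @param in_channels Input channel count `C` (3 for RGB).
#' @param num_classes Number of classes `K` (>= 2; 2 = background/foreground).
#' @param depth Number of resolution levels (>= 2). An input must have sides
#'   divisible by `2^(depth - 1)`.
#' @param base_channels Channel count at the first level; doubled per level.
#' @param dilation_rates Integer vector of per-level encoder dilation factors
#'   (length `depth`). Defaults: all 1 for `"unet"`; doubling at the two
#'   deepest levels (e.g. `c(1, 1, 2, 4)` at depth 4) for `"enhanced"`, which
#'   widens the receptive field without extra downsampling.
#' @param use_residual_skips Additive projected skips instead of
#'   concatenation (enhanced default `TRUE`).
#' @param use_adaptive_fusion Learned convex gate between skip and upsampled
#'   decoder features (enhanced default `TRUE`).
#' @param use_depthwise_separable Replace 3x3 convolutions by a depthwise 3x3
#'   plus pointwise 1x1 pair (enhanced default `TRUE`).
#' @return An object of class `model_config`.
#' @export
model_config <- function(variant = c("enhanced", "unet"), in_channels = 3L,
                         num_classes = 2L, depth = 4L, base_channels = 8L,
                         dilation_rates = NULL, use_residual_skips = NULL,
                         use_adaptive_fusion = NULL,
                         use_depthwise_separable = NULL) {
  variant <- match.arg(variant)
  check_scalar_number(in_channels, "in_channels", lo = 1, integer = TRUE)
  check_scalar_number(num_classes, "num_classes", lo = 2, integer = TRUE)
  check_scalar_number(depth, "depth", lo = 2, integer = TRUE)
  check_scalar_number(base_channels, "base_channels", lo = 1, integer = TRUE)
  enh <- variant == "enhanced"
  if (is.null(dilation_rates)) {
    dilation_rates <- rep(1L, depth)
    if (enh && depth >= 2) {
      dilation_rates[depth] <- 4L
      dilation_rates[depth - 1L] <- 2L
    }
  }
  if (length(dilation_rates) != depth || any(dilation_rates < 1) ||
      any(dilation_rates != round(dilation_rates)))
    stop_invalid("dilation_rates must be ", depth, " positive integers")
  if (!enh && any(dilation_rates != 1))
    stop_invalid("the unet variant uses dilation 1 everywhere")
  flag <- function(x) if (is.null(x)) enh else isTRUE(x)
  structure(list(variant = variant, in_channels = as.integer(in_channels),
                 num_classes = as.integer(num_classes),
                 depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 dilation_rates = as.integer(dilation_rates),
                 use_residual_skips = flag(use_residual_skips),
                 use_adaptive_fusion = flag(use_adaptive_fusion),
                 use_depthwise_separable = flag(use_depthwise_separable)),
            class = "model_config")
}

# parameter initialisers (He for ReLU layers), drawn from the R RNG
init_conv <- function(cin, cout, k) {
  fan_in <- k * k * cin
  list(w = matrix(rnorm(fan_in * cout, sd = sqrt(2 / fan_in)), fan_in, cout),
       b = numeric(cout))
}
init_dwconv <- function(c, k) {
  list(w = matrix(rnorm(k * k * c, sd = sqrt(2 / (k * k))), k * k, c),
       b = numeric(c))
}

level_channels <- function(config) {
  config$base_channels * 2L^(seq_len(config$depth) - 1L)
}

#' Build a segmentation model
#'
#' Instantiates the parameter set described by a [model_config()]. Weights
#' are drawn from the R random stream (He initialisation), so
#' `set.seed(); build_model(cfg)` is reproducible.
#'
#' @param config A [model_config()].
#' @param seed Optional integer; when given, `set.seed(seed)` is called first.
#' @return An object of class `seg_model` with elements `config`, `params`
#'   (named list of weight arrays) and `layers` (layer descriptors).
#' @seealso [predict.seg_model()], [parameter_count()], [train_model()]
#' @export
build_model <- function(config, seed = NULL) {
  if (!inherits(config, "model_config"))
    stop_invalid("config must be a model_config")
  if (!is.null(seed)) set.seed(seed)
  ch <- level_channels(config)
  params <- list()
  layers <- list()
  add_conv3 <- function(name, cin, cout) {
    # a "3x3 conv" is either standard or a depthwise + pointwise pair
    if (config$use_depthwise_separable) {
      params[[paste0(name, "_dw")]] <<- init_dwconv(cin, 3L)
      params[[paste0(name, "_pw")]] <<- init_conv(cin, cout, 1L)
      layers[[name]] <<- list(type = "sepconv", cin = cin, cout = cout)
    } else {
      params[[name]] <<- init_conv(cin, cout, 3L)
      layers[[name]] <<- list(type = "conv", k = 3L, cin = cin, cout = cout)
    }
  }
  add_conv1 <- function(name, cin, cout) {
    params[[name]] <<- init_conv(cin, cout, 1L)
    layers[[name]] <<- list(type = "conv", k = 1L, cin = cin, cout = cout)
  }
  for (l in seq_len(config$depth)) {
    cin <- if (l == 1L) config$in_channels else ch[l - 1L]
    add_conv3(sprintf("enc%d_conv1", l), cin, ch[l])
    add_conv3(sprintf("enc%d_conv2", l), ch[l], ch[l])
  }
  for (l in seq(config$depth - 1L, 1L)) {
    add_conv3(sprintf("up%d_conv", l), ch[l + 1L], ch[l])
    if (config$use_residual_skips) {
      add_conv1(sprintf("proj%d", l), ch[l], ch[l])
      if (config$use_adaptive_fusion)
        add_conv1(sprintf("fuse%d", l), 2L * ch[l], ch[l])
      dec_in <- ch[l]
    } else {
      dec_in <- 2L * ch[l]
    }
    add_conv3(sprintf("dec%d_conv1", l), dec_in, ch[l])
    add_conv3(sprintf("dec%d_conv2", l), ch[l], ch[l])
  }
  add_conv1("head", ch[1L], config$num_classes)
  structure(list(config = config, params = params, layers = layers),
            class = "seg_model")
}

#' @export
print.seg_model <- function(x, ...) {
  cat(sprintf("seg_model (%s): depth %d, base %d channels, %d classes, %d parameters\n",
              x$config$variant, x$config$depth, x$config$base_channels,
              x$config$num_classes, parameter_count(x)))
  invisible(x)
}

#' Total trainable parameter count of a model
#' @param model A `seg_model`.
#' @return Integer parameter count.
#' @export
parameter_count <- function(model) {
  sum(vapply(model$params, function(p) length(p$w) + length(p$b), numeric(1)))
}

# wrap the model parameters as graph leaves; returns (nodes, same names)
param_leaves <- function(graph, model) {
  lapply(model$params, function(p)
    list(w = ag_leaf(graph, p$w), b = ag_leaf(graph, p$b)))
}

# one named "3x3 conv" unit (standard or separable) followed by ReLU
fwd_conv3 <- function(graph, x, leaves, layer, name, dil) {
  if (layer$type == "sepconv") {
    dw <- leaves[[paste0(name, "_dw")]]
    pw <- leaves[[paste0(name, "_pw")]]
    h <- op_dwconv(graph, x, dw$w, dw$b, 3L, dil)
    op_conv(graph, h, pw$w, pw$b, 1L, 1L)
  } else {
    p <- leaves[[name]]
    op_conv(graph, x, p$w, p$b, 3L, dil)
  }
}

# full forward pass; returns the scores node (H x W x K)
forward_scores <- function(graph, model, leaves, x_node) {
  cfg <- model$config
  d <- dim(x_node$v)
  div <- 2L^(cfg$depth - 1L)
  if (d[1] %% div != 0 || d[2] %% div != 0)
    stop_invalid("input sides must be divisible by ", div,
                 " for depth ", cfg$depth)
  enc <- vector("list", cfg$depth)
  h <- x_node
  for (l in seq_len(cfg$depth)) {
    dil <- cfg$dilation_rates[l]
    h <- op_relu(graph, fwd_conv3(graph, h, leaves, model$layers[[
      sprintf("enc%d_conv1", l)]], sprintf("enc%d_conv1", l), dil))
    h <- op_relu(graph, fwd_conv3(graph, h, leaves, model$layers[[
      sprintf("enc%d_conv2", l)]], sprintf("enc%d_conv2", l), dil))
    enc[[l]] <- h
    if (l < cfg$depth) h <- op_maxpool(graph, h)
  }
  for (l in seq(cfg$depth - 1L, 1L)) {
    h <- op_upsample(graph, h)
    h <- op_relu(graph, fwd_conv3(graph, h, leaves, model$layers[[
      sprintf("up%d_conv", l)]], sprintf("up%d_conv", l), 1L))
    skip <- enc[[l]]
    if (cfg$use_residual_skips) {
      p <- leaves[[sprintf("proj%d", l)]]
      proj <- op_conv(graph, skip, p$w, p$b, 1L, 1L)
      if (cfg$use_adaptive_fusion) {
        f <- leaves[[sprintf("fuse%d", l)]]
        gate <- op_sigmoid(graph, op_conv(graph, op_concat(graph, proj, h),
                                          f$w, f$b, 1L, 1L))
        h <- op_gate_mix(graph, gate, proj, h)
      } else {
        h <- op_add(graph, proj, h)
      }
    } else {
      h <- op_concat(graph, skip, h)
    }
    h <- op_relu(graph, fwd_conv3(graph, h, leaves, model$layers[[
      sprintf("dec%d_conv1", l)]], sprintf("dec%d_conv1", l), 1L))
    h <- op_relu(graph, fwd_conv3(graph, h, leaves, model$layers[[
      sprintf("dec%d_conv2", l)]], sprintf("dec%d_conv2", l), 1L))
  }
  hp <- leaves[["head"]]
  op_conv(graph, h, hp$w, hp$b, 1L, 1L)
}

# forward without gradient bookkeeping; returns plain score array
model_scores <- function(model, image) {
  graph <- ag_graph()
  leaves <- param_leaves(graph, model)
  x <- ag_leaf(graph, image)
  forward_scores(graph, model, leaves, x)$v
}

#' Predict a label mask for one image
#'
#' Runs the forward pass and takes the per-pixel argmax over class scores.
#'
#' @param object A `seg_model`.
#' @param image An `H x W x C` array with sides divisible by
#'   `2^(depth - 1)`.
#' @param type `"mask"` (default) for the integer label matrix, `"scores"`
#'   for the raw `H x W x K` score array.
#' @param ... Unused.
#' @return An integer `H x W` matrix of class labels in `0..K-1`, or the
#'   score array.
#' @export
predict.seg_model <- function(object, image, type = c("mask", "scores"),
                              ...) {
  type <- match.arg(type)
  check_image(image)
  s <- model_scores(object, image)
  if (type == "scores") return(s)
  lab <- apply(s, c(1, 2), which.max) - 1L
  storage.mode(lab) <- "integer"
  lab
}

#' Adaptive feature fusion
#'
#' Convexly combines encoder skip features with upsampled decoder features
#' through a learned gate: `g * enc + (1 - g) * up`, where
#' `g = sigmoid(conv1x1(concat(enc, up)))` gives a per-channel, per-position
#' weight in (0, 1). Exposed standalone for inspection; inside the network it
#' is applied at every decoder stage when `use_adaptive_fusion` is on.
#'
#' @param encoder_features,upsampled_features `H x W x C` arrays of equal
#'   shape.
#' @param gate_w A `(2C) x C` weight matrix of the 1x1 gate convolution.
#' @param gate_b Length-`C` bias of the gate convolution.
#' @return The fused `H x W x C` array.
#' @export
adaptive_fuse <- function(encoder_features, upsampled_features, gate_w,
                          gate_b) {
  de <- dim(encoder_features); du <- dim(upsampled_features)
  if (!identical(de, du))
    stop_invalid("encoder and upsampled features must have identical shape")
  cc <- array(c(encoder_features, upsampled_features),
              c(de[1], de[2], 2L * de[3]))
  g <- conv2d_fwd(cc, gate_w, gate_b, 1L, 1L)
  g <- 1 / (1 + exp(-g))
  g * encoder_features + (1 - g) * upsampled_features
}

#' Analytic receptive field of stacked convolutions
#'
#' Accumulates the receptive-field recurrence `rf' = rf + (k_eff - 1) * jump`,
#' `jump' = jump * stride`, with effective kernel
#' `k_eff = k + (k - 1)(dilation - 1)`.
#'
#' @param kernels Integer vector of kernel sizes, in order.
#' @param dilations Dilation factor per layer (recycled, default 1).
#' @param strides Stride per layer (recycled, default 1).
#' @return The receptive-field side length in pixels.
#' @examples
#' conv_receptive_field(3)                 # 3
#' conv_receptive_field(c(3, 3))           # 5
#' conv_receptive_field(3, dilations = 2)  # 5
#' @export
conv_receptive_field <- function(kernels, dilations = 1L, strides = 1L) {
  n <- length(kernels)
  dilations <- rep_len(dilations, n)
  strides <- rep_len(strides, n)
  rf <- 1; jump <- 1
  for (i in seq_len(n)) {
    keff <- kernels[i] + (kernels[i] - 1) * (dilations[i] - 1)
    rf <- rf + (keff - 1) * jump
    jump <- jump * strides[i]
  }
  rf
}

#' Receptive field of the deepest encoder unit
#'
#' Computes the analytic receptive field seen by the deepest encoder block of
#' a configuration: two 3x3 convolutions per level at that level's dilation,
#' with a 2x2 stride-2 pooling between levels.
#'
#' @param config A [model_config()].
#' @return Receptive-field side length in input pixels.
#' @export
receptive_field <- function(config) {
  if (!inherits(config, "model_config"))
    stop_invalid("config must be a model_config")
  kernels <- integer(0); dils <- integer(0); strides <- integer(0)
  for (l in seq_len(config$depth)) {
    kernels <- c(kernels, 3L, 3L)
    dils <- c(dils, rep(config$dilation_rates[l], 2L))
    strides <- c(strides, 1L, 1L)
    if (l < config$depth) {
      kernels <- c(kernels, 2L); dils <- c(dils, 1L); strides <- c(strides, 2L)
    }
  }
  conv_receptive_field(kernels, dils, strides)
}

#' Save / load a model checkpoint
#'
#' Serialises the full `seg_model` (configuration and weights) with
#' `saveRDS()`.
#'
#' @param model A `seg_model`.
#' @param path Destination / source file path.
#' @return `load_model` returns the `seg_model`; `save_model` returns `path`
#'   invisibly.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "seg_model")) stop_invalid("file does not hold a seg_model")
  m
}
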