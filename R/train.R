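#' Training configuration
#'
#' Hyperparameters of the training loop: epochs, batch size, the triangular
#' cyclical learning-rate (CLR) schedule with bounds `(base_lr, max_lr)` —
#' defaults `1e-4` and `1e-2` — the class-weighting mode for the balanced
#' cross-entropy, and the augmentation policies applied per sample (standard
#' stack first, then GridMask).
#'
#' @param epochs Number of passes over the training split (>= 1).
#' @param batch_size Samples per optimisation step.
#' @param seed Root seed for shuffling, augmentation and initialisation.
#' @param base_lr,max_lr CLR bounds, `0 < base_lr < max_lr`.
#' @param cycle_steps Length of one CLR cycle in optimisation steps; `NULL`
#'   (default) sets it to two epochs' worth of steps at training time.
#' @param weight_mode `"dataset"` (class frequencies counted once over the
#'   training split, the default), `"batch"` (recomputed per batch) or
#'   `"none"` (uniform weights).
#' @param momentum SGD momentum coefficient.
#' @param val_fraction Fraction of the dataset held out for the per-epoch
#'   validation curves.
#' @param gridmask A [gridmask_policy()] (or `NULL` to disable GridMask).
#' @param augment An [augment_config()] (default: all transforms disabled).
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 10L, batch_size = 4L, seed = 1L,
                         base_lr = 1e-4, max_lr = 1e-2, cycle_steps = NULL,
                         weight_mode = c("dataset", "batch", "none"),
                         momentum = 0.9, val_fraction = 0.2,
                         gridmask = gridmask_policy(),
                         augment = augment_config()) {
  check_scalar_number(epochs, "epochs", lo = 1, integer = TRUE)
  check_scalar_number(batch_size, "batch_size", lo = 1, integer = TRUE)
  check_scalar_number(seed, "seed", integer = TRUE)
  check_scalar_number(base_lr, "base_lr", lo = 1e-12)
  check_scalar_number(max_lr, "max_lr")
  if (max_lr <= base_lr) stop_invalid("train.clr: base_lr must be < max_lr")
  if (!is.null(cycle_steps))
    check_scalar_number(cycle_steps, "cycle_steps", lo = 2, integer = TRUE)
  weight_mode <- match.arg(weight_mode)
  check_scalar_number(momentum, "momentum", lo = 0, hi = 1)
  check_scalar_number(val_fraction, "val_fraction", lo = 0, hi = 0.9)
  if (!is.null(gridmask) && !inherits(gridmask, "gridmask_policy"))
    stop_invalid("gridmask must be a gridmask_policy or NULL")
  if (!inherits(augment, "augment_config"))
    stop_invalid("augment must be an augment_config")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 base_lr = base_lr, max_lr = max_lr,
                 cycle_steps = if (is.null(cycle_steps)) NULL
                               else as.integer(cycle_steps),
                 weight_mode = weight_mode, momentum = momentum,
                 val_fraction = val_fraction, gridmask = gridmask,
                 augment = augment),
            class = "train_config")
}

#' Triangular cyclical learning rate
#'
#' The learning rate rises linearly from `base_lr` at the cycle start to
#' `max_lr` at mid-cycle and falls back linearly, so it attains `base_lr`
#' exactly at step 0 (and every cycle start) and `max_lr` exactly at
#' mid-cycle, never leaving `[base_lr, max_lr]`.
#'
#' @param step Zero-based optimisation step index (vectorised).
#' @param config A [train_config()] whose `cycle_steps` is set, or a list
#'   with `base_lr`, `max_lr`, `cycle_steps`.
#' @return Learning rate(s).
#' @examples
#' cfg <- train_config(cycle_steps = 100)
#' clr(0, cfg)    # 1e-4
#' clr(50, cfg)   # 1e-2
#' @export
clr <- function(step, config) {
  if (any(step < 0)) stop_invalid("step must be >= 0")
  cycle <- config$cycle_steps
  if (is.null(cycle)) stop_invalid("cycle_steps is not set")
  half <- cycle / 2
  pos <- step %% cycle
  config$base_lr + (config$max_lr - config$base_lr) *
    (1 - abs(pos - half) / half)
}

#' Inverse-frequency class weights
#'
#' `w_k` proportional to `1 / max(freq_k, eps)`, normalised so the weights
#' sum to `K`. Classes absent from the histogram hit the `1 / eps` cap, so
#' they get the maximum weight. `mode = "none"` returns uniform weights.
#'
#' @param label_histogram Non-negative per-class pixel counts (length `K`).
#' @param mode `"inverse"` (default) or `"none"`.
#' @param eps Frequency floor (default `1e-6`).
#' @return Numeric weight vector of length `K` summing to `K`.
#' @examples
#' class_weights(c(90, 10)) # (0.2, 1.8)
#' @export
class_weights <- function(label_histogram, mode = c("inverse", "none"),
                          eps = 1e-6) {
  mode <- match.arg(mode)
  if (any(label_histogram < 0) || sum(label_histogram) == 0)
    stop_invalid("label_histogram must be non-negative with a nonzero entry")
  k <- length(label_histogram)
  if (mode == "none") return(rep(1, k))
  freq <- label_histogram / sum(label_histogram)
  w <- 1 / pmax(freq, eps)
  w * k / sum(w)
}

#' Class-weighted cross-entropy loss
#'
#' Softmax cross-entropy over pixels, each pixel's term multiplied by the
#' weight of its true class, averaged over pixels. With uniform weights this
#' is the ordinary per-pixel cross-entropy.
#'
#' @param scores `H x W x K` array of class scores (logits).
#' @param truth `H x W` integer matrix in `0..K-1`.
#' @param weights Length-`K` class weights (default uniform).
#' @return A single non-negative loss value.
#' @export
balanced_loss <- function(scores, truth, weights = NULL) {
  if (!is.array(scores) || length(dim(scores)) != 3L)
    stop_invalid("scores must be an H x W x K array")
  d <- dim(scores)
  if (!is.matrix(truth) || !identical(dim(truth), d[1:2]))
    stop_invalid("truth shape must match the scores' spatial shape")
  if (is.null(weights)) weights <- rep(1, d[3])
  if (length(weights) != d[3]) stop_invalid("weights must have length K")
  t <- truth
  storage.mode(t) <- "integer"
  wce_loss(scores, t, weights)$loss
}

# dataset-level class histogram
label_histogram <- function(masks, k) {
  h <- numeric(k)
  for (m in masks) h <- h + tabulate(as.integer(m) + 1L, nbins = k)
  h
}

#' Train a segmentation model
#'
#' Stochastic-gradient training with momentum under the triangular CLR
#' schedule. Per epoch the training split is visited in a fresh random order;
#' each sample passes through the standard augmentation stack, then GridMask
#' per its policy, before the forward/backward pass of the class-weighted
#' cross-entropy. A held-out split (never augmented) provides the per-epoch
#' validation curves: loss, pixel accuracy, and macro mean DSC. Fully
#' reproducible under the config seed.
#'
#' @param model A `seg_model` from [build_model()].
#' @param dataset A `seg_dataset` or list with `images` (H x W x C arrays in
#'   `[0, 1]`) and `masks` (binary matrices).
#' @param config A [train_config()].
#' @return A list of class `train_history`: `model` (trained), `history`
#'   (data frame with columns epoch, loss, accuracy, mean_dsc) and
#'   `class_weights` used.
#' @export
train_model <- function(model, dataset, config) {
  if (!inherits(model, "seg_model")) stop_invalid("model must be a seg_model")
  if (!inherits(config, "train_config"))
    stop_invalid("config must be a train_config")
  n <- length(dataset$images)
  if (n == 0L) stop_invalid("dataset is empty")
  set.seed(config$seed)
  k <- model$config$num_classes

  n_val <- floor(config$val_fraction * n)
  idx <- sample.int(n)
  val_idx <- if (n_val > 0) idx[seq_len(n_val)] else integer(0)
  tr_idx <- setdiff(idx, val_idx)
  if (length(tr_idx) == 0L) stop_invalid("no training samples after split")

  weights <- switch(config$weight_mode,
    none = rep(1, k),
    batch = NULL, # computed per batch below
    dataset = class_weights(label_histogram(dataset$masks[tr_idx], k)))

  steps_per_epoch <- ceiling(length(tr_idx) / config$batch_size)
  cfg <- config
  if (is.null(cfg$cycle_steps))
    cfg$cycle_steps <- max(2L, 2L * steps_per_epoch)

  velocity <- lapply(model$params, function(p)
    list(w = p$w * 0, b = p$b * 0))
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        accuracy = numeric(0), mean_dsc = numeric(0))
  step <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    order_ <- sample(tr_idx)
    epoch_loss <- 0; n_batches <- 0L
    for (b0 in seq(1L, length(order_), by = cfg$batch_size)) {
      batch <- order_[b0:min(b0 + cfg$batch_size - 1L, length(order_))]
      lr <- clr(step, cfg)
      grads <- NULL
      batch_loss <- 0
      bw <- weights
      if (cfg$weight_mode == "batch")
        bw <- class_weights(label_histogram(dataset$masks[batch], k))
      for (i in batch) {
        img <- dataset$images[[i]]
        lab <- dataset$masks[[i]]
        storage.mode(lab) <- "integer"
        aug <- apply_standard(img, lab, cfg$augment)
        if (!is.null(cfg$gridmask)) {
          gm <- augment_sample(aug$image, aug$label, cfg$gridmask)
          aug <- gm
        }
        graph <- ag_graph()
        leaves <- param_leaves(graph, model)
        x <- ag_leaf(graph, aug$image)
        scores <- forward_scores(graph, model, leaves, x)
        lt <- aug$label
        storage.mode(lt) <- "integer"
        loss_node <- op_wce(graph, scores, lt, bw)
        ag_backward(graph, loss_node)
        batch_loss <- batch_loss + loss_node$v
        g_i <- lapply(leaves, function(l)
          list(w = if (is.null(l$w$g)) l$w$v * 0 else l$w$g,
               b = if (is.null(l$b$g)) l$b$v * 0 else l$b$g))
        grads <- if (is.null(grads)) g_i else
          mapply(function(a, b) list(w = a$w + b$w, b = a$b + b$b),
                 grads, g_i, SIMPLIFY = FALSE)
      }
      nb <- length(batch)
      for (nm in names(model$params)) {
        velocity[[nm]]$w <- cfg$momentum * velocity[[nm]]$w -
          lr * grads[[nm]]$w / nb
        velocity[[nm]]$b <- cfg$momentum * velocity[[nm]]$b -
          lr * grads[[nm]]$b / nb
        model$params[[nm]]$w <- model$params[[nm]]$w + velocity[[nm]]$w
        model$params[[nm]]$b <- model$params[[nm]]$b + velocity[[nm]]$b
      }
      epoch_loss <- epoch_loss + batch_loss / nb
      n_batches <- n_batches + 1L
      step <- step + 1L
    }
    eval_idx <- if (length(val_idx) > 0) val_idx else tr_idx
    ev <- evaluate_model(model, list(images = dataset$images[eval_idx],
                                     masks = dataset$masks[eval_idx]))
    acc <- with(as.data.frame(unclass(ev$counts)),
                sum(tp) / (sum(tp) + sum(fp)))
    history <- rbind(history, data.frame(
      epoch = epoch, loss = epoch_loss / n_batches, accuracy = acc,
      mean_dsc = ev$macro$mean_dsc))
  }
  structure(list(model = model, history = history,
                 class_weights = weights),
            class = "train_history")
}

#' @export
print.train_history <- function(x, ...) {
  cat("Training history:\n")
  print(x$history, row.names = FALSE)
  invisible(x)
}
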