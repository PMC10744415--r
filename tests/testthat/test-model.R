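# closed-form parameter counts for the conv units actually built
count_conv <- function(cin, cout, k) k * k * cin * cout + cout
count_sep <- function(cin, cout) (9 * cin + cin) + (cin * cout + cout)

expected_param_count <- function(cfg) {
  ch <- cfg$base_channels * 2^(seq_len(cfg$depth) - 1)
  unit <- function(cin, cout) {
    if (cfg$use_depthwise_separable) count_sep(cin, cout)
    else count_conv(cin, cout, 3)
  }
  total <- 0
  for (l in seq_len(cfg$depth)) {
    cin <- if (l == 1) cfg$in_channels else ch[l - 1]
    total <- total + unit(cin, ch[l]) + unit(ch[l], ch[l])
  }
  for (l in seq(cfg$depth - 1, 1)) {
    total <- total + unit(ch[l + 1], ch[l])
    if (cfg$use_residual_skips) {
      total <- total + count_conv(ch[l], ch[l], 1)
      if (cfg$use_adaptive_fusion)
        total <- total + count_conv(2 * ch[l], ch[l], 1)
      dec_in <- ch[l]
    } else dec_in <- 2 * ch[l]
    total <- total + unit(dec_in, ch[l]) + unit(ch[l], ch[l])
  }
  total + count_conv(ch[1], cfg$num_classes, 1)
}

test_that("forward pass preserves spatial shape for both variants", {
  for (variant in c("unet", "enhanced")) {
    cfg <- model_config(variant, depth = 4, base_channels = 8)
    model <- build_model(cfg, seed = 1)
    img <- array(runif(64 * 64 * 3), c(64, 64, 3))
    s <- predict(model, img, type = "scores")
    expect_identical(dim(s), c(64L, 64L, 2L))
    lab <- predict(model, img)
    expect_identical(dim(lab), c(64L, 64L))
    expect_true(all(lab %in% 0:1))
  }
  # indivisible input sides are refused
  model <- build_model(model_config(depth = 4), seed = 1)
  expect_error(predict(model, array(0.5, c(60, 60, 3))), "divisible")
})

test_that("parameter counts match the closed-form layer sums", {
  for (variant in c("unet", "enhanced")) {
    for (dw in c(FALSE, TRUE)) {
      cfg <- model_config(variant, depth = 3, base_channels = 4,
                          use_depthwise_separable = dw)
      expect_equal(parameter_count(build_model(cfg, seed = 1)),
                   expected_param_count(cfg))
    }
  }
})

test_that("depthwise separable convolutions strictly reduce parameters", {
  base <- model_config("enhanced", depth = 4, base_channels = 8,
                       use_depthwise_separable = FALSE)
  sep <- model_config("enhanced", depth = 4, base_channels = 8,
                      use_depthwise_separable = TRUE)
  expect_lt(parameter_count(build_model(sep, seed = 1)),
            parameter_count(build_model(base, seed = 1)))
})

test_that("builds are deterministic under a fixed seed", {
  cfg <- model_config("enhanced", depth = 3, base_channels = 4)
  a <- build_model(cfg, seed = 7)
  b <- build_model(cfg, seed = 7)
  expect_identical(a$params, b$params)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  expect_identical(predict(a, img, type = "scores"),
                   predict(b, img, type = "scores"))
})

test_that("adaptive fusion interpolates between its inputs", {
  h <- 4; w <- 4; cc <- 3
  a <- array(runif(h * w * cc), c(h, w, cc))
  b <- array(runif(h * w * cc), c(h, w, cc))
  # saturate the gate high: g -> 1 returns the encoder features
  wz <- matrix(0, 2 * cc, cc)
  expect_equal(adaptive_fuse(a, b, wz, rep(50, cc)), a, tolerance = 1e-12)
  # saturate low: g -> 0 returns the upsampled features
  expect_equal(adaptive_fuse(a, b, wz, rep(-50, cc)), b, tolerance = 1e-12)
  # zero logits: g = 0.5, elementwise mean
  expect_equal(adaptive_fuse(a, b, wz, rep(0, cc)), (a + b) / 2)
  expect_error(adaptive_fuse(a, b[, , 1:2], wz, rep(0, cc)), "shape")
})

test_that("receptive field follows the dilated-convolution recurrence", {
  expect_equal(conv_receptive_field(3), 3)
  expect_equal(conv_receptive_field(c(3, 3)), 5)
  expect_equal(conv_receptive_field(3, dilations = 2), 5)
  # dilated encoder widens the field at equal depth, for several depths
  for (depth in 2:5) {
    rf_enh <- receptive_field(model_config("enhanced", depth = depth))
    rf_base <- receptive_field(model_config("unet", depth = depth))
    expect_gt(rf_enh, rf_base)
  }
})

test_that("analytic gradients match finite differences on a tiny model", {
  cfg <- model_config("enhanced", depth = 2, base_channels = 3,
                      in_channels = 2)
  model <- build_model(cfg, seed = 42)
  set.seed(9)
  img <- array(runif(8 * 8 * 2), c(8, 8, 2))
  lab <- matrix(sample(0:1, 64, TRUE), 8, 8)
  storage.mode(lab) <- "integer"
  wts <- c(0.7, 1.3)
  loss_at <- function(params) {
    model$params <- params
    g <- gridunet:::ag_graph()
    lv <- gridunet:::param_leaves(g, model)
    x <- gridunet:::ag_leaf(g, img)
    s <- gridunet:::forward_scores(g, model, lv, x)
    gridunet:::op_wce(g, s, lab, wts)$v
  }
  g <- gridunet:::ag_graph()
  lv <- gridunet:::param_leaves(g, model)
  x <- gridunet:::ag_leaf(g, img)
  s <- gridunet:::forward_scores(g, model, lv, x)
  ln <- gridunet:::op_wce(g, s, lab, wts)
  gridunet:::ag_backward(g, ln)
  eps <- 1e-6
  for (nm in names(model$params)) for (fld in c("w", "b")) {
    analytic <- lv[[nm]][[fld]]$g
    expect_false(is.null(analytic), label = paste(nm, fld, "gradient"))
    pv <- model$params[[nm]][[fld]]
    for (i in sample(seq_along(pv), min(2, length(pv)))) {
      p2 <- model$params
      p2[[nm]][[fld]][i] <- pv[i] + eps
      l1 <- loss_at(p2)
      p2[[nm]][[fld]][i] <- pv[i] - eps
      l0 <- loss_at(p2)
      num <- (l1 - l0) / (2 * eps)
      expect_lt(abs(num - analytic[i]),
                1e-4 * max(1, abs(num)))
    }
  }
})

test_that("every parameter group receives gradient on a training step", {
  set.seed(3)
  for (variant in c("unet", "enhanced")) {
    model <- build_model(model_config(variant, depth = 3, base_channels = 4),
                         seed = 11)
    sc <- generate_scene(scene_config(height = 32, width = 32), seed = 2)
    g <- gridunet:::ag_graph()
    lv <- gridunet:::param_leaves(g, model)
    x <- gridunet:::ag_leaf(g, sc$image)
    s <- gridunet:::forward_scores(g, model, lv, x)
    lab <- sc$label
    storage.mode(lab) <- "integer"
    ln <- gridunet:::op_wce(g, s, lab, c(1, 1))
    gridunet:::ag_backward(g, ln)
    for (nm in names(lv))
      expect_gt(max(abs(lv[[nm]]$w$g)), 0, label = paste(variant, nm))
  }
})

test_that("model checkpoints round-trip through save/load", {
  model <- build_model(model_config(depth = 2, base_channels = 2), seed = 5)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(model, path)
  expect_identical(load_model(path)$params, model$params)
})
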