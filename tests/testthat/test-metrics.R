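make_example_counts <- function() {
  # 4x4 masks: truth has 4 foreground pixels, prediction covers 2 of them
  # plus 2 background pixels
  truth <- matrix(0L, 4, 4)
  truth[1, 1:4] <- 1L
  pred <- matrix(0L, 4, 4)
  pred[1, 1:2] <- 1L # 2 true positives
  pred[2, 1:2] <- 1L # 2 false positives
  confusion(pred, truth)
}

test_that("confusion produces exact per-class counts", {
  cc <- make_example_counts()
  expect_equal(unname(cc["class1", ]), c(2L, 2L, 2L, 10L))
  # background duality for K = 2
  expect_equal(cc["class0", "tp"], cc["class1", "tn"])
  expect_equal(cc["class0", "fp"], cc["class1", "fn"])
  # perfect prediction: no errors anywhere
  m <- matrix(sample(0:1, 36, TRUE), 6, 6)
  p <- confusion(m, m)
  expect_true(all(p[, c("fp", "fn")] == 0))
  # complement prediction: zero TP and TN for the foreground
  comp <- confusion(1L - m, m)
  expect_equal(unname(comp["class1", "tp"]), 0L)
  expect_equal(unname(comp["class1", "tn"]), 0L)
  expect_error(confusion(m, m[1:3, ]), "shape")
  expect_error(confusion(m + 2L, m), "labels")
})

test_that("mean IoU and mean DSC match direct substitution", {
  cc <- make_example_counts()
  expect_equal(mean_iou(cc), (2 / 6 + 10 / 14) / 2)
  expect_equal(mean_dsc(cc), (4 / 8 + 20 / 24) / 2)
  # perfect prediction scores 1
  m <- matrix(sample(0:1, 36, TRUE), 6, 6)
  expect_equal(mean_iou(confusion(m, m)), 1)
  expect_equal(mean_dsc(confusion(m, m)), 1)
  # all-background prediction vs all-background truth: empty-union => 1
  z <- matrix(0L, 4, 4)
  expect_equal(mean_iou(confusion(z, z)), 1)
  expect_equal(mean_dsc(confusion(z, z)), 1)
})

test_that("balanced accuracy (fg) matches direct substitution", {
  cc <- make_example_counts()
  expect_equal(balanced_accuracy_fg(cc), (2 / 4 + 10 / 12) / 2)
  m <- matrix(sample(0:1, 36, TRUE), 6, 6)
  expect_equal(balanced_accuracy_fg(confusion(m, m)), 1)
  # all-foreground prediction with half-foreground truth: chance level
  truth <- matrix(c(rep(0L, 8), rep(1L, 8)), 4, 4)
  pred <- matrix(1L, 4, 4)
  expect_equal(balanced_accuracy_fg(confusion(pred, truth)), 0.5)
  expect_error(balanced_accuracy_fg(confusion(m, m, num_classes = 3L)),
               "K = 2")
})

test_that("metrics agree with the pixel-counting oracle on random masks", {
  set.seed(17)
  for (rep in 1:50) {
    k <- sample(2:3, 1)
    pred <- matrix(sample(0:(k - 1), 64, TRUE), 8, 8)
    truth <- matrix(sample(0:(k - 1), 64, TRUE), 8, 8)
    cc <- confusion(pred, truth, k)
    orc <- oracle_metrics(pred, truth, k)
    expect_equal(mean_iou(cc), orc$mean_iou)
    expect_equal(mean_dsc(cc), orc$mean_dsc)
    # per-class DSC/IoU identity and ordering
    iou <- gridunet:::per_class_iou(cc)
    dsc <- gridunet:::per_class_dsc(cc)
    expect_equal(dsc, 2 * iou / (1 + iou), tolerance = 1e-13)
    expect_true(mean_dsc(cc) >= mean_iou(cc))
  }
})

test_that("class weights follow inverse frequency with sum K", {
  expect_equal(class_weights(c(50, 50)), c(1, 1))
  expect_equal(class_weights(c(90, 10)), c(0.2, 1.8))
  expect_equal(class_weights(c(90, 10), mode = "none"), c(1, 1))
  # an absent class hits the eps cap, i.e. gets almost all the mass
  w <- class_weights(c(100, 0))
  expect_gt(w[2], 1.99)
  expect_equal(sum(w), 2)
  expect_error(class_weights(c(0, 0)), "nonzero")
})

test_that("balanced loss reduces to cross-entropy and is linear in weights", {
  set.seed(2)
  truth <- matrix(sample(0:1, 64, TRUE), 8, 8)
  # uniform scores with equal weights: exactly log 2 per pixel
  scores <- array(0, c(8, 8, 2))
  expect_equal(balanced_loss(scores, truth), log(2))
  # saturated on the truth: loss approaches zero
  sat <- array(0, c(8, 8, 2))
  sat[, , 1] <- 50 * (truth == 0)
  sat[, , 2] <- 50 * (truth == 1)
  expect_lt(balanced_loss(sat, truth), 1e-10)
  # weighted loss with equal weights equals the unweighted loss
  sc <- array(rnorm(128), c(8, 8, 2))
  expect_equal(balanced_loss(sc, truth, c(1, 1)), balanced_loss(sc, truth))
  # doubling the foreground weight doubles the foreground contribution
  l_bg <- balanced_loss(sc, truth, c(1, 0))
  l_fg <- balanced_loss(sc, truth, c(0, 1))
  expect_equal(balanced_loss(sc, truth, c(1, 2)), l_bg + 2 * l_fg)
  expect_error(balanced_loss(sc, truth[1:4, ]), "shape")
})

test_that("evaluate_model aggregates frames and honours the identities", {
  ds <- tiny_dataset(n = 3, size = 32, seed = 21)
  model <- build_model(model_config(depth = 2, base_channels = 4), seed = 1)
  rep <- evaluate_model(model, ds)
  for (agg in list(rep$macro, rep$micro)) {
    expect_true(all(agg$dsc >= agg$iou - 1e-12))
    expect_gte(agg$mean_dsc, agg$mean_iou)
  }
  expect_equal(rep$micro$dsc, 2 * rep$micro$iou / (1 + rep$micro$iou),
               tolerance = 1e-12)
  # an oracle that returns the ground truth scores 1 everywhere
  oracle_model <- structure(list(config = model$config), class = "seg_model")
  with_mocked_bindings(
    model_scores = function(model, image) {
      lab <- ds$masks[[which(vapply(ds$images, identical, logical(1),
                                    image))]]
      s <- array(0, c(dim(image)[1], dim(image)[2], 2))
      s[, , 2] <- 100 * lab
      s[, , 1] <- 100 * (1 - lab)
      s
    },
    {
      r <- evaluate_model(oracle_model, ds)
      expect_equal(r$macro$mean_dsc, 1)
      expect_equal(r$micro$mean_iou, 1)
      expect_equal(r$macro$balanced_accuracy_fg, 1)
    },
    .package = "gridunet"
  )
  expect_error(evaluate_model(model, list(images = list(), masks = list())),
               "empty")
})
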