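test_that("the architecture caps downsampling at one eighth of the input", {
  cfg <- net_config(encoder_filters = c(4, 6, 8, 10, 10), aspp_rates = c(2, 4))
  mod <- build_model(cfg, seed = 2)
  for (side in c(32, 64)) {
    fw <- model_logits(mod, matrix(0.5, side, side))
    fd <- fw$feature_dims
    expect_equal(unname(fd["enc1", ]), c(side, side))
    expect_equal(unname(fd["enc4", ]), c(side / 8, side / 8))
    expect_equal(unname(fd["enc5", ]), c(side / 8, side / 8))
    expect_equal(min(fd[1:6, ]), side / 8)
    expect_equal(dim(fw$logits), c(side, side, 3))
  }
  expect_error(model_logits(mod, matrix(0, 30, 30)), "divisible by 8")
})

test_that("prediction resolves exact logit ties to the lowest class", {
  cfg <- net_config(encoder_filters = c(2, 2, 2, 2, 2), aspp_rates = c(2))
  mod <- build_model(cfg, seed = 1)
  mod$weights <- lapply(mod$weights, function(w) { w[] <- 0; w })
  lab <- predict_mask(mod, matrix(runif(64^2), 64, 64))
  expect_true(all(lab == 0L))
})

test_that("a stack is predicted slice by slice with order preserved", {
  cfg <- net_config(encoder_filters = c(2, 3, 3, 4, 4), aspp_rates = c(2))
  mod <- build_model(cfg, seed = 5)
  set.seed(1)
  stack <- array(runif(3 * 24 * 24), c(3, 24, 24))
  got <- predict_mask(mod, stack)
  for (i in 1:3)
    expect_identical(got[i, , ], predict_mask(mod, stack[i, , ]))
})

test_that("the full-scale schedule steps the learning rate down after epoch 150", {
  lrs <- lr_schedule(train_config())
  expect_length(lrs, 200)
  expect_true(all(lrs[1:150] == 1e-4))
  expect_true(all(lrs[151:200] == 1e-5))
})

test_that("zero-epoch training is the identity and bad labels are rejected", {
  cfg <- net_config(encoder_filters = c(2, 2, 2, 2, 2), aspp_rates = c(2))
  mod <- build_model(cfg, seed = 1)
  img <- matrix(runif(16^2), 16, 16)
  lab <- matrix(0L, 16, 16)
  out <- train_model(mod, list(img), list(lab), train_config(epochs = 0))
  expect_identical(out$model$weights, mod$weights)
  expect_equal(nrow(out$history), 0)
  expect_error(train_model(mod, list(), list(), train_config(epochs = 1)),
               "empty dataset")
  bad <- lab; bad[1] <- 7L
  expect_error(train_model(mod, list(img), list(bad), train_config(epochs = 1)),
               "label outside")
})

test_that("training is deterministic given a seed and reduces the loss", {
  cfg <- net_config(encoder_filters = c(2, 3, 3, 4, 4), aspp_rates = c(2, 3))
  mod <- build_model(cfg, seed = 4)
  pr <- make_seg_pair(1, side = 32)
  tc <- train_config(epochs = 4, batch_size = 1, lr_initial = 2e-3,
                     augment = FALSE, seed = 11)
  a <- train_model(mod, list(pr$image), list(pr$label), tc)
  b <- train_model(mod, list(pr$image), list(pr$label), tc)
  expect_identical(a$model$weights, b$model$weights)
  expect_lt(tail(a$history$loss, 1), a$history$loss[1])
})

test_that("augmented labels are exactly the stored geometric transform of the label", {
  set.seed(21)
  pr <- make_seg_pair(2, side = 48)
  cfg <- train_config(aug_prob = 0.9)
  for (i in 1:10) {
    au <- augment_pair(pr$image, pr$label, cfg)
    expect_identical(au$label, apply_geometric_transform(pr$label, au$transform))
  }
})

test_that("segmentation metrics reproduce hand-counted confusion tables", {
  # 4 truth px of class 2, 4 predicted with 2 overlapping
  truth <- matrix(0L, 6, 6); truth[1, 1:4] <- 2L
  pred <- matrix(0L, 6, 6); pred[1, 3:6] <- 2L
  m <- evaluate_segmentation(pred, truth)
  r2 <- m$per_class[m$per_class$class == 2, ]
  expect_equal(r2$dice, 0.5)
  expect_equal(r2$iou, 1 / 3)
  expect_equal(r2$precision, 0.5)
  expect_equal(r2$recall, 0.5)
  # class 1 absent from both -> vacuously perfect
  expect_equal(m$per_class$dice[m$per_class$class == 1], 1)
  # perfect prediction
  mp <- evaluate_segmentation(truth, truth)
  expect_true(all(unlist(mp$macro) == 1))
  expect_error(evaluate_segmentation(matrix(0L, 2, 2), truth), "shape mismatch")
})

test_that("metric identities hold on random label maps", {
  set.seed(33)
  for (i in 1:20) {
    a <- matrix(sample(0:2, 400, TRUE), 20, 20)
    b <- matrix(sample(0:2, 400, TRUE), 20, 20)
    m <- evaluate_segmentation(a, b)
    # dice = 2 iou / (1 + iou), per class
    expect_equal(m$per_class$dice,
                 2 * m$per_class$iou / (1 + m$per_class$iou), tolerance = 1e-12)
    # swapping arguments swaps precision and recall, iou is symmetric
    ms <- evaluate_segmentation(b, a)
    expect_equal(m$per_class$precision, ms$per_class$recall, tolerance = 1e-12)
    expect_equal(m$per_class$iou, ms$per_class$iou, tolerance = 1e-12)
  }
})
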