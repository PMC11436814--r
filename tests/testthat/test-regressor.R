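test_that("the head matches the prescribed sequence exactly", {
  m <- build_model(backbone_spec(), seed = 1)
  h <- head_structure(m)
  expect_equal(h$kind, c("gap", "dropout", "dense", "dense", "dense", "dense"))
  expect_equal(h$rate[h$kind == "dropout"], 0.2)
  dense <- h[h$kind == "dense", ]
  expect_equal(dense$width, c(32L, 16L, 8L, 1L))
  expect_equal(dense$activation, c("relu", "relu", "relu", "identity"))
})

test_that("head parameter count follows the closed form in the feature width", {
  for (w in list(c(8, 8), c(32, 16))) {
    m <- build_model(backbone_spec(conv_widths = w), seed = 2)
    F <- utils::tail(w, 1)
    expect_equal(n_parameters(m, "head"),
                 F * 32 + 32 + 32 * 16 + 16 + 16 * 8 + 8 + 8 + 1)
  }
})

test_that("phase freezing matches the recipe and bounds are enforced", {
  m <- build_model(backbone_spec(conv_widths = c(16, 16)), seed = 3)
  nb <- backbone_layer_count(m)
  mI <- set_phase(m, "I")
  expect_equal(n_parameters(mI, "backbone", trainable_only = TRUE), 0L)
  expect_gt(n_parameters(mI, "head", trainable_only = TRUE), 0L)
  ## phase II with n_unfrozen = 0 is identical in trainability to phase I
  mII0 <- set_phase(m, "II", n_unfrozen = 0)
  expect_identical(vapply(mII0$layers, function(l) isTRUE(l$trainable), logical(1)),
                   vapply(mI$layers, function(l) isTRUE(l$trainable), logical(1)))
  ## default phase II unfreezes the tail of the backbone, including its
  ## trainable conv layers
  mII <- set_phase(m, "II", n_unfrozen = backbone_layer_count(m) - 1L)
  expect_gt(n_parameters(mII, "backbone", trainable_only = TRUE), 0L)
  expect_error(set_phase(m, "II", n_unfrozen = nb + 1), "backbone depth")
})

test_that("the published MobileNetV2 path reports 154 layers and errors offline", {
  spec <- backbone_spec("pretrained_mobilenet_v2", weights_source = "imagenet")
  expect_equal(backbone_layer_count(spec), 154L)
  expect_equal(154L - 54L, 100L)  # phase II default leaves 100 layers frozen
  expect_error(build_model(spec), "standin_cnn")
})

test_that("frozen layers are bit-identical after training; trainable ones move", {
  ds <- quiet_dataset(2, 3)
  inputs <- lapply(ds$records, function(r) to_model_input(r$grid))
  y <- dataset_targets(ds, "K268")
  m <- set_phase(build_model(backbone_spec(conv_widths = c(16, 16)), seed = 5), "I")
  conv_idx <- which(vapply(m$layers, function(l) l$kind == "conv1x1", logical(1)))
  before <- lapply(m$layers[conv_idx], `[[`, "W")
  fit <- train_phase(m, inputs, y, standin_phase_config("I", epochs = 3, seed = 1))
  after <- lapply(fit$model$layers[conv_idx], `[[`, "W")
  expect_identical(before, after)
  ## head moved
  head_idx <- which(vapply(m$layers, function(l)
    l$kind == "dense", logical(1)))[1]
  expect_false(identical(m$layers[[head_idx]]$W, fit$model$layers[[head_idx]]$W))
})

test_that("zero-epoch training is a no-op with empty history", {
  ds <- quiet_dataset(1, 2)
  inputs <- lapply(ds$records, function(r) to_model_input(r$grid))
  m <- set_phase(build_model(backbone_spec(), seed = 6), "I")
  fit <- train_phase(m, inputs, c(0.1, 0.2),
                     standin_phase_config("I", epochs = 0))
  expect_identical(fit$model, m)
  expect_equal(nrow(fit$history), 0L)
})

test_that("training fits non-constant targets below the mean-predictor variance", {
  ds <- quiet_dataset(3, 4, seed = 17)
  inputs <- lapply(ds$records, function(r) to_model_input(r$grid))
  y <- dataset_targets(ds, "K268")
  fit <- train_two_phase(inputs, y, seed = 2)
  ## standardised scale: mean-only predictor has MSE ~= 1
  expect_lt(utils::tail(fit$history$loss[fit$history$phase == "I"], 1), 0.6)
  pred <- predict(fit$model, inputs)
  expect_lt(mean((pred - y)^2), stats::var(y))
})

test_that("constant targets are predicted exactly via the stored standardisation", {
  ds <- quiet_dataset(2, 2, seed = 19)
  inputs <- lapply(ds$records, function(r) to_model_input(r$grid))
  m <- set_phase(build_model(backbone_spec(), seed = 7), "I")
  fit <- train_phase(m, inputs, rep(0.42, 4),
                     standin_phase_config("I", epochs = 60))
  expect_equal(predict(fit$model, inputs), rep(0.42, 4), tolerance = 0.02)
})

test_that("training and prediction are reproducible given the seed", {
  ds <- quiet_dataset(2, 2, seed = 23)
  inputs <- lapply(ds$records, function(r) to_model_input(r$grid))
  y <- dataset_targets(ds, "K268")
  f1 <- train_two_phase(inputs, y,
                        config_I = standin_phase_config("I", epochs = 4),
                        config_II = standin_phase_config("II", epochs = 2),
                        seed = 9)
  f2 <- train_two_phase(inputs, y,
                        config_I = standin_phase_config("I", epochs = 4),
                        config_II = standin_phase_config("II", epochs = 2),
                        seed = 9)
  expect_identical(predict(f1$model, inputs), predict(f2$model, inputs))
})

test_that("phase configs default to the study hyperparameters", {
  cI <- phase_config("I")
  expect_equal(cI$learning_rate, 1e-4)
  expect_equal(cI$batch_size, 230L)
  expect_equal(cI$epochs, 1000L)
  expect_equal(cI$loss, "mse")
  cII_268 <- phase_config("II", target = "K268")
  expect_equal(cII_268$learning_rate, 1e-5)
  expect_equal(cII_268$batch_size, 32L)
  expect_equal(cII_268$epochs, 500L)
  cII_232 <- phase_config("II", target = "K232")
  expect_equal(cII_232$learning_rate, 1e-6)
  expect_equal(cII_232$batch_size, 230L)
  expect_equal(cII_232$epochs, 500L)
})

test_that("models survive a save/load round trip", {
  ds <- quiet_dataset(2, 2, seed = 29)
  inputs <- lapply(ds$records, function(r) to_model_input(r$grid))
  fit <- train_two_phase(inputs, dataset_targets(ds, "K268"),
                         config_I = standin_phase_config("I", epochs = 2),
                         config_II = standin_phase_config("II", epochs = 1),
                         seed = 10)
  path <- withr::local_tempfile(fileext = ".json")
  save_model(fit$model, path)
  m2 <- load_model(path)
  expect_equal(predict(m2, inputs), predict(fit$model, inputs),
               tolerance = 1e-12)
})

test_that("backpropagation matches finite-difference gradients", {
  ds <- quiet_dataset(1, 3, seed = 31)
  inputs <- lapply(ds$records, function(r) to_model_input(r$grid))
  y <- c(-0.3, 0.1, 0.6)
  m <- set_phase(build_model(backbone_spec(pool_size = 8, basis_grid = 3,
                                           conv_widths = c(4, 4)), seed = 8),
                 "II")
  stems <- eemda:::model_stems(m, inputs)
  fw <- eemda:::nn_forward(m$layers, stems, training = FALSE)
  grads <- eemda:::nn_backward(m$layers, fw, 2 * (fw$out - y) / 3)
  loss_at <- function(layers)
    mean((eemda:::nn_forward(layers, stems, training = FALSE)$out - y)^2)
  eps <- 1e-6
  for (li in seq_along(m$layers)) {
    if (is.null(grads[[li]])) next
    ids <- withr::with_seed(li, sample(length(m$layers[[li]]$W), 3))
    for (id in ids) {
      lp <- m$layers; lp[[li]]$W[id] <- lp[[li]]$W[id] + eps
      lm <- m$layers; lm[[li]]$W[id] <- lm[[li]]$W[id] - eps
      num <- (loss_at(lp) - loss_at(lm)) / (2 * eps)
      expect_equal(grads[[li]]$W[id], num, tolerance = 1e-5)
    }
  }
})
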