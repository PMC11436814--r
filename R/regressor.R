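#' Backbone specification
#'
#' Two backbone kinds share one contract (ordered layer list, freezable
#' prefix, feature-map output), so all downstream code is backbone
#' agnostic:
#'
#' * `"pretrained_mobilenet_v2"` -- the published 154-layer architecture
#'   with ImageNet weights. The weights are an external asset; building
#'   this backbone without them raises an asset-missing error.
#' * `"standin_cnn"` -- a lightweight trainable network shipped with the
#'   package: a parameter-free stem (8-bit pixels rescaled to `[-1, 1]`,
#'   block-averaged to `pool_size x pool_size`, intensity gated by a
#'   `basis_grid x basis_grid` bank of fixed Gaussian spatial bumps -- a
#'   regional-pooling encoding analogous to the spatially structured
#'   features a pretrained vision backbone provides -- plus raw intensity
#'   and two coordinate channels), then `length(conv_widths)` pointwise
#'   1x1 convolution layers with ReLU, then a frozen per-channel feature
#'   normalisation (batch-norm analogue with training-set statistics).
#'   Its canonical input rescaling is the same `[-1, 1]` mapping.
#'
#' @param kind backbone kind.
#' @param weights_source `"random"`, `"imagenet"` or a file path.
#' @param input_shape expected input geometry.
#' @param pool_size stem pooling side (stand-in only); must divide the
#'   image side.
#' @param basis_grid side of the stem's spatial-basis grid (stand-in only).
#' @param conv_widths channel widths of the stand-in's 1x1 conv layers.
#' @return object of class `backbone_spec`.
#' @export
backbone_spec <- function(kind = c("standin_cnn", "pretrained_mobilenet_v2"),
                          weights_source = c("random", "imagenet", "file"),
                          input_shape = c(160, 160, 3),
                          pool_size = 16, basis_grid = 6,
                          conv_widths = integer(0)) {
  kind <- match.arg(kind)
  weights_source <- match.arg(weights_source)
  structure(list(kind = kind, weights_source = weights_source,
                 input_shape = input_shape, pool_size = pool_size,
                 basis_grid = basis_grid, conv_widths = conv_widths),
            class = "backbone_spec")
}

#' Number of backbone layers under the per-operation enumeration
#'
#' @param x a `backbone_spec` or `eem_model`.
#' @return integer layer count (154 for the published MobileNetV2
#'   architecture; stem + conv layers for the stand-in).
#' @export
backbone_layer_count <- function(x) {
  if (inherits(x, "eem_model"))
    return(sum(vapply(x$layers, function(l) l$part == "backbone", logical(1))))
  if (!inherits(x, "backbone_spec")) stopf("need a backbone_spec or eem_model")
  if (x$kind == "pretrained_mobilenet_v2") 154L else length(x$conv_widths) + 4L
}

#' Build the backbone-plus-head regression model
#'
#' The head is fixed: global average pooling, dropout 0.2, dense layers of
#' 32, 16 and 8 ReLU units, and a final 1-unit dense layer with identity
#' activation, emitting one scalar per input image.
#'
#' @param spec a [backbone_spec].
#' @param seed integer seed for weight initialisation.
#' @return object of class `eem_model`.
#' @export
build_model <- function(spec = backbone_spec(), seed = 1) {
  if (spec$kind == "pretrained_mobilenet_v2")
    stopf(paste("pretrained MobileNetV2 weights (source '%s') are an external",
                "asset and are not available offline; use",
                'backbone_spec(kind = "standin_cnn") instead'),
          spec$weights_source)
  withr::with_seed(as.integer(seed), {
    layers <- list(list(kind = "stem", part = "backbone", trainable = FALSE,
                        P = spec$pool_size, G = spec$basis_grid))
    widths <- c(spec$basis_grid^2 + 3L, spec$conv_widths)
    for (i in seq_along(spec$conv_widths)) {
      wb <- init_dense_weights(widths[i], widths[i + 1L])
      layers[[length(layers) + 1L]] <-
        list(kind = "conv1x1", part = "backbone", trainable = FALSE,
             activation = "relu", W = wb$W, b = wb$b)
    }
    feat <- utils::tail(widths, 1L)
    ## the backbone ends in its own spatial pooling (a 1 x 1 x C feature
    ## map), per-channel normalisation with statistics frozen from the
    ## first training set this model sees (batch-norm analogue), and a
    ## +-3 SD clip so no held-out sample exerts unbounded leverage
    ## through a nuisance channel
    layers[[length(layers) + 1L]] <- list(kind = "bpool", part = "backbone",
                                          trainable = FALSE)
    layers[[length(layers) + 1L]] <- list(kind = "featnorm", part = "backbone",
                                          trainable = FALSE,
                                          mu = NULL, sd = NULL)
    layers[[length(layers) + 1L]] <- list(kind = "featclip", part = "backbone",
                                          trainable = FALSE, limit = 3)
    layers[[length(layers) + 1L]] <- list(kind = "gap", part = "head",
                                          trainable = TRUE)
    layers[[length(layers) + 1L]] <- list(kind = "dropout", part = "head",
                                          trainable = TRUE, rate = 0.2)
    hw <- c(feat, 32L, 16L, 8L, 1L)
    for (i in seq_len(4L)) {
      wb <- init_dense_weights(hw[i], hw[i + 1L], final = (i == 4L))
      layers[[length(layers) + 1L]] <-
        list(kind = "dense", part = "head", trainable = TRUE,
             activation = if (i == 4L) "identity" else "relu",
             W = wb$W, b = wb$b)
    }
    structure(list(spec = spec, layers = layers, phase = NULL,
                   target_center = NULL, target_scale = NULL),
              class = "eem_model")
  })
}

#' @export
print.eem_model <- function(x, ...) {
  cat(sprintf("<eem_model> %s backbone (%d layers, %d trainable params), phase %s\n",
              x$spec$kind, backbone_layer_count(x),
              n_parameters(x, trainable_only = TRUE),
              x$phase %||% "unset"))
  invisible(x)
}

#' Count model parameters
#' @param model an `eem_model`.
#' @param part `"all"`, `"backbone"` or `"head"`.
#' @param trainable_only count only currently trainable layers.
#' @return integer parameter count.
#' @export
n_parameters <- function(model, part = c("all", "backbone", "head"),
                         trainable_only = FALSE) {
  part <- match.arg(part)
  tot <- 0L
  for (l in model$layers) {
    if (!layer_has_params(l)) next
    if (part != "all" && l$part != part) next
    if (trainable_only && !isTRUE(l$trainable)) next
    tot <- tot + length(l$W) + length(l$b)
  }
  tot
}

#' Audit the head structure
#' @param model an `eem_model`.
#' @return data.frame of head layers with kind, width and activation.
#' @export
head_structure <- function(model) {
  rows <- lapply(model$layers, function(l) {
    if (l$part != "head") return(NULL)
    data.frame(kind = l$kind,
               width = if (layer_has_params(l)) ncol(l$W) else NA_integer_,
               activation = l$activation %||% NA_character_,
               rate = l$rate %||% NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Set the training phase (freezing pattern)
#'
#' Phase I (transfer learning): the whole backbone is frozen and only the
#' head trains. Phase II (fine-tuning): the last `n_unfrozen` backbone
#' layers train along with the head; the published recipe unfreezes the
#' last 54 of the 154 MobileNetV2 layers, keeping the first 100 frozen.
#'
#' @param model an `eem_model`.
#' @param phase `"I"` or `"II"`.
#' @param n_unfrozen number of backbone layers to unfreeze in phase II
#'   (counted from the end). Default: 54 for the MobileNetV2 backbone, all
#'   conv layers for the stand-in.
#' @return the model with updated trainable flags.
#' @export
set_phase <- function(model, phase = c("I", "II"), n_unfrozen = NULL) {
  phase <- match.arg(phase)
  nb <- backbone_layer_count(model)
  if (is.null(n_unfrozen))
    n_unfrozen <- if (model$spec$kind == "pretrained_mobilenet_v2") 54L else nb - 1L
  n_unfrozen <- as.integer(n_unfrozen)
  if (n_unfrozen < 0L || n_unfrozen > nb)
    stopf("n_unfrozen = %d outside 0..%d (backbone depth)", n_unfrozen, nb)
  bi <- 0L
  for (li in seq_along(model$layers)) {
    l <- model$layers[[li]]
    if (l$part == "backbone") {
      bi <- bi + 1L
      model$layers[[li]]$trainable <-
        phase == "II" && bi > nb - n_unfrozen
    } else {
      model$layers[[li]]$trainable <- TRUE
    }
  }
  model$phase <- phase
  model
}

#' Training configuration for one phase
#'
#' Defaults are the full-scale recipe: phase I uses Adam with learning rate
#' 1e-4, mini-batch 230 and 1000 epochs for both indicators; phase II uses
#' 1e-6 / batch 230 / 500 epochs for K232 and 1e-5 / batch 32 / 500 epochs
#' for K268. The loss is always mean squared error. When the training set
#' is smaller than the batch size, one full batch per epoch is used.
#'
#' @param phase `"I"` or `"II"`.
#' @param target `"K232"` or `"K268"` (selects the phase-II defaults).
#' @param learning_rate,batch_size,epochs overrides.
#' @param seed RNG seed for shuffling and dropout.
#' @param tail_average fraction of final optimisation steps whose weights
#'   are averaged into the returned model (Polyak-Ruppert averaging; 0
#'   keeps the last iterate, the full-scale recipe's behaviour).
#' @param mixup probability that a training sample is replaced by a
#'   convex combination of itself and a random partner (features and
#'   target mixed with the same uniform weight). 0 disables mixup, the
#'   full-scale recipe's behaviour; the stand-in's small-data defaults
#'   enable it to decorrelate sample-level nuisance from the target.
#' @param adam_epsilon Adam's denominator constant. The conventional 1e-8
#'   normalises every parameter's step to the learning rate; a larger
#'   value keeps steps proportional to gradient magnitude (closer to SGD
#'   with momentum), which preserves the fit-the-strongest-correlations
#'   -first behaviour that early stopping relies on for regularisation.
#' @return object of class `phase_config`.
#' @export
phase_config <- function(phase = c("I", "II"), target = c("K268", "K232"),
                         learning_rate = NULL, batch_size = NULL,
                         epochs = NULL, seed = 1, tail_average = 0,
                         mixup = 0, adam_epsilon = 1e-8) {
  phase <- match.arg(phase)
  target <- match.arg(target)
  if (phase == "I") {
    learning_rate <- learning_rate %||% 1e-4
    batch_size <- batch_size %||% 230L
    epochs <- epochs %||% 1000L
  } else if (target == "K232") {
    learning_rate <- learning_rate %||% 1e-6
    batch_size <- batch_size %||% 230L
    epochs <- epochs %||% 500L
  } else {
    learning_rate <- learning_rate %||% 1e-5
    batch_size <- batch_size %||% 32L
    epochs <- epochs %||% 500L
  }
  if (learning_rate <= 0) stopf("learning_rate must be > 0")
  if (batch_size < 1 || epochs < 0) stopf("invalid batch_size/epochs")
  if (tail_average < 0 || tail_average > 1)
    stopf("tail_average must be in [0, 1]")
  if (mixup < 0 || mixup > 1) stopf("mixup must be in [0, 1]")
  structure(list(phase = phase, target = target, loss = "mse",
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 tail_average = tail_average, mixup = mixup,
                 adam_epsilon = adam_epsilon),
            class = "phase_config")
}

#' Desk-scale training configuration for the stand-in backbone
#'
#' The full-scale learning rates are fine-tuning rates for a pretrained
#' backbone; a randomly initialised stand-in trained for tens of epochs
#' needs proportionally larger steps, while keeping the recipe's shape: a
#' large-step head-only phase, then fine-tuning one to two decades slower
#' (the full-scale recipe drops the rate 10-100x between phases). These
#' defaults -- Adam at 0.05 then 1e-3 with `adam_epsilon = 0.01` (steps
#' proportional to gradient magnitude, preserving early stopping's
#' implicit regularisation), mini-batch 8, 30 + 15 epochs, mixup on --
#' train the stand-in on small synthetic datasets in seconds.
#'
#' @param phase `"I"` or `"II"`.
#' @param ... overrides passed to [phase_config()].
#' @return a [phase_config].
#' @export
standin_phase_config <- function(phase = c("I", "II"), ...) {
  phase <- match.arg(phase)
  defaults <- if (phase == "I")
    list(learning_rate = 0.05, batch_size = 8L, epochs = 30L, mixup = 1,
         adam_epsilon = 0.01)
  else
    list(learning_rate = 1e-3, batch_size = 8L, epochs = 15L, mixup = 1,
         adam_epsilon = 0.01)
  args <- utils::modifyList(c(list(phase = phase), defaults), list(...))
  do.call(phase_config, args)
}

model_stems <- function(model, inputs) {
  P <- model$layers[[1L]]$P
  G <- model$layers[[1L]]$G
  lapply(inputs, function(inp) {
    if (!inherits(inp, "model_input")) stopf("inputs must be model_input objects")
    stem_features(inp$pixels, P, G)
  })
}

#' Train one phase
#'
#' Runs Adam on the mean-squared-error loss for the configured number of
#' epochs, honouring the current freezing pattern (a frozen layer's
#' parameters are bit-identical before and after). Targets are
#' standardised internally with training-set statistics (stored in the
#' model and reused by later phases and predictions, so no validation
#' statistic ever enters); the reported history is on that standardised
#' scale. Dropout is active only here; prediction is deterministic. A
#' fresh optimiser state is used for every call, so phase II restarts
#' Adam at its own learning rate.
#'
#' @param model an `eem_model` with a phase set (see [set_phase()]).
#' @param inputs list of `model_input` objects.
#' @param targets numeric vector of indicator values, one per input.
#' @param config a [phase_config].
#' @return list with elements `model` (updated weights) and `history`
#'   (data.frame of per-epoch mean training loss).
#' @export
train_phase <- function(model, inputs, targets, config) {
  if (length(inputs) == 0L) stopf("training data is empty")
  if (length(targets) != length(inputs) || any(!is.finite(targets)))
    stopf("targets must be finite, one per input")
  if (config$epochs == 0L)
    return(list(model = model, history = data.frame(epoch = integer(),
                                                    loss = numeric())))
  if (is.null(model$target_center)) {
    model$target_center <- mean(targets)
    s <- stats::sd(targets)
    model$target_scale <- if (!is.finite(s) || s < 1e-12) 1 else s
  }
  y <- (targets - model$target_center) / model$target_scale
  stems <- model_stems(model, inputs)
  ## freeze backbone-output normalisation statistics from the first
  ## training set (train-only; reused unchanged by later phases)
  for (li in seq_along(model$layers)) {
    l <- model$layers[[li]]
    if (l$kind == "featnorm" && is.null(l$mu)) {
      feats <- nn_features(model$layers, stems, li - 1L)  # post-pool: n x C
      mu <- colMeans(feats)
      sd_ <- apply(feats, 2L, stats::sd)
      sd_[!is.finite(sd_)] <- 0
      ## variance floor: channels carrying almost no across-sample
      ## variation are not amplified into unit-scale noise regressors
      sd_ <- pmax(sd_, 0.1 * max(sd_, 1e-12))
      model$layers[[li]]$mu <- mu
      model$layers[[li]]$sd <- sd_
    }
  }
  n <- length(stems)
  b <- min(config$batch_size, n)
  adam <- adam_init(model$layers)
  hist <- numeric(config$epochs)
  tail_frac <- config$tail_average %||% 0
  total_steps <- config$epochs * ceiling(n / b)
  avg_from <- if (tail_frac > 0) ceiling((1 - tail_frac) * total_steps) + 1L
              else total_steps + 1L
  step <- 0L
  avg <- NULL
  n_avg <- 0L
  withr::with_seed(config$seed, {
    for (ep in seq_len(config$epochs)) {
      ord <- if (b < n) sample.int(n) else seq_len(n)
      batches <- split(ord, ceiling(seq_along(ord) / b))
      losses <- numeric(length(batches))
      for (bi in seq_along(batches)) {
        idx <- batches[[bi]]
        batch_stems <- stems[idx]
        yb <- y[idx]
        mix_p <- config$mixup %||% 0
        if (mix_p > 0) {
          use <- stats::runif(length(idx)) < mix_p
          partner <- sample.int(n, length(idx), replace = TRUE)
          lam <- stats::runif(length(idx))
          for (k in which(use)) {
            batch_stems[[k]] <- lam[k] * batch_stems[[k]] +
              (1 - lam[k]) * stems[[partner[k]]]
            yb[k] <- lam[k] * yb[k] + (1 - lam[k]) * y[partner[k]]
          }
        }
        fw <- nn_forward(model$layers, batch_stems, training = TRUE)
        err <- fw$out - yb
        loss <- mean(err^2)
        if (!is.finite(loss))
          stopf("training diverged: non-finite loss at epoch %d (lr = %g)",
                ep, config$learning_rate)
        grads <- nn_backward(model$layers, fw,
                             2 * err / length(idx))
        upd <- adam_step(model$layers, grads, adam, config$learning_rate,
                         eps = config$adam_epsilon %||% 1e-8)
        model$layers <- upd$layers
        adam <- upd$adam
        losses[bi] <- loss
        step <- step + 1L
        if (step >= avg_from) {
          if (is.null(avg)) avg <- lapply(model$layers, function(l)
            if (layer_has_params(l) && isTRUE(l$trainable))
              list(W = l$W, b = l$b))
          else for (li in seq_along(avg)) if (!is.null(avg[[li]])) {
            avg[[li]]$W <- avg[[li]]$W + model$layers[[li]]$W
            avg[[li]]$b <- avg[[li]]$b + model$layers[[li]]$b
          }
          n_avg <- n_avg + 1L
        }
      }
      hist[ep] <- mean(losses)
    }
  })
  if (!is.null(avg) && n_avg > 1L) {
    for (li in seq_along(avg)) if (!is.null(avg[[li]])) {
      model$layers[[li]]$W <- avg[[li]]$W / n_avg
      model$layers[[li]]$b <- avg[[li]]$b / n_avg
    }
  }
  list(model = model, history = data.frame(epoch = seq_len(config$epochs),
                                           loss = hist))
}

#' Predict indicator values for model inputs
#'
#' Deterministic forward pass (dropout inactive); the backbone's canonical
#' input rescaling is applied internally and the stored target
#' standardisation is inverted, returning values on the indicator scale.
#'
#' @param object an `eem_model`.
#' @param inputs one `model_input` or a list of them.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.eem_model <- function(object, inputs, ...) {
  if (inherits(inputs, "model_input")) inputs <- list(inputs)
  stems <- model_stems(object, inputs)
  out <- nn_forward(object$layers, stems, training = FALSE)$out
  center <- object$target_center %||% 0
  scale <- object$target_scale %||% 1
  center + scale * out
}

#' Convenience: the full two-phase domain-adaptation recipe
#'
#' Builds a fresh model, runs phase I (frozen backbone) then phase II
#' (last layers unfrozen) on the same training data.
#'
#' @param inputs list of `model_input` objects.
#' @param targets numeric vector.
#' @param backbone a [backbone_spec].
#' @param config_I,config_II [phase_config]s for the two phases.
#' @param seed seed for weight initialisation.
#' @return list with `model` and `history` (both phases' losses, with a
#'   `phase` column).
#' @export
train_two_phase <- function(inputs, targets, backbone = backbone_spec(),
                            config_I = standin_phase_config("I"),
                            config_II = standin_phase_config("II"),
                            seed = 1) {
  model <- build_model(backbone, seed = seed)
  model <- set_phase(model, "I")
  r1 <- train_phase(model, inputs, targets, config_I)
  model <- set_phase(r1$model, "II")
  r2 <- train_phase(model, inputs, targets, config_II)
  hist <- rbind(cbind(r1$history, phase = "I"),
                cbind(r2$history, phase = "II"))
  list(model = r2$model, history = hist)
}

#' Save / load a model as a JSON archive
#'
#' The archive holds the backbone spec, phase, target standardisation and
#' all layer weights as plain JSON, making saved models text artifacts.
#'
#' @param model an `eem_model`.
#' @param path file path.
#' @return `path` invisibly (`save_model`); the restored `eem_model`
#'   (`load_model`).
#' @export
save_model <- function(model, path) {
  ser <- list(spec = unclass(model$spec), phase = model$phase,
              target_center = model$target_center,
              target_scale = model$target_scale,
              layers = lapply(model$layers, function(l) {
                if (layer_has_params(l)) l$W <- as.vector(l$W)
                l
              }))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = FALSE)
  spec <- backbone_spec(kind = ser$spec$kind,
                        weights_source = ser$spec$weights_source,
                        input_shape = unlist(ser$spec$input_shape),
                        pool_size = ser$spec$pool_size,
                        basis_grid = ser$spec$basis_grid,
                        conv_widths = unlist(ser$spec$conv_widths))
  layers <- lapply(ser$layers, function(l) {
    l <- lapply(l, function(v) if (is.list(v)) unlist(v) else v)
    if (!is.null(l$W)) {
      l$b <- as.numeric(l$b)
      l$W <- matrix(as.numeric(l$W), ncol = length(l$b))
    }
    l
  })
  structure(list(spec = spec, layers = layers, phase = ser$phase,
                 target_center = ser$target_center,
                 target_scale = ser$target_scale),
            class = "eem_model")
}
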