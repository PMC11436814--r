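#' Oil-grouped leave-one-out splits
#'
#' One split per oil: all oxidation stages of that oil form the validation
#' set and every other record trains. Grouping by oil prevents leakage of
#' an oil's oxidation trajectory between training and validation.
#'
#' @param ds an [oil_dataset] with at least two oils.
#' @return list of `loo_split` objects, each with `validation_oil`,
#'   `train` and `validation` (record index vectors).
#' @export
make_loo_splits <- function(ds) {
  oils <- dataset_oils(ds)
  if (length(oils) < 2L)
    stopf("leave-one-out needs >= 2 oils (got %d)", length(oils))
  lapply(oils, function(o) {
    v <- which(ds$index$oil_id == o)
    structure(list(validation_oil = o, train = setdiff(seq_len(n_records(ds)), v),
                   validation = v),
              class = "loo_split")
  })
}

#' Run oil-grouped leave-one-out cross-validation
#'
#' For each split a fresh model is built and trained with the two-phase
#' recipe on the training records only, then scored on the held-out oil.
#' All normalisation is fixed (unit-scale pixel divisor) or computed from
#' the training records alone, so no validation statistic enters training.
#'
#' @param ds an [oil_dataset].
#' @param target `"K232"` or `"K268"`.
#' @param backbone a [backbone_spec].
#' @param config_I,config_II [phase_config]s; defaults are the desk-scale
#'   stand-in settings.
#' @param seed base seed; each fold derives its own child seed.
#' @param trainer optional override: a function
#'   `function(train_inputs, train_targets, seed)` returning a prediction
#'   function `function(inputs) -> numeric`. Used to inject mock or
#'   baseline predictors; when supplied, no model is built.
#' @param preprocess_args extra arguments to [to_model_input()].
#' @param verbose log per-fold progress.
#' @return data.frame of class `prediction_records` with one row per
#'   validation record: `oil_id`, `stage_index`, `target`, `true`,
#'   `predicted`, `ae` (absolute error).
#' @export
run_loo <- function(ds, target = c("K268", "K232"),
                    backbone = backbone_spec(),
                    config_I = standin_phase_config("I"),
                    config_II = standin_phase_config("II"),
                    seed = 1, trainer = NULL, preprocess_args = list(),
                    verbose = FALSE) {
  target <- match.arg(target)
  splits <- make_loo_splits(ds)
  y <- dataset_targets(ds, target)
  inputs <- lapply(ds$records, function(r)
    do.call(to_model_input, c(list(r$grid), preprocess_args)))
  seeds <- derive_seeds(seed, length(splits))
  out <- vector("list", length(splits))
  for (k in seq_along(splits)) {
    sp <- splits[[k]]
    t0 <- Sys.time()
    predict_fn <- tryCatch({
      if (is.null(trainer)) {
        cI <- config_I; cI$seed <- seeds[k]
        cII <- config_II; cII$seed <- seeds[k] + 1L
        fit <- train_two_phase(inputs[sp$train], y[sp$train],
                               backbone = backbone, config_I = cI,
                               config_II = cII, seed = seeds[k])
        function(xs) predict(fit$model, xs)
      } else {
        trainer(inputs[sp$train], y[sp$train], seeds[k])
      }
    }, error = function(e)
      stopf("training failed for validation oil '%s': %s",
            sp$validation_oil, conditionMessage(e)))
    pred <- predict_fn(inputs[sp$validation])
    out[[k]] <- data.frame(
      oil_id = ds$index$oil_id[sp$validation],
      stage_index = ds$index$stage_index[sp$validation],
      target = target, true = y[sp$validation], predicted = pred,
      ae = abs(y[sp$validation] - pred), stringsAsFactors = FALSE)
    if (verbose)
      log_msg("loo_eval", "fold %d/%d (oil %s): MAE %.4f [%.1fs]",
              k, length(splits), sp$validation_oil, mean(out[[k]]$ae),
              as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }
  res <- do.call(rbind, out)
  class(res) <- c("prediction_records", class(res))
  res
}

#' Leave-one-out mean-predictor baseline
#'
#' For every split, predicts the mean of the training targets for all
#' validation records -- the natural no-information reference for the MAE.
#'
#' @inheritParams run_loo
#' @return `prediction_records` data.frame (same shape as [run_loo()]).
#' @export
baseline_loo <- function(ds, target = c("K268", "K232")) {
  target <- match.arg(target)
  run_loo(ds, target = target,
          trainer = function(train_inputs, train_targets, seed) {
            m <- mean(train_targets)
            function(xs) rep(m, length(xs))
          })
}

#' Summarise prediction records
#'
#' @param records a `prediction_records` data.frame.
#' @return list with `total_mae` (mean AE over all records), `per_oil`
#'   (data.frame: oil_id, n, mae and AE quantiles q0/q25/q50/q75/q100,
#'   the numbers behind per-oil violin plots) and `table` (the
#'   predicted-vs-actual records).
#' @export
summarize_predictions <- function(records) {
  if (is.null(records) || nrow(records) == 0L) stopf("no prediction records")
  per_oil <- do.call(rbind, lapply(split(records, records$oil_id), function(d) {
    q <- stats::quantile(d$ae, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
    data.frame(oil_id = d$oil_id[1L], n = nrow(d), mae = mean(d$ae),
               q0 = q[1], q25 = q[2], q50 = q[3], q75 = q[4], q100 = q[5],
               stringsAsFactors = FALSE)
  }))
  per_oil <- per_oil[match(unique(records$oil_id), per_oil$oil_id), ]
  rownames(per_oil) <- NULL
  list(total_mae = mean(records$ae), per_oil = per_oil,
       table = as.data.frame(records))
}

#' Write prediction records and metrics to disk
#' @param records a `prediction_records` data.frame.
#' @param dir output directory.
#' @return paths of the two files, invisibly.
#' @export
write_predictions <- function(records, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, "predictions.csv")
  js <- file.path(dir, "metrics.json")
  utils::write.csv(as.data.frame(records), csv, row.names = FALSE)
  s <- summarize_predictions(records)
  jsonlite::write_json(list(total_mae = s$total_mae, per_oil = s$per_oil),
                       js, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(c(csv, js))
}
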