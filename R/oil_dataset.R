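#' Construct an oil dataset
#'
#' An `oil_dataset` is an ordered collection of (EEM, quality indicators)
#' records covering one or more oils at one or more oxidation stages. Every
#' (oil, stage) pair must be unique and every record must carry both labels.
#'
#' @param records list where each element is `list(grid = <eem_grid>,
#'   labels = <quality_indicators>)`.
#' @return object of class `oil_dataset` with fields `records` (the list)
#'   and `index` (a data.frame with one row per record: `oil_id`,
#'   `stage_index`, `k232`, `k268`).
#' @export
oil_dataset <- function(records) {
  if (!is.list(records) || length(records) == 0L)
    stopf("empty dataset: no records supplied")
  idx <- do.call(rbind, lapply(records, function(r) {
    if (!inherits(r$grid, "eem_grid"))
      stopf("every record needs a $grid of class eem_grid")
    if (!inherits(r$labels, "quality_indicators"))
      stopf("record for oil '%s' stage %s has no quality_indicators label",
            r$grid$oil_id, r$grid$stage_index)
    data.frame(oil_id = r$grid$oil_id, stage_index = r$grid$stage_index,
               k232 = r$labels$k232, k268 = r$labels$k268,
               stringsAsFactors = FALSE)
  }))
  key <- paste(idx$oil_id, idx$stage_index, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    stopf("duplicate (oil, stage) keys: %s",
          paste(gsub("\r", "/stage ", dup), collapse = ", "))
  }
  structure(list(records = records, index = idx), class = "oil_dataset")
}

#' Number of records in an oil dataset
#' @param ds an `oil_dataset`.
#' @return integer count.
#' @export
n_records <- function(ds) length(ds$records)

#' Oil identifiers present in a dataset
#' @param ds an `oil_dataset`.
#' @return character vector of unique oil ids, in order of first appearance.
#' @export
dataset_oils <- function(ds) unique(ds$index$oil_id)

#' Ordered stage indices per oil
#' @param ds an `oil_dataset`.
#' @return named list mapping oil_id to its sorted stage indices.
#' @export
stages_per_oil <- function(ds) {
  lapply(split(ds$index$stage_index, ds$index$oil_id), sort)[dataset_oils(ds)]
}

#' Label table of a dataset
#' @param ds an `oil_dataset`.
#' @return data.frame with columns oil_id, stage_index, k232, k268.
#' @export
labels_table <- function(ds) ds$index

#' Extract target values from a dataset
#' @param ds an `oil_dataset`.
#' @param target `"K232"` or `"K268"`.
#' @return numeric vector, one value per record.
#' @export
dataset_targets <- function(ds, target = c("K268", "K232")) {
  target <- match.arg(target)
  if (target == "K232") ds$index$k232 else ds$index$k268
}

#' @export
print.oil_dataset <- function(x, ...) {
  cat(sprintf("<oil_dataset> %d records: %d oils x stages {%s}\n",
              n_records(x), length(dataset_oils(x)),
              paste(range(x$index$stage_index), collapse = "-")))
  invisible(x)
}
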