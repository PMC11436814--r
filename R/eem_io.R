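## EEM CSV dialect
##
## Canonical layout: header row = emission wavelengths (nm), first column =
## excitation wavelengths (nm), body = intensities (counts), excitation on
## the rows. A transposed variant (rows = emission, columns = excitation),
## as produced by some instrument exports, is autodetected from the axis
## spacing of the headers (emission is sampled every 2 nm, excitation every
## 10 nm).

#' Read one EEM from a CSV file
#'
#' Expects a numeric matrix with wavelength headers (see the dialect note
#' above). Orientation (excitation-by-emission vs the transpose) is detected
#' from the header spacing; the returned grid always has excitation on the
#' rows. When headers are absent or unusable the documented standard axes
#' are synthesised, provided the body has the matching shape.
#'
#' @param path CSV file path.
#' @param oil_id,stage_index identity attached to the returned grid.
#' @param permissive accept any rectangular grid with consistent ascending
#'   axes instead of enforcing the standard 35 x 251 geometry.
#' @return an [eem_grid].
#' @export
read_eem_csv <- function(path, oil_id = "oil", stage_index = 0L,
                         permissive = FALSE) {
  if (!file.exists(path)) stopf("EEM file not found: %s", path)
  raw <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                         colClasses = "character", row.names = NULL)
  if (ncol(raw) < 2L || nrow(raw) < 1L)
    stopf("%s: not a wavelength-headed matrix (need >= 1 data row and >= 2 columns)", path)
  row_head <- suppressWarnings(as.numeric(raw[[1L]]))
  col_head <- suppressWarnings(as.numeric(colnames(raw)[-1L]))
  body <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stopf("%s: non-numeric cell '%s' at data row %d, column %d",
          path, body[bad[1L], bad[2L]], bad[1L], bad[2L])
  }
  if (anyNA(row_head)) row_head <- NULL
  if (anyNA(col_head)) col_head <- NULL

  ## orientation: excitation is sampled every ~10 nm, emission every ~2 nm
  spacing <- function(w) if (is.null(w) || length(w) < 2L) NA_real_ else stats::median(diff(w))
  transposed <- isTRUE(spacing(row_head) <= 5) && isTRUE(spacing(col_head) > 5)
  if (transposed) {
    num <- t(num)
    tmp <- row_head; row_head <- col_head; col_head <- tmp
  }

  excitation <- row_head %||% (if (nrow(num) == 35L) eem_excitation_axis() else
    stopf("%s: no excitation header and %d rows (expected 35)", path, nrow(num)))
  emission <- col_head %||% (if (ncol(num) == 251L) eem_emission_axis() else
    stopf("%s: no emission header and %d columns (expected 251)", path, ncol(num)))

  if (!permissive && (nrow(num) != 35L || ncol(num) != 251L))
    stopf("%s: grid is %d x %d, expected 35 excitation x 251 emission (use permissive = TRUE to accept)",
          path, nrow(num), ncol(num))
  eem_grid(num, excitation = excitation, emission = emission,
           oil_id = oil_id, stage_index = stage_index, strict = !permissive)
}

#' Write one EEM to a CSV file
#'
#' Emits the canonical dialect readable by [read_eem_csv()]: emission
#' wavelengths as the header row, excitation wavelengths as the first
#' column. Values are written with `digits` significant digits, so the
#' round trip is lossless at that precision.
#'
#' @param grid an [eem_grid].
#' @param path output path.
#' @param digits significant digits for intensities.
#' @return `path`, invisibly.
#' @export
write_eem_csv <- function(grid, path, digits = 8L) {
  validate_eem_grid(grid, strict = FALSE)
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stopf("cannot write '%s': %s", path, conditionMessage(e)))
  on.exit(close(con))
  cat("excitation_nm", paste(format(grid$emission, trim = TRUE, scientific = FALSE),
                             collapse = ","),
      sep = ",", file = con)
  cat("\n", file = con)
  body <- formatC(signif(grid$intensities, digits), format = "g",
                  digits = digits, width = 1)
  for (i in seq_along(grid$excitation)) {
    cat(format(grid$excitation[i], trim = TRUE, scientific = FALSE),
        paste(body[i, ], collapse = ","), sep = ",", file = con)
    cat("\n", file = con)
  }
  invisible(path)
}

#' Read a quality-indicator label table
#'
#' Delimited table (comma or tab, autodetected) with a header row and
#' columns `oil_id`, `stage_index`, `k232`, `k268`.
#'
#' @param path file path.
#' @return data.frame with the four columns, types coerced.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stopf("labels file not found: %s", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("oil_id", "stage_index", "k232", "k268")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("labels file %s lacks column(s): %s", path, paste(miss, collapse = ", "))
  df$oil_id <- as.character(df$oil_id)
  df$stage_index <- as.integer(df$stage_index)
  df$k232 <- as.numeric(df$k232)
  df$k268 <- as.numeric(df$k268)
  df[need]
}

#' Write a quality-indicator label table
#' @param labels data.frame with columns oil_id, stage_index, k232, k268.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  utils::write.csv(labels, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load a directory of EEM CSVs joined to a label table
#'
#' EEM files are expected to be named `<oil_id>_stage<k>.csv` (the naming
#' used by [write_dataset()] and `command_simulate()`). Each file is joined
#' to the label row with the same (oil_id, stage_index) key.
#'
#' @param eem_dir directory containing the EEM CSV files.
#' @param labels_path path of the label table (see [read_labels()]).
#' @param permissive passed to [read_eem_csv()].
#' @param verbose log counts of oils/stages/records.
#' @return an [oil_dataset].
#' @export
load_dataset <- function(eem_dir, labels_path, permissive = FALSE,
                         verbose = FALSE) {
  files <- list.files(eem_dir, pattern = "\\.csv$", full.names = TRUE)
  files <- files[grepl("_stage[0-9]+\\.csv$", files)]
  if (length(files) == 0L)
    stopf("empty dataset: no EEM files matching '*_stage<k>.csv' in %s", eem_dir)
  base <- basename(files)
  oil <- sub("_stage[0-9]+\\.csv$", "", base)
  stage <- as.integer(sub("^.*_stage([0-9]+)\\.csv$", "\\1", base))
  labels <- read_labels(labels_path)
  lkey <- paste(labels$oil_id, labels$stage_index, sep = "\r")
  if (anyDuplicated(lkey))
    stopf("duplicate (oil, stage) rows in labels table: %s",
          paste(unique(gsub("\r", "/stage ", lkey[duplicated(lkey)])), collapse = ", "))
  fkey <- paste(oil, stage, sep = "\r")
  missing <- setdiff(fkey, lkey)
  if (length(missing))
    stopf("EEM file(s) without a matching label row: %s",
          paste(gsub("\r", "/stage ", missing), collapse = ", "))
  ord <- order(oil, stage)
  records <- lapply(ord, function(i) {
    g <- read_eem_csv(files[i], oil_id = oil[i], stage_index = stage[i],
                      permissive = permissive)
    row <- labels[match(fkey[i], lkey), ]
    list(grid = g, labels = quality_indicators(row$k232, row$k268))
  })
  ds <- oil_dataset(records)
  if (verbose)
    log_msg("eem_io", "loaded %d records: %d oils, stages %s",
            n_records(ds), length(dataset_oils(ds)),
            paste(range(ds$index$stage_index), collapse = "-"))
  ds
}

#' Write a dataset to disk as EEM CSVs plus a label table and manifest
#'
#' One CSV per record named `<oil_id>_stage<k>.csv`, a `labels.csv`, and a
#' JSON `manifest.json` listing oils, stages and file paths.
#'
#' @param ds an [oil_dataset].
#' @param dir output directory (created if needed).
#' @param digits significant digits for intensities.
#' @return the manifest, invisibly.
#' @export
write_dataset <- function(ds, dir, digits = 8L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(n_records(ds))
  for (i in seq_len(n_records(ds))) {
    g <- ds$records[[i]]$grid
    paths[i] <- file.path(dir, sprintf("%s_stage%d.csv", g$oil_id, g$stage_index))
    write_eem_csv(g, paths[i], digits = digits)
  }
  write_labels(labels_table(ds), file.path(dir, "labels.csv"))
  manifest <- list(oils = dataset_oils(ds),
                   stages_per_oil = stages_per_oil(ds),
                   n_records = n_records(ds),
                   files = basename(paths),
                   labels = "labels.csv")
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
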