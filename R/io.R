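# CSV / JSON serialization of datasets, models, metrics and maps

#' Write a unit-step dataset bundle to disk
#'
#' Layout: one directory per subject containing `step_<i>.csv` (header row
#' of channel names, one row per time stamp), plus a top-level
#' `manifest.json` with the subject ids, T, the pressure floor delta and
#' the generation settings.
#'
#' @param dataset a `gait_dataset`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_gait_bundle <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (a in names(dataset$steps)) {
    sd <- file.path(dir, a)
    dir.create(sd, showWarnings = FALSE)
    ss <- dataset$steps[[a]]
    for (i in seq_along(ss))
      utils::write.csv(as.data.frame(ss[[i]]),
                       file.path(sd, sprintf("step_%d.csv", i)),
                       row.names = FALSE)
  }
  manifest <- list(subjects = names(dataset$steps),
                   steps_per_subject = as.list(vapply(dataset$steps,
                                                      length, 1L)),
                   T = dataset$T_len, delta = dataset$delta,
                   config = if (!is.null(dataset$config))
                     lapply(unclass(dataset$config), unclass))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a unit-step dataset bundle from disk
#'
#' @param dir directory written by [write_gait_bundle()].
#' @return A `gait_dataset` (without templates).
#' @export
read_gait_bundle <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  steps <- stats::setNames(lapply(mf$subjects, function(a) {
    files <- sprintf("step_%d.csv",
                     seq_len(mf$steps_per_subject[[a]]))
    lapply(files, function(f) {
      m <- as.matrix(utils::read.csv(file.path(dir, a, f)))
      colnames(m) <- modality_layout()$channels
      m
    })
  }), mf$subjects)
  structure(list(steps = steps, templates = NULL, T_len = mf$T,
                 delta = mf$delta, config = mf$config),
            class = "gait_dataset")
}

#' Save a trained model checkpoint
#'
#' Weights go to a single binary file; a JSON sidecar records the
#' configuration and training history.
#'
#' @param model a `gait_model` from [train_gait_model()].
#' @param path checkpoint file path (e.g. `model.rds`); the sidecar is
#'   written next to it as `<path>.json`.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  side <- list(config = unclass(model$config), history = model$history)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path path given to [save_checkpoint()].
#' @return The `gait_model`.
#' @export
load_checkpoint <- function(path) readRDS(path)

#' Write a metrics report as JSON and CSV
#'
#' @param per_repetition data frame with one row per repetition.
#' @param path_prefix files `<prefix>.json` and `<prefix>.csv` are written;
#'   the CSV carries one row per repetition plus a `mean` row.
#' @return The JSON path, invisibly.
#' @export
write_metrics <- function(per_repetition, path_prefix) {
  mean_row <- per_repetition[1, ]
  for (cn in names(per_repetition))
    mean_row[[cn]] <- if (is.numeric(per_repetition[[cn]]))
      mean(per_repetition[[cn]]) else "mean"
  out <- rbind(cbind(row = as.character(per_repetition$repetition),
                     per_repetition),
               cbind(row = "mean", mean_row))
  utils::write.csv(out, paste0(path_prefix, ".csv"), row.names = FALSE)
  jsonlite::write_json(list(per_repetition = per_repetition,
                            mean = as.list(colMeans(
                              per_repetition[vapply(per_repetition,
                                                    is.numeric, TRUE)]))),
                       paste0(path_prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(paste0(path_prefix, ".json"))
}

#' Write an attribution map as CSV plus JSON metadata
#'
#' @param map T x 28 attribution map (e.g. a `common_attribution_map`).
#' @param path_prefix files `<prefix>.csv` and `<prefix>.json`.
#' @return The CSV path, invisibly.
#' @export
write_attribution_map <- function(map, path_prefix) {
  m <- as.matrix(map)
  colnames(m) <- modality_layout()$channels
  utils::write.csv(as.data.frame(m), paste0(path_prefix, ".csv"),
                   row.names = FALSE)
  meta <- list(method = attr(map, "method"), eps = attr(map, "eps"),
               n_steps = attr(map, "n_steps"),
               n_subjects = attr(map, "n_subjects"),
               T = nrow(m), channels = ncol(m))
  jsonlite::write_json(meta, paste0(path_prefix, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(paste0(path_prefix, ".csv"))
}

#' Render an attribution map as a heat map
#'
#' Channels on the x-axis, time stamps on the y-axis.
#'
#' @param map T x 28 attribution map.
#' @param path optional PNG path; when `NULL`, plots to the active device.
#' @param main plot title.
#' @return `path` (or `NULL`), invisibly.
#' @export
plot_attribution_map <- function(map, path = NULL, main = "attribution map") {
  if (!is.null(path)) grDevices::png(path, width = 700, height = 900)
  lay <- modality_layout()
  graphics::image(x = seq_len(ncol(map)), y = seq_len(nrow(map)),
                  z = t(as.matrix(map)),
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "channel", ylab = "time stamp", main = main,
                  axes = FALSE)
  graphics::axis(1, at = seq_len(ncol(map)), labels = lay$channels,
                 las = 2, cex.axis = 0.6)
  graphics::axis(2)
  if (!is.null(path)) grDevices::dev.off()
  invisible(path)
}
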