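#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> branch %s: %d-fold speaker-independent CV (seed %d)\n",
              x$branch, x$config$k, x$config$seed))
  agg <- x$aggregate
  for (i in seq_len(nrow(agg))) {
    cat(sprintf("  %-12s %5.1f +/- %4.1f %%\n", agg$metric[i], agg$mean[i],
                agg$sd[i]))
  }
  invisible(x)
}

#' Per-fold metrics of a cross-validation report
#'
#' @param x A `cv_report` from [run_experiment()].
#' @param ... Unused.
#' @return A tibble with one row per fold: `fold`, `n_test`, `accuracy`,
#'   `sensitivity`, `specificity`, `f1` (percent).
#' @export
tidy.cv_report <- function(x, ...) x$per_fold

#' One-row summary of a cross-validation report
#'
#' @param x A `cv_report`.
#' @param ... Unused.
#' @return A one-row tibble with `branch`, `k`, `n_speakers`, and
#'   `<metric>_mean` / `<metric>_sd` columns (percent).
#' @export
glance.cv_report <- function(x, ...) {
  agg <- x$aggregate
  vals <- c(rbind(agg$mean, agg$sd))
  names(vals) <- as.vector(rbind(paste0(agg$metric, "_mean"),
                                 paste0(agg$metric, "_sd")))
  tibble::tibble(branch = x$branch, k = x$config$k,
                 n_speakers = nrow(x$fold_plan), !!!vals)
}

#' Score histogram of a cross-validation report
#'
#' Histogram of the per-subject decision scores by class with the
#' decision threshold marked, the standard way to visualize how far the
#' two classes sit from the operating point.
#'
#' @param object A `cv_report`.
#' @param bins Histogram bins (default 15).
#' @param threshold Decision threshold to mark (default 0.5).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cv_report <- function(object, bins = 15, threshold = 0.5, ...) {
  df <- object$scores
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score, fill = .data$label)) +
    ggplot2::geom_histogram(bins = bins, alpha = 0.6, position = "identity",
                            boundary = 0) +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed") +
    ggplot2::scale_fill_manual(values = c(HC = "#2166ac", PD = "#b2182b")) +
    ggplot2::labs(x = "PD score", y = "subjects",
                  title = paste0("Decision scores: ", object$branch)) +
    ggplot2::theme_minimal()
}

#' Training-history curve of a trained deep model
#'
#' @param object A `trained_model` from [train_deep()].
#' @param ... Unused.
#' @return A ggplot object with train/validation loss per epoch.
#' @export
autoplot.trained_model <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                           names_to = "set", values_to = "loss")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  color = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "cross-entropy loss") +
    ggplot2::theme_minimal()
}

#' Plot a mel spectrogram
#'
#' @param object A `mel_spectrogram`.
#' @param ... Unused.
#' @return A ggplot object (time on x, mel band on y).
#' @export
autoplot.mel_spectrogram <- function(object, ...) {
  df <- expand.grid(band = seq_len(nrow(object)),
                    frame = seq_len(ncol(object)))
  df$value <- as.vector(unclass(object))
  df$time_s <- attr(object, "frame_times")[df$frame]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$band,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "log energy") +
    ggplot2::labs(x = "time (s)", y = "mel band") +
    ggplot2::theme_minimal()
}

#' Export a cross-validation report to disk
#'
#' Writes `report.json` (branch, config echo, aggregate and per-fold
#' metrics), `per_fold.csv`, and `scores.csv` (per-subject decision
#' scores with labels, the data behind the score histograms).
#'
#' @param report A `cv_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(branch = report$branch,
         k = report$config$k, seed = report$config$seed,
         aggregate = report$aggregate, per_fold = report$per_fold),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(as.data.frame(report$per_fold),
                   file.path(dir, "per_fold.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(report$scores),
                   file.path(dir, "scores.csv"), row.names = FALSE)
  invisible(dir)
}

#' @importFrom rlang .data
NULL
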