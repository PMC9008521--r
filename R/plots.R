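#' Basic figure renderers for exported tables
#'
#' Each renderer reads one of the pipeline's TSV artifacts (never in-memory
#' state, so the table exports are the complete interface) and returns a
#' ggplot object: the anchor rank/ambient timeline, a word-shift bar chart,
#' the divergence rank-rank histogram, and the contagiogram balance panel.
#'
#' @param rank_series_path,ambient_path,shift_path,histogram_path,balance_path
#'   paths to the corresponding TSV exports of [run_pipeline()].
#' @return a ggplot object.
#' @name pipeline_plots
NULL

#' @rdname pipeline_plots
#' @export
plot_rank_series <- function(rank_series_path, ambient_path = NULL) {
  rs <- fread(rank_series_path, sep = "\t")
  rs[, date := as.Date(date)]
  rs <- rs[!is.na(rank)]
  ggplot2::ggplot(rs, ggplot2::aes(x = date, y = log10(rank))) +
    ggplot2::geom_line(linewidth = 0.3, color = "grey40") +
    ggplot2::geom_hline(yintercept = log10(median(rs$rank)),
                        color = "red", linewidth = 0.3) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = NULL, y = "log10 rank (inverted axis)") +
    ggplot2::theme_minimal()
}

#' @rdname pipeline_plots
#' @export
plot_word_shift <- function(shift_path, top_k = 20L) {
  sh <- fread(shift_path, sep = "\t")
  sh <- sh[in_top_k == TRUE][seq_len(min(top_k, .N))]
  sh[, word := factor(word, levels = rev(word))]
  ggplot2::ggplot(sh, ggplot2::aes(x = contribution, y = word, fill = class)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(pos_up = "#f2c511",
                                          pos_down = "#f8e597",
                                          neg_up = "#2166ac",
                                          neg_down = "#92b8d9",
                                          none = "grey70")) +
    ggplot2::labs(x = "happiness shift contribution", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname pipeline_plots
#' @export
plot_divergence_histogram <- function(histogram_path) {
  h <- fread(histogram_path, sep = "\t")
  shared <- h[band == "shared"]
  ggplot2::ggplot(shared, ggplot2::aes(x = cell_x, y = cell_y, fill = count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(trans = "log10") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "log10 rank, system 1 (binned)",
                  y = "log10 rank, system 2 (binned)") +
    ggplot2::theme_minimal()
}

#' @rdname pipeline_plots
#' @export
plot_contagiogram_balance <- function(balance_path) {
  b <- fread(balance_path, sep = "\t")
  b <- b[!is.na(f_rt)]
  b[, date := as.Date(paste0(month, "-01"))]
  long <- melt(b[, .(date, organic = f_ot, retweeted = f_rt)],
               id.vars = "date", variable.name = "kind",
               value.name = "fraction")
  ggplot2::ggplot(long, ggplot2::aes(x = date, y = fraction, color = kind)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, linewidth = 0.3) +
    ggplot2::scale_color_manual(values = c(organic = "#2166ac",
                                           retweeted = "#e08214")) +
    ggplot2::labs(x = NULL, y = "monthly fraction of occurrences") +
    ggplot2::theme_minimal()
}

render_pipeline_plots <- function(paths, out_dir) {
  try_plot <- function(expr, file) {
    tryCatch({
      g <- expr
      ggplot2::ggsave(file.path(out_dir, file), g, width = 7, height = 4,
                      dpi = 150)
    }, error = function(e) message("plot skipped (", file, "): ",
                                   conditionMessage(e)))
  }
  if (!is.null(paths$rank_series)) {
    try_plot(plot_rank_series(paths$rank_series), "fig_rank_series.png")
  }
  if (!is.null(paths$shifts) && length(paths$shifts)) {
    try_plot(plot_word_shift(paths$shifts[[1]]), "fig_word_shift.png")
  }
  if (!is.null(paths$divergence_histogram)) {
    try_plot(plot_divergence_histogram(paths$divergence_histogram),
             "fig_divergence.png")
  }
  if (!is.null(paths$balance)) {
    try_plot(plot_contagiogram_balance(paths$balance), "fig_balance.png")
  }
  invisible(NULL)
}
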