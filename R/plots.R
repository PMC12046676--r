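# Diagnostic figures: CNA heatmap (genes in genomic order, bins grouped by
# cluster), spatial cluster map, arm-profile bars, and a top-DEG dot plot.
# All plots are side effects of a run; tables are the canonical output.

#' CNA score heatmap
#'
#' Bins (rows, grouped by cluster) x genes (columns, genomic order);
#' amplification (> 1) in red, deletion (< 1) in blue.
#'
#' @param run A `cna_run` (or a `bin_set` plus `clusters`).
#' @param clusters Optional named cluster vector when passing a `bin_set`.
#' @return A ggplot object.
#' @export
plot_cna_heatmap <- function(run, clusters = NULL) {
  binset <- if (inherits(run, "cna_run")) run$binset else run
  if (is.null(clusters) && inherits(run, "cna_run"))
    clusters <- run$clones$clusters
  cna <- binset$cna
  ord <- order(clusters[rownames(cna)])
  df <- data.frame(
    bin = factor(rep(rownames(cna)[ord], times = ncol(cna)),
                 levels = rownames(cna)[ord]),
    gene = factor(rep(colnames(cna), each = nrow(cna)),
                  levels = colnames(cna)),
    score = as.vector(cna[ord, ]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gene, y = .data$bin,
                                   fill = .data$score)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(midpoint = 1, low = "blue", mid = "white",
                                  high = "red", limits = c(0.6, 1.4)) +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "right") +
    ggplot2::labs(fill = "CNA score")
}

#' Spatial map of bins coloured by cluster
#'
#' @param run A `cna_run`.
#' @return A ggplot object.
#' @export
plot_spatial_clusters <- function(run) {
  bins <- run$binset$bins
  bins$cluster <- factor(run$clones$clusters[bins$bin])
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$cluster)) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)")
}

#' Arm-profile bar panel
#'
#' @param profiles Arm-profile matrix (sources x arms).
#' @return A ggplot object.
#' @export
plot_arm_profiles <- function(profiles) {
  df <- data.frame(
    source = rep(rownames(profiles), times = ncol(profiles)),
    arm = factor(rep(colnames(profiles), each = nrow(profiles)),
                 levels = colnames(profiles)),
    score = as.vector(profiles))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$arm, y = .data$score - 1)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$source)) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5)) +
    ggplot2::labs(y = "mean CNA score - 1")
}

#' Dot plot of top differentially expressed genes per cluster
#'
#' @param dge DGE table from [differential_expression()].
#' @param top_n Genes per cluster (default 5, by fold change among
#'   significant genes).
#' @param alpha Adjusted-p cutoff (default 0.05).
#' @return A ggplot object.
#' @export
plot_dge_dotplot <- function(dge, top_n = 5, alpha = 0.05) {
  sig <- dge[dge$p_adjusted < alpha, ]
  if (nrow(sig) == 0L) stop("no significant genes at p_adj < ", alpha)
  keep <- do.call(rbind, lapply(split(sig, sig$cluster), function(d)
    utils::head(d[order(-d$log2_fold_change), ], top_n)))
  keep$cluster <- factor(keep$cluster)
  ggplot2::ggplot(keep, ggplot2::aes(x = .data$cluster, y = .data$gene,
                                     size = .data$pct_expressing,
                                     colour = .data$log2_fold_change)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_gradient2(low = "blue", mid = "grey90", high = "red") +
    ggplot2::theme_minimal() +
    ggplot2::labs(size = "% expressing", colour = "log2 FC")
}

#' Save the standard plot set for a run
#'
#' Writes heatmap, spatial cluster map, and arm-profile panel (plus DEG dot
#' plot when DGE was run) as PNGs. Failures (e.g. no graphics device
#' available) are warnings, never errors.
#'
#' @param run A `cna_run`.
#' @param out_dir Output directory.
#' @return Invisibly, the files written.
#' @export
save_run_plots <- function(run, out_dir) {
  written <- character(0)
  save1 <- function(name, plot) {
    path <- file.path(out_dir, name)
    ok <- tryCatch({
      grDevices::png(path, width = 1400, height = 1000, res = 150)
      print(plot)
      grDevices::dev.off()
      TRUE
    }, error = function(e) {
      warning("could not write ", name, ": ", conditionMessage(e))
      FALSE
    })
    if (ok) written <<- c(written, path)
  }
  save1("cna_heatmap.png", plot_cna_heatmap(run))
  save1("spatial_clusters.png", plot_spatial_clusters(run))
  save1("arm_profiles.png", plot_arm_profiles(run$arm_profiles))
  if (!is.null(run$dge)) {
    p <- tryCatch(plot_dge_dotplot(run$dge), error = function(e) NULL)
    if (!is.null(p)) save1("dge_dotplot.png", p)
  }
  invisible(written)
}
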