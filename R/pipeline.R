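# End-to-end orchestration: preprocess -> smooth -> bin -> clones ->
# arm profiles, with all tables written to an output directory together
# with a reproducibility manifest. Plots are side effects; every
# downstream-consumable surface is a table.

#' Assemble a run configuration
#'
#' @param preprocess A [preprocess_config()].
#' @param smooth A [smoothing_config()].
#' @param binning A [binning_config()].
#' @param k_max_clones Largest clone number tested (default 10).
#' @param signal_threshold Arm signal threshold for concordance
#'   (default 0.02).
#' @param run_dge Whether to run differential expression (default TRUE).
#' @param seed Seed for any stochastic step (inference itself is
#'   deterministic; the seed covers simulation when driven from the same
#'   config).
#' @return A `run_config` list.
#' @export
run_config <- function(preprocess = preprocess_config(),
                       smooth = smoothing_config(),
                       binning = binning_config(),
                       k_max_clones = 10,
                       signal_threshold = 0.02,
                       run_dge = TRUE,
                       seed = 1L) {
  structure(list(preprocess = preprocess, smooth = smooth, binning = binning,
                 k_max_clones = k_max_clones,
                 signal_threshold = signal_threshold,
                 run_dge = isTRUE(run_dge), seed = as.integer(seed)),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Recognised blocks: `preprocess`, `smooth`, `binning`, and top-level
#' `k_max_clones`, `signal_threshold`, `run_dge`, `seed`; unset keys keep
#' their defaults.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- run_config()
  if (!is.null(y$preprocess)) cfg$preprocess <- do.call(preprocess_config, y$preprocess)
  if (!is.null(y$smooth)) cfg$smooth <- do.call(smoothing_config, y$smooth)
  if (!is.null(y$binning)) cfg$binning <- do.call(binning_config, y$binning)
  for (k in c("k_max_clones", "signal_threshold", "run_dge", "seed"))
    if (!is.null(y[[k]])) cfg[[k]] <- y[[k]]
  cfg
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the CNA inference pipeline
#'
#' Executes preprocessing, chromosomal smoothing, spatio-molecular binning,
#' CNA scoring, clone calling, optional differential expression, and arm
#' aggregation on a `spatial_expression` input. With `out_dir` set, writes
#' bins, CNA scores, clones, silhouette trace, arm profiles, concordance,
#' DGE tables (TSV), diagnostic plots (PNG, best effort), and a YAML run
#' manifest.
#'
#' @param se A `spatial_expression` (raw counts).
#' @param gp A `gene_positions` table.
#' @param cfg A [run_config()].
#' @param out_dir Optional output directory.
#' @return A `cna_run` list: `se` (filtered), `intensity` (rescaled bead
#'   matrix), `binset` (with CNA scores), `clones` (a `clone_assignment`),
#'   `bead_clusters`, `dge` (or `NULL`), `arm_profiles`, `concordance`,
#'   `config`.
#' @export
run_pipeline <- function(se, gp, cfg = run_config(), out_dir = NULL) {
  t0 <- Sys.time()
  se_f <- .stage("preprocess", {
    x <- filter_matrix(se, cfg$preprocess)
    if (!any(x$bead_type == "reference"))
      stop("no reference beads survive filtering")
    if (!any(x$bead_type == "malignant"))
      stop("no malignant beads survive filtering")
    x
  })
  ref <- names(se_f$bead_type)[se_f$bead_type == "reference"]
  inten <- .stage("smooth", {
    m <- log_tpm(se_f)
    m <- center_and_cap(m, ref, gp, cap = cfg$preprocess$log_cap)
    m <- smooth_intensities(m, gp, cfg$smooth)
    recenter_and_rescale(m, ref)
  })
  binset <- .stage("bin_cna", {
    b <- bin_beads(inten, se_f, cfg$binning)
    cna_scores(b, cfg$binning)
  })
  cl <- .stage("clones", call_clones(binset, k_max = cfg$k_max_clones))
  bead_clusters <- cl$clusters[binset$membership]
  names(bead_clusters) <- names(binset$membership)
  dge <- NULL
  if (cfg$run_dge) {
    dge <- .stage("dge", differential_expression(se_f, bead_clusters))
  }
  profs <- .stage("evaluate",
                  arm_aggregate(binset$cna, gp,
                                groups = paste0("cluster_", cl$clusters[rownames(binset$cna)])))
  conc <- tryCatch(
    suppressMessages(concordance(profs, signal_threshold = cfg$signal_threshold)),
    error = function(e) NULL)
  run <- structure(list(se = se_f, intensity = inten, binset = binset,
                        clones = cl, bead_clusters = bead_clusters,
                        dge = dge, arm_profiles = profs, concordance = conc,
                        config = cfg),
                   class = "cna_run")
  if (!is.null(out_dir)) write_run(run, out_dir, elapsed = Sys.time() - t0)
  run
}

#' @export
print.cna_run <- function(x, ...) {
  cat("cna_run: ", n_beads(x$se), " beads, ", nrow(x$binset$bins), " bins, ",
      "k_malignant = ", x$clones$k_malignant, "\n", sep = "")
  invisible(x)
}

#' Write pipeline outputs and a run manifest
#'
#' @param run A `cna_run` from [run_pipeline()].
#' @param out_dir Output directory (created).
#' @param elapsed Optional elapsed time recorded in the manifest.
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir, elapsed = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) utils::write.table(
    df, file.path(out_dir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  bins <- run$binset$bins
  bins$cluster <- run$clones$clusters[bins$bin]
  bins$is_normal_cluster <- bins$cluster == run$clones$normal_cluster
  tsv(bins, "bins.tsv")
  tsv(data.frame(bead = names(run$binset$membership),
                 bin = run$binset$membership,
                 cluster = run$bead_clusters), "bead_assignments.tsv")
  cna <- data.frame(bin = rownames(run$binset$cna), run$binset$cna,
                    check.names = FALSE)
  tsv(cna, "cna_scores.tsv")
  tsv(data.frame(k = names(run$clones$silhouette_trace),
                 mean_silhouette = run$clones$silhouette_trace),
      "silhouette_trace.tsv")
  tsv(data.frame(source = rownames(run$arm_profiles), run$arm_profiles,
                 check.names = FALSE), "arm_profiles.tsv")
  if (!is.null(run$concordance))
    tsv(data.frame(source = rownames(run$concordance), run$concordance,
                   check.names = FALSE), "concordance.tsv")
  if (!is.null(run$dge)) tsv(run$dge, "dge.tsv")
  manifest <- list(
    package = "spotcna",
    version = as.character(utils::packageVersion("spotcna")),
    seed = run$config$seed,
    config = rapply(unclass(run$config), identity, how = "list"),
    n_beads = n_beads(run$se), n_genes = n_genes(run$se),
    n_bins = nrow(run$binset$bins),
    k_malignant = run$clones$k_malignant,
    elapsed_sec = if (!is.null(elapsed)) as.numeric(elapsed, units = "secs"))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  try(save_run_plots(run, out_dir), silent = TRUE)
  invisible(out_dir)
}
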