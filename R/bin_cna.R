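# Spatio-molecular binning: beads are grouped (separately within the
# malignant and the non-malignant population) by Ward clustering of a
# pseudo-distance combining physical and expression distance, then bin-level
# relative intensities are UMI-adjusted and clamped into CNA scores.

#' Binning configuration
#'
#' @param k_spatial Weight of the spatial distance matrix (default 55).
#' @param k_expression Weight of the expression distance matrix (default 1).
#' @param beads_per_bin Target bin size; each population is cut into
#'   `round(n / beads_per_bin)` bins (banker's rounding, minimum 1).
#' @param spatial If `FALSE` (non-spatial data such as dissociated
#'   single-cell profiles), the spatial term is omitted entirely.
#' @param cna_cap_high,cna_cap_low Clamp bounds for CNA scores
#'   (defaults 1.4 and 0.6; 1 = copy neutral).
#' @param umi_adjust `"none"` (default): scores are the capped bin
#'   intensities; `"shrink"`: deviations from 1 in bins with below-median
#'   UMI are additionally shrunk proportionally toward 1. Sparse counts
#'   already attenuate low-depth deviations in log space, so the shrink
#'   option double-penalises low-UMI bins and is kept only for
#'   sensitivity analyses.
#' @return A `binning_config` list.
#' @export
binning_config <- function(k_spatial = 55, k_expression = 1,
                           beads_per_bin = 12, spatial = TRUE,
                           cna_cap_high = 1.4, cna_cap_low = 0.6,
                           umi_adjust = c("none", "shrink")) {
  stopifnot(k_spatial >= 0, k_expression >= 0, k_spatial + k_expression > 0,
            beads_per_bin >= 1, cna_cap_low < 1, cna_cap_high > 1)
  structure(list(k_spatial = k_spatial, k_expression = k_expression,
                 beads_per_bin = beads_per_bin, spatial = isTRUE(spatial),
                 cna_cap_high = cna_cap_high, cna_cap_low = cna_cap_low,
                 umi_adjust = match.arg(umi_adjust)),
            class = "binning_config")
}

#' Combined spatial/expression pseudo-distance
#'
#' `k_spatial * D_spatial + k_expression * D_expression`, where `D_spatial`
#' is the pairwise Euclidean distance on the (x, y) coordinates and
#' `D_expression` the pairwise Euclidean distance on the rescaled intensity
#' rows. With `spatial = FALSE` the spatial term is omitted.
#'
#' @param intensities Rescaled intensity matrix (beads x genes).
#' @param coords data.frame with rownames = bead ids and columns `x`, `y`.
#' @param cfg A [binning_config()].
#' @return A symmetric bead x bead matrix with zero diagonal.
#' @export
pseudo_distance <- function(intensities, coords, cfg = binning_config()) {
  beads <- rownames(intensities)
  d_expr <- as.matrix(stats::dist(intensities))
  if (!cfg$spatial) {
    out <- cfg$k_expression * d_expr
  } else {
    xy <- as.matrix(coords[beads, c("x", "y")])
    if (!all(is.finite(xy))) stop("non-finite coordinates")
    d_sp <- as.matrix(stats::dist(xy))
    out <- cfg$k_spatial * d_sp + cfg$k_expression * d_expr
  }
  dimnames(out) <- list(beads, beads)
  out
}

#' Cut a pseudo-distance matrix into bins
#'
#' Ward (ward.D2) agglomeration on the pseudo-distance, cut into
#' `round(n / beads_per_bin)` bins (minimum 1).
#'
#' @param pseudo Symmetric pseudo-distance matrix.
#' @param cfg A [binning_config()].
#' @return Named integer vector bead -> bin index (within this group).
#' @export
assign_bins <- function(pseudo, cfg = binning_config()) {
  n <- nrow(pseudo)
  if (n == 1L) return(stats::setNames(1L, rownames(pseudo)))
  n_bins <- max(1L, as.integer(round(n / cfg$beads_per_bin)))
  hc <- stats::hclust(stats::as.dist(pseudo), method = "ward.D2")
  stats::setNames(stats::cutree(hc, k = min(n_bins, n)), rownames(pseudo))
}

.label_mode <- function(x) {
  tab <- sort(table(as.character(x)), decreasing = TRUE)
  top <- names(tab)[tab == tab[1L]]
  if (length(top) > 1L) {
    top <- sort(top)
    message("bin type tie {", paste(names(tab)[tab == tab[1L]], collapse = ", "),
            "}; using '", top[1L], "'")
  }
  top[1L]
}

#' Bin beads of a SpatialExpression dataset
#'
#' Runs [pseudo_distance()] and [assign_bins()] separately for the malignant
#' and the non-malignant (reference + non-reference normal) populations, so
#' no bin ever mixes the two, then aggregates: bin intensity = unweighted
#' mean of member intensities, bin coordinates = mean member coordinates,
#' bin UMI = summed member UMI, bin type = mode of member types (ties broken
#' by label sort order).
#'
#' @param intensities Rescaled intensity matrix (beads x genes).
#' @param se The (filtered) `spatial_expression` the intensities came from.
#' @param cfg A [binning_config()].
#' @return A `bin_set` list: `bins` (data.frame bin, x, y, umi, type,
#'   n_beads, malignant), `membership` (named vector bead -> bin id),
#'   `intensity` (bin x gene matrix).
#' @export
bin_beads <- function(intensities, se, cfg = binning_config()) {
  beads <- rownames(intensities)
  type <- se$bead_type[beads]
  groups <- list(non_malignant = beads[type != "malignant"],
                 malignant = beads[type == "malignant"])
  membership <- integer(0)
  offset <- 0L
  for (g in names(groups)) {
    ids <- groups[[g]]
    if (length(ids) == 0L) { message("no ", g, " beads; group skipped"); next }
    ps <- pseudo_distance(intensities[ids, , drop = FALSE],
                          se$coords, cfg)
    lab <- assign_bins(ps, cfg)
    membership <- c(membership, lab + offset)
    offset <- offset + max(lab)
  }
  aggregate_bins(intensities, se, membership)
}

#' Aggregate beads into bins
#'
#' @param intensities Rescaled intensity matrix (beads x genes).
#' @param se The `spatial_expression` object (for coordinates, UMI, types).
#' @param membership Named integer vector bead -> bin id (a partition).
#' @return A `bin_set` (see [bin_beads()]).
#' @export
aggregate_bins <- function(intensities, se, membership) {
  beads <- names(membership)
  stopifnot(!anyDuplicated(beads), all(beads %in% rownames(intensities)))
  bins <- sort(unique(membership))
  G <- Matrix::sparseMatrix(i = match(membership, bins),
                            j = seq_along(beads),
                            x = 1, dims = c(length(bins), length(beads)))
  sizes <- Matrix::rowSums(G)
  inten <- as.matrix(G %*% intensities[beads, , drop = FALSE]) / sizes
  rownames(inten) <- paste0("bin_", bins)
  colnames(inten) <- colnames(intensities)
  xy <- as.matrix(se$coords[beads, c("x", "y")])
  bxy <- as.matrix(G %*% xy) / sizes
  umi <- as.numeric(G %*% se$umi_per_bead[beads])
  btype <- vapply(split(as.character(se$bead_type[beads]), membership),
                  .label_mode, character(1L))
  df <- data.frame(bin = rownames(inten), x = bxy[, 1L], y = bxy[, 2L],
                   umi = umi, type = btype[as.character(bins)],
                   n_beads = as.integer(sizes),
                   malignant = btype[as.character(bins)] == "malignant",
                   stringsAsFactors = FALSE)
  rownames(df) <- df$bin
  structure(list(bins = df,
                 membership = stats::setNames(paste0("bin_", membership), beads),
                 intensity = inten),
            class = "bin_set")
}

#' @export
print.bin_set <- function(x, ...) {
  cat("bin_set: ", nrow(x$bins), " bins (",
      sum(x$bins$malignant), " malignant) over ",
      length(x$membership), " beads\n", sep = "")
  invisible(x)
}

#' Bin-level CNA scores
#'
#' Adjusts bin intensities for sequencing depth and clamps them into
#' `[cna_cap_low, cna_cap_high]`. With `umi_adjust = "shrink"`, a bin with
#' UMI total below the median has its deviations from copy-neutral 1 shrunk
#' by the factor `umi / median(umi)` (bins at or above the median are left
#' untouched), damping noise-driven deviations in sparse bins.
#'
#' @param binset A `bin_set` from [bin_beads()].
#' @param cfg A [binning_config()].
#' @return The `bin_set` with a `cna` element (bin x gene CNA score matrix).
#' @export
cna_scores <- function(binset, cfg = binning_config()) {
  if (any(binset$bins$umi <= 0)) stop("bin with zero UMI total")
  v <- binset$intensity
  if (cfg$umi_adjust == "shrink") {
    s <- pmin(1, binset$bins$umi / stats::median(binset$bins$umi))
    v <- 1 + (v - 1) * s
  }
  v[v > cfg$cna_cap_high] <- cfg$cna_cap_high
  v[v < cfg$cna_cap_low] <- cfg$cna_cap_low
  binset$cna <- v
  binset
}
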