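# Per-chromosome pyramidal weighted moving-average smoothing of centred log
# expression, followed by the two re-centring steps that turn smoothed values
# into relative expression intensities (copy-neutral = 1 after un-logging).
#
# For gene position i on a chromosome of n genes, the window covers genes
# max(1, i-m) .. min(n, i+m) with m = (k-1)/2; the raw weight of gene j is
# m + 1 - |i - j| (a symmetric pyramid, truncated at chromosome ends),
# normalised to sum to 1. The default window k = 101 is reduced to n on
# chromosomes with fewer than k genes.

#' Smoothing configuration
#'
#' @param window_k Odd window width in genes (default 101); the half-window
#'   is `m = (window_k - 1) / 2`. Chromosomes with fewer than `window_k`
#'   genes use their own gene count as the window.
#' @return A `smoothing_config` list with `window_k` and `m`.
#' @export
smoothing_config <- function(window_k = 101) {
  stopifnot(length(window_k) == 1L, window_k >= 3, window_k %% 2 == 1)
  structure(list(window_k = as.integer(window_k),
                 m = as.integer((window_k - 1) / 2)),
            class = "smoothing_config")
}

#' Pyramidal window weights
#'
#' Normalised weights of the smoothing window centred at gene position `i`
#' on a chromosome of `n` genes with half-window `m`: raw weight of gene
#' `j` in `max(1, i-m) .. min(n, i+m)` is `m + 1 - |i - j|`, rescaled to
#' sum to 1.
#'
#' @param i Centre position, `1 <= i <= n`.
#' @param n Number of genes on the chromosome.
#' @param m Half-window (`>= 1`).
#' @return Named list with `idx` (window gene positions) and `w` (weights
#'   summing to 1).
#' @export
pyramid_weights <- function(i, n, m) {
  stopifnot(i >= 1, i <= n, m >= 1)
  idx <- max(1L, i - m):min(n, i + m)
  raw <- m + 1 - abs(i - idx)
  list(idx = idx, w = raw / sum(raw))
}

#' Smooth one chromosome
#'
#' Applies the pyramidal weighted moving average along the gene (column)
#' axis of a bead x gene matrix whose columns are the genomically ordered
#' genes of a single chromosome. The effective window is
#' `min(window_k, n_genes)`.
#'
#' @param values bead x n_genes matrix (one chromosome, genomic order).
#' @param cfg A [smoothing_config()].
#' @return Matrix of the same shape.
#' @export
smooth_chromosome <- function(values, cfg = smoothing_config()) {
  n <- ncol(values)
  if (n == 0L) return(values)
  if (n == 1L) return(values)
  k <- min(cfg$window_k, if (n %% 2 == 0) n - 1 else n)
  m <- max(1L, as.integer((k - 1) / 2))
  trip_i <- vector("list", n)
  trip_w <- vector("list", n)
  for (i in seq_len(n)) {
    pw <- pyramid_weights(i, n, m)
    trip_i[[i]] <- pw$idx
    trip_w[[i]] <- pw$w
  }
  W <- Matrix::sparseMatrix(
    i = unlist(trip_i),
    j = rep.int(seq_len(n), lengths(trip_i)),
    x = unlist(trip_w), dims = c(n, n))
  out <- as.matrix(values %*% W)            # out[, i] = sum_j values[, j] W[j, i]
  dimnames(out) <- dimnames(values)
  out
}

#' Smooth all chromosomes of an intensity matrix
#'
#' Splits the genomically ordered gene axis by chromosome and smooths each
#' chromosome independently (karyotype order). Empty chromosomes are
#' skipped.
#'
#' @param m Intensity matrix from [center_and_cap()] (beads x genes,
#'   genomic order).
#' @param gp A `gene_positions` table covering the matrix's genes.
#' @param cfg A [smoothing_config()].
#' @return Smoothed matrix with `stage = "smoothed"`.
#' @export
smooth_intensities <- function(m, gp, cfg = smoothing_config()) {
  gp <- gp[match(colnames(m), gp$gene), , drop = FALSE]
  if (anyNA(gp$gene)) stop("genes missing from the gene-position table")
  out <- m
  for (chr in unique(gp$chrom)) {
    cols <- which(gp$chrom == chr)
    out[, cols] <- smooth_chromosome(m[, cols, drop = FALSE], cfg)
  }
  attr(out, "stage") <- "smoothed"
  attr(out, "gene_order") <- colnames(m)
  out
}

#' Re-centre smoothed intensities and rescale to relative expression
#'
#' First each bead (malignant and non-malignant alike) is centred by
#' subtracting its own mean smoothed intensity across genes, creating a
#' per-bead baseline of zero intensity change; this removes additive
#' library-size offsets that sparse counts induce in log space, which would
#' otherwise dominate downstream clustering. Then, per gene, the mean over
#' the reference beads is subtracted, and the log2 transform is reversed
#' (`2^x`). The result is a strictly positive relative expression intensity
#' matrix with copy-neutral values near 1.
#'
#' @param m Smoothed matrix from [smooth_intensities()].
#' @param reference_beads Character vector of reference bead ids.
#' @return Rescaled intensity matrix, `stage = "rescaled"`.
#' @export
recenter_and_rescale <- function(m, reference_beads) {
  reference_beads <- intersect(reference_beads, rownames(m))
  if (length(reference_beads) == 0L) stop("reference set empty")
  m <- m - rowMeans(m)
  m <- sweep(m, 2L, colMeans(m[reference_beads, , drop = FALSE]), "-")
  out <- 2^m
  attr(out, "stage") <- "rescaled"
  attr(out, "gene_order") <- colnames(m)
  out
}
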