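# Filtering and transformation of raw bead counts into capped,
# reference-centred log2 expression, the input to chromosomal smoothing.
# Conventions follow expression-based CNA callers: per-bead counts-per-million
# ("TPM" in the UMI sense, no length normalisation), log2(x+1), per-gene
# centring on the reference beads, capping at +/- 3.

#' Preprocessing configuration
#'
#' @param min_counts_per_gene Genes with total counts `<=` this across all
#'   beads are removed (default 300).
#' @param bead_min_counts Beads with fewer counts than this are "low-quality"
#'   candidates for removal (default 100).
#' @param max_low_bead_fraction Low-count beads are removed (ascending by
#'   count) only until the surviving fraction of such beads is at most this
#'   (default 0.35), or none remain.
#' @param log_cap Symmetric cap on centred log2 expression (default 3).
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(min_counts_per_gene = 300,
                              bead_min_counts = 100,
                              max_low_bead_fraction = 0.35,
                              log_cap = 3) {
  stopifnot(min_counts_per_gene >= 0, bead_min_counts >= 0,
            max_low_bead_fraction >= 0, max_low_bead_fraction <= 1,
            log_cap > 0)
  structure(list(min_counts_per_gene = min_counts_per_gene,
                 bead_min_counts = bead_min_counts,
                 max_low_bead_fraction = max_low_bead_fraction,
                 log_cap = log_cap),
            class = "preprocess_config")
}

#' Filter genes and beads of a raw count matrix
#'
#' Removes genes whose total count across all beads is at most
#' `min_counts_per_gene`, then removes low-count beads conservatively:
#' beads with fewer than `bead_min_counts` counts are removed in ascending
#' count order (ties by bead id) only until the fraction of surviving beads
#' that are still below the threshold is at most `max_low_bead_fraction`.
#' Beads with zero counts are always removed (they carry no information and
#' make the log-TPM transform undefined).
#'
#' Idempotent: running it twice gives the same result as once.
#'
#' @param se A `spatial_expression` object.
#' @param cfg A [preprocess_config()].
#' @return The filtered `spatial_expression`, with a `"filter_report"`
#'   attribute listing removed gene/bead counts.
#' @export
filter_matrix <- function(se, cfg = preprocess_config()) {
  if (n_beads(se) == 0L || n_genes(se) == 0L) stop("empty count matrix")
  gene_tot <- Matrix::colSums(se$counts)
  keep_genes <- gene_tot > cfg$min_counts_per_gene
  if (!any(keep_genes)) stop("no genes left after gene filter")
  counts <- se$counts[, keep_genes, drop = FALSE]

  bead_tot <- Matrix::rowSums(counts)
  ord <- order(bead_tot, rownames(counts))   # ascending count, ties by id
  drop <- rownames(counts)[bead_tot == 0]
  n <- nrow(counts)
  low_ids <- rownames(counts)[bead_tot < cfg$bead_min_counts]
  for (b in rownames(counts)[ord]) {
    n_low <- sum(!(low_ids %in% drop))
    n_left <- n - length(drop)
    if (n_left == 0L || n_low / n_left <= cfg$max_low_bead_fraction) break
    if (!(b %in% low_ids) || b %in% drop) next
    drop <- c(drop, b)
  }
  keep_beads <- setdiff(rownames(counts), drop)
  if (length(keep_beads) == 0L) stop("all beads removed by quality filter")
  out <- spatial_expression(counts[keep_beads, , drop = FALSE],
                            se$coords[keep_beads, , drop = FALSE],
                            se$bead_type[keep_beads],
                            require_reference = FALSE)
  attr(out, "filter_report") <- list(
    genes_removed = sum(!keep_genes),
    beads_removed = length(drop),
    low_fraction = mean(Matrix::rowSums(out$counts) < cfg$bead_min_counts))
  if (length(drop) || sum(!keep_genes))
    message("filter: removed ", sum(!keep_genes), " gene(s), ",
            length(drop), " bead(s)")
  out
}

#' Per-bead log2(TPM + 1) transform
#'
#' Scales each bead's counts to sum to one million (counts-per-million; UMI
#' data carries no gene-length bias, so no length term) and applies
#' `log2(x + 1)` elementwise.
#'
#' @param se A filtered `spatial_expression`.
#' @return A dense bead x gene matrix with `"stage"` attribute
#'   `"log_tpm"`.
#' @export
log_tpm <- function(se) {
  tot <- Matrix::rowSums(se$counts)
  if (any(tot == 0)) stop("bead(s) with zero total counts; filter first")
  m <- as.matrix(se$counts / tot * 1e6)
  m <- log2(m + 1)
  attr(m, "stage") <- "log_tpm"
  m
}

#' Centre on reference beads, cap, and restrict to positioned autosomes
#'
#' Per gene, subtracts the mean log2 expression over the reference beads,
#' clamps the centred values to `[-cap, cap]`, then removes mitochondrial
#' (chrM) and Y-chromosome genes and restricts to (and genomically orders by)
#' the gene-position table.
#'
#' @param m Matrix from [log_tpm()] (beads x genes).
#' @param reference_beads Character vector of reference bead ids.
#' @param gp A `gene_positions` table.
#' @param cap Symmetric cap (default 3).
#' @return An intensity matrix (beads x genes, genomic gene order) with
#'   attributes `stage = "log_centered"` and `gene_order`.
#' @export
center_and_cap <- function(m, reference_beads, gp, cap = 3) {
  reference_beads <- intersect(reference_beads, rownames(m))
  if (length(reference_beads) == 0L) stop("reference set empty")
  ref_mean <- colMeans(m[reference_beads, , drop = FALSE])
  m <- sweep(m, 2L, ref_mean, "-")
  m[m > cap] <- cap
  m[m < -cap] <- -cap
  keep <- gp[!(gp$chrom %in% c("chrM", "chrY")), , drop = FALSE]
  genes <- genomic_order(colnames(m), keep)
  if (length(genes) == 0L) stop("no genes overlap the gene-position table")
  m <- m[, genes, drop = FALSE]
  attr(m, "stage") <- "log_centered"
  attr(m, "gene_order") <- genes
  m
}
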