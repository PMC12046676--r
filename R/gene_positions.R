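# Genomic gene coordinates: ordering for smoothing, arm membership for
# evaluation. The on-disk dialect is the 4-column TSV used by expression-based
# CNA callers: gene symbol, chromosome, start, end.

.karyotype_levels <- c(paste0("chr", 1:22), "chrX", "chrY", "chrM")

#' Centromere positions for a genome build
#'
#' Returns the bundled centromere midpoints used to assign genes to
#' chromosome arms (p: gene start before the centromere; q: after).
#'
#' @param genome `"hg38"` or `"hg19"`.
#' @return A data.frame with columns `chrom` and `centromere` (bp).
#' @export
centromere_positions <- function(genome = c("hg38", "hg19")) {
  genome <- match.arg(genome)
  path <- system.file("extdata", paste0("centromeres_", genome, ".tsv"),
                      package = "spotcna", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read a gene-position table
#'
#' Reads a tab-separated table of gene coordinates (gene, chromosome, start,
#' end; header optional, auto-detected from a non-numeric third column in the
#' first row), sorts it into karyotype order (chr1..chr22, chrX, chrY, chrM;
#' ties by start), and assigns each gene to a chromosome arm using a
#' centromere table.
#'
#' Duplicated gene symbols keep the first occurrence (later rows are dropped
#' with a message). Genes on chromosomes absent from the centromere table get
#' `NA` arms and are flagged via the `"unplaced"` attribute rather than
#' dropped.
#'
#' @param path Path to the TSV.
#' @param genome Genome build selecting the bundled centromere table
#'   (ignored when `centromeres` is supplied).
#' @param centromeres Optional data.frame with columns `chrom`, `centromere`
#'   overriding the bundled table (used for synthetic genomes).
#' @return A `gene_positions` data.frame with columns `gene`, `chrom`,
#'   `start`, `end`, `arm` (e.g. `"1p"`), sorted genomically.
#' @export
read_gene_positions <- function(path, genome = c("hg38", "hg19"),
                                centromeres = NULL) {
  if (!file.exists(path)) stop("gene-position file not found: ", path)
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 4L) stop("gene-position table needs >= 4 columns (gene, chr, start, end)")
  has_header <- suppressWarnings(is.na(as.numeric(raw[1L, 3L])))
  offset <- 0L
  if (isTRUE(has_header)) {
    raw <- raw[-1L, , drop = FALSE]
    offset <- 1L
  }
  start <- suppressWarnings(as.numeric(raw[[3L]]))
  end <- suppressWarnings(as.numeric(raw[[4L]]))
  bad <- which(!is.finite(start) | !is.finite(end))
  if (length(bad)) {
    stop("unparseable coordinates in gene-position file at line ",
         bad[1L] + offset, ": '", raw[bad[1L], 3L], "', '", raw[bad[1L], 4L], "'")
  }
  gp <- data.frame(gene = raw[[1L]], chrom = raw[[2L]],
                   start = as.integer(start), end = as.integer(end),
                   stringsAsFactors = FALSE)
  if (any(gp$start > gp$end)) stop("gene-position table has start > end")
  dup <- duplicated(gp$gene)
  if (any(dup)) {
    message("dropping ", sum(dup), " duplicated gene symbol(s), keeping first occurrence")
    gp <- gp[!dup, , drop = FALSE]
  }
  if (is.null(centromeres)) centromeres <- centromere_positions(genome)
  gene_positions(gp, centromeres)
}

#' Construct a gene_positions table
#'
#' @param gp data.frame with columns `gene`, `chrom`, `start`, `end`.
#' @param centromeres data.frame with columns `chrom`, `centromere`.
#' @return A `gene_positions` data.frame (see [read_gene_positions()]).
#' @export
gene_positions <- function(gp, centromeres) {
  stopifnot(all(c("gene", "chrom", "start", "end") %in% names(gp)))
  if (anyDuplicated(gp$gene)) stop("gene symbols must be unique")
  if (any(gp$start > gp$end)) stop("start must be <= end")
  known <- unique(c(.karyotype_levels, centromeres$chrom))
  lev <- c(intersect(.karyotype_levels, known),
           setdiff(known, .karyotype_levels))
  chrom <- factor(gp$chrom, levels = lev)
  ord <- order(chrom, gp$start, gp$gene, na.last = TRUE)
  gp <- gp[ord, , drop = FALSE]
  cen <- stats::setNames(centromeres$centromere, centromeres$chrom)
  side <- ifelse(gp$start < cen[gp$chrom], "p", "q")
  gp$arm <- ifelse(is.na(side), NA_character_,
                   paste0(sub("^chr", "", gp$chrom), side))
  unplaced <- gp$gene[is.na(gp$arm)]
  if (length(unplaced)) {
    message(length(unplaced), " gene(s) on chromosomes without a centromere entry; arm set to NA")
  }
  rownames(gp) <- NULL
  structure(gp, unplaced = unplaced,
            class = c("gene_positions", "data.frame"))
}

#' Restrict and order a gene set genomically
#'
#' @param genes Character vector of gene symbols.
#' @param gp A `gene_positions` table.
#' @return The subset of `genes` present in `gp`, in genomic order.
#' @export
genomic_order <- function(genes, gp) {
  gp$gene[gp$gene %in% genes]
}
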