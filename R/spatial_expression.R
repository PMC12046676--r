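# The pipeline's input container: bead x gene raw UMI counts plus planar
# coordinates (um) and a per-bead malignancy annotation. Counts are kept
# sparse (dgCMatrix, beads in rows) since Slide-seq matrices are ~95% zeros.

.bead_types <- c("reference", "non_reference_normal", "malignant")

#' Construct a SpatialExpression object
#'
#' @param counts bead x gene matrix of non-negative integer UMI counts
#'   (dense or `Matrix` sparse), with bead ids as rownames and gene symbols
#'   as colnames.
#' @param coords data.frame with columns `bead`, `x`, `y` (um).
#' @param bead_type named character vector (or data.frame with columns
#'   `bead`, `type`) giving each bead's population:
#'   `"reference"`, `"non_reference_normal"`/`"normal"`, or `"malignant"`.
#' @param require_reference Require at least one reference and one malignant
#'   bead (the pipeline's minimum); disable for intermediate objects.
#' @return A `spatial_expression` list with elements `counts` (sparse
#'   bead x gene), `coords` (data.frame, rownames = bead ids), `bead_type`
#'   (named factor), `umi_per_bead` (named numeric).
#' @export
spatial_expression <- function(counts, coords, bead_type,
                               require_reference = TRUE) {
  counts <- as_count_matrix(counts)
  if (!methods::is(counts, "sparseMatrix"))
    counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- methods::as(methods::as(counts, "generalMatrix"), "CsparseMatrix")
  beads <- rownames(counts)
  if (is.null(beads) || is.null(colnames(counts)))
    stop("counts must carry bead rownames and gene colnames")
  if (anyDuplicated(beads)) stop("duplicate bead ids in counts")
  if (anyDuplicated(colnames(counts))) stop("duplicate gene names in counts")

  if (is.data.frame(bead_type)) {
    bead_type <- stats::setNames(as.character(bead_type$type), bead_type$bead)
  }
  bead_type <- as.character(bead_type[beads])
  bead_type[bead_type == "normal"] <- "non_reference_normal"
  if (anyNA(bead_type)) stop("bead_type missing for some beads")
  if (!all(bead_type %in% .bead_types))
    stop("bead_type values must be in {", paste(.bead_types, collapse = ", "), "}")
  bead_type <- factor(bead_type, levels = .bead_types)
  names(bead_type) <- beads

  stopifnot(all(c("bead", "x", "y") %in% names(coords)))
  coords <- coords[match(beads, coords$bead), c("bead", "x", "y")]
  if (anyNA(coords$bead)) stop("coordinates missing for some beads")
  if (!all(is.finite(coords$x)) || !all(is.finite(coords$y)))
    stop("non-finite bead coordinates")
  rownames(coords) <- coords$bead

  if (require_reference) {
    if (!any(bead_type == "reference"))
      stop("reference population required: no bead annotated as reference")
    if (!any(bead_type == "malignant"))
      stop("at least one malignant bead required")
  }
  structure(list(counts = counts, coords = coords, bead_type = bead_type,
                 umi_per_bead = stats::setNames(Matrix::rowSums(counts), beads)),
            class = "spatial_expression")
}

as_count_matrix <- function(counts) {
  vals <- if (methods::is(counts, "sparseMatrix")) counts@x else as.numeric(counts)
  if (any(vals < 0)) stop("counts must be non-negative")
  if (any(vals != round(vals))) stop("counts must be integer-valued")
  counts
}

#' @export
print.spatial_expression <- function(x, ...) {
  cat("spatial_expression: ", nrow(x$counts), " beads x ", ncol(x$counts),
      " genes\n", sep = "")
  print(table(x$bead_type))
  invisible(x)
}

#' Number of beads / genes
#' @param se A `spatial_expression` object.
#' @return Integer count.
#' @export
n_beads <- function(se) nrow(se$counts)

#' @rdname n_beads
#' @export
n_genes <- function(se) ncol(se$counts)

#' Read a raw count matrix
#'
#' Reads a bead x gene UMI count matrix from either a MatrixMarket triplet
#' file with sibling `barcodes.tsv` / `features.tsv` label files (10x-style,
#' genes in rows; transposed on read) or a dense TSV with bead/gene labels.
#' Orientation of a dense TSV is resolved later against the coordinate file
#' by [attach_metadata()]; pass `orientation` to force it.
#'
#' @param path Path to the `.mtx` file (or a directory containing
#'   `matrix.mtx`) or to the dense TSV.
#' @param dialect `"auto"` (by extension), `"mtx_triplet"`, or `"dense_tsv"`.
#' @param orientation For dense TSVs: `"beads_by_genes"`, `"genes_by_beads"`,
#'   or `"auto"` (resolved by [attach_metadata()]).
#' @return A sparse dgCMatrix with dimnames; orientation recorded in the
#'   `"orientation"` attribute.
#' @export
read_counts <- function(path, dialect = c("auto", "mtx_triplet", "dense_tsv"),
                        orientation = c("auto", "beads_by_genes", "genes_by_beads")) {
  dialect <- match.arg(dialect)
  orientation <- match.arg(orientation)
  if (dir.exists(path)) {
    path <- file.path(path, "matrix.mtx")
    dialect <- "mtx_triplet"
  }
  if (!file.exists(path)) stop("counts file not found: ", path)
  if (dialect == "auto")
    dialect <- if (grepl("\\.mtx$", path)) "mtx_triplet" else "dense_tsv"

  if (dialect == "mtx_triplet") {
    m <- Matrix::readMM(path)
    dirn <- dirname(path)
    genes <- utils::read.delim(file.path(dirn, "features.tsv"), header = FALSE)[[1L]]
    beads <- utils::read.delim(file.path(dirn, "barcodes.tsv"), header = FALSE)[[1L]]
    if (length(genes) != nrow(m) || length(beads) != ncol(m))
      stop("label files do not match matrix dimensions")
    if (anyDuplicated(beads)) stop("duplicate bead ids in barcodes.tsv")
    if (anyDuplicated(genes)) stop("duplicate gene names in features.tsv")
    dimnames(m) <- list(genes, beads)
    m <- Matrix::t(m)                      # beads x genes
    orientation <- "beads_by_genes"
  } else {
    df <- utils::read.delim(path, header = TRUE, row.names = 1L,
                            check.names = FALSE)
    m <- as.matrix(df)
    if (!is.numeric(m)) stop("non-numeric entries in dense counts TSV")
    if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m)))
      stop("duplicate row or column ids in dense counts TSV")
  }
  m <- as_count_matrix(m)
  m <- methods::as(methods::as(methods::as(m, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  attr(m, "orientation") <- orientation
  m
}

#' Attach coordinates and annotations to a count matrix
#'
#' Joins a count matrix with a coordinate CSV (header `bead,x,y`; columns
#' matched by name, not position) and an annotation CSV (header `bead,type`,
#' type in reference/normal/malignant). Beads missing coordinates or
#' annotation are dropped with a message; zero surviving reference beads is
#' an error. For dense TSVs read with `orientation = "auto"`, the matrix is
#' transposed if its column (not row) labels match the coordinate bead ids.
#'
#' @param counts Matrix from [read_counts()] (or any labelled count matrix).
#' @param coords_path CSV path (`bead,x,y`).
#' @param annotation_path CSV path (`bead,type`).
#' @return A `spatial_expression` object.
#' @export
attach_metadata <- function(counts, coords_path, annotation_path) {
  if (!file.exists(coords_path)) stop("coordinates file not found: ", coords_path)
  if (!file.exists(annotation_path)) stop("annotation file not found: ", annotation_path)
  coords <- utils::read.csv(coords_path, stringsAsFactors = FALSE)
  stopifnot(all(c("bead", "x", "y") %in% names(coords)))
  annot <- utils::read.csv(annotation_path, stringsAsFactors = FALSE)
  stopifnot(all(c("bead", "type") %in% names(annot)))

  orientation <- attr(counts, "orientation")
  if (identical(orientation, "auto")) {
    row_hit <- mean(rownames(counts) %in% coords$bead)
    col_hit <- mean(colnames(counts) %in% coords$bead)
    if (col_hit > row_hit) counts <- Matrix::t(counts)
  } else if (identical(orientation, "genes_by_beads")) {
    counts <- Matrix::t(counts)
  }

  keep <- rownames(counts) %in% coords$bead & rownames(counts) %in% annot$bead
  if (!all(keep)) {
    message("dropped ", sum(!keep), " bead(s) missing coordinates or annotation")
    counts <- counts[keep, , drop = FALSE]
  }
  if (nrow(counts) == 0L) stop("no beads left after metadata join")
  spatial_expression(counts, coords,
                     stats::setNames(annot$type, annot$bead))
}

#' Write a SpatialExpression bundle to disk
#'
#' Writes `matrix.mtx` + `barcodes.tsv` + `features.tsv` (genes in rows,
#' 10x-style), `coords.csv` and `annotations.csv` into `dir`.
#'
#' @param se A `spatial_expression` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_spatial_expression <- function(se, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::t(se$counts), file.path(dir, "matrix.mtx"))
  utils::write.table(colnames(se$counts), file.path(dir, "features.tsv"),
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(rownames(se$counts), file.path(dir, "barcodes.tsv"),
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.csv(se$coords, file.path(dir, "coords.csv"), row.names = FALSE)
  ann <- data.frame(bead = names(se$bead_type),
                    type = as.character(se$bead_type))
  utils::write.csv(ann, file.path(dir, "annotations.csv"), row.names = FALSE)
  invisible(dir)
}

#' Subset beads of a SpatialExpression object
#'
#' @param se A `spatial_expression` object.
#' @param beads Character vector of bead ids (or logical/integer index).
#' @param genes Optional gene subset.
#' @return The subsetted `spatial_expression` (validation relaxed).
#' @export
subset_beads <- function(se, beads, genes = NULL) {
  counts <- se$counts[beads, , drop = FALSE]
  if (!is.null(genes)) counts <- counts[, genes, drop = FALSE]
  spatial_expression(counts, se$coords[rownames(counts), , drop = FALSE],
                     se$bead_type[rownames(counts)],
                     require_reference = FALSE)
}
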