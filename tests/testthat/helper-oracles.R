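# Independent reference implementations used as oracles, deliberately
# written from the definitions rather than sharing code with the package.

# Naive O(n * k) pyramidal moving average: explicit double loop over the
# truncated window with raw weights m + 1 - |i - j|.
naive_pyramid_smooth <- function(values, m) {
  n <- ncol(values)
  out <- values
  for (i in seq_len(n)) {
    idx <- max(1, i - m):min(n, i + m)
    w <- m + 1 - abs(i - idx)
    w <- w / sum(w)
    for (b in seq_len(nrow(values))) {
      acc <- 0
      for (t in seq_along(idx)) acc <- acc + w[t] * values[b, idx[t]]
      out[b, i] <- acc
    }
  }
  out
}

# Mean silhouette width from its definition: a(i) mean intra-cluster
# distance, b(i) smallest mean distance to another cluster,
# s(i) = (b - a) / max(a, b); singletons get s = 0.
naive_silhouette <- function(d, labels) {
  d <- as.matrix(d)
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) { s[i] <- 0; next }
    a <- mean(d[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(k) mean(d[i, labels == k]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Spearman's rho via explicit average ranks and Pearson on the ranks.
naive_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Small spatial_expression fixture: counts laid out deterministically with
# optional overrides; beads on a grid.
tiny_se <- function(counts = NULL, n_beads = 6, n_genes = 8,
                    types = NULL, seed = 7) {
  set.seed(seed)
  if (is.null(counts))
    counts <- matrix(rpois(n_beads * n_genes, lambda = 40),
                     nrow = n_beads,
                     dimnames = list(paste0("b", seq_len(n_beads)),
                                     paste0("g", seq_len(n_genes))))
  if (is.null(types))
    types <- rep(c("reference", "malignant"), length.out = nrow(counts))
  coords <- data.frame(bead = rownames(counts),
                       x = as.numeric(seq_len(nrow(counts))) * 10,
                       y = rep(c(0, 50), length.out = nrow(counts)))
  spatial_expression(counts, coords,
                     stats::setNames(types, rownames(counts)),
                     require_reference = FALSE)
}

# Gene positions for the tiny fixtures: two chromosomes, centromere between
# genes, matching tiny_se gene names.
tiny_gp <- function(n_genes = 8) {
  per <- ceiling(n_genes / 2)
  chrom <- rep(c("chr1", "chr2"), each = per)[seq_len(n_genes)]
  idx <- unlist(lapply(rle(chrom)$lengths, seq_len))
  gene_positions(
    data.frame(gene = paste0("g", seq_len(n_genes)), chrom = chrom,
               start = idx * 1000L, end = idx * 1000L + 10L),
    data.frame(chrom = c("chr1", "chr2"),
               centromere = (per / 2 + 0.25) * 1000))
}

# Gaussian blob bins for clustering tests.
make_blobs <- function(k, n_per = 12, n_genes = 30, sep = 4, sd = 0.25,
                       seed = 11) {
  set.seed(seed)
  centers <- matrix(rnorm(k * n_genes), nrow = k) * 0
  for (i in seq_len(k)) centers[i, ((i - 1) * 3 + 1):((i - 1) * 3 + 3)] <- sep
  X <- do.call(rbind, lapply(seq_len(k), function(i)
    matrix(rnorm(n_per * n_genes, mean = rep(centers[i, ], each = n_per),
                 sd = sd), nrow = n_per)))
  rownames(X) <- paste0("bin_", seq_len(k * n_per))
  list(X = X, labels = rep(seq_len(k), each = n_per))
}
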