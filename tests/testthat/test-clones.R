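# Silhouette-based clone number selection, clone assignment, and NB DGE.

test_that("silhouette selection matches the from-definition oracle on blob data", {
  for (k_true in c(2, 3, 4)) {
    blobs <- make_blobs(k_true, n_per = 10, seed = 100 + k_true)
    sel <- select_k_malignant(blobs$X)
    expect_equal(sel$k_malignant, k_true)
    # trace agrees with the naive silhouette at the chosen k
    d <- dist(blobs$X)
    hc <- hclust(d, method = "ward.D2")
    cl <- cutree(hc, k = k_true)
    expect_equal(unname(sel$silhouette_trace[as.character(k_true)]),
                 naive_silhouette(d, cl), tolerance = 1e-8)
    expect_true(all(sel$silhouette_trace >= -1 & sel$silhouette_trace <= 1,
                    na.rm = TRUE))
  }
})

test_that("k search range clamps to n_bins - 1 and small inputs error", {
  blobs <- make_blobs(2, n_per = 2, seed = 5)   # 4 bins
  sel <- select_k_malignant(blobs$X)
  expect_setequal(names(sel$silhouette_trace), c("2", "3"))
  expect_error(select_k_malignant(blobs$X[1:2, ]), "too few bins")
})

test_that("clone assignment separates populations and designates the normal cluster", {
  blobs <- make_blobs(2, n_per = 10, n_genes = 20, seed = 31)
  X <- blobs$X + 1                             # CNA-score-like scale
  nm <- matrix(1, 8, 20, dimnames = list(paste0("nbin_", 1:8), colnames(X)))
  cna <- rbind(X, nm)
  bins <- data.frame(bin = rownames(cna), x = 0, y = 0, umi = 100,
                     type = c(rep("malignant", 20), rep("reference", 8)),
                     n_beads = 1,
                     malignant = c(rep(TRUE, 20), rep(FALSE, 8)))
  rownames(bins) <- bins$bin
  bs <- structure(list(bins = bins, membership = setNames(rownames(cna), rownames(cna)),
                       intensity = cna, cna = cna), class = "bin_set")
  ca <- assign_clones(bs, k_malignant = 2)
  expect_equal(ca$k_all, 3L)
  expect_equal(unname(ca$clusters[paste0("nbin_", 1:8)]), rep(3L, 8))
  expect_equal(ca$normal_cluster, 3L)
  mal_cl <- ca$clusters[rownames(X)]
  expect_equal(length(unique(mal_cl[1:10])), 1L)
  expect_equal(length(unique(mal_cl[11:20])), 1L)
  expect_false(mal_cl[1] == mal_cl[11])
  # joint re-clustering also finds a normal-dominated cluster
  ca2 <- assign_clones(bs, k_malignant = 2, method = "joint")
  expect_equal(ca2$k_all, 3L)
  norm_frac <- mean(ca2$clusters[paste0("nbin_", 1:8)] == ca2$normal_cluster)
  expect_gte(norm_frac, 0.9)
})

test_that("degenerate identical bins still return k_all labels with a warning message", {
  cna <- matrix(1, 6, 5, dimnames = list(paste0("bin_", 1:6), paste0("g", 1:5)))
  bins <- data.frame(bin = rownames(cna), x = 0, y = 0, umi = 10,
                     type = "malignant", n_beads = 1, malignant = TRUE)
  rownames(bins) <- bins$bin
  bs <- structure(list(bins = bins, membership = setNames(rownames(cna), rownames(cna)),
                       intensity = cna, cna = cna), class = "bin_set")
  expect_message(ca <- assign_clones(bs, k_malignant = 2), "degenerate")
  expect_equal(length(ca$clusters), 6L)
})

simulate_dge_counts <- function(n_per_group, n_genes, fc_genes = integer(0),
                                fc = 4, mu = 5, dispersion = 0.5, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  grp <- rep(c(1L, 2L), each = n_per_group)
  depth <- exp(rnorm(n, sd = 0.3))             # bead-to-bead depth variation
  counts <- matrix(0L, n, n_genes,
                   dimnames = list(paste0("b", seq_len(n)),
                                   paste0("g", seq_len(n_genes))))
  for (g in seq_len(n_genes)) {
    m <- rep(mu, n) * depth
    if (g %in% fc_genes) m[grp == 1L] <- m[grp == 1L] * fc
    counts[, g] <- rnbinom(n, mu = m, size = 1 / dispersion)
  }
  coords <- data.frame(bead = rownames(counts), x = seq_len(n), y = 0)
  se <- spatial_expression(counts, coords,
                           setNames(rep(c("malignant", "reference"),
                                        each = n_per_group), rownames(counts)),
                           require_reference = FALSE)
  list(se = se, clusters = setNames(grp, rownames(counts)))
}

test_that("NB GLM detects strong fold changes with Bonferroni control and sane output shape", {
  sim <- simulate_dge_counts(n_per_group = 120, n_genes = 40, fc_genes = 1:5,
                             fc = 4, seed = 7)
  res <- differential_expression(sim$se, sim$clusters, clusters = 1L)
  expect_true(all(c("gene", "cluster", "log2_fold_change", "p_value",
                    "p_adjusted", "pct_expressing") %in% names(res)))
  expect_true(all(diff(res$log2_fold_change) <= 1e-12))
  expect_equal(res$p_adjusted, pmin(1, res$p_value * nrow(res)))
  hits <- res$gene[res$p_adjusted < 0.05 & res$log2_fold_change > 0]
  expect_true(all(paste0("g", 1:5) %in% hits))
  up <- res[res$gene %in% paste0("g", 1:5), "log2_fold_change"]
  expect_true(all(up > 1))                     # ~log2(4) = 2
  expect_true(all(res$pct_expressing >= 0 & res$pct_expressing <= 1))
})

test_that("permuting cluster labels destroys significance on signal genes", {
  sim <- simulate_dge_counts(n_per_group = 100, n_genes = 20, fc_genes = 1:10,
                             fc = 4, seed = 11)
  set.seed(12)
  perm <- setNames(sample(sim$clusters), names(sim$clusters))
  res <- differential_expression(sim$se, perm, clusters = 1L,
                                 genes = paste0("g", 1:10))
  expect_gte(median(res$p_adjusted), 0.99)
})

test_that("all-zero one-sided genes get a finite pseudocounted fold change", {
  sim <- simulate_dge_counts(n_per_group = 30, n_genes = 4, seed = 3)
  counts <- as.matrix(sim$se$counts)
  counts[, "g1"] <- c(rep(0L, 30), rpois(30, 20))
  se <- spatial_expression(counts, sim$se$coords, sim$se$bead_type,
                           require_reference = FALSE)
  res <- differential_expression(se, sim$clusters, clusters = 1L, genes = "g1")
  expect_true(is.finite(res$log2_fold_change))
  expect_lt(res$log2_fold_change, 0)
  expect_error(differential_expression(se, setNames(rep(1L, 60), names(sim$clusters))),
               ">= 2 clusters")
})
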