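# Clone determination: malignant bins are Ward-clustered on their CNA score
# rows; the number of clones k_malignant (2..10) maximises the mean
# silhouette width; all bins are then re-clustered into k_malignant + 1
# clusters, one of which is designated the non-malignant cluster.

#' Select the number of malignant clones by silhouette
#'
#' Builds a Ward (ward.D2) tree on the Euclidean distances between
#' malignant-bin CNA score rows, cuts it at each `k` in
#' `2 .. min(10, n_bins - 1)` (each cut refined by a nearest-centroid
#' pass), and returns the `k` maximising the mean silhouette width (ties
#' broken toward the smallest `k`).
#'
#' @param cna Malignant-bin CNA score matrix (bins x genes).
#' @param k_max Largest number of clones considered (default 10).
#' @return List with `k_malignant` and `silhouette_trace` (named numeric,
#'   one mean silhouette width per tested `k`).
#' @export
select_k_malignant <- function(cna, k_max = 10) {
  n <- nrow(cna)
  if (n < 3L) stop("too few bins for clone calling (need >= 3 malignant bins)")
  d <- stats::dist(cna)
  ks <- 2:min(k_max, n - 1L)
  trace <- vapply(ks, function(k) {
    cl <- .ward_kmeans(cna, k)
    if (length(unique(cl)) < 2L) return(NA_real_)
    mean(cluster::silhouette(cl, d)[, "sil_width"])
  }, numeric(1L))
  names(trace) <- ks
  k_best <- ks[which.max(trace)]             # which.max takes the first tie
  list(k_malignant = k_best, silhouette_trace = trace)
}

# Ward cut refined by one nearest-centroid (k-means) pass: the Ward
# boundary between two clusters is biased toward the weaker-signature
# clone when signature magnitudes differ, whereas the nearest-centroid
# boundary sits at the 50:50 mixture point for (near-)orthogonal
# signatures.
.ward_kmeans <- function(X, k) {
  if (k >= nrow(X)) return(stats::setNames(seq_len(nrow(X)), rownames(X)))
  hc <- stats::hclust(stats::dist(X), method = "ward.D2")
  cl <- stats::cutree(hc, k = k)
  cent <- do.call(rbind, lapply(split(seq_len(nrow(X)), cl),
                                function(i) colMeans(X[i, , drop = FALSE])))
  if (anyDuplicated(cent) || stats::sd(X) == 0) return(stats::setNames(cl, rownames(X)))
  km <- tryCatch(stats::kmeans(X, centers = cent, iter.max = 25),
                 error = function(e) NULL)
  out <- if (is.null(km)) cl else km$cluster
  stats::setNames(out, rownames(X))
}

#' Assign bins to clone clusters
#'
#' With `method = "malignant_tree"` (default), the malignant bins are
#' clustered into `k_malignant` clones by cutting their own Ward (ward.D2)
#' tree on Euclidean CNA-score distances — the same tree silhouette model
#' selection was run on — refined by a nearest-centroid pass, and the whole
#' non-malignant population forms the `k_all`-th cluster, so that
#' `k_all = k_malignant + 1` with one cluster assigned to the non-malignant
#' population by construction. With `method = "joint"`, all bins are
#' re-clustered jointly into `k_all` clusters and the cluster holding the
#' greatest fraction of non-malignant bins is designated the normal
#' cluster.
#'
#' @param binset A `bin_set` with CNA scores ([cna_scores()]).
#' @param k_malignant Number of malignant clones (see
#'   [select_k_malignant()]).
#' @param method `"malignant_tree"` or `"joint"`.
#' @return A `clone_assignment` list: `clusters` (named integer, bin ->
#'   cluster), `k_malignant`, `k_all`, `normal_cluster` (the designated
#'   cluster id), `silhouette_trace` (if attached by the caller).
#' @export
assign_clones <- function(binset, k_malignant,
                          method = c("malignant_tree", "joint")) {
  method <- match.arg(method)
  cna <- binset$cna
  if (is.null(cna)) stop("bin_set lacks CNA scores; run cna_scores() first")
  k_all <- as.integer(k_malignant) + 1L
  if (stats::sd(cna) == 0) message("all bins identical; tree cut is degenerate")
  nm_bins <- binset$bins$bin[!binset$bins$malignant]
  if (method == "malignant_tree") {
    mal_bins <- binset$bins$bin[binset$bins$malignant]
    cl <- stats::setNames(rep(k_all, nrow(cna)), rownames(cna))
    cl[mal_bins] <- .ward_kmeans(cna[mal_bins, , drop = FALSE],
                                 min(k_malignant, length(mal_bins)))
    normal_cluster <- if (length(nm_bins)) k_all else NA_integer_
  } else {
    cl <- stats::cutree(stats::hclust(stats::dist(cna), method = "ward.D2"),
                        k = min(k_all, nrow(cna)))
    names(cl) <- rownames(cna)
    normal_cluster <- if (length(nm_bins)) {
      frac <- vapply(split(names(cl), cl),
                     function(b) mean(b %in% nm_bins), numeric(1L))
      as.integer(names(frac)[which.max(frac)])
    } else NA_integer_
  }
  structure(list(clusters = cl, k_malignant = as.integer(k_malignant),
                 k_all = k_all, normal_cluster = normal_cluster),
            class = "clone_assignment")
}

#' Run the full clone-calling step
#'
#' @param binset A `bin_set` with CNA scores.
#' @param k_max Largest number of clones considered.
#' @param method Clone assignment method, see [assign_clones()].
#' @return A `clone_assignment` with the silhouette trace attached.
#' @export
call_clones <- function(binset, k_max = 10,
                        method = c("malignant_tree", "joint")) {
  sel <- select_k_malignant(binset$cna[binset$bins$malignant, , drop = FALSE],
                            k_max = k_max)
  ca <- assign_clones(binset, sel$k_malignant, method = method)
  ca$silhouette_trace <- sel$silhouette_trace
  ca
}

# Method-of-moments NB dispersion for one gene given fitted means;
# theta = sum(mu^2) / sum((y - mu)^2 - mu); non-positive -> Poisson.
.mom_theta <- function(y, mu) {
  denom <- sum((y - mu)^2 - mu)
  if (denom <= 0) return(Inf)
  sum(mu^2) / denom
}

#' Differential expression between clone clusters
#'
#' One-vs-rest negative binomial GLM per gene and cluster on raw bead
#' counts (beads inherit their bin's cluster), with a log total-UMI offset
#' and a cluster-indicator covariate. The per-gene dispersion is estimated
#' by method of moments from a Poisson fit, falling back to Poisson when
#' the estimate is non-positive. Wald p-values are Bonferroni-corrected
#' over all gene x cluster tests.
#'
#' @param se The filtered `spatial_expression` (raw counts).
#' @param bead_clusters Named integer vector bead -> cluster.
#' @param min_beads Minimum beads per side (default 3).
#' @param clusters Optional subset of clusters to test (default: all).
#' @param genes Optional subset of genes to test (default: all genes with
#'   nonzero counts).
#' @return data.frame with columns `gene`, `cluster`, `log2_fold_change`,
#'   `p_value`, `p_adjusted`, `pct_expressing`, ordered by decreasing
#'   `log2_fold_change`.
#' @export
differential_expression <- function(se, bead_clusters, min_beads = 3,
                                    clusters = NULL, genes = NULL) {
  beads <- intersect(names(bead_clusters), rownames(se$counts))
  cl <- bead_clusters[beads]
  if (length(unique(cl)) < 2L) stop("need >= 2 clusters for differential expression")
  counts <- se$counts[beads, , drop = FALSE]
  total <- Matrix::rowSums(counts)
  if (is.null(clusters)) clusters <- sort(unique(cl))
  if (is.null(genes)) genes <- colnames(counts)[Matrix::colSums(counts) > 0]

  res <- list()
  log_off <- log(total)
  for (k in clusters) {
    in_k <- cl == k
    if (sum(in_k) < min_beads || sum(!in_k) < min_beads) {
      message("cluster ", k, " skipped (fewer than ", min_beads, " beads on one side)")
      next
    }
    grp <- as.numeric(in_k)
    for (g in genes) {
      y <- counts[, g]
      if (sum(y[in_k]) == 0 && sum(y[!in_k]) == 0) next
      fit_p <- suppressWarnings(
        stats::glm(y ~ grp + offset(log_off), family = stats::poisson()))
      theta <- .mom_theta(y, stats::fitted(fit_p))
      fit <- if (is.finite(theta)) {
        suppressWarnings(stats::glm(y ~ grp + offset(log_off),
                                    family = MASS::negative.binomial(theta)))
      } else fit_p
      sm <- summary(fit)$coefficients
      if (!"grp" %in% rownames(sm)) next
      beta <- sm["grp", 1L]
      pval <- sm["grp", 4L]
      # degenerate all-zero side: report a finite pseudocounted fold change
      if (!is.finite(beta) || abs(beta) > 20) {
        mu1 <- (sum(y[in_k]) + 1) / sum(total[in_k])
        mu0 <- (sum(y[!in_k]) + 1) / sum(total[!in_k])
        beta <- log(mu1 / mu0)
      }
      res[[length(res) + 1L]] <- data.frame(
        gene = g, cluster = k,
        log2_fold_change = beta / log(2),
        p_value = pval,
        pct_expressing = mean(y[in_k] > 0),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) stop("no testable genes")
  out <- do.call(rbind, res)
  out$p_adjusted <- pmin(1, out$p_value * nrow(out))
  out[order(-out$log2_fold_change), ]
}
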