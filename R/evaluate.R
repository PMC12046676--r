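# Chromosome-arm aggregation of CNA profiles and rank-based concordance
# between profiles (across methods, modalities, clones, or against
# simulated ground truth). 1 = copy neutral everywhere.

#' Aggregate gene-level CNA scores to chromosome arms
#'
#' Per group (e.g. clone cluster), the unweighted mean of gene-level CNA
#' scores over the genes on each arm. Arms without genes are omitted, not
#' reported as `NA`; arms on chrY/chrM or without an arm assignment are
#' excluded.
#'
#' @param cna Bin x gene (or group x gene) CNA score matrix.
#' @param gp A `gene_positions` table covering the genes.
#' @param groups Optional vector assigning each row of `cna` to a group;
#'   default: one group per row.
#' @return A matrix of arm means (groups x arms, karyotype arm order), of
#'   class `arm_profile`.
#' @export
arm_aggregate <- function(cna, gp, groups = NULL) {
  gp <- gp[match(colnames(cna), gp$gene), , drop = FALSE]
  ok <- !is.na(gp$arm) & !(gp$chrom %in% c("chrY", "chrM"))
  if (!any(ok)) stop("no gene maps to a chromosome arm")
  cna <- cna[, ok, drop = FALSE]
  gp <- gp[ok, , drop = FALSE]
  if (is.null(groups)) groups <- rownames(cna)
  if (is.null(groups)) groups <- seq_len(nrow(cna))
  arms <- unique(gp$arm)                    # gp is genomically ordered
  grp_levels <- unique(as.character(groups))
  out <- matrix(NA_real_, nrow = length(grp_levels), ncol = length(arms),
                dimnames = list(grp_levels, arms))
  for (g in grp_levels) {
    rows <- which(as.character(groups) == g)
    v <- colMeans(cna[rows, , drop = FALSE])
    out[g, ] <- vapply(arms, function(a) mean(v[gp$arm == a]), numeric(1L))
  }
  structure(out, class = c("arm_profile", "matrix"))
}

#' Pairwise Spearman concordance of arm profiles
#'
#' For each pair of profiles, restricts to the arms showing CNA signal in
#' both (`|score - 1| >= signal_threshold`) and computes Spearman's rank
#' correlation (average ranks for ties) on that intersection. Pairs sharing
#' fewer than `min_arms` signal arms get `NA` with a message rather than a
#' fabricated value.
#'
#' @param profiles Matrix of arm profiles (sources x arms), e.g. from
#'   [arm_aggregate()], or a list of named numeric vectors.
#' @param signal_threshold Minimum `|score - 1|` for an arm to count as
#'   carrying signal (default 0.02).
#' @param min_arms Minimum shared signal arms (default 3).
#' @return Symmetric correlation matrix with unit diagonal; the threshold
#'   used is recorded in the `"signal_threshold"` attribute.
#' @export
concordance <- function(profiles, signal_threshold = 0.02, min_arms = 3) {
  if (is.list(profiles) && !is.matrix(profiles)) {
    arms <- Reduce(union, lapply(profiles, names))
    profiles <- do.call(rbind, lapply(profiles, function(p) p[arms]))
    colnames(profiles) <- arms
  }
  ns <- nrow(profiles)
  if (ns < 2L) stop("need at least two profiles")
  src <- rownames(profiles)
  if (is.null(src)) src <- paste0("profile_", seq_len(ns))
  rho <- diag(1, ns)
  dimnames(rho) <- list(src, src)
  for (a in seq_len(ns - 1L)) for (b in (a + 1L):ns) {
    pa <- profiles[a, ]; pb <- profiles[b, ]
    shared <- which(is.finite(pa) & is.finite(pb) &
                      abs(pa - 1) >= signal_threshold &
                      abs(pb - 1) >= signal_threshold)
    if (length(shared) < min_arms) {
      message("profiles '", src[a], "' and '", src[b], "' share only ",
              length(shared), " signal arm(s); correlation undefined")
      rho[a, b] <- rho[b, a] <- NA_real_
    } else {
      rho[a, b] <- rho[b, a] <-
        stats::cor(pa[shared], pb[shared], method = "spearman")
    }
  }
  attr(rho, "signal_threshold") <- signal_threshold
  rho
}

#' Arm profile from a segment-level copy-ratio profile
#'
#' Converts segment calls (e.g. from exome copy-number analysis) into an
#' arm profile comparable with expression-derived CNA scores: arm values
#' are segment-length-weighted means, then the whole profile is divided by
#' its genome-wide length-weighted mean so that copy neutral sits at 1.
#'
#' @param segments data.frame with columns `arm`, `value` (copy ratio),
#'   `length` (bp or any consistent unit).
#' @return Named numeric vector of centred arm means.
#' @export
center_segment_profile <- function(segments) {
  stopifnot(all(c("arm", "value", "length") %in% names(segments)))
  if (sum(segments$length) <= 0) stop("zero total segment length")
  wm <- vapply(split(segments, segments$arm), function(s)
    stats::weighted.mean(s$value, s$length), numeric(1L))
  genome_mean <- stats::weighted.mean(segments$value, segments$length)
  wm[unique(segments$arm)] / genome_mean
}

#' Score a pipeline run against simulated ground truth
#'
#' Computes the recovery metrics used to validate the pipeline on
#' simulator output: bin-level clone-assignment accuracy after optimal
#' label matching (each bin's true label is the clone contributing the
#' largest summed kernel-weight fraction over its member beads), the
#' fraction of implanted (altered) arms whose inferred mean CNA score
#' deviates from 1 in the direction of the true fold change, and the
#' Spearman correlation between each matched clone's inferred arm profile
#' and the true fold-change arm profile (via [concordance()], so restricted
#' to arms with signal in both).
#'
#' @param run A `cna_run` from [run_pipeline()].
#' @param sim A simulation bundle from [simulate_slideseq()] (synthetic
#'   profiles, so `arm_fc` is available).
#' @return List: `k_malignant`, `accuracy`, `mapping`, `sign_match`
#'   (fraction over altered arms), `spearman` (named per clone),
#'   `spearman_min`.
#' @export
score_recovery <- function(run, sim) {
  fr <- sim$truth
  rownames(fr) <- fr$bead
  memb <- run$binset$membership
  memb <- memb[names(memb) %in% rownames(fr)]
  clone_cols <- c(normal = "frac_normal", clone1 = "frac_clone1",
                  clone2 = "frac_clone2")
  bin_truth <- vapply(split(names(memb), memb), function(b) {
    names(clone_cols)[which.max(colSums(fr[b, clone_cols, drop = FALSE]))]
  }, character(1L))
  cl <- run$clones$clusters[names(bin_truth)]
  mm <- match_clusters(cl, bin_truth)

  arm_fc <- sim$arm_fc
  profs <- run$arm_profiles
  # inferred cluster matched to each clone (invert the mapping)
  inv <- stats::setNames(names(mm$mapping), mm$mapping)
  sign_ok <- integer(0)
  rho <- c()
  for (clone in setdiff(rownames(arm_fc), "normal")) {
    if (!clone %in% names(inv)) next
    src <- paste0("cluster_", inv[[clone]])
    if (!src %in% rownames(profs)) next
    truth_prof <- arm_fc[clone, ]
    altered <- names(truth_prof)[truth_prof != 1]
    shared <- intersect(altered, colnames(profs))
    sign_ok <- c(sign_ok, sign(profs[src, shared] - 1) ==
                   sign(truth_prof[shared] - 1))
    r <- suppressMessages(
      concordance(rbind(inferred = profs[src, ],
                        truth = truth_prof[colnames(profs)])))["inferred", "truth"]
    rho[clone] <- r
  }
  list(k_malignant = run$clones$k_malignant,
       accuracy = mm$accuracy, mapping = mm$mapping,
       sign_match = mean(sign_ok),
       spearman = rho,
       spearman_min = suppressWarnings(min(rho, na.rm = TRUE)))
}

#' Simulate, run the pipeline, and score recovery
#'
#' Convenience wrapper used by the validation suite: simulates a base
#' dataset at full depth, binomially thins it to `fraction`, runs the
#' pipeline, and scores it against ground truth. A pipeline failure (e.g.
#' the malignant population not surviving quality filtering at extreme
#' downsampling) is reported as `status = "failed"` with `accuracy = 0`
#' rather than an error.
#'
#' @param base A simulation bundle from [simulate_slideseq()] at
#'   `downsample_fraction = 1`.
#' @param fraction Thinning fraction applied to the base counts.
#' @param cfg A [run_config()].
#' @param thin_seed Seed for the thinning draw (default 1).
#' @return The [score_recovery()] list plus `status` and `run` (or `NULL`
#'   when failed).
#' @export
run_recovery <- function(base, fraction, cfg = run_config(), thin_seed = 1L) {
  set.seed(thin_seed)
  se <- downsample(base$se, fraction)
  run <- tryCatch(
    suppressMessages(run_pipeline(se, base$gene_positions, cfg)),
    error = function(e) e)
  if (inherits(run, "error")) {
    return(list(status = "failed", message = conditionMessage(run),
                k_malignant = NA_integer_, accuracy = 0,
                sign_match = NA_real_, spearman_min = NA_real_, run = NULL))
  }
  out <- score_recovery(run, base)
  out$status <- "ok"
  out$run <- run
  out
}

#' Match inferred clusters to true clone labels
#'
#' Exhaustively searches cluster -> clone label assignments (injective maps)
#' and returns the one maximising agreement, together with the resulting
#' accuracy. Used to score simulated data where cluster numbering is
#' arbitrary.
#'
#' @param inferred Vector of inferred cluster labels.
#' @param truth Vector of true labels (same length).
#' @return List with `accuracy`, `mapping` (named vector cluster -> truth
#'   label).
#' @export
match_clusters <- function(inferred, truth) {
  inferred <- as.character(inferred); truth <- as.character(truth)
  stopifnot(length(inferred) == length(truth))
  cl <- unique(inferred); tl <- unique(truth)
  if (length(cl) > 8L) stop("too many clusters for exhaustive matching")
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) for (p in perms(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  # pad the shorter label set so the map is a permutation of the longer
  k <- max(length(cl), length(tl))
  tl_pad <- c(tl, paste0(".unmatched", seq_len(max(0L, k - length(tl)))))
  best <- list(accuracy = -1)
  for (p in perms(tl_pad)) {
    map <- stats::setNames(p[seq_along(cl)], cl)
    acc <- mean(map[inferred] == truth)
    if (acc > best$accuracy) best <- list(accuracy = acc, mapping = map)
  }
  best
}
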