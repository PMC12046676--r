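# In silico bead simulator: cell (or nucleus) expression profiles with
# implanted arm-level CNAs are placed on a square field, two malignant
# clones in opposing horizontal gradients and a normal population either
# spatially separated (a band at the top) or intermixed; beads then capture
# a Gaussian-kernel-weighted mixture of nearby cell profiles, and counts can
# be binomially thinned to spot-level sparsity. Ground truth (per-bead clone
# weight fractions, per-arm fold changes) is carried along.

#' Simulation configuration
#'
#' Defaults reproduce the study design the simulator emulates: a
#' 3000 x 3000 um field, 10,000 beads, 6000 normal cells plus 7000 cells
#' per malignant clone, 100 vertical zones of width 30 um carrying opposing
#' clone gradients in 1% decrements (99:0, 98:1, ..., 0:99), and a Gaussian
#' capture kernel of width `1500 * sqrt(1 / total_cells)`.
#'
#' @param field_size Side of the square field in um (default 3000).
#' @param n_beads Number of beads (default 10000).
#' @param n_normal_cells Normal cells placed (default 6000).
#' @param n_malignant_per_clone Malignant cells per clone (default 7000).
#' @param scenario `"separated"` (normals confined to the top band
#'   `y > 0.9 * field_size`) or `"mixed"` (normals across the field).
#' @param n_zones Number of gradient zones (default 100).
#' @param kernel_width Gaussian kernel sd in um; default
#'   `1500 * sqrt(1 / total_cells)`.
#' @param kernel_truncate Kernel support radius in sds (default 3).
#' @param bead_size_um Physical bead diameter, metadata only (default 10).
#' @param downsample_fraction Binomial thinning fraction in (0, 1]
#'   (default 1 = no thinning).
#' @param n_genes,n_chromosomes Synthetic genome size (defaults 1000 genes
#'   on 10 chromosomes, p/q arms split at the chromosome midpoint).
#' @param nb_dispersion Per-gene NB dispersion of cell profiles
#'   (default 0.5; `size = 1/dispersion`).
#' @param meanlog,sdlog Log-normal parameters of per-gene NB mean counts
#'   (defaults 0 and 1).
#' @param clone_cna_spec data.frame `clone`, `arm`, `fc` of implanted
#'   arm-level fold changes; default [default_clone_cna_spec()].
#' @param seed Integer seed governing all stochastic steps.
#' @return A `sim_config` list (with derived `zone_width`).
#' @export
sim_config <- function(field_size = 3000, n_beads = 10000,
                       n_normal_cells = 6000, n_malignant_per_clone = 7000,
                       scenario = c("separated", "mixed"),
                       n_zones = 100, kernel_width = NULL,
                       kernel_truncate = 3, bead_size_um = 10,
                       downsample_fraction = 1,
                       n_genes = 1000, n_chromosomes = 10,
                       nb_dispersion = 0.5, meanlog = 0, sdlog = 1,
                       clone_cna_spec = default_clone_cna_spec(),
                       seed = 1L) {
  scenario <- match.arg(scenario)
  total_cells <- n_normal_cells + 2 * n_malignant_per_clone
  if (is.null(kernel_width)) kernel_width <- 1500 * sqrt(1 / total_cells)
  stopifnot(field_size %% n_zones == 0, kernel_width > 0,
            downsample_fraction > 0, downsample_fraction <= 1)
  structure(list(field_size = field_size, n_beads = n_beads,
                 n_normal_cells = n_normal_cells,
                 n_malignant_per_clone = n_malignant_per_clone,
                 scenario = scenario, n_zones = n_zones,
                 zone_width = field_size / n_zones,
                 kernel_width = kernel_width,
                 kernel_truncate = kernel_truncate,
                 bead_size_um = bead_size_um,
                 downsample_fraction = downsample_fraction,
                 n_genes = n_genes, n_chromosomes = n_chromosomes,
                 nb_dispersion = nb_dispersion,
                 meanlog = meanlog, sdlog = sdlog,
                 clone_cna_spec = clone_cna_spec, seed = as.integer(seed)),
            class = "sim_config")
}

#' Default implanted clone CNA specification
#'
#' Two clones with four disjoint arm-level alterations each (two
#' amplifications at fold change 1.5 and two deletions at 0.5), on the
#' default 10-chromosome synthetic genome.
#'
#' @return data.frame with columns `clone`, `arm`, `fc`.
#' @export
default_clone_cna_spec <- function() {
  data.frame(
    clone = rep(c("clone1", "clone2"), each = 4L),
    arm = c("1p", "2q", "3p", "4q", "6p", "7q", "8p", "9q"),
    fc = rep(c(1.5, 0.5, 1.5, 0.5), 2L),
    stringsAsFactors = FALSE)
}

#' Synthetic genome gene positions
#'
#' `n_genes` genes spread evenly over `n_chromosomes` chromosomes, 1 Mb
#' apart, with the centromere at the chromosome midpoint (so arms split the
#' genes roughly in half).
#'
#' @param n_genes,n_chromosomes Genome size.
#' @return A `gene_positions` table; the centromere table used is attached
#'   as the `"centromeres"` attribute.
#' @export
synth_genome <- function(n_genes = 1000, n_chromosomes = 10) {
  per <- ceiling(n_genes / n_chromosomes)
  chrom <- paste0("chr", rep(seq_len(n_chromosomes), each = per))[seq_len(n_genes)]
  idx <- unlist(lapply(rle(chrom)$lengths, seq_len))
  start <- idx * 1000000L
  gp <- data.frame(gene = sprintf("g%04d", seq_len(n_genes)),
                   chrom = chrom, start = start, end = start + 1000L,
                   stringsAsFactors = FALSE)
  cen <- data.frame(chrom = paste0("chr", seq_len(n_chromosomes)),
                    centromere = (floor(per / 2) + 0.5) * 1000000,
                    stringsAsFactors = FALSE)
  out <- gene_positions(gp, cen)
  attr(out, "centromeres") <- cen
  out
}

#' Generate synthetic cell profiles with implanted CNAs
#'
#' Per-gene NB mean counts are drawn log-normally; normal cells draw counts
#' from `NB(mean_g, dispersion)` and clone cells from
#' `NB(mean_g * fc(arm(g), clone), dispersion)`, where `fc` comes from the
#' clone CNA specification (1 on unaltered arms).
#'
#' @param gp A `gene_positions` table (e.g. [synth_genome()]).
#' @param clone_cna_spec data.frame `clone`, `arm`, `fc`; fold changes must
#'   be positive.
#' @param n_normal,n_per_clone Cell numbers.
#' @param nb_dispersion NB dispersion (`size = 1/dispersion`).
#' @param meanlog,sdlog Log-normal parameters of gene mean counts.
#' @param gene_means Optional fixed per-gene means (overrides the draw).
#' @return List: `counts` (cell x gene integer matrix), `label` (per-cell
#'   clone in normal/clone1/clone2), `gene_means`, `arm_fc` (clone x arm
#'   fold-change matrix over all arms).
#' @export
synth_profiles <- function(gp, clone_cna_spec = default_clone_cna_spec(),
                           n_normal = 6000, n_per_clone = 7000,
                           nb_dispersion = 0.5, meanlog = 0, sdlog = 1,
                           gene_means = NULL) {
  if (any(clone_cna_spec$fc <= 0)) stop("fold changes must be positive")
  n_genes <- nrow(gp)
  if (is.null(gene_means))
    gene_means <- stats::rlnorm(n_genes, meanlog = meanlog, sdlog = sdlog)
  clones <- unique(clone_cna_spec$clone)
  arms <- unique(gp$arm)
  arm_fc <- matrix(1, nrow = length(clones) + 1L, ncol = length(arms),
                   dimnames = list(c("normal", clones), arms))
  for (r in seq_len(nrow(clone_cna_spec))) {
    if (!clone_cna_spec$arm[r] %in% arms)
      stop("CNA spec arm not in genome: ", clone_cna_spec$arm[r])
    arm_fc[clone_cna_spec$clone[r], clone_cna_spec$arm[r]] <- clone_cna_spec$fc[r]
  }
  label <- c(rep("normal", n_normal),
             rep(clones, each = n_per_clone))
  n_cells <- length(label)
  size <- 1 / nb_dispersion
  counts <- matrix(0L, nrow = n_cells, ncol = n_genes,
                   dimnames = list(sprintf("cell_%05d", seq_len(n_cells)),
                                   gp$gene))
  for (who in rownames(arm_fc)) {
    rows <- which(label == who)
    if (!length(rows)) next
    mu <- gene_means * arm_fc[who, gp$arm]
    counts[rows, ] <- matrix(
      stats::rnbinom(length(rows) * n_genes, mu = rep(mu, each = length(rows)),
                     size = size),
      nrow = length(rows))
  }
  list(counts = counts, label = stats::setNames(label, rownames(counts)),
       gene_means = gene_means, arm_fc = arm_fc)
}

#' Place cells on the field
#'
#' Normal cells go to the top band (`y` in the top tenth of the field) in
#' the separated scenario or uniformly in the mixed scenario. Malignant
#' cells are placed in vertical zones: zone `z` of `n_zones` receives
#' clone1 and clone2 in ratio `(n_zones - z) : (z - 1)`, reproducing the
#' 99:0, 98:1, ..., 0:99 gradient for 100 zones. Coordinates are integers.
#'
#' @param label Per-cell clone labels (normal/clone1/clone2).
#' @param cfg A [sim_config()].
#' @return data.frame `cell`, `clone`, `x`, `y`.
#' @export
place_cells <- function(label, cfg) {
  fs <- cfg$field_size
  nz <- cfg$n_zones
  zw <- cfg$zone_width
  mal_ymax <- as.integer(fs * 0.9)
  x <- y <- integer(length(label))
  is_norm <- label == "normal"
  x[is_norm] <- sample.int(fs, sum(is_norm), replace = TRUE)
  y[is_norm] <- if (cfg$scenario == "separated") {
    mal_ymax + sample.int(fs - mal_ymax, sum(is_norm), replace = TRUE)
  } else sample.int(fs, sum(is_norm), replace = TRUE)

  zone_w <- list(clone1 = (nz - seq_len(nz)) / sum(nz - seq_len(nz)),
                 clone2 = (seq_len(nz) - 1) / sum(seq_len(nz) - 1))
  for (cl in c("clone1", "clone2")) {
    rows <- which(label == cl)
    if (!length(rows)) next
    z <- sample.int(nz, length(rows), replace = TRUE, prob = zone_w[[cl]])
    x[rows] <- as.integer((z - 1L) * zw) + sample.int(zw, length(rows), replace = TRUE)
    y[rows] <- if (cfg$scenario == "separated") {
      sample.int(mal_ymax, length(rows), replace = TRUE)
    } else sample.int(fs, length(rows), replace = TRUE)
  }
  data.frame(cell = names(label), clone = as.character(label),
             x = x, y = y, stringsAsFactors = FALSE)
}

# floor + Bernoulli on the fractional part: integer counts whose
# expectation equals the real-valued input.
stochastic_round <- function(x) {
  f <- floor(x)
  as.integer(f + (stats::runif(length(x)) < (x - f)))
}

#' Aggregate placed cells into beads
#'
#' Beads get random integer coordinates on the field; each bead's
#' expression is the Gaussian-kernel-weighted sum of nearby cell profiles
#' (`w = exp(-d^2 / (2 sigma^2))`, truncated beyond
#' `kernel_truncate * sigma`), rounded stochastically to integer counts
#' (expectation-preserving). Beads capturing no cell are dropped with a
#' message. Each bead's per-clone kernel-weight fractions and dominant
#' clone are recorded as ground truth; the dominant clone also sets the
#' bead annotation (`reference` for normal-dominated beads, `malignant`
#' otherwise).
#'
#' @param counts Cell x gene count matrix.
#' @param positions data.frame from [place_cells()].
#' @param cfg A [sim_config()].
#' @return List: `se` (a `spatial_expression`), `truth` (data.frame `bead`,
#'   `dominant`, `frac_normal`, `frac_clone1`, `frac_clone2`).
#' @export
beads_from_cells <- function(counts, positions, cfg) {
  fs <- cfg$field_size
  sigma <- cfg$kernel_width
  cutoff <- cfg$kernel_truncate * sigma
  bead_xy <- cbind(x = sample.int(fs, cfg$n_beads, replace = TRUE),
                   y = sample.int(fs, cfg$n_beads, replace = TRUE))
  bead_id <- sprintf("bead_%05d", seq_len(cfg$n_beads))
  cell_xy <- as.matrix(positions[, c("x", "y")])
  clones <- c("normal", "clone1", "clone2")
  clone_ind <- outer(positions$clone, clones, "==") * 1

  expr <- matrix(0, nrow = cfg$n_beads, ncol = ncol(counts))
  fracs <- matrix(0, nrow = cfg$n_beads, ncol = 3L,
                  dimnames = list(bead_id, clones))
  chunk <- 500L
  for (s in seq(1L, cfg$n_beads, by = chunk)) {
    rows <- s:min(cfg$n_beads, s + chunk - 1L)
    d2 <- outer(bead_xy[rows, 1L], cell_xy[, 1L], "-")^2 +
      outer(bead_xy[rows, 2L], cell_xy[, 2L], "-")^2
    w <- exp(-d2 / (2 * sigma^2))
    w[d2 > cutoff^2] <- 0
    expr[rows, ] <- w %*% counts
    fracs[rows, ] <- w %*% clone_ind
  }
  tot_w <- rowSums(fracs)
  keep <- tot_w > 0
  if (!all(keep)) message("dropped ", sum(!keep), " bead(s) capturing no cell")
  expr <- expr[keep, , drop = FALSE]
  fracs <- fracs[keep, , drop = FALSE] / tot_w[keep]
  bead_id <- bead_id[keep]
  bead_xy <- bead_xy[keep, , drop = FALSE]

  cnt <- matrix(stochastic_round(expr), nrow = nrow(expr),
                dimnames = list(bead_id, colnames(counts)))
  dominant <- clones[max.col(fracs, ties.method = "first")]
  bead_type <- ifelse(dominant == "normal", "reference", "malignant")
  se <- spatial_expression(
    cnt,
    data.frame(bead = bead_id, x = bead_xy[, 1L], y = bead_xy[, 2L]),
    stats::setNames(bead_type, bead_id),
    require_reference = FALSE)
  truth <- data.frame(bead = bead_id, dominant = dominant,
                      frac_normal = fracs[, "normal"],
                      frac_clone1 = fracs[, "clone1"],
                      frac_clone2 = fracs[, "clone2"],
                      stringsAsFactors = FALSE)
  list(se = se, truth = truth)
}

#' Binomial downsampling (thinning) of bead counts
#'
#' Each count is replaced by a `Binomial(count, fraction)` draw, preserving
#' expected totals; `fraction = 1` is the identity.
#'
#' @param se A `spatial_expression` object.
#' @param fraction Thinning fraction in (0, 1].
#' @return The thinned `spatial_expression`.
#' @export
downsample <- function(se, fraction) {
  if (!(fraction > 0 && fraction <= 1)) stop("fraction must be in (0, 1]")
  if (fraction == 1) return(se)
  counts <- se$counts
  counts@x <- as.numeric(stats::rbinom(length(counts@x), counts@x, fraction))
  counts <- Matrix::drop0(counts)
  spatial_expression(counts, se$coords, se$bead_type,
                     require_reference = FALSE)
}

#' Run the full bead simulation
#'
#' Generates (or resamples) cell profiles, places them, aggregates beads
#' with the Gaussian kernel, and applies binomial thinning. All randomness
#' is governed by `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @param profiles Optional real cell profiles: a list with `counts`
#'   (cell x gene) and `label` (per-cell normal/clone1/clone2); cells are
#'   then resampled with replacement instead of generated. Gene positions
#'   for such profiles must be supplied via `gp`.
#' @param gp Gene positions matching `profiles` (default: the synthetic
#'   genome of `cfg`).
#' @return List: `se` (bead `spatial_expression`), `truth` (per-bead
#'   ground-truth table), `gene_positions`, `arm_fc` (clone x arm true
#'   fold changes; `NULL` for resampled real profiles), `config`.
#' @export
simulate_slideseq <- function(cfg = sim_config(), profiles = NULL, gp = NULL) {
  set.seed(cfg$seed)
  if (is.null(profiles)) {
    if (is.null(gp)) gp <- synth_genome(cfg$n_genes, cfg$n_chromosomes)
    prof <- synth_profiles(gp, cfg$clone_cna_spec,
                           n_normal = cfg$n_normal_cells,
                           n_per_clone = cfg$n_malignant_per_clone,
                           nb_dispersion = cfg$nb_dispersion,
                           meanlog = cfg$meanlog, sdlog = cfg$sdlog)
    counts <- prof$counts
    label <- prof$label
    arm_fc <- prof$arm_fc
  } else {
    if (is.null(gp)) stop("gene positions required for supplied profiles")
    pools <- split(seq_len(nrow(profiles$counts)), profiles$label)
    pick <- c(sample(pools$normal, cfg$n_normal_cells, replace = TRUE),
              sample(pools$clone1, cfg$n_malignant_per_clone, replace = TRUE),
              sample(pools$clone2, cfg$n_malignant_per_clone, replace = TRUE))
    counts <- profiles$counts[pick, , drop = FALSE]
    rownames(counts) <- sprintf("cell_%05d", seq_along(pick))
    label <- stats::setNames(as.character(profiles$label)[pick], rownames(counts))
    arm_fc <- NULL
  }
  pos <- place_cells(label, cfg)
  sim <- beads_from_cells(counts, pos, cfg)
  if (cfg$downsample_fraction < 1)
    sim$se <- downsample(sim$se, cfg$downsample_fraction)
  list(se = sim$se, truth = sim$truth, gene_positions = gp,
       arm_fc = arm_fc, cells = pos, config = cfg)
}
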