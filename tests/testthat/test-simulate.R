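# The in silico bead generator: profiles, placement, kernel aggregation,
# thinning, and its ground-truth bookkeeping.

test_that("synthetic profiles realise the implanted fold changes and reject bad specs", {
  gp <- synth_genome(200, 4)
  set.seed(1)
  spec <- data.frame(clone = "clone1", arm = "1p", fc = 2.0)
  prof <- synth_profiles(gp, spec, n_normal = 2000, n_per_clone = 2000,
                         gene_means = rep(2, 200))
  chr1p <- gp$gene[gp$arm == "1p"]
  ratio <- colMeans(prof$counts[prof$label == "clone1", chr1p]) /
    colMeans(prof$counts[prof$label == "normal", chr1p])
  expect_equal(mean(ratio), 2, tolerance = 0.05)
  other <- gp$gene[gp$arm != "1p"]
  ratio0 <- colMeans(prof$counts[prof$label == "clone1", other]) /
    colMeans(prof$counts[prof$label == "normal", other])
  expect_equal(mean(ratio0), 1, tolerance = 0.05)
  expect_error(synth_profiles(gp, data.frame(clone = "clone1", arm = "1p", fc = -1)),
               "positive")
  expect_error(synth_profiles(gp, data.frame(clone = "clone1", arm = "99q", fc = 2)),
               "not in genome")
})

test_that("cell placement respects the separated band and the zone gradient", {
  cfg <- sim_config(n_normal_cells = 500, n_malignant_per_clone = 2000,
                    n_genes = 10, seed = 2)
  set.seed(2)
  label <- setNames(c(rep("normal", 500), rep("clone1", 2000), rep("clone2", 2000)),
                    paste0("c", 1:4500))
  pos <- place_cells(label, cfg)
  expect_true(all(pos$y[pos$clone == "normal"] > 2700))
  expect_true(all(pos$y[pos$clone != "normal"] <= 2700))
  expect_true(all(pos$x >= 1 & pos$x <= 3000 & pos$x == round(pos$x)))
  # zone 1 (x in 1..30) must contain no clone2 cells: ratio 99:0
  expect_equal(sum(pos$clone == "clone2" & pos$x <= 30), 0L)
  # and symmetric for clone1 in the last zone
  expect_equal(sum(pos$clone == "clone1" & pos$x > 2970), 0L)
  # gradient: clone1 frequency decreases with x (Spearman over zone means)
  zones <- ceiling(pos$x[pos$clone != "normal"] / 30)
  f1 <- tapply(pos$clone[pos$clone != "normal"] == "clone1", zones, mean)
  expect_lt(cor(as.numeric(names(f1)), f1, method = "spearman"), -0.95)

  # mixed scenario: normal y roughly uniform over the square
  cfg_m <- sim_config(scenario = "mixed", n_normal_cells = 2000,
                      n_malignant_per_clone = 100, n_genes = 10, seed = 3)
  set.seed(3)
  label_m <- setNames(rep(c("normal", "clone1", "clone2"), c(2000, 100, 100)),
                      paste0("c", 1:2200))
  pos_m <- place_cells(label_m, cfg_m)
  ks <- suppressWarnings(ks.test(pos_m$y[pos_m$clone == "normal"] / 3000, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("kernel aggregation weights cells by distance and records unit fractions", {
  gp <- synth_genome(20, 2)
  counts <- matrix(c(rep(10L, 20), rep(0L, 19), 40L), nrow = 2, byrow = TRUE,
                   dimnames = list(c("cell_1", "cell_2"), gp$gene))
  pos <- data.frame(cell = c("cell_1", "cell_2"), clone = c("clone1", "normal"),
                    x = c(100L, 2900L), y = c(100L, 2900L))
  cfg <- sim_config(n_beads = 400, n_normal_cells = 1, n_malignant_per_clone = 1,
                    n_genes = 20, kernel_width = 400, seed = 4)
  set.seed(4)
  out <- beads_from_cells(counts, pos, cfg)
  expect_equal(rowSums(out$truth[, c("frac_normal", "frac_clone1", "frac_clone2")]),
               setNames(rep(1, nrow(out$truth)), out$truth$bead))
  # a bead close to cell_1 only is pure clone1 and proportional to its profile
  d1 <- sqrt((out$se$coords$x - 100)^2 + (out$se$coords$y - 100)^2)
  near1 <- which(d1 < cfg$kernel_width)[1]
  expect_false(is.na(near1))
  b <- rownames(out$se$counts)[near1]
  expect_equal(out$truth[out$truth$bead == b, "frac_clone1"], 1)
  expect_equal(as.character(out$se$bead_type[[b]]), "malignant")
  # default kernel width formula
  expect_equal(sim_config()$kernel_width, 1500 * sqrt(1 / 20000))
})

test_that("stochastic rounding preserves expectation", {
  set.seed(8)
  x <- runif(20000, 0, 5)
  r <- spotcna:::stochastic_round(x)
  expect_true(all(r %in% c(floor(x), ceiling(x))))
  expect_equal(mean(r), mean(x), tolerance = 0.01)
})

test_that("binomial thinning preserves expected totals and identities", {
  se <- tiny_se(n_beads = 8, n_genes = 50, seed = 10)
  expect_identical(downsample(se, 1)$counts, se$counts)
  total <- sum(se$counts)
  for (s in 1:20) {
    set.seed(s)
    thin <- downsample(se, 0.1)
    expect_lt(abs(sum(thin$counts) - 0.1 * total),
              3 * sqrt(0.1 * 0.9 * total) + 1e-9)
    expect_true(all(thin$counts <= se$counts))
  }
  expect_error(downsample(se, 0), "fraction")
  expect_error(downsample(se, 1.2), "fraction")
})

test_that("bead-level clone gradient follows the implanted spatial design", {
  cfg <- sim_config(n_beads = 1200, n_normal_cells = 600,
                    n_malignant_per_clone = 700, n_genes = 200,
                    n_chromosomes = 10, seed = 6)
  sim <- simulate_slideseq(cfg)
  tr <- sim$truth
  xs <- sim$se$coords[tr$bead, "x"]
  zone <- cut(xs, breaks = seq(0, 3000, by = 300))
  mal <- tr$frac_clone1 + tr$frac_clone2 > 0.5
  zmeans <- tapply(tr$frac_clone1[mal] / (tr$frac_clone1 + tr$frac_clone2)[mal],
                   zone[mal], mean)
  expect_lt(cor(seq_along(zmeans), zmeans, method = "spearman"), -0.95)
  # determinism under the same seed
  sim2 <- simulate_slideseq(cfg)
  expect_identical(as.matrix(sim$se$counts), as.matrix(sim2$se$counts))
})
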