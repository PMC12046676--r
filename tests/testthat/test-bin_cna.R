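# Pseudo-distance, bin assignment, aggregation, and CNA scoring.

test_that("pseudo-distance is the stated linear combination and respects spatial_mode", {
  inten <- matrix(c(1, 1, 1, 1, 4, 1), nrow = 2, byrow = TRUE,
                  dimnames = list(c("b1", "b2"), c("g1", "g2", "g3")))
  coords <- data.frame(bead = c("b1", "b2"), x = c(0, 2), y = c(0, 0))
  rownames(coords) <- coords$bead
  cfg <- binning_config(k_spatial = 55, k_expression = 1)
  ps <- pseudo_distance(inten, coords, cfg)
  expect_equal(ps["b1", "b2"], 55 * 2 + 1 * 3)   # expression distance = 3
  expect_equal(diag(ps), c(b1 = 0, b2 = 0))
  expect_equal(ps, t(ps))
  # k_expression = 0 -> pure spatial
  ps0 <- pseudo_distance(inten, coords, binning_config(k_spatial = 7, k_expression = 0))
  expect_equal(ps0["b1", "b2"], 14)
  # spatial_mode off -> expression only
  psn <- pseudo_distance(inten, coords, binning_config(spatial = FALSE))
  expect_equal(psn["b1", "b2"], 3)
  bad <- coords; bad$x[1] <- Inf
  rownames(bad) <- bad$bead
  expect_error(pseudo_distance(inten, bad, cfg), "finite")
})

test_that("bin counts follow round(n / beads_per_bin) and spatial blobs separate", {
  set.seed(2)
  # 24 beads in two tight spatial blobs
  n <- 24
  xy <- rbind(cbind(rnorm(12, 0, 1), rnorm(12, 0, 1)),
              cbind(rnorm(12, 1000, 1), rnorm(12, 1000, 1)))
  coords <- data.frame(bead = paste0("b", 1:n), x = xy[, 1], y = xy[, 2])
  rownames(coords) <- coords$bead
  inten <- matrix(1, n, 5, dimnames = list(coords$bead, paste0("g", 1:5)))
  ps <- pseudo_distance(inten, coords, binning_config())
  lab <- assign_bins(ps, binning_config(beads_per_bin = 12))
  expect_equal(length(unique(lab)), 2L)
  expect_equal(length(lab), n)
  expect_equal(length(unique(lab[1:12])), 1L)
  expect_equal(length(unique(lab[13:24])), 1L)
  expect_false(lab[1] == lab[13])
  # singleton group
  expect_equal(unname(assign_bins(ps[1, 1, drop = FALSE], binning_config())), 1L)
})

test_that("bins never mix malignant and non-malignant beads and partition all beads", {
  set.seed(9)
  se <- tiny_se(n_beads = 30, n_genes = 10,
                types = rep(c("reference", "malignant", "malignant"), 10))
  inten <- matrix(2^rnorm(30 * 10, sd = 0.1), 30, 10,
                  dimnames = dimnames(se$counts))
  bs <- bin_beads(inten, se, binning_config(beads_per_bin = 5))
  expect_equal(sort(names(bs$membership)), sort(rownames(se$counts)))
  expect_equal(sum(bs$bins$n_beads), 30L)
  for (b in bs$bins$bin) {
    members <- names(bs$membership)[bs$membership == b]
    mal <- se$bead_type[members] == "malignant"
    expect_true(all(mal) || all(!mal))
  }
})

test_that("aggregation takes means, sums UMI, and breaks type ties deterministically", {
  se <- tiny_se(n_beads = 3, n_genes = 2,
                counts = matrix(c(4L, 0L, 2L, 2L, 0L, 6L), nrow = 3, byrow = TRUE,
                                dimnames = list(c("b1", "b2", "b3"), c("g1", "g2"))),
                types = c("malignant", "malignant", "reference"))
  inten <- matrix(c(0.8, 1.0, 1.2, 1.0, 1.0, 1.0), nrow = 3,
                  dimnames = list(c("b1", "b2", "b3"), c("g1", "g2")))
  bs <- aggregate_bins(inten, se, c(b1 = 1L, b2 = 1L, b3 = 2L))
  expect_equal(unname(bs$intensity["bin_1", "g1"]), 0.9)
  expect_equal(bs$bins["bin_1", "umi"], 8)
  expect_equal(bs$bins["bin_1", "x"], mean(se$coords[c("b1", "b2"), "x"]))
  expect_equal(bs$bins["bin_1", "type"], "malignant")
  # tie between malignant and reference -> earliest in sort order, with message
  se2 <- tiny_se(n_beads = 2, n_genes = 2,
                 types = c("malignant", "reference"))
  expect_message(
    bs2 <- aggregate_bins(inten[1:2, ], se2, c(b1 = 1L, b2 = 1L)),
    "tie")
  expect_equal(bs2$bins[1, "type"], "malignant")   # "malignant" < "reference"
})

test_that("cna scores clamp to the configured caps and UMI options behave", {
  bins <- data.frame(bin = c("bin_1", "bin_2"), x = 0, y = 0,
                     umi = c(100, 100), type = "malignant", n_beads = 1,
                     malignant = TRUE)
  rownames(bins) <- bins$bin
  inten <- matrix(c(1.7, 0.5, 1.1, 0.9), 2, byrow = TRUE,
                  dimnames = list(bins$bin, c("g1", "g2")))
  bs <- structure(list(bins = bins, membership = c(a = "bin_1", b = "bin_2"),
                       intensity = inten), class = "bin_set")
  out <- cna_scores(bs, binning_config())
  expect_equal(unname(out$cna["bin_1", ]), c(1.4, 0.6))
  expect_equal(unname(out$cna["bin_2", ]), c(1.1, 0.9))
  # equal UMI -> shrink is a no-op beyond capping
  out2 <- cna_scores(bs, binning_config(umi_adjust = "shrink"))
  expect_equal(out2$cna, out$cna)
  # below-median UMI bin shrunk toward 1 under "shrink"
  bs$bins$umi <- c(50, 100)
  out3 <- cna_scores(bs, binning_config(umi_adjust = "shrink"))
  s <- 50 / 75
  expect_equal(unname(out3$cna["bin_1", "g2"]), 1 + (0.5 - 1) * s)
  bs$bins$umi <- c(0, 100)
  expect_error(cna_scores(bs, binning_config()), "zero UMI")
})

test_that("with k_expression = 0, binning ignores the expression matrix entirely", {
  set.seed(13)
  se <- tiny_se(n_beads = 20, n_genes = 6,
                types = rep("malignant", 20))
  intenA <- matrix(2^rnorm(20 * 6), 20, 6, dimnames = dimnames(se$counts))
  intenB <- matrix(2^rnorm(20 * 6), 20, 6, dimnames = dimnames(se$counts))
  cfg <- binning_config(k_expression = 0, beads_per_bin = 5)
  psA <- pseudo_distance(intenA, se$coords, cfg)
  psB <- pseudo_distance(intenB, se$coords, cfg)
  expect_equal(assign_bins(psA, cfg), assign_bins(psB, cfg))
})

test_that("within-bin spatial spread does not increase with k_spatial", {
  set.seed(21)
  n <- 60
  se <- tiny_se(n_beads = n, n_genes = 8, types = rep("malignant", n))
  se$coords$x <- runif(n, 0, 1000); se$coords$y <- runif(n, 0, 1000)
  inten <- matrix(2^rnorm(n * 8, sd = 0.5), n, 8, dimnames = dimnames(se$counts))
  spread <- sapply(c(0, 5, 55, 500), function(ks) {
    cfg <- binning_config(k_spatial = ks, k_expression = 1, beads_per_bin = 6)
    bs <- bin_beads(inten, se, cfg)
    mean(sapply(split(names(bs$membership), bs$membership), function(b) {
      xy <- se$coords[b, c("x", "y")]
      mean(sqrt((xy$x - mean(xy$x))^2 + (xy$y - mean(xy$y))^2))
    }))
  })
  expect_true(all(diff(spread) <= 1e-9))
})
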