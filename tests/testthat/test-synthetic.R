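test_that("generate_slide honours tissue/signal fractions and the background rule", {
  # degenerate: no tissue at all
  sl0 <- generate_slide(4, 3, tissue_fraction = 0, signal_fraction = 0.5,
                        tile_size = 8, seed = 1)
  expect_false(any(sl0$tissue_mask))
  expect_false(any(sl0$signal_mask))
  tiles0 <- extract_tiles(sl0, 8)
  expect_true(all(vapply(tiles0, function(t) mean(t$pixels), 0) > 220))

  # all tissue, no signal
  sl1 <- generate_slide(4, 3, tissue_fraction = 1, signal_fraction = 0,
                        tile_size = 8, seed = 2)
  expect_true(all(sl1$tissue_mask))
  expect_false(any(sl1$signal_mask))

  # brute-force tile means match the tissue mask
  sl <- generate_slide(8, 8, tissue_fraction = 0.5, signal_fraction = 0.3,
                       tile_size = 8, seed = 1)
  means <- matrix(NA_real_, 8, 8)
  for (r in 1:8) for (cc in 1:8)
    means[r, cc] <- mean(sl$image[((r - 1) * 8 + 1):(r * 8),
                                  ((cc - 1) * 8 + 1):(cc * 8), ])
  expect_identical(sum(means <= 220), sum(sl$tissue_mask))
  expect_identical(unname(means <= 220), unname(sl$tissue_mask))
  # signal tiles are tissue tiles
  expect_true(all(sl$tissue_mask[sl$signal_mask]))
})

test_that("generate_slide is seed-deterministic and validates arguments", {
  a <- generate_slide(5, 5, tile_size = 8, seed = 9)
  b <- generate_slide(5, 5, tile_size = 8, seed = 9)
  expect_identical(a$image, b$image)
  c <- generate_slide(5, 5, tile_size = 8, seed = 10)
  expect_false(identical(a$image, c$image))
  expect_error(generate_slide(0, 5, tile_size = 8), "width_tiles")
  expect_error(generate_slide(5, 5, tile_size = 4), "tile_size")
})

test_that("feature bags satisfy the bag-label invariant with variable sizes", {
  bs <- generate_feature_bags(30, c(5, 25), 0.3, dim = 8, effect_size = 2,
                              seed = 3)
  sizes <- vapply(bs$bags, function(b) nrow(b$features), 1L)
  expect_gt(length(unique(sizes)), 1L)
  for (i in seq_along(bs$bags)) {
    n_flag <- sum(bs$instance_flags[[i]])
    if (bs$bag_labels[i] == 1L) expect_gte(n_flag, 1L) else expect_identical(n_flag, 0L)
    expect_identical(length(bs$instance_flags[[i]]), nrow(bs$bags[[i]]$features))
  }
  expect_setequal(unique(bs$bag_labels), c(0L, 1L))
  # determinism
  expect_identical(bs$bags[[1]]$features,
                   generate_feature_bags(30, c(5, 25), 0.3, dim = 8,
                                         effect_size = 2, seed = 3)$bags[[1]]$features)
  expect_error(generate_feature_bags(10, c(5, 10), 0, dim = 8), "signal_fraction")
})

test_that("zero effect size gives exchangeable instances; large effect is separable", {
  # null: flagged vs unflagged locations indistinguishable
  bs0 <- generate_feature_bags(100, c(10, 30), 0.3, dim = 8, effect_size = 0,
                               seed = 11)
  x <- do.call(rbind, lapply(bs0$bags, function(b) b$features))
  fl <- unlist(bs0$instance_flags)
  proj <- rowSums(x) / sqrt(ncol(x))   # the planted direction
  expect_gt(t.test(proj[fl == 1], proj[fl == 0])$p.value, 0.01)

  # strong effect: a per-instance linear classifier separates flags
  bs <- generate_feature_bags(200, c(20, 50), 0.3, dim = 32, effect_size = 4,
                              seed = 7)
  x <- do.call(rbind, lapply(bs$bags, function(b) b$features))
  fl <- unlist(bs$instance_flags)
  n <- nrow(x)
  tr <- seq_len(n) %% 2L == 0L   # deterministic held-out split
  beta_hat <- stats::glm.fit(cbind(1, x[tr, ]), fl[tr],
                             family = stats::binomial())$coefficients
  scores <- drop(cbind(1, x[!tr, ]) %*% beta_hat)
  expect_gt(auc(scores, fl[!tr]), 0.95)
})

test_that("synthetic omics plants recoverable prevalence and pathway activity", {
  gs <- data.frame(gene = c("G0", "G1", "G5"), prevalence = c(0, 1, 0.05))
  om <- generate_omics(1000, gs, seed = 3)
  expect_true(all(om$mutation$values["G0", ] == 0))
  expect_true(all(om$mutation$values["G1", ] == 1))
  # binomial 99% interval for p = 0.05, n = 1000 is within [0.03, 0.07]
  expect_true(mean(om$mutation$values["G5", ]) >= 0.03)
  expect_true(mean(om$mutation$values["G5", ]) <= 0.07)

  expect_error(generate_omics(10, data.frame(gene = c("A", "A"),
                                             prevalence = c(0.1, 0.2))),
               "duplicate")

  # planted pathway activity is recovered by the weighted-mean score
  defs <- data.frame(pathway = rep("pw", 4),
                     gene = c("ON1", "ON2", "SU1", "SU2"),
                     role = c("oncogene", "oncogene", "suppressor", "suppressor"))
  om2 <- generate_omics(200, data.frame(gene = "X", prevalence = 0.1),
                        pathway_defs = defs, seed = 5)
  act <- pathway_activity(om2$expression, defs)
  planted <- (om2$truth$pathway_activity[, "pw"] > 0) * 1L
  expect_gt(mean(act$l[, "pw"] == planted), 0.95)
})

test_that("slide and omics writers round-trip through disk formats", {
  dir <- withr::local_tempdir()
  sl <- generate_slide(4, 3, tile_size = 8, seed = 2)
  paths <- write_slide(sl, dir)
  raster <- read_slide_raster(file.path(dir, paste0(sl$slide_id, ".png")))
  expect_equal(raster, sl$image, ignore_attr = TRUE)
  masks <- read.delim(file.path(dir, paste0(sl$slide_id, "_masks.tsv")))
  expect_identical(nrow(masks), 12L)
  expect_identical(sum(masks$is_tissue), sum(sl$tissue_mask))

  om <- generate_omics(8, data.frame(gene = c("A", "B"), prevalence = c(0.5, 0.2)),
                       seed = 1)
  f <- file.path(dir, "mut.tsv")
  write_omics_tsv(om$mutation, f)
  back <- read_omics_tsv(f, "point_mutation")
  expect_equal(back$values, om$mutation$values)
})
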