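test_that("extract_tiles covers the largest grid and drops partial edges", {
  r <- array(100, dim = c(1024, 1024, 3))
  tiles <- extract_tiles(r, 512)
  expect_length(tiles, 4L)
  pos <- t(sapply(tiles, `[[`, "grid_pos"))
  expect_equal(pos, cbind(row = c(0L, 0L, 1L, 1L), col = c(0L, 1L, 0L, 1L)))

  expect_length(extract_tiles(array(1, dim = c(1023, 1024, 3)), 512), 2L)
  expect_length(extract_tiles(array(1, dim = c(1536, 2048, 3)), 512), 12L)
  expect_length(extract_tiles(array(1, dim = c(100, 100, 3)), 512), 0L)
  expect_error(extract_tiles(matrix(1, 10, 10), 5), "3 array")
  # nonoverlapping: all grid positions distinct
  tiles2 <- extract_tiles(array(1, dim = c(96, 64, 3)), 32)
  keys <- sapply(tiles2, function(t) paste(t$grid_pos, collapse = ","))
  expect_identical(anyDuplicated(keys), 0L)
})

test_that("background rule is strict at the threshold", {
  expect_true(is_background(const_tile(255)))
  expect_false(is_background(const_tile(0)))
  expect_false(is_background(const_tile(220)))   # exactly 220 is tissue
  expect_true(is_background(const_tile(220.5)))
  expect_true(is_background(const_tile(150), threshold = 100))
  expect_false(is_background(const_tile(99), threshold = 100))
})

test_that("downsample_flatten has the contracted length and area semantics", {
  big <- const_tile(37, size = 512L)
  v <- downsample_flatten(big, 128)
  expect_length(v, 49152L)
  expect_true(all(abs(v - 37) < 1e-9))

  # side = 1 gives the three per-channel means
  t1 <- random_tile(4, size = 16L)
  v1 <- downsample_flatten(t1, 1)
  expect_equal(v1, c(mean(t1$pixels[, , 1]), mean(t1$pixels[, , 2]),
                     mean(t1$pixels[, , 3])), tolerance = 1e-12)
})

test_that("k-means tumor selection recovers planted colour groups deterministically", {
  # two well-separated colour populations
  tiles <- c(lapply(1:6, function(i) {
    t <- random_tile(i, lo = 80, hi = 120)   # dark: tumor
    t$grid_pos <- c(row = 0L, col = i - 1L)
    t
  }), lapply(7:12, function(i) {
    t <- random_tile(i, lo = 180, hi = 215)  # light: nontumor
    t$grid_pos <- c(row = 1L, col = i - 7L)
    t
  }))
  sel <- cluster_tumor_tiles(tiles, seed = 1, side = 8)
  expect_identical(sel$assignments$status, rep(c("tumor", "nontumor"), each = 6))
  sel2 <- cluster_tumor_tiles(tiles, seed = 1, side = 8)
  expect_identical(sel$assignments, sel2$assignments)

  expect_error(cluster_tumor_tiles(tiles[1], seed = 1), "undefined")
  # degenerate: identical tiles -> warning, all tumor
  same <- lapply(1:4, function(i) const_tile(100, pos = c(row = 0L, col = i - 1L)))
  expect_warning(sel3 <- cluster_tumor_tiles(same, seed = 1, side = 8), "degenerate")
  expect_true(all(sel3$assignments$status == "tumor"))
})

test_that("refinement overrides flip exactly the forced tiles", {
  tiles <- lapply(1:6, function(i) {
    t <- random_tile(i, lo = if (i <= 3) 80 else 180,
                     hi = if (i <= 3) 120 else 215)
    t$grid_pos <- c(row = 0L, col = i - 1L)
    t
  })
  sel <- cluster_tumor_tiles(tiles, seed = 1, side = 8)
  expect_identical(apply_refinement(sel, data.frame(row = integer(),
                                                    col = integer(),
                                                    status = character()))$assignments,
                   sel$assignments)
  ov <- data.frame(row = c(0L, 0L), col = c(0L, 5L),
                   status = c("force_exclude", "force_tumor"))
  ref <- apply_refinement(sel, ov)
  expect_identical(sum(ref$assignments$status != sel$assignments$status), 2L)
  expect_identical(ref$assignments$status[ref$assignments$col == 0], "nontumor")
  expect_identical(ref$assignments$status[ref$assignments$col == 5], "tumor")
  expect_error(apply_refinement(sel, data.frame(row = 9L, col = 9L,
                                                status = "force_tumor")),
               "9 9")
})

test_that("colour normalization is the slide-level affine map and is idempotent", {
  tiles <- lapply(1:5, function(i) random_tile(i, lo = 60, hi = 200))
  stats <- slide_color_stats(tiles)
  # identity: source == target
  out <- normalize_colors(tiles, stats, stats)
  expect_equal(out[[1]]$pixels, tiles[[1]]$pixels, tolerance = 1e-9)

  # constant tile at the source mean maps to the target mean
  src <- structure(list(mean = c(100, 110, 120), std = c(10, 10, 10),
                        color_space = "RGB"), class = "slide_color_stats")
  tgt <- structure(list(mean = c(150, 140, 130), std = c(20, 20, 20),
                        color_space = "RGB"), class = "slide_color_stats")
  ct <- list(const_tile(0))
  ct[[1]]$pixels[, , 1] <- 100; ct[[1]]$pixels[, , 2] <- 110
  ct[[1]]$pixels[, , 3] <- 120
  mapped <- normalize_colors(ct, src, tgt)[[1]]$pixels
  expect_equal(unique(as.vector(mapped[, , 1])), 150)
  expect_equal(unique(as.vector(mapped[, , 3])), 130)

  # two slides with different planted stats align after mapping to one target
  s1 <- lapply(1:6, function(i) random_tile(i, lo = 60, hi = 140))
  s2 <- lapply(7:12, function(i) random_tile(i, lo = 120, hi = 200))
  st1 <- slide_color_stats(s1); st2 <- slide_color_stats(s2)
  n1 <- normalize_colors(s1, st1, tgt); n2 <- normalize_colors(s2, st2, tgt)
  m1 <- slide_color_stats(n1)$mean; m2 <- slide_color_stats(n2)$mean
  expect_true(all(abs(m1 - m2) < 1))

  # idempotence once source == target
  stn <- slide_color_stats(n1)
  again <- normalize_colors(n1, stn, stn)
  expect_equal(again[[1]]$pixels, n1[[1]]$pixels, tolerance = 1e-9)

  flat <- structure(list(mean = c(1, 1, 1), std = c(0, 1, 1),
                         color_space = "RGB"), class = "slide_color_stats")
  expect_error(normalize_colors(tiles, flat, tgt), "flat channel")
})

test_that("the preprocessing chain keeps grid positions and finds planted tumor tiles", {
  sl <- generate_slide(8, 6, tissue_fraction = 0.5, signal_fraction = 0.5,
                       tile_size = 8, seed = 4)
  pp <- preprocess_slide(sl, tile_size = 8, side = 8,
                         target_stats = slide_color_stats(extract_tiles(sl, 8)))
  expect_identical(unname(pp$counts["foreground"]), sum(sl$tissue_mask))
  # every surviving tile's grid position is a tissue position
  pos <- t(sapply(pp$tiles, `[[`, "grid_pos"))
  expect_true(all(sl$tissue_mask[pos + 1L]))
  # selection accuracy vs the planted masks: assignments either match the
  # signal partition or are a subset of tissue (both clusters are tissue)
  sel <- pp$selection
  truth <- sl$signal_mask[cbind(sel$assignments$row + 1L, sel$assignments$col + 1L)]
  acc <- mean((sel$assignments$status == "tumor") == truth)
  expect_gte(max(acc, 1 - acc), 0.95)
})
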