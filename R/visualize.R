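#' Project tile weights back onto the slide grid as a log-weight map
#'
#' Places `log(beta_i)` (natural log) at each tumor tile's grid position;
#' positions without a tumor tile are `NA`. Weights must be positive, which
#' Eq. `beta = 1 + gamma * attention received` guarantees whenever
#' `gamma > -1`.
#'
#' @param weights a [tile_weights()] or bare positive numeric vector.
#' @param positions N x 2 matrix of 0-based grid coordinates (row, col)
#'   aligned with the weights.
#' @param grid_dim `c(n_rows, n_cols)` of the tile grid.
#' @param slide_id identifier attached to the map.
#' @return Object of class `weight_map`: `grid` (n_rows x n_cols matrix of
#'   log-weights, `NA` off tumor tiles), `beta`, `positions`, `slide_id`.
#' @export
build_weight_map <- function(weights, positions, grid_dim, slide_id = "slide") {
  beta <- if (inherits(weights, "tile_weights")) weights$beta else as.numeric(weights)
  positions <- as.matrix(positions)
  if (any(beta <= 0)) stop_arg("tile weights must be positive (log undefined)")
  if (nrow(positions) != length(beta))
    stop_arg("positions must align with weights")
  grid <- matrix(NA_real_, grid_dim[1], grid_dim[2])
  grid[cbind(positions[, 1] + 1L, positions[, 2] + 1L)] <- log(beta)
  structure(list(grid = grid, beta = beta, positions = positions,
                 slide_id = slide_id),
            class = "weight_map")
}

#' Render a weight map as a green-intensity RGB overlay
#'
#' Log-weights are min–max scaled per slide to the green channel, so brighter
#' green means larger weight (a monotone mapping); non-tumor positions are
#' black. If all weights are equal the map renders at full intensity.
#'
#' @param map a [build_weight_map()] result.
#' @param tile_size optional upscaling factor: each grid cell becomes a
#'   `tile_size` x `tile_size` pixel block.
#' @return h x w x 3 numeric array in \[0, 1\].
#' @export
render_weight_map <- function(map, tile_size = 1L) {
  stopifnot(inherits(map, "weight_map"))
  g <- map$grid
  fin <- is.finite(g)
  rng <- range(g[fin])
  scaled <- g
  scaled[fin] <- if (diff(rng) == 0) 1 else (g[fin] - rng[1]) / diff(rng)
  scaled[!fin] <- 0
  if (tile_size > 1L) {
    scaled <- scaled[rep(seq_len(nrow(scaled)), each = tile_size),
                     rep(seq_len(ncol(scaled)), each = tile_size)]
  }
  out <- array(0, dim = c(dim(scaled), 3L))
  out[, , 2L] <- scaled
  out
}

#' @export
print.weight_map <- function(x, ...) {
  cat(sprintf("weight map '%s': %d x %d grid, %d tumor tiles, log-beta range [%.3f, %.3f]\n",
              x$slide_id, nrow(x$grid), ncol(x$grid), length(x$beta),
              min(log(x$beta)), max(log(x$beta))))
  invisible(x)
}

#' @export
plot.weight_map <- function(x, tile_size = 8L, ...) {
  img <- render_weight_map(x, tile_size = tile_size)
  graphics::plot.new()
  graphics::plot.window(c(0, 1), c(0, 1), asp = ncol(img) / nrow(img))
  graphics::rasterImage(img, 0, 0, 1, 1, interpolate = FALSE)
  graphics::title(main = paste("tile log-weight map:", x$slide_id))
  invisible(x)
}

#' Write a weight map as PNG overlay plus a machine-readable TSV
#'
#' The TSV has columns tile_row, tile_col, beta, log_beta so that any figure
#' can be reproduced from data.
#'
#' @param map a `weight_map`.
#' @param path_stem writes `<path_stem>.png` and `<path_stem>.tsv`.
#' @param tile_size upscaling factor for the PNG.
#' @return Invisibly, the two paths.
#' @export
write_weight_map <- function(map, path_stem, tile_size = 8L) {
  png_path <- paste0(path_stem, ".png")
  png::writePNG(render_weight_map(map, tile_size), png_path)
  tsv_path <- paste0(path_stem, ".tsv")
  utils::write.table(
    data.frame(tile_row = map$positions[, 1], tile_col = map$positions[, 2],
               beta = map$beta, log_beta = log(map$beta)),
    tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(png_path, tsv_path))
}

#' Select the top-k weighted tiles of a slide
#'
#' Tiles sorted by descending weight, ties broken by row-major grid position.
#' If fewer than `k` tiles exist, all are returned with a warning.
#'
#' @param weights a [tile_weights()] or numeric vector aligned with `tiles`.
#' @param tiles list of tiles (or any list aligned with the weights); may be
#'   `NULL` to return positions only.
#' @param positions N x 2 grid coordinates (taken from the tiles when
#'   omitted).
#' @param k number of tiles to keep (default 20).
#' @param slide_id identifier attached to the result.
#' @return Object of class `top_tiles`: data.frame `ranking` (rank, row, col,
#'   beta) and the selected `tiles` (possibly `NULL`).
#' @export
top_k_tiles <- function(weights, tiles = NULL, positions = NULL, k = 20L,
                        slide_id = NULL) {
  beta <- if (inherits(weights, "tile_weights")) weights$beta else as.numeric(weights)
  k <- check_scalar_int(k, "k")
  if (is.null(positions)) {
    if (is.null(tiles)) stop_arg("supply `positions` or tiles carrying grid_pos")
    positions <- t(vapply(tiles, function(t) t$grid_pos, c(row = 0L, col = 0L)))
  }
  positions <- as.matrix(positions)
  if (is.null(slide_id))
    slide_id <- if (!is.null(tiles)) tiles[[1]]$slide_id else "slide"
  n <- length(beta)
  if (n < k) {
    warning(sprintf("only %d tiles available for top-%d selection; returning all", n, k))
    k <- n
  }
  ord <- order(-beta, positions[, 1], positions[, 2])[seq_len(k)]
  structure(list(
    ranking = data.frame(rank = seq_len(k), row = positions[ord, 1],
                         col = positions[ord, 2], beta = beta[ord]),
    tiles = if (is.null(tiles)) NULL else tiles[ord],
    slide_id = slide_id),
    class = "top_tiles")
}

#' @export
print.top_tiles <- function(x, ...) {
  cat(sprintf("top %d weighted tiles of slide '%s' (beta %.3f .. %.3f)\n",
              nrow(x$ranking), x$slide_id, x$ranking$beta[1],
              x$ranking$beta[nrow(x$ranking)]))
  invisible(x)
}

#' Overlap between the top-k tile sets of two tasks on one slide
#'
#' Reports the grid positions selected by both tasks (e.g. a mutation task
#' and its related pathway task) together with the Jaccard index of the two
#' position sets.
#'
#' @param top_a,top_b [top_k_tiles()] results for the same slide.
#' @return List with `shared` (data.frame row/col), `n_shared`, `jaccard`.
#' @export
overlap_report <- function(top_a, top_b) {
  stopifnot(inherits(top_a, "top_tiles"), inherits(top_b, "top_tiles"))
  if (!identical(top_a$slide_id, top_b$slide_id))
    stop_arg("top-tile sets come from different slides")
  ka <- paste(top_a$ranking$row, top_a$ranking$col)
  kb <- paste(top_b$ranking$row, top_b$ranking$col)
  shared <- intersect(ka, kb)
  un <- union(ka, kb)
  parts <- do.call(rbind, strsplit(shared, " "))
  list(shared = if (length(shared))
         data.frame(row = as.integer(parts[, 1]), col = as.integer(parts[, 2]))
       else data.frame(row = integer(), col = integer()),
       n_shared = length(shared),
       jaccard = if (length(un)) length(shared) / length(un) else NA_real_)
}

#' Export the top-k tiles as PNG files named by rank
#'
#' @param top a [top_k_tiles()] result carrying tiles.
#' @param dir output directory.
#' @return Invisibly, the written paths.
#' @export
export_top_tiles <- function(top, dir) {
  stopifnot(inherits(top, "top_tiles"))
  if (is.null(top$tiles)) stop_arg("top-tile object carries no tile pixels")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(top$tiles))
  for (i in seq_along(top$tiles)) {
    paths[i] <- file.path(dir, sprintf("%s_rank%02d_r%d_c%d.png", top$slide_id,
                                       i, top$ranking$row[i], top$ranking$col[i]))
    png::writePNG(pmin(pmax(top$tiles[[i]]$pixels, 0), 255) / 255, paths[i])
  }
  invisible(paths)
}
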