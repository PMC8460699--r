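#' Cut a slide raster into a grid of nonoverlapping tiles
#'
#' The grid is the largest one fitting entirely inside the raster; partial
#' edge tiles are dropped. Tiles are returned in row-major order with 0-based
#' grid coordinates.
#'
#' @param raster height x width x 3 numeric array with pixel values in 0–255,
#'   or a `synthetic_slide` (its image is used and its id propagated).
#' @param tile_size tile edge length in pixels.
#' @param slide_id identifier attached to each tile.
#' @return List of tiles; each tile is a list with `pixels`
#'   (tile_size x tile_size x 3), `grid_pos` (0-based `c(row, col)`), and
#'   `slide_id`. Empty list if the raster is smaller than one tile.
#' @examples
#' r <- array(128, dim = c(64, 96, 3))
#' length(extract_tiles(r, 32))  # 2 x 3 grid
#' @export
extract_tiles <- function(raster, tile_size = 512L, slide_id = "slide") {
  if (inherits(raster, "synthetic_slide")) {
    slide_id <- raster$slide_id
    raster <- raster$image
  }
  tile_size <- check_scalar_int(tile_size, "tile_size")
  if (length(dim(raster)) != 3L || dim(raster)[3L] != 3L)
    stop_arg("`raster` must be a height x width x 3 array")
  nr <- dim(raster)[1L] %/% tile_size
  nc <- dim(raster)[2L] %/% tile_size
  if (nr < 1L || nc < 1L) return(list())
  tiles <- vector("list", nr * nc)
  k <- 0L
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      k <- k + 1L
      rows <- ((r - 1L) * tile_size + 1L):(r * tile_size)
      cols <- ((cc - 1L) * tile_size + 1L):(cc * tile_size)
      tiles[[k]] <- list(pixels = raster[rows, cols, , drop = FALSE],
                         grid_pos = c(row = r - 1L, col = cc - 1L),
                         slide_id = slide_id)
    }
  }
  tiles
}

#' Background test for a tile
#'
#' A tile is background when its mean pixel value, taken over all pixels and
#' channels, is strictly higher than the threshold (default 220 on the 0–255
#' scale). A tile with mean exactly at the threshold is tissue.
#'
#' @param tile a tile (list with `pixels`) or a bare pixel array.
#' @param threshold background threshold on the 0–255 scale.
#' @return `TRUE` if background.
#' @export
is_background <- function(tile, threshold = 220) {
  px <- if (is.list(tile)) tile$pixels else tile
  mean(px) > threshold
}

#' Downsample a tile and flatten it into a feature vector
#'
#' The tile is area-resampled (box filter) to `side` x `side` per channel and
#' flattened channel by channel (column-major within each channel), giving a
#' vector of length `side^2 * 3`. With the defaults (512 px tiles, side 128)
#' the vector has length 49,152. `side = 1` yields the three per-channel tile
#' means.
#'
#' @param tile a square RGB tile (list with `pixels`) or pixel array.
#' @param side output resolution per edge.
#' @return Numeric vector of length `side * side * 3`.
#' @export
downsample_flatten <- function(tile, side = 128L) {
  px <- if (is.list(tile)) tile$pixels else tile
  side <- check_scalar_int(side, "side")
  if (dim(px)[1L] != dim(px)[2L]) stop_arg("tile must be square")
  as.vector(area_resize(px, side, side))
}

#' Split a slide's tiles into tumor and nontumor groups by k-means
#'
#' Each tile is downsampled and flattened ([downsample_flatten()]) and the
#' vectors are clustered into two groups with seeded k-means (10 restarts).
#' The cluster whose centroid has the lower mean intensity (luminance) is
#' labelled tumor — tissue is darker than background and stroma. Degenerate
#' input (all tiles identical, so one cluster would be empty) raises a warning
#' and labels every tile tumor. Background tiles should be filtered out before
#' calling this.
#'
#' @param tiles list of tiles (at least 2).
#' @param seed integer seed; fixed seed gives identical assignments.
#' @param side downsampling resolution passed to [downsample_flatten()].
#' @return Object of class `tumor_selection`: data.frame `assignments` with
#'   columns `row`, `col`, `status` ("tumor"/"nontumor"), the two
#'   `cluster_centroids`, and an empty `overrides` set.
#' @export
cluster_tumor_tiles <- function(tiles, seed = 1L, side = 128L) {
  if (length(tiles) < 2L)
    stop_arg("clustering is undefined for fewer than 2 tiles")
  seed <- check_scalar_int(seed, "seed", min = 0L)
  feats <- t(vapply(tiles, downsample_flatten, numeric(side * side * 3L), side = side))
  pos <- t(vapply(tiles, function(t) t$grid_pos, c(row = 0L, col = 0L)))
  degenerate <- nrow(unique(feats)) < 2L
  if (degenerate) {
    warning("degenerate clustering (all tiles identical); labelling all tiles tumor")
    status <- rep("tumor", length(tiles))
    centroids <- rbind(colMeans(feats), colMeans(feats))
  } else {
    km <- withr::with_seed(seed, stats::kmeans(feats, centers = 2L, nstart = 10L))
    # darker centroid (lower mean intensity) = tumor
    tumor_cluster <- which.min(rowMeans(km$centers))
    status <- ifelse(km$cluster == tumor_cluster, "tumor", "nontumor")
    centroids <- km$centers
  }
  structure(
    list(assignments = data.frame(row = pos[, "row"], col = pos[, "col"],
                                  status = status, stringsAsFactors = FALSE),
         cluster_centroids = centroids,
         overrides = data.frame(row = integer(), col = integer(),
                                status = character(), stringsAsFactors = FALSE)),
    class = "tumor_selection"
  )
}

#' @export
print.tumor_selection <- function(x, ...) {
  cat(sprintf("tumor selection: %d tiles (%d tumor, %d nontumor, %d overrides)\n",
              nrow(x$assignments), sum(x$assignments$status == "tumor"),
              sum(x$assignments$status == "nontumor"), nrow(x$overrides)))
  invisible(x)
}

#' Apply manual refinement overrides to a tumor selection
#'
#' Mirrors the pathologist-revision step: forced statuses are applied on top
#' of the clustering result, leaving all other assignments unchanged.
#'
#' @param selection a `tumor_selection` from [cluster_tumor_tiles()].
#' @param overrides data.frame with columns `row`, `col`, `status` where
#'   status is `"force_tumor"` or `"force_exclude"`, or the path of a TSV
#'   file with those columns (columns may also be named tile_row/tile_col).
#' @return The refined `tumor_selection`; forced tiles get status "tumor" or
#'   "nontumor" accordingly and the override set is recorded.
#' @export
apply_refinement <- function(selection, overrides) {
  stopifnot(inherits(selection, "tumor_selection"))
  if (is.character(overrides)) overrides <- utils::read.delim(overrides)
  names(overrides) <- sub("^tile_", "", names(overrides))
  if (nrow(overrides) == 0L) return(selection)
  if (!all(c("row", "col", "status") %in% names(overrides)))
    stop_arg("overrides need columns row, col, status")
  if (!all(overrides$status %in% c("force_tumor", "force_exclude")))
    stop_arg("override status must be force_tumor or force_exclude")
  key <- paste(selection$assignments$row, selection$assignments$col)
  okey <- paste(overrides$row, overrides$col)
  missing <- !okey %in% key
  if (any(missing))
    stop_arg("overrides reference unknown grid positions: ",
             paste(okey[missing], collapse = "; "))
  idx <- match(okey, key)
  selection$assignments$status[idx] <-
    ifelse(overrides$status == "force_tumor", "tumor", "nontumor")
  selection$overrides <- rbind(selection$overrides, overrides)
  selection
}

#' Per-channel colour statistics of a set of tiles
#'
#' Computes the slide-level per-channel pixel mean and standard deviation over
#' all supplied tiles, the statistics used for colour normalization. All tiles
#' of one slide must be normalized with the same slide-level statistics.
#'
#' @param tiles list of tiles.
#' @return Object of class `slide_color_stats`: list with `mean` and `std`
#'   (3-vectors) and `color_space = "RGB"`.
#' @export
slide_color_stats <- function(tiles) {
  if (length(tiles) == 0L) stop_arg("no tiles supplied")
  px <- lapply(tiles, function(t) t$pixels)
  ch <- function(i) unlist(lapply(px, function(p) p[, , i]), use.names = FALSE)
  m <- vapply(1:3, function(i) mean(ch(i)), 0)
  s <- vapply(1:3, function(i) stats::sd(ch(i)), 0)
  structure(list(mean = m, std = s, color_space = "RGB"),
            class = "slide_color_stats")
}

#' Colour-normalize tiles by a slide-level mean/std affine map
#'
#' Per channel c: `out = (in - source$mean[c]) / source$std[c] * target$std[c]
#' + target$mean[c]`, clipped to \[0, 255\]. `source` must be the statistics of
#' the slide the tiles come from (typically over its tumor tiles); `target`
#' is a common reference so slides become comparable.
#'
#' @param tiles list of tiles.
#' @param source,target `slide_color_stats` objects.
#' @return List of tiles with mapped pixel values; metadata unchanged.
#' @export
normalize_colors <- function(tiles, source, target) {
  stopifnot(inherits(source, "slide_color_stats"),
            inherits(target, "slide_color_stats"))
  if (any(source$std <= 0))
    stop_arg("source std has a non-positive component (flat channel)")
  lapply(tiles, function(t) {
    px <- t$pixels
    for (ch in 1:3)
      px[, , ch] <- (px[, , ch] - source$mean[ch]) / source$std[ch] *
        target$std[ch] + target$mean[ch]
    t$pixels <- pmin(pmax(px, 0), 255)
    t
  })
}

#' Write slide colour statistics to JSON
#' @param stats a `slide_color_stats`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_color_stats <- function(stats, path) {
  jsonlite::write_json(list(mean = stats$mean, std = stats$std,
                            color_space = stats$color_space),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read slide colour statistics from JSON
#' @param path JSON path written by [write_color_stats()].
#' @return A `slide_color_stats`.
#' @export
read_color_stats <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(mean = x$mean, std = x$std,
                 color_space = x$color_space %||% "RGB"),
            class = "slide_color_stats")
}

#' Write a tumor selection (or any tile-status table) to TSV
#' @param selection a `tumor_selection`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_selection_tsv <- function(selection, path) {
  df <- selection$assignments
  names(df)[1:2] <- c("tile_row", "tile_col")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the tile-level preprocessing chain on one slide
#'
#' Convenience composition: extract tiles, drop background tiles, cluster the
#' rest into tumor/nontumor (with optional refinement overrides), keep the
#' tumor tiles and colour-normalize them against `target_stats` using the
#' slide-level statistics of the tumor tiles themselves. Grid positions are
#' preserved end to end.
#'
#' @param raster slide raster or `synthetic_slide`.
#' @param tile_size tile edge length in pixels.
#' @param background_threshold mean-intensity threshold for background tiles.
#' @param target_stats `slide_color_stats` reference; `NULL` skips
#'   normalization.
#' @param overrides optional refinement overrides (see [apply_refinement()]).
#' @param seed seed for the tumor clustering.
#' @param side downsampling resolution for clustering features.
#' @return List with `tiles` (normalized tumor tiles), `selection`, `stats`
#'   (source slide statistics), and `counts` per stage.
#' @export
preprocess_slide <- function(raster, tile_size = 512L, background_threshold = 220,
                             target_stats = NULL, overrides = NULL, seed = 1L,
                             side = 128L) {
  tiles <- extract_tiles(raster, tile_size)
  n_total <- length(tiles)
  fg <- Filter(function(t) !is_background(t, background_threshold), tiles)
  if (length(fg) < 2L)
    stop_arg("fewer than 2 foreground tiles; cannot select tumor tiles")
  sel <- cluster_tumor_tiles(fg, seed = seed, side = side)
  if (!is.null(overrides)) sel <- apply_refinement(sel, overrides)
  keep <- sel$assignments$status == "tumor"
  key <- paste(sel$assignments$row, sel$assignments$col)
  tkey <- vapply(fg, function(t) paste(t$grid_pos[1], t$grid_pos[2]), "")
  tumor_tiles <- fg[tkey %in% key[keep]]
  stats <- slide_color_stats(tumor_tiles)
  out <- if (is.null(target_stats)) tumor_tiles else
    normalize_colors(tumor_tiles, stats, target_stats)
  list(tiles = out, selection = sel, stats = stats,
       counts = c(total = n_total, foreground = length(fg),
                  tumor = length(tumor_tiles)))
}
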