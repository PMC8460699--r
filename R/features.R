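#' ImageNet channel statistics
#'
#' The per-channel mean and standard deviation conventionally used to
#' standardize natural-image inputs; the defaults for [prepare_tile()].
#' @format Numeric 3-vectors (R, G, B).
#' @export
imagenet_mean <- c(0.485, 0.456, 0.406)

#' @rdname imagenet_mean
#' @export
imagenet_std <- c(0.229, 0.224, 0.225)

#' Prepare a tile tensor for feature extraction
#'
#' Scales pixel values from \[0, 255\] to \[0, 1\], area-resamples to
#' `side` x `side` (default 224), and standardizes each channel by the
#' configured mean and standard deviation (defaults: the ImageNet constants).
#'
#' @param tile tile (list with `pixels`) or pixel array in 0–255.
#' @param side output spatial size.
#' @param channel_mean,channel_std per-channel statistics on the \[0, 1\]
#'   scale.
#' @return `side` x `side` x 3 numeric array.
#' @export
prepare_tile <- function(tile, side = 224L, channel_mean = imagenet_mean,
                         channel_std = imagenet_std) {
  px <- if (is.list(tile)) tile$pixels else tile
  side <- check_scalar_int(side, "side")
  x <- area_resize(px / 255, side, side)
  for (ch in 1:3)
    x[, , ch] <- (x[, , ch] - channel_mean[ch]) / channel_std[ch]
  x
}

#' Construct a tile feature extractor
#'
#' A feature extractor is a frozen, deterministic map from a prepared tile
#' tensor to a fixed-length feature vector. Extractor parameters are never
#' updated anywhere in the pipeline; only the aggregation head is trained.
#' Any backbone honouring this contract (e.g. the convolutional layers of a
#' pretrained deep network) can be wrapped with this constructor; the package
#' ships [projection_extractor()] as its built-in implementation.
#'
#' @param id identifier recorded with every bag and cache entry.
#' @param dim output feature dimension.
#' @param side input spatial size expected by `fn`.
#' @param fn function taking a `side` x `side` x 3 tensor and returning a
#'   numeric vector of length `dim`.
#' @param channel_mean,channel_std channel statistics used by
#'   [prepare_tile()] for this extractor.
#' @return Object of class `feature_extractor`.
#' @export
feature_extractor <- function(id, dim, side, fn,
                              channel_mean = imagenet_mean,
                              channel_std = imagenet_std) {
  stopifnot(is.function(fn))
  structure(list(id = id, dim = check_scalar_int(dim, "dim"),
                 side = check_scalar_int(side, "side"), fn = fn,
                 channel_mean = channel_mean, channel_std = channel_std),
            class = "feature_extractor")
}

#' @export
print.feature_extractor <- function(x, ...) {
  cat(sprintf("feature extractor '%s': %dx%d tile -> %d-dim vector\n",
              x$id, x$side, x$side, x$dim))
  invisible(x)
}

#' Seeded random-projection feature extractor
#'
#' A deterministic, frozen extractor: the prepared tile is area-downsampled to
#' `proj_side` per edge, flattened, and mapped through a fixed Gaussian
#' random projection (seeded, scaled by `1/sqrt(input dim)`). The default
#' output dimension is 2048, matching the feature width the aggregation head
#' expects from a convolutional backbone; a small configuration (e.g.
#' `dim = 64, proj_side = 8`) is convenient for fast tests.
#'
#' @param dim output feature dimension (default 2048).
#' @param side input tile size after [prepare_tile()] (default 224).
#' @param proj_side internal downsampling resolution before projection.
#' @param seed seed fixing the projection matrix.
#' @param channel_mean,channel_std channel statistics for preparation.
#' @return A [feature_extractor()].
#' @examples
#' ex <- projection_extractor(dim = 16, side = 32, proj_side = 8, seed = 1)
#' ex$dim
#' @export
projection_extractor <- function(dim = 2048L, side = 224L, proj_side = 32L,
                                 seed = 1L, channel_mean = imagenet_mean,
                                 channel_std = imagenet_std) {
  dim <- check_scalar_int(dim, "dim")
  proj_side <- check_scalar_int(proj_side, "proj_side")
  in_dim <- proj_side * proj_side * 3L
  P <- withr::with_seed(seed,
    matrix(stats::rnorm(dim * in_dim, sd = 1 / sqrt(in_dim)), dim, in_dim))
  fn <- function(tensor) {
    v <- as.vector(area_resize(tensor, proj_side, proj_side))
    drop(P %*% v)
  }
  feature_extractor(id = sprintf("proj%d_p%d_seed%d", dim, proj_side, seed),
                    dim = dim, side = side, fn = fn,
                    channel_mean = channel_mean, channel_std = channel_std)
}

#' Construct a feature bag
#'
#' One patient's bag of tile features: an N x D matrix whose rows align 1:1
#' with the tile grid positions.
#'
#' @param patient_id patient identifier.
#' @param features N x D numeric matrix (N >= 1).
#' @param tile_positions N x 2 matrix of 0-based grid coordinates
#'   (columns row, col).
#' @param extractor_id identifier of the extractor that produced the rows.
#' @return Object of class `feature_bag`.
#' @export
feature_bag <- function(patient_id, features, tile_positions, extractor_id) {
  features <- as.matrix(features)
  tile_positions <- as.matrix(tile_positions)
  if (nrow(features) < 1L) stop_arg("a bag needs at least one tile")
  if (nrow(tile_positions) != nrow(features))
    stop_arg("tile_positions rows must align with feature rows")
  colnames(tile_positions) <- c("row", "col")
  structure(list(patient_id = patient_id, features = features,
                 tile_positions = tile_positions, extractor_id = extractor_id),
            class = "feature_bag")
}

#' @export
print.feature_bag <- function(x, ...) {
  cat(sprintf("feature bag '%s': %d tiles x %d features (%s)\n",
              x$patient_id, nrow(x$features), ncol(x$features), x$extractor_id))
  invisible(x)
}

#' Extract a feature bag from a list of tiles
#'
#' Runs `extractor` over each tile (after [prepare_tile()] with the
#' extractor's input size and channel statistics) and stacks the vectors into
#' the patient's N x D bag. Row i corresponds to `tiles[[i]]`.
#'
#' @param tiles nonempty list of tiles.
#' @param extractor a [feature_extractor()].
#' @param patient_id patient identifier for the bag.
#' @return A [feature_bag()].
#' @export
extract_features <- function(tiles, extractor, patient_id = "patient") {
  stopifnot(inherits(extractor, "feature_extractor"))
  if (length(tiles) == 0L) stop_arg("no tiles supplied")
  rows <- lapply(tiles, function(t) {
    v <- extractor$fn(prepare_tile(t, extractor$side,
                                   extractor$channel_mean, extractor$channel_std))
    if (length(v) != extractor$dim)
      stop_arg(sprintf("extractor returned %d values, expected %d",
                       length(v), extractor$dim))
    v
  })
  pos <- t(vapply(tiles, function(t) t$grid_pos, c(row = 0L, col = 0L)))
  feature_bag(patient_id, do.call(rbind, rows), pos, extractor$id)
}
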