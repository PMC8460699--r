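#' Generate a synthetic slide with planted tissue and signal tiles
#'
#' Draws an RGB raster organised as a grid of square tiles. Background tiles
#' are near-white (uniform in \[230, 255\] per channel, so their mean pixel
#' value always exceeds the 220 background threshold), tissue tiles carry a
#' darker texture (values in \[80, 200\]), and a subset of tissue tiles — the
#' "signal" tiles — get a distinct colour tint so they are separable both by
#' clustering in pixel space and, downstream, by any extractor that sees pixel
#' intensities. The tile-resolution tissue and signal masks are returned as
#' ground truth.
#'
#' @param width_tiles,height_tiles grid size in tiles (>= 1).
#' @param tissue_fraction fraction of tiles carrying tissue texture, in \[0, 1\].
#' @param signal_fraction fraction of tissue tiles carrying the
#'   label-predictive tint, in \[0, 1\].
#' @param tile_size tile edge length in pixels (>= 8).
#' @param seed integer seed; identical seeds give bit-identical slides.
#' @param slide_id identifier stored with the slide.
#' @return An object of class `synthetic_slide`: list with `image`
#'   (height x width x 3 integer array, 0–255), `tissue_mask` and
#'   `signal_mask` (logical tile-grid matrices), `slide_id`, `tile_size`,
#'   `seed`.
#' @examples
#' sl <- generate_slide(6, 4, tissue_fraction = 0.5, signal_fraction = 0.4,
#'                      tile_size = 16, seed = 1)
#' sum(sl$tissue_mask)
#' @export
generate_slide <- function(width_tiles, height_tiles, tissue_fraction = 0.6,
                           signal_fraction = 0.3, tile_size = 32L, seed = 1L,
                           slide_id = sprintf("synth%03d", seed)) {
  width_tiles <- check_scalar_int(width_tiles, "width_tiles")
  height_tiles <- check_scalar_int(height_tiles, "height_tiles")
  tile_size <- check_scalar_int(tile_size, "tile_size", min = 8L)
  tissue_fraction <- check_fraction(tissue_fraction, "tissue_fraction")
  signal_fraction <- check_fraction(signal_fraction, "signal_fraction")
  seed <- check_scalar_int(seed, "seed", min = 0L)

  n <- width_tiles * height_tiles
  npx <- tile_size * tile_size
  tissue_base <- c(170, 120, 150)   # H&E-like pink/purple tissue
  signal_base <- c(105, 90, 175)    # bluer tint for signal tiles

  withr::with_seed(seed, {
    tissue_mask <- matrix(FALSE, height_tiles, width_tiles)
    n_tissue <- round(tissue_fraction * n)
    tissue_idx <- sample.int(n, n_tissue)
    tissue_mask[tissue_idx] <- TRUE
    signal_mask <- matrix(FALSE, height_tiles, width_tiles)
    n_signal <- round(signal_fraction * n_tissue)
    if (n_signal > 0)
      signal_mask[sample(tissue_idx, n_signal)] <- TRUE

    img <- array(0L, dim = c(height_tiles * tile_size, width_tiles * tile_size, 3L))
    for (r in seq_len(height_tiles)) {
      for (cc in seq_len(width_tiles)) {
        rows <- ((r - 1L) * tile_size + 1L):(r * tile_size)
        cols <- ((cc - 1L) * tile_size + 1L):(cc * tile_size)
        if (!tissue_mask[r, cc]) {
          block <- array(stats::runif(npx * 3L, 230, 255), dim = c(tile_size, tile_size, 3L))
        } else {
          base <- if (signal_mask[r, cc]) signal_base else tissue_base
          block <- array(0, dim = c(tile_size, tile_size, 3L))
          for (ch in 1:3)
            block[, , ch] <- pmin(pmax(base[ch] + stats::runif(npx, -45, 45), 80), 200)
        }
        img[rows, cols, ] <- as.integer(round(block))
      }
    }
  })
  structure(
    list(image = img, tissue_mask = tissue_mask, signal_mask = signal_mask,
         slide_id = slide_id, tile_size = tile_size, seed = seed),
    class = "synthetic_slide"
  )
}

#' @export
print.synthetic_slide <- function(x, ...) {
  cat(sprintf("synthetic slide '%s': %d x %d tiles of %d px (%d tissue, %d signal)\n",
              x$slide_id, nrow(x$tissue_mask), ncol(x$tissue_mask), x$tile_size,
              sum(x$tissue_mask), sum(x$signal_mask)))
  invisible(x)
}

#' Generate synthetic feature bags with planted instance-level signal
#'
#' Builds a multiple-instance data set: each bag is one patient's tile-feature
#' matrix. Noise instances are standard normal; in positive bags a fraction of
#' instances is flagged and shifted by `effect_size` along a fixed unit
#' direction. A bag carries label 1 if and only if it contains at least one
#' flagged instance, and bag sizes vary across bags.
#'
#' @param n_bags number of bags (>= 2; both labels are always represented).
#' @param bag_size_range integer pair, inclusive range of bag sizes.
#' @param signal_fraction fraction of instances flagged in a positive bag,
#'   in (0, 1\]; at least one instance is always flagged.
#' @param dim feature dimension (>= 2).
#' @param effect_size shift magnitude along the signal direction.
#' @param seed integer seed.
#' @param direction optional unit vector of length `dim` giving the signal
#'   direction; defaults to the constant direction `rep(1, dim) / sqrt(dim)`.
#' @return An object of class `bag_set`: list with `bags` (list of
#'   [feature_bag()]), `bag_labels` (0/1 vector), `instance_flags` (list of
#'   0/1 vectors aligned with bag rows), and `generation_params`.
#' @examples
#' bs <- generate_feature_bags(10, c(5, 12), 0.3, dim = 8, effect_size = 2, seed = 1)
#' bs$bag_labels
#' @export
generate_feature_bags <- function(n_bags, bag_size_range = c(20L, 50L),
                                  signal_fraction = 0.3, dim = 32L,
                                  effect_size = 4, seed = 1L, direction = NULL) {
  n_bags <- check_scalar_int(n_bags, "n_bags", min = 2L)
  dim <- check_scalar_int(dim, "dim", min = 2L)
  seed <- check_scalar_int(seed, "seed", min = 0L)
  if (length(bag_size_range) != 2L || any(bag_size_range < 1) ||
      bag_size_range[1] > bag_size_range[2])
    stop_arg("`bag_size_range` must be an increasing pair of positive integers")
  if (signal_fraction <= 0 || signal_fraction > 1)
    stop_arg("`signal_fraction` must be in (0, 1] for positive bags")
  if (is.null(direction)) direction <- rep(1, dim) / sqrt(dim)
  if (length(direction) != dim)
    stop_arg("`direction` must have length `dim`")
  direction <- direction / sqrt(sum(direction^2))

  withr::with_seed(seed, {
    n_pos <- max(1L, round(n_bags / 2))
    labels <- sample(rep(c(1L, 0L), c(n_pos, n_bags - n_pos)))
    bags <- vector("list", n_bags)
    flags <- vector("list", n_bags)
    for (b in seq_len(n_bags)) {
      N <- sample(seq(bag_size_range[1], bag_size_range[2]), 1L)
      x <- matrix(stats::rnorm(N * dim), N, dim)
      fl <- integer(N)
      if (labels[b] == 1L) {
        n_flag <- max(1L, round(signal_fraction * N))
        idx <- sample.int(N, n_flag)
        fl[idx] <- 1L
        x[idx, ] <- x[idx, , drop = FALSE] +
          matrix(effect_size * direction, n_flag, dim, byrow = TRUE)
      }
      w <- ceiling(sqrt(N))
      pos <- cbind(row = (seq_len(N) - 1L) %/% w, col = (seq_len(N) - 1L) %% w)
      bags[[b]] <- feature_bag(sprintf("P%04d", b), x, pos,
                               extractor_id = "synthetic")
      flags[[b]] <- fl
    }
  })
  structure(
    list(bags = bags, bag_labels = labels, instance_flags = flags,
         generation_params = list(n_bags = n_bags, bag_size_range = bag_size_range,
                                  signal_fraction = signal_fraction, dim = dim,
                                  effect_size = effect_size, seed = seed)),
    class = "bag_set"
  )
}

#' @export
print.bag_set <- function(x, ...) {
  cat(sprintf("bag set: %d bags (%d positive), dim %d, sizes %d-%d\n",
              length(x$bags), sum(x$bag_labels), x$generation_params$dim,
              min(vapply(x$bags, function(b) nrow(b$features), 1L)),
              max(vapply(x$bags, function(b) nrow(b$features), 1L))))
  invisible(x)
}

#' Generate synthetic omics tables with planted ground truth
#'
#' Produces per-patient mutation, copy-number and expression tables whose
#' structure downstream label derivation can recover. Mutation calls are
#' Bernoulli draws at each gene's planted prevalence. Every pathway gets a
#' planted per-patient activity sign; expression of a member gene n with
#' oncogene/suppressor weight w_n is `w_n * sign * effect + noise`, so the
#' weighted-mean pathway score recovers the planted sign. Copy-number calls of
#' member genes are the analogous discrete (GISTIC-style, -2..2) values;
#' non-member genes get discrete calls at their planted prevalence.
#'
#' @param n_patients number of patients.
#' @param gene_specs data.frame with columns `gene`, `prevalence` (in \[0,1\])
#'   and optionally `role`; one row per gene, names unique.
#' @param pathway_defs optional pathway-definition data.frame (columns
#'   `pathway`, `gene`, `role`), e.g. from [read_pathway_defs()]. Member genes
#'   are added to the tables if absent from `gene_specs`.
#' @param effect planted expression effect size for member genes.
#' @param noise_sd expression noise standard deviation.
#' @param seed integer seed.
#' @return Object of class `synthetic_omics`: `mutation`, `cna`, `expression`
#'   ([omics_table()] objects, genes x patients), and `truth` (planted
#'   prevalences and the patients x pathways activity-sign matrix).
#' @examples
#' gs <- data.frame(gene = c("TP53", "PIK3CA"), prevalence = c(0.3, 0.2))
#' om <- generate_omics(50, gs, seed = 1)
#' rowMeans(om$mutation$values)
#' @export
generate_omics <- function(n_patients, gene_specs, pathway_defs = NULL,
                           effect = 2, noise_sd = 1, seed = 1L) {
  n_patients <- check_scalar_int(n_patients, "n_patients")
  seed <- check_scalar_int(seed, "seed", min = 0L)
  if (!is.data.frame(gene_specs) || !all(c("gene", "prevalence") %in% names(gene_specs)))
    stop_arg("`gene_specs` must be a data.frame with columns gene, prevalence")
  if (anyDuplicated(gene_specs$gene))
    stop_arg("duplicate gene names in `gene_specs`: ",
             paste(unique(gene_specs$gene[duplicated(gene_specs$gene)]), collapse = ", "))
  if (any(gene_specs$prevalence < 0 | gene_specs$prevalence > 1))
    stop_arg("prevalences must be in [0, 1]")
  if (!is.null(pathway_defs)) pathway_defs <- validate_pathway_defs(pathway_defs)

  patients <- sprintf("S%04d", seq_len(n_patients))
  member_genes <- if (is.null(pathway_defs)) character() else unique(pathway_defs$gene)
  genes <- union(gene_specs$gene, member_genes)
  prev <- stats::setNames(rep(0.05, length(genes)), genes)  # default for pathway-only genes
  prev[gene_specs$gene] <- gene_specs$prevalence

  withr::with_seed(seed, {
    mut <- matrix(stats::rbinom(length(genes) * n_patients, 1L, rep(prev, n_patients)),
                  nrow = length(genes), dimnames = list(genes, patients))
    expr <- matrix(stats::rnorm(length(genes) * n_patients, 0, noise_sd),
                   nrow = length(genes), dimnames = list(genes, patients))
    cna <- matrix(0L, length(genes), n_patients, dimnames = list(genes, patients))
    # non-member genes: discrete calls at planted prevalence
    for (g in setdiff(genes, member_genes)) {
      altered <- stats::rbinom(n_patients, 1L, prev[g]) == 1L
      cna[g, altered] <- sample(c(-2L, -1L, 1L, 2L), sum(altered), replace = TRUE)
    }
    activity <- NULL
    if (!is.null(pathway_defs)) {
      pws <- unique(pathway_defs$pathway)
      activity <- matrix(sample(c(-1, 1), n_patients * length(pws), replace = TRUE),
                         n_patients, length(pws), dimnames = list(patients, pws))
      for (k in seq_len(nrow(pathway_defs))) {
        g <- pathway_defs$gene[k]
        w <- if (pathway_defs$role[k] == "oncogene") 1 else -1
        a <- activity[, pathway_defs$pathway[k]]
        expr[g, ] <- w * a * effect + stats::rnorm(n_patients, 0, noise_sd)
        cna[g, ] <- pmin(pmax(round(w * a * 1.5 + stats::rnorm(n_patients, 0, 0.7)), -2L), 2L)
      }
    }
  })
  structure(
    list(mutation = omics_table(mut, "point_mutation"),
         cna = omics_table(cna, "cna"),
         expression = omics_table(expr, "expression"),
         truth = list(prevalence = prev, pathway_activity = activity),
         seed = seed),
    class = "synthetic_omics"
  )
}

#' Write a synthetic slide and its masks to disk
#'
#' The raster goes to `<dir>/<slide_id>.png`; the tile-resolution masks go to
#' `<dir>/<slide_id>_masks.tsv` with columns tile_row, tile_col, is_tissue,
#' is_signal (0-based grid coordinates).
#'
#' @param slide a `synthetic_slide`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the two file paths.
#' @export
write_slide <- function(slide, dir) {
  stopifnot(inherits(slide, "synthetic_slide"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  png_path <- file.path(dir, paste0(slide$slide_id, ".png"))
  png::writePNG(slide$image / 255, png_path)
  grid <- expand.grid(tile_col = seq_len(ncol(slide$tissue_mask)) - 1L,
                      tile_row = seq_len(nrow(slide$tissue_mask)) - 1L)
  grid <- grid[, c("tile_row", "tile_col")]
  grid$is_tissue <- as.integer(slide$tissue_mask[cbind(grid$tile_row + 1L, grid$tile_col + 1L)])
  grid$is_signal <- as.integer(slide$signal_mask[cbind(grid$tile_row + 1L, grid$tile_col + 1L)])
  tsv_path <- file.path(dir, paste0(slide$slide_id, "_masks.tsv"))
  utils::write.table(grid, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(png_path, tsv_path))
}

#' Read a slide raster from a PNG file
#'
#' @param path PNG path.
#' @return height x width x 3 numeric array with values in 0–255.
#' @export
read_slide_raster <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  round(img[, , 1:3, drop = FALSE] * 255)
}

#' Write an omics table to TSV (genes in rows, patients in columns)
#' @param table an [omics_table()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_omics_tsv <- function(table, path) {
  stopifnot(inherits(table, "omics_table"))
  df <- data.frame(gene = rownames(table$values), table$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an omics TSV written by [write_omics_tsv()]
#' @param path TSV path; first column `gene`, remaining columns patients.
#' @param kind one of "expression", "cna", "point_mutation".
#' @return An [omics_table()].
#' @export
read_omics_tsv <- function(path, kind) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  omics_table(m, kind)
}
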