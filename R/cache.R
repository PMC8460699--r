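#' Open (or create) an on-disk feature cache
#'
#' Feature bags are extracted once and cached so training never re-reads
#' images. The cache is a directory holding one binary matrix file and one
#' tile-position TSV per patient, plus `manifest.tsv` recording
#' (patient_id, n_tiles, dim, extractor_id, checksum). Reads verify the md5
#' checksum and fail loudly on corruption.
#'
#' @param path cache directory; created if missing.
#' @return Object of class `feature_cache`.
#' @export
feature_cache <- function(path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  mf <- file.path(path, "manifest.tsv")
  if (!file.exists(mf))
    utils::write.table(
      data.frame(patient_id = character(), n_tiles = integer(), dim = integer(),
                 extractor_id = character(), checksum = character()),
      mf, sep = "\t", quote = FALSE, row.names = FALSE)
  structure(list(path = path), class = "feature_cache")
}

read_manifest <- function(cache) {
  utils::read.delim(file.path(cache$path, "manifest.tsv"),
                    colClasses = c("character", "integer", "integer",
                                   "character", "character"))
}

write_manifest <- function(cache, manifest) {
  utils::write.table(manifest, file.path(cache$path, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a feature bag to the cache
#'
#' The feature matrix is stored column-major as little-endian doubles; a
#' round-trip through [read_cache()] is bit-exact. Re-writing a patient
#' replaces the previous entry.
#'
#' @param cache a [feature_cache()].
#' @param bag a [feature_bag()].
#' @return Invisibly, the cache.
#' @export
write_cache <- function(cache, bag) {
  stopifnot(inherits(cache, "feature_cache"), inherits(bag, "feature_bag"))
  bin <- file.path(cache$path, paste0(bag$patient_id, ".bin"))
  con <- file(bin, "wb")
  writeBin(as.vector(bag$features), con, size = 8L, endian = "little")
  close(con)
  utils::write.table(as.data.frame(bag$tile_positions),
                     file.path(cache$path, paste0(bag$patient_id, "_pos.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- read_manifest(cache)
  manifest <- manifest[manifest$patient_id != bag$patient_id, , drop = FALSE]
  manifest <- rbind(manifest, data.frame(
    patient_id = bag$patient_id, n_tiles = nrow(bag$features),
    dim = ncol(bag$features), extractor_id = bag$extractor_id,
    checksum = md5_of_file(bin)))
  write_manifest(cache, manifest)
  invisible(cache)
}

#' Read a feature bag back from the cache
#'
#' @param cache a [feature_cache()].
#' @param patient_id patient to read.
#' @return The cached [feature_bag()].
#' @export
read_cache <- function(cache, patient_id) {
  stopifnot(inherits(cache, "feature_cache"))
  manifest <- read_manifest(cache)
  row <- manifest[manifest$patient_id == patient_id, , drop = FALSE]
  if (nrow(row) == 0L)
    stop_arg("patient '", patient_id, "' not found in cache")
  bin <- file.path(cache$path, paste0(patient_id, ".bin"))
  if (!file.exists(bin))
    stop_arg("cache file missing for patient '", patient_id, "'")
  if (!identical(md5_of_file(bin), row$checksum))
    stop_arg("cache corruption: checksum mismatch for patient '", patient_id, "'")
  con <- file(bin, "rb")
  vals <- readBin(con, "double", n = row$n_tiles * row$dim, size = 8L,
                  endian = "little")
  close(con)
  pos <- as.matrix(utils::read.delim(
    file.path(cache$path, paste0(patient_id, "_pos.tsv"))))
  feature_bag(patient_id, matrix(vals, row$n_tiles, row$dim), pos,
              row$extractor_id)
}

#' List patients present in a cache
#' @param cache a [feature_cache()].
#' @return The manifest data.frame.
#' @export
cache_manifest <- function(cache) read_manifest(cache)
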