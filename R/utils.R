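# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_arg <- function(...) stop(..., call. = FALSE)

check_scalar_int <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != as.integer(x) || x < min)
    stop_arg(sprintf("`%s` must be a single integer >= %d", name, min))
  as.integer(x)
}

check_fraction <- function(x, name, lo = 0, hi = 1) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < lo || x > hi)
    stop_arg(sprintf("`%s` must be a single number in [%g, %g]", name, lo, hi))
  as.numeric(x)
}

# row-wise softmax with max-shift stabilisation
softmax_rows <- function(s) {
  e <- exp(s - apply(s, 1L, max))
  e / rowSums(e)
}

relu <- function(x) pmax(x, 0)

# averaging matrix for area (box) resampling: out = A %*% in
box_matrix <- function(n_out, n_in) {
  s <- n_in / n_out
  A <- matrix(0, n_out, n_in)
  for (o in seq_len(n_out)) {
    lo <- (o - 1) * s
    hi <- o * s
    for (i in (floor(lo) + 1L):min(ceiling(hi), n_in)) {
      ov <- min(i, hi) - max(i - 1L, lo)
      if (ov > 0) A[o, i] <- ov / s
    }
  }
  A
}

# area-resample an h x w x 3 (or h x w) array
area_resize <- function(img, out_h, out_w) {
  A <- box_matrix(out_h, dim(img)[1L])
  B <- box_matrix(out_w, dim(img)[2L])
  if (length(dim(img)) == 2L) return(A %*% img %*% t(B))
  out <- array(0, dim = c(out_h, out_w, dim(img)[3L]))
  for (ch in seq_len(dim(img)[3L])) out[, , ch] <- A %*% img[, , ch] %*% t(B)
  out
}

md5_of_file <- function(path) unname(tools::md5sum(path))
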