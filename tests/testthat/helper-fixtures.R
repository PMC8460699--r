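# shared fixtures: small deterministic objects built in code

# a constant-valued square tile
const_tile <- function(value, size = 16L, pos = c(row = 0L, col = 0L),
                       slide_id = "t") {
  list(pixels = array(value, dim = c(size, size, 3L)), grid_pos = pos,
       slide_id = slide_id)
}

# a seeded random tile with values in [lo, hi]
random_tile <- function(seed, size = 16L, lo = 0, hi = 255,
                        pos = c(row = 0L, col = 0L), slide_id = "t") {
  withr::with_seed(seed, {
    px <- array(runif(size * size * 3L, lo, hi), dim = c(size, size, 3L))
  })
  list(pixels = px, grid_pos = pos, slide_id = slide_id)
}

# small extractor for fast feature tests
test_extractor <- function(seed = 1L, dim = 12L) {
  projection_extractor(dim = dim, side = 16L, proj_side = 8L, seed = seed)
}

# small model dimensions for fast training tests
small_config <- function(epochs = 3L, seed = 1L) {
  mil_config(epochs = epochs, hidden = c(16L, 8L), d_attn = 4L, seed = seed)
}

# brute-force AUC by counting positive-negative pairs
pairwise_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg)
    total <- total + (p > n) + 0.5 * (p == n)
  total / (length(pos) * length(neg))
}
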