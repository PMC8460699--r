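test_that("attention algebra on degenerate bags", {
  p <- mil_params(6, hidden = c(8L, 6L), d_attn = 3L, seed = 1)

  # N = 1: single-element softmax
  h1 <- matrix(rnorm(6), 1, 6)
  st <- attention_forward(h1, p)
  expect_equal(st$alpha, matrix(1, 1, 1))
  expect_equal(st$o, h1)
  expect_equal(st$y_global, drop((1 + p$gamma) * h1), ignore_attr = TRUE)

  # gamma = 0: attention has no effect on the pooled output
  p0 <- p; p0$gamma <- 0
  withr::with_seed(2, h <- matrix(rnorm(5 * 6), 5, 6))
  st0 <- attention_forward(h, p0)
  expect_equal(st0$y_global, colMeans(h), tolerance = 1e-12)

  expect_error(attention_forward(matrix(c(1, NA), 1, 2), p), "non-finite")
})

test_that("attention matches an explicit-loop oracle on small random bags", {
  for (trial in 1:10) {
    withr::with_seed(trial, {
      N <- sample(2:8, 1)
      d <- 6L
      h <- matrix(rnorm(N * d), N, d)
    })
    p <- mil_params(d, hidden = c(8L, d), d_attn = 3L, seed = trial)
    st <- attention_forward(h, p)

    # brute force, no matrix shortcuts
    f <- matrix(0, N, 3); g <- matrix(0, N, 3)
    for (i in 1:N) for (k in 1:3) {
      f[i, k] <- sum(h[i, ] * p$Wf[, k])
      g[i, k] <- sum(h[i, ] * p$Wg[, k])
    }
    alpha <- matrix(0, N, N)
    for (j in 1:N) {
      sc <- numeric(N)
      for (i in 1:N) sc[i] <- sum(f[i, ] * g[j, ])
      alpha[j, ] <- exp(sc - max(sc)) / sum(exp(sc - max(sc)))
    }
    o <- matrix(0, N, d)
    for (j in 1:N) for (i in 1:N) o[j, ] <- o[j, ] + alpha[j, i] * h[i, ]
    y <- numeric(d)
    for (j in 1:N) y <- y + (h[j, ] + p$gamma * o[j, ]) / N

    expect_equal(st$alpha, alpha, tolerance = 1e-6)
    expect_equal(st$o, o, tolerance = 1e-6)
    expect_equal(st$y_global, y, tolerance = 1e-6)
    expect_equal(rowSums(st$alpha), rep(1, N), tolerance = 1e-6)
    expect_true(all(st$alpha > 0 & st$alpha < 1 | N == 1))
  }
})

test_that("tile weights are one plus gamma times attention received", {
  # gamma = 0 -> all weights 1
  a <- matrix(1 / 3, 3, 3)
  expect_equal(tile_weights(a, 0)$beta, rep(1, 3))
  # N = 1, gamma = 1 -> beta = 2
  expect_equal(tile_weights(matrix(1, 1, 1), 1)$beta, 2)
  # column sums of a row-stochastic matrix total N, so sum(beta) = N(1+gamma)
  withr::with_seed(5, {
    for (trial in 1:5) {
      N <- sample(2:10, 1)
      alpha <- matrix(rexp(N * N), N, N)
      alpha <- alpha / rowSums(alpha)
      gam <- runif(1, 0, 2)
      expect_equal(sum(tile_weights(alpha, gam)$beta), N * (1 + gam),
                   tolerance = 1e-9)
    }
  })
})

test_that("model forward is permutation and duplication invariant", {
  p <- mil_params(10, hidden = c(12L, 8L), d_attn = 4L, seed = 3)
  withr::with_seed(4, x <- matrix(rnorm(7 * 10), 7, 10))
  out <- model_forward(x, p)
  expect_equal(sum(out$prob), 1, tolerance = 1e-12)

  perm <- c(4, 1, 7, 3, 6, 2, 5)
  out_p <- model_forward(x[perm, ], p)
  expect_equal(out_p$prob, out$prob, tolerance = 1e-5)
  # beta permutes identically
  b <- tile_weights(out$state, p$gamma)$beta
  b_p <- tile_weights(out_p$state, p$gamma)$beta
  expect_equal(b_p, b[perm], tolerance = 1e-5)

  # duplicated bag with gamma = 0 leaves the prediction unchanged
  p0 <- p; p0$gamma <- 0
  expect_equal(model_forward(rbind(x, x), p0)$prob,
               model_forward(x, p0)$prob, tolerance = 1e-9)

  # probabilities sum to 1 across many random bags
  withr::with_seed(9, {
    for (i in 1:25) {
      n <- sample(1:9, 1)
      pr <- model_forward(matrix(rnorm(n * 10), n, 10), p)$prob
      expect_equal(sum(pr), 1, tolerance = 1e-12)
      expect_true(all(pr >= 0))
    }
  })

  expect_error(model_forward(matrix(1, 2, 3), p), "dimension")
})

test_that("gamma = 0 model equals a mean-pooling MLP built from the same weights", {
  p <- mil_params(10, hidden = c(12L, 8L), d_attn = 4L, seed = 6)
  p$gamma <- 0
  withr::with_seed(7, x <- matrix(rnorm(6 * 10), 6, 10))
  out <- model_forward(x, p)
  # plain MLP + mean pooling
  h <- pmax(sweep(pmax(sweep(x %*% p$W1, 2, p$b1, "+"), 0) %*% p$W2, 2, p$b2, "+"), 0)
  y <- colMeans(h)
  logits <- drop(y %*% p$Wo) + p$bo
  pr <- exp(logits - max(logits)); pr <- pr / sum(pr)
  expect_equal(unname(out$prob), pr, tolerance = 1e-12)
})

test_that("analytic gradients match finite differences", {
  p <- mil_params(5, hidden = c(7L, 6L), d_attn = 3L, seed = 8)
  withr::with_seed(8, x <- matrix(rnorm(4 * 5), 4, 5))
  label <- 1L
  fw <- wsimil:::mil_forward_full(x, p)
  gr <- wsimil:::mil_backward(x, label, fw, p)
  loss_at <- function(p2) -log(wsimil:::mil_forward_full(x, p2)$prob[label + 1])
  eps <- 1e-6
  for (nm in names(gr)) {
    idx <- seq_len(min(3, length(p[[nm]])))
    for (i in idx) {
      p_hi <- p; p_hi[[nm]][i] <- p_hi[[nm]][i] + eps
      p_lo <- p; p_lo[[nm]][i] <- p_lo[[nm]][i] - eps
      expect_equal(gr[[nm]][i], (loss_at(p_hi) - loss_at(p_lo)) / (2 * eps),
                   tolerance = 1e-4)
    }
  }
})
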