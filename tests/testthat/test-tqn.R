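# literal step-by-step re-implementation of the normalisation recipe, used
# as an independent oracle for trimmed_quantile_normalize()
tqn_oracle <- function(v, trim) {
  n <- nrow(v)
  k <- floor(trim * n)
  ords <- lapply(seq_len(ncol(v)), function(j) order(v[, j], rownames(v)))
  sorted <- vapply(seq_len(ncol(v)), function(j) v[ords[[j]], j], numeric(n))
  mid_rows <- seq.int(k + 1L, n - k)
  ref <- rowMeans(sorted[mid_rows, , drop = FALSE])
  mu <- mean(ref)
  sigma <- sqrt(mean((ref - mu)^2))
  z <- (ref - mu) / sigma
  out <- v
  for (j in seq_len(ncol(v))) {
    col <- numeric(n)
    col[mid_rows] <- ref
    if (k > 0) {
      npos <- sum(z > 0); nneg <- sum(z < 0)
      col[seq_len(k)] <- rev(mu - abs(min(z)) / nneg * (nneg + seq_len(k)) * sigma)
      col[seq.int(n - k + 1L, n)] <- mu + abs(max(z)) / npos * (npos + seq_len(k)) * sigma
    }
    out[ords[[j]], j] <- col
  }
  out
}

random_matrix <- function(n, p, seed) {
  set.seed(seed)
  matrix(rlnorm(n * p, meanlog = 5, sdlog = 1.2), n, p,
         dimnames = list(sprintf("G%03d", seq_len(n)), paste0("c", seq_len(p))))
}

test_that("TQN matches a literal step-by-step re-implementation", {
  v <- random_matrix(50, 4, seed = 1)
  out <- trimmed_quantile_normalize(v, 0.1)
  expect_equal(out, tqn_oracle(v, 0.1), tolerance = 1e-12)
  # middle-distribution equality: middle 40 sorted values identical across columns
  sorted <- apply(out, 2, sort)
  mid <- sorted[6:45, ]
  expect_true(all(abs(mid - mid[, 1]) < 1e-9))
})

test_that("TQN preserves within-column rank order", {
  for (seed in 1:5) {
    v <- random_matrix(60, 5, seed)
    out <- trimmed_quantile_normalize(v, 0.08)
    for (j in seq_len(ncol(v)))
      expect_identical(order(out[, j], rownames(v)),
                       order(v[, j], rownames(v)))
  }
})

test_that("columns that are permutations of one another become identical multisets", {
  set.seed(3)
  base <- rlnorm(40, 4, 1)
  v <- cbind(c1 = base, c2 = sample(base), c3 = sample(base))
  rownames(v) <- sprintf("G%02d", 1:40)
  out <- trimmed_quantile_normalize(v, 0.1)
  sorted <- apply(out, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
  for (j in 1:3) expect_identical(order(out[, j]), order(v[, j]))
})

test_that("a single column is a fixed point of the middle and gets ramped tails", {
  set.seed(4)
  v <- matrix(sort(rlnorm(30, 5, 1)), 30, 1,
              dimnames = list(sprintf("G%02d", 1:30), "c1"))
  out <- trimmed_quantile_normalize(v, 0.1)
  expect_equal(out[4:27, 1], v[4:27, 1])  # middle untouched (reference = itself)
  d <- decompose_column(out[, 1], 0.1)
  expect_equal(unname(out[1:3, 1]),
               unname(rev(d$mu - abs(min(d$z_m)) / d$n_neg *
                            (d$n_neg + 1:3) * d$sigma)))
})

test_that("TQN is idempotent on the middle part", {
  v <- random_matrix(50, 3, seed = 9)
  once <- trimmed_quantile_normalize(v, 0.1)
  twice <- trimmed_quantile_normalize(once, 0.1)
  mid <- function(m) apply(m, 2, function(x) sort(x)[6:45])
  expect_equal(mid(twice), mid(once), tolerance = 1e-9)
})

test_that("the inner quantile normalisation agrees with limma on the middles", {
  skip_if_not_installed("limma")
  v <- random_matrix(80, 4, seed = 12)
  k <- floor(0.1 * 80)
  out <- trimmed_quantile_normalize(v, 0.1)
  mids <- vapply(seq_len(4), function(j) sort(v[, j])[(k + 1):(80 - k)],
                 numeric(80 - 2 * k))
  lim <- limma::normalizeQuantiles(mids)
  expect_equal(unname(sort(out[, 1])[(k + 1):(80 - k)]),
               unname(sort(lim[, 1])), tolerance = 1e-9)
})

test_that("tail revision follows the Z-ramp formula", {
  # symmetric middle: mu = 10, sigma = 2, max(Z) = 1.5, three positive Zs
  decomp <- structure(
    list(small = c(NA, NA), large = c(NA, NA, NA), mu = 10, sigma = 2,
         z_m = c(-1.5, -1, -0.5, 0, 0.5, 1, 1.5), n_pos = 3, n_neg = 3),
    class = "column_decomposition")
  expect_equal(revise_tail(decomp, "large"),
               10 + (1.5 / 3) * (3 + 1:3) * 2)
  # small side mirrors below the mean, ascending order
  expect_equal(revise_tail(decomp, "small"),
               rev(10 - (1.5 / 3) * (3 + 1:2) * 2))
  # equal one-element tails sit equidistant from the mean
  d1 <- structure(c(decomp[-(1:2)], list(small = NA, large = NA)),
                  class = "column_decomposition")
  expect_equal(revise_tail(d1, "large") - 10, 10 - revise_tail(d1, "small"))
  # empty tail when the trim rounds to zero genes
  d0 <- structure(c(decomp[-(1:2)],
                    list(small = numeric(0), large = numeric(0))),
                  class = "column_decomposition")
  expect_length(revise_tail(d0, "large"), 0L)
  # one-sided middle cannot anchor a ramp
  d2 <- decomp; d2$n_neg <- 0L
  expect_error(revise_tail(d2, "small"), "one-sided")
})

test_that("degenerate inputs are rejected with informative errors", {
  v <- random_matrix(40, 3, seed = 5)
  v[, 2] <- 7  # constant column: middle sigma = 0
  expect_error(trimmed_quantile_normalize(v, 0.1), "c2")
  expect_error(decompose_column(rnorm(10), 0.6), "0, 0.5")
  expect_error(decompose_column(rnorm(6), 0.4), "smaller than 3")
})
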