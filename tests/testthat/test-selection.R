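test_that("min-max normalization follows the linear map and its edge cases", {
  expect_equal(minmax_normalize(cbind(f = c(2, 4, 6)))[, 1], c(0, 0.5, 1))
  expect_equal(minmax_normalize(cbind(f = c(5, 5)))[, 1], c(0, 0))
  already <- cbind(f = c(0, 0.25, 1))
  expect_equal(minmax_normalize(already), already)
  # idempotence on random data
  set.seed(1)
  x <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  n1 <- minmax_normalize(x)
  expect_equal(minmax_normalize(n1), n1)
  expect_true(all(apply(n1, 2, min) == 0) && all(apply(n1, 2, max) == 1))
  expect_error(minmax_normalize(cbind(f = c(NA_real_, NA_real_))),
               "no finite values")
})

test_that("median imputation fills undefined features", {
  x <- cbind(a = c(1, NA, 3), b = c(2, 2, 2))
  out <- impute_median(x)
  expect_equal(unname(out[2, "a"]), 2)
  expect_false(anyNA(out))
  expect_error(impute_median(cbind(a = c(NA_real_, NA_real_))),
               "entirely missing")
})

test_that("ReliefF reproduces the hand-computed 1-D weight", {
  x <- cbind(f = c(0, 0.1, 0.9, 1.0))
  y <- c("A", "A", "B", "B")
  r <- relieff_rank(x, y, k = 1)
  # per-anchor (miss - hit) diffs: 0.8, 0.7, 0.7, 0.8 -> mean 0.75
  expect_equal(unname(r$scores["f"]), 0.75)
})

test_that("ReliefF matches an independent brute-force oracle on small sets", {
  set.seed(21)
  for (rep in 1:5) {
    n <- 6
    x <- matrix(runif(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
    y <- rep(c("A", "B"), each = 3)
    r <- relieff_rank(x, y, k = 1)
    expected <- brute_relieff(x, y, k = 1)
    expect_equal(unname(r$scores[c("a", "b", "c")]), expected,
                 tolerance = 1e-12)
  }
})

test_that("duplicated feature columns tie in weight and resolve by name", {
  set.seed(5)
  x <- cbind(zf = runif(8), af = 0)
  x[, "af"] <- x[, "zf"]                       # duplicate under another name
  y <- rep(c("A", "B"), 4)
  r <- relieff_rank(x, y, k = 2)
  expect_equal(unname(r$scores["af"]), unname(r$scores["zf"]))
  expect_equal(which(r$ranking == "af") + 1, which(r$ranking == "zf"))
})

test_that("a pure-noise feature's ReliefF weight sits inside its permutation null", {
  set.seed(77)
  n <- 60
  x <- cbind(signal = c(rnorm(n / 2, 0), rnorm(n / 2, 2)), noise = rnorm(n))
  y <- rep(c("A", "B"), each = n / 2)
  obs <- relieff_rank(minmax_normalize(x), y, k = 5)$scores
  null_w <- replicate(200, {
    yp <- sample(y)
    relieff_rank(minmax_normalize(x), yp, k = 5)$scores[["noise"]]
  })
  lim <- stats::quantile(null_w, c(0.025, 0.975))
  expect_gt(obs[["noise"]], lim[1])
  expect_lt(obs[["noise"]], lim[2])
  expect_gt(obs[["signal"]], lim[2])          # the real signal is far outside
})

test_that("ReliefF rejects k at or above the smallest class size", {
  x <- cbind(f = runif(5))
  expect_error(relieff_rank(x, c("A", "A", "A", "B", "B"), k = 2),
               "smaller than the smallest class")
})

test_that("GainRatio reproduces hand-computed entropies on toy tables", {
  # binary feature identical to a balanced label: Gain 1 bit / SplitInfo 1 bit
  x <- cbind(f = c(0, 0, 1, 1))
  y <- c("A", "A", "B", "B")
  expect_equal(unname(gainratio_rank(x, y)$scores["f"]), 1.0)
  # constant feature carries no information
  expect_equal(unname(gainratio_rank(cbind(f = rep(2, 4), g = c(0, 0, 1, 1)),
                                     y)$scores["f"]), 0)
  # monotone feature: the 2.5 midpoint splits classes perfectly
  x2 <- cbind(f = c(1, 2, 3, 4))
  y2 <- c("A", "A", "B", "B")
  r2 <- gainratio_rank(x2, y2)
  expect_equal(unname(r2$scores["f"]), brute_gainratio(x2[, 1], y2))
  expect_equal(unname(r2$scores["f"]), 1.0)    # perfect midpoint split exists
})

test_that("label permutation strictly lowers GainRatio on a separable set", {
  set.seed(8)
  x <- cbind(f = c(rnorm(10, 0), rnorm(10, 5)))
  y <- rep(c("A", "B"), each = 10)
  g_true <- gainratio_rank(x, y)$scores[["f"]]
  y_perm <- sample(y)
  while (all(y_perm == y)) y_perm <- sample(y)
  g_perm <- gainratio_rank(x, y_perm)$scores[["f"]]
  expect_lt(g_perm, g_true)
  expect_equal(g_true, brute_gainratio(x[, 1], y))
})

test_that("GainRatio matches the brute-force oracle on random columns", {
  set.seed(31)
  for (rep in 1:5) {
    col <- sample(round(runif(12), 2))          # with duplicated values
    y <- sample(rep(c("A", "B"), 6))
    got <- gainratio_rank(cbind(f = col), y)$scores[["f"]]
    expect_equal(got, brute_gainratio(col, y), tolerance = 1e-12)
  }
  expect_error(gainratio_rank(cbind(f = 1:4), rep("A", 4)), "two classes")
})

test_that("adding a duplicate of the most informative feature keeps its GainRatio", {
  x <- cbind(best = c(0, 0, 0, 1, 1, 1), junk = c(0, 1, 0, 1, 0, 1))
  y <- rep(c("A", "B"), each = 3)
  g1 <- gainratio_rank(x, y)$scores[["best"]]
  g2 <- gainratio_rank(cbind(x, best2 = x[, "best"]), y)$scores[["best"]]
  expect_equal(g2, g1)
  expect_gte(g2, gainratio_rank(x, y)$scores[["junk"]])
})

test_that("top-k intersection follows ReliefF order and handles saturation", {
  mk <- function(method, names, scores) {
    ord <- order(-scores, names)
    structure(list(method = method, scores = stats::setNames(scores, names)[ord],
                   ranking = names[ord]), class = "gsat_ranking")
  }
  feats <- paste0("f", sprintf("%02d", 1:36))
  s1 <- seq(36, 1); names(s1) <- feats
  r1 <- mk("ReliefF", feats, s1)
  # second ranking shares exactly two of the first's top 18
  s2 <- s1; s2[] <- seq(1, 36)
  s2[c("f03", "f07")] <- c(100, 99)
  r2 <- mk("GainRatio", feats, s2)
  expect_equal(intersect_top_k(r1, r2, k = 18), c("f03", "f07"))
  # identical rankings return the full top-18, in order
  expect_equal(intersect_top_k(r1, r1, k = 18), feats[1:18])
  # k = 36 saturates to the whole universe
  expect_setequal(intersect_top_k(r1, r2, k = 36), feats)
  # empty intersection errors with a remediation hint
  s3 <- rev(s1); names(s3) <- feats
  r3 <- mk("GainRatio", feats, s3)
  expect_error(intersect_top_k(r1, r3, k = 18), "raise k")
})
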