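test_that("softMin matches the log-sum-exp formula and its limits", {
  expect_equal(softMin(c(2, 5, 7), 0), 2)
  expect_equal(softMin(c(4, 4, 4), 1), 4 - log(3))
  expect_error(softMin(numeric(0), 1), "empty")
  set.seed(2)
  for (gamma in c(0.1, 1, 10)) {
    for (rep in 1:20) {
      a <- rnorm(3, sd = 5)
      expect_equal(softMin(a, gamma), -gamma * log(sum(exp(-a / gamma))),
                   tolerance = 1e-12)
      expect_lte(softMin(a, gamma), min(a) + 1e-12)
    }
  }
})

test_that("Soft-DTW forward equals the enumerated alignment-set soft minimum", {
  set.seed(13)
  for (rep in 1:30) {
    p <- sample(c(1, 2), 1)
    n <- sample(1:4, 1); m <- sample(1:4, 1)
    x <- randomSeries(p, n); y <- randomSeries(p, m)
    delta <- pairwiseCost(x, y)
    for (gamma in c(0.5, 1)) {
      expect_equal(softDTW(x, y, gamma)$value, bruteSoftDTW(delta, gamma),
                   tolerance = 1e-10)
    }
    # gamma = 0 reduces exactly to classic DTW on the same costs
    expect_identical(softDTW(x, y, 0)$value, dtwDistance(x, y))
  }
  # single alignment matrix: value is delta itself for any gamma
  expect_equal(softDTW(2, 5, gamma = 3)$value, 9)
})

test_that("Soft-DTW is monotone non-increasing in gamma and below hard DTW", {
  set.seed(17)
  for (rep in 1:10) {
    x <- randomSeries(1, 5); y <- randomSeries(1, 6)
    vals <- vapply(c(0, 0.1, 0.5, 1, 5), function(g) softDTW(x, y, g)$value, 0)
    expect_true(all(diff(vals) <= 1e-12))
  }
})

test_that("the backward E-matrix is a valid derivative table", {
  set.seed(19)
  x <- randomSeries(2, 4); y <- randomSeries(2, 5)
  g <- softDTWGrad(x, y, gamma = 1)
  expect_equal(g$e[4, 5], 1)
  expect_true(all(g$e >= 0 & g$e <= 1 + 1e-12))
  expect_error(softDTWGrad(x, y, gamma = 0), "gamma > 0")
  # reusing a precomputed forward table gives identical results
  fw <- softDTW(x, y, gamma = 1)
  g2 <- softDTWGrad(x, y, gamma = 1, forward = fw)
  expect_equal(g2$grad, g$grad, tolerance = 1e-12)
})

test_that("gradients agree with central finite differences", {
  set.seed(23)
  h <- 1e-5
  maxRel <- 0
  for (rep in 1:12) {
    x <- randomSeries(3, 4); y <- randomSeries(3, 5)
    g <- softDTWGrad(x, y, gamma = 1)
    for (i in seq_along(x)) {
      xp <- x; xp[i] <- xp[i] + h
      xm <- x; xm[i] <- xm[i] - h
      num <- (softDTW(xp, y, 1)$value - softDTW(xm, y, 1)$value) / (2 * h)
      maxRel <- max(maxRel, abs(num - g$grad[i]) / max(abs(num), 1e-8))
    }
  }
  expect_lt(maxRel, 1e-4)
})

test_that("as gamma shrinks the E-matrix concentrates on the optimal path", {
  set.seed(29)
  x <- c(0, 1, 3, 6); y <- c(0, 1.1, 2.9, 6.2, 6.1)
  pth <- dtwPath(x, y)
  e <- softDTWGrad(x, y, gamma = 0.01)$e
  onPath <- e[cbind(pth$i, pth$j)]
  expect_true(all(onPath > 0.99))
  off <- e; off[cbind(pth$i, pth$j)] <- 0
  expect_true(all(off < 0.01))
})

test_that("forward and backward stay finite for tiny gamma and large costs", {
  x <- c(0, 1000, 0); y <- c(1000, 0, 1000)
  for (gamma in c(1e-3, 1)) {
    f <- softDTW(x, y, gamma)
    expect_true(is.finite(f$value))
    g <- softDTWGrad(x, y, gamma)
    expect_true(all(is.finite(g$grad)))
    expect_true(all(is.finite(g$e)))
  }
})
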